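#' @include potentials.R
NULL

## run expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.normalize <- function(v) v / sqrt(sum(v^2))

#' Build a single crescent rod
#'
#' Constructs a rod fragment in a canonical frame: the 10 backbone particles
#' lie on a circular arc of curvature \code{cRod} (straight when 0) with
#' consecutive particles at the bond rest length, orientations normal to the
#' arc (radially outward, i.e. the membrane-normal side), and, for hooked
#' variants, two hook particles at bond-length distance from their two
#' anchor backbone particles (between the 1st/2nd and 9th/10th particles),
#' displaced off the backbone axis.  Chiral rods place the two hooks on
#' opposite lateral sides (a right-handed arrangement); achiral hooked rods
#' place both on the same side.
#'
#' @param spec a \code{RodSpec}.
#' @return A \code{ParticleState} fragment (rodId 0) centred near the origin.
#' @examples
#' rod <- buildRod(rodSpec(cRod = 0.3, chirality = "chiral"))
#' detectHandedness(rod)
#' @export
buildRod <- function(spec) {
  nb <- spec@nBackbone
  l0 <- rodBondLength(spec)
  C <- spec@cRod
  if (abs(C) < 1e-12) {
    xs <- (seq_len(nb) - (nb + 1) / 2) * l0
    pos <- cbind(xs, 0, 0)
    orient <- matrix(rep(c(0, 0, 1), each = nb), nb, 3)
  } else {
    R <- 1 / abs(C)
    delta <- 2 * asin(min(1, l0 / (2 * R)))
    th <- (seq_len(nb) - (nb + 1) / 2) * delta
    ## centre of curvature on the -u side; u radially outward
    pos <- cbind(R * sin(th), 0, R * cos(th) - R)
    orient <- cbind(sin(th), 0, cos(th))
    if (C < 0) { pos[, 3] <- -pos[, 3]; orient[, 3] <- -orient[, 3] }
  }
  kind <- rep("rod_backbone", nb)
  rodId <- rep(0L, nb)
  seg <- 0:(nb - 1)
  side <- rep(0, nb)
  if (spec@chirality != "achiral_plain") {
    sides <- if (spec@chirality == "chiral") c(1, -1) else c(1, 1)
    anchors <- list(c(1L, 2L), c(nb - 1L, nb))
    for (h in 1:2) {
      a <- anchors[[h]]
      m <- colMeans(pos[a, , drop = FALSE])
      tl <- .normalize(pos[a[2], ] - pos[a[1], ])
      ub <- .normalize(orient[a[1], ] + orient[a[2], ])
      bb <- c(tl[2] * ub[3] - tl[3] * ub[2],
              tl[3] * ub[1] - tl[1] * ub[3],
              tl[1] * ub[2] - tl[2] * ub[1])
      hp <- m + sides[h] * spec@hookLateral * bb + spec@hookNormal * ub
      pos <- rbind(pos, hp)
      orient <- rbind(orient, ub)
      kind <- c(kind, "rod_hook")
      rodId <- c(rodId, 0L)
      seg <- c(seg, -1L)
      side <- c(side, sides[h])
    }
  }
  particleState(pos, orient, kind = kind, rodId = as.integer(rodId),
                segmentIndex = as.integer(seg), hookSide = side)
}

#' Detect the handedness of a rod fragment
#'
#' Signed handedness from the scalar triple product of (backbone tangent
#' taken outward from the rod centre at each hook's end, curvature vector,
#' hook offset), summed over the two hooks: a positive sum is a right-handed
#' rod, negative left-handed, and a (near-)zero sum an achiral hook
#' arrangement.  Rods without hooks are achiral by construction.
#'
#' @param fragment a \code{ParticleState} holding exactly one rod.
#' @return One of \code{"right"}, \code{"left"}, \code{"achiral"}.
#' @export
detectHandedness <- function(fragment) {
  bb <- which(fragment@kind == "rod_backbone")
  bb <- bb[order(fragment@segmentIndex[bb])]
  nb <- length(bb)
  hooks <- sort(which(fragment@kind == "rod_hook"))
  if (length(hooks) == 0) return("achiral")
  p <- fragment@pos
  ## curvature vector: chord midpoint minus arc midpoint
  cv <- (p[bb[1], ] + p[bb[nb], ]) / 2 -
    (p[bb[floor(nb / 2)], ] + p[bb[ceiling(nb / 2) + 1], ]) / 2
  if (sqrt(sum(cv^2)) < 1e-6)
    stop("degenerate geometry: backbone is collinear, handedness undefined")
  cv <- .normalize(cv)
  anchors <- list(c(bb[1], bb[2]), c(bb[nb - 1], bb[nb]))
  touts <- list(.normalize(p[bb[1], ] - p[bb[2], ]),
                .normalize(p[bb[nb], ] - p[bb[nb - 1], ]))
  tot <- 0
  for (h in seq_along(hooks)) {
    a <- anchors[[min(h, 2)]]
    d <- p[hooks[h], ] - colMeans(p[a, , drop = FALSE])
    tot <- tot + det(rbind(touts[[min(h, 2)]], cv, d))
  }
  if (abs(tot) < 1e-6) "achiral" else if (tot > 0) "right" else "left"
}

#' Mirror a configuration
#'
#' Reflects positions, orientations and velocities through the plane
#' perpendicular to \code{axis}, and flips the hook-side labels so the hooks
#' are rebuilt with the opposite handedness (the mirror image of a chiral
#' system).  The energy of a configuration and of its mirror image are
#' identical; for achiral rods the mirror image is superimposable on the
#' original.
#'
#' @param state a \code{ParticleState}.
#' @param axis 1, 2 or 3: the coordinate flipped.
#' @return The mirrored \code{ParticleState}.
#' @export
mirrorParticleState <- function(state, axis = 2L) {
  s <- state
  s@pos[, axis] <- -s@pos[, axis]
  s@orient[, axis] <- -s@orient[, axis]
  s@vel[, axis] <- -s@vel[, axis]
  s@avel[, axis] <- -s@avel[, axis]   # pseudo-vector handled with labels
  s@hookSide <- -s@hookSide
  s
}

#' Fraction of particles in rod backbones
#'
#' The rod density phi_rod counts backbone particles against all
#' density-counted (non-hook) particles: 10 n_rods / N.
#'
#' @param state a \code{ParticleState}.
#' @return Numeric fraction.
#' @examples
#' ## 40 rods in N = 4800 -> 400/4800 = 0.0833
#' @export
rodAreaFraction <- function(state) {
  n <- sum(state@kind != "rod_hook")
  sum(state@kind == "rod_backbone") / n
}

#' Dimensionless rod curvature from protein geometry
#'
#' Converts a crescent protein's curvature radius and length to the model's
#' dimensionless spontaneous curvature \eqn{C_{rod} r_{rod} = L / R}.  For
#' the BAR-family protein APPL1 (curvature radius 5.5 nm, length 17 nm) this
#' gives 3.09, i.e. about 3.
#'
#' @param radius curvature radius of the protein (any length unit).
#' @param length protein length (same unit).
#' @return The dimensionless product C_rod * r_rod.
#' @examples
#' rodCurvatureFromGeometry(5.5, 17)   # APPL1 -> 3.09
#' @export
rodCurvatureFromGeometry <- function(radius, length) {
  length / radius
}

#' Embed rods in a membrane
#'
#' Inserts \code{nRods} rods at random positions and in-plane orientations,
#' each rod replacing its 10 nearest free membrane particles (conserving the
#' density-counted particle number N); hook particles are added on top and
#' excluded from the density bookkeeping.  Insertion enforces a hard-core
#' threshold of 0.8 sigma against all retained particles and retries a
#' bounded number of times before failing.
#'
#' @param membrane a \code{ParticleState} of free membrane particles (may
#'   already contain rods; new rod ids continue from the maximum).
#' @param box a \code{SimulationBox}.
#' @param nRods number of rods to insert.
#' @param spec a \code{RodSpec}.
#' @param seed integer seed (placements are deterministic given the seed).
#' @param maxTry insertion attempts per rod.
#' @return The combined \code{ParticleState}.
#' @export
embedRods <- function(membrane, box, nRods, spec, seed = 1L, maxTry = 400L) {
  if (nRods == 0) return(membrane)
  .withSeed(seed, .embedRodsImpl(membrane, box, nRods, spec, maxTry))
}

.embedRodsImpl <- function(state, box, nRods, spec, maxTry) {
  nb <- spec@nBackbone
  l0 <- rodBondLength(spec)
  topo <- topologyType(box)
  L <- boxLengths(box)
  nextRod <- max(c(-1L, state@rodId)) + 1L
  for (r in seq_len(nRods)) {
    placed <- FALSE
    for (try in seq_len(maxTry)) {
      free <- which(state@kind == "membrane")
      if (length(free) < nb) stop("not enough free membrane particles")
      if (topo == "flat") {
        x0 <- stats::runif(1, 0, L[1]); y0 <- stats::runif(1, 0, L[2])
        phi <- stats::runif(1, 0, 2 * pi)
        ks <- seq_len(nb) - (nb + 1) / 2
        bpos <- cbind(x0 + ks * l0 * cos(phi), y0 + ks * l0 * sin(phi), 0)
        bor <- matrix(rep(c(0, 0, 1), each = nb), nb, 3)
      } else {
        r2d <- sqrt(state@pos[free, 1]^2 + state@pos[free, 2]^2)
        R <- mean(r2d)
        z0 <- stats::runif(1, 0, L[3])
        th0 <- stats::runif(1, 0, 2 * pi)
        psi <- stats::runif(1, 0, 2 * pi)
        ks <- seq_len(nb) - (nb + 1) / 2
        th <- th0 + ks * l0 * sin(psi) / R
        zz <- z0 + ks * l0 * cos(psi)   # continuous; wrapped after hooks
        bpos <- cbind(R * cos(th), R * sin(th), zz)
        bor <- cbind(cos(th), sin(th), 0)
      }
      ## claim the nearest free membrane particle for each bead: the rod is
      ## built from existing membrane particles (relabelled in place), so the
      ## density-counted N is conserved and no overlaps are created
      dm <- .pairDistances(bpos, state@pos[free, , drop = FALSE], box)
      claimed <- integer(0)
      ok <- TRUE
      for (k in seq_len(nb)) {
        ord <- order(dm[k, ])
        pick <- ord[!ord %in% claimed][1]
        if (is.na(pick) || dm[k, pick] > 2 * l0) { ok <- FALSE; break }
        claimed <- c(claimed, pick)
      }
      if (!ok) next
      ## snap the backbone onto the claimed particles (unwrapped along the
      ## ideal path so the hook frames are built from coherent coordinates)
      cpos <- state@pos[free[claimed], , drop = FALSE]
      for (d in which(periodicDims(box)))
        cpos[, d] <- bpos[, d] +
          (cpos[, d] - bpos[, d]) -
          L[d] * round((cpos[, d] - bpos[, d]) / L[d])
      dl <- sqrt(rowSums((cpos[-1, , drop = FALSE] -
                          cpos[-nb, , drop = FALSE])^2))
      if (any(dl > 1.75 * l0) || any(dl < 0.85 * l0)) next
      ## the end bonds are 3x stiffer (hook triangles): keep their initial
      ## strain small so the insertion does not detonate
      if (max(dl[c(1L, nb - 1L)]) > 1.3 * l0) next
      bpos <- cpos
      ## assemble the fragment (hooks from the local frames), then wrap the
      ## periodic coordinates
      frag <- .rodFragmentAt(bpos, bor, spec)
      for (d in which(periodicDims(box)))
        frag$pos[, d] <- frag$pos[, d] %% L[d]
      keep <- setdiff(seq_len(nrow(state@pos)), free[claimed])
      if (nrow(frag$pos) > nb) {
        hooks <- frag$pos[-seq_len(nb), , drop = FALSE]
        ## hook clearance against the own backbone (beyond the two bonded
        ## anchors); crowding free membrane particles are nudged away from
        ## the hook instead (N is conserved, the displacement is < 0.2 sigma)
        dself <- .pairDistances(hooks, frag$pos[seq_len(nb), , drop = FALSE],
                                box)
        dself[1, 1:2] <- Inf; dself[2, (nb - 1):nb] <- Inf
        if (min(dself) < 0.85) next
        posBackup <- state@pos
        nudged <- integer(0)
        for (hh in seq_len(nrow(hooks))) {
          dh <- .pairDistances(hooks[hh, , drop = FALSE],
                               state@pos[keep, , drop = FALSE], box)
          for (ci in which(dh[1, ] < 0.97)) {
            j <- keep[ci]
            if (state@kind[j] != "membrane") next
            dv <- minimumImage(state@pos[j, ] - hooks[hh, ], box)
            d0 <- max(sqrt(sum(dv^2)), 0.2)
            state@pos[j, ] <- state@pos[j, ] + dv / d0 * (1.0 - d0)
            nudged <- c(nudged, j)
          }
        }
        ## the nudges themselves must not create new contacts, and nothing
        ## may remain close to the hooks (e.g. another rod's particles)
        ok2 <- TRUE
        for (j in unique(nudged)) {
          dj <- .pairDistances(state@pos[j, , drop = FALSE],
                               rbind(state@pos[setdiff(keep, j), , drop = FALSE],
                                     frag$pos), box)
          if (min(dj) < 0.88) { ok2 <- FALSE; break }
        }
        dmin <- min(.pairDistances(hooks, state@pos[keep, , drop = FALSE], box))
        if (!ok2 || dmin < 0.9) { state@pos <- posBackup; next }
      }
      ## self-check of hook placement against own backbone handled by build
      state <- particleState(
        rbind(state@pos[keep, , drop = FALSE], frag$pos),
        rbind(state@orient[keep, , drop = FALSE], frag$orient),
        kind = c(state@kind[keep], frag$kind),
        rodId = c(state@rodId[keep], rep(nextRod, length(frag$kind))),
        segmentIndex = c(state@segmentIndex[keep], frag$seg),
        hookSide = c(state@hookSide[keep], frag$side),
        vel = rbind(state@vel[keep, , drop = FALSE],
                    matrix(0, length(frag$kind), 3)),
        avel = rbind(state@avel[keep, , drop = FALSE],
                     matrix(0, length(frag$kind), 3)))
      nextRod <- nextRod + 1L
      placed <- TRUE
      break
    }
    if (!placed)
      stop("rod insertion failed after ", maxTry, " attempts (rod ", r, ")")
  }
  state
}

## hook construction shared by buildRod-style placement on arbitrary bead
## positions/orientations
.rodFragmentAt <- function(bpos, bor, spec) {
  nb <- nrow(bpos)
  kind <- rep("rod_backbone", nb)
  seg <- 0:(nb - 1)
  side <- rep(0, nb)
  if (spec@chirality != "achiral_plain") {
    sides <- if (spec@chirality == "chiral") c(1, -1) else c(1, 1)
    anchors <- list(c(1L, 2L), c(nb - 1L, nb))
    for (h in 1:2) {
      a <- anchors[[h]]
      m <- colMeans(bpos[a, , drop = FALSE])
      tl <- .normalize(bpos[a[2], ] - bpos[a[1], ])
      ub <- .normalize(bor[a[1], ] + bor[a[2], ])
      bb <- c(tl[2] * ub[3] - tl[3] * ub[2],
              tl[3] * ub[1] - tl[1] * ub[3],
              tl[1] * ub[2] - tl[2] * ub[1])
      hp <- m + sides[h] * spec@hookLateral * bb + spec@hookNormal * ub
      bpos <- rbind(bpos, hp)
      bor <- rbind(bor, ub)
      kind <- c(kind, "rod_hook")
      seg <- c(seg, -1L)
      side <- c(side, sides[h])
    }
  }
  list(pos = bpos, orient = bor, kind = kind, seg = as.integer(seg),
       side = side)
}
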