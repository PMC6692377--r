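#' @include observables.R
NULL

## deterministically replace the free membrane particles nearest to the
## intended bead positions by a rod fragment
.placeRod <- function(state, box, bpos, bor, spec, minDist = 0.8) {
  ## bead positions must be continuous (not yet wrapped) so the hook frames
  ## are built correctly; wrap the finished fragment instead
  nb <- nrow(bpos)
  frag <- .rodFragmentAt(bpos, bor, spec)
  for (d in which(periodicDims(box)))
    frag$pos[, d] <- frag$pos[, d] %% boxLengths(box)[d]
  free <- which(state@kind == "membrane")
  dm <- .pairDistances(bpos, state@pos[free, , drop = FALSE], box)
  claimed <- integer(0)
  for (k in seq_len(nb)) {
    ord <- order(dm[k, ])
    pick <- ord[!ord %in% claimed][1]
    if (is.na(pick)) return(NULL)
    claimed <- c(claimed, pick)
  }
  ## additionally clear membrane particles crowding the new fragment
  dmf <- .pairDistances(frag$pos, state@pos[free, , drop = FALSE], box)
  crowd <- unique(which(apply(dmf, 2, min) < minDist))
  claimed <- union(claimed, crowd)
  keep <- setdiff(seq_len(nrow(state@pos)), free[claimed])
  if (min(.pairDistances(frag$pos, state@pos[keep, , drop = FALSE], box)) <
      0.95 * minDist)
    return(NULL)   # collides with an existing rod; skip this placement
  nextRod <- max(c(-1L, state@rodId)) + 1L
  particleState(
    rbind(state@pos[keep, , drop = FALSE], frag$pos),
    rbind(state@orient[keep, , drop = FALSE], frag$orient),
    kind = c(state@kind[keep], frag$kind),
    rodId = c(state@rodId[keep], rep(nextRod, length(frag$kind))),
    segmentIndex = c(state@segmentIndex[keep], frag$seg),
    hookSide = c(state@hookSide[keep], frag$side))
}

## elliptical tube lattice with two axial rod lanes at the major-axis edges
.ellipticalFixture <- function(N = 600L, aspect = 1.9, rodsPerLane = 3L,
                               spec = rodSpec(cRod = 0.25,
                                              chirality = "achiral_plain")) {
  a0 <- .A0_REF
  l <- sqrt(2 * a0 / sqrt(3))
  R0 <- sqrt(N * a0 / (2 * pi) / (0.0015 * N * 10) * 10) # placeholder scale
  ## choose geometry: perimeter P and length Lz with P*Lz = N a0
  Lz <- 0.0015 * N * 10
  P <- N * a0 / Lz
  ## ellipse with given aspect and perimeter P (Ramanujan approximation)
  ab <- P / pi / (3 * (1 + 1 / aspect) -
                  sqrt((3 + 1 / aspect) * (1 + 3 / aspect))) * 2
  a <- ab; b <- ab / aspect
  ## tabulate arc length
  tt <- seq(0, 2 * pi, length.out = 4000)
  dx <- -a * sin(tt); dy <- b * cos(tt)
  ds <- sqrt(dx^2 + dy^2)
  s <- cumsum(ds) * (tt[2] - tt[1]); s <- s - s[1]
  Ptrue <- s[length(s)]
  nz <- max(3L, round(Lz / (l * sqrt(3) / 2)))
  m <- max(8L, round(N / nz))
  pos <- NULL; orient <- NULL
  for (iz in seq_len(nz)) {
    starget <- (seq_len(m) - 1 + 0.5 * (iz %% 2)) / m * Ptrue
    ti <- stats::approx(s, tt, xout = starget %% Ptrue, rule = 2)$y
    x <- a * cos(ti); y <- b * sin(ti)
    nrm <- cbind(b * cos(ti), a * sin(ti))
    nrm <- nrm / sqrt(rowSums(nrm^2))
    z <- (iz - 0.5) * Lz / nz
    pos <- rbind(pos, cbind(x, y, z))
    orient <- rbind(orient, cbind(nrm, 0))
  }
  state <- particleState(pos, orient)
  box <- simulationBox(c(6 * a + 20, 6 * a + 20, Lz), "tube")
  l0 <- rodBondLength(spec)
  for (side in c(1, -1)) {
    for (rr in seq_len(rodsPerLane)) {
      z0 <- (rr - 0.5) * Lz / rodsPerLane
      zz <- z0 + (seq_len(spec@nBackbone) - (spec@nBackbone + 1) / 2) * l0
      bpos <- cbind(side * a, 0, zz)
      bor <- matrix(rep(c(side, 0, 0), each = spec@nBackbone),
                    spec@nBackbone, 3)
      st <- .placeRod(state, box, bpos, bor, spec)
      if (!is.null(st)) state <- st
    }
  }
  list(state = state, box = box, rodSpec = spec)
}

## membrane tube wrapped by a connected helix of rods
.helicalFixture <- function(N = 600L, turns = 1.4, coverage = 0.75,
                            lZ = NULL,
                            spec = rodSpec(cRod = 0.3, chirality = "chiral")) {
  if (is.null(lZ)) lZ <- tubeGeometry(N, "wide")$lZ
  sp <- tubeSpec(N, lZ = lZ)
  tb <- buildTube(sp, seed = 1L)
  state <- tb$state; box <- tb$box
  R <- sp@rCyl
  Lz <- lZ
  l0 <- rodBondLength(spec)
  ## helix: theta advances 2 pi turns while z advances coverage * Lz
  totLen <- sqrt((2 * pi * turns * R)^2 + (coverage * Lz)^2)
  nRods <- floor(totLen / (spec@nBackbone * l0 * 1.08))
  nbeads <- spec@nBackbone
  sgl <- 0
  for (k in seq_len(nRods)) {
    ii <- sgl + seq_len(nbeads) * 1.08 - 0.54
    frac <- ii * l0 / totLen
    th <- 2 * pi * turns * frac
    zz <- 0.2 * Lz + coverage * Lz * frac
    bpos <- cbind(R * cos(th), R * sin(th), zz)
    bor <- cbind(cos(th), sin(th), 0)
    st <- .placeRod(state, box, bpos, bor, spec)
    if (!is.null(st)) state <- st
    sgl <- sgl + nbeads * 1.08
  }
  list(state = state, box = box, rodSpec = spec)
}

#' Deterministic test fixtures
#'
#' Small constructed configurations used throughout the test-surface:
#' \describe{
#'   \item{flat_patch_100}{100-particle flat hexagonal patch.}
#'   \item{flat_patch_400}{400-particle flat patch.}
#'   \item{tube_400 / tube_1200}{membrane tubes (wide-family geometry).}
#'   \item{single_rod_chiral / single_rod_achiral / single_rod_plain}{one
#'     rod fragment in a large open box (curvature 0.3/sigma).}
#'   \item{elliptical}{elliptical tube with rods in two axial lanes at the
#'     high-curvature edges.}
#'   \item{helical_wrap}{cylindrical tube wrapped by a connected helix of
#'     rods.}
#' }
#' All fixtures are deterministic given \code{seed}.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param ... overrides passed to the individual builders (e.g. \code{N},
#'   \code{spec}, \code{turns}).
#' @return List with \code{state}, \code{box} and, where applicable,
#'   \code{rodSpec}.
#' @examples
#' makeFixture("flat_patch_100", seed = 1)$state
#' @export
makeFixture <- function(name, seed = 1L, ...) {
  args <- list(...)
  .withSeed(seed, switch(
    name,
    flat_patch_100 = {
      hp <- .hexPatch(100L)
      list(state = hp$state, box = hp$box)
    },
    flat_patch_400 = {
      hp <- .hexPatch(400L)
      list(state = hp$state, box = hp$box)
    },
    tube_400 = {
      g <- tubeGeometry(400L, "wide")
      buildTube(tubeSpec(400L, lZ = g$lZ), seed = seed)
    },
    tube_1200 = {
      g <- tubeGeometry(1200L, "wide")
      buildTube(tubeSpec(1200L, lZ = g$lZ), seed = seed)
    },
    single_rod_chiral = {
      spec <- if (is.null(args$spec)) rodSpec(cRod = 0.3, chirality = "chiral")
              else args$spec
      list(state = buildRod(spec),
           box = simulationBox(c(100, 100, 100), "flat"), rodSpec = spec)
    },
    single_rod_achiral = {
      spec <- if (is.null(args$spec)) rodSpec(cRod = 0.3,
                                              chirality = "achiral_hooked")
              else args$spec
      list(state = buildRod(spec),
           box = simulationBox(c(100, 100, 100), "flat"), rodSpec = spec)
    },
    single_rod_plain = {
      spec <- if (is.null(args$spec)) rodSpec(cRod = 0.3,
                                              chirality = "achiral_plain")
              else args$spec
      list(state = buildRod(spec),
           box = simulationBox(c(100, 100, 100), "flat"), rodSpec = spec)
    },
    elliptical = do.call(.ellipticalFixture, args),
    helical_wrap = do.call(.helicalFixture, args),
    stop("unknown fixture name: ", name)))
}
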