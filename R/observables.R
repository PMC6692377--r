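#' @include system-setup.R
NULL

## recentre xy on the centre of mass and return polar coordinates
.tubePolar <- function(pos) {
  x <- pos[, 1] - mean(pos[, 1])
  y <- pos[, 2] - mean(pos[, 2])
  list(r2d = sqrt(x^2 + y^2), theta = atan2(x, y), x = x, y = y)
}

#' Fourier shape and rod-density modes of a membrane tube
#'
#' Lowest Fourier modes along the tube axis and the azimuthal direction:
#' \deqn{r_{qz} = (1/N) \sum_i r_{2D,i} \exp(-2\pi i z_i / L_z), \quad
#'       r_{q\theta} = (1/N) \sum_i r_{2D,i} \exp(-2 i \theta_i)}
#' with \eqn{r_{2D,i}} the distance from the tube axis (recentred on the
#' frame's centre of mass) and \eqn{\theta_i} the azimuth (two-argument
#' arctangent of (x, y)).  Shape modes run over all non-hook particles; the
#' rod-density modes \eqn{n_{qz}, n_{q\theta}} use the same sums restricted
#' to rod backbone particles (normalised by their own count).  An elliptic
#' deformation shows up in \eqn{|r_{q\theta}|}, axial segregation in
#' \eqn{|r_{qz}|}.
#'
#' @param state a \code{ParticleState}.
#' @param box a \code{SimulationBox} with tube topology.
#' @param reference optional named numeric of reference amplitudes (moduli
#'   from a zero-curvature run) stored alongside for normalisation.
#' @return A \code{\link{ModeAmplitudes-class}} object.
#' @examples
#' fx <- makeFixture("tube_400", seed = 1)
#' fourierModes(fx$state, fx$box)
#' @export
fourierModes <- function(state, box, reference = numeric(0)) {
  if (topologyType(box) != "tube")
    stop("Fourier tube modes are undefined for flat topology")
  Lz <- boxLengths(box)[3]
  sel <- state@kind != "rod_hook"
  p <- .tubePolar(state@pos[sel, , drop = FALSE])
  z <- state@pos[sel, 3]
  phz <- exp(-2i * pi * z / Lz)
  phth <- exp(-2i * p$theta)
  rqz <- mean(p$r2d * phz)
  rqth <- mean(p$r2d * phth)
  bb <- state@kind[sel] == "rod_backbone"
  if (any(bb)) {
    nqz <- mean((p$r2d * phz)[bb])
    nqth <- mean((p$r2d * phth)[bb])
  } else {
    nqz <- complex(real = 0); nqth <- complex(real = 0)
  }
  new("ModeAmplitudes", rQz = rqz, rQtheta = rqth, nQz = nqz, nQtheta = nqth,
      reference = reference)
}

#' Radius of the helical rod assembly
#'
#' Restricts to rod backbone particles in the axial slice of width
#' \code{0.4 r_rod} centred at the assembly's axial midpoint (circular mean
#' of the rod z coordinates on the periodic axis) and returns the mean
#' projected radial distance from the slice's projected centre of mass:
#' \eqn{R_{hel} = (1/N_{sl}) \sum_i |r_{2D,i} - r_{2D,g}|}.
#'
#' @param state a \code{ParticleState} with rods on a tube.
#' @param box a \code{SimulationBox} (tube topology).
#' @param sliceWidth axial slice width in sigma (default 4 = 0.4 r_rod).
#' @return A \code{\link{HelixFit-class}} object.
#' @export
helixRadius <- function(state, box, sliceWidth = 4) {
  bb <- which(state@kind == "rod_backbone")
  if (length(bb) == 0) stop("no rod backbone particles present")
  Lz <- boxLengths(box)[3]
  z <- state@pos[bb, 3]
  ang <- 2 * pi * z / Lz
  zc <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1 * Lz
  dz <- z - zc
  dz <- dz - Lz * floor(dz / Lz + 0.5)
  inSlice <- abs(dz) <= sliceWidth / 2
  if (sum(inSlice) < 3)
    stop("fewer than 3 rod particles in the central slice")
  sel <- bb[inSlice]
  xy <- state@pos[sel, 1:2, drop = FALSE]
  g <- colMeans(xy)
  rr <- sqrt((xy[, 1] - g[1])^2 + (xy[, 2] - g[2])^2)
  new("HelixFit", rHel = mean(rr),
      sliceBounds = c(zc - sliceWidth / 2, zc + sliceWidth / 2),
      nSl = as.integer(sum(inSlice)), residual = stats::sd(rr))
}

## single-linkage rod clusters via union-find on backbone contacts
.rodClusters <- function(state, box, cutoff) {
  bb <- which(state@kind == "rod_backbone")
  rids <- sort(unique(state@rodId[bb]))
  nr <- length(rids)
  if (nr == 0) return(list(sizes = integer(0), membership = integer(0)))
  parent <- seq_len(nr)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  dm <- .pairDistances(state@pos[bb, , drop = FALSE],
                       state@pos[bb, , drop = FALSE], box)
  ri <- match(state@rodId[bb], rids)
  hit <- which(dm < cutoff, arr.ind = TRUE)
  hit <- hit[ri[hit[, 1]] < ri[hit[, 2]], , drop = FALSE]
  for (k in seq_len(nrow(hit))) {
    a <- findp(ri[hit[k, 1]]); b <- findp(ri[hit[k, 2]])
    if (a != b) parent[a] <- b
  }
  memb <- vapply(seq_len(nr), findp, integer(1))
  sizes <- as.integer(table(memb))
  list(sizes = sizes, membership = match(memb, unique(memb)), rids = rids)
}

#' Mean rod cluster size
#'
#' Two rods are connected when any pair of their backbone particles is
#' closer than \code{cutoff}; clusters are the single-linkage connected
#' components.  Both weightings of the mean are returned: per cluster
#' (\eqn{\sum N_c / n_{clusters}}) and per rod
#' (\eqn{\sum N_c^2 / \sum N_c}, the size of the cluster a randomly chosen
#' rod sits in, which is the default reported value).
#'
#' @param state a \code{ParticleState} with rods.
#' @param box a \code{SimulationBox}.
#' @param cutoff contact cutoff in sigma (default 1.25, just outside the
#'   hard core and inside the first neighbour shell).
#' @return List with \code{perRod}, \code{perCluster} and the cluster
#'   \code{sizes}.
#' @export
meanClusterSize <- function(state, box, cutoff = 1.25) {
  cl <- .rodClusters(state, box, cutoff)
  if (length(cl$sizes) == 0)
    return(list(perRod = NA_real_, perCluster = NA_real_, sizes = integer(0)))
  list(perRod = sum(cl$sizes^2) / sum(cl$sizes),
       perCluster = mean(cl$sizes), sizes = cl$sizes)
}

#' Vertical membrane span
#'
#' Root-mean-square z excursion of the membrane particles about their mean
#' plane, the paper-style tubulation progress variable
#' \eqn{\langle z_{mb}^2\rangle^{1/2}}.
#'
#' @param state a \code{ParticleState}.
#' @return Numeric scalar (sigma).
#' @export
membraneZSpan <- function(state) {
  z <- state@pos[state@kind == "membrane", 3]
  sqrt(mean((z - mean(z))^2))
}

#' Winding of the rod assembly around the tube axis
#'
#' Total winding (in turns) of the largest rod cluster: its backbone
#' particles are ordered along z and the minimum-image azimuthal increments
#' accumulated.  A helical wrap winds by about one turn or more; elliptical
#' edge lanes and axial stripes wind by much less.
#'
#' @inheritParams meanClusterSize
#' @param contactCutoff connectivity cutoff used to pick the largest
#'   cluster (sigma).
#' @return List with \code{turns}, the largest-cluster \code{fraction} of
#'   all rods, and the particle count used.
#' @export
rodWinding <- function(state, box, contactCutoff = 1.6) {
  cl <- .rodClusters(state, box, contactCutoff)
  if (length(cl$sizes) == 0) return(list(turns = 0, fraction = 0, n = 0L))
  big <- which.max(tabulate(cl$membership))
  nRods <- length(cl$membership)
  rodsIn <- cl$rids[cl$membership == big]
  bb <- which(state@kind == "rod_backbone" & state@rodId %in% rodsIn)
  p <- .tubePolar(state@pos[bb, , drop = FALSE])
  ord <- order(state@pos[bb, 3])
  th <- p$theta[ord]
  dth <- diff(th)
  dth <- dth - 2 * pi * floor(dth / (2 * pi) + 0.5)
  list(turns = abs(sum(dth)) / (2 * pi),
       fraction = length(rodsIn) / nRods, n = length(bb))
}

#' Classify the tube shape
#'
#' Assigns one of the assembly phases to a (series of) tube frame(s):
#' \code{"cylindrical"} (axisymmetric, no organised rod assembly),
#' \code{"elliptical"} (large normalised azimuthal shape mode, rods in edge
#' lanes), or \code{"helical_cylinder"} (small shape deformation while a
#' single connected rod cluster winds around the axis).  Frames are
#' averaged before thresholding; configurations matching neither pattern
#' are reported as \code{"ambiguous"} rather than silently coerced.
#'
#' @param states a \code{ParticleState}, a list of them, or a
#'   \code{Trajectory}.
#' @param box a \code{SimulationBox} (used for all frames unless a
#'   Trajectory supplies its own).
#' @param ellipThreshold threshold on the ellipticity
#'   \eqn{|r_{q\theta}|/\langle r_{2D}\rangle}.
#' @param windingThreshold threshold on the winding (turns) of the largest
#'   rod cluster.
#' @param clusterFraction minimum fraction of rods in the winding cluster.
#' @param contactCutoff connectivity cutoff (sigma).
#' @return Character label, with attribute \code{"metrics"}.
#' @export
classifyTubeShape <- function(states, box = NULL, ellipThreshold = 0.10,
                              windingThreshold = 0.75, clusterFraction = 0.6,
                              contactCutoff = 1.6) {
  if (is(states, "Trajectory")) {
    boxes <- states@boxes
    states <- states@frames
  } else if (is(states, "ParticleState")) {
    states <- list(states); boxes <- list(box)
  } else boxes <- rep(list(box), length(states))
  ell <- wind <- frac <- numeric(length(states))
  for (k in seq_along(states)) {
    st <- states[[k]]; bx <- boxes[[k]]
    sel <- st@kind != "rod_hook"
    p <- .tubePolar(st@pos[sel, , drop = FALSE])
    fm <- fourierModes(st, bx)
    ell[k] <- Mod(fm@rQtheta) / mean(p$r2d)
    w <- rodWinding(st, bx, contactCutoff)
    wind[k] <- w$turns; frac[k] <- w$fraction
  }
  m <- c(ellipticity = mean(ell), winding = mean(wind),
         clusterFraction = mean(frac))
  lab <- if (m["ellipticity"] >= ellipThreshold &&
             m["winding"] < windingThreshold) "elliptical"
  else if (m["ellipticity"] < ellipThreshold &&
           m["winding"] >= windingThreshold &&
           m["clusterFraction"] >= clusterFraction) "helical_cylinder"
  else if (m["ellipticity"] < ellipThreshold &&
           m["winding"] < windingThreshold) "cylindrical"
  else "ambiguous"
  attr(lab, "metrics") <- m
  lab
}
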