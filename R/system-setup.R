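#' @include dynamics.R
NULL

## reference area per particle used to size freshly built lattices; the
## equilibrated value is measured, not imposed (see measureA0)
.A0_REF <- 1.2778

#' Membrane tube specification
#'
#' @slot N integer, total density-counted particles.
#' @slot rCyl numeric, nominal tube radius (sigma).
#' @slot lZ numeric, tube length (sigma, the imposed periodic length).
#' @slot a0 numeric, area per particle used for the area bookkeeping.
#' @export
setClass("TubeSpec",
  representation(N = "integer", rCyl = "numeric", lZ = "numeric",
                 a0 = "numeric"))

setValidity("TubeSpec", function(object) {
  area <- 2 * pi * object@rCyl * object@lZ
  if (abs(area - object@N * object@a0) > 0.1 * object@N * object@a0)
    sprintf("inconsistent geometry: 2 pi R L = %.4g differs from N a0 = %.4g by more than 10%%",
            area, object@N * object@a0)
  else TRUE
})

#' @param N particle number.
#' @param rCyl,lZ tube radius and length in sigma (supply one; the other is
#'   derived from the area bookkeeping 2 pi R L = N a0).
#' @param a0 area per particle (sigma^2).
#' @return A \code{TubeSpec}.
#' @rdname TubeSpec-class
#' @export
tubeSpec <- function(N, rCyl = NULL, lZ = NULL, a0 = .A0_REF) {
  if (is.null(rCyl) && is.null(lZ))
    stop("supply rCyl or lZ")
  if (is.null(rCyl)) rCyl <- N * a0 / (2 * pi * lZ)
  if (is.null(lZ)) lZ <- N * a0 / (2 * pi * rCyl)
  new("TubeSpec", N = as.integer(N), rCyl = rCyl, lZ = lZ, a0 = a0)
}

#' Flat membrane patch specification
#'
#' @slot N integer particle number.
#' @slot a0Init numeric, area per particle of the initial lattice.
#' @slot tension numeric, target in-plane tension (0 = tensionless).
#' @export
setClass("FlatSpec",
  representation(N = "integer", a0Init = "numeric", tension = "numeric"))

setValidity("FlatSpec", function(object) {
  if (object@N <= 0) "N must be positive" else TRUE
})

#' @param N particle number (must factor into nx * ny with ny even for the
#'   periodic hexagonal lattice; e.g. 100, 400, 1024, 1200).
#' @param a0Init initial area per particle.
#' @param tension target tension (kBT/sigma^2 * sigma; 0 = tensionless).
#' @return A \code{FlatSpec}.
#' @rdname FlatSpec-class
#' @export
flatSpec <- function(N, a0Init = .A0_REF, tension = 0) {
  new("FlatSpec", N = as.integer(N), a0Init = a0Init, tension = tension)
}

#' Paper tube geometries
#'
#' The two tube families used in the study: radius R_cyl/r_rod = 1.18 with
#' length L_z/r_rod = 0.00167 N, and R_cyl/r_rod = 1.31 with
#' L_z/r_rod = 0.0015 N.
#'
#' @param N particle number.
#' @param family \code{"narrow"} (1.18) or \code{"wide"} (1.31).
#' @return List with \code{lZ} (sigma), \code{lZOverRrod}, the nominal
#'   \code{rCyl} from the area bookkeeping, and the family radius ratio.
#' @examples
#' tubeGeometry(4800, "wide")$lZOverRrod   # 0.0015 * 4800 = 7.2
#' @export
tubeGeometry <- function(N, family = c("narrow", "wide")) {
  family <- match.arg(family)
  coef <- if (family == "narrow") 0.00167 else 0.0015
  lZOverRrod <- coef * N
  lZ <- lZOverRrod * 10
  list(lZ = lZ, lZOverRrod = lZOverRrod,
       rCyl = N * .A0_REF / (2 * pi * lZ),
       radiusRatio = if (family == "narrow") 1.18 else 1.31)
}

## even-row factorisation of N for a periodic hexagonal lattice,
## closest to a square box
.hexDims <- function(N, a0 = .A0_REF) {
  l <- sqrt(2 * a0 / sqrt(3))
  best <- NULL; bestScore <- Inf
  for (ny in seq(2L, N, by = 2L)) {
    if (N %% ny != 0) next
    nx <- N %/% ny
    score <- abs(log((nx * l) / (ny * l * sqrt(3) / 2)))
    if (score < bestScore) { bestScore <- score; best <- c(nx, ny) }
  }
  if (is.null(best))
    stop("N = ", N, " does not factor into nx * ny with ny even")
  best
}

## hexagonal lattice patch at area per particle a0, orientations +z
.hexPatch <- function(N, a0 = .A0_REF) {
  d <- .hexDims(N, a0)
  nx <- d[1]; ny <- d[2]
  l <- sqrt(2 * a0 / sqrt(3))
  Lx <- nx * l; Ly <- ny * l * sqrt(3) / 2
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  x <- (ix + 0.5 * (iy %% 2)) * l
  y <- iy * l * sqrt(3) / 2
  pos <- cbind(x %% Lx, y, 0)
  orient <- matrix(rep(c(0, 0, 1), each = N), N, 3)
  list(state = particleState(pos, orient),
       box = simulationBox(c(Lx, Ly, max(40, 6 * sqrt(Lx * Ly))), "flat"))
}

#' Build a membrane tube
#'
#' Places \code{N} particles on a cylinder of radius \code{rCyl} with axis z
#' and periodic length \code{lZ} (near-hexagonal ring packing), orientations
#' along the outward normal, and optionally relaxes the tube briefly.  The
#' radius is an initial condition only: during tube runs N and L_z are
#' fixed while the radius is free to relax.
#'
#' @param spec a \code{TubeSpec}.
#' @param mp a \code{MembraneParams} (needed when \code{relaxSteps > 0}).
#' @param seed integer seed.
#' @param relaxSteps optional thermostatted relaxation steps.
#' @param cfg an \code{IntegratorConfig}.
#' @return List with \code{state}, \code{box} and (after relaxation)
#'   \code{rngState}.
#' @examples
#' tb <- buildTube(tubeSpec(400, lZ = 14), seed = 1)
#' @export
buildTube <- function(spec, mp = NULL, seed = 1L, relaxSteps = 0L,
                      cfg = integratorConfig(seed = seed)) {
  N <- spec@N; R <- spec@rCyl; Lz <- spec@lZ
  area <- 2 * pi * R * Lz
  if (abs(area - N * spec@a0) > 0.1 * N * spec@a0)
    stop("inconsistent N / rCyl / lZ: area mismatch exceeds 10%")
  l <- sqrt(2 * spec@a0 / sqrt(3))
  nz <- max(3L, round(Lz / (l * sqrt(3) / 2)))
  base <- N %/% nz; extra <- N %% nz
  counts <- rep(base, nz)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  pos <- matrix(0, N, 3); orient <- matrix(0, N, 3)
  k <- 0L
  for (iz in seq_len(nz)) {
    m <- counts[iz]
    th <- 2 * pi * (seq_len(m) - 1) / m + (iz %% 2) * pi / m
    z <- (iz - 0.5) * Lz / nz
    idx <- k + seq_len(m)
    pos[idx, ] <- cbind(R * cos(th), R * sin(th), z)
    orient[idx, ] <- cbind(cos(th), sin(th), 0)
    k <- k + m
  }
  state <- particleState(pos, orient)
  box <- simulationBox(c(6 * R + 20, 6 * R + 20, Lz), "tube")
  if (relaxSteps > 0) {
    if (is.null(mp)) mp <- membraneParams()
    out <- runDynamics(state, box, mp, nsteps = relaxSteps, cfg = cfg,
                       sampleEvery = max(1L, relaxSteps))
    return(list(state = out$state, box = out$box, rngState = out$rngState))
  }
  list(state = state, box = box, rngState = NULL)
}

#' Build and equilibrate a tensionless flat membrane
#'
#' Starts from a periodic hexagonal lattice and equilibrates under the
#' Langevin thermostat with Monte-Carlo area moves, which sample the
#' zero-tension ensemble; the box side adjusts until the measured in-plane
#' tension fluctuates around zero.  The time-averaged tension over the
#' second half of the equilibration is reported and checked against
#' \code{convTol}.
#'
#' @param spec a \code{FlatSpec}.
#' @param mp a \code{MembraneParams}.
#' @param seed integer seed.
#' @param eqSteps equilibration steps.
#' @param cfg an \code{IntegratorConfig}.
#' @param mcEvery,mcDelta area-move stride and ln-area proposal width.
#' @param convTol convergence tolerance on the mean tension (kBT/sigma^2).
#' @return List with \code{state}, \code{box}, \code{samples},
#'   \code{meanTension} and \code{rngState}.
#' @export
buildFlatTensionless <- function(spec, mp, seed = 1L, eqSteps = 20000L,
                                 cfg = integratorConfig(seed = seed),
                                 mcEvery = 20L, mcDelta = 0.002,
                                 convTol = 0.25) {
  init <- .hexPatch(spec@N, spec@a0Init)
  out <- runDynamics(init$state, init$box, mp, nsteps = eqSteps, cfg = cfg,
                     sampleEvery = 100L, mcEvery = mcEvery, mcDelta = mcDelta)
  sm <- out$samples
  half <- sm[sm$step > max(sm$step) / 2, ]
  gbar <- mean(half$tension)
  if (!is.finite(gbar) || abs(gbar) > convTol)
    warning(sprintf("tension controller not converged: <gamma> = %.3g", gbar))
  list(state = out$state, box = out$box, samples = sm, meanTension = gbar,
       rngState = out$rngState)
}

#' Prepare a tubulation protocol
#'
#' Builds the tubulation initial condition of the study: protein rods
#' embedded at density \code{phiRod} in a tensionless flat membrane,
#' equilibrated with rod curvature 0, after which the curvature is switched
#' to the target value at t = 0.  Returns a protocol handle to execute with
#' \code{\link{runProtocol}}.
#'
#' @param N density-counted particle number of the patch.
#' @param phiRod rod density (fraction of particles in rod backbones).
#' @param cRodTarget target rod curvature (1/sigma).
#' @param mp a \code{MembraneParams}.
#' @param chirality rod chirality.
#' @param epsilonSS side-to-side LJ depth (kBT).
#' @param seed integer seed.
#' @param eqSteps,prodSteps phase durations in MD steps.
#' @param preRelaxSteps rod-free lattice relaxation before embedding.
#' @param cfg an \code{IntegratorConfig}.
#' @param mcEvery area-move stride (both phases stay tensionless).
#' @return List with \code{state}, \code{box}, \code{rodSpec} and
#'   \code{phases} (ready for \code{runProtocol}).
#' @export
prepareTubulation <- function(N = 25600L, phiRod = 0.2, cRodTarget,
                              mp = membraneParams(),
                              chirality = "chiral", epsilonSS = 0,
                              seed = 1L, eqSteps = 10000L, prodSteps = 40000L,
                              preRelaxSteps = 2000L,
                              cfg = integratorConfig(dt = 0.004, seed = seed),
                              mcEvery = 50L) {
  nRods <- round(phiRod * N / 10)
  init <- .hexPatch(N)
  state <- init$state; box <- init$box
  if (preRelaxSteps > 0) {
    out <- runDynamics(state, box, mp, nsteps = preRelaxSteps, cfg = cfg,
                       sampleEvery = max(1L, preRelaxSteps), mcEvery = mcEvery)
    state <- out$state; box <- out$box
  }
  rs <- rodSpec(cRod = 0, chirality = chirality, epsilonSS = epsilonSS)
  if (nRods > 0)
    state <- embedRods(state, box, nRods, rs, seed = seed)
  phases <- list(
    list(steps = eqSteps, cRod = 0, mcEvery = mcEvery, production = FALSE),
    list(steps = prodSteps, cRod = cRodTarget, mcEvery = mcEvery,
         production = TRUE))
  list(state = state, box = box, rodSpec = rs, phases = phases,
       phiRod = rodAreaFraction(state), nRods = nRods)
}
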