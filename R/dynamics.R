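#' @include rod-builder.R
NULL

#' Integrator configuration
#'
#' Parameters of the Langevin (BAOAB) integrator.  Units: sigma = kBT =
#' mass = 1, so time is in sigma (m/kBT)^(1/2); physical comparisons are
#' made in the intrinsic unit tau = r_rod^2/D (see
#' \code{\link{measureDiffusion}}).
#'
#' @slot dt time step.
#' @slot gammaT,gammaR translational and rotational friction coefficients.
#' @slot seed integer RNG seed.
#' @slot maxMove abort threshold on |F| dt^2/m (sigma), the force-overflow
#'   guard.
#' @export
setClass("IntegratorConfig",
  representation(dt = "numeric", gammaT = "numeric", gammaR = "numeric",
                 seed = "integer", maxMove = "numeric"))

setValidity("IntegratorConfig", function(object) {
  msg <- NULL
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@gammaT <= 0 || object@gammaR <= 0)
    msg <- c(msg, "friction coefficients must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param dt time step (default 0.005 for plain membranes; rod systems
#'   typically use 0.003-0.004 to resolve the stiff bonds).
#' @param gammaT,gammaR friction coefficients.
#' @param seed integer seed.
#' @param maxMove force-overflow guard.
#' @return An \code{IntegratorConfig}.
#' @rdname IntegratorConfig-class
#' @export
integratorConfig <- function(dt = 0.005, gammaT = 1, gammaR = 1, seed = 1L,
                             maxMove = 1) {
  new("IntegratorConfig", dt = dt, gammaT = gammaT, gammaR = gammaR,
      seed = as.integer(seed), maxMove = maxMove)
}

.SAMPLE_COLS <- c("step", "time", "uRep", "uAtt", "uBend", "uTilt", "uBond",
                  "uLj", "uPot", "kTrans", "kRot", "Lx", "Ly", "Lz", "area",
                  "wxx", "wyy", "tension", "axialForce", "msdXY", "msdXYZ",
                  "mcAccept")

#' Run Langevin dynamics
#'
#' Advances a configuration with the BAOAB Langevin integrator: velocity
#' half-kicks, position/orientation drifts (orientations rotated exactly and
#' kept at unit norm), and an Ornstein-Uhlenbeck velocity refresh whose
#' noise amplitude satisfies fluctuation-dissipation.  Optionally interleaves
#' Monte-Carlo area moves (\code{mcEvery > 0}) that realise the zero-tension
#' ensemble for flat patches.
#'
#' @param state a \code{ParticleState}.
#' @param box a \code{SimulationBox}.
#' @param mp a \code{MembraneParams}.
#' @param rodSpec optional \code{RodSpec}.
#' @param nsteps number of MD steps.
#' @param cfg an \code{IntegratorConfig}.
#' @param thermostat logical; \code{FALSE} runs plain (energy-conserving)
#'   velocity-Verlet dynamics.
#' @param sampleEvery sampling stride for the observable table.
#' @param frameEvery stride for stored trajectory frames (0 = none).
#' @param mcEvery stride of MC area moves (0 = fixed box).
#' @param mcDelta half-width of the ln-area proposals.
#' @param qModes optional integer matrix of (nx, ny) height-spectrum modes to
#'   accumulate.
#' @param t0 time offset of the returned sample times.
#' @param rngState optional 32-byte raw RNG state from a previous run
#'   (continues the stream exactly; used for checkpoint/restart).
#' @return List with the advanced \code{state}, possibly rescaled \code{box},
#'   \code{samples} (data.frame, one row per sampling time: energy
#'   components, kinetic energies, box, virial diagonal, in-plane tension,
#'   axial force, mean-square displacements, MC acceptance), \code{spec}
#'   (mean height-spectrum power per q mode), \code{trajectory} (a
#'   \code{Trajectory} or NULL) and \code{rngState}.
#' @examples
#' fx <- makeFixture("flat_patch_100", seed = 1)
#' out <- runDynamics(fx$state, fx$box, membraneParams(), nsteps = 50,
#'                    cfg = integratorConfig(seed = 7))
#' tail(out$samples$uPot, 1)
#' @export
runDynamics <- function(state, box, mp, rodSpec = NULL, nsteps,
                        cfg = integratorConfig(), thermostat = TRUE,
                        sampleEvery = 100L, frameEvery = 0L,
                        mcEvery = 0L, mcDelta = 0.002, qModes = NULL,
                        t0 = 0, rngState = NULL) {
  sys <- .packSys(state, box, rodSpec)
  par <- .packParams(mp, rodSpec)
  opts <- list(nsteps = as.double(nsteps), dt = cfg@dt, gammaT = cfg@gammaT,
               gammaR = cfg@gammaR, thermostat = as.double(thermostat),
               seed = as.double(cfg@seed), sampleEvery = as.double(sampleEvery),
               frameEvery = as.double(frameEvery), mcEvery = as.double(mcEvery),
               mcDelta = mcDelta, t0 = t0, maxMove = cfg@maxMove,
               qmodes = if (is.null(qModes)) NULL else
                 matrix(as.integer(qModes), nrow = nrow(qModes)),
               rngState = rngState)
  out <- .Call(C_run, sys, par, opts)
  newState <- state
  newState@pos <- out$pos
  newState@orient <- out$orient
  newState@vel <- out$vel
  newState@avel <- out$avel
  newBox <- box
  newBox@lengths <- out$L
  samples <- as.data.frame(out$samples)
  names(samples) <- .SAMPLE_COLS
  traj <- NULL
  if (frameEvery > 0 && !is.null(out$framesPos)) {
    nf <- dim(out$framesPos)[3]
    frames <- vector("list", nf)
    boxes <- vector("list", nf)
    for (f in seq_len(nf)) {
      fs <- state
      fs@pos <- out$framesPos[, , f]
      fs@orient <- out$framesOrient[, , f]
      fs@vel <- matrix(0, nrow(fs@pos), 3)
      fs@avel <- matrix(0, nrow(fs@pos), 3)
      frames[[f]] <- fs
      boxes[[f]] <- simulationBox(out$frameL[, f], topologyType(box))
    }
    traj <- new("Trajectory", frames = frames, times = out$frameTime,
                boxes = boxes,
                metadata = list(seed = cfg@seed, dt = cfg@dt,
                                cRod = if (is.null(rodSpec)) NA_real_ else rodSpec@cRod,
                                epsilonSS = if (is.null(rodSpec)) 0 else rodSpec@epsilonSS,
                                N = sum(state@kind != "rod_hook"),
                                topology = topologyType(box)))
  }
  list(state = newState, box = newBox, samples = samples, spec = out$spec,
       trajectory = traj, rngState = out$rngState)
}

#' Single integration step
#'
#' One BAOAB Langevin step (a thin wrapper over \code{\link{runDynamics}}).
#'
#' @inheritParams runDynamics
#' @return As \code{\link{runDynamics}}.
#' @export
langevinStep <- function(state, box, mp, rodSpec = NULL,
                         cfg = integratorConfig(), thermostat = TRUE,
                         rngState = NULL) {
  runDynamics(state, box, mp, rodSpec, nsteps = 1, cfg = cfg,
              thermostat = thermostat, sampleEvery = 1, rngState = rngState)
}

#' Run a multi-phase protocol
#'
#' Executes a schedule of phases, each with its own duration and parameter
#' overrides (rod curvature \code{cRod}, side attraction \code{epsilonSS},
#' area-move stride \code{mcEvery}).  Parameter switches are applied exactly
#' at the phase boundaries.  Time is reported relative to the start of the
#' first phase marked \code{production = TRUE} (the paper-style convention
#' that t = 0 is the moment the rod curvature is switched on); earlier
#' phases carry negative times.
#'
#' @inheritParams runDynamics
#' @param phases list of phase descriptors; each a list with \code{steps}
#'   and optional \code{cRod}, \code{epsilonSS}, \code{mcEvery},
#'   \code{production}.
#' @return List with final \code{state}, \code{box}, the per-phase
#'   \code{samples} (single row-bound data.frame with a \code{phase}
#'   column), a combined \code{trajectory} and \code{rngState}; the metadata
#'   records the switch time.
#' @export
runProtocol <- function(state, box, mp, rodSpec, phases,
                        cfg = integratorConfig(), sampleEvery = 200L,
                        frameEvery = 0L, mcDelta = 0.002) {
  if (length(phases) == 0)
    return(list(state = state, box = box,
                samples = NULL,
                trajectory = new("Trajectory",
                                 frames = list(state), times = 0,
                                 boxes = list(box),
                                 metadata = list(seed = cfg@seed, switchTime = NA_real_)),
                rngState = NULL))
  prodIdx <- which(vapply(phases, function(p) isTRUE(p$production), logical(1)))
  ## steps before the production phase define t < 0
  stepsBefore <- if (length(prodIdx))
    sum(vapply(phases[seq_len(prodIdx[1] - 1)], function(p) p$steps, numeric(1)))
  else 0
  t <- -stepsBefore * cfg@dt
  rngState <- NULL
  allSamples <- list()
  allFrames <- list(); allTimes <- numeric(0); allBoxes <- list()
  rs <- rodSpec
  for (k in seq_along(phases)) {
    ph <- phases[[k]]
    if (!is.null(rs)) {
      if (!is.null(ph$cRod)) rs@cRod <- ph$cRod
      if (!is.null(ph$epsilonSS)) rs@epsilonSS <- ph$epsilonSS
    }
    out <- runDynamics(state, box, mp, rs, nsteps = ph$steps, cfg = cfg,
                       sampleEvery = sampleEvery, frameEvery = frameEvery,
                       mcEvery = if (is.null(ph$mcEvery)) 0L else ph$mcEvery,
                       mcDelta = mcDelta, t0 = t, rngState = rngState)
    state <- out$state; box <- out$box; rngState <- out$rngState
    sm <- out$samples
    sm$phase <- k
    allSamples[[k]] <- if (k == 1) sm else sm[-1, , drop = FALSE]
    if (!is.null(out$trajectory)) {
      allFrames <- c(allFrames, out$trajectory@frames)
      allTimes <- c(allTimes, out$trajectory@times)
      allBoxes <- c(allBoxes, out$trajectory@boxes)
    }
    t <- t + ph$steps * cfg@dt
  }
  meta <- list(seed = cfg@seed, dt = cfg@dt,
               switchTime = if (length(prodIdx)) 0 else NA_real_,
               phases = phases,
               cRod = if (is.null(rs)) NA_real_ else rs@cRod,
               N = sum(state@kind != "rod_hook"),
               topology = topologyType(box))
  traj <- new("Trajectory", frames = allFrames, times = allTimes,
              boxes = allBoxes, metadata = meta)
  list(state = state, box = box, samples = do.call(rbind, allSamples),
       trajectory = traj, rngState = rngState)
}

#' Measure the membrane diffusion coefficient and the time unit tau
#'
#' Runs a rod-free tensionless flat membrane, accumulates the in-plane
#' mean-square displacement of its particles, and fits the long-time slope:
#' D = slope/4, and the intrinsic time unit is tau = r_rod^2 / D = 100/D.
#' The fit window is checked for linearity by comparing the slopes of its
#' two halves.
#'
#' @param mp a \code{MembraneParams}.
#' @param N particle number of the patch.
#' @param seed integer seed.
#' @param eqSteps equilibration steps (zero-tension ensemble).
#' @param prodSteps production steps (fixed area) for the MSD fit.
#' @param cfg an \code{IntegratorConfig}.
#' @param fitWindow fraction of the production window used (start, end).
#' @return List with \code{D}, \code{tau}, the fitted \code{slope}, the
#'   half-window slopes and the samples table.
#' @export
measureDiffusion <- function(mp, N = 400L, seed = 1L, eqSteps = 10000L,
                             prodSteps = 40000L, cfg = integratorConfig(seed = seed),
                             fitWindow = c(0.2, 1.0)) {
  built <- buildFlatTensionless(flatSpec(N), mp, seed = seed,
                                eqSteps = eqSteps, cfg = cfg)
  out <- runDynamics(built$state, built$box, mp, nsteps = prodSteps,
                     cfg = cfg, sampleEvery = 200L, rngState = built$rngState)
  sm <- out$samples
  i0 <- max(2L, ceiling(fitWindow[1] * nrow(sm)))
  i1 <- floor(fitWindow[2] * nrow(sm))
  win <- sm[i0:i1, ]
  fit <- stats::lm(msdXY ~ time, data = win)
  slope <- unname(stats::coef(fit)[2])
  mid <- floor((i0 + i1) / 2)
  s1 <- unname(stats::coef(stats::lm(msdXY ~ time, data = sm[i0:mid, ]))[2])
  s2 <- unname(stats::coef(stats::lm(msdXY ~ time, data = sm[(mid + 1):i1, ]))[2])
  if (!is.finite(slope) || slope <= 0 ||
      abs(s1 - s2) > 0.75 * max(abs(s1), abs(s2)))
    stop("non-diffusive regime: MSD is not linear over the fit window ",
         sprintf("(half-window slopes %.3g / %.3g)", s1, s2))
  D <- slope / 4
  list(D = D, tau = 100 / D, slope = slope, slopeHalves = c(s1, s2),
       samples = sm)
}
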