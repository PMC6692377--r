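#' @include system-setup.R
NULL

.blockSe <- function(x, nblock = 10L) {
  nb <- min(nblock, length(x))
  if (nb < 2) return(NA_real_)
  idx <- cut(seq_along(x), nb, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(nb)
}

#' Area per particle of the tensionless membrane
#'
#' Equilibrates rod-free flat patches in the zero-tension ensemble and
#' averages the projected box area per particle over the production window,
#' for several independent seeds.
#'
#' @param mp a \code{MembraneParams}.
#' @param N patch size.
#' @param seeds integer vector of seeds (>= 1).
#' @param eqSteps,prodSteps equilibration and production steps.
#' @param cfg an \code{IntegratorConfig} template (its seed is overridden).
#' @param mcEvery,mcDelta area-move parameters.
#' @return List with \code{a0}, \code{a0Se} (between-seed standard error,
#'   or a block-average error for a single seed) and the per-seed values.
#' @export
measureA0 <- function(mp, N = 1024L, seeds = 1:3, eqSteps = 15000L,
                      prodSteps = 25000L, cfg = integratorConfig(),
                      mcEvery = 20L, mcDelta = 0.002) {
  vals <- numeric(0)
  ses <- numeric(0)
  for (s in seeds) {
    ccfg <- cfg; ccfg@seed <- as.integer(s)
    built <- buildFlatTensionless(flatSpec(N), mp, seed = s,
                                  eqSteps = eqSteps, cfg = ccfg,
                                  mcEvery = mcEvery, mcDelta = mcDelta)
    out <- runDynamics(built$state, built$box, mp, nsteps = prodSteps,
                       cfg = ccfg, sampleEvery = 100L, mcEvery = mcEvery,
                       mcDelta = mcDelta, rngState = built$rngState)
    a <- out$samples$area[-1] / N
    vals <- c(vals, mean(a))
    ses <- c(ses, .blockSe(a))
  }
  se <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else ses[1]
  list(a0 = mean(vals), a0Se = se, perSeed = vals)
}

#' In-plane tension of a fixed-area patch
#'
#' Virial in-plane tension
#' \eqn{\gamma = -(\sum_i m(v_{ix}^2+v_{iy}^2) + W_{xx} + W_{yy})/(2A)}
#' averaged over a fixed-area run of the given configuration.
#'
#' @param state,box,mp system (box is kept fixed).
#' @param rodSpec optional rods.
#' @param nsteps production steps.
#' @param eqSteps discarded initial steps.
#' @param cfg an \code{IntegratorConfig}.
#' @return List with \code{tension}, \code{tensionSe} and the samples.
#' @export
measureTension <- function(state, box, mp, rodSpec = NULL, nsteps = 10000L,
                           eqSteps = 4000L, cfg = integratorConfig()) {
  out <- runDynamics(state, box, mp, rodSpec, nsteps = eqSteps + nsteps,
                     cfg = cfg, sampleEvery = 50L)
  sm <- out$samples[out$samples$step > eqSteps, ]
  list(tension = mean(sm$tension), tensionSe = .blockSe(sm$tension),
       samples = out$samples, state = out$state)
}

#' Area compression modulus
#'
#' Strain route (default): patches are built at fixed projected areas above
#' the tensionless area \code{a0}, the virial tension is measured at each,
#' and K_A is the slope of tension versus \emph{elastic} strain.  At small
#' tension part of the imposed projected-area strain is supplied by ironing
#' out thermal undulations rather than by stretching the material, which
#' softens the apparent modulus; with \code{correctUndulation = TRUE} the
#' released undulation area
#' \eqn{\Delta\epsilon_{und} = (k_BT/8\pi\kappa)\ln(1 + \gamma L^2/\pi^2\kappa)}
#' is subtracted before fitting, giving the material modulus.  With
#' \code{correctUndulation = FALSE} the bare slope (the apparent small-strain
#' modulus) is returned, which is the quantity the fluctuation route
#' measures: in the zero-tension ensemble
#' \eqn{K_A = k_BT \langle A\rangle / \mathrm{Var}(A)}.
#'
#' @param mp a \code{MembraneParams}.
#' @param N patch size.
#' @param a0 tensionless area per particle (measure it first, e.g. with
#'   \code{\link{measureA0}}).
#' @param strains areal strains for the strain route.
#' @param seed integer seed.
#' @param eqSteps,prodSteps steps per strain point (strain route) or for
#'   the tensionless run (fluctuation route).
#' @param route \code{"strain"} or \code{"fluctuation"}.
#' @param correctUndulation subtract the undulation-release strain (strain
#'   route only).
#' @param kappa bending rigidity used by the undulation correction.
#' @param cfg an \code{IntegratorConfig}.
#' @return List with \code{KA}, \code{KASe} and route details.
#' @export
measureKA <- function(mp, N = 576L, a0 = .A0_REF,
                      strains = c(0.015, 0.025, 0.035, 0.045), seed = 1L,
                      eqSteps = 4000L, prodSteps = 10000L,
                      route = c("strain", "fluctuation"),
                      correctUndulation = TRUE, kappa = 15,
                      cfg = integratorConfig(seed = seed)) {
  route <- match.arg(route)
  if (route == "strain") {
    g <- gs <- numeric(length(strains))
    for (k in seq_along(strains)) {
      hp <- .hexPatch(N, a0 * (1 + strains[k]))
      ccfg <- cfg; ccfg@seed <- as.integer(seed + 101L * k)
      mt <- measureTension(hp$state, hp$box, mp, nsteps = prodSteps,
                           eqSteps = eqSteps, cfg = ccfg)
      g[k] <- mt$tension; gs[k] <- mt$tensionSe
    }
    eps <- strains
    if (correctUndulation) {
      L2 <- N * a0
      rel <- (mp@kT / (8 * pi * kappa)) *
        log(pmax(1e-12, 1 + g * L2 / (pi^2 * kappa)))
      eps <- strains - rel
    }
    fit <- stats::lm(g ~ eps, weights = 1 / pmax(gs, 1e-6)^2)
    list(KA = unname(stats::coef(fit)[2]),
         KASe = summary(fit)$coefficients[2, 2],
         strains = strains, elasticStrains = eps, tensions = g,
         tensionSes = gs)
  } else {
    built <- buildFlatTensionless(flatSpec(N), mp, seed = seed,
                                  eqSteps = eqSteps, cfg = cfg)
    out <- runDynamics(built$state, built$box, mp, nsteps = prodSteps,
                       cfg = cfg, sampleEvery = 50L, mcEvery = 10L,
                       mcDelta = 0.004, rngState = built$rngState)
    A <- out$samples$area[-1]
    KA <- mp@kT * mean(A) / stats::var(A)
    ## the area decorrelates slowly under the MC moves: error from the
    ## effective number of independent samples (integrated autocorrelation)
    ac <- stats::acf(A, lag.max = min(200, length(A) %/% 4), plot = FALSE)
    pos <- which(ac$acf < 0.05)[1]
    tint <- 1 + 2 * sum(ac$acf[2:max(2, ifelse(is.na(pos), 50, pos))])
    neff <- max(4, length(A) / max(1, tint))
    list(KA = KA, KASe = KA * sqrt(2 / neff), areas = A, nEff = neff)
  }
}

## integer q grid (half plane, conjugate-unique) with |q| <= qmax
.qGrid <- function(L, qmax) {
  nmax <- ceiling(qmax * max(L[1], L[2]) / (2 * pi))
  g <- as.matrix(expand.grid(nx = -nmax:nmax, ny = 0:nmax))
  keep <- !(g[, 2] == 0 & g[, 1] <= 0)
  g <- g[keep, , drop = FALSE]
  q <- sqrt((2 * pi * g[, 1] / L[1])^2 + (2 * pi * g[, 2] / L[2])^2)
  sel <- q <= qmax & q > 0
  list(modes = g[sel, , drop = FALSE], q = q[sel])
}

#' Per-mode bending-rigidity estimates from a height spectrum
#'
#' For the thermally fluctuating tensionless membrane the height spectrum
#' obeys \eqn{\langle|h_q|^2\rangle = k_BT/(\kappa q^4 A)} per projected
#' area; with the particle-sum convention
#' \eqn{S_q = \langle|\sum_i z_i e^{-i q r_i}|^2\rangle} this gives the
#' estimator \eqn{\kappa_q = N^2 k_BT / (A q^4 S_q)}.
#'
#' @param S mean spectral power per mode (particle-sum convention).
#' @param q mode wavenumbers.
#' @param A projected area.
#' @param N particle count.
#' @param kT thermal energy.
#' @return Numeric vector of per-mode kappa estimates.
#' @export
kappaFromSpectrum <- function(S, q, A, N, kT = 1) {
  N^2 * kT / (A * q^4 * S)
}

#' Bending rigidity from the height-fluctuation spectrum
#'
#' Equilibrates a tensionless patch, freezes the projected area, accumulates
#' the long-wavelength height spectrum and averages the per-mode estimator
#' over the fit window.  The default window discards the two smallest
#' distinct wavenumbers (residual tension and finite-size effects) and all
#' modes above \code{qmax} (protrusion regime).
#'
#' @param mp a \code{MembraneParams}.
#' @param N patch size (linear size should be at least ~4 r_rod).
#' @param seeds integer seeds.
#' @param eqSteps,prodSteps steps.
#' @param qmax upper wavenumber of the window (1/sigma).
#' @param dropSmallest number of smallest distinct |q| shells discarded
#'   (their relaxation times exceed desk-scale runs).
#' @param route \code{"fit"} decomposes the spectrum as
#'   \eqn{S(q) = c_4 q^{-4} + c_2 q^{-2} + c_0} (bending + residual
#'   tension/tilt + protrusion floor) by weighted linear least squares and
#'   reads kappa from \eqn{c_4}; \code{"window"} averages the bare per-mode
#'   estimator over the window.
#' @param cfg an \code{IntegratorConfig}.
#' @return List with \code{kappa}, \code{kappaSe}, the per-mode table and
#'   the window used.
#' @export
measureKappa <- function(mp, N = 1024L, seeds = 1L, eqSteps = 10000L,
                         prodSteps = 60000L, qmax = 2 * pi / 3,
                         dropSmallest = 2L, route = c("fit", "window"),
                         cfg = integratorConfig()) {
  route <- match.arg(route)
  perSeed <- numeric(0)
  tabs <- list()
  for (s in seeds) {
    ccfg <- cfg; ccfg@seed <- as.integer(s)
    built <- buildFlatTensionless(flatSpec(N), mp, seed = s,
                                  eqSteps = eqSteps, cfg = ccfg)
    L <- boxLengths(built$box)
    qg <- .qGrid(L, qmax)
    ## keep the zero-tension area moves on while accumulating the spectrum:
    ## a residual tension (compression especially) biases the low-q modes
    out <- runDynamics(built$state, built$box, mp, nsteps = prodSteps,
                       cfg = ccfg, sampleEvery = 40L, qModes = qg$modes,
                       mcEvery = 20L, rngState = built$rngState)
    A <- mean(out$samples$area)
    qd <- sort(unique(round(qg$q, 9)))
    qmin <- if (length(qd) > dropSmallest) qd[dropSmallest + 1] else qd[1]
    win <- qg$q >= qmin - 1e-9
    kap <- .kappaFit(out$spec[win], qg$q[win], A, N, mp@kT, route)
    perSeed <- c(perSeed, kap)
    Alast <- A
    tabs[[length(tabs) + 1]] <-
      data.frame(seed = s, q = qg$q,
                 kappa = kappaFromSpectrum(out$spec, qg$q, A, N, mp@kT),
                 S = out$spec, inWindow = win)
  }
  tab <- do.call(rbind, tabs)
  se <- if (length(perSeed) > 1) stats::sd(perSeed) / sqrt(length(perSeed))
  else {
    ## single seed: spread of leave-one-shell-out refits
    w <- tab$inWindow
    qs <- tab$q[w]
    sh <- match(round(qs, 6), sort(unique(round(qs, 6))))
    loo <- vapply(unique(sh), function(k) {
      keep <- sh != k
      .kappaFit(tab$S[w][keep], qs[keep], Alast, N, mp@kT, route)
    }, numeric(1))
    stats::sd(loo)
  }
  list(kappa = mean(perSeed), kappaSe = se, perMode = tab,
       window = c(qmin = min(tab$q[tab$inWindow]), qmax = qmax))
}

.kappaFit <- function(S, q, A, N, kT, route) {
  if (route == "window") return(mean(kappaFromSpectrum(S, q, A, N, kT)))
  X <- cbind(q^-4, q^-2, 1)
  ## iteratively reweighted LS: weights from the fitted (not the noisy)
  ## spectrum avoid the bias of 1/S^2 weights under multiplicative noise
  w <- 1 / S^2
  for (it in 1:3) {
    fit <- stats::lm.fit(X * sqrt(w), S * sqrt(w))
    Shat <- pmax(drop(X %*% fit$coefficients), 1e-12)
    w <- 1 / Shat^2
  }
  c4 <- fit$coefficients[1]
  unname(N^2 * kT / (A * c4))
}

#' Edge line tension from a membrane strip
#'
#' Builds a strip spanning the periodic x direction with two straight free
#' edges, runs fixed-box dynamics, and reads the line tension from the
#' contractile axial force: \eqn{\Gamma = f_x / 2} (two edges), with
#' \eqn{f_x = -(\sum_i m v_{ix}^2 + W_{xx})/L_x}.
#'
#' @param mp a \code{MembraneParams}.
#' @param N particle number of the full patch before cutting.
#' @param stripFraction fraction of the y extent kept.
#' @param seeds integer seeds.
#' @param eqSteps,prodSteps steps.
#' @param zConf weak flat-plane confinement spring (kBT/sigma^2) holding the
#'   strip flat: an open strip is metastable against rolling up into an
#'   edge-free tube, and the confinement acts only along z so it does not
#'   enter the axial virial.
#' @param cfg an \code{IntegratorConfig}.
#' @return List with \code{gamma}, \code{gammaSe}, per-seed values, and the
#'   final state of the last run (edge integrity can be inspected).
#' @export
measureGamma <- function(mp, N = 784L, stripFraction = 0.6, seeds = 1L,
                         eqSteps = 4000L, prodSteps = 16000L, zConf = 0.005,
                         cfg = integratorConfig()) {
  vals <- ses <- numeric(0)
  lastState <- NULL
  mp@zConf <- zConf
  for (s in seeds) {
    hp <- .hexPatch(N)
    keep <- hp$state@pos[, 2] >= 0.5 * (1 - stripFraction) * boxLengths(hp$box)[2] &
            hp$state@pos[, 2] < 0.5 * (1 + stripFraction) * boxLengths(hp$box)[2]
    st <- particleState(hp$state@pos[keep, , drop = FALSE],
                        hp$state@orient[keep, , drop = FALSE])
    ccfg <- cfg; ccfg@seed <- as.integer(s)
    out <- runDynamics(st, hp$box, mp, nsteps = eqSteps + prodSteps,
                       cfg = ccfg, sampleEvery = 50L)
    sm <- out$samples[out$samples$step > eqSteps, ]
    vals <- c(vals, mean(sm$axialForce) / 2)
    ses <- c(ses, .blockSe(sm$axialForce / 2))
    lastState <- out$state
  }
  se <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else ses[1]
  list(gamma = mean(vals), gammaSe = se, perSeed = vals, state = lastState)
}

#' Measure the full elastic report
#'
#' Convenience wrapper running the four estimators (and optionally the
#' diffusion/time-unit calibration) at configurable desk-scale settings.
#'
#' @param mp a \code{MembraneParams}.
#' @param settings named list overriding the per-quantity arguments, e.g.
#'   \code{list(a0 = list(N = 1024, seeds = 1:3), kappa = list(N = 900))}.
#' @param measureD logical, also measure the diffusion coefficient.
#' @return An \code{\link{ElasticReport-class}}.
#' @export
measureElasticConstants <- function(mp, settings = list(), measureD = FALSE) {
  a0args <- modifyList(list(mp = mp), settings$a0 %||% list())
  a0 <- do.call(measureA0, a0args)
  kaargs <- modifyList(list(mp = mp, a0 = a0$a0), settings$KA %||% list())
  ka <- do.call(measureKA, kaargs)
  kpargs <- modifyList(list(mp = mp), settings$kappa %||% list())
  kp <- do.call(measureKappa, kpargs)
  ggargs <- modifyList(list(mp = mp), settings$gamma %||% list())
  gg <- do.call(measureGamma, ggargs)
  D <- DSe <- NA_real_
  if (measureD) {
    dd <- do.call(measureDiffusion,
                  modifyList(list(mp = mp), settings$D %||% list()))
    D <- dd$D; DSe <- NA_real_
  }
  new("ElasticReport", kappa = kp$kappa, kappaSe = kp$kappaSe,
      a0 = a0$a0, a0Se = a0$a0Se, KA = ka$KA, KASe = ka$KASe,
      gamma = gg$gamma, gammaSe = gg$gammaSe, D = D, DSe = DSe,
      runInfo = list(settings = settings))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the free potential coefficients
#'
#' Iterative derivative-free tuning of the free coefficients of the
#' repulsion/attraction/weight functions against target elastic constants:
#' the attraction strength is scaled toward the edge-tension target, the
#' saturation density is shifted toward the area-per-particle target, and
#' the w_cv amplitude is scaled toward the bending-rigidity target (kappa
#' responds linearly to the weight amplitude at fixed k_bend = k_tilt).
#' Measurement noise is handled by bounded relaxation steps; the loop stops
#' when every measured quantity is within \code{nSigma} combined errors (or
#' the absolute tolerances) of its target.
#'
#' @param targets named list with \code{a0}, \code{gamma}, \code{kappa}
#'   (any subset; missing entries are not tuned).
#' @param mp0 starting \code{MembraneParams}.
#' @param maxIter iteration budget.
#' @param tol named list of absolute tolerances (defaults: a0 0.005,
#'   gamma 0.3, kappa 2).
#' @param nSigma combined-error multiple accepted as converged.
#' @param settings per-quantity measurement settings (see
#'   \code{\link{measureElasticConstants}}).
#' @param verbose print progress.
#' @return List with the calibrated \code{mp}, convergence flag and the
#'   iteration \code{history}.
#' @export
calibrateMembrane <- function(targets, mp0 = membraneParams(), maxIter = 6L,
                              tol = list(a0 = 0.005, gamma = 0.3, kappa = 2),
                              nSigma = 2, settings = list(), verbose = FALSE) {
  mp <- mp0
  history <- list()
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    meas <- list()
    if (!is.null(targets$a0))
      meas$a0 <- do.call(measureA0, modifyList(list(mp = mp),
                                               settings$a0 %||% list()))
    if (!is.null(targets$gamma))
      meas$gamma <- do.call(measureGamma, modifyList(list(mp = mp),
                                                     settings$gamma %||% list()))
    if (!is.null(targets$kappa))
      meas$kappa <- do.call(measureKappa, modifyList(list(mp = mp),
                                                     settings$kappa %||% list()))
    ok <- TRUE
    if (!is.null(targets$a0)) {
      d <- meas$a0$a0 - targets$a0
      ok <- ok && (abs(d) <= max(tol$a0, nSigma * meas$a0$a0Se))
    }
    if (!is.null(targets$gamma)) {
      d <- meas$gamma$gamma - targets$gamma
      ok <- ok && (abs(d) <= max(tol$gamma, nSigma * meas$gamma$gammaSe))
    }
    if (!is.null(targets$kappa)) {
      d <- meas$kappa$kappa - targets$kappa
      ok <- ok && (abs(d) <= max(tol$kappa, nSigma * meas$kappa$kappaSe))
    }
    history[[it]] <- list(iter = it,
                          epsAtt = mp@epsAtt, rhoStar = mp@rhoStar,
                          alphaCv = mp@alphaCv,
                          a0 = meas$a0$a0 %||% NA_real_,
                          gamma = meas$gamma$gamma %||% NA_real_,
                          kappa = meas$kappa$kappa %||% NA_real_)
    if (verbose) print(unlist(history[[it]]))
    if (ok) { converged <- TRUE; break }
    ## bounded multiplicative/additive relaxation updates
    if (!is.null(targets$gamma) && is.finite(meas$gamma$gamma) &&
        meas$gamma$gamma > 0) {
      fac <- (targets$gamma / meas$gamma$gamma)^0.8
      mp@epsAtt <- mp@epsAtt * min(1.5, max(0.67, fac))
    }
    if (!is.null(targets$a0) && is.finite(meas$a0$a0)) {
      ## denser saturation (larger rho*) packs tighter: smaller a0
      mp@rhoStar <- mp@rhoStar + max(-0.5, min(0.5,
        8 * (meas$a0$a0 - targets$a0)))
    }
    if (!is.null(targets$kappa) && is.finite(meas$kappa$kappa) &&
        meas$kappa$kappa > 0) {
      fac <- targets$kappa / meas$kappa$kappa
      mp@alphaCv <- mp@alphaCv * min(2, max(0.5, fac))
    }
  }
  list(mp = mp, converged = converged, history = history)
}
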