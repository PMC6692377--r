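#' @include dynamics.R
NULL

#' Metropolis exchange decision for a curvature swap
#'
#' Hamiltonian replica exchange over the rod curvature at common
#' temperature: for replicas a and b with curvature labels C_a, C_b, the
#' energy change of swapping the labels is
#' \deqn{\Delta U = [U_a(C_b) + U_b(C_a)] - [U_a(C_a) + U_b(C_b)]}
#' and the swap is accepted with probability \eqn{\min(1, e^{-\Delta U/k_BT})}.
#' Only the intra-rod bending terms depend on C_rod, so the four energies
#' are cheap to evaluate (see \code{\link{runREMD}}).
#'
#' @param uaCa,uaCb energies of configuration a under its own and the
#'   partner's curvature (kBT).
#' @param ubCb,ubCa same for configuration b.
#' @param kT thermal energy.
#' @param u optional uniform random number in [0,1) (drawn from R's RNG if
#'   omitted).
#' @return List with \code{accepted}, \code{dU} and the acceptance
#'   probability \code{pAcc}.
#' @examples
#' attemptExchange(1, 2, 5, 4, u = 0.5)  # dU = 0 -> always accepted
#' @export
attemptExchange <- function(uaCa, uaCb, ubCb, ubCa, kT = 1, u = NULL) {
  dU <- (uaCb + ubCa) - (uaCa + ubCb)
  p <- min(1, exp(-dU / kT))
  if (is.null(u)) u <- stats::runif(1)
  list(accepted = u < p, dU = dU, pAcc = p)
}

#' Replica exchange over the rod curvature
#'
#' Runs one replica per ladder value, alternating MD segments with
#' Metropolis label swaps between adjacent replicas (even and odd pairs on
#' alternating rounds).  A swap exchanges the curvature labels only, so the
#' multiset of configurations is untouched.  Replicas use disjoint RNG
#' streams derived from the ladder seeds.
#'
#' @param state,box,mp,rodSpec starting system (all replicas start from this
#'   configuration; \code{rodSpec@cRod} is overridden by the ladder).
#' @param ladder a \code{\link{ReplicaLadder-class}}.
#' @param nCycles number of MD-segment + exchange rounds.
#' @param cfg an \code{IntegratorConfig} (per-replica seeds come from the
#'   ladder).
#' @param sampleEvery sampling stride within segments.
#' @param observe optional function(state, box) evaluated per replica per
#'   cycle; results are collected in the demultiplexed observable table.
#' @param exchangeSeed seed of the exchange-decision RNG stream.
#' @return List with \code{states} (per replica), \code{cRodOf} (current
#'   curvature label of each replica), \code{exchangeLog} (data.frame:
#'   cycle, pair, dU, accepted), \code{acceptanceRate} per adjacent pair,
#'   \code{observables} (data.frame: cycle, cRod, value columns) and
#'   \code{walkerPath} (ladder position of each walker per cycle, for
#'   round-trip diagnostics).
#' @export
runREMD <- function(state, box, mp, rodSpec, ladder, nCycles,
                    cfg = integratorConfig(dt = 0.004),
                    sampleEvery = 500L, observe = NULL,
                    exchangeSeed = 12345L) {
  nr <- length(ladder@cRodValues)
  reps <- vector("list", nr)
  for (k in seq_len(nr))
    reps[[k]] <- list(state = state, box = box, rngState = NULL,
                      cRod = ladder@cRodValues[k],
                      seed = ladder@seeds[k])
  logRows <- list()
  obsRows <- list()
  walker <- matrix(0L, nCycles, nr)
  att <- acc <- integer(max(1, nr - 1))
  .withSeed(exchangeSeed, {
    for (cyc in seq_len(nCycles)) {
      for (k in seq_len(nr)) {
        rs <- rodSpec; rs@cRod <- reps[[k]]$cRod
        ccfg <- cfg; ccfg@seed <- reps[[k]]$seed
        out <- runDynamics(reps[[k]]$state, reps[[k]]$box, mp, rs,
                           nsteps = ladder@exchangeEvery, cfg = ccfg,
                           sampleEvery = sampleEvery,
                           rngState = reps[[k]]$rngState)
        reps[[k]]$state <- out$state
        reps[[k]]$box <- out$box
        reps[[k]]$rngState <- out$rngState
        if (!is.null(observe)) {
          ob <- observe(out$state, out$box)
          obsRows[[length(obsRows) + 1]] <-
            data.frame(cycle = cyc, replica = k, cRod = reps[[k]]$cRod,
                       t(unlist(ob)))
        }
      }
      ## alternating even/odd adjacent pairs
      start <- if (cyc %% 2 == 1) 1L else 2L
      ks <- if (nr >= start + 1L) seq(start, nr - 1L, by = 2L) else integer(0)
      for (k in ks) {
        a <- k; b <- k + 1L
        Ca <- reps[[a]]$cRod; Cb <- reps[[b]]$cRod
        uaCa <- .rodBendEnergy(reps[[a]]$state, reps[[a]]$box, mp, rodSpec, Ca)
        uaCb <- .rodBendEnergy(reps[[a]]$state, reps[[a]]$box, mp, rodSpec, Cb)
        ubCb <- .rodBendEnergy(reps[[b]]$state, reps[[b]]$box, mp, rodSpec, Cb)
        ubCa <- .rodBendEnergy(reps[[b]]$state, reps[[b]]$box, mp, rodSpec, Ca)
        ex <- attemptExchange(uaCa, uaCb, ubCb, ubCa, kT = mp@kT)
        att[k] <- att[k] + 1L
        if (ex$accepted) {
          acc[k] <- acc[k] + 1L
          reps[[a]]$cRod <- Cb; reps[[b]]$cRod <- Ca
        }
        logRows[[length(logRows) + 1]] <-
          data.frame(cycle = cyc, pair = k, dU = ex$dU, pAcc = ex$pAcc,
                     accepted = ex$accepted)
      }
      ## walker = configuration stream (replica); its current ladder slot
      walker[cyc, ] <- match(vapply(reps, function(r) r$cRod, numeric(1)),
                             ladder@cRodValues)
    }
  })
  list(states = lapply(reps, function(r) r$state),
       boxes = lapply(reps, function(r) r$box),
       cRodOf = vapply(reps, function(r) r$cRod, numeric(1)),
       exchangeLog = if (length(logRows)) do.call(rbind, logRows) else NULL,
       acceptanceRate = ifelse(att > 0, acc / att, NA_real_),
       observables = if (length(obsRows)) do.call(rbind, obsRows) else NULL,
       walkerPath = walker)
}
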