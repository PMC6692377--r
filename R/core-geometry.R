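#' @include params.R
NULL

#' Minimum-image displacement
#'
#' Wraps each periodic component of a displacement vector by integer
#' multiples of the corresponding cell length so that it lies in
#' \code{[-L/2, L/2)}.  Non-periodic components (the radial directions of a
#' tube, the normal of a flat patch) pass through unchanged.
#'
#' @param displacement numeric vector of length 3, or an N x 3 matrix of
#'   displacements.
#' @param box a \code{SimulationBox}.
#' @return Object of the same shape as \code{displacement}.
#' @examples
#' box <- simulationBox(c(10, 10, 20), "tube")
#' minimumImage(c(0, 0, 12), box)   # -> (0, 0, -8)
#' @export
minimumImage <- function(displacement, box) {
  per <- periodicDims(box)
  L <- boxLengths(box)
  if (is.matrix(displacement)) {
    out <- displacement
    for (d in which(per))
      out[, d] <- out[, d] - L[d] * floor(out[, d] / L[d] + 0.5)
    return(out)
  }
  out <- displacement
  for (d in which(per))
    out[d] <- out[d] - L[d] * floor(out[d] / L[d] + 0.5)
  out
}

#' Minimum-image pair distances
#'
#' @param a,b N x 3 and M x 3 position matrices.
#' @param box a \code{SimulationBox}.
#' @return N x M matrix of minimum-image distances.
#' @keywords internal
.pairDistances <- function(a, b, box) {
  per <- periodicDims(box)
  L <- boxLengths(box)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (d in 1:3) {
    dd <- outer(a[, d], b[, d], "-")
    if (per[d]) dd <- dd - L[d] * floor(dd / L[d] + 0.5)
    d2 <- d2 + dd * dd
  }
  sqrt(d2)
}

#' Diagnose a particle configuration
#'
#' Checks the structural invariants of a \code{ParticleState}: unit-norm
#' orientations (within 1e-9), well-formed rods (10 backbone particles with
#' segment indices 0..9 and 0 or 2 hooks each), hook particles belonging to
#' a rod, and the absence of catastrophic overlaps (minimum-image pair
#' distance below \code{overlapTol}).  The empty report means the state is
#' valid; this is a diagnostic, not an error path.
#'
#' @param state a \code{ParticleState}.
#' @param box a \code{SimulationBox}.
#' @param nBackbone expected backbone particles per rod.
#' @param overlapTol hard-core overlap threshold in sigma.
#' @return Character vector of violation messages (empty if valid).
#' @examples
#' fx <- makeFixture("flat_patch_100", seed = 1)
#' validateState(fx$state, fx$box)   # character(0)
#' @export
validateState <- function(state, box, nBackbone = 10L, overlapTol = 0.8) {
  report <- character(0)
  nrm <- sqrt(rowSums(state@orient^2))
  bad <- which(abs(nrm - 1) > 1e-9)
  for (i in utils::head(bad, 10))
    report <- c(report,
                sprintf("particle %d: orientation norm %.6g is not 1", i, nrm[i]))
  if (length(bad) > 10)
    report <- c(report, sprintf("...and %d more non-unit orientations",
                                length(bad) - 10))
  for (r in sort(unique(state@rodId[state@rodId >= 0]))) {
    bb <- which(state@rodId == r & state@kind == "rod_backbone")
    segs <- sort(state@segmentIndex[bb])
    if (length(bb) != nBackbone || !identical(segs, 0:(nBackbone - 1)))
      report <- c(report, sprintf(
        "rod %d incomplete: %d backbone particles (need %d with segments 0..%d)",
        r, length(bb), nBackbone, nBackbone - 1))
    nh <- sum(state@rodId == r & state@kind == "rod_hook")
    if (!nh %in% c(0L, 2L))
      report <- c(report, sprintf("rod %d has %d hook particles (need 0 or 2)",
                                  r, nh))
  }
  stray <- which(state@kind == "rod_hook" & state@rodId < 0)
  for (i in stray)
    report <- c(report, sprintf("particle %d: rod_hook without a rod", i))
  ## overlap scan in chunks to bound memory
  n <- nrow(state@pos)
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dm <- .pairDistances(state@pos[s:e, , drop = FALSE], state@pos, box)
    dm[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    hit <- which(dm < overlapTol, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      hit <- hit[hit[, 1] + s - 1L < hit[, 2], , drop = FALSE]
      for (k in seq_len(min(nrow(hit), 5)))
        report <- c(report, sprintf(
          "particles %d and %d overlap (distance %.3g < %.3g)",
          hit[k, 1] + s - 1L, hit[k, 2], dm[hit[k, 1], hit[k, 2]], overlapTol))
      if (nrow(hit) > 5) {
        report <- c(report, "...more overlaps omitted")
        break
      }
    }
  }
  report
}
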