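#' @include core-geometry.R
NULL

.F_REP <- 1L; .F_ATT <- 2L; .F_BT <- 4L; .F_BOND <- 8L; .F_LJ <- 16L
.F_RODBEND <- 32L
.F_ALL <- 31L

.callForces <- function(state, box, mp, rs = NULL, flags = .F_ALL,
                        parOverride = NULL) {
  sys <- .packSys(state, box, rs)
  par <- if (is.null(parOverride)) .packParams(mp, rs) else parOverride
  .Call(C_forces, sys, par, as.integer(flags))
}

.checkUnitOrient <- function(state, tol = 1e-6) {
  nrm <- sqrt(rowSums(state@orient^2))
  if (any(abs(nrm - 1) > tol))
    stop("non-unit orientation vectors (max deviation ",
         format(max(abs(nrm - 1))), "); renormalise before evaluating energies")
}

#' Bending and tilt energy
#'
#' Evaluates the orientation pair potentials
#' \deqn{U_{bend} = (k_{bend}/2) \sum_{i<j} (u_i - u_j - C_{bd}\hat r_{ij})^2
#'   w_{cv}(r_{ij})}
#' \deqn{U_{tilt} = (k_{tilt}/2) \sum_{i<j} [(u_i\cdot\hat r_{ij})^2 +
#'   (u_j\cdot\hat r_{ij})^2] w_{cv}(r_{ij})}
#' with per-pair parameters: membrane pairs use \code{kBend}/\code{kTilt}
#' and \eqn{C_{bd} = 0} (zero spontaneous curvature), intra-rod pairs use
#' the stiffened rod coefficients and \eqn{C_{bd} = 2 C_{rod}\sigma}, the
#' mapping through which the rod curvature is imposed.
#'
#' @param state a \code{ParticleState} (orientations must be unit vectors).
#' @param box a \code{SimulationBox}.
#' @param mp a \code{MembraneParams}.
#' @param rodSpec optional \code{RodSpec} supplying the intra-rod pair
#'   parameters.
#' @return List with \code{uBend}, \code{uTilt} (kBT), \code{posGrad} and
#'   \code{orientGrad} (N x 3 gradients of \code{uBend + uTilt}; orientation
#'   gradients are projected tangent to the unit sphere).
#' @examples
#' fx <- makeFixture("flat_patch_100", seed = 1)
#' bendTiltEnergy(fx$state, fx$box, membraneParams())$uBend
#' @export
bendTiltEnergy <- function(state, box, mp, rodSpec = NULL) {
  .checkUnitOrient(state)
  r <- .callForces(state, box, mp, rodSpec, flags = .F_BT)
  list(uBend = r$energy[3], uTilt = r$energy[4],
       posGrad = -r$force, orientGrad = r$ugrad)
}

#' Repulsion and multibody attraction energy
#'
#' Excluded-volume repulsion of diameter sigma plus the implicit-solvent
#' attraction, a saturating function of each particle's local density
#' \eqn{\rho_i = \sum_j f_\rho(r_{ij})}: attraction grows linearly with
#' density and saturates above \code{rhoStar}, which makes the assembled
#' membrane fluid and nearly tensionless at its preferred density.  Hook
#' particles participate in the repulsion only.
#'
#' @inheritParams bendTiltEnergy
#' @return List with \code{uRep}, \code{uAtt}, \code{posGrad} (gradient of
#'   the sum) and the per-particle densities \code{rho}.
#' @export
repulsionAttractionEnergy <- function(state, box, mp, rodSpec = NULL) {
  r <- .callForces(state, box, mp, rodSpec, flags = .F_REP + .F_ATT)
  list(uRep = r$energy[1], uAtt = r$energy[2], posGrad = -r$force,
       rho = r$rho)
}

#' Rod internal energy
#'
#' Energy holding each rod together: harmonic backbone bonds, the
#' 3x-stiffened triangle bonds and site restraints anchoring the hook
#' particles on their handed side, and the intra-rod bending/tilt terms
#' (coefficients 80) whose per-pair curvature parameter imposes the
#' spontaneous curvature \code{cRod} along the backbone.
#'
#' @inheritParams bendTiltEnergy
#' @param rodSpec a \code{RodSpec} (required).
#' @return List with \code{uBond} (bonds + hook anchoring), \code{uBend},
#'   \code{uTilt} (intra-rod only), \code{total}, \code{posGrad} and
#'   \code{orientGrad}.
#' @export
rodInternalEnergy <- function(state, box, mp, rodSpec) {
  if (is.null(rodSpec)) stop("rodSpec is required")
  .checkUnitOrient(state)
  ## zero the membrane coefficients so bend/tilt picks up intra-rod pairs only
  par <- .packParams(mp, rodSpec)
  par[9] <- 0; par[10] <- 0
  r <- .callForces(state, box, mp, rodSpec, flags = .F_BT + .F_BOND,
                   parOverride = par)
  list(uBond = r$energy[5], uBend = r$energy[3], uTilt = r$energy[4],
       total = r$energy[5] + r$energy[3] + r$energy[4],
       posGrad = -r$force, orientGrad = r$ugrad)
}

#' Side-to-side Lennard-Jones attraction between rods
#'
#' When \code{epsilonSS > 0}, the excluded-volume repulsion between the
#' attraction-segment particles (2nd and 3rd from both rod ends) of
#' \emph{different} rods is replaced by the Lennard-Jones potential
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} (smoothly switched off
#' between 2.5 and 3 sigma).  Intra-rod pairs are excluded.
#'
#' @inheritParams rodInternalEnergy
#' @return List with \code{uLj} and \code{posGrad}.
#' @export
sideAttractionEnergy <- function(state, box, mp, rodSpec) {
  if (is.null(rodSpec)) stop("rodSpec is required")
  if (rodSpec@epsilonSS <= 0)
    return(list(uLj = 0, posGrad = matrix(0, nrow(state@pos), 3)))
  r <- .callForces(state, box, mp, rodSpec, flags = .F_LJ)
  list(uLj = r$energy[6], posGrad = -r$force)
}

#' Total potential energy
#'
#' @inheritParams bendTiltEnergy
#' @return An \code{\link{EnergyBreakdown-class}} object.
#' @examples
#' fx <- makeFixture("flat_patch_100", seed = 1)
#' totalEnergy(fx$state, fx$box, membraneParams())
#' @export
totalEnergy <- function(state, box, mp, rodSpec = NULL) {
  .checkUnitOrient(state)
  r <- .callForces(state, box, mp, rodSpec, flags = .F_ALL)
  e <- r$energy
  new("EnergyBreakdown", uRep = e[1], uAtt = e[2], uBend = e[3],
      uTilt = e[4], uRodBond = e[5], uLj = e[6], total = sum(e[1:6]))
}

#' Total forces and orientation gradients
#'
#' @inheritParams bendTiltEnergy
#' @return List with \code{force} (N x 3), \code{orientGrad} (N x 3,
#'   projected), \code{energy} (named numeric of the six components) and the
#'   in-plane virial diagonal \code{virial}.
#' @export
totalForces <- function(state, box, mp, rodSpec = NULL) {
  r <- .callForces(state, box, mp, rodSpec, flags = .F_ALL)
  names(r$energy) <- c("uRep", "uAtt", "uBend", "uTilt", "uRodBond", "uLj",
                       "uZConf")
  list(force = r$force, orientGrad = r$ugrad, energy = r$energy,
       virial = r$virial)
}

## intra-rod bend energy at a given rod curvature (REMD exchange helper)
.rodBendEnergy <- function(state, box, mp, rodSpec, cRod) {
  par <- .packParams(mp, rodSpec)
  par[16] <- 2 * cRod
  r <- .callForces(state, box, mp, rodSpec, flags = .F_RODBEND,
                   parOverride = par)
  r$energy[3]
}
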