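#' @include AllGenerics.R
NULL

.KINDS <- c("membrane", "rod_backbone", "rod_hook")
.TOPOLOGIES <- c("tube", "flat")
.CHIRALITIES <- c("achiral_plain", "achiral_hooked", "chiral")

#' Simulation cell
#'
#' Periodic cell for the two geometries of the model: a membrane \emph{tube}
#' (periodic along z only, open radially) and a \emph{flat} patch (periodic
#' along x and y, open along z).  Lengths are in units of the particle
#' diameter sigma.
#'
#' @slot lengths numeric(3), cell lengths (Lx, Ly, Lz) in sigma.
#' @slot topology \code{"tube"} or \code{"flat"}.
#' @export
setClass("SimulationBox",
  representation(lengths = "numeric", topology = "character"))

setValidity("SimulationBox", function(object) {
  msg <- NULL
  if (length(object@lengths) != 3 || any(!is.finite(object@lengths)) ||
      any(object@lengths <= 0))
    msg <- c(msg, "lengths must be 3 positive finite numbers")
  if (length(object@topology) != 1 || !object@topology %in% .TOPOLOGIES)
    msg <- c(msg, "topology must be 'tube' or 'flat'")
  if (is.null(msg)) TRUE else msg
})

#' @param lengths numeric(3) cell lengths in sigma.
#' @param topology \code{"tube"} (periodic z) or \code{"flat"} (periodic x, y).
#' @return A \code{SimulationBox}.
#' @rdname SimulationBox-class
#' @examples
#' simulationBox(c(30, 30, 60), "tube")
#' @export
simulationBox <- function(lengths, topology = c("flat", "tube")) {
  topology <- match.arg(topology)
  new("SimulationBox", lengths = as.numeric(lengths), topology = topology)
}

#' Particle configuration
#'
#' Positions, unit orientation vectors and bookkeeping labels for all
#' particles of a membrane/rod system, plus translational and angular
#' velocities (zero for freshly built states).  \code{hookSide} carries the
#' signed lateral placement of each hook particle (+1 / -1 relative to the
#' local binormal; 0 for non-hooks); mirroring a configuration and rebuilding
#' its hooks with the opposite handedness corresponds to flipping this sign.
#'
#' @slot pos N x 3 matrix of positions (sigma).
#' @slot orient N x 3 matrix of orientation vectors (unit norm).
#' @slot kind character vector, one of \code{"membrane"},
#'   \code{"rod_backbone"}, \code{"rod_hook"}.
#' @slot rodId integer vector, rod index (0-based) or -1.
#' @slot segmentIndex integer vector, 0..9 along the backbone, -1 otherwise.
#' @slot hookSide numeric vector, +/-1 for hooks, 0 otherwise.
#' @slot vel,avel N x 3 velocity and angular-velocity matrices.
#' @export
setClass("ParticleState",
  representation(pos = "matrix", orient = "matrix", kind = "character",
                 rodId = "integer", segmentIndex = "integer",
                 hookSide = "numeric", vel = "matrix", avel = "matrix"))

setValidity("ParticleState", function(object) {
  n <- nrow(object@pos)
  msg <- NULL
  if (ncol(object@pos) != 3) msg <- c(msg, "pos must be N x 3")
  if (!all(dim(object@orient) == c(n, 3))) msg <- c(msg, "orient must be N x 3")
  if (length(object@kind) != n) msg <- c(msg, "kind length mismatch")
  if (!all(object@kind %in% .KINDS))
    msg <- c(msg, "kind labels must be membrane/rod_backbone/rod_hook")
  if (length(object@rodId) != n) msg <- c(msg, "rodId length mismatch")
  if (length(object@segmentIndex) != n) msg <- c(msg, "segmentIndex length mismatch")
  if (length(object@hookSide) != n) msg <- c(msg, "hookSide length mismatch")
  if (!all(dim(object@vel) == c(n, 3))) msg <- c(msg, "vel must be N x 3")
  if (!all(dim(object@avel) == c(n, 3))) msg <- c(msg, "avel must be N x 3")
  if (any(object@kind == "rod_hook" & object@rodId < 0))
    msg <- c(msg, "rod_hook particles must belong to a rod")
  if (is.null(msg)) TRUE else msg
})

#' @param pos,orient N x 3 matrices (orientations should be unit vectors).
#' @param kind,rodId,segmentIndex,hookSide per-particle labels (recycled
#'   defaults describe a plain membrane).
#' @param vel,avel optional velocity matrices (default zero).
#' @return A \code{ParticleState}.
#' @rdname ParticleState-class
#' @export
particleState <- function(pos, orient, kind = "membrane", rodId = -1L,
                          segmentIndex = -1L, hookSide = 0,
                          vel = NULL, avel = NULL) {
  pos <- as.matrix(pos); orient <- as.matrix(orient)
  dimnames(pos) <- NULL; dimnames(orient) <- NULL
  n <- nrow(pos)
  zero <- matrix(0, n, 3)
  new("ParticleState", pos = pos, orient = orient,
      kind = rep_len(as.character(kind), n),
      rodId = rep_len(as.integer(rodId), n),
      segmentIndex = rep_len(as.integer(segmentIndex), n),
      hookSide = rep_len(as.numeric(hookSide), n),
      vel = if (is.null(vel)) zero else as.matrix(vel),
      avel = if (is.null(avel)) zero else as.matrix(avel))
}

#' Membrane interaction parameters
#'
#' Coefficients of the meshless-membrane potential
#' \eqn{U = U_{rep} + U_{att} + U_{bend} + U_{tilt}}.  The excluded-volume
#' repulsion is \eqn{\epsilon_{rep} e^{-b(r-1)}} with a smooth compact
#' cutoff, the implicit-solvent attraction is the saturating multibody well
#' \eqn{\epsilon_{att}[0.25\ln(1+e^{-4(\rho_i-\rho^*)}) - c_0]} of the local
#' density \eqn{\rho_i}, and the bending/tilt pair potentials are weighted by
#' the compact Gaussian-like \eqn{w_{cv}(r)}.  Defaults are the shipped
#' calibrated set reproducing the target elastic constants (bending rigidity
#' kappa = 15 kBT, area per particle a0 = 1.2778 sigma^2, area compression
#' modulus K_A = 83.1 kBT/sigma^2, edge line tension Gamma = 5.73 kBT/sigma).
#'
#' @slot kBend,kTilt dimensionless bending and tilt coefficients (membrane
#'   pairs; the paper's value 10).
#' @slot cbd spontaneous-curvature bond parameter of the free membrane
#'   (1/sigma; 0 here, i.e. zero spontaneous curvature).
#' @slot epsRep,bRep,sRepCut,aRep repulsion strength, steepness, cutoff and
#'   cutoff-smoothness parameters.
#' @slot epsAtt,rhoStar,sRhoCut,aRho attraction strength, saturation density,
#'   density-weight cutoff and smoothness.
#' @slot attSharp sharpness of the attraction's saturation knee (the
#'   density-compressibility dial).
#' @slot alphaCv,rGa,rCc amplitude, Gaussian width and cutoff of w_cv.
#' @slot zConf optional flat-plane confinement spring (kBT/sigma^2; a
#'   measurement scaffold holding strips flat during edge-tension runs, 0
#'   in production).
#' @slot kT thermal energy (fixed unit, 1).
#' @slot mass,inertia particle mass and orientational inertia (units where
#'   sigma = kBT = mass = 1).
#' @export
setClass("MembraneParams",
  representation(kBend = "numeric", kTilt = "numeric", cbd = "numeric",
                 epsRep = "numeric", bRep = "numeric", sRepCut = "numeric",
                 aRep = "numeric",
                 epsAtt = "numeric", rhoStar = "numeric", sRhoCut = "numeric",
                 aRho = "numeric", attSharp = "numeric",
                 alphaCv = "numeric", rGa = "numeric", rCc = "numeric",
                 zConf = "numeric",
                 kT = "numeric", mass = "numeric", inertia = "numeric"))

setValidity("MembraneParams", function(object) {
  msg <- NULL
  if (object@kBend < 0 || object@kTilt < 0)
    msg <- c(msg, "kBend and kTilt must be >= 0")
  if (object@rCc <= 1)
    msg <- c(msg, "w_cv cutoff rCc must exceed the particle diameter")
  if (object@kT < 0) msg <- c(msg, "kT must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Crescent protein-rod specification
#'
#' Geometry, stiffness and interaction parameters of a crescent-shaped
#' protein rod: 10 membrane particles linearly connected by harmonic bonds
#' (rod length 10 sigma), stiffened bending/tilt coefficients (80), and a
#' spontaneous curvature \code{cRod} along the rod axis imposed through the
#' per-pair curvature parameter C_bd = 2 C_rod sigma of intra-rod pairs.
#' Chiral rods carry two hook particles placed right-handedly (opposite
#' lateral sides at the two ends); \code{"achiral_hooked"} places both hooks
#' on the same side; \code{"achiral_plain"} has none.  Hooks interact through
#' excluded volume only and are anchored by the triangle bonds (3x bond
#' coefficient) plus a harmonic site restraint to the handed rest position,
#' which penalises a flip to the opposite side.
#'
#' @slot nBackbone integer, backbone particles per rod (10).
#' @slot rodLength numeric, rod length in sigma (10).
#' @slot cRod numeric, spontaneous curvature along the rod axis (1/sigma).
#' @slot chirality one of \code{"achiral_plain"}, \code{"achiral_hooked"},
#'   \code{"chiral"}.
#' @slot kBendRod,kTiltRod rod bending/tilt coefficients (80).
#' @slot bondK harmonic bond coefficient (kBT/sigma^2).
#' @slot triangleBondFactor stiffening factor of the hook triangle bonds (3).
#' @slot siteK hook site-restraint coefficient (kBT/sigma^2).
#' @slot epsilonSS side-to-side Lennard-Jones depth epsilon (kBT; 0 disables).
#' @slot attractionSegments 0-based segment indices carrying the LJ
#'   attraction (2nd and 3rd particles from both ends: 1, 2, 7, 8).
#' @slot hookLateral,hookNormal lateral (binormal) and normal components of
#'   the hook offset from the anchor midpoint (sigma).
#' @export
setClass("RodSpec",
  representation(nBackbone = "integer", rodLength = "numeric",
                 cRod = "numeric", chirality = "character",
                 kBendRod = "numeric", kTiltRod = "numeric",
                 bondK = "numeric", triangleBondFactor = "numeric",
                 siteK = "numeric", epsilonSS = "numeric",
                 attractionSegments = "integer",
                 hookLateral = "numeric", hookNormal = "numeric"))

setValidity("RodSpec", function(object) {
  msg <- NULL
  if (object@nBackbone < 2) msg <- c(msg, "need at least 2 backbone particles")
  if (!object@chirality %in% .CHIRALITIES)
    msg <- c(msg, "chirality must be achiral_plain/achiral_hooked/chiral")
  if (object@triangleBondFactor < 1) msg <- c(msg, "triangleBondFactor must be >= 1")
  if (object@epsilonSS < 0) msg <- c(msg, "epsilonSS must be >= 0")
  if (object@rodLength <= 0) msg <- c(msg, "rodLength must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Energy breakdown
#'
#' Components of the total potential energy in kBT: membrane repulsion and
#' attraction, bending and tilt (membrane and intra-rod), rod bond energy
#' (backbone bonds, hook triangle bonds and hook site restraints) and
#' inter-rod Lennard-Jones side attraction.
#'
#' @slot uRep,uAtt,uBend,uTilt,uRodBond,uLj,total numeric scalars (kBT).
#' @export
setClass("EnergyBreakdown",
  representation(uRep = "numeric", uAtt = "numeric", uBend = "numeric",
                 uTilt = "numeric", uRodBond = "numeric", uLj = "numeric",
                 total = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  s <- object@uRep + object@uAtt + object@uBend + object@uTilt +
    object@uRodBond + object@uLj
  tol <- 1e-10 * max(1, abs(s))
  if (abs(s - object@total) > tol) "total must equal the component sum" else TRUE
})

#' Trajectory of a simulation run
#'
#' Time-ordered configuration frames with per-frame boxes (the box area can
#' change under the zero-tension ensemble) and run metadata (seed, rod
#' curvature, particle number, topology, parameter-switch times, ...).
#'
#' @slot frames list of \code{ParticleState}.
#' @slot times numeric, frame times (strictly increasing, simulation units).
#' @slot boxes list of \code{SimulationBox}, one per frame.
#' @slot metadata named list.
#' @export
setClass("Trajectory",
  representation(frames = "list", times = "numeric", boxes = "list",
                 metadata = "list"))

setValidity("Trajectory", function(object) {
  msg <- NULL
  nf <- length(object@frames)
  if (length(object@times) != nf) msg <- c(msg, "times length mismatch")
  if (length(object@boxes) != nf) msg <- c(msg, "boxes length mismatch")
  if (nf > 1) {
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
    ns <- vapply(object@frames, function(f) nrow(f@pos), integer(1))
    if (length(unique(ns)) > 1)
      msg <- c(msg, "particle number must be constant across frames")
  }
  if (is.null(msg)) TRUE else msg
})

#' Fourier mode amplitudes of a membrane tube
#'
#' Lowest Fourier modes of the membrane shape (all non-hook particles) and
#' the rod density (backbone particles), along the tube axis (qz) and the
#' azimuthal direction (qtheta):
#' \eqn{r_{qz} = (1/N)\sum_i r_{2D,i} e^{-2\pi i z_i/L_z}} and
#' \eqn{r_{q\theta} = (1/N)\sum_i r_{2D,i} e^{-2 i \theta_i}} with
#' \eqn{r_{2D,i}^2 = x_i^2+y_i^2} and \eqn{\theta_i} the azimuth.
#'
#' @slot rQz,rQtheta complex shape-mode amplitudes (sigma).
#' @slot nQz,nQtheta complex rod-density-mode amplitudes (sigma).
#' @slot reference named numeric, optional normalisation amplitudes from a
#'   zero-curvature reference run (the starred quantities).
#' @export
setClass("ModeAmplitudes",
  representation(rQz = "complex", rQtheta = "complex",
                 nQz = "complex", nQtheta = "complex",
                 reference = "numeric"))

#' Helical-assembly radius fit
#'
#' @slot rHel numeric, mean projected radial distance of rod backbone
#'   particles in the central axial slice (sigma).
#' @slot sliceBounds numeric(2), axial slice limits (sigma).
#' @slot nSl integer, number of particles used.
#' @slot residual numeric, standard deviation of the radial distances.
#' @export
setClass("HelixFit",
  representation(rHel = "numeric", sliceBounds = "numeric", nSl = "integer",
                 residual = "numeric"))

setValidity("HelixFit", function(object) {
  msg <- NULL
  if (object@rHel <= 0) msg <- c(msg, "rHel must be positive")
  if (object@nSl < 3) msg <- c(msg, "need at least 3 particles in the slice")
  if (is.null(msg)) TRUE else msg
})

#' Emergent elastic constants of the membrane
#'
#' @slot kappa,kappaSe bending rigidity (kBT) and its standard error.
#' @slot a0,a0Se area per particle of the tensionless membrane (sigma^2).
#' @slot KA,KASe area compression modulus (kBT/sigma^2).
#' @slot gamma,gammaSe edge line tension (kBT/sigma).
#' @slot D,DSe membrane-particle diffusion coefficient (sigma^2/time).
#' @slot runInfo list, run parameters behind each estimate.
#' @export
setClass("ElasticReport",
  representation(kappa = "numeric", kappaSe = "numeric",
                 a0 = "numeric", a0Se = "numeric",
                 KA = "numeric", KASe = "numeric",
                 gamma = "numeric", gammaSe = "numeric",
                 D = "numeric", DSe = "numeric",
                 runInfo = "list"))

#' Replica ladder for curvature replica exchange
#'
#' @slot cRodValues numeric, ordered (non-decreasing) rod curvatures
#'   (1/sigma); equal values are allowed (their swaps always accept).
#' @slot exchangeEvery integer, MD steps between exchange attempts.
#' @slot seeds integer, per-replica RNG seeds.
#' @slot stats list, exchange statistics (filled by \code{runREMD}).
#' @export
setClass("ReplicaLadder",
  representation(cRodValues = "numeric", exchangeEvery = "integer",
                 seeds = "integer", stats = "list"))

setValidity("ReplicaLadder", function(object) {
  msg <- NULL
  if (length(object@cRodValues) < 1) msg <- c(msg, "need at least one replica")
  if (length(object@cRodValues) > 1 && any(diff(object@cRodValues) < 0))
    msg <- c(msg, "cRodValues must be non-decreasing")
  if (length(object@seeds) != length(object@cRodValues))
    msg <- c(msg, "one seed per replica required")
  if (is.null(msg)) TRUE else msg
})

#' @param cRodValues strictly increasing rod curvatures (1/sigma).
#' @param exchangeEvery MD steps between exchange attempts.
#' @param seeds optional per-replica seeds (derived from \code{baseSeed} if
#'   omitted).
#' @param baseSeed integer used to derive per-replica seeds.
#' @return A \code{ReplicaLadder}.
#' @rdname ReplicaLadder-class
#' @export
replicaLadder <- function(cRodValues, exchangeEvery = 500L, seeds = NULL,
                          baseSeed = 1L) {
  if (is.null(seeds))
    seeds <- as.integer((baseSeed + 7919L * seq_along(cRodValues)) %% .Machine$integer.max)
  new("ReplicaLadder", cRodValues = as.numeric(cRodValues),
      exchangeEvery = as.integer(exchangeEvery), seeds = as.integer(seeds),
      stats = list())
}

#' Run configuration
#'
#' Validated configuration of a single experiment (see
#' \code{\link{loadRunConfig}}).
#'
#' @slot experiment one of tube, tube_remd, flat, tubulate, calibrate, analyze.
#' @slot opts named list of validated fields.
#' @export
setClass("RunConfig",
  representation(experiment = "character", opts = "list"))

## ---- show methods ----

setMethod("show", "SimulationBox", function(object) {
  cat(sprintf("SimulationBox: %s topology, L = (%.4g, %.4g, %.4g) sigma\n",
              object@topology, object@lengths[1], object@lengths[2],
              object@lengths[3]))
})

setMethod("show", "ParticleState", function(object) {
  n <- nrow(object@pos)
  nrod <- length(unique(object@rodId[object@rodId >= 0]))
  cat(sprintf("ParticleState: %d particles (%d membrane, %d backbone, %d hook), %d rods\n",
              n, sum(object@kind == "membrane"),
              sum(object@kind == "rod_backbone"),
              sum(object@kind == "rod_hook"), nrod))
})

setMethod("show", "MembraneParams", function(object) {
  cat("MembraneParams (meshless membrane, units sigma = kBT = 1):\n")
  cat(sprintf("  bend/tilt: k_bend = %g, k_tilt = %g, C_bd = %g; w_cv: alpha = %.4g, r_ga = %.4g, r_cc = %g\n",
              object@kBend, object@kTilt, object@cbd, object@alphaCv,
              object@rGa, object@rCc))
  cat(sprintf("  repulsion: eps = %.4g, b = %g, cutoff = %g; attraction: eps = %.4g, rho* = %.4g, cutoff = %g\n",
              object@epsRep, object@bRep, object@sRepCut, object@epsAtt,
              object@rhoStar, object@sRhoCut))
})

setMethod("show", "RodSpec", function(object) {
  cat(sprintf("RodSpec: %d-particle %s rod, C_rod*r_rod = %.3g, k = %g, eps_ss = %g kBT\n",
              object@nBackbone, object@chirality,
              object@cRod * object@rodLength, object@kBendRod,
              object@epsilonSS))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("EnergyBreakdown (kBT):\n")
  cat(sprintf("  rep %.6g | att %.6g | bend %.6g | tilt %.6g | rod-bond %.6g | LJ %.6g\n",
              object@uRep, object@uAtt, object@uBend, object@uTilt,
              object@uRodBond, object@uLj))
  cat(sprintf("  total %.6g\n", object@total))
})

setMethod("show", "Trajectory", function(object) {
  nf <- length(object@frames)
  cat(sprintf("Trajectory: %d frames", nf))
  if (nf > 0)
    cat(sprintf(", t = %.4g .. %.4g, N = %d", object@times[1],
                object@times[nf], nrow(object@frames[[1]]@pos)))
  cat("\n")
})

setMethod("show", "ElasticReport", function(object) {
  cat("ElasticReport:\n")
  cat(sprintf("  kappa/kBT        = %.4g +/- %.2g\n", object@kappa, object@kappaSe))
  cat(sprintf("  a0/sigma^2       = %.6g +/- %.2g\n", object@a0, object@a0Se))
  cat(sprintf("  K_A sigma^2/kBT  = %.4g +/- %.2g\n", object@KA, object@KASe))
  cat(sprintf("  Gamma sigma/kBT  = %.4g +/- %.2g\n", object@gamma, object@gammaSe))
  if (length(object@D) && is.finite(object@D))
    cat(sprintf("  D sigma^2/t, tau = %.4g, %.4g\n", object@D, 100 / object@D))
})

setMethod("show", "HelixFit", function(object) {
  cat(sprintf("HelixFit: R_hel = %.4g sigma (N_sl = %d, residual %.3g)\n",
              object@rHel, object@nSl, object@residual))
})

setMethod("show", "ModeAmplitudes", function(object) {
  cat(sprintf("ModeAmplitudes: |r_qz| = %.4g, |r_qtheta| = %.4g, |n_qz| = %.4g, |n_qtheta| = %.4g\n",
              Mod(object@rQz), Mod(object@rQtheta), Mod(object@nQz),
              Mod(object@nQtheta)))
})

## ---- accessors ----

#' @rdname accessors
setMethod("positions", "ParticleState", function(x) x@pos)

#' @rdname accessors
setMethod("positions<-", "ParticleState", function(x, value) {
  x@pos <- as.matrix(value); validObject(x); x
})

#' @rdname accessors
setMethod("orientations", "ParticleState", function(x) x@orient)

#' @rdname accessors
setMethod("orientations<-", "ParticleState", function(x, value) {
  x@orient <- as.matrix(value); validObject(x); x
})

#' @rdname accessors
setMethod("particleKind", "ParticleState", function(x) x@kind)

#' @rdname accessors
setMethod("rodIds", "ParticleState", function(x) x@rodId)

#' @rdname accessors
setMethod("segmentIndex", "ParticleState", function(x) x@segmentIndex)

#' @rdname accessors
setMethod("nParticles", "ParticleState", function(x) nrow(x@pos))

#' @rdname accessors
setMethod("boxLengths", "SimulationBox", function(x) x@lengths)

#' @rdname accessors
setMethod("topologyType", "SimulationBox", function(x) x@topology)

#' @rdname accessors
setMethod("periodicDims", "SimulationBox", function(x) {
  if (x@topology == "tube") c(FALSE, FALSE, TRUE) else c(TRUE, TRUE, FALSE)
})

#' @rdname trajectory-accessors
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' @rdname trajectory-accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname trajectory-accessors
setMethod("getFrame", "Trajectory", function(x, i) x@frames[[i]])

#' @rdname trajectory-accessors
setMethod("frameBox", "Trajectory", function(x, i) x@boxes[[i]])

#' @rdname trajectory-accessors
setMethod("trajMetadata", "Trajectory", function(x) x@metadata)
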