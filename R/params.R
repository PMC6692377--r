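#' @include AllClasses.R
NULL

## Lennard-Jones cutoff and switch-on radii for the side-to-side attraction
.LJ_CUT <- 3.0
.LJ_ON <- 2.5

## smoothness parameter A of f(s) = exp[A(1 + 1/(s^12 - 1))] such that
## f(sHalf/sCut) = 1/2
.acut <- function(sHalf, sCut, n = 12) {
  x <- (sHalf / sCut)^n
  log(2) * (1 - x) / x
}

.paramEnv <- new.env(parent = emptyenv())

#' Shipped calibrated parameter set
#'
#' Reads the canonical calibrated coefficient file shipped with the package
#' (\code{inst/extdata/calibrated_params.json}).  These are the coefficients
#' the calibration suite settled on so that the membrane reproduces the
#' target elastic constants; \code{\link{membraneParams}} uses them as
#' defaults.
#'
#' @return Named list of coefficients.
#' @examples
#' str(calibratedDefaults())
#' @export
calibratedDefaults <- function() {
  if (is.null(.paramEnv$defaults)) {
    path <- system.file("extdata", "calibrated_params.json", package = "memrod")
    .paramEnv$defaults <- jsonlite::fromJSON(path)
  }
  .paramEnv$defaults
}

#' @param kBend,kTilt,cbd,epsRep,bRep,sRepCut,epsAtt,rhoStar,attSharp,alphaCv,rGa,rCc,kT,mass,inertia
#'   see the class slots; defaults come from \code{\link{calibratedDefaults}}.
#' @param sRepHalf,sRhoHalf,sRhoCut radii at which the repulsion/density
#'   cutoff functions reach one half, and the density cutoff.
#' @return A \code{MembraneParams}.
#' @rdname MembraneParams-class
#' @examples
#' membraneParams()
#' @export
membraneParams <- function(kBend = NULL, kTilt = NULL, cbd = 0,
                           epsRep = NULL, bRep = NULL, sRepCut = NULL,
                           sRepHalf = NULL, epsAtt = NULL, rhoStar = NULL,
                           attSharp = NULL,
                           sRhoCut = NULL, sRhoHalf = NULL, alphaCv = NULL,
                           rGa = NULL, rCc = NULL, zConf = 0, kT = 1,
                           mass = 1, inertia = 1) {
  d <- calibratedDefaults()
  pick <- function(x, nm) if (is.null(x)) d[[nm]] else x
  sRepCut <- pick(sRepCut, "sRepCut"); sRepHalf <- pick(sRepHalf, "sRepHalf")
  sRhoCut <- pick(sRhoCut, "sRhoCut"); sRhoHalf <- pick(sRhoHalf, "sRhoHalf")
  new("MembraneParams",
      kBend = pick(kBend, "kBend"), kTilt = pick(kTilt, "kTilt"),
      cbd = cbd,
      epsRep = pick(epsRep, "epsRep"), bRep = pick(bRep, "bRep"),
      sRepCut = sRepCut, aRep = .acut(sRepHalf, sRepCut),
      epsAtt = pick(epsAtt, "epsAtt"), rhoStar = pick(rhoStar, "rhoStar"),
      attSharp = pick(attSharp, "attSharp"),
      sRhoCut = sRhoCut, aRho = .acut(sRhoHalf, sRhoCut),
      alphaCv = pick(alphaCv, "alphaCv"), rGa = pick(rGa, "rGa"),
      rCc = pick(rCc, "rCc"), zConf = zConf,
      kT = kT, mass = mass, inertia = inertia)
}

#' @param cRod spontaneous curvature along the rod axis (1/sigma).  The
#'   dimensionless product is \code{cRod * rodLength}.
#' @param chirality \code{"chiral"}, \code{"achiral_hooked"} or
#'   \code{"achiral_plain"}.
#' @param epsilonSS side-to-side LJ depth in kBT (0 disables).
#' @param nBackbone,rodLength,kBendRod,kTiltRod,bondK,triangleBondFactor,siteK,attractionSegments,hookLateral,hookNormal
#'   see the class slots.
#' @return A \code{RodSpec}.
#' @rdname RodSpec-class
#' @examples
#' rodSpec(cRod = 0.3, chirality = "chiral")
#' @export
rodSpec <- function(cRod = 0, chirality = c("chiral", "achiral_hooked",
                                            "achiral_plain"),
                    epsilonSS = 0, nBackbone = 10L, rodLength = 10,
                    kBendRod = 80, kTiltRod = 80, bondK = 2000,
                    triangleBondFactor = 3, siteK = 300,
                    attractionSegments = NULL,
                    hookLateral = NULL, hookNormal = NULL) {
  chirality <- match.arg(chirality)
  nBackbone <- as.integer(nBackbone)
  l0 <- rodLength / (nBackbone - 1)
  if (is.null(attractionSegments))
    attractionSegments <- c(1L, 2L, nBackbone - 3L, nBackbone - 2L)
  ## hook at bond length from both anchors, offset split equally between the
  ## lateral (binormal) and normal directions
  h <- l0 * sqrt(3) / 2 / sqrt(2)
  new("RodSpec", nBackbone = nBackbone, rodLength = rodLength,
      cRod = cRod, chirality = chirality,
      kBendRod = kBendRod, kTiltRod = kTiltRod, bondK = bondK,
      triangleBondFactor = triangleBondFactor, siteK = siteK,
      epsilonSS = epsilonSS,
      attractionSegments = as.integer(attractionSegments),
      hookLateral = if (is.null(hookLateral)) h else hookLateral,
      hookNormal = if (is.null(hookNormal)) h else hookNormal)
}

#' Rest bond length of a rod backbone
#' @param spec a \code{RodSpec}.
#' @return Bond rest length in sigma.
#' @export
rodBondLength <- function(spec) spec@rodLength / (spec@nBackbone - 1)

## ---- internal packing for the C core ----

.kindCode <- function(kind) {
  match(kind, .KINDS) - 1L
}

## parameter vector in the fixed order expected by the C core
.packParams <- function(mp, rs = NULL) {
  cbdRod <- if (is.null(rs)) 0 else 2 * rs@cRod
  c(mp@epsRep, mp@bRep, mp@sRepCut, mp@aRep,
    mp@epsAtt, mp@rhoStar, mp@aRho, mp@sRhoCut,
    mp@kBend, mp@kTilt, mp@alphaCv, mp@rGa, mp@rCc,
    if (is.null(rs)) mp@kBend else rs@kBendRod,
    if (is.null(rs)) mp@kTilt else rs@kTiltRod,
    cbdRod,
    if (is.null(rs)) 0 else rs@siteK,
    if (is.null(rs)) 0 else rs@epsilonSS,
    .LJ_CUT, .LJ_ON,
    mp@kT, mp@mass, mp@inertia,
    mp@attSharp, mp@zConf)
}

## bond and hook-site tables of a state given the rod spec
.rodTables <- function(state, rs) {
  bonds <- list(i = integer(0), j = integer(0), k = numeric(0), l0 = numeric(0))
  sites <- list(hook = integer(0), a1 = integer(0), a2 = integer(0),
                clat = numeric(0), cup = numeric(0))
  if (is.null(rs)) return(list(bonds = bonds, sites = sites))
  l0 <- rodBondLength(rs)
  nb <- rs@nBackbone
  for (r in sort(unique(state@rodId[state@rodId >= 0]))) {
    bb <- which(state@rodId == r & state@kind == "rod_backbone")
    bb <- bb[order(state@segmentIndex[bb])]
    if (length(bb) != nb)
      stop("rod ", r, " is incomplete: ", length(bb), " backbone particles")
    hooks <- which(state@rodId == r & state@kind == "rod_hook")
    kvec <- rep(rs@bondK, nb - 1)
    if (length(hooks) > 0) {
      kvec[1] <- rs@bondK * rs@triangleBondFactor
      kvec[nb - 1] <- rs@bondK * rs@triangleBondFactor
    }
    bonds$i <- c(bonds$i, bb[-nb]); bonds$j <- c(bonds$j, bb[-1])
    bonds$k <- c(bonds$k, kvec); bonds$l0 <- c(bonds$l0, rep(l0, nb - 1))
    if (length(hooks) > 0) {
      if (length(hooks) != 2)
        stop("rod ", r, " must carry exactly 0 or 2 hook particles")
      hooks <- sort(hooks)  # first = head (segments 0,1), second = tail
      anchors <- list(c(bb[1], bb[2]), c(bb[nb - 1], bb[nb]))
      for (hh in 1:2) {
        h <- hooks[hh]; a <- anchors[[hh]]
        bonds$i <- c(bonds$i, h, h); bonds$j <- c(bonds$j, a[1], a[2])
        bonds$k <- c(bonds$k, rep(rs@bondK * rs@triangleBondFactor, 2))
        bonds$l0 <- c(bonds$l0, rep(l0, 2))
        sites$hook <- c(sites$hook, h)
        sites$a1 <- c(sites$a1, a[1]); sites$a2 <- c(sites$a2, a[2])
        sites$clat <- c(sites$clat, state@hookSide[h] * rs@hookLateral)
        sites$cup <- c(sites$cup, rs@hookNormal)
      }
    }
  }
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  sites$hook <- as.integer(sites$hook)
  sites$a1 <- as.integer(sites$a1); sites$a2 <- as.integer(sites$a2)
  list(bonds = bonds, sites = sites)
}

.packSys <- function(state, box, rs = NULL) {
  tb <- .rodTables(state, rs)
  att <- as.integer(state@kind == "rod_backbone" &
                    !is.null(rs) &
                    state@segmentIndex %in% (if (is.null(rs)) integer(0)
                                             else rs@attractionSegments))
  list(pos = state@pos, orient = state@orient,
       kind = .kindCode(state@kind), rod = state@rodId,
       seg = state@segmentIndex, att = att,
       L = boxLengths(box), per = as.integer(periodicDims(box)),
       bonds = tb$bonds, sites = tb$sites,
       vel = state@vel, avel = state@avel)
}
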