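#' Accessor generics
#'
#' Small accessor API shared by the particle-configuration classes:
#' \code{positions}/\code{orientations} return N x 3 matrices,
#' \code{particleKind} the per-particle label (\code{"membrane"},
#' \code{"rod_backbone"}, \code{"rod_hook"}), \code{rodIds} the rod index of
#' each particle (-1 for free membrane particles), \code{segmentIndex} the
#' position of a backbone particle along its rod (0-based, -1 otherwise) and
#' \code{nParticles} the particle count.  \code{boxLengths},
#' \code{topologyType} and \code{periodicDims} describe the simulation cell.
#'
#' @param x object.
#' @param value replacement value.
#' @return The corresponding slot value (see above).
#' @name accessors
#' @aliases positions orientations particleKind rodIds segmentIndex
#'   nParticles boxLengths topologyType periodicDims
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("positions<-", function(x, value) standardGeneric("positions<-"))

#' @rdname accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @rdname accessors
#' @export
setGeneric("orientations<-", function(x, value) standardGeneric("orientations<-"))

#' @rdname accessors
#' @export
setGeneric("particleKind", function(x) standardGeneric("particleKind"))

#' @rdname accessors
#' @export
setGeneric("rodIds", function(x) standardGeneric("rodIds"))

#' @rdname accessors
#' @export
setGeneric("segmentIndex", function(x) standardGeneric("segmentIndex"))

#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @rdname accessors
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))

#' @rdname accessors
#' @export
setGeneric("topologyType", function(x) standardGeneric("topologyType"))

#' @rdname accessors
#' @export
setGeneric("periodicDims", function(x) standardGeneric("periodicDims"))

#' Trajectory accessors
#'
#' @param x a \code{Trajectory}.
#' @param i frame index.
#' @return \code{nFrames}: number of stored frames; \code{frameTimes}: frame
#'   times in simulation time units; \code{getFrame}: the i-th frame as a
#'   \code{ParticleState}; \code{frameBox}: the box of the i-th frame;
#'   \code{trajMetadata}: the run metadata list.
#' @name trajectory-accessors
NULL

#' @rdname trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname trajectory-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname trajectory-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname trajectory-accessors
#' @export
setGeneric("frameBox", function(x, i) standardGeneric("frameBox"))

#' @rdname trajectory-accessors
#' @export
setGeneric("trajMetadata", function(x) standardGeneric("trajMetadata"))
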