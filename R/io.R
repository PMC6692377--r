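#' @include fixtures.R
NULL

.SPECIES <- c(membrane = "M", rod_backbone = "B", rod_hook = "H")

#' Write a configuration frame in extended-XYZ format
#'
#' One frame per block: a count line, a comment line carrying the lattice,
#' topology and time, and one row per particle with columns
#' \code{species x y z ux uy uz rod_id segment hook_side}.
#'
#' @param state a \code{ParticleState}.
#' @param box a \code{SimulationBox}.
#' @param path output file.
#' @param time frame time.
#' @param append append as an additional frame.
#' @return Invisibly, \code{path}.
#' @export
writeFrame <- function(state, box, path, time = 0, append = FALSE) {
  n <- nrow(state@pos)
  L <- boxLengths(box)
  head1 <- sprintf("%d", n)
  head2 <- sprintf(
    paste0('Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" ',
           'Properties=species:S:1:pos:R:3:orient:R:3:rod_id:I:1:segment:I:1:hook_side:R:1 ',
           'Topology=%s Time=%.12g'),
    L[1], L[2], L[3], topologyType(box), time)
  rows <- sprintf("%s %.12g %.12g %.12g %.12g %.12g %.12g %d %d %.12g",
                  .SPECIES[state@kind],
                  state@pos[, 1], state@pos[, 2], state@pos[, 3],
                  state@orient[, 1], state@orient[, 2], state@orient[, 3],
                  state@rodId, state@segmentIndex, state@hookSide)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(head1, head2, rows), con)
  invisible(path)
}

.parseFrame <- function(lines) {
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n) || length(lines) < n + 2)
    stop("malformed extended-XYZ frame: bad count line or truncated block")
  hdr <- lines[2]
  lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
  if (length(lat) == 0) stop("malformed frame: missing Lattice")
  latv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), "\\s+")[[1]])
  L <- latv[c(1, 5, 9)]
  topo <- sub('.*Topology=(\\S+).*', "\\1", hdr)
  if (!topo %in% .TOPOLOGIES) topo <- "flat"
  time <- suppressWarnings(as.numeric(sub('.*Time=(\\S+).*', "\\1", hdr)))
  if (is.na(time)) time <- 0
  body <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  ncols <- lengths(body)
  if (any(ncols != 10))
    stop("malformed frame: expected 10 columns ",
         "(species pos orient rod_id segment hook_side), found ",
         paste(unique(ncols), collapse = "/"))
  m <- do.call(rbind, body)
  kind <- names(.SPECIES)[match(m[, 1], .SPECIES)]
  if (anyNA(kind)) stop("malformed frame: unknown species tag")
  num <- apply(m[, 2:10, drop = FALSE], 2, as.numeric)
  state <- particleState(num[, 1:3, drop = FALSE], num[, 4:6, drop = FALSE],
                         kind = kind, rodId = as.integer(num[, 7]),
                         segmentIndex = as.integer(num[, 8]),
                         hookSide = num[, 9])
  list(state = state, box = simulationBox(L, topo), time = time,
       used = n + 2L)
}

#' Read an extended-XYZ frame
#'
#' @param path file written by \code{\link{writeFrame}}.
#' @param frame 1-based frame index within the file.
#' @return List with \code{state}, \code{box}, \code{time}.
#' @export
readFrame <- function(path, frame = 1L) {
  lines <- readLines(path)
  at <- 1L
  for (f in seq_len(frame)) {
    if (at > length(lines)) stop("frame ", frame, " not present in ", path)
    fr <- .parseFrame(lines[at:length(lines)])
    at <- at + fr$used
  }
  fr[c("state", "box", "time")]
}

#' Write a trajectory as multi-frame extended XYZ
#'
#' @param traj a \code{Trajectory}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  for (f in seq_len(nFrames(traj)))
    writeFrame(getFrame(traj, f), frameBox(traj, f), path,
               time = frameTimes(traj)[f], append = f > 1)
  invisible(path)
}

#' Read a multi-frame extended-XYZ trajectory
#'
#' @param path file.
#' @return A \code{Trajectory}.
#' @export
readTrajectoryXYZ <- function(path) {
  lines <- readLines(path)
  at <- 1L
  frames <- list(); boxes <- list(); times <- numeric(0)
  while (at <= length(lines) && nzchar(trimws(lines[at]))) {
    fr <- .parseFrame(lines[at:length(lines)])
    frames[[length(frames) + 1]] <- fr$state
    boxes[[length(boxes) + 1]] <- fr$box
    times <- c(times, fr$time)
    at <- at + fr$used
  }
  new("Trajectory", frames = frames, times = times, boxes = boxes,
      metadata = list(source = path))
}

## ---- run configuration ----

.CONFIG_KEYS <- list(
  common = c("experiment", "seed", "steps", "dt", "gammaT", "gammaR",
             "sampleEvery", "frameEvery", "out",
             "kBend", "kTilt", "epsRep", "bRep", "epsAtt", "rhoStar",
             "alphaCv", "rGa", "rCc",
             "cRodRrod", "chirality", "epsilonSS", "nRods", "phiRod"),
  tube = c("nParticles", "radiusFamily", "rCyl", "lZ", "relaxSteps"),
  tube_remd = c("nParticles", "radiusFamily", "rCyl", "lZ", "ladder",
                "exchangeEvery", "nCycles"),
  flat = c("nParticles", "eqSteps", "mcEvery", "mcDelta"),
  tubulate = c("nParticles", "eqSteps", "mcEvery"),
  calibrate = c("targetA0", "targetKappa", "targetGamma", "maxIter",
                "nParticles"),
  analyze = c("input", "contactCutoff"))

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, validates the experiment kind and the
#' field names (unknown keys are rejected with a field-level message), and
#' fills membrane-parameter defaults from the shipped calibrated set.
#'
#' @param path YAML file.
#' @return A \code{\link{RunConfig-class}}.
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || is.null(cfg$experiment))
    stop("config error: missing required field 'experiment' ",
         "(one of tube, tube_remd, flat, tubulate, calibrate, analyze); ",
         "other required fields depend on the experiment (see .CONFIG_KEYS)")
  exp <- cfg$experiment
  if (!exp %in% names(.CONFIG_KEYS)[-1])
    stop("config error: unknown experiment '", exp, "'")
  allowed <- c(.CONFIG_KEYS$common, .CONFIG_KEYS[[exp]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  defaults <- calibratedDefaults()
  for (k in intersect(names(defaults),
                      c("kBend", "kTilt", "epsRep", "bRep", "epsAtt",
                        "rhoStar", "alphaCv", "rGa", "rCc")))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$dt)) cfg$dt <- if (is.null(cfg$cRodRrod)) 0.005 else 0.004
  new("RunConfig", experiment = exp, opts = cfg)
}

#' Write the effective configuration
#'
#' @param config a \code{RunConfig}.
#' @param path output YAML file.
#' @return Invisibly, \code{path}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config@opts, path)
  invisible(path)
}
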