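# Persistent formats: stack container, amplitude-map CSV/TIFF export,
# ROI JSON, run configuration (YAML/JSON) and results tables.

.STACK_MAGIC <- "MMUSSTACK"
.STACK_VERSION <- "1.0"
.STACK_MANDATORY <- c("format_version", "frame_rate_hz", "f0_hz", "field_mT",
                      "center_freq_mhz", "sound_speed_m_s", "mag_state",
                      "seed")

#' Write / read an I/Q stack container
#'
#' Single-file, self-describing container: a magic string, a JSON header
#' carrying the array shape and the mandatory acquisition attributes
#' (\code{format_version}, \code{frame_rate_hz}, \code{f0_hz},
#' \code{field_mT}, \code{center_freq_mhz}, \code{sound_speed_m_s},
#' \code{mag_state}, \code{seed}), then the real and imaginary parts as
#' little-endian float64 arrays in (x, z, frame) order.
#' \code{readStack(writeStack(x))} reproduces the arrays and metadata
#' bitwise. Files missing a mandatory attribute, or written with a
#' different format version, are rejected with an error naming the
#' offending attribute.
#'
#' @param stack an \linkS4class{IQStack} whose metadata carry f0,
#'   fieldStrength, centerFreq, soundSpeed and seed.
#' @param path file path.
#' @return \code{writeStack}: \code{path}, invisibly. \code{readStack}:
#'   an \linkS4class{IQStack}.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "IQStack"))
  m <- stack@meta
  need <- c(f0 = "f0_hz", fieldStrength = "field_mT",
            centerFreq = "center_freq_mhz", soundSpeed = "sound_speed_m_s",
            seed = "seed")
  for (k in names(need))
    if (is.null(m[[k]]))
      .err("stack metadata lack '%s' (attribute %s)", k, need[[k]])
  d <- dim(stack@iq)
  hdr <- list(format_version = .STACK_VERSION,
              nx = d[1L], nz = d[2L], n_frames = d[3L],
              frame_rate_hz = stack@frameRate,
              f0_hz = m$f0, field_mT = m$fieldStrength,
              center_freq_mhz = m$centerFreq,
              sound_speed_m_s = m$soundSpeed,
              mag_state = stack@magState, seed = m$seed)
  js <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  raw <- charToRaw(as.character(js))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.STACK_MAGIC, con, eos = NULL)
  writeBin(length(raw), con, size = 4L, endian = "little")
  writeBin(raw, con)
  writeBin(as.vector(Re(stack@iq)), con, size = 8L, endian = "little")
  writeBin(as.vector(Im(stack@iq)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(.STACK_MAGIC), useBytes = TRUE)
  if (!identical(magic, .STACK_MAGIC))
    .err("'%s' is not an MMUS stack container", path)
  n <- readBin(con, "integer", size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  for (k in .STACK_MANDATORY)
    if (is.null(hdr[[k]]))
      .err("stack file '%s' lacks mandatory attribute '%s'", path, k)
  if (!identical(as.character(hdr$format_version), .STACK_VERSION))
    .err("unsupported format_version '%s' (expected '%s')",
         hdr$format_version, .STACK_VERSION)
  npix <- hdr$nx * hdr$nz * hdr$n_frames
  re <- readBin(con, "numeric", npix, size = 8L, endian = "little")
  im <- readBin(con, "numeric", npix, size = 8L, endian = "little")
  iq <- array(complex(real = re, imaginary = im),
              dim = c(hdr$nx, hdr$nz, hdr$n_frames))
  new("IQStack", iq = iq, frameRate = as.numeric(hdr$frame_rate_hz),
      magState = hdr$mag_state,
      meta = list(f0 = as.numeric(hdr$f0_hz),
                  fieldStrength = as.numeric(hdr$field_mT),
                  centerFreq = as.numeric(hdr$center_freq_mhz),
                  soundSpeed = as.numeric(hdr$sound_speed_m_s),
                  seed = as.integer(hdr$seed)))
}

#' Export / import an amplitude map as a CSV matrix
#'
#' Lossless full-precision matrix export; the map kind is recorded in a
#' comment line.
#'
#' @param map an \linkS4class{AmplitudeMap}.
#' @param path CSV path.
#' @return \code{writeAmplitudeCSV}: \code{path} invisibly;
#'   \code{readAmplitudeCSV}: an \linkS4class{AmplitudeMap}.
#' @export
writeAmplitudeCSV <- function(map, path) {
  stopifnot(is(map, "AmplitudeMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mmus amplitude map kind=%s", map@kind), con)
  utils::write.table(format(map@values, digits = 17, trim = TRUE), con,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeAmplitudeCSV
#' @export
readAmplitudeCSV <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub(".*kind=", "", first)
  v <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                   colClasses = "numeric"))
  dimnames(v) <- NULL
  new("AmplitudeMap", values = v, kind = kind)
}

#' Export an amplitude map as 32-bit float TIFF
#'
#' Values are stored divided by \code{scale} (TIFF float samples are
#' expected in [0, 1]); the scale used is returned so the caller can
#' restore physical units. Default scale is the map maximum (or 1 for an
#' all-zero map).
#'
#' @param map an \linkS4class{AmplitudeMap}.
#' @param path TIFF path.
#' @param scale divisor applied before writing.
#' @return the scale, invisibly.
#' @export
writeAmplitudeTIFF <- function(map, path, scale = NULL) {
  stopifnot(is(map, "AmplitudeMap"))
  if (is.null(scale)) scale <- max(map@values, 1e-12)
  tiff::writeTIFF(t(map@values) / scale, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Write / read a set of ROIs as JSON
#'
#' Each ROI is one JSON object \code{{label, x0, z0, x1, z1}} (0-based,
#' half-open pixel bounds).
#'
#' @param rois list of \linkS4class{ROI}.
#' @param path JSON path.
#' @return \code{writeROISet}: \code{path} invisibly; \code{readROISet}:
#'   a named list of \linkS4class{ROI} (names = labels).
#' @export
writeROISet <- function(rois, path) {
  lst <- lapply(rois, function(r)
    list(label = r@label, x0 = r@x0, z0 = r@z0, x1 = r@x1, z1 = r@z1))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeROISet
#' @export
readROISet <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(lst, function(r)
    roi(r$x0, r$z0, r$x1, r$z1, label = r$label))
  names(out) <- vapply(out, function(r) r@label, character(1L))
  out
}

#' Read a run configuration from YAML or JSON
#'
#' The configuration schema shipped at
#' \code{system.file("extdata", "runconfig-schema.json", package = "mmus")}
#' documents all fields; \code{\link{validateRunConfig}} enforces it
#' before any computation.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a raw configuration list (unvalidated).
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else .err("unsupported config extension '.%s' (use .yaml or .json)", ext)
}

.cfgStop <- function(...) {
  msg <- sprintf(...)
  cond <- structure(class = c("mmusConfigError", "error", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

#' Validate a run configuration
#'
#' Checks types, required fields, well geometry and ROI bounds, and
#' returns the fully constructed objects. Invalid configurations are
#' rejected (condition class \code{mmusConfigError}) before any
#' computation starts.
#'
#' @param config a configuration list, e.g. from
#'   \code{\link{readRunConfig}}.
#' @return list with elements \code{phantom}
#'   (\linkS4class{PhantomSpec}), \code{params}
#'   (\linkS4class{AcquisitionParams}), \code{rois} (named
#'   \linkS4class{ROI} list), \code{pairings} (data.frame sample /
#'   background labels), \code{options} and \code{schedule} (or NULL).
#' @export
validateRunConfig <- function(config) {
  if (!is.list(config)) .cfgStop("config must be a list")
  for (k in c("phantom", "acquisition", "rois"))
    if (is.null(config[[k]])) .cfgStop("config lacks required section '%s'", k)

  ph <- config$phantom
  if (is.null(ph$grid_shape)) .cfgStop("phantom.grid_shape is required")
  wl <- ph$wells
  if (is.data.frame(wl)) wl <- split(wl, seq_len(nrow(wl)))
  wellsL <- lapply(wl, function(w) {
    for (k in c("center", "half_size", "elastic_modulus", "concentration"))
      if (is.null(w[[k]])) .cfgStop("well lacks field '%s'", k)
    wellSpec(unlist(w$center), unlist(w$half_size), w$elastic_modulus,
             w$concentration, agent = if (is.null(w$agent)) "MGV" else w$agent)
  })
  phantom <- tryCatch(
    phantomSpec(unlist(ph$grid_shape),
                pixelPitch = if (is.null(ph$pixel_pitch)) 0.1 else ph$pixel_pitch,
                wells = unname(wellsL),
                backgroundEchogenicity =
                  if (is.null(ph$background_echogenicity)) 1
                  else ph$background_echogenicity),
    error = function(e) .cfgStop("invalid phantom: %s", conditionMessage(e)))

  aq <- config$acquisition
  argmap <- c(frame_rate = "frameRate", n_frames = "nFrames", f0 = "f0",
              field_strength = "fieldStrength", center_freq = "centerFreq",
              sound_speed = "soundSpeed", n_loops = "nLoops",
              noise_sd = "noiseSd", coupling_kappa = "couplingKappa",
              seed = "seed")
  args <- list()
  for (k in names(aq)) {
    if (!k %in% names(argmap)) .cfgStop("unknown acquisition field '%s'", k)
    args[[argmap[[k]]]] <- aq[[k]]
  }
  if (!is.null(config$seed)) args$seed <- config$seed
  params <- tryCatch(do.call(acquisitionParams, args),
    error = function(e) .cfgStop("invalid acquisition: %s",
                                 conditionMessage(e)))

  rl <- config$rois
  if (is.data.frame(rl)) rl <- split(rl, seq_len(nrow(rl)))
  roisL <- lapply(rl, function(r) {
    for (k in c("label", "x0", "z0", "x1", "z1"))
      if (is.null(r[[k]])) .cfgStop("roi lacks field '%s'", k)
    tryCatch(roi(r$x0, r$z0, r$x1, r$z1, label = r$label),
             error = function(e) .cfgStop("invalid roi '%s': %s", r$label,
                                          conditionMessage(e)))
  })
  names(roisL) <- vapply(roisL, function(r) r@label, character(1L))
  gs <- gridShape(phantom)
  for (r in roisL)
    if (r@x1 > gs[1L] || r@z1 > gs[2L])
      .cfgStop("roi '%s' exceeds the %d x %d grid", r@label, gs[1L], gs[2L])

  pr <- config$pairings
  if (is.null(pr))
    .cfgStop("config lacks required section 'pairings' (sample/background ROI labels)")
  if (!is.data.frame(pr)) pr <- do.call(rbind, lapply(pr, as.data.frame))
  for (k in c("sample", "background"))
    if (is.null(pr[[k]])) .cfgStop("pairings need '%s' labels", k)
  for (lab in c(pr$sample, pr$background))
    if (!lab %in% names(roisL)) .cfgStop("pairing references unknown roi '%s'",
                                         lab)

  opts <- config$options
  options <- list(
    reject = isTRUE(opts$reject_loops),
    rejectThreshold = opts$reject_threshold,
    decimals = if (is.null(opts$decimals)) 1L else as.integer(opts$decimals))

  schedule <- config$schedule
  if (!is.null(schedule)) {
    schedule <- as.data.frame(schedule)
    if (!all(c("day", "modulus") %in% names(schedule)))
      .cfgStop("schedule needs 'day' and 'modulus' columns")
  }

  list(phantom = phantom, params = params, rois = roisL,
       pairings = pr[c("sample", "background")], options = options,
       schedule = schedule,
       session = if (is.null(config$session)) "session1" else config$session,
       outputDir = config$output_dir)
}

#' Write / read a results table as CSV
#'
#' Plain CSV with a typed header; \code{readResultsTable} restores the
#' column types so the round trip is lossless.
#'
#' @param results a results data.frame from \code{\link{runExperiment}}.
#' @param path CSV path.
#' @return \code{writeResultsTable}: \code{path} invisibly;
#'   \code{readResultsTable}: the data.frame.
#' @export
writeResultsTable <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
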