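# Full-precision number formatting: 17 significant digits round-trips IEEE
# doubles exactly through text.
fmtFull <- function(x) sprintf("%.17g", x)

#' Write an acquisition as per-frame text files
#'
#' Mirrors a spectrometer-software export: one tab-delimited two-column text
#' file per frame (`wavelength_nm`, `intensity_counts`) with `#`-prefixed
#' header lines carrying the frame index, the frame time in seconds and an
#' ISO 8601 timestamp. Zero-padded frame indices make lexicographic filename
#' order equal time order. Values are written with 17 significant digits, so
#' a write/read round trip is bit-exact.
#'
#' @param spectra a \linkS4class{TimeResolvedSpectra}
#' @param directory output directory (created if absent)
#' @param origin POSIXct acquisition start used for the ISO timestamps
#' @return invisibly, the character vector of files written, in time order
#' @seealso [readFrames()], [writeCube()]
#' @export
writeFrames <- function(spectra, directory,
                        origin = as.POSIXct("2026-01-01 00:00:00",
                                            tz = "UTC")) {
  stopifnot(is(spectra, "TimeResolvedSpectra"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  m <- intensities(spectra)
  wl <- fmtFull(wavelengthAxis(spectra))
  tm <- timeAxis(spectra)
  files <- file.path(directory,
                     sprintf("frame_%06d.tsv", seq_along(tm) - 1L))
  for (k in seq_along(tm)) {
    con <- file(files[k], "w")
    iso <- format(origin + tm[k], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    writeLines(c(sprintf("# frame: %d", k - 1L),
                 sprintf("# time_s: %s", fmtFull(tm[k])),
                 sprintf("# timestamp: %s", iso),
                 "wavelength_nm\tintensity_counts",
                 paste(wl, fmtFull(m[, k]), sep = "\t")), con)
    close(con)
  }
  invisible(files)
}

#' Read per-frame text files back into an acquisition
#'
#' Reassembles the wavelength-time matrix from a directory (or explicit file
#' list) of per-frame exports written by [writeFrames()] or a compatible
#' instrument export. The time axis is taken from the `# time_s:` header
#' lines when present; otherwise it is filled uniformly at `rate` frames per
#' second. All frames must share an identical wavelength grid.
#'
#' @param fileset a directory containing `frame_*.tsv` files, or a character
#'   vector of file paths in time order
#' @param rate fallback sampling rate (Hz) when the files carry no
#'   timestamps
#' @return a \linkS4class{TimeResolvedSpectra}
#' @export
readFrames <- function(fileset, rate = 10) {
  files <- if (length(fileset) == 1L && dir.exists(fileset))
    sort(list.files(fileset, pattern = "\\.tsv$", full.names = TRUE))
  else fileset
  if (!length(files)) stop("no frame files found in: ", fileset)
  wl <- NULL
  times <- rep(NA_real_, length(files))
  cols <- vector("list", length(files))
  for (k in seq_along(files)) {
    lines <- readLines(files[k])
    hdr <- grep("^#", lines, value = TRUE)
    ts <- sub("^# time_s:\\s*", "", grep("^# time_s:", hdr, value = TRUE))
    if (length(ts)) times[k] <- as.numeric(ts[1])
    body <- lines[!grepl("^#", lines)]
    if (length(body) && grepl("^wavelength", body[1])) body <- body[-1]
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed frame file: ", files[k])
    w <- as.numeric(vapply(parts, `[[`, "", 1L))
    v <- as.numeric(vapply(parts, `[[`, "", 2L))
    if (is.null(wl)) wl <- w
    else if (length(w) != length(wl) || any(w != wl))
      stop("wavelength grid mismatch in frame file: ", files[k])
    cols[[k]] <- v
  }
  if (all(is.na(times)))
    times <- (seq_along(files) - 1) / rate
  else if (anyNA(times))
    stop("timestamps present in some frame files but missing in others")
  else if (any(diff(times) <= 0))
    stop("frame timestamps are not strictly increasing")
  TimeResolvedSpectra(do.call(cbind, cols), wavelength = wl, time = times,
                      metadata = list(source = "frames_tsv",
                                      n_files = length(files)))
}

#' Single-file cube container
#'
#' Packs the whole acquisition — intensity matrix, wavelength and time axes,
#' and metadata — into one serialized container file for a lossless, fast
#' round trip. Use the per-frame text format ([writeFrames()]) when
#' greppable interchange matters.
#'
#' @param spectra a \linkS4class{TimeResolvedSpectra}
#' @param path file path (conventional extension `.rds`)
#' @return `writeCube()` returns `path` invisibly; `readCube()` a
#'   \linkS4class{TimeResolvedSpectra}.
#' @export
writeCube <- function(spectra, path) {
  stopifnot(is(spectra, "TimeResolvedSpectra"))
  saveRDS(list(container = "respirolaser_cube", version = 1L,
               intensities = intensities(spectra),
               wavelength_nm = wavelengthAxis(spectra),
               time_s = timeAxis(spectra),
               metadata = metadata(spectra)),
          path)
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read cube container ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$container, "respirolaser_cube"))
    stop("not a spectra cube container: ", path)
  TimeResolvedSpectra(obj$intensities, wavelength = obj$wavelength_nm,
                      time = obj$time_s, metadata = obj$metadata)
}
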