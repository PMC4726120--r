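#' Read a multi-page TIFF time-lapse into a FrameStack
#'
#' Reads an 8/12/16-bit grayscale multi-page TIFF holding one field of view.
#' When the file encodes T x Z pages (Z z-planes per time point, planes
#' fastest), the stack is reduced to 2D per time point either by pixelwise
#' maximum-intensity projection over z (`zPolicy = "max_projection"`, the
#' default -- it preserves the stripe signal under focal drift) or by keeping
#' a single plane (`zPolicy = "single_plane"` with `zPlane`).
#'
#' Frame times are supplied explicitly (numeric vector) or as a sidecar CSV
#' with a `time_min` column; embedded TIFF timestamps are not trusted across
#' writer dialects.
#'
#' @param path path to a multi-page TIFF file.
#' @param times numeric vector of frame times in minutes, or path to a sidecar
#'   CSV with a `time_min` column.
#' @param nz number of z-planes per time point (default 1).
#' @param zPolicy `"max_projection"` or `"single_plane"`.
#' @param zPlane plane index (1-based) used when `zPolicy = "single_plane"`.
#' @param pixelSizeUm,channelLabel optional metadata stored on the stack.
#' @return A [FrameStack-class] with one 2D frame per time point. Pixel values
#'   are kept on their native integer scale.
#' @seealso [writeStack()], [frameStack()]
#' @export
readStack <- function(path, times, nz = 1L,
                      zPolicy = c("max_projection", "single_plane"),
                      zPlane = 1L, pixelSizeUm = NA_real_, channelLabel = "") {
  zPolicy <- match.arg(zPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse trivial channel dim
    storage.mode(p) <- "double"
    p
  })
  nz <- as.integer(nz)
  if (nz < 1L) stop("nz must be >= 1")
  if (length(pages) %% nz != 0L)
    stop(sprintf("page count (%d) not divisible by declared number of z-planes (%d)",
                 length(pages), nz))
  nt <- length(pages) %/% nz
  frames <- vector("list", nt)
  for (i in seq_len(nt)) {
    planes <- pages[((i - 1L) * nz + 1L):(i * nz)]
    frames[[i]] <- if (nz == 1L) planes[[1L]]
      else if (zPolicy == "max_projection") Reduce(pmax, planes)
      else {
        if (zPlane < 1L || zPlane > nz) stop("zPlane out of range")
        planes[[zPlane]]
      }
  }
  if (is.character(times)) times <- readTimesSidecar(times)
  if (length(times) != nt)
    stop(sprintf("got %d time points for %d frames", length(times), nt))
  frameStack(frames, times, pixelSizeUm = pixelSizeUm, channelLabel = channelLabel)
}

#' Write a FrameStack as a 16-bit multi-page TIFF
#'
#' Values are rounded to integers and clamped to `[0, 65535]`; integer-valued
#' stacks within range round-trip exactly through [readStack()].
#'
#' @param stack a [FrameStack-class].
#' @param path output TIFF path.
#' @param timesPath optional path for a times sidecar CSV (column `time_min`).
#' @return Invisibly, `path`.
#' @export
writeStack <- function(stack, path, timesPath = NULL) {
  frames <- lapply(stack@frames, function(f) {
    f <- round(f)
    f[f < 0] <- 0
    f[f > 65535] <- 65535
    f / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(timesPath))
    utils::write.csv(data.frame(time_min = stack@timesMin), timesPath,
                     row.names = FALSE)
  invisible(path)
}

readTimesSidecar <- function(path) {
  if (!file.exists(path)) stop("times sidecar not found: ", path)
  d <- utils::read.csv(path)
  if (!"time_min" %in% names(d)) stop("times sidecar must have a 'time_min' column")
  as.numeric(d$time_min)
}

msTableColumns <- c("field_id", "nucleus_id", "time_min", "ms", "j_meas",
                    "j_expt", "stripe_D", "stripe_P", "angle_deg", "f_value",
                    "flagged")

#' Write / read a Measure-of-Striation table
#'
#' One row per nucleus per time point. Numeric columns are written with
#' full double precision (`%.17g`), so a write/read round trip reproduces the
#' values exactly. Flagged rows (failed fits, zero-signal nuclei) are retained
#' in the table and excluded from curve building downstream.
#'
#' @param records data.frame as produced by [msSeries()] / [analyzeStack()],
#'   with columns `field_id`, `nucleus_id`, `time_min`, `ms`, `j_meas`,
#'   `j_expt`, `stripe_D`, `stripe_P`, `angle_deg`, `f_value`, `flagged`.
#' @param path CSV path (UTF-8, `.` decimal separator).
#' @return `writeMSTable` invisibly returns `path`; `readMSTable` returns the
#'   data.frame.
#' @export
writeMSTable <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(setNames(
      lapply(msTableColumns, function(x) logical(0)), msTableColumns))
  }
  missing <- setdiff(msTableColumns, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  out <- records[, msTableColumns, drop = FALSE]
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA", sprintf("%.17g", out[[nm]]))
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMSTable
#' @export
readMSTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("time_min", "ms", "j_meas", "j_expt", "angle_deg", "f_value"))
    if (nm %in% names(d)) d[[nm]] <- as.numeric(d[[nm]])
  if ("flagged" %in% names(d)) d$flagged <- as.logical(d$flagged)
  d
}
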