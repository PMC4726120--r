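#' DDR curve parameters from a Measure-of-Striation time series
#'
#' Summarizes the DDR curve (MS as a function of time for one nucleus) into:
#' * `amp` -- the maximum MS over all observed time points (amount of protein
#'   recruited to the stripes at peak);
#' * `tpeak_min` -- the time in minutes from micro-irradiation until MS first
#'   reaches its maximum (ties go to the earliest time point);
#' * `relax` -- the OLS slope of the line fitted to `MS(t)` for `t > tpeak`
#'   (post-peak relaxation). When the curve never peaks within the observed
#'   window (the maximum falls on the final time point, `peaked = FALSE`),
#'   the slope is instead fitted over `t > 30` min;
#' * `relax30` -- always the OLS slope over `t > 30` min.
#'
#' Flagged records are dropped first. Slopes with fewer than two usable
#' points are `NA` (undefined, never silently zero) and such nuclei are
#' excluded from group statistics for that parameter.
#'
#' @param series data.frame with columns `time_min`, `ms` and optionally
#'   `flagged` (as produced by [msSeries()]); at least two unflagged points
#'   with `time_min >= 0`.
#' @param relaxFallbackMin fallback window start for unpeaked curves
#'   (default 30 minutes, strict inequality).
#' @return One-row data.frame: `mode`, `amp`, `tpeak_min`, `relax`,
#'   `relax30`, `peaked`, `n_points`, `n_relax`, `n_relax30`.
#' @examples
#' s <- data.frame(time_min = c(0, 5, 10, 20, 30), ms = c(0, 0.4, 1.1, 0.8, 0.5))
#' ddrParams(s)   # amp 1.1 at 10 min, relax -0.03 / min
#' @export
ddrParams <- function(series, relaxFallbackMin = 30) {
  s <- usableSeries(series)
  if (nrow(s) < 2L) stop("need at least two usable time points")
  iMax <- which.max(s$ms)           # which.max returns the earliest maximum
  amp <- s$ms[iMax]
  tpeak <- s$time_min[iMax]
  peaked <- iMax < nrow(s)
  tRelax <- if (peaked) tpeak else relaxFallbackMin
  selRelax <- s$time_min > tRelax
  sel30 <- s$time_min > relaxFallbackMin
  data.frame(
    mode = "DDR", amp = amp, tpeak_min = tpeak,
    relax = olsSlope(s$time_min[selRelax], s$ms[selRelax]),
    relax30 = olsSlope(s$time_min[sel30], s$ms[sel30]),
    peaked = peaked, n_points = nrow(s),
    n_relax = sum(selRelax), n_relax30 = sum(sel30))
}

#' FRAP curve parameters from a Measure-of-Striation time series
#'
#' For a bleaching experiment the MS is negative and recovers toward zero:
#' `amp` is the minimum MS. No time-to-peak is reported, since maximum
#' (negative) striation is reached immediately after bleaching. The recovery
#' slopes are `relax30`, the OLS slope of the curve between t = 1 and
#' t = 30 min, and `relax`, the slope between t = 1 and t = 60 min (both
#' windows inclusive); recovery implies positive slopes.
#'
#' @inheritParams ddrParams
#' @param shortWindowMin,longWindowMin upper ends of the two inclusive fit
#'   windows (defaults 30 and 60 minutes, both starting at 1 minute).
#' @return One-row data.frame as in [ddrParams()] with `tpeak_min = NA`.
#' @export
frapParams <- function(series, shortWindowMin = 30, longWindowMin = 60) {
  s <- usableSeries(series)
  if (nrow(s) < 2L) stop("need at least two usable time points")
  sel30 <- s$time_min >= 1 & s$time_min <= shortWindowMin
  sel60 <- s$time_min >= 1 & s$time_min <= longWindowMin
  data.frame(
    mode = "FRAP", amp = min(s$ms), tpeak_min = NA_real_,
    relax = olsSlope(s$time_min[sel60], s$ms[sel60]),
    relax30 = olsSlope(s$time_min[sel30], s$ms[sel30]),
    peaked = NA, n_points = nrow(s),
    n_relax = sum(sel60), n_relax30 = sum(sel30))
}

usableSeries <- function(series) {
  s <- series
  if ("flagged" %in% names(s)) s <- s[!isTRUE_vec(s$flagged), ]
  s <- s[is.finite(s$ms) & is.finite(s$time_min), ]
  s[order(s$time_min), c("time_min", "ms")]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Median MS curve across nuclei
#'
#' For illustrative group curves the median MS at each shared time point is
#' computed over all nuclei with a usable (unflagged, finite) value there;
#' medians of even counts use the midpoint convention of [stats::median()].
#'
#' @param records long data.frame with columns `nucleus_id`, `time_min`, `ms`
#'   and optionally `flagged`.
#' @param timepoints time points at which to evaluate (default: all distinct
#'   times present).
#' @return data.frame with `time_min`, `median_ms` (`NA` where no usable
#'   value exists) and `n` (values contributing).
#' @export
medianCurve <- function(records, timepoints = sort(unique(records$time_min))) {
  ok <- is.finite(records$ms)
  if ("flagged" %in% names(records)) ok <- ok & !isTRUE_vec(records$flagged)
  r <- records[ok, ]
  med <- vapply(timepoints, function(tp) {
    v <- r$ms[r$time_min == tp]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  n <- vapply(timepoints, function(tp) sum(r$time_min == tp), integer(1))
  data.frame(time_min = timepoints, median_ms = med, n = n)
}

#' Curve parameters for every nucleus in an MS table
#'
#' Applies [ddrParams()] or [frapParams()] per nucleus; nuclei with fewer
#' than two usable time points are skipped with a count in the attribute
#' `nSkipped`.
#'
#' @param records long MS table (columns `nucleus_id`, `time_min`, `ms`,
#'   optionally `flagged`, `field_id`).
#' @param mode `"DDR"` or `"FRAP"`.
#' @return data.frame, one row per nucleus, with `nucleus_id` (and `field_id`
#'   if present) prepended to the parameter columns.
#' @export
curveParams <- function(records, mode = c("DDR", "FRAP")) {
  mode <- match.arg(mode)
  fn <- if (mode == "DDR") ddrParams else frapParams
  skipped <- 0L
  rows <- lapply(split(records, records$nucleus_id), function(s) {
    p <- tryCatch(fn(s), error = function(e) NULL)
    if (is.null(p)) { skipped <<- skipped + 1L; return(NULL) }
    pre <- data.frame(nucleus_id = s$nucleus_id[1L])
    if ("field_id" %in% names(s)) pre <- cbind(data.frame(field_id = s$field_id[1L]), pre)
    cbind(pre, p)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "nSkipped") <- skipped
  out
}
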