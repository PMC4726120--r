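#' Kruskal-Wallis test on per-nucleus curve parameters
#'
#' Thin, validated wrapper around [stats::kruskal.test()]: H is computed on
#' mid-ranks with the standard tie correction, and the p-value comes from the
#' chi-square approximation with k - 1 degrees of freedom. The degenerate
#' case of all values identical (tie correction denominator zero) returns
#' `H = 0`, `p = 1`. Being rank-based, H is invariant under any strictly
#' monotone transformation of the pooled values.
#'
#' @param groups list of two or more numeric vectors; each must contain at
#'   least one finite value and at least three values in total.
#' @return List with elements `H` and `p`.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 27/7
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of two or more numeric vectors")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must contain at least one finite value")
  if (sum(lengths(groups)) < 3L) stop("need at least three values in total")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Compare per-nucleus curve parameters against a mock-treated control
#'
#' For each curve parameter, the treated values (technical duplicates pooled
#' by the caller, e.g. by row-binding the per-well tables) are tested against
#' the pooled mock-treated values with the Kruskal-Wallis test at level
#' `alpha`. The effect direction is the sign of (treated median - mock
#' median). When a `replicate` column with two or more biological replicates
#' is present in both tables, a parameter is reported significant only if
#' every replicate is independently significant with the same direction (the
#' concordance rule that stands in for multiple-testing correction); the
#' reported H and p then refer to the pooled test. Non-significant parameters
#' have direction `"ns"`.
#'
#' @param treated,mock data.frames of per-nucleus parameters (as from
#'   [curveParams()]); an optional `replicate` column marks biological
#'   replicates.
#' @param parameters parameter columns to test (default the four DDR/FRAP
#'   curve parameters).
#' @param alpha significance level (default 0.05; no correction across
#'   parameters is applied).
#' @param minCells minimum recommended nuclei per condition (default 100, the
#'   scale the test is intended for); fewer triggers a warning, not an error.
#' @return data.frame with one row per parameter: `parameter`, `H`, `p`,
#'   `significant`, `direction` (`"up"`, `"down"` or `"ns"`), `n_treated`,
#'   `n_mock`.
#' @export
compareToMock <- function(treated, mock,
                          parameters = c("amp", "tpeak_min", "relax", "relax30"),
                          alpha = 0.05, minCells = 100L) {
  if (is.null(mock) || nrow(mock) == 0L) stop("missing mock group")
  if (is.null(treated) || nrow(treated) == 0L) stop("missing treated group")
  reps <- NULL
  if ("replicate" %in% names(treated) && "replicate" %in% names(mock)) {
    reps <- sort(unique(c(treated$replicate, mock$replicate)))
    if (length(reps) < 2L) reps <- NULL
  }
  rows <- lapply(parameters, function(par) {
    tv <- treated[[par]][is.finite(treated[[par]])]
    mv <- mock[[par]][is.finite(mock[[par]])]
    if (length(tv) < minCells || length(mv) < minCells)
      warning(sprintf("parameter %s: fewer than %d usable cells per condition",
                      par, minCells), call. = FALSE)
    pooled <- kruskalWallis(list(tv, mv))
    if (is.null(reps)) {
      sig <- pooled$p < alpha
      dir <- sign(stats::median(tv) - stats::median(mv))
    } else {
      per <- lapply(reps, function(r) {
        tr <- treated[[par]][treated$replicate == r]
        mr <- mock[[par]][mock$replicate == r]
        tr <- tr[is.finite(tr)]; mr <- mr[is.finite(mr)]
        if (length(tr) == 0L || length(mr) == 0L)
          return(list(sig = FALSE, dir = 0))
        kw <- kruskalWallis(list(tr, mr))
        list(sig = kw$p < alpha,
             dir = sign(stats::median(tr) - stats::median(mr)))
      })
      dirs <- vapply(per, `[[`, numeric(1), "dir")
      sigs <- vapply(per, `[[`, logical(1), "sig")
      sig <- all(sigs) && length(unique(dirs)) == 1L && dirs[1L] != 0
      dir <- if (sig) dirs[1L] else 0
    }
    data.frame(parameter = par, H = pooled$H, p = pooled$p,
               significant = sig,
               direction = if (!sig) "ns" else if (dir > 0) "up" else "down",
               n_treated = length(tv), n_mock = length(mv))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary table of screen outcomes across compounds
#'
#' Builds the compounds-by-parameters table of effect codes (`"up"`, `"down"`,
#' `"ns"`) from a named list of [compareToMock()] results -- the tabular
#' equivalent of the red/blue/grey screen summary.
#'
#' @param comparisons named list (one entry per compound) of data.frames
#'   returned by [compareToMock()].
#' @return data.frame with a `compound` column and one column per parameter.
#' @export
screenSummary <- function(comparisons) {
  stopifnot(is.list(comparisons), length(comparisons) > 0L,
            !is.null(names(comparisons)))
  pars <- comparisons[[1L]]$parameter
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    codes <- cmp$direction[match(pars, cmp$parameter)]
    stats::setNames(data.frame(nm, t(codes), stringsAsFactors = FALSE),
                    c("compound", pars))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
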