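#' Half-transition time (t-half) of a time course
#'
#' The time at which a sampled series crosses the midpoint between its first
#' and last values, `m = (v_first + v_last) / 2` — i.e. the time at which
#' half of the total change between the start and the end of the time course
#' has occurred. The crossing time is linearly interpolated between the
#' bracketing sampled times; when a sampled value equals `m` exactly, that
#' sampled time is returned without interpolation. Series whose total
#' relative change is below `flatTolerance` are flagged `"flat"` with an
#' undefined t-half. For a non-monotone series the first crossing is used by
#' default (`crossing = "last"` selects the last).
#'
#' The crossing time is invariant under affine transforms of the values
#' (`v -> a*v + b`, `a != 0`); note that the flatness guard compares the
#' total change to the baseline magnitude, so a transform that shrinks the
#' relative change below `flatTolerance` turns the status flat — disable the
#' guard (`flatTolerance = 0`) when strict affine invariance is needed.
#'
#' @param values Numeric series, one value per sampled time.
#' @param times Strictly increasing sampling times in days (default
#'   `c(0, 2, 4, 7, 12)`).
#' @param flatTolerance Relative change below which the series is considered
#'   flat (default 0.01, i.e. 1%).
#' @param crossing `"first"` or `"last"` midpoint crossing.
#' @param eps Guard for the denominator of the flatness test (default
#'   1e-8).
#' @return List with `t_half` (days, or `NA` when not ok), `status`
#'   (`"ok"`, `"flat"` or `"non_crossing"`) and `crossing_segment` (index
#'   of the bracketing time interval, or `NA`).
#' @examples
#' tHalf(c(0, 1/6, 1/3, 7/12, 1))$t_half   # 6: linear ramp crosses at
#'                                          # mid-time
#' tHalf(c(0, 1, 1, 1, 1))$t_half           # 1: interpolated on day 0-2
#' @export
tHalf <- function(values, times = c(0, 2, 4, 7, 12), flatTolerance = 0.01,
                  crossing = c("first", "last"), eps = 1e-8) {
  crossing <- match.arg(crossing)
  if (length(values) != length(times) || length(values) < 2L)
    stop("values and times must have equal length >= 2")
  if (anyNA(values) || anyNA(times)) stop("missing values in time course")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  v1 <- values[1]; vL <- values[length(values)]
  if (abs(vL - v1) / max(abs(v1), eps) < flatTolerance)
    return(list(t_half = NA_real_, status = "flat",
                crossing_segment = NA_integer_))
  m <- (v1 + vL) / 2
  segs <- integer(0); ts <- numeric(0)
  for (i in seq_len(length(values) - 1L)) {
    a <- values[i] - m; b <- values[i + 1L] - m
    t <- if (a == 0) {
      times[i]
    } else if (b == 0) {
      times[i + 1L]
    } else if (a * b < 0) {
      times[i] + (m - values[i]) / (values[i + 1L] - values[i]) *
        (times[i + 1L] - times[i])
    } else NA_real_
    if (!is.na(t)) { segs <- c(segs, i); ts <- c(ts, t) }
  }
  if (!length(ts))
    return(list(t_half = NA_real_, status = "non_crossing",
                crossing_segment = NA_integer_))
  pick <- if (crossing == "first") 1L else length(ts)
  list(t_half = ts[pick], status = "ok", crossing_segment = segs[pick])
}

#' t-half for every row of a time-course matrix
#'
#' @param mat Numeric matrix, rows = genes (named), columns = sampled times.
#' @param times Sampling times in days.
#' @param ... Passed to [tHalf()].
#' @return Data frame with columns `gene_id`, `t_half`, `status`,
#'   `crossing_segment`.
#' @export
tHalfCohort <- function(mat, times = c(0, 2, 4, 7, 12), ...) {
  res <- lapply(seq_len(nrow(mat)), function(i) tHalf(mat[i, ], times, ...))
  data.frame(gene_id = rownames(mat),
             t_half = vapply(res, `[[`, numeric(1), "t_half"),
             status = vapply(res, `[[`, character(1), "status"),
             crossing_segment = vapply(res, `[[`, integer(1),
                                       "crossing_segment"),
             row.names = NULL)
}

#' Median t-half over a cohort
#'
#' Median of the valid (`status == "ok"`) t-half values; an even count takes
#' the mean of the central pair. Non-ok genes are excluded and counted.
#'
#' @param results Data frame as returned by [tHalfCohort()].
#' @return List with `median` (days), `n_ok` and `n_excluded`.
#' @export
medianTHalf <- function(results) {
  ok <- results$status == "ok"
  if (!any(ok)) stop("no time course with a valid t-half")
  list(median = median(results$t_half[ok]), n_ok = sum(ok),
       n_excluded = sum(!ok))
}

#' Lead/lag comparison of expression and H3K27me3 timing
#'
#' Pairs per-gene t-half values for expression and H3K27me3 and summarizes
#' the lag of the chromatin change behind the transcriptional change: the
#' per-gene difference `t_half(me3) - t_half(expr)`, its cohort median, and
#' the fraction of genes in which the chromatin change comes later
#' (difference > 0).
#'
#' @param exprResults,me3Results Data frames from [tHalfCohort()], matched
#'   by `gene_id`; only genes with `status == "ok"` in both are compared.
#' @return List with `perGene` (data frame of paired values and
#'   differences), `medianDifference` (days), `fractionPositive`, and
#'   `nPairs`.
#' @export
compareTiming <- function(exprResults, me3Results) {
  e <- exprResults[exprResults$status == "ok",
                   c("gene_id", "t_half")]
  m <- me3Results[me3Results$status == "ok", c("gene_id", "t_half")]
  merged <- merge(e, m, by = "gene_id", suffixes = c("_expr", "_me3"))
  if (!nrow(merged)) stop("no gene with a valid t-half in both signals")
  merged$difference <- merged$t_half_me3 - merged$t_half_expr
  list(perGene = merged,
       medianDifference = median(merged$difference),
       fractionPositive = mean(merged$difference > 0),
       nPairs = nrow(merged))
}
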