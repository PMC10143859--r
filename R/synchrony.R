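## Align two series on shared support. rws objects align by calendar year;
## bare numeric vectors align by position (names taken as years when set).
align_pair <- function(x, y) {
  xv <- series_values(x); yv <- series_values(y)
  shared <- intersect(names(xv), names(yv))
  if (inherits(x, "rws") || inherits(y, "rws")) {
    shared <- as.character(sort(as.integer(shared)))
  }
  list(x = unname(xv[shared]), y = unname(yv[shared]), years = shared)
}

#' Gleichlaeufigkeit: percentage of parallel variation
#'
#' Cross-dating agreement of the year-to-year signs of change between two
#' ring-width series over their shared years. An interval where both series
#' move in the same direction scores 1, opposite directions 0, and a tie
#' (either difference exactly zero) scores 1/2 (Eckstein-Bauch convention).
#' Glk is 100 times the mean score over the `n - 1` intervals of the
#' `n`-year overlap.
#'
#' Significance uses a one-sided (upper) normal null centred at 50 percent.
#' Under independence each of the `m = n - 1` intervals is a fair coin, but
#' adjacent intervals share a ring and are therefore positively dependent
#' (the agreement indicator has lag-1 autocovariance 1/36 for continuous
#' series); the null variance used here,
#' `Var(Glk) = 100^2 (m/4 + (m-1)/18) / m^2`, carries that first-order
#' correction, which keeps the nominal test size accurate.
#'
#' @param x,y [rws] objects (aligned by calendar year) or numeric vectors
#'   (aligned by position). Overlap must be at least 3 years.
#' @return List with `glk_percent`, `glk_p` (one-sided upper p-value) and
#'   `overlap_n` (shared years).
#' @examples
#' glk(c(1, 3, 2, 4), c(2, 4, 3, 5))$glk_percent  # 100
#' @export
glk <- function(x, y) {
  al <- align_pair(x, y)
  n <- length(al$x)
  if (n < 3L) stop("glk needs an overlap of at least 3 years")
  dx <- diff(al$x); dy <- diff(al$y)
  score <- ifelse(dx == 0 | dy == 0, 0.5, as.numeric(sign(dx) == sign(dy)))
  # scores are exact multiples of 1/2, so this form is exact up to the
  # single final division
  g <- 100 * sum(score) / (n - 1L)
  p <- stats::pnorm(g, mean = 50, sd = glk_null_sd(n - 1L),
                    lower.tail = FALSE)
  list(glk_percent = g, glk_p = p, overlap_n = n)
}

## null SD of Glk (percent) over m sign intervals, with the lag-1
## dependence correction (adjacent intervals share a ring)
glk_null_sd <- function(m) (100 / m) * sqrt(m / 4 + (m - 1) / 18)

#' Critical Glk value for a given overlap
#'
#' The Glk percentage a pair must reach to be significant at level `p`
#' under the one-sided normal null (used for the dashed guide lines of
#' synchrony box plots).
#'
#' @param overlap_n Number of shared years.
#' @param p Significance level (e.g. 0.05 or 0.001).
#' @return Critical Glk in percent.
#' @export
glk_critical <- function(overlap_n, p = 0.05) {
  m <- overlap_n - 1
  if (any(m < 1)) stop("overlap must be at least 2 years")
  50 + stats::qnorm(1 - p) * glk_null_sd(m)
}

#' Overlap-adjusted t statistic from a correlation
#'
#' The standard cross-dating conversion of a product-moment correlation `r`
#' computed on an overlap of `n` years:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#' A correlation of +/-1 (within 1e-12, absorbing floating-point error in
#' correlations of identical series) returns a signed infinity flag rather
#' than raising.
#'
#' @param r Correlation in `[-1, 1]`.
#' @param n Overlap length (>= 3).
#' @return The t value (possibly `Inf`/`-Inf`).
#' @export
t_from_r <- function(r, n) {
  if (any(n < 3)) stop("t_from_r needs an overlap of at least 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  ifelse(abs(r) >= 1 - 1e-12, sign(r) * Inf,
         r * sqrt(n - 2) / sqrt(1 - r^2))
}

#' Baillie-Pilcher synchrony of two series
#'
#' The full pairwise cross-dating record: Glk (with significance) on the raw
#' shared years, and the t_BP score — the product-moment correlation of the
#' two [bp_standardize]d series over their shared retained years, converted
#' with [t_from_r]. A t_BP of 3.5 or more is conventionally regarded as an
#' acceptable agreement between ring-width series.
#'
#' @param x,y [rws] objects or numeric vectors; at least 7 shared years are
#'   required before the Baillie-Pilcher edge trimming.
#' @return An object of class `"sync_result"`: list with `glk_percent`,
#'   `glk_p`, `overlap_n`, `r`, `t_bp`, `n_bp` (retained overlap) and
#'   `t_inf` (TRUE when `r = +/-1` made the t infinite).
#' @export
tbp <- function(x, y) {
  al <- align_pair(x, y)
  if (length(al$x) < 7L)
    stop("tbp needs at least 7 shared years before edge trimming")
  g <- glk(x, y)
  bx <- bp_standardize(x); by <- bp_standardize(y)
  shared <- intersect(names(bx), names(by))
  if (length(shared) < 3L)
    stop("tbp: fewer than 3 shared years after edge trimming")
  r <- stats::cor(bx[shared], by[shared])
  t_bp <- t_from_r(r, length(shared))
  structure(list(glk_percent = g$glk_percent, glk_p = g$glk_p,
                 overlap_n = g$overlap_n, r = r, t_bp = t_bp,
                 n_bp = length(shared), t_inf = is.infinite(t_bp)),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> Glk %.1f%% (p=%.3g, N=%d), r=%.3f, t_BP=%s (n=%d)\n",
              x$glk_percent, x$glk_p, x$overlap_n, x$r,
              if (x$t_inf) "Inf" else sprintf("%.2f", x$t_bp), x$n_bp))
  invisible(x)
}

#' Pairwise synchrony matrix of a group
#'
#' Evaluates a synchrony metric over all unordered pairs of a group of
#' series. The diagonal is `NA`; pairs that fail (insufficient overlap) get
#' `NA` cells with a recorded finding instead of raising. The group mean
#' excludes the diagonal, `NA` cells and infinity-flagged t values (their
#' count is reported).
#'
#' @param group List of [rws] objects (or numeric vectors) — at least 2 —
#'   or an [rws_collection].
#' @param metric `"glk"` (Glk percent), `"tbp"` (t_BP) or `"r"`
#'   (correlation of BP-standardized series).
#' @return An object of class `"sync_matrix"`: list with `matrix`
#'   (symmetric, `NA` diagonal), `mean`, `n_excluded_infinite` and
#'   `findings` (data frame).
#' @export
pairwise_matrix <- function(group, metric = c("glk", "tbp", "r")) {
  metric <- match.arg(metric)
  if (inherits(group, "rws_collection")) group <- group$series
  k <- length(group)
  if (k < 2L) stop("pairwise_matrix needs at least 2 series")
  ids <- vapply(seq_len(k), function(i) {
    s <- group[[i]]
    if (inherits(s, "rws")) s$series_id else paste0("S", i)
  }, character(1))
  mat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  findings <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    val <- tryCatch({
      if (metric == "glk") glk(group[[i]], group[[j]])$glk_percent
      else {
        s <- tbp(group[[i]], group[[j]])
        if (metric == "tbp") s$t_bp else s$r
      }
    }, error = function(e) {
      findings[[length(findings) + 1L]] <<- data.frame(
        series_1 = ids[i], series_2 = ids[j], message = conditionMessage(e),
        stringsAsFactors = FALSE)
      NA_real_
    })
    mat[i, j] <- mat[j, i] <- val
  }
  off <- mat[upper.tri(mat)]
  n_inf <- sum(is.infinite(off), na.rm = TRUE)
  m <- mean(off[is.finite(off)])
  structure(list(matrix = mat, mean = m, n_excluded_infinite = n_inf,
                 findings = if (length(findings)) do.call(rbind, findings)
                            else data.frame(series_1 = character(),
                                            series_2 = character(),
                                            message = character(),
                                            stringsAsFactors = FALSE)),
            class = "sync_matrix")
}

#' @export
print.sync_matrix <- function(x, ...) {
  cat(sprintf("<sync_matrix> %d series, mean %.2f (%d infinite excluded)\n",
              nrow(x$matrix), x$mean, x$n_excluded_infinite))
  invisible(x)
}

#' Leave-one-out dating screen
#'
#' A simplified whole-series dating check in the spirit of COFECHA's quality
#' control: each series' BP-standardized values are correlated against the
#' mean of all other series' BP-standardized values at a small range of year
#' lags. A series is flagged when its best lag is not zero (suggesting a
#' dating shift, e.g. a missing or false ring) or when its lag-0 correlation
#' falls below `r_threshold`.
#'
#' Sign convention: the screen evaluates `cor(x[year + lag], reference[year])`,
#' so a positive best lag means the series matches the group better when its
#' values are taken from `lag` years later — i.e. its assigned dates appear
#' to be `lag` years too late.
#'
#' @param group List of [rws] objects or an [rws_collection]; at least 3.
#' @param lags Integer vector of lags to scan (default `-2:2`).
#' @param r_threshold Minimum acceptable lag-0 correlation (default 0.32).
#' @return Data frame with one row per series: `series_id`, `best_lag`,
#'   `r_best`, `r_lag0`, `flagged`.
#' @export
crossdate_screen <- function(group, lags = -2:2, r_threshold = 0.32) {
  if (inherits(group, "rws_collection")) group <- group$series
  k <- length(group)
  if (k < 3L) stop("crossdate_screen needs at least 3 series")
  bp <- lapply(group, bp_standardize)
  ids <- vapply(seq_len(k), function(i) {
    s <- group[[i]]
    if (inherits(s, "rws")) s$series_id else paste0("S", i)
  }, character(1))
  rows <- lapply(seq_len(k), function(i) {
    others <- bp[-i]
    yrs <- sort(unique(as.integer(unlist(lapply(others, names)))))
    ref <- vapply(yrs, function(y) {
      v <- unlist(lapply(others, function(b) b[as.character(y)]))
      mean(v, na.rm = TRUE)
    }, numeric(1))
    names(ref) <- yrs
    self <- bp[[i]]
    self_years <- as.integer(names(self))
    rs <- vapply(lags, function(L) {
      shifted_years <- self_years - L        # value at year+L compared at year
      shared <- intersect(shifted_years, yrs)
      if (length(shared) < 3L) return(NA_real_)
      stats::cor(self[as.character(shared + L)], ref[as.character(shared)])
    }, numeric(1))
    if (all(is.na(rs))) {
      best <- NA_integer_; rb <- NA_real_
    } else {
      best <- lags[which.max(rs)]
      rb <- max(rs, na.rm = TRUE)
    }
    r0 <- rs[match(0L, lags)]
    data.frame(series_id = ids[i], best_lag = best, r_best = rb,
               r_lag0 = r0,
               flagged = isTRUE(best != 0L) || isTRUE(r0 < r_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
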