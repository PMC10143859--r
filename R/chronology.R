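#' Mean sensitivity
#'
#' Mean relative change between adjacent ring widths,
#' `100 * mean(2 |x_t - x_{t-1}| / (x_t + x_{t-1}))` in percent; the
#' classical measure of how responsive a series is to year-to-year
#' environmental forcing. Bounded in \[0, 200\] percent (200 is attained
#' when rings alternate with zeros). Adjacent pairs whose sum is zero (two
#' consecutive missing rings) are skipped; their count is attached as
#' attribute `"n_skipped"`.
#'
#' @param x An [rws] object or numeric vector, length >= 2.
#' @return Mean sensitivity in percent.
#' @examples
#' mean_sensitivity(c(100, 200))  # 66.67
#' @export
mean_sensitivity <- function(x) {
  w <- series_values(x)
  n <- length(w)
  if (n < 2L) stop("mean_sensitivity needs at least 2 values")
  s <- w[-1] + w[-n]
  ok <- s > 0
  if (!any(ok)) stop("all adjacent pairs are zero")
  ms <- 100 * mean(2 * abs(diff(w))[ok] / s[ok])
  structure(ms, n_skipped = sum(!ok))
}

#' First-order autocorrelation
#'
#' Pearson correlation of a series with itself shifted by one year,
#' quantifying the dependence of growth on the previous year's growth.
#'
#' @param x An [rws] object or numeric vector, length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   lagged slice has zero variance.
#' @export
ac1 <- function(x) {
  w <- unname(series_values(x))
  n <- length(w)
  if (n < 3L) stop("ac1 needs at least 3 values")
  a <- w[-n]; b <- w[-1]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("ac1 undefined: zero variance in a lagged slice")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Mean inter-series correlation (Rbar)
#'
#' Arithmetic mean of all pairwise Pearson correlations in a group of
#' (typically detrended) series. By default each pair is correlated over its
#' own maximal shared years; passing `interval` restricts every pair to a
#' fixed common window. Pairs with fewer than 3 shared years are skipped
#' (count in attribute `"n_skipped_pairs"`).
#'
#' @param group List of [rws] objects / numeric vectors or an
#'   [rws_collection]; at least 2 series.
#' @param interval Optional `c(start, end)` calendar years.
#' @return Mean correlation.
#' @export
rbar <- function(group, interval = NULL) {
  if (inherits(group, "rws_collection")) group <- group$series
  k <- length(group)
  if (k < 2L) stop("rbar needs at least 2 series")
  vals <- lapply(group, series_values)
  if (!is.null(interval)) {
    keepyrs <- as.character(seq(interval[1], interval[2]))
    vals <- lapply(vals, function(v) v[intersect(names(v), keepyrs)])
  }
  rs <- c(); skipped <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- intersect(names(vals[[i]]), names(vals[[j]]))
    if (length(shared) < 3L) { skipped <- skipped + 1L; next }
    rs <- c(rs, stats::cor(vals[[i]][shared], vals[[j]][shared]))
  }
  if (!length(rs)) stop("no series pair has 3 or more shared years")
  structure(mean(rs), n_skipped_pairs = skipped)
}

#' Signal-to-noise ratio of a chronology
#'
#' `S/N = N * r / (1 - r)` where `r` is the mean inter-series correlation
#' and `N` the number of series: the strength of the common signal relative
#' to series-specific noise.
#'
#' @param n Number of series.
#' @param rbar Mean inter-series correlation, `< 1`.
#' @return The ratio (with a warning when `rbar < 0`); `Inf` when
#'   `rbar = 1`.
#' @export
snr <- function(n, rbar) {
  if (n < 1) stop("n must be >= 1")
  if (rbar > 1) stop("rbar must be <= 1")
  if (rbar == 1) return(Inf)
  if (rbar < 0) warning("negative rbar: signal-to-noise ratio is negative")
  n * rbar / (1 - rbar)
}

#' Expressed population signal
#'
#' `EPS = SNR / (1 + SNR)`: how closely a finite-sample chronology tracks
#' the hypothetically perfect (infinite-sample) chronology. A value of 0.85
#' is the conventional acceptability threshold.
#'
#' @param snr Signal-to-noise ratio, `>= 0` (infinite SNR gives EPS 1).
#' @return EPS in `[0, 1]`.
#' @examples
#' eps_from_snr(24.9)  # 0.961
#' @export
eps_from_snr <- function(snr) {
  ifelse(is.infinite(snr), 1, snr / (1 + snr))
}

#' @rdname eps_from_snr
#' @param n Number of series.
#' @param rbar Mean inter-series correlation.
#' @export
eps <- function(n, rbar) eps_from_snr(snr(n, rbar))

#' Variance explained by the first principal component
#'
#' Eigen-decomposes the inter-series correlation matrix of a group over a
#' fixed interval (every series must cover it) and reports the percentage
#' of variance carried by the first eigenvector — the share of common
#' (typically climatic) variance.
#'
#' @param group List of [rws] objects / numeric vectors or an
#'   [rws_collection]; at least 2 series fully covering `interval`.
#' @param interval `c(start, end)` calendar years, at least 3 years; when
#'   `NULL`, the group's common interval is used.
#' @return Percentage in `(0, 100]`.
#' @export
ev_first <- function(group, interval = NULL) {
  if (inherits(group, "rws_collection")) group <- group$series
  if (length(group) < 2L) stop("ev_first needs at least 2 series")
  vals <- lapply(group, series_values)
  if (is.null(interval)) {
    shared <- Reduce(intersect, lapply(vals, names))
    if (length(shared) < 3L) stop("interval must span at least 3 years")
  } else {
    if (interval[2] - interval[1] + 1 < 3)
      stop("interval must span at least 3 years")
    shared <- as.character(seq(interval[1], interval[2]))
  }
  mat <- vapply(vals, function(v) {
    if (!all(shared %in% names(v)))
      stop("every series must fully cover the interval")
    unname(v[shared])
  }, numeric(length(shared)))
  cm <- stats::cor(mat)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  100 * max(ev) / ncol(mat)
}

#' Build a chronology with spread bands
#'
#' Per calendar year, across the series present that year: mean, median,
#' quartiles (25th/75th), 5th/95th percentiles and sample depth. This is
#' the plain (unweighted arithmetic) chronology used throughout the
#' package's comparisons and reports.
#'
#' @param group List of [rws] objects or an [rws_collection]; at least 1.
#' @return A data frame of class `"chronology"` with columns `year`, `mean`,
#'   `median`, `q25`, `q75`, `p5`, `p95`, `depth`.
#' @export
build_chronology <- function(group) {
  if (inherits(group, "rws_collection")) group <- group$series
  if (length(group) < 1L) stop("build_chronology needs at least 1 series")
  vals <- lapply(group, series_values)
  yrs <- sort(unique(as.integer(unlist(lapply(vals, names)))))
  rows <- lapply(yrs, function(y) {
    v <- unlist(lapply(vals, function(w) w[as.character(y)]))
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(year = y, mean = mean(v), median = q[3], q25 = q[2],
               q75 = q[4], p5 = q[1], p95 = q[5], depth = length(v))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("chronology", "data.frame")
  out
}

#' Chronology mean as a series
#'
#' The per-year mean of a group, wrapped as an [rws] so it can feed the
#' synchrony machinery (e.g. stock-versus-stock comparisons).
#'
#' @param group List of [rws] objects or an [rws_collection].
#' @param series_id,site,stock,shoot,radius Labels for the mean series.
#' @return An [rws].
#' @export
chronology_mean_series <- function(group, series_id = "mean",
                                   site = NA_character_,
                                   stock = NA_character_,
                                   shoot = NA_character_, radius = "mean") {
  ch <- build_chronology(group)
  if (any(diff(ch$year) != 1L))
    stop("group coverage has gaps; cannot form a dense mean series")
  rws(series_id, ch$mean, ch$year[1], site = site, stock = stock,
      shoot = shoot, radius = radius)
}

#' Homogeneity statistics of a detrended group
#'
#' The per-group summary used for Table-style reporting: each series is
#' conservatively detrended ([fit_conservative]); mean sensitivity and
#' first-order autocorrelation are computed per detrended series over the
#' interval and averaged; Rbar is the mean pairwise correlation of the
#' detrended series (each pair over its maximal shared years); S/N and EPS
#' follow from (N, Rbar); EV is the first-eigenvector variance of the
#' detrended series over the fixed interval.
#'
#' @param group List of [rws] objects or an [rws_collection]; at least 2
#'   series covering `interval`.
#' @param interval `c(start, end)` calendar years; defaults to the group's
#'   common interval.
#' @return An object of class `"chronology_stats"`: list with `n_series`,
#'   `ms_percent`, `ac1`, `rbar`, `snr`, `eps`, `ev_percent`, `interval`.
#' @export
group_stats <- function(group, interval = NULL) {
  if (inherits(group, "rws_collection")) group <- group$series
  if (length(group) < 2L) stop("group_stats needs at least 2 series")
  if (is.null(interval)) interval <- unname(common_interval(group))
  idx <- lapply(group, detrended_indices)
  idx_win <- lapply(idx, rws_window, start = interval[1], end = interval[2])
  ms <- mean(vapply(idx_win, function(s) as.numeric(mean_sensitivity(s)),
                    numeric(1)))
  acs <- vapply(idx_win, function(s)
    suppressWarnings(as.numeric(ac1(s))), numeric(1))
  rb <- as.numeric(rbar(idx))
  n <- length(group)
  s <- snr(n, rb)
  structure(list(n_series = n, ms_percent = ms,
                 ac1 = mean(acs, na.rm = TRUE), rbar = rb, snr = s,
                 eps = eps_from_snr(s),
                 ev_percent = ev_first(idx, interval),
                 interval = as.integer(interval)),
            class = "chronology_stats")
}

#' @export
print.chronology_stats <- function(x, ...) {
  cat(sprintf(
    "<chronology_stats> N=%d [%d-%d]  MS %.1f%%  AC %.3f  Rbar %.3f  S/N %.1f  EPS %.3f  EV %.1f%%\n",
    x$n_series, x$interval[1], x$interval[2], x$ms_percent, x$ac1, x$rbar,
    x$snr, x$eps, x$ev_percent))
  invisible(x)
}

#' Sample size needed to reach an EPS target
#'
#' Inverts the EPS formula: the smallest integer number of series `N` with
#' `N * rbar / (N * rbar + 1 - rbar) >= eps_target`. The basis of
#' replication recommendations for sampling designs.
#'
#' @param rbar Mean inter-series correlation, in `(0, 1)`.
#' @param eps_target EPS threshold, in `(0, 1)`; default 0.85.
#' @return Integer `N`, or `NA` (with a warning) when `rbar <= 0` makes the
#'   target unattainable.
#' @examples
#' recommend_n(0.5)        # 6
#' recommend_n(0.9, 0.85)  # 1
#' @export
recommend_n <- function(rbar, eps_target = 0.85) {
  if (eps_target <= 0 || eps_target >= 1) stop("eps_target must be in (0, 1)")
  if (rbar >= 1) stop("rbar must be < 1")
  if (rbar <= 0) {
    warning("rbar <= 0: EPS target unattainable")
    return(NA_integer_)
  }
  n <- ceiling(eps_target * (1 - rbar) / (rbar * (1 - eps_target)) - 1e-12)
  n <- max(1L, as.integer(n))
  while (eps(n, rbar) < eps_target) n <- n + 1L   # guard against rounding
  n
}
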