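#' Conservative detrending to dimensionless growth indices
#'
#' Removes the age/size-related growth trend from a ring-width series the
#' conservative way: a modified negative exponential
#' `w(tau) = a * exp(-b * tau) + k` (with `a > 0`, `b > 0`, `k >= 0`, `tau`
#' the ring index from the pith) is attempted first; if the fit fails, is
#' non-declining, or is not everywhere positive, an ordinary least-squares
#' line is used when its slope is non-positive and its predictions stay
#' positive; otherwise a horizontal line at the series mean. Indices are the
#' ratio observed / predicted, so a trend-free series has indices around 1.
#'
#' Zero widths (inserted missing rings) are kept in the fit: they carry
#' level information, and the ratio index at such a year is simply 0.
#'
#' @param x An [rws] object or numeric vector of ring widths (micrometres).
#' @return An object of class `"detrend_result"`: list with `method` (one of
#'   `"negexp"`, `"linear"`, `"mean"`), `coef`, `fitted` (always positive),
#'   `indices` (same length as the input, named by year when available) and
#'   `notes` (character vector of soft findings, e.g. an index mean far from
#'   1).
#' @examples
#' w <- 800 * exp(-0.08 * (1:30)) + 200
#' fit_conservative(w)$method
#' @export
fit_conservative <- function(x) {
  w <- series_values(x)
  n <- length(w)
  if (sum(w > 0) < 5L)
    stop("fit_conservative needs at least 5 non-zero widths")
  if (all(w == 0)) stop("degenerate series: all widths zero")
  tau <- seq_len(n)
  notes <- character()
  method <- NULL; fitted <- NULL; cf <- NULL

  if (stats::var(w) > 0) {
    a0 <- max(mean(utils::head(w, 3)) - mean(utils::tail(w, 3)),
              0.1 * mean(w[w > 0]))
    k0 <- max(mean(utils::tail(w, 3)), 1)
    st <- list(a = a0, b = 2 / n, k = k0)
    fit <- tryCatch(
      minpack.lm::nlsLM(w ~ a * exp(-b * tau) + k, start = st,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      f <- p["a"] * exp(-p["b"] * tau) + p["k"]
      decline <- f[1] - f[n]
      if (is.finite(p["a"]) && p["a"] > 0 && p["b"] > 0 && p["k"] >= 0 &&
          all(f > 0) && decline > 1e-4 * mean(w)) {
        method <- "negexp"; fitted <- as.numeric(f); cf <- p
      }
    }
  }
  if (is.null(method)) {
    lf <- stats::lm.fit(cbind(1, tau), w)
    slope <- lf$coefficients[2]
    f <- as.numeric(cbind(1, tau) %*% lf$coefficients)
    if (slope <= 0 && all(f > 0)) {
      method <- "linear"; fitted <- f
      cf <- c(intercept = unname(lf$coefficients[1]), slope = unname(slope))
    }
  }
  if (is.null(method)) {
    method <- "mean"
    fitted <- rep(mean(w), n)
    cf <- c(mean = mean(w))
  }
  indices <- w / fitted
  names(indices) <- names(w)
  mi <- mean(indices)
  if (mi < 0.8 || mi > 1.2)
    notes <- c(notes, sprintf("mean index %.3f outside [0.8, 1.2]", mi))
  structure(list(method = method, coef = cf, fitted = fitted,
                 indices = indices, notes = notes),
            class = "detrend_result")
}

#' @export
print.detrend_result <- function(x, ...) {
  cat(sprintf("<detrend_result> method=%s, n=%d, mean index %.3f\n",
              x$method, length(x$indices), mean(x$indices)))
  invisible(x)
}

#' Detrended indices as a year-indexed series
#'
#' Convenience wrapper: detrends an [rws] and returns its indices as an
#' `rws`-like object so the synchrony and chronology machinery can align
#' them by calendar year. The `radius` label is preserved.
#'
#' @param x An [rws] object.
#' @return An [rws] whose "widths" slot carries dimensionless indices.
#' @export
detrended_indices <- function(x) {
  stopifnot(inherits(x, "rws"))
  d <- fit_conservative(x)
  rws(x$series_id, unname(d$indices), x$first_year,
      site = x$site, stock = x$stock, shoot = x$shoot, radius = x$radius)
}

#' Baillie-Pilcher log standardization
#'
#' The classic pre-processing behind the t_BP cross-dating score: each ring
#' width is expressed as the natural log of 100 times its ratio to the
#' centred 5-year moving average of the series. The first two and last two
#' years are dropped so that every retained value is built from a complete
#' 5-year window. Missing rings (width 0) are floored at 1 micrometre before
#' the log.
#'
#' @param x An [rws] object or numeric vector (length >= 7).
#' @return Numeric vector of length `n - 4`, named by calendar year when the
#'   input carries years.
#' @examples
#' bp_standardize(rep(500, 10))[1]  # log(100) for any constant series
#' @export
bp_standardize <- function(x) {
  w <- series_values(x)
  n <- length(w)
  if (n < 7L) stop("bp_standardize needs at least 7 rings")
  w[w == 0] <- 1
  ma <- stats::filter(w, rep(1 / 5, 5), sides = 2)
  keep <- 3:(n - 2)
  out <- log(100 * w[keep] / as.numeric(ma[keep]))
  names(out) <- names(w)[keep]
  out
}

#' FFT low-pass filter
#'
#' Extracts the long-term trend of a series by zeroing all discrete Fourier
#' coefficients whose period is strictly shorter than `cutoff_years` and
#' inverting the transform. The DC component is untouched, so the output
#' mean equals the input mean; the operator is linear and idempotent.
#'
#' @param x Numeric vector (length >= 4); an [rws] is accepted and its
#'   widths used.
#' @param cutoff_years Shortest period (in years) to retain; default 3.
#' @return Numeric vector of the same length (names preserved).
#' @export
lowpass_trend <- function(x, cutoff_years = 3) {
  v <- series_values(x)
  if (length(v) < 4L) stop("lowpass_trend needs at least 4 values")
  if (any(!is.finite(v))) stop("non-finite input")
  n <- length(v)
  fv <- stats::fft(v)
  k <- 0:(n - 1)
  cycles <- pmin(k, n - k)          # cycles over the record
  period <- ifelse(cycles == 0, Inf, n / cycles)
  fv[period < cutoff_years] <- 0
  out <- Re(stats::fft(fv, inverse = TRUE)) / n
  names(out) <- if (inherits(x, "rws")) names(v) else names(x)
  out
}
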