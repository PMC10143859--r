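## Box-plot style summary (mean + median + quartiles + 5/95 percentiles) of
## the finite values of v.
box_stats <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v))
    return(data.frame(n = 0L, mean = NA_real_, median = NA_real_,
                      q25 = NA_real_, q75 = NA_real_, p5 = NA_real_,
                      p95 = NA_real_))
  q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  data.frame(n = length(v), mean = mean(v), median = q[3], q25 = q[2],
             q75 = q[4], p5 = q[1], p95 = q[5])
}

## One shoot's series for a single radius or a combination label, truncated
## (for combinations) to the radii's common window. NULL when a required
## radius is absent.
shoot_label_series <- function(x, stock, shoot, label) {
  own <- select_series(x, stock = stock, shoot = shoot)
  if (label %in% c("a", "b", "c", "d")) {
    s <- select_series(own, radius = label)
    if (length(s) != 1L) return(NULL)
    return(s$series[[1]])
  }
  need <- strsplit(label, "")[[1]]
  mem <- lapply(need, function(r) {
    s <- select_series(own, radius = r)
    if (length(s) == 1L) s$series[[1]] else NULL
  })
  if (any(vapply(mem, is.null, logical(1)))) return(NULL)
  ci <- tryCatch(common_interval(mem), error = function(e) NULL)
  if (is.null(ci)) return(NULL)
  mem <- lapply(mem, rws_window, start = ci[1], end = ci[2])
  names(mem) <- need
  combine_radii(mem, label)
}

stocks_of <- function(x) {
  st <- collection_meta(x)$stock
  sort(unique(st[!is.na(st)]))
}

shoots_of <- function(x, stock) {
  m <- collection_meta(select_series(x, stock = stock))
  sort(unique(m$shoot[!is.na(m$shoot)]))
}

significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "")))
}

#' Pooled-variance two-sample t test
#'
#' Student's classic independent-samples t test with the pooled variance
#' estimate and `n1 + n2 - 2` degrees of freedom (two-sided p). Degenerate
#' inputs are handled explicitly: zero pooled variance yields `t = 0, p = 1`
#' when the means are equal and an infinity-flagged `t` with `p = 0`
#' otherwise.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `mean1`, `mean2`.
#' @examples
#' group_ttest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p = 0.021
#' @export
group_ttest <- function(sample1, sample2) {
  s1 <- as.numeric(sample1); s2 <- as.numeric(sample2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  if (any(!is.finite(c(s1, s2)))) stop("samples must be finite")
  m1 <- mean(s1); m2 <- mean(s2)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(s1) + (n2 - 1) * stats::var(s2)) / df
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1, mean1 = m1, mean2 = m2))
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0,
                mean1 = m1, mean2 = m2))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean1 = m1, mean2 = m2)
}

## Compact letter display: groups sharing a letter are not significantly
## different pairwise at level alpha. pmat is a symmetric matrix of pairwise
## p-values. Brute-force maximal cliques of the "not different" graph
## (fine for the handful of groups the reports compare).
cld_letters <- function(pmat, alpha) {
  k <- nrow(pmat)
  if (k == 1L) return("a")
  if (k > 14L) stop("compact letter display limited to 14 groups")
  adj <- pmat > alpha
  diag(adj) <- TRUE
  subsets <- list()
  for (m in 1:(2^k - 1)) {
    idx <- which(bitwAnd(m, 2^(0:(k - 1))) > 0)
    if (all(adj[idx, idx])) subsets[[length(subsets) + 1L]] <- idx
  }
  # keep maximal cliques only
  is_max <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  cliques <- subsets[is_max]
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  letters_out <- rep("", k)
  for (ci in seq_along(cliques))
    for (g in cliques[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  letters_out
}

#' Synchrony of radii within each shoot
#'
#' The innermost level of the variability analysis: for every shoot of a
#' stock that carries all four radii, pairwise synchrony ([tbp]) is computed
#' for the comparisons a:b, c:d, a:cd, b:cd and ab:cd (cd and ab built by
#' [combine_radii] on the radii's common window). The per-stock distribution
#' of Glk and t_BP per comparison label is summarised in box-plot form.
#'
#' @param x An [rws_collection].
#' @param stock Stock label.
#' @return An object of class `"comparison_report"` with `level`
#'   `"radius_within_shoot"`, `cells` (one row per shoot x comparison),
#'   `summary` (box stats per comparison for both metrics) and `findings`.
#' @export
compare_radii_within_shoot <- function(x, stock) {
  labels <- c("a:b", "c:d", "a:cd", "b:cd", "ab:cd")
  cells <- list(); findings <- list()
  for (shoot in shoots_of(x, stock)) {
    own <- select_series(x, stock = stock, shoot = shoot)
    rads <- collection_meta(own)$radius
    if (!all(c("a", "b", "c", "d") %in% rads)) {
      findings[[length(findings) + 1L]] <- data.frame(
        stock = stock, shoot = shoot,
        message = "shoot lacks a radius; excluded", stringsAsFactors = FALSE)
      next
    }
    ci <- common_interval(own)
    win <- lapply(c("a", "b", "c", "d"), function(r)
      rws_window(select_series(own, radius = r)$series[[1]], ci[1], ci[2]))
    names(win) <- c("a", "b", "c", "d")
    win$ab <- combine_radii(win[c("a", "b")], "ab")
    win$cd <- combine_radii(win[c("c", "d")], "cd")
    for (lab in labels) {
      pr <- strsplit(lab, ":")[[1]]
      s <- tryCatch(tbp(win[[pr[1]]], win[[pr[2]]]), error = function(e) NULL)
      if (is.null(s)) {
        findings[[length(findings) + 1L]] <- data.frame(
          stock = stock, shoot = shoot,
          message = sprintf("comparison %s failed (overlap)", lab),
          stringsAsFactors = FALSE)
        next
      }
      cells[[length(cells) + 1L]] <- data.frame(
        stock = stock, shoot = shoot, comparison = lab,
        glk_percent = s$glk_percent, glk_p = s$glk_p,
        overlap_n = s$overlap_n, r = s$r, t_bp = s$t_bp,
        stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(stock = character(), shoot = character(),
               comparison = character(), glk_percent = numeric(),
               glk_p = numeric(), overlap_n = integer(), r = numeric(),
               t_bp = numeric(), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(labels, function(lab) {
    sub <- cells[cells$comparison == lab, ]
    cbind(data.frame(comparison = lab, metric = c("glk", "t_bp"),
                     stringsAsFactors = FALSE),
          rbind(box_stats(sub$glk_percent), box_stats(sub$t_bp)))
  }))
  structure(list(level = "radius_within_shoot", stock = stock, cells = cells,
                 summary = summ,
                 findings = if (length(findings)) do.call(rbind, findings)
                            else NULL),
            class = "comparison_report")
}

#' Synchrony of shoots within a stock
#'
#' For each series label (single radii a-d and combinations ab, cd, abcd),
#' the pairwise synchrony matrix over all shoots of the stock carrying that
#' label, with group means and a flag for whether the mean t_BP reaches the
#' conventional 3.5 dating threshold.
#'
#' @param x An [rws_collection].
#' @param stock Stock label.
#' @param labels Series labels to evaluate.
#' @return A `"comparison_report"` with `level` `"shoot_within_stock"`:
#'   `summary` has one row per label (mean/median Glk and t_BP, series
#'   count, infinite-t count, `meets_t35`), `matrices` holds the Glk and
#'   t_BP [pairwise_matrix] objects per label.
#' @export
compare_shoots_within_stock <- function(x, stock,
                                        labels = c("a", "b", "c", "d",
                                                   "ab", "cd", "abcd")) {
  mats <- list(); rows <- list(); findings <- list()
  for (lab in labels) {
    series <- list()
    for (shoot in shoots_of(x, stock)) {
      s <- shoot_label_series(x, stock, shoot, lab)
      if (!is.null(s)) series[[length(series) + 1L]] <- s
    }
    if (length(series) < 2L) {
      findings[[length(findings) + 1L]] <- data.frame(
        stock = stock, label = lab,
        message = "fewer than 2 shoots carry this label",
        stringsAsFactors = FALSE)
      next
    }
    mg <- pairwise_matrix(series, "glk")
    mt <- pairwise_matrix(series, "tbp")
    mats[[lab]] <- list(glk = mg, tbp = mt)
    tvals <- mt$matrix[upper.tri(mt$matrix)]
    gvals <- mg$matrix[upper.tri(mg$matrix)]
    rows[[length(rows) + 1L]] <- data.frame(
      stock = stock, label = lab, n_series = length(series),
      mean_glk = mg$mean, median_glk = stats::median(gvals, na.rm = TRUE),
      mean_t_bp = mt$mean,
      median_t_bp = stats::median(tvals[is.finite(tvals)], na.rm = TRUE),
      n_infinite_t = mt$n_excluded_infinite,
      meets_t35 = is.finite(mt$mean) && mt$mean >= 3.5,
      stringsAsFactors = FALSE)
  }
  structure(list(level = "shoot_within_stock", stock = stock,
                 summary = if (length(rows)) do.call(rbind, rows) else NULL,
                 matrices = mats,
                 findings = if (length(findings)) do.call(rbind, findings)
                            else NULL),
            class = "comparison_report")
}

#' Synchrony of stock mean series
#'
#' The outermost level: per label, each stock's mean series (per-year
#' arithmetic mean over its shoots' series of that label) is built and all
#' stock pairs are compared with [tbp]; Glk significance is annotated with
#' the usual stars (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001).
#'
#' @param x An [rws_collection] with at least 2 stocks.
#' @param labels Series labels to evaluate.
#' @return A `"comparison_report"` with `level` `"stock_vs_stock"`; `cells`
#'   has one row per label x stock pair with Glk, stars, t_BP and overlap.
#' @export
compare_stocks <- function(x, labels = c("a", "b", "c", "d",
                                         "ab", "cd", "abcd")) {
  sts <- stocks_of(x)
  if (length(sts) < 2L) stop("compare_stocks needs at least 2 stocks")
  cells <- list(); findings <- list()
  for (lab in labels) {
    means <- list()
    for (st in sts) {
      series <- list()
      for (shoot in shoots_of(x, st)) {
        s <- shoot_label_series(x, st, shoot, lab)
        if (!is.null(s)) series[[length(series) + 1L]] <- s
      }
      if (length(series) == 0L) next
      means[[st]] <- chronology_mean_series(
        series, series_id = paste0(st, "_", lab), stock = st, radius = lab)
    }
    have <- names(means)
    if (length(have) < 2L) {
      findings[[length(findings) + 1L]] <- data.frame(
        label = lab, message = "fewer than 2 stocks carry this label",
        stringsAsFactors = FALSE)
      next
    }
    for (i in seq_len(length(have) - 1)) for (j in (i + 1):length(have)) {
      s <- tryCatch(tbp(means[[have[i]]], means[[have[j]]]),
                    error = function(e) NULL)
      if (is.null(s)) {
        findings[[length(findings) + 1L]] <- data.frame(
          label = lab,
          message = sprintf("pair %s:%s failed (overlap)", have[i], have[j]),
          stringsAsFactors = FALSE)
        next
      }
      cells[[length(cells) + 1L]] <- data.frame(
        label = lab, stock_1 = have[i], stock_2 = have[j],
        glk_percent = s$glk_percent, glk_p = s$glk_p,
        stars = significance_stars(s$glk_p), t_bp = s$t_bp,
        overlap_n = s$overlap_n, stringsAsFactors = FALSE)
    }
  }
  structure(list(level = "stock_vs_stock",
                 cells = if (length(cells)) do.call(rbind, cells) else NULL,
                 findings = if (length(findings)) do.call(rbind, findings)
                            else NULL),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> level=%s\n", x$level))
  if (!is.null(x$summary)) print(utils::head(x$summary, 10))
  else if (!is.null(x$cells)) print(utils::head(x$cells, 10))
  invisible(x)
}

#' Extreme growth-year test
#'
#' Tests whether growth in a given calendar year departs from (i) the
#' preceding year — a paired two-sided t test of per-shoot widths, the same
#' shoots measured in both years — and (ii) all other years pooled — an
#' independent two-sample test ([group_ttest]).
#'
#' @param group List of shoot-level [rws] series (typically abcd means) or
#'   an [rws_collection]; at least 3 shoots must cover both `year` and
#'   `year - 1`.
#' @param year Calendar year to test.
#' @param paired Use the paired test against the preceding year (default);
#'   `FALSE` falls back to an independent-samples comparison.
#' @return List with `year`, `n_shoots`, and two records `vs_previous` and
#'   `vs_other_years`, each with `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
extreme_year_test <- function(group, year, paired = TRUE) {
  if (inherits(group, "rws_collection")) group <- group$series
  vals <- lapply(group, series_values)
  y1 <- as.character(year); y0 <- as.character(year - 1)
  has <- vapply(vals, function(v) all(c(y0, y1) %in% names(v)), logical(1))
  if (sum(has) < 3L)
    stop("fewer than 3 shoots cover the year and its predecessor")
  wy <- vapply(vals[has], function(v) v[[y1]], numeric(1))
  wp <- vapply(vals[has], function(v) v[[y0]], numeric(1))
  n <- length(wy)
  if (paired) {
    d <- wy - wp
    sdd <- stats::sd(d)
    if (sdd == 0) {
      vp <- list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 df = n - 1L, p = if (mean(d) == 0) 1 else 0,
                 mean1 = mean(wy), mean2 = mean(wp))
    } else {
      t <- mean(d) / (sdd / sqrt(n))
      vp <- list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1),
                 mean1 = mean(wy), mean2 = mean(wp))
    }
  } else {
    vp <- group_ttest(wy, wp)
  }
  other <- unlist(lapply(vals, function(v) v[setdiff(names(v), y1)]))
  vo <- group_ttest(wy, unname(other))
  list(year = as.integer(year), n_shoots = n, vs_previous = vp,
       vs_other_years = vo)
}

#' Long-term growth trends per stock
#'
#' Builds each stock's mean abcd chronology, extracts its long-term trend
#' with the 3-year FFT low-pass filter ([lowpass_trend]) and classifies the
#' recent trend from the least-squares slope of the final `last_k` smoothed
#' years: `"increasing"` / `"decreasing"` when the slope magnitude exceeds
#' a dead-band of `deadband_frac` of the series mean per year, otherwise
#' `"constant"`.
#'
#' @param x An [rws_collection].
#' @param cutoff_years Low-pass cutoff period (default 3 years).
#' @param last_k Number of final smoothed years to classify (default 5).
#' @param deadband_frac Dead-band fraction of the series mean (default
#'   0.01 per year).
#' @return List with `stocks` (per stock: `chronology` data frame with
#'   `year`, `mean`, `trend`; `slope`; `classification`) and `findings`.
#' @export
trend_report <- function(x, cutoff_years = 3, last_k = 5,
                         deadband_frac = 0.01) {
  out <- list(); findings <- list()
  for (st in stocks_of(x)) {
    series <- list()
    for (shoot in shoots_of(x, st)) {
      s <- shoot_label_series(x, st, shoot, "abcd")
      if (!is.null(s)) series[[length(series) + 1L]] <- s
    }
    if (!length(series)) next
    ch <- build_chronology(series)
    if (nrow(ch) < 8L) {
      findings[[length(findings) + 1L]] <- data.frame(
        stock = st, message = "mean series shorter than 8 years; excluded",
        stringsAsFactors = FALSE)
      next
    }
    tr <- lowpass_trend(ch$mean, cutoff_years)
    tail_idx <- (nrow(ch) - last_k + 1):nrow(ch)
    fit <- stats::lm.fit(cbind(1, seq_len(last_k)), tr[tail_idx])
    slope <- unname(fit$coefficients[2])
    band <- deadband_frac * mean(ch$mean)
    cls <- if (abs(slope) < band) "constant"
           else if (slope > 0) "increasing" else "decreasing"
    out[[st]] <- list(
      chronology = data.frame(year = ch$year, mean = ch$mean, trend = tr),
      slope = slope, classification = cls)
  }
  list(stocks = out,
       findings = if (length(findings)) do.call(rbind, findings) else NULL)
}

#' Run the full three-level analysis pipeline
#'
#' Orchestrates the package on one collection: validation; a per-stock
#' sample description with significance letters (shoot counts, age and mean
#' ring width, pairwise [group_ttest] at `alpha_desc`); per-stock
#' homogeneity statistics per series label ([group_stats]); the three
#' comparison levels ([compare_radii_within_shoot],
#' [compare_shoots_within_stock], [compare_stocks]); extreme-year tests; and
#' the low-pass trend report. Stages fail independently: an error is
#' recorded under `errors` and later stages still run. Output is
#' deterministic given the input collection and config.
#'
#' @param x An [rws_collection].
#' @param config List of options: `alpha_desc` (letters in the sample
#'   description, default 0.01), `interval` (`c(start, end)` for the
#'   statistics table; default each stock's common interval),
#'   `extreme_years` (years to test; `NULL` picks the strongest increase
#'   and decrease of the all-stock mean chronology), `labels` (series
#'   labels, default a, b, c, d, ab, cd, abcd).
#' @return An object of class `"pipeline_report"`: list with `validation`,
#'   `description`, `stats_table`, `stock_comparison`, `radius_reports`,
#'   `shoot_reports`, `extreme_years`, `trends`, `errors`.
#' @seealso [write_report_bundle()]
#' @export
run_pipeline <- function(x, config = list()) {
  cfg <- utils::modifyList(
    list(alpha_desc = 0.01, interval = NULL, extreme_years = NULL,
         labels = c("a", "b", "c", "d", "ab", "cd", "abcd")), config)
  errors <- list()
  note_err <- function(stage, e)
    errors[[stage]] <<- conditionMessage(e)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) { note_err(name, e); NULL })

  validation <- validate_collection(x)
  sts <- stocks_of(x)

  ## per-shoot abcd mean series per stock, reused by several stages
  shoot_means <- list()
  for (st in sts) {
    lst <- list()
    for (shoot in shoots_of(x, st)) {
      s <- shoot_label_series(x, st, shoot, "abcd")
      if (!is.null(s)) lst[[shoot]] <- s
    }
    shoot_means[[st]] <- lst
  }

  description <- stage("description", {
    if (!length(sts)) NULL else {
      rows <- lapply(sts, function(st) {
        lst <- shoot_means[[st]]
        ages <- vapply(lst, function(s) length(s$widths), integer(1))
        mw <- vapply(lst, function(s) mean(s$widths), numeric(1))
        data.frame(stock = st, n_shoots = length(lst),
                   age_min = min(ages), age_max = max(ages),
                   age_mean = mean(ages), age_sd = stats::sd(ages),
                   rw_mean = mean(mw), rw_sd = stats::sd(mw),
                   stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, rows)
      if (length(sts) > 1L) {
        pm_rw <- pm_age <- matrix(1, length(sts), length(sts))
        for (i in seq_len(length(sts) - 1)) for (j in (i + 1):length(sts)) {
          mi <- shoot_means[[sts[i]]]; mj <- shoot_means[[sts[j]]]
          pm_rw[i, j] <- pm_rw[j, i] <- group_ttest(
            vapply(mi, function(s) mean(s$widths), numeric(1)),
            vapply(mj, function(s) mean(s$widths), numeric(1)))$p
          pm_age[i, j] <- pm_age[j, i] <- group_ttest(
            vapply(mi, function(s) length(s$widths), numeric(1)),
            vapply(mj, function(s) length(s$widths), numeric(1)))$p
        }
        d$rw_letters <- cld_letters(pm_rw, cfg$alpha_desc)
        d$age_letters <- cld_letters(pm_age, cfg$alpha_desc)
      }
      d
    }
  })

  stats_table <- stage("stats_table", {
    rows <- list()
    for (st in sts) for (lab in cfg$labels) {
      series <- list()
      for (shoot in shoots_of(x, st)) {
        s <- shoot_label_series(x, st, shoot, lab)
        if (!is.null(s)) series[[length(series) + 1L]] <- s
      }
      if (length(series) < 2L) next
      iv <- cfg$interval
      if (is.null(iv)) iv <- unname(common_interval(series))
      g <- group_stats(series, iv)
      rows[[length(rows) + 1L]] <- data.frame(
        stock = st, label = lab, n_series = g$n_series,
        interval_start = g$interval[1], interval_end = g$interval[2],
        ms_percent = g$ms_percent, ac1 = g$ac1, eps = g$eps, snr = g$snr,
        rbar = g$rbar, ev_percent = g$ev_percent, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  stock_comparison <- if (length(sts) >= 2L)
    stage("stock_comparison", compare_stocks(x, cfg$labels)) else NULL
  radius_reports <- stage("radius_reports",
    stats::setNames(lapply(sts, function(st)
      compare_radii_within_shoot(x, st)), sts))
  shoot_reports <- stage("shoot_reports",
    stats::setNames(lapply(sts, function(st)
      compare_shoots_within_stock(x, st,
        labels = intersect(cfg$labels, c("a", "b", "c", "d",
                                         "ab", "cd", "abcd")))), sts))

  extreme <- stage("extreme_years", {
    yrs <- cfg$extreme_years
    if (is.null(yrs)) {
      all_means <- unlist(shoot_means, recursive = FALSE)
      if (length(all_means)) {
        ch <- build_chronology(all_means)
        rel <- diff(ch$mean) / utils::head(ch$mean, -1)
        cov_ok <- utils::tail(ch$depth, -1) >= 3 & utils::head(ch$depth, -1) >= 3
        rel[!cov_ok] <- NA
        yrs <- unique(c(ch$year[-1][which.max(rel)],
                        ch$year[-1][which.min(rel)]))
      }
    }
    if (is.null(yrs) || !length(yrs)) NULL else {
      recs <- list()
      for (st in sts) for (y in yrs) {
        r <- tryCatch(extreme_year_test(unname(shoot_means[[st]]), y),
                      error = function(e) NULL)
        if (is.null(r)) next
        recs[[length(recs) + 1L]] <- data.frame(
          stock = st, year = r$year, n_shoots = r$n_shoots,
          t_vs_previous = r$vs_previous$t, p_vs_previous = r$vs_previous$p,
          t_vs_other = r$vs_other_years$t, p_vs_other = r$vs_other_years$p,
          mean_year = r$vs_previous$mean1,
          mean_previous = r$vs_previous$mean2, stringsAsFactors = FALSE)
      }
      if (length(recs)) do.call(rbind, recs) else NULL
    }
  })

  trends <- stage("trends", trend_report(x))

  structure(list(validation = validation, description = description,
                 stats_table = stats_table,
                 stock_comparison = stock_comparison,
                 radius_reports = radius_reports,
                 shoot_reports = shoot_reports,
                 extreme_years = extreme, trends = trends,
                 errors = errors),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  validation findings: %d\n", nrow(x$validation)))
  if (!is.null(x$description)) {
    cat("  sample description:\n"); print(x$description)
  }
  if (!is.null(x$stats_table))
    cat(sprintf("  stats table: %d rows\n", nrow(x$stats_table)))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

## Deterministic number formatting for report files.
fmt_table <- function(d, digits = 6) {
  for (nm in names(d)) {
    if (is.numeric(d[[nm]]) && !is.integer(d[[nm]]))
      d[[nm]] <- formatC(d[[nm]], digits = digits, format = "g")
  }
  d
}

#' Write a pipeline report bundle to disk
#'
#' Serialises every table of a [run_pipeline] result as tab-separated text
#' plus a short plain-text summary. Output is byte-deterministic for a given
#' report.
#'
#' @param report A `"pipeline_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(d, name) {
    if (is.null(d) || !nrow(d)) return()
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(fmt_table(d), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <<- c(paths, p)
  }
  put(report$validation, "validation")
  put(report$description, "description")
  put(report$stats_table, "stats_table")
  if (!is.null(report$stock_comparison))
    put(report$stock_comparison$cells, "stock_comparison")
  for (st in names(report$radius_reports)) {
    put(report$radius_reports[[st]]$cells, paste0("radius_cells_", st))
    put(report$radius_reports[[st]]$summary, paste0("radius_summary_", st))
  }
  for (st in names(report$shoot_reports))
    put(report$shoot_reports[[st]]$summary, paste0("shoot_summary_", st))
  put(report$extreme_years, "extreme_years")
  if (!is.null(report$trends)) {
    for (st in names(report$trends$stocks)) {
      d <- report$trends$stocks[[st]]$chronology
      put(d, paste0("trend_", st))
    }
    cls <- lapply(names(report$trends$stocks), function(st)
      data.frame(stock = st,
                 slope = report$trends$stocks[[st]]$slope,
                 classification = report$trends$stocks[[st]]$classification,
                 stringsAsFactors = FALSE))
    if (length(cls)) put(do.call(rbind, cls), "trend_classification")
  }
  summ <- c("shrubrings pipeline report",
            sprintf("validation findings: %d", nrow(report$validation)),
            sprintf("stage errors: %s",
                    if (length(report$errors))
                      paste(names(report$errors), collapse = ", ")
                    else "none"),
            sprintf("tables written: %d", length(paths)))
  writeLines(summ, file.path(dir, "summary.txt"))
  invisible(c(paths, file.path(dir, "summary.txt")))
}
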