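test_that("pooled t test matches hand computation and base R", {
  r <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- group_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$t, -3.674, tolerance = 1e-3)
  expect_equal(r2$df, 4L)
  expect_equal(r2$p, 0.0213, tolerance = 1e-3)
  bt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r2$t, unname(bt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, bt$p.value, tolerance = 1e-12)

  # invariant under a common shift
  set.seed(3)
  a <- rnorm(8); b <- rnorm(10, 1)
  expect_equal(group_ttest(a + 100, b + 100)$t, group_ttest(a, b)$t,
               tolerance = 1e-9)

  # degenerate: zero pooled variance
  expect_equal(group_ttest(c(2, 2), c(2, 2))$p, 1)
  dg <- group_ttest(c(2, 2), c(5, 5))
  expect_identical(dg$t, -Inf)
  expect_equal(dg$p, 0)
})

test_that("extreme-year test is null on identical years and antisymmetric", {
  sh <- lapply(1:5, function(i)
    rws(paste0("s", i), c(100 + i, 100 + i, 100 + i), 2000))
  r <- extreme_year_test(sh, 2001)
  expect_equal(r$vs_previous$t, 0)
  expect_equal(r$vs_previous$p, 1)

  set.seed(8)
  A <- rnorm(6, 200, 20); B <- rnorm(6, 260, 20)
  g1 <- lapply(1:6, function(i) rws(paste0("s", i), c(B[i], A[i]), 2000))
  g2 <- lapply(1:6, function(i) rws(paste0("s", i), c(A[i], B[i]), 2000))
  r1 <- extreme_year_test(g1, 2001)
  r2 <- extreme_year_test(g2, 2001)
  expect_equal(r1$vs_previous$t, -r2$vs_previous$t, tolerance = 1e-12)
  expect_error(extreme_year_test(sh[1:2], 2001), "3 shoots")
})

test_that("a constructed single-year growth pulse is detected", {
  for (sd in 1:3) {
    stand <- generate_stand(quiet_scenario(
      seed = 900 + sd, n_stocks = 1, shoots_per_stock = 15,
      site_multipliers = c(WE = 1), sigma_climate = 0, sigma_noise = 0.15,
      pulse_years = c("2010" = 1.6)))
    shoots <- lapply(shrubrings:::shoots_of(stand, "WE1"), function(s)
      shrubrings:::shoot_label_series(stand, "WE1", s, "abcd"))
    r <- extreme_year_test(shoots, 2010)
    expect_lte(r$vs_previous$p, 0.001)
    expect_gt(r$vs_previous$mean1, r$vs_previous$mean2)
  }
})

test_that("four identical radii give perfect within-shoot synchrony", {
  base <- make_series(seed = 70, n = 21)
  coll <- rws_collection(lapply(c("a", "b", "c", "d"), function(r)
    rws(paste0("XX101", r), unname(base$widths), base$first_year,
        site = "XX", stock = "XX1", shoot = "01", radius = r)))
  rep1 <- compare_radii_within_shoot(coll, "XX1")
  expect_equal(nrow(rep1$cells), 5L)  # a:b, c:d, a:cd, b:cd, ab:cd
  expect_true(all(rep1$cells$glk_percent == 100))
  expect_true(all(is.infinite(rep1$cells$t_bp)))
})

test_that("permuting one radius's years destroys within-shoot synchrony", {
  stand <- generate_stand(quiet_scenario(seed = 91, sigma_climate = 0.3,
                                         sigma_noise = 0.1))
  coll <- select_series(stand, stock = "WE1", shoot = "01")
  ok <- compare_radii_within_shoot(coll, "WE1")
  expect_gt(min(ok$cells$t_bp), 3.5)   # intact shoot: strong agreement

  set.seed(92)
  ser <- coll$series
  ia <- which(vapply(ser, `[[`, character(1), "radius") == "a")
  ser[[ia]] <- rws(ser[[ia]]$series_id,
                   sample(unname(ser[[ia]]$widths)),
                   ser[[ia]]$first_year, site = ser[[ia]]$site,
                   stock = ser[[ia]]$stock, shoot = ser[[ia]]$shoot,
                   radius = "a")
  shuf <- compare_radii_within_shoot(rws_collection(ser), "WE1")
  a_cells <- shuf$cells[shuf$cells$comparison %in% c("a:b", "a:cd"), ]
  expect_lt(stats::median(a_cells$t_bp), 3.5)
})

test_that("a stand of clones has perfect shoot-level synchrony", {
  base <- make_series(seed = 81, n = 21)  # no tied adjacent widths
  ser <- list()
  for (sh in 1:4) for (r in c("a", "b", "c", "d"))
    ser[[length(ser) + 1L]] <- rws(
      sprintf("XX1%02d%s", sh, r), unname(base$widths), base$first_year,
      site = "XX", stock = "XX1", shoot = sprintf("%02d", sh), radius = r)
  rep2 <- compare_shoots_within_stock(rws_collection(ser), "XX1")
  expect_true(all(rep2$summary$mean_glk == 100))
  expect_true(all(rep2$summary$n_infinite_t ==
                  choose(rep2$summary$n_series, 2)))
})

test_that("boosted low-noise radius a attains the highest shoot-level Glk", {
  stand <- generate_stand(quiet_scenario(
    seed = 85, sigma_climate = 0.25,
    sigma_noise = c(a = 0.1, b = 0.35, c = 0.35, d = 0.35)))
  rep3 <- compare_shoots_within_stock(stand, "IM2")
  singles <- rep3$summary[rep3$summary$label %in% c("a", "b", "c", "d"), ]
  expect_equal(singles$label[which.max(singles$mean_glk)], "a")
})

test_that("averaging radii does not hurt shoot-level synchrony", {
  stand <- generate_stand(scenario_paper_like(seed = 86))
  rep4 <- compare_shoots_within_stock(stand, "WE1")
  s <- rep4$summary
  best_single <- max(s$mean_t_bp[s$label %in% c("a", "b", "c", "d")])
  expect_gte(s$mean_t_bp[s$label == "abcd"], best_single - 0.5)
})

test_that("stocks sharing a climate signal synchronise significantly", {
  stand <- generate_stand(quiet_scenario(
    seed = 95, n_stocks = 2, shoots_per_stock = 8,
    site_multipliers = c(WE = 0.9, IM = 1.1),
    sigma_climate = 0.3, sigma_noise = 0.1))
  rep5 <- compare_stocks(stand, labels = c("a", "abcd"))
  expect_true(all(rep5$cells$glk_p <= 0.001))
  expect_true(all(rep5$cells$stars == "***"))
})

test_that("stock comparison is symmetric in series order", {
  stand <- generate_stand(quiet_scenario(
    seed = 96, n_stocks = 2, shoots_per_stock = 5,
    site_multipliers = c(WE = 0.9, IM = 1.1)))
  r1 <- compare_stocks(stand, labels = "abcd")
  r2 <- compare_stocks(stand[rev(seq_len(length(stand)))], labels = "abcd")
  expect_equal(r1$cells$glk_percent, r2$cells$glk_percent)
  expect_equal(r1$cells$t_bp, r2$cells$t_bp)
})

test_that("stocks with independent year signals rarely synchronise", {
  sig <- vapply(1:25, function(sd) {
    s1 <- generate_stand(quiet_scenario(
      seed = 2000 + sd, n_stocks = 1, shoots_per_stock = 5,
      site_multipliers = c(WE = 1), sigma_climate = 0.25))
    s2 <- generate_stand(quiet_scenario(
      seed = 3000 + sd, n_stocks = 1, shoots_per_stock = 5,
      site_multipliers = c(IM = 1), sigma_climate = 0.25))
    # relabel the second stand's stock index to keep ids distinct
    ser2 <- lapply(s2$series, function(s) {
      rws(sub("^IM1", "IM2", s$series_id), unname(s$widths), s$first_year,
          site = s$site, stock = "IM2", shoot = s$shoot, radius = s$radius)
    })
    both <- rws_collection(c(s1$series, ser2))
    r <- compare_stocks(both, labels = "abcd")
    r$cells$glk_p <= 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.8)
})

test_that("trend classification honours its dead-band and detects ramps", {
  ser <- list()
  for (sh in 1:3) for (r in c("a", "b", "c", "d"))
    ser[[length(ser) + 1L]] <- rws(
      sprintf("XX1%02d%s", sh, r), rep(500, 20), 2002,
      site = "XX", stock = "XX1", shoot = sprintf("%02d", sh), radius = r)
  tr <- trend_report(rws_collection(ser))
  expect_equal(tr$stocks[["XX1"]]$classification, "constant")
  expect_equal(tr$stocks[["XX1"]]$chronology$trend, rep(500, 20),
               tolerance = 1e-9)

  ramped <- lapply(ser, function(s) {
    w <- unname(s$widths)
    w[14:20] <- w[14:20] + seq(0, 240, by = 40)
    rws(s$series_id, w, s$first_year, site = s$site, stock = s$stock,
        shoot = s$shoot, radius = s$radius)
  })
  tr2 <- trend_report(rws_collection(ramped))
  expect_equal(tr2$stocks[["XX1"]]$classification, "increasing")
})

test_that("the pipeline is deterministic and complete on a seeded stand", {
  stand <- generate_stand(scenario_paper_like(seed = 42))
  cfg <- list(extreme_years = c(2003, 2016))
  rep1 <- run_pipeline(stand, cfg)
  rep2 <- run_pipeline(stand, cfg)
  expect_length(rep1$errors, 0L)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report_bundle(rep1, d1)
  write_report_bundle(rep2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  # Table-1 analogue letters: WE (narrow rings) separated from IM/AG
  expect_equal(rep1$description$stock, c("AG3", "IM2", "WE1"))
  # Table-2 analogue: strong common signal throughout
  expect_true(all(rep1$stats_table$eps > 0.85))
  # extreme-year records exist for both configured years in every stock
  expect_equal(nrow(rep1$extreme_years), 6L)
  expect_setequal(unique(rep1$extreme_years$year), c(2003, 2016))
})

test_that("the pipeline degrades gracefully on an empty collection", {
  rep0 <- run_pipeline(rws_collection())
  expect_s3_class(rep0, "pipeline_report")
  expect_equal(nrow(rep0$validation), 0L)
  expect_null(rep0$stats_table)
})
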