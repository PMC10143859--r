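test_that("rwl decoding matches a hand-decoded record", {
  lines <- c("WEA01Aa 2000   462   570 -9999")
  x <- read_rwl(text = lines)
  expect_length(x, 1L)
  s <- x$series[[1]]
  expect_equal(s$series_id, "WEA01Aa")
  expect_equal(s$first_year, 2000L)
  expect_equal(unname(s$widths), c(462, 570))
  expect_equal(s$radius, "a")   # position-6 letter, case-insensitive
  expect_equal(s$site, "WE")
})

test_that("empty rwl input yields an empty collection", {
  x <- read_rwl(text = character())
  expect_s3_class(x, "rws_collection")
  expect_length(x, 0L)
  expect_equal(write_rwl(x), character())
})

test_that("0.01 mm precision records are scaled to micrometres", {
  x <- read_rwl(text = "AB1      1990    10    20    30   999")
  expect_equal(unname(x$series[[1]]$widths), c(100, 200, 300))
})

test_that("a trailing 999 data value is not mistaken for a sentinel", {
  lines <- c("AB102a  1998    50   999",
             "AB102a  2000    60    70 -9999")
  x <- read_rwl(text = lines)
  expect_equal(unname(x$series[[1]]$widths), c(50, 999, 60, 70))
})

test_that("malformed rwl input raises located format errors", {
  expect_error(read_rwl(text = c("AB102a  1990    50    60 -9999",
                                 "AB102a  1990    70 -9999")),
               "overlapping|sentinel")
  expect_error(read_rwl(text = "AB102a  1990    5x    60 -9999"),
               "line 1.*non-numeric|non-numeric.*line 1")
})

test_that("write/read round trip is exact, including hierarchy labels", {
  for (sd in c(2, 9)) {
    stand <- generate_stand(sim_params(
      n_stocks = 2, shoots_per_stock = 3,
      site_multipliers = c(WE = 0.8, IM = 1.0), seed = sd))
    f <- withr::local_tempfile()
    write_rwl(stand, f)
    back <- read_rwl(f)
    expect_identical(collection_meta(stand), collection_meta(back))
    expect_identical(lapply(stand$series, `[[`, "widths"),
                     lapply(back$series, `[[`, "widths"))
  }
})

test_that("rwl writer emits one terminated record per series", {
  stand <- generate_stand(sim_params(
    n_stocks = 1, shoots_per_stock = 2, radii_labels = "a",
    site_multipliers = c(WE = 1), seed = 1))
  lines <- write_rwl(stand)
  expect_equal(sum(grepl("-9999", lines)), 2L)
  expect_error(write_rwl(rws_collection(list(
    rws("far-too-long-id", c(100, 200), 2000)))), "8 char")
})

test_that("wide table round trip preserves series and sidecar overrides labels", {
  stand <- generate_stand(sim_params(
    n_stocks = 2, shoots_per_stock = 2,
    site_multipliers = c(WE = 0.8, IM = 1.0), seed = 5))
  f <- withr::local_tempfile()
  fm <- withr::local_tempfile()
  write_rw_table(stand, f)
  write_series_meta(stand, fm)
  back <- read_rw_table(f, meta = read_series_meta(fm))
  reord <- match(collection_meta(stand)$series_id,
                 collection_meta(back)$series_id)
  expect_identical(collection_meta(stand), collection_meta(back[reord]))
  expect_identical(lapply(stand$series, `[[`, "widths"),
                   lapply(back[reord]$series, `[[`, "widths"))
})

test_that("combine_radii averages widths year by year", {
  a <- rws("XX101a", c(100, 200), 2000, radius = "a")
  b <- rws("XX101b", c(300, 400), 2000, radius = "b")
  ab <- combine_radii(list(a = a, b = b), "ab")
  expect_equal(unname(ab$widths), c(200, 300))
  expect_equal(ab$radius, "ab")

  # idempotent mean of identical members
  aa <- rws("XX101b", c(100, 200), 2000, radius = "b")
  expect_equal(unname(combine_radii(list(a = a, b = aa), "ab")$widths),
               unname(a$widths))

  abcd <- combine_radii(list(
    a = rws("s1", c(100, 100), 2000, radius = "a"),
    b = rws("s2", c(100, 100), 2000, radius = "b"),
    c = rws("s3", c(400, 400), 2000, radius = "c"),
    d = rws("s4", c(400, 400), 2000, radius = "d")), "abcd")
  expect_equal(unname(abcd$widths), c(250, 250))

  # zeros (missing rings) enter the mean as true zeros
  z <- combine_radii(list(a = rws("s1", c(0, 100), 2000, radius = "a"),
                          b = rws("s2", c(100, 100), 2000, radius = "b")),
                     "ab")
  expect_equal(unname(z$widths), c(50, 100))

  expect_error(combine_radii(list(a = a), "ab"), "required")
  expect_error(combine_radii(list(
    a = a, b = rws("s", c(1, 2, 3), 1999, radius = "b")), "ab"),
    "identical years")
})

test_that("abcd combination equals the mean of the ab and cd combinations", {
  sh <- make_shoot(seed = 11)
  ab <- combine_radii(sh[c("a", "b")], "ab")
  cd <- combine_radii(sh[c("c", "d")], "cd")
  abcd <- combine_radii(sh, "abcd")
  expect_equal(unname(abcd$widths),
               (unname(ab$widths) + unname(cd$widths)) / 2)
})

test_that("validator reports findings without raising", {
  stand <- generate_stand(sim_params(n_stocks = 1, shoots_per_stock = 2,
                                     site_multipliers = c(WE = 1), seed = 3))
  expect_equal(nrow(validate_collection(stand)), 0L)

  bad <- rws_collection(list(
    rws("XX101a", c(100, -1), 2000, stock = "XX1", shoot = "01",
        radius = "a"),
    rws("XX101a", c(100, 200), 2000, stock = "XX1", shoot = "01",
        radius = "b")))
  f <- validate_collection(bad)
  expect_true("negative_width" %in% f$kind)
  expect_true("duplicate_id" %in% f$kind)
  expect_equal(sum(f$kind == "duplicate_id"), 1L)

  single <- rws_collection(list(
    rws("XX101a", c(100, 200), 2000, stock = "XX1", shoot = "01",
        radius = "a")))
  expect_true("singleton_shoot" %in% validate_collection(single)$kind)
})

test_that("hierarchy selection partitions a stand", {
  stand <- generate_stand(sim_params(n_stocks = 2, shoots_per_stock = 3,
                                     site_multipliers = c(WE = 0.8, IM = 1),
                                     seed = 7))
  m <- collection_meta(stand)
  hits <- integer(length(stand))
  for (st in unique(m$stock)) for (sh in unique(m$shoot))
    for (r in c("a", "b", "c", "d")) {
      sel <- select_series(stand, stock = st, shoot = sh, radius = r)
      hits[match(collection_meta(sel)$series_id, m$series_id)] <-
        hits[match(collection_meta(sel)$series_id, m$series_id)] + 1L
    }
  expect_true(all(hits == 1L))
})

test_that("series windows and common intervals behave", {
  s <- rws("XX101a", c(10, 20, 30, 40), 2000)
  w <- rws_window(s, 2001, 2002)
  expect_equal(unname(w$widths), c(20, 30))
  expect_error(rws_window(s, 1999, 2002), "cover")
  g <- list(rws("p", c(1, 2, 3), 2000), rws("q", c(1, 2, 3), 2002))
  expect_equal(unname(common_interval(g)), c(2002L, 2002L))
  expect_error(common_interval(list(rws("p", c(1, 2), 2000),
                                    rws("q", c(1, 2), 2010))),
               "no common interval")
})
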