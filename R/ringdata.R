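#' Ring-width series
#'
#' The atomic unit of the package: one dated, gap-free sequence of annual
#' radial increments measured along a single radius (or a mean of radii),
#' together with its position in the sampling hierarchy
#' site / stock / shoot / radius.
#'
#' Widths are stored in micrometres. A width of exactly zero encodes a
#' missing ring inserted during cross-dating; physically absent years cannot
#' be represented (series are dense, one value per consecutive calendar
#' year).
#'
#' @param series_id Character scalar identifying the series (at most 8
#'   characters if the series is to be written to a Tucson .rwl file).
#' @param widths Numeric vector of ring widths in micrometres, length >= 2,
#'   one value per consecutive calendar year. Zero encodes a missing ring.
#' @param first_year Integer calendar year of the first width.
#' @param site,stock,shoot Character labels placing the series in the
#'   sampling hierarchy; may be `NA` when unknown.
#' @param radius Radius label: one of `"a"`, `"b"`, `"c"`, `"d"`, a
#'   combination tag (`"ab"`, `"cd"`, `"abcd"`), `"mean"`, or `NA`.
#' @return An object of class `"rws"`: a list with elements `series_id`,
#'   `site`, `stock`, `shoot`, `radius`, `first_year` and `widths` (named by
#'   calendar year).
#' @examples
#' x <- rws("WE101a", c(462, 570, 510), first_year = 2000,
#'          site = "WE", stock = "WE", shoot = "01", radius = "a")
#' rws_years(x)
#' @export
rws <- function(series_id, widths, first_year,
                site = NA_character_, stock = NA_character_,
                shoot = NA_character_, radius = NA_character_) {
  if (!is.character(series_id) || length(series_id) != 1L || is.na(series_id))
    stop("series_id must be a single character string")
  if (!is.numeric(widths) || length(widths) < 2L)
    stop("widths must be a numeric vector of length >= 2")
  if (anyNA(widths))
    stop("widths must not contain NA (a missing ring is encoded as 0)")
  first_year <- as.integer(first_year)
  if (is.na(first_year)) stop("first_year must be an integer calendar year")
  widths <- as.numeric(widths)
  names(widths) <- seq(first_year, length.out = length(widths))
  structure(
    list(series_id = series_id,
         site = as.character(site), stock = as.character(stock),
         shoot = as.character(shoot), radius = as.character(radius),
         first_year = first_year, widths = widths),
    class = "rws")
}

#' @export
print.rws <- function(x, ...) {
  cat(sprintf("<rws> %s  [%d-%d, n=%d]  site=%s stock=%s shoot=%s radius=%s\n",
              x$series_id, x$first_year, rws_last_year(x),
              length(x$widths), x$site, x$stock, x$shoot, x$radius))
  invisible(x)
}

#' Calendar years covered by a series
#' @param x An `rws` object.
#' @return Integer vector of consecutive calendar years.
#' @export
rws_years <- function(x) seq(x$first_year, length.out = length(x$widths))

#' @rdname rws_years
#' @export
rws_last_year <- function(x) x$first_year + length(x$widths) - 1L

#' Restrict a series to a year window
#'
#' @param x An `rws` object.
#' @param start,end First and last calendar year to keep (inclusive). The
#'   window must be fully covered by the series.
#' @return An `rws` object covering exactly `start:end`.
#' @export
rws_window <- function(x, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("start must be <= end")
  if (start < x$first_year || end > rws_last_year(x))
    stop(sprintf("series %s does not cover %d-%d", x$series_id, start, end))
  keep <- rws_years(x) >= start & rws_years(x) <= end
  rws(x$series_id, unname(x$widths[keep]), start,
      site = x$site, stock = x$stock, shoot = x$shoot, radius = x$radius)
}

## numeric payload of either an rws or a bare numeric vector
series_values <- function(x) {
  if (inherits(x, "rws")) return(x$widths)
  if (is.numeric(x)) {
    v <- as.numeric(x)
    if (is.null(names(v))) names(v) <- seq_along(v)
    return(v)
  }
  stop("expected an 'rws' object or a numeric vector")
}

#' Collection of ring-width series
#'
#' A `rws_collection` holds a set of [rws] series and supports selection by
#' the sampling hierarchy. The constructor does not reject an invalid set
#' (e.g. duplicated ids); use [validate_collection()] to audit one.
#'
#' @param series A list of [rws] objects (possibly empty).
#' @return An object of class `"rws_collection"`.
#' @seealso [select_series()], [validate_collection()], [read_rwl()]
#' @export
rws_collection <- function(series = list()) {
  if (inherits(series, "rws")) series <- list(series)
  if (!is.list(series) || !all(vapply(series, inherits, logical(1), "rws")))
    stop("series must be a list of 'rws' objects")
  structure(list(series = unname(series)), class = "rws_collection")
}

#' @export
length.rws_collection <- function(x) length(x$series)

#' @export
print.rws_collection <- function(x, ...) {
  m <- collection_meta(x)
  cat(sprintf("<rws_collection> %d series, %d stock(s), %d shoot(s)\n",
              length(x), length(unique(m$stock[!is.na(m$stock)])),
              nrow(unique(m[!is.na(m$shoot), c("stock", "shoot")]))))
  invisible(x)
}

#' @export
`[.rws_collection` <- function(x, i) rws_collection(x$series[i])

#' Metadata table of a collection
#'
#' @param x An `rws_collection`.
#' @return A data frame with one row per series: `series_id`, `site`,
#'   `stock`, `shoot`, `radius`, `first_year`, `last_year`, `n_years`.
#' @export
collection_meta <- function(x) {
  stopifnot(inherits(x, "rws_collection"))
  if (length(x) == 0L)
    return(data.frame(series_id = character(), site = character(),
                      stock = character(), shoot = character(),
                      radius = character(), first_year = integer(),
                      last_year = integer(), n_years = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    series_id = vapply(x$series, `[[`, character(1), "series_id"),
    site = vapply(x$series, `[[`, character(1), "site"),
    stock = vapply(x$series, `[[`, character(1), "stock"),
    shoot = vapply(x$series, `[[`, character(1), "shoot"),
    radius = vapply(x$series, `[[`, character(1), "radius"),
    first_year = vapply(x$series, `[[`, integer(1), "first_year"),
    last_year = vapply(x$series, rws_last_year, integer(1)),
    n_years = vapply(x$series, function(s) length(s$widths), integer(1)),
    stringsAsFactors = FALSE)
}

#' Select series by hierarchy
#'
#' Filters a collection by any combination of site, stock, shoot and radius
#' label. `NULL` (the default) leaves a dimension unconstrained.
#'
#' @param x An `rws_collection`.
#' @param site,stock,shoot,radius Character vectors of admissible labels, or
#'   `NULL`.
#' @return An `rws_collection` with the matching series, in input order.
#' @export
select_series <- function(x, site = NULL, stock = NULL, shoot = NULL,
                          radius = NULL) {
  m <- collection_meta(x)
  keep <- rep(TRUE, nrow(m))
  if (!is.null(site))   keep <- keep & m$site %in% site
  if (!is.null(stock))  keep <- keep & m$stock %in% stock
  if (!is.null(shoot))  keep <- keep & m$shoot %in% shoot
  if (!is.null(radius)) keep <- keep & m$radius %in% radius
  x[which(keep)]
}

#' Common interval of a group of series
#'
#' @param x An `rws_collection` or list of [rws] objects.
#' @return Integer vector `c(start, end)`: the maximal interval covered by
#'   every series. Errors if the intersection is empty.
#' @export
common_interval <- function(x) {
  series <- if (inherits(x, "rws_collection")) x$series else x
  if (length(series) == 0L) stop("no series given")
  start <- max(vapply(series, `[[`, integer(1), "first_year"))
  end <- min(vapply(series, rws_last_year, integer(1)))
  if (start > end) stop("series share no common interval")
  c(start = start, end = end)
}

## ---------------------------------------------------------------------------
## Tucson decadal (.rwl) reader / writer
## ---------------------------------------------------------------------------

## Hierarchy convention for 8-character Tucson ids:
## chars 1-2 site, 3 stock index, 4-5 shoot index, 6 radius letter (a-d,
## case-insensitive). The stock label combines site code and stock index
## (e.g. "WE101a" -> site "WE", stock "WE1", shoot "01", radius "a") so that
## labels survive an rwl round trip. Ids that do not follow the convention
## yield NA labels; a metadata sidecar (read_series_meta /
## apply_series_meta) overrides.
parse_rwl_id <- function(id) {
  out <- list(site = NA_character_, stock = NA_character_,
              shoot = NA_character_, radius = NA_character_)
  if (nchar(id) >= 6L) {
    rad <- tolower(substr(id, 6L, 6L))
    if (rad %in% c("a", "b", "c", "d")) {
      out$site <- substr(id, 1L, 2L)
      out$stock <- substr(id, 1L, 3L)
      out$shoot <- substr(id, 4L, 5L)
      out$radius <- rad
    }
  }
  out
}

#' Read a Tucson decadal (.rwl) file
#'
#' Parses the classic decadal exchange format: each line carries a series id
#' (columns 1-8), the calendar year of the line's first value, and up to ten
#' integer ring widths; a sentinel ends each series. Values stored at
#' 0.001 mm precision (sentinel `-9999`) are taken as micrometres; values at
#' 0.01 mm precision (sentinel `999` as the final token of its line) are
#' multiplied by 10.
#'
#' Hierarchy labels are parsed from the id by the package convention
#' (characters 1-2 site, 3 stock, 4-5 shoot, 6 radius letter); ids not
#' following it get `NA` labels, which a metadata sidecar can fill in
#' ([apply_series_meta()]).
#'
#' @param file Path, connection, or (with `text`) a character vector of
#'   lines.
#' @param text Optional character vector of lines, used instead of `file`.
#' @return An [rws_collection].
#' @export
read_rwl <- function(file, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()   # per id: list of (lineno, year, values)
  order_ids <- character()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    id <- trimws(substr(line, 1L, 8L))
    if (!nzchar(id))
      stop(sprintf("rwl format error at line %d: empty series id", i))
    toks <- strsplit(trimws(substring(line, 9L)), "\\s+")[[1]]
    if (length(toks) < 2L)
      stop(sprintf("rwl format error at line %d: need a year and values", i))
    nums <- suppressWarnings(as.numeric(toks))
    if (anyNA(nums))
      stop(sprintf("rwl format error at line %d: non-numeric field '%s'",
                   i, toks[which(is.na(nums))[1]]))
    if (is.null(recs[[id]])) {
      recs[[id]] <- list()
      order_ids <- c(order_ids, id)
    }
    recs[[id]][[length(recs[[id]]) + 1L]] <-
      list(lineno = i, year = as.integer(nums[1]), values = nums[-1])
  }
  series <- lapply(order_ids, function(id) {
    chunks <- recs[[id]]
    allv <- unlist(lapply(chunks, `[[`, "values"))
    # sentinel/precision: -9999 anywhere marks 0.001 mm data; otherwise a
    # trailing 999 marks 0.01 mm data. A plain 999 data value is safe as long
    # as the series carries the -9999 sentinel.
    factor <- 1
    if (any(allv == -9999)) {
      k <- which(allv == -9999)[1]
      if (k != length(allv))
        stop(sprintf("rwl format error: series %s has data after its end sentinel", id))
      allv <- allv[-k]
    } else if (length(allv) && allv[length(allv)] == 999) {
      factor <- 10
      allv <- allv[-length(allv)]
    }
    # per-line year continuity (detects overlapping/gapped decades)
    first_year <- chunks[[1]]$year
    count <- 0L
    left <- length(allv)
    for (ch in chunks) {
      if (ch$year != first_year + count)
        stop(sprintf(
          "rwl format error at line %d: series %s expects year %d, found %d (overlapping or gapped decades)",
          ch$lineno, id, first_year + count, ch$year))
      count <- count + min(length(ch$values), left)
      left <- length(allv) - count
    }
    h <- parse_rwl_id(id)
    rws(id, allv * factor, first_year,
        site = h$site, stock = h$stock, shoot = h$shoot, radius = h$radius)
  })
  rws_collection(series)
}

#' Write a collection as a Tucson decadal (.rwl) file
#'
#' Emits 0.001 mm (micrometre) precision with the `-9999` end-of-series
#' sentinel; widths must be integral micrometres. `read_rwl(write_rwl(x))`
#' reproduces the collection exactly (ids, years, widths).
#'
#' @param x An [rws_collection].
#' @param file Path or connection to write to; if `NULL`, the lines are
#'   returned as a character vector.
#' @return Invisibly (or visibly when `file` is `NULL`) the lines written.
#' @export
write_rwl <- function(x, file = NULL) {
  stopifnot(inherits(x, "rws_collection"))
  out <- character()
  for (s in x$series) {
    id <- s$series_id
    if (nchar(id) > 8L)
      stop(sprintf("series id '%s' not encodable in 8 characters", id))
    w <- round(s$widths)
    if (max(abs(s$widths - w)) > 1e-6)
      stop(sprintf("series %s: widths must be integral micrometres", id))
    yrs <- rws_years(s)
    vals <- as.integer(w)
    i <- 1L
    n <- length(vals)
    while (i <= n) {
      y <- yrs[i]
      decade_end <- (y %/% 10L) * 10L + 9L
      j <- min(n, i + (decade_end - y))
      slot <- vals[i:j]
      inline_sentinel <- (j == n && yrs[j] < decade_end)
      if (inline_sentinel) slot <- c(slot, -9999L)
      out <- c(out, paste0(formatC(id, width = -8L),
                           formatC(y, width = 4L),
                           paste0(formatC(slot, width = 6L), collapse = "")))
      if (j == n && !inline_sentinel) {
        # decade ended exactly at the last value: sentinel on its own line
        out <- c(out, paste0(formatC(id, width = -8L),
                             formatC(yrs[j] + 1L, width = 4L),
                             formatC(-9999L, width = 6L)))
      }
      i <- j + 1L
    }
  }
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

## ---------------------------------------------------------------------------
## Delimited wide table + metadata sidecar
## ---------------------------------------------------------------------------

#' Read/write ring widths as a delimited wide table
#'
#' The wide layout has a `year` column plus one column per series (header =
#' series id); cells outside a series' coverage are empty/NA. Hierarchy
#' labels come from the id convention or a metadata sidecar.
#'
#' @param file Path or connection.
#' @param sep Field separator (default tab).
#' @param meta Optional metadata data frame as returned by
#'   [read_series_meta()].
#' @return `read_rw_table()`: an [rws_collection]; `write_rw_table()`:
#'   invisibly the data frame written.
#' @export
read_rw_table <- function(file, sep = "\t", meta = NULL) {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!"year" %in% names(d)) stop("wide table must have a 'year' column")
  yrs <- as.integer(d$year)
  if (any(diff(yrs) != 1L)) stop("year column must be consecutive")
  series <- list()
  for (id in setdiff(names(d), "year")) {
    v <- as.numeric(d[[id]])
    ok <- !is.na(v)
    if (!any(ok)) next
    rng <- range(which(ok))
    if (anyNA(v[rng[1]:rng[2]]))
      stop(sprintf("series %s has interior gaps in the wide table", id))
    h <- parse_rwl_id(id)
    series[[length(series) + 1L]] <-
      rws(id, v[rng[1]:rng[2]], yrs[rng[1]],
          site = h$site, stock = h$stock, shoot = h$shoot, radius = h$radius)
  }
  x <- rws_collection(series)
  if (!is.null(meta)) x <- apply_series_meta(x, meta)
  x
}

#' @rdname read_rw_table
#' @param x An [rws_collection].
#' @export
write_rw_table <- function(x, file, sep = "\t") {
  stopifnot(inherits(x, "rws_collection"))
  if (length(x) == 0L) {
    d <- data.frame(year = integer())
  } else {
    rng <- c(min(vapply(x$series, `[[`, integer(1), "first_year")),
             max(vapply(x$series, rws_last_year, integer(1))))
    yrs <- seq(rng[1], rng[2])
    d <- data.frame(year = yrs)
    for (s in x$series) {
      col <- rep(NA_real_, length(yrs))
      col[match(rws_years(s), yrs)] <- unname(s$widths)
      d[[s$series_id]] <- col
    }
  }
  utils::write.table(d, file, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(d)
}

#' Series metadata sidecar
#'
#' A delimited table with columns `series_id`, `site`, `stock`, `shoot`,
#' `radius` that overrides labels parsed from Tucson ids.
#'
#' @param file Path or connection.
#' @param sep Field separator (default tab).
#' @return A data frame of metadata.
#' @export
read_series_meta <- function(file, sep = "\t") {
  m <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("series_id", "site", "stock", "shoot", "radius")
  if (!all(need %in% names(m)))
    stop("metadata sidecar must have columns ",
         paste(need, collapse = ", "))
  m[need]
}

#' @rdname read_series_meta
#' @param x An [rws_collection].
#' @param meta Data frame as returned by `read_series_meta()`.
#' @export
apply_series_meta <- function(x, meta) {
  stopifnot(inherits(x, "rws_collection"))
  series <- lapply(x$series, function(s) {
    i <- match(s$series_id, meta$series_id)
    if (is.na(i)) return(s)
    rws(s$series_id, unname(s$widths), s$first_year,
        site = meta$site[i], stock = meta$stock[i],
        shoot = meta$shoot[i], radius = meta$radius[i])
  })
  rws_collection(series)
}

#' @rdname read_series_meta
#' @export
write_series_meta <- function(x, file, sep = "\t") {
  m <- collection_meta(x)[c("series_id", "site", "stock", "shoot", "radius")]
  utils::write.table(m, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(m)
}

## ---------------------------------------------------------------------------
## Radial combinations & validation
## ---------------------------------------------------------------------------

#' Average radii of one shoot into a combination series
#'
#' Builds the mean-of-radii series the analysis uses alongside single radii:
#' `ab` (lower/upper stem side), `cd` (orthogonal pair) and `abcd` (all
#' four). The mean is taken on ring widths, year by year; inserted missing
#' rings (width 0) enter as true zeros. All member series must cover
#' identical years — truncate to a common window first (see [rws_window()]).
#'
#' @param shoot_series Named list of [rws] objects (names = radius labels)
#'   or an [rws_collection] holding one shoot's radii.
#' @param subset Combination tag: `"ab"`, `"cd"` or `"abcd"`.
#' @return An [rws] with `radius` set to the combination tag.
#' @export
combine_radii <- function(shoot_series, subset = c("ab", "cd", "abcd")) {
  subset <- match.arg(subset)
  if (inherits(shoot_series, "rws_collection")) {
    lst <- shoot_series$series
    names(lst) <- vapply(lst, `[[`, character(1), "radius")
    shoot_series <- lst
  }
  want <- strsplit(subset, "")[[1]]
  if (!all(want %in% names(shoot_series)))
    stop(sprintf("radii {%s} required for combination '%s'",
                 paste(setdiff(want, names(shoot_series)), collapse = ","),
                 subset))
  members <- shoot_series[want]
  fy <- vapply(members, `[[`, integer(1), "first_year")
  ln <- vapply(members, function(s) length(s$widths), integer(1))
  if (length(unique(fy)) != 1L || length(unique(ln)) != 1L)
    stop("member radii must cover identical years; truncate to a common window first")
  wmat <- vapply(members, function(s) unname(s$widths), numeric(ln[1]))
  ref <- members[[1]]
  stem <- if (nchar(ref$series_id) >= 6L) substr(ref$series_id, 1L, 5L)
          else ref$series_id
  rws(paste0(stem, subset), rowMeans(wmat), fy[1],
      site = ref$site, stock = ref$stock, shoot = ref$shoot, radius = subset)
}

#' Audit a collection for structural problems
#'
#' Reports rather than raises: duplicated series ids, duplicated
#' (stock, shoot, radius) cells, negative or non-finite widths, and shoots
#' represented by a single series.
#'
#' @param x An [rws_collection].
#' @return A data frame of findings with columns `kind`, `series_id`,
#'   `message`; zero rows means the collection is valid.
#' @export
validate_collection <- function(x) {
  stopifnot(inherits(x, "rws_collection"))
  f <- list()
  add <- function(kind, id, msg)
    f[[length(f) + 1L]] <<- data.frame(kind = kind, series_id = id,
                                       message = msg, stringsAsFactors = FALSE)
  m <- collection_meta(x)
  dup <- unique(m$series_id[duplicated(m$series_id)])
  for (id in dup) add("duplicate_id", id, "series id occurs more than once")
  cell <- m[!is.na(m$stock) & !is.na(m$shoot) & !is.na(m$radius), ]
  if (nrow(cell)) {
    key <- paste(cell$stock, cell$shoot, cell$radius)
    for (k in unique(key[duplicated(key)]))
      add("duplicate_cell", paste(cell$series_id[key == k], collapse = ","),
          sprintf("more than one series in hierarchy cell (%s)", k))
    sh <- paste(cell$stock, cell$shoot)
    for (k in unique(sh[!(sh %in% sh[duplicated(sh)])]))
      add("singleton_shoot", cell$series_id[sh == k][1],
          sprintf("shoot (%s) has a single series", k))
  }
  for (s in x$series) {
    if (any(!is.finite(s$widths)))
      add("nonfinite_width", s$series_id, "non-finite width value")
    else if (any(s$widths < 0))
      add("negative_width", s$series_id, "negative width value")
  }
  if (length(f)) do.call(rbind, f)
  else data.frame(kind = character(), series_id = character(),
                  message = character(), stringsAsFactors = FALSE)
}
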