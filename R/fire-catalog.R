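#' Construct a fire catalog
#'
#' A fire catalog is the queryable collection of ignition records that every
#' downstream analysis consumes. Each record carries a unique id, projected
#' planar coordinates in metres, a discovery date at year/month precision, a
#' burned area in acres (> 0), a raw cause code from the closed vocabulary
#' ([cause_vocabulary()]) and an optional fuel type (`timber`, `brush`,
#' `grass`, or `NA`).
#'
#' @param records data frame with columns `id`, `x`, `y`, `year`, `month`,
#'   `size` (acres), `cause`, and optionally `fuel`.
#' @param crs_note free-text tag describing the projected CRS. Coordinates
#'   are assumed already projected (metres); no geodesy is performed.
#' @return an object of class `fire_catalog`: list with elements `records`
#'   (tibble), `crs_note`, and `period` (`c(min_year, max_year)`).
#' @examples
#' cat <- fire_catalog(data.frame(
#'   id = "a", x = 0, y = 0, year = 2005, month = 7,
#'   size = 120, cause = "lightning"))
#' n_fires(cat)
#' @export
fire_catalog <- function(records, crs_note = "unspecified planar CRS (m)") {
  records <- as_tibble(records)
  required <- c("id", "x", "y", "year", "month", "size", "cause")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing catalog column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "firescape_schema_error")
  }
  if (!("fuel" %in% names(records))) records$fuel <- NA_character_
  records <- records[, c(required, "fuel")]
  records$id <- as.character(records$id)
  records$cause <- as.character(records$cause)
  records$fuel <- as.character(records$fuel)
  for (col in c("x", "y", "year", "month", "size")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  validate_fire_records(records)
  period <- if (nrow(records) > 0) {
    c(min(records$year), max(records$year))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(records = records, crs_note = crs_note, period = period),
    class = "fire_catalog"
  )
}

validate_fire_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  problems <- character(0)
  bad_size <- which(!is.finite(records$size) | records$size <= 0)
  if (length(bad_size) > 0) {
    problems <- c(problems, paste0("non-positive or non-finite size at row(s) ",
                                   paste(head(bad_size, 10), collapse = ", ")))
  }
  bad_month <- which(!is.finite(records$month) | records$month < 1 |
                       records$month > 12 | records$month != round(records$month))
  if (length(bad_month) > 0) {
    problems <- c(problems, paste0("month outside 1..12 at row(s) ",
                                   paste(head(bad_month, 10), collapse = ", ")))
  }
  bad_xy <- which(!is.finite(records$x) | !is.finite(records$y))
  if (length(bad_xy) > 0) {
    problems <- c(problems, paste0("non-finite coordinates at row(s) ",
                                   paste(head(bad_xy, 10), collapse = ", ")))
  }
  bad_cause <- which(!(records$cause %in% names(cause_lookup())))
  if (length(bad_cause) > 0) {
    problems <- c(problems, paste0("cause outside vocabulary at row(s) ",
                                   paste(head(bad_cause, 10), collapse = ", ")))
  }
  if (anyDuplicated(records$id)) {
    problems <- c(problems, "duplicate record ids")
  }
  bad_fuel <- which(!is.na(records$fuel) &
                      !(records$fuel %in% c("timber", "brush", "grass")))
  if (length(bad_fuel) > 0) {
    problems <- c(problems, paste0("unknown fuel type at row(s) ",
                                   paste(head(bad_fuel, 10), collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid fire records: ", paste(problems, collapse = "; ")),
          class = "firescape_record_error")
  }
  invisible(records)
}

#' @export
print.fire_catalog <- function(x, ...) {
  cat("<fire_catalog> ", nrow(x$records), " records, period ",
      x$period[1], "-", x$period[2], "\n", sep = "")
  cat("CRS: ", x$crs_note, "\n", sep = "")
  print(head(x$records, 5))
  invisible(x)
}

#' @rdname fire_catalog
#' @param catalog a `fire_catalog`.
#' @export
n_fires <- function(catalog) {
  stopifnot(inherits(catalog, "fire_catalog"))
  nrow(catalog$records)
}

#' Read and write fire catalogs
#'
#' The on-disk CSV dialect has a header row with columns
#' `id,x,y,year,month,size_acres,cause,fuel` (UTF-8); the GeoJSON form is a
#' FeatureCollection of Point features with the same properties. Rows that
#' violate the record invariants (non-positive size, month outside 1..12,
#' cause outside the vocabulary, non-finite coordinates) are rejected with
#' row-level diagnostics, returned in the `rejected` attribute.
#'
#' @param path file path.
#' @param format `"csv"` or `"geojson"`; inferred from the file extension by
#'   default.
#' @param crs_note free-text CRS tag stored on the catalog.
#' @return `read_catalog()` returns a `fire_catalog` with an attribute
#'   `rejected` (tibble of rejected rows and reasons); `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path, format = c("auto", "csv", "geojson"),
                         crs_note = "unspecified planar CRS (m)") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "firescape_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE)) {
      "geojson"
    } else {
      "csv"
    }
  }
  raw <- if (format == "csv") read_catalog_csv(path) else read_catalog_geojson(path)
  if (nrow(raw) == 0) {
    abort(paste0("Empty catalog file: ", path), class = "firescape_empty_error")
  }
  screened <- screen_rows(raw)
  cat_obj <- fire_catalog(screened$good, crs_note = crs_note)
  attr(cat_obj, "rejected") <- screened$bad
  cat_obj
}

read_catalog_csv <- function(path) {
  # missing columns are reported as a schema error below, not by the parser
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double(),
    year = readr::col_double(),
    month = readr::col_double(),
    size_acres = readr::col_double(),
    cause = readr::col_character(),
    fuel = readr::col_character()
  ), progress = FALSE))
  required <- c("id", "x", "y", "year", "month", "size_acres", "cause")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Catalog file missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "firescape_schema_error")
  }
  if (!("fuel" %in% names(df))) df$fuel <- NA_character_
  names(df)[names(df) == "size_acres"] <- "size"
  df
}

read_catalog_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) {
    abort("GeoJSON file has no 'features' array",
          class = "firescape_schema_error")
  }
  rows <- lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates
    p <- f$properties
    tibble(
      id = as.character(p$id %||% NA_character_),
      x = as.numeric(coords[[1]]),
      y = as.numeric(coords[[2]]),
      year = as.numeric(p$year %||% NA_real_),
      month = as.numeric(p$month %||% NA_real_),
      size = as.numeric(p$size_acres %||% NA_real_),
      cause = as.character(p$cause %||% NA_character_),
      fuel = as.character(p$fuel %||% NA_character_)
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

screen_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(idx, why) {
    newly <- idx[is.na(reason[idx])]
    reason[newly] <<- why
    reason[setdiff(idx, newly)] <<- paste(reason[setdiff(idx, newly)], why,
                                          sep = "; ")
  }
  flag(which(!is.finite(df$size) | df$size <= 0), "invalid size")
  flag(which(!is.finite(df$month) | df$month < 1 | df$month > 12), "invalid month")
  flag(which(!is.finite(df$year)), "invalid year")
  flag(which(!is.finite(df$x) | !is.finite(df$y)), "invalid coordinates")
  flag(which(!(df$cause %in% names(cause_lookup()))), "unknown cause code")
  bad <- which(!is.na(reason))
  bad_tbl <- df[bad, , drop = FALSE]
  if (length(bad) > 0) {
    bad_tbl$row <- bad
    bad_tbl$reason <- reason[bad]
    warn(paste0(length(bad), " row(s) rejected while reading catalog (",
                paste(head(unique(reason[bad]), 3), collapse = "; "), ")"))
  } else {
    bad_tbl$row <- integer(0)
    bad_tbl$reason <- character(0)
  }
  list(good = df[setdiff(seq_len(nrow(df)), bad), , drop = FALSE], bad = bad_tbl)
}

#' @rdname read_catalog
#' @param catalog a `fire_catalog`.
#' @export
write_catalog <- function(catalog, path, format = c("auto", "csv", "geojson")) {
  stopifnot(inherits(catalog, "fire_catalog"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE)) {
      "geojson"
    } else {
      "csv"
    }
  }
  df <- catalog$records
  if (format == "csv") {
    out <- df
    names(out)[names(out) == "size"] <- "size_acres"
    readr::write_csv(out, path, progress = FALSE)
  } else {
    features <- lapply(seq_len(nrow(df)), function(i) {
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(df$x[i], df$y[i])),
        properties = list(
          id = df$id[i], year = df$year[i], month = df$month[i],
          size_acres = df$size[i], cause = df$cause[i],
          fuel = if (is.na(df$fuel[i])) NULL else df$fuel[i]
        )
      )
    })
    gj <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Filter a fire catalog
#'
#' Retains only records satisfying every supplied criterion; record order is
#' preserved and the input catalog is untouched. The database minimum-size
#' rule reflects the inclusion thresholds of statewide fire-perimeter
#' databases: 10 acres for timber fires, 30 acres for brush fires, 300 acres
#' for grass fires (records with unknown fuel are held to the smallest
#' threshold, 10 acres).
#'
#' @param catalog a `fire_catalog`.
#' @param period optional `c(min_year, max_year)`, inclusive.
#' @param min_size_rule logical; apply the fuel-type minimum-size rule.
#' @param cause_groups optional character vector of cause groups to retain
#'   (see [cause_groups()]).
#' @param min_size optional flat minimum size in acres (applied in addition
#'   to the fuel-type rule if both given).
#' @return a new `fire_catalog`.
#' @export
filter_catalog <- function(catalog, period = NULL, min_size_rule = FALSE,
                           cause_groups = NULL, min_size = NULL) {
  stopifnot(inherits(catalog, "fire_catalog"))
  df <- catalog$records
  keep <- rep(TRUE, nrow(df))
  if (!is.null(period)) {
    stopifnot(length(period) == 2)
    if (period[1] > period[2]) {
      abort("Inverted period bounds", class = "firescape_argument_error")
    }
    keep <- keep & df$year >= period[1] & df$year <= period[2]
  }
  if (isTRUE(min_size_rule)) {
    fuel_min <- c(timber = 10, brush = 30, grass = 300)
    thresh <- unname(fuel_min[df$fuel])
    thresh[is.na(thresh)] <- 10
    keep <- keep & df$size >= thresh
  }
  if (!is.null(min_size)) {
    keep <- keep & df$size >= min_size
  }
  if (!is.null(cause_groups)) {
    stopifnot(all(cause_groups %in% cause_groups()))
    keep <- keep & classify_cause(df$cause) %in% cause_groups
  }
  fire_catalog(df[keep, , drop = FALSE], crs_note = catalog$crs_note)
}

#' Split a catalog into large and small fires at a size threshold
#'
#' Large fires are those with burned area at or above the threshold
#' (`size >= threshold`); small fires fall strictly below. The split is an
#' exact partition of the input.
#'
#' @param catalog a `fire_catalog`.
#' @param threshold size threshold in acres (> 0); 500 acres is the
#'   large-fire cutoff selected from the mean-excess plot for California.
#' @return list with elements `large` and `small`, both `fire_catalog`s.
#' @export
split_by_size <- function(catalog, threshold = 500) {
  stopifnot(inherits(catalog, "fire_catalog"), threshold > 0)
  df <- catalog$records
  is_large <- df$size >= threshold
  list(
    large = fire_catalog(df[is_large, , drop = FALSE], catalog$crs_note),
    small = fire_catalog(df[!is_large, , drop = FALSE], catalog$crs_note)
  )
}

#' Summarize ignition causes
#'
#' Counts records per cause group and expresses each as a percentage of the
#' catalog total (rounded to two decimals).
#'
#' @param catalog a `fire_catalog`.
#' @return tibble with columns `group`, `count`, `percentage`; groups in
#'   canonical order, absent groups present with count 0.
#' @export
summarize_causes <- function(catalog) {
  stopifnot(inherits(catalog, "fire_catalog"))
  if (n_fires(catalog) == 0) {
    abort("Cannot summarize an empty catalog",
          class = "firescape_empty_error")
  }
  grp <- classify_cause(catalog$records$cause)
  counts <- table(factor(grp, levels = cause_groups()))
  tibble(
    group = cause_groups(),
    count = as.integer(counts),
    percentage = round(100 * as.integer(counts) / sum(counts), 2)
  )
}

#' Convert acres to square kilometres
#'
#' Uses the international acre: 1 acre = 0.0040468564224 km^2 exactly.
#'
#' @param a area in acres (finite; sign preserved).
#' @return area in km^2.
#' @examples
#' acres_to_km2(1000) # ~ 4.05 km^2
#' @export
acres_to_km2 <- function(a) {
  stopifnot(all(is.finite(a)))
  a * 0.0040468564224
}
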