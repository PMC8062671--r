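# Annual series, segmented trend regression, monthly seasonality profiles.

subset_group <- function(catalog, group) {
  groups <- c("all", "large", "small", "natural", "human")
  if (!(group %in% groups)) {
    abort(paste0("Unknown group '", group, "'; must be one of ",
                 paste(groups, collapse = ", ")),
          class = "firescape_argument_error")
  }
  if (group == "all") return(catalog)
  if (group %in% c("large", "small")) {
    split_by_size(catalog, 500)[[group]]
  } else {
    df <- catalog$records
    keep <- cause_binary(classify_cause(df$cause)) == group
    fire_catalog(df[keep, , drop = FALSE], catalog$crs_note)
  }
}

#' Annual wildfire frequency or burned-area series
#'
#' Sums fires (frequency) or acres (burned area) per calendar year over the
#' catalog period; years without fires are present with value 0 so trend
#' regressions are not biased by missing rows.
#'
#' @param catalog a `fire_catalog`.
#' @param measure `"frequency"` (fires/yr) or `"burned_area"` (acres/yr).
#' @param group `"all"`, `"large"` (>= 500 acres), `"small"`, `"natural"`
#'   or `"human"`.
#' @param period optional `c(min_year, max_year)` for the zero-filled span;
#'   defaults to the catalog period.
#' @return tibble of class `annual_series` with columns `year`, `value`,
#'   `measure`, `group`; one row per year, years contiguous.
#' @export
annual_series <- function(catalog, measure = c("frequency", "burned_area"),
                          group = "all", period = NULL) {
  stopifnot(inherits(catalog, "fire_catalog"))
  measure <- match.arg(measure)
  if (n_fires(catalog) == 0) {
    abort("Empty catalog", class = "firescape_empty_error")
  }
  if (is.null(period)) period <- catalog$period
  sub <- subset_group(catalog, group)
  df <- sub$records
  years <- seq(period[1], period[2])
  w <- if (measure == "frequency") rep(1, nrow(df)) else df$size
  sums <- vapply(years, function(yr) sum(w[df$year == yr]), numeric(1))
  out <- tibble(year = years, value = sums, measure = measure, group = group)
  class(out) <- c("annual_series", class(out))
  out
}

#' Segmented linear regression around a fixed breakpoint
#'
#' Fits independent ordinary least squares lines to the years before the
#' breakpoint (`year < breakpoint`) and from it onward (`year >=
#' breakpoint`). No continuity constraint is imposed at the join: the two
#' periods are treated as separate regimes. Per segment the slope,
#' intercept, R-squared, two-sided slope p-value and the 95% confidence
#' band of the mean prediction at each year are reported.
#'
#' @param series an `annual_series` (or tibble with `year`, `value`).
#' @param breakpoint the first year of the second segment (default 2000).
#' @return list of class `segmented_fit` with `breakpoint`, `segments`
#'   (tibble: segment, start, end, slope, intercept, r_squared, p_value)
#'   and `band` (tibble: year, fitted, half_width, segment).
#' @export
segmented_regression <- function(series, breakpoint = 2000) {
  stopifnot(all(c("year", "value") %in% names(series)))
  pre <- series[series$year < breakpoint, ]
  post <- series[series$year >= breakpoint, ]
  if (nrow(pre) < 3) {
    abort("Segment before the breakpoint has fewer than 3 years",
          class = "firescape_fit_error")
  }
  if (nrow(post) < 3) {
    abort("Segment from the breakpoint onward has fewer than 3 years",
          class = "firescape_fit_error")
  }
  fit_one <- function(df, label) {
    m <- lm(value ~ year, data = df)
    sm <- summary(m)
    slope_row <- sm$coefficients["year", ]
    pr <- predict(m, newdata = df, interval = "confidence", level = 0.95)
    list(
      row = tibble(
        segment = label, start = min(df$year), end = max(df$year),
        slope = unname(coef(m)["year"]),
        intercept = unname(coef(m)["(Intercept)"]),
        r_squared = sm$r.squared,
        p_value = unname(slope_row["Pr(>|t|)"])
      ),
      band = tibble(year = df$year, fitted = pr[, "fit"],
                    half_width = (pr[, "upr"] - pr[, "lwr"]) / 2,
                    segment = label)
    )
  }
  a <- fit_one(pre, "pre")
  b <- fit_one(post, "post")
  structure(
    list(breakpoint = breakpoint,
         segments = dplyr::bind_rows(a$row, b$row),
         band = dplyr::bind_rows(a$band, b$band)),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented_fit> breakpoint at", x$breakpoint, "\n")
  print(x$segments)
  invisible(x)
}

#' Monthly seasonality profile
#'
#' Per (month, year) totals of fire frequency or burned area, suitable for
#' box statistics across years. All 12 months are always present
#' (zero-filled), for every year of the period.
#'
#' @inheritParams annual_series
#' @return tibble of class `monthly_profile` with columns `month`, `year`,
#'   `value`, `measure`, `group`.
#' @export
monthly_profile <- function(catalog, measure = c("frequency", "burned_area"),
                            group = "all", period = NULL) {
  stopifnot(inherits(catalog, "fire_catalog"))
  measure <- match.arg(measure)
  if (n_fires(catalog) == 0) {
    abort("Empty catalog", class = "firescape_empty_error")
  }
  if (is.null(period)) period <- catalog$period
  sub <- subset_group(catalog, group)
  df <- sub$records
  grid <- expand.grid(month = 1:12, year = seq(period[1], period[2]))
  w <- if (measure == "frequency") rep(1, nrow(df)) else df$size
  agg <- vapply(seq_len(nrow(grid)), function(i) {
    sum(w[df$year == grid$year[i] & df$month == grid$month[i]])
  }, numeric(1))
  out <- tibble(month = as.integer(grid$month), year = grid$year,
                value = agg, measure = measure, group = group)
  class(out) <- c("monthly_profile", class(out))
  out
}

#' Peak month of a seasonality profile
#'
#' The month maximising the across-year mean value; ties break to the
#' earlier month.
#'
#' @param profile a `monthly_profile`.
#' @return integer month in 1..12.
#' @export
peak_month <- function(profile) {
  stopifnot(all(c("month", "value") %in% names(profile)))
  means <- vapply(1:12, function(m) mean(profile$value[profile$month == m]),
                  numeric(1))
  if (all(means == 0)) {
    abort("All-zero profile: peak month undefined",
          class = "firescape_empty_error")
  }
  which.max(means)  # which.max returns the first maximum -> earlier month
}

#' Fire-season span of a seasonality profile
#'
#' Descriptive season rule: the season starts at the first month whose
#' across-year mean exceeds `fraction` of the peak month's mean, and its
#' length is the number of such months. A reporting convenience, not an
#' inferential quantity.
#'
#' @param profile a `monthly_profile`.
#' @param fraction fraction of the peak mean (default 0.5).
#' @return list with `start_month`, `length_months`, `active_months`.
#' @export
season_span <- function(profile, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  means <- vapply(1:12, function(m) mean(profile$value[profile$month == m]),
                  numeric(1))
  if (all(means == 0)) {
    abort("All-zero profile: season undefined",
          class = "firescape_empty_error")
  }
  active <- which(means >= fraction * max(means))
  list(start_month = min(active), length_months = length(active),
       active_months = active)
}
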