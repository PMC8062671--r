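#' Parameters for kernel density hot-spot mapping
#'
#' @param search_radius kernel search radius `R` in metres; the kernel
#'   reaches exactly zero at distance `R`. Must exceed `cell_size`.
#' @param cell_size raster resolution in metres (default 500).
#' @param weight_mode `"unit"` (occurrence density) or `"burned_area"`
#'   (burned-area-weighted density).
#' @return object of class `kde_params`.
#' @export
kde_params <- function(search_radius, cell_size = 500,
                       weight_mode = c("unit", "burned_area")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(search_radius > cell_size, cell_size > 0)
  structure(list(search_radius = search_radius, cell_size = cell_size,
                 weight_mode = weight_mode),
            class = "kde_params")
}

#' Quartic kernel density surface of fire occurrence points
#'
#' Evaluates, at every cell centre, the weighted quartic (biweight) kernel
#' density
#' \deqn{f(x) = \frac{1}{R^2} \sum_{i: d_i < R}
#'   \frac{3}{\pi} P_i \left(1 - (d_i/R)^2\right)^2}
#' where `R` is the search radius, `P_i` the per-point weight (the
#' "population field": 1 for occurrence density, burned area in acres for
#' area-weighted density) and `d_i` the distance from point `i` to the cell
#' centre. Points at `d_i >= R` contribute exactly zero. Densities are in
#' weight per square metre; the raster extent is the point bounding box
#' padded by `R` (snapped to whole cells), so no kernel is clipped. No
#' edge correction is applied.
#'
#' The implementation sums each point's kernel over the cell window it can
#' reach, which is algebraically identical to direct per-cell summation
#' over all points.
#'
#' @param points a `fire_catalog` (ignition coordinates are used).
#' @param params a `kde_params`.
#' @return a `raster_grid` of densities (weight / m^2).
#' @export
kernel_density <- function(points, params) {
  stopifnot(inherits(points, "fire_catalog"), inherits(params, "kde_params"))
  df <- points$records
  if (nrow(df) == 0) {
    abort("No points to smooth", class = "firescape_empty_error")
  }
  R <- params$search_radius
  cs <- params$cell_size
  w <- if (params$weight_mode == "unit") rep(1, nrow(df)) else df$size
  if (params$weight_mode == "burned_area" && any(w <= 0)) {
    abort("Non-positive burned-area weight",
          class = "firescape_data_error")
  }
  pad <- ceiling(R / cs) * cs
  x0 <- floor((min(df$x) - pad) / cs) * cs
  y1 <- ceiling((max(df$y) + pad) / cs) * cs
  n_cols <- ceiling((max(df$x) + pad - x0) / cs)
  n_rows <- ceiling((y1 - (min(df$y) - pad)) / cs)
  vals <- matrix(0, nrow = n_rows, ncol = n_cols)
  cx <- x0 + (seq_len(n_cols) - 0.5) * cs
  cy <- y1 - (seq_len(n_rows) - 0.5) * cs
  half <- ceiling(R / cs) + 1L
  const <- 3 / (pi * R^2)
  for (i in seq_len(nrow(df))) {
    ci <- floor((df$x[i] - x0) / cs) + 1L
    ri <- floor((y1 - df$y[i]) / cs) + 1L
    cols <- max(1L, ci - half):min(n_cols, ci + half)
    rows <- max(1L, ri - half):min(n_rows, ri + half)
    dx2 <- (cx[cols] - df$x[i])^2
    dy2 <- (cy[rows] - df$y[i])^2
    d2 <- outer(dy2, dx2, "+")
    u <- 1 - d2 / R^2
    k <- ifelse(d2 < R^2, const * w[i] * u^2, 0)
    vals[rows, cols] <- vals[rows, cols] + k
  }
  raster_grid(vals, origin = c(x0, y1), cell_size = cs)
}

#' Default kernel search radius
#'
#' The standard point-pattern rule of thumb (as used by common GIS kernel
#' density tools):
#' \deqn{R = 0.9 \cdot \min\left(SD_w,\ \sqrt{1/\ln 2}\; D_m\right)
#'   \cdot n_w^{-0.2}}
#' where `SD_w` is the weighted standard distance of the points about their
#' weighted mean centre, `D_m` the weighted median distance to that centre,
#' and `n_w` the Kish effective sample size `(sum w)^2 / sum(w^2)` (the
#' point count for any constant weights). The rule is deterministic and
#' scale-equivariant: scaling all coordinates by `s` scales `R` by `s`.
#'
#' @param points a `fire_catalog`.
#' @param weights optional per-point weights (default 1).
#' @return search radius in metres (> 0).
#' @export
default_search_radius <- function(points, weights = NULL) {
  stopifnot(inherits(points, "fire_catalog"))
  df <- points$records
  if (nrow(df) < 2) {
    abort("Need at least 2 points", class = "firescape_argument_error")
  }
  w <- if (is.null(weights)) rep(1, nrow(df)) else as.numeric(weights)
  stopifnot(length(w) == nrow(df), all(w > 0))
  wm <- w / sum(w)
  mx <- sum(wm * df$x)
  my <- sum(wm * df$y)
  d2 <- (df$x - mx)^2 + (df$y - my)^2
  sdw <- sqrt(sum(wm * d2))
  if (sdw == 0) {
    abort("All points coincident: zero spread",
          class = "firescape_degenerate_error")
  }
  dm <- weighted_median(sqrt(d2), w)
  n_eff <- sum(w)^2 / sum(w^2)
  0.9 * min(sdw, sqrt(1 / log(2)) * dm) * n_eff^(-0.2)
}

weighted_median <- function(x, w) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= 0.5)[1]]
}

#' Quantile density classes for hot-spot maps
#'
#' Classifies the nonzero cells of a density raster into `n_classes`
#' ordinal classes ("very low" to "very high") at the empirical quantiles
#' of the nonzero values. Quantiles of type 1 (order statistics) are used,
#' so the class map is invariant under strictly monotone transforms of the
#' densities. Zero and nodata cells stay nodata.
#'
#' @param raster a `raster_grid` of densities.
#' @param n_classes number of classes (>= 2; default 5).
#' @return a `raster_grid` of integer classes 1..`n_classes` (NA where the
#'   input was zero or nodata), with the class boundaries in attribute
#'   `breaks`.
#' @export
classify_density <- function(raster, n_classes = 5) {
  stopifnot(inherits(raster, "raster_grid"), n_classes >= 2)
  v <- raster$values
  nz <- v[!is.na(v) & v > 0]
  if (length(unique(nz)) < n_classes) {
    abort("Too few distinct nonzero values for the requested class count",
          class = "firescape_classification_error")
  }
  probs <- seq_len(n_classes - 1) / n_classes
  breaks <- quantile(nz, probs = probs, type = 1, names = FALSE)
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  sel <- !is.na(v) & v > 0
  cls[sel] <- as.numeric(cut(v[sel], breaks = c(-Inf, breaks, Inf),
                             labels = FALSE, right = TRUE))
  out <- raster_grid(cls, raster$origin, raster$cell_size,
                     nodata = raster$nodata)
  attr(out, "breaks") <- breaks
  out
}

#' Integrate a density raster
#'
#' Total mass `sum(value * cell_area)` over non-missing cells; for a kernel
#' density surface whose kernels are interior to the raster this
#' approximates the total point weight.
#'
#' @param raster a `raster_grid` (values per m^2).
#' @return total mass (same units as the point weights).
#' @export
raster_mass <- function(raster) {
  stopifnot(inherits(raster, "raster_grid"))
  sum(raster$values, na.rm = TRUE) * raster$cell_size^2
}
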