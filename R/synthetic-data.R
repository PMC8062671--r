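#' Configuration for synthetic fire catalogs and covariate rasters
#'
#' Describes a full generative scenario: how many fires, over which years,
#' how sizes, months, causes and locations are drawn, the smooth random
#' fields standing in for covariate rasters, and the logistic coefficients
#' that tie ignition presence to the covariates. Every generator consumes
#' the scenario seed through fixed per-component sub-streams, so output is
#' reproducible and adding one generator never perturbs another.
#'
#' @param n_fires number of fire records (>= 0).
#' @param period `c(first_year, last_year)`.
#' @param size_law list describing the size distribution. Either a single
#'   family, e.g. `list(family = "pareto", shape = 0.728, scale = 61.935)`
#'   (families as in [fit_distribution()], plus `H` for
#'   `truncated_pareto`), or a spliced law
#'   `list(family = "spliced", body = <lognormal params>, tail = <pareto or
#'   truncated_pareto params>, splice = 500, tail_prob = 0.2, min_size =
#'   10)`: body truncated to `[min_size, splice)`, tail at or above the
#'   splice point with probability `tail_prob`.
#' @param cause_mix named probabilities over the six cause groups
#'   ([cause_groups()]); records receive a concrete raw code uniformly
#'   within the drawn group.
#' @param month_weights 12 probabilities (Jan..Dec).
#' @param spatial_intensity list of Gaussian hot spots, each
#'   `list(center = c(x, y), sd = metres, weight = w)`, over `window`.
#' @param window `c(xmin, ymin, xmax, ymax)` in metres.
#' @param covariate_fields named list of per-variable specs
#'   `list(mean =, sd =, corr_length = metres)`.
#' @param cross_correlation optional list of `list(a = "var1", b = "var2",
#'   r = rho)` pairwise target correlations between covariate fields.
#' @param logistic_coefficients named vector of weights, with an
#'   `"(Intercept)"` entry.
#' @param grid list `list(n_rows =, n_cols =, cell_size =, origin = c(x0,
#'   y0))` for the covariate rasters.
#' @param fuel_mix named probabilities over `timber`, `brush`, `grass`.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_fires, period, size_law, cause_mix,
                             month_weights, spatial_intensity, window,
                             covariate_fields = NULL,
                             cross_correlation = NULL,
                             logistic_coefficients = NULL,
                             grid = NULL,
                             fuel_mix = c(timber = 0.5, brush = 0.35,
                                          grass = 0.15),
                             seed = 1L) {
  stopifnot(n_fires >= 0, length(period) == 2, period[1] <= period[2])
  check_probs <- function(p, what, n = NULL) {
    if (!is.null(n) && length(p) != n) {
      abort(paste0(what, " must have length ", n),
            class = "firescape_config_error")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0(what, " must be nonnegative and sum to 1"),
            class = "firescape_config_error")
    }
  }
  check_probs(month_weights, "month_weights", 12)
  if (!all(names(cause_mix) %in% cause_groups()) ||
      is.null(names(cause_mix))) {
    abort("cause_mix must be named by cause groups",
          class = "firescape_config_error")
  }
  check_probs(unname(cause_mix), "cause_mix")
  check_probs(unname(fuel_mix), "fuel_mix")
  wts <- vapply(spatial_intensity, function(h) h$weight, numeric(1))
  if (any(wts <= 0)) {
    abort("Hot spot weights must be positive",
          class = "firescape_config_error")
  }
  for (h in spatial_intensity) stopifnot(h$sd > 0, length(h$center) == 2)
  stopifnot(length(window) == 4, window[1] < window[3], window[2] < window[4])
  structure(
    list(n_fires = as.integer(n_fires), period = period, size_law = size_law,
         cause_mix = cause_mix, month_weights = month_weights,
         spatial_intensity = spatial_intensity, window = window,
         covariate_fields = covariate_fields,
         cross_correlation = cross_correlation,
         logistic_coefficients = logistic_coefficients,
         grid = grid, fuel_mix = fuel_mix, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' The canonical "california-like" scenario
#'
#' A self-contained scenario with the statistical structure the analysis
#' assumes for a recent two-decade statewide record: 5234 fires over
#' 2000-2019; a spliced size law (truncated-lognormal body on 10-500
#' acres, truncated-Pareto tail at or above 500 acres with shape 0.482 and
#' a 1.3-million-acre ceiling, tail mass 0.1968); a cause mix matching the
#' published two-decade group shares; July-peaked seasonality; three
#' Gaussian ignition hot spots in a 600 km square window; twelve covariate
#' fields with realistic means, spreads and cross-correlations (collinear
#' road/powerline distances, housing/population densities, and
#' elevation-climate couplings); and the published logistic coefficient
#' vector for ignition presence.
#'
#' @param seed integer seed.
#' @param n_fires number of fires (default 5234).
#' @return a `synthetic_config`.
#' @export
california_like_config <- function(seed = 1L, n_fires = 5234) {
  synthetic_config(
    n_fires = n_fires,
    period = c(2000, 2019),
    size_law = list(
      family = "spliced",
      body = list(meanlog = 4.79, sdlog = 1.83),
      tail = list(family = "truncated_pareto", shape = 0.482,
                  scale = 500, H = 1.3e6),
      splice = 500, tail_prob = 1247 / 6336, min_size = 10
    ),
    cause_mix = c(natural = 1530, human_transportation = 419,
                  human_activity = 1754, human_construction = 302,
                  miscellaneous = 746, unknown = 1585) / 6336,
    month_weights = c(0.02, 0.02, 0.03, 0.05, 0.08, 0.13,
                      0.20, 0.17, 0.12, 0.09, 0.05, 0.04),
    spatial_intensity = list(
      list(center = c(150000, 450000), sd = 40000, weight = 0.35),
      list(center = c(350000, 350000), sd = 60000, weight = 0.40),
      list(center = c(450000, 120000), sd = 50000, weight = 0.25)
    ),
    window = c(0, 0, 600000, 600000),
    covariate_fields = list(
      dist_roads = list(mean = 3, sd = 2, corr_length = 30000),
      dist_powerline = list(mean = 5, sd = 3, corr_length = 30000),
      housing_density = list(mean = 50, sd = 60, corr_length = 20000),
      population_density = list(mean = 120, sd = 150, corr_length = 20000),
      elevation = list(mean = 0.9, sd = 0.7, corr_length = 50000),
      slope = list(mean = 10, sd = 7, corr_length = 10000),
      aspect = list(mean = 180, sd = 90, corr_length = 5000),
      tree = list(mean = 30, sd = 20, corr_length = 40000),
      shrub = list(mean = 25, sd = 15, corr_length = 40000),
      grass = list(mean = 20, sd = 15, corr_length = 40000),
      tmax = list(mean = 24, sd = 4, corr_length = 80000),
      vpdmax = list(mean = 20, sd = 6, corr_length = 80000)
    ),
    cross_correlation = list(
      list(a = "dist_roads", b = "dist_powerline", r = 0.55),
      list(a = "housing_density", b = "population_density", r = 0.81),
      list(a = "elevation", b = "tmax", r = -0.84),
      list(a = "elevation", b = "vpdmax", r = -0.61),
      list(a = "tmax", b = "vpdmax", r = 0.60)
    ),
    logistic_coefficients = c(
      `(Intercept)` = -9.68,
      dist_roads = -0.0354, housing_density = -0.0017,
      slope = 0.0059, aspect = 0.0143,
      tree = -0.0070, shrub = 0.0009, grass = 0.0230,
      tmax = 0.0934, vpdmax = 0.0655
    ),
    grid = list(n_rows = 200, n_cols = 200, cell_size = 3000,
                origin = c(0, 600000)),
    seed = seed
  )
}

# size sampler dispatch (expects RNG state already set by caller)
sample_sizes <- function(law, n) {
  if (n == 0) return(numeric(0))
  fam <- law$family
  if (fam == "spliced") {
    is_tail <- runif(n) < law$tail_prob
    out <- numeric(n)
    nt <- sum(is_tail)
    if (nt > 0) {
      tl <- law$tail
      out[is_tail] <- if (tl$family == "truncated_pareto") {
        rtpareto(nt, tl$shape, tl$scale, tl$H)
      } else {
        rpareto(nt, tl$shape, tl$scale)
      }
    }
    nb <- n - nt
    if (nb > 0) {
      lo <- plnorm(law$min_size, law$body$meanlog, law$body$sdlog)
      hi <- plnorm(law$splice, law$body$meanlog, law$body$sdlog)
      u <- lo + runif(nb) * (hi - lo)
      out[!is_tail] <- qlnorm(u, law$body$meanlog, law$body$sdlog)
    }
    return(out)
  }
  switch(fam,
    pareto = rpareto(n, law$shape, law$scale),
    truncated_pareto = rtpareto(n, law$shape, law$scale, law$H),
    lognormal = rlnorm(n, law$shape, law$scale),
    gamma = stats::rgamma(n, shape = law$shape, rate = law$scale),
    weibull = stats::rweibull(n, shape = law$shape, scale = law$scale),
    abort(paste0("Unknown size family: ", fam),
          class = "firescape_config_error")
  )
}

#' Generate a synthetic fire catalog
#'
#' Draws `n_fires` records from the scenario: sizes i.i.d. from the size
#' law (inverse-CDF sampling for the Pareto laws), months multinomial on
#' the month weights, cause groups multinomial on the cause mix (then a
#' concrete raw code uniform within the group), fuel types from the fuel
#' mix, and locations from the Gaussian-mixture spatial intensity
#' (truncated to the window by resampling). Fully reproducible per seed.
#'
#' @param config a `synthetic_config`.
#' @return a `fire_catalog`.
#' @export
gen_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_fires
  if (n == 0) {
    return(fire_catalog(tibble(id = character(0), x = numeric(0),
                               y = numeric(0), year = numeric(0),
                               month = numeric(0), size = numeric(0),
                               cause = character(0), fuel = character(0)),
                        crs_note = "synthetic planar CRS (m)"))
  }
  sizes <- with_sub_seed(config$seed, 1, sample_sizes(config$size_law, n))
  months <- with_sub_seed(config$seed, 2,
    sample.int(12, n, replace = TRUE, prob = config$month_weights))
  groups <- with_sub_seed(config$seed, 3, {
    gs <- names(config$cause_mix)
    gs[sample.int(length(gs), n, replace = TRUE,
                  prob = unname(config$cause_mix))]
  })
  causes <- with_sub_seed(config$seed, 4, {
    vocab <- cause_vocabulary()
    vapply(groups, function(g) {
      codes <- vocab$code[vocab$group == g]
      codes[sample.int(length(codes), 1)]
    }, character(1), USE.NAMES = FALSE)
  })
  xy <- with_sub_seed(config$seed, 5, {
    hs <- config$spatial_intensity
    wts <- vapply(hs, function(h) h$weight, numeric(1))
    comp <- sample.int(length(hs), n, replace = TRUE, prob = wts)
    x <- numeric(n); y <- numeric(n)
    win <- config$window
    for (i in seq_len(n)) {
      h <- hs[[comp[i]]]
      repeat {
        px <- rnorm(1, h$center[1], h$sd)
        py <- rnorm(1, h$center[2], h$sd)
        if (px >= win[1] && px < win[3] && py >= win[2] && py < win[4]) break
      }
      x[i] <- px; y[i] <- py
    }
    list(x = x, y = y)
  })
  years <- with_sub_seed(config$seed, 6,
    sample(seq(config$period[1], config$period[2]), n, replace = TRUE))
  fuel <- with_sub_seed(config$seed, 7, {
    fm <- config$fuel_mix
    names(fm)[sample.int(length(fm), n, replace = TRUE, prob = unname(fm))]
  })
  fire_catalog(tibble(
    id = sprintf("F%06d", seq_len(n)),
    x = xy$x, y = xy$y, year = years, month = months,
    size = sizes, cause = causes, fuel = fuel
  ), crs_note = "synthetic planar CRS (m)")
}

# Smooth standardized Gaussian random field on an n_rows x n_cols grid:
# white noise convolved with a separable Gaussian kernel of the given
# correlation length (in cells), then standardized to mean 0, sd 1.
smooth_field <- function(n_rows, n_cols, corr_cells) {
  e <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_cells > 0) {
    kern <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      k <- exp(-d^2 / (2 * corr_cells^2))
      k / rowSums(k)
    }
    e <- kern(n_rows) %*% e %*% t(kern(n_cols))
  }
  (e - mean(e)) / sd(e)
}

#' Generate a synthetic covariate raster stack
#'
#' One smooth Gaussian random field per configured variable, with the
#' requested mean, spread and spatial correlation length; requested
#' pairwise cross-correlations are imposed by linear mixing of the
#' standardized base fields through the Cholesky factor of the target
#' correlation matrix (so the spec must be positive definite). Variables
#' with `sd = 0` become constant layers. Seeded through the scenario seed.
#'
#' @param config a `synthetic_config` with `covariate_fields` and `grid`.
#' @return a `covariate_stack`.
#' @export
gen_covariate_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$covariate_fields) || is.null(config$grid)) {
    abort("Config lacks covariate_fields or grid",
          class = "firescape_config_error")
  }
  g <- config$grid
  fields <- config$covariate_fields
  nms <- names(fields)
  C <- diag(length(nms))
  dimnames(C) <- list(nms, nms)
  for (cc in config$cross_correlation %||% list()) {
    C[cc$a, cc$b] <- cc$r
    C[cc$b, cc$a] <- cc$r
  }
  L <- tryCatch(t(chol(C)), error = function(e) {
    abort("cross_correlation spec is not positive definite",
          class = "firescape_config_error")
  })
  base <- with_sub_seed(config$seed, 10, {
    lapply(nms, function(nm) {
      smooth_field(g$n_rows, g$n_cols, fields[[nm]]$corr_length / g$cell_size)
    })
  })
  E <- vapply(base, as.vector, numeric(g$n_rows * g$n_cols))
  Z <- E %*% t(L)
  layers <- list()
  for (j in seq_along(nms)) {
    f <- fields[[nms[j]]]
    z <- Z[, j]
    if (f$sd == 0) {
      v <- matrix(f$mean, g$n_rows, g$n_cols)
    } else {
      z <- (z - mean(z)) / sd(z)
      v <- matrix(f$mean + f$sd * z, g$n_rows, g$n_cols)
    }
    layers[[nms[j]]] <- raster_grid(v, g$origin, g$cell_size)
  }
  covariate_stack(layers)
}

#' Generate a synthetic ignition-presence grid from covariates
#'
#' Uses the logistic model generatively: per analysis cell the covariates
#' are averaged, the linear predictor `w0 + sum w_j x_j` is mapped through
#' the inverse logit to a probability `P`, and presence is drawn as
#' `Bernoulli(P)`. Seeded.
#'
#' @param stack a `covariate_stack`.
#' @param coefficients named weights incl. `"(Intercept)"`; all other
#'   names must be stack layers.
#' @param cell_size analysis cell edge in metres (default 3000).
#' @param seed integer seed.
#' @return a `grid_dataset` with the realized `presence` column and an
#'   extra column `true_p` of generating probabilities.
#' @export
gen_presence_grid <- function(stack, coefficients, cell_size = 3000,
                              seed = 1L) {
  stopifnot(inherits(stack, "covariate_stack"))
  vars <- setdiff(names(coefficients), "(Intercept)")
  if (!("(Intercept)" %in% names(coefficients))) {
    abort("coefficients must include an \"(Intercept)\" entry",
          class = "firescape_config_error")
  }
  missing_layers <- setdiff(vars, names(stack$layers))
  if (length(missing_layers) > 0) {
    abort(paste0("Coefficient name(s) not in stack: ",
                 paste(missing_layers, collapse = ", ")),
          class = "firescape_config_error")
  }
  grid <- grid_aggregate(NULL, stack, cell_size = cell_size)
  eta <- rep(coefficients[["(Intercept)"]], nrow(grid))
  for (v in vars) eta <- eta + coefficients[[v]] * grid[[v]]
  p <- plogis(eta)
  pres <- with_sub_seed(seed, 20, rbinom(length(p), 1, p))
  grid$presence <- as.integer(pres)
  grid$true_p <- p
  grid
}

#' Read and write scenario configurations as YAML
#'
#' @param config a `synthetic_config`.
#' @param path YAML file path.
#' @return `read_scenario()` returns a `synthetic_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  # named atomic vectors serialize as YAML maps (not bare sequences)
  obj <- unclass(config)
  for (f in c("cause_mix", "fuel_mix", "logistic_coefficients")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.list(obj[[f]])
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cause_mix <- unlist(raw$cause_mix)
  raw$fuel_mix <- unlist(raw$fuel_mix)
  if (!is.null(raw$logistic_coefficients)) {
    raw$logistic_coefficients <- unlist(raw$logistic_coefficients)
  }
  raw$month_weights <- as.numeric(unlist(raw$month_weights))
  raw$period <- as.numeric(unlist(raw$period))
  raw$window <- as.numeric(unlist(raw$window))
  for (i in seq_along(raw$spatial_intensity)) {
    raw$spatial_intensity[[i]]$center <-
      as.numeric(unlist(raw$spatial_intensity[[i]]$center))
  }
  if (!is.null(raw$grid)) {
    raw$grid$origin <- as.numeric(unlist(raw$grid$origin))
  }
  do.call(synthetic_config, raw)
}
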