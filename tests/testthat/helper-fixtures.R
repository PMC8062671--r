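# Shared fixtures, built in code.

# Small well-formed catalog spanning both periods and all cause groups.
toy_catalog <- function() {
  fire_catalog(data.frame(
    id = sprintf("T%02d", 1:8),
    x = c(1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000),
    y = c(1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000),
    year = c(1950, 1960, 1999, 2000, 2005, 2010, 2015, 2019),
    month = c(6, 7, 8, 7, 7, 9, 5, 7),
    size = c(12, 700, 35, 480, 5200, 18, 90, 1500),
    cause = c("lightning", "vehicle", "campfire", "powerline",
              "lightning", "arson", "unknown", "miscellaneous"),
    fuel = c("timber", "brush", "timber", "grass",
             "timber", "brush", NA, "timber")
  ))
}

# The published 11-variable correlation pattern used by the collinearity
# screen (upper triangle; variable order as printed, density column
# dropped). Values transcribed into a symmetric matrix.
published_correlation_fixture <- function() {
  vars <- c("dist_powerline", "dist_roads", "housing_density",
            "population_density", "aspect", "elevation", "slope",
            "grass", "shrub", "tree", "tmax", "vpdmax")
  m <- diag(length(vars))
  dimnames(m) <- list(vars, vars)
  set_r <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  # row: powerline distance
  set_r("dist_powerline", "vpdmax", -0.3949)
  set_r("dist_powerline", "tmax", -0.4819)
  set_r("dist_powerline", "tree", 0.0116)
  set_r("dist_powerline", "shrub", -0.0371)
  set_r("dist_powerline", "grass", -0.0065)
  set_r("dist_powerline", "slope", 0.1136)
  set_r("dist_powerline", "elevation", 0.4290)
  set_r("dist_powerline", "aspect", -0.0067)
  set_r("dist_powerline", "population_density", -0.1620)
  set_r("dist_powerline", "housing_density", -0.1626)
  set_r("dist_powerline", "dist_roads", 0.5524)
  # row: road distance
  set_r("dist_roads", "vpdmax", -0.3112)
  set_r("dist_roads", "tmax", -0.3867)
  set_r("dist_roads", "tree", 0.0193)
  set_r("dist_roads", "shrub", -0.0367)
  set_r("dist_roads", "grass", -0.0028)
  set_r("dist_roads", "slope", 0.0039)
  set_r("dist_roads", "elevation", 0.2895)
  set_r("dist_roads", "aspect", -0.0216)
  set_r("dist_roads", "population_density", -0.1609)
  set_r("dist_roads", "housing_density", -0.1617)
  # row: housing density
  set_r("housing_density", "vpdmax", 0.1268)
  set_r("housing_density", "tmax", 0.2019)
  set_r("housing_density", "tree", -0.0086)
  set_r("housing_density", "shrub", -0.0162)
  set_r("housing_density", "grass", 0.0016)
  set_r("housing_density", "slope", -0.0904)
  set_r("housing_density", "elevation", -0.1880)
  set_r("housing_density", "aspect", 0.0042)
  set_r("housing_density", "population_density", 0.8132)
  # row: population density
  set_r("population_density", "vpdmax", 0.1250)
  set_r("population_density", "tmax", 0.2059)
  set_r("population_density", "tree", -0.0085)
  set_r("population_density", "shrub", -0.0189)
  set_r("population_density", "grass", 0.0027)
  set_r("population_density", "slope", -0.0732)
  set_r("population_density", "elevation", -0.1908)
  set_r("population_density", "aspect", 0.0051)
  # row: aspect
  set_r("aspect", "vpdmax", -0.0315)
  set_r("aspect", "tmax", -0.0052)
  set_r("aspect", "tree", 0.0470)
  set_r("aspect", "shrub", 0.0291)
  set_r("aspect", "grass", 0.0079)
  set_r("aspect", "slope", 0.0832)
  set_r("aspect", "elevation", 0.0018)
  # row: elevation
  set_r("elevation", "vpdmax", -0.6086)
  set_r("elevation", "tmax", -0.8359)
  set_r("elevation", "tree", -0.0771)
  set_r("elevation", "shrub", -0.0398)
  set_r("elevation", "grass", 0.0035)
  set_r("elevation", "slope", 0.0017)
  # row: slope
  set_r("slope", "vpdmax", 0.0778)
  set_r("slope", "tmax", -0.0797)
  set_r("slope", "tree", -0.0159)
  set_r("slope", "shrub", 0.1342)
  set_r("slope", "grass", 0.0579)
  # row: grass
  set_r("grass", "vpdmax", 0.0193)
  set_r("grass", "tmax", 0.0176)
  set_r("grass", "tree", 0.0207)
  set_r("grass", "shrub", 0.1331)
  # row: shrub
  set_r("shrub", "vpdmax", 0.0503)
  set_r("shrub", "tmax", -0.0174)
  set_r("shrub", "tree", 0.0258)
  # row: tree
  set_r("tree", "vpdmax", 0.0316)
  set_r("tree", "tmax", 0.0598)
  # row: tmax
  set_r("tmax", "vpdmax", 0.0501)
  class(m) <- c("correlation_matrix", class(m))
  m
}

# A tiny covariate stack built from explicit matrices (2x2 cells).
tiny_stack <- function(z1, z2) {
  covariate_stack(list(
    a = raster_grid(matrix(z1, 2, 2), c(0, 2000), 1000),
    b = raster_grid(matrix(z2, 2, 2), c(0, 2000), 1000)
  ))
}

# Construct a bare distribution_fit for formula-level GOF checks.
manual_fit <- function(family, shape, scale, loglik, H = NA_real_, n = 1L) {
  structure(
    list(family = family, shape = shape, scale = scale, H = H,
         loglik = loglik, n = n, support_min = scale, log_transform = FALSE),
    class = "distribution_fit"
  )
}

# Reduced california-like scenario for pipeline-level tests.
reduced_scenario <- function(seed = 1L, n_fires = 600) {
  cfg <- california_like_config(seed = seed, n_fires = n_fires)
  cfg$grid <- list(n_rows = 50, n_cols = 50, cell_size = 12000,
                   origin = c(0, 600000))
  cfg
}
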