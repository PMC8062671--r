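test_that("generators are pure functions of the config (seed included)", {
  cfg <- california_like_config(seed = 101, n_fires = 400)
  c1 <- gen_catalog(cfg)
  c2 <- gen_catalog(cfg)
  expect_identical(c1$records, c2$records)
  cfg$grid <- list(n_rows = 30, n_cols = 30, cell_size = 20000,
                   origin = c(0, 600000))
  s1 <- gen_covariate_stack(cfg)
  s2 <- gen_covariate_stack(cfg)
  expect_identical(lapply(s1$layers, `[[`, "values"),
                   lapply(s2$layers, `[[`, "values"))
  g1 <- gen_presence_grid(s1, cfg$logistic_coefficients, 20000, seed = 3)
  g2 <- gen_presence_grid(s2, cfg$logistic_coefficients, 20000, seed = 3)
  expect_identical(g1$presence, g2$presence)
  # a different seed changes the draw
  c3 <- gen_catalog(california_like_config(seed = 102, n_fires = 400))
  expect_false(identical(c1$records$size, c3$records$size))
})

test_that("zero fires produce an empty catalog", {
  cfg <- california_like_config(seed = 1, n_fires = 0)
  expect_equal(n_fires(gen_catalog(cfg)), 0)
})

test_that("cause draws match the configured mix within binomial error", {
  cfg <- california_like_config(seed = 7, n_fires = 6336)
  cat0 <- gen_catalog(cfg)
  sm <- summarize_causes(cat0)
  n <- 6336
  p <- 1530 / 6336
  sigma <- sqrt(n * p * (1 - p))
  expect_lt(abs(sm$count[sm$group == "natural"] - 1530), 3 * sigma)
})

test_that("size draws reproduce closed-form moments of the size law", {
  set.seed(1)
  cfg <- california_like_config(seed = 61, n_fires = 20000)
  cfg$size_law <- list(family = "lognormal", shape = 4, scale = 0.5)
  x <- gen_catalog(cfg)$records$size
  true_mean <- exp(4 + 0.5^2 / 2)
  true_sd <- true_mean * sqrt(exp(0.5^2) - 1)
  expect_lt(abs(mean(x) - true_mean), 4 * true_sd / sqrt(20000))
  # truncated Pareto: sampled values respect the support exactly
  cfg$size_law <- list(family = "truncated_pareto", shape = 0.482,
                       scale = 52.627, H = 1e6)
  y <- gen_catalog(cfg)$records$size
  expect_gte(min(y), 52.627)
  expect_lte(max(y), 1e6)
  # inverse-CDF sampler matches the analytic CDF (KS-style check)
  Fy <- (1 - (52.627 / sort(y))^0.482) / (1 - (52.627 / 1e6)^0.482)
  ks <- max(abs(seq_along(y) / length(y) - Fy))
  expect_lt(ks, 1.63 / sqrt(length(y))) # 1% critical value
})

test_that("spliced size law puts the configured mass in the tail", {
  cfg <- california_like_config(seed = 13, n_fires = 20000)
  x <- gen_catalog(cfg)$records$size
  tail_frac <- mean(x >= 500)
  p <- 1247 / 6336
  expect_lt(abs(tail_frac - p), 3 * sqrt(p * (1 - p) / 20000))
  expect_gte(min(x), 10)
})

test_that("covariate fields hit their means, sds and cross-correlations", {
  cfg <- california_like_config(seed = 31)
  cfg$grid <- list(n_rows = 100, n_cols = 100, cell_size = 6000,
                   origin = c(0, 600000))
  st <- gen_covariate_stack(cfg)
  tm <- st$layers$tmax$values
  expect_equal(mean(tm), 24, tolerance = 1e-6)
  expect_equal(sd(as.vector(tm)), 4, tolerance = 1e-6)
  r <- cor(as.vector(st$layers$housing_density$values),
           as.vector(st$layers$population_density$values))
  expect_lt(abs(r - 0.81), 0.05)
  r2 <- cor(as.vector(st$layers$elevation$values),
            as.vector(st$layers$tmax$values))
  expect_lt(abs(r2 - (-0.84)), 0.05)
})

test_that("sd = 0 yields a constant layer and bad specs are rejected", {
  cfg <- california_like_config(seed = 5)
  cfg$grid <- list(n_rows = 10, n_cols = 10, cell_size = 60000,
                   origin = c(0, 600000))
  cfg$covariate_fields$tmax$sd <- 0
  st <- gen_covariate_stack(cfg)
  expect_true(all(st$layers$tmax$values == 24))

  bad <- california_like_config(seed = 5)
  bad$grid <- cfg$grid
  bad$cross_correlation <- list(
    list(a = "tmax", b = "vpdmax", r = 0.99),
    list(a = "tmax", b = "elevation", r = 0.99),
    list(a = "vpdmax", b = "elevation", r = -0.99))
  expect_error(gen_covariate_stack(bad), class = "firescape_config_error")
})

test_that("presence generation follows the logistic model", {
  cfg <- california_like_config(seed = 91)
  cfg$grid <- list(n_rows = 100, n_cols = 100, cell_size = 6000,
                   origin = c(0, 600000))
  st <- gen_covariate_stack(cfg)
  # all slopes zero, intercept zero -> rate 1/2
  co <- c(`(Intercept)` = 0)
  g <- gen_presence_grid(st, co, 6000, seed = 2)
  n <- nrow(g)
  expect_lt(abs(mean(g$presence) - 0.5), 3 * sqrt(0.25 / n))
  # one huge weight -> presence tracks that variable's sign pattern
  co2 <- c(`(Intercept)` = -24 * 50, tmax = 50)
  g2 <- gen_presence_grid(st, co2, 6000, seed = 2)
  ind <- as.integer(g2$tmax > 24)
  expect_gt(mean(g2$presence == ind), 0.95)
  expect_error(gen_presence_grid(st, c(`(Intercept)` = 0, nope = 1), 6000),
               class = "firescape_config_error")
})

test_that("scenario configs round-trip through YAML", {
  cfg <- california_like_config(seed = 17, n_fires = 123)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  back <- read_scenario(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-9)
  expect_identical(gen_catalog(back)$records, gen_catalog(cfg)$records)
})
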