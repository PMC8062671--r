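test_that("raster correlation matches the N-1 definition", {
  st <- tiny_stack(c(1, 2, 3, 4), c(1, 2, 3, 5))
  m <- raster_correlation(st)
  # hand computation: cov = 6.5/3, sds 1.2910 and 1.7078
  expect_equal(m["a", "b"], (6.5 / 3) / (sd(c(1, 2, 3, 4)) * sd(c(1, 2, 3, 5))),
               tolerance = 1e-12)
  expect_equal(m["a", "b"], 0.9827, tolerance = 1e-4)
  expect_equal(diag(unclass(m)), c(a = 1, b = 1))
  expect_true(isSymmetric(unclass(m)))

  st2 <- tiny_stack(c(1, 2, 3, 4), -c(1, 2, 3, 4))
  expect_equal(raster_correlation(st2)["a", "b"], -1)
  st3 <- tiny_stack(c(1, 2, 3, 4), c(7, 7, 7, 7))
  expect_error(raster_correlation(st3), class = "firescape_degenerate_error",
               regexp = "b")
})

test_that("collinearity screen reproduces the published removal set", {
  m <- published_correlation_fixture()
  res <- filter_correlated(
    m, threshold = 0.5,
    keep_rules = c("dist_roads", "housing_density", "tmax", "vpdmax"))
  expect_setequal(res$removed,
                  c("dist_powerline", "population_density", "elevation"))
  expect_length(res$retained, 9)
})

test_that("collinearity screen is the identity below threshold and always terminates clean", {
  m <- published_correlation_fixture()
  ok <- filter_correlated(m, threshold = 0.99)
  expect_equal(ok$retained, colnames(m))
  expect_length(ok$removed, 0)

  set.seed(33)
  for (rep in 1:5) {
    A <- matrix(rnorm(64), 8)
    C <- cov2cor(crossprod(A) + diag(8) * 0.1)
    dimnames(C) <- list(letters[1:8], letters[1:8])
    class(C) <- c("correlation_matrix", class(C))
    res <- filter_correlated(C, 0.5)
    sub <- abs(C[res$retained, res$retained])
    diag(sub) <- 0
    expect_true(all(sub <= 0.5))
  }
})

test_that("PCA satisfies its algebraic invariants", {
  set.seed(44)
  X <- as.data.frame(matrix(rnorm(600), ncol = 6))
  p <- pca_covariates(X, standardize = TRUE)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
  L <- p$loadings
  expect_equal(t(L) %*% L, diag(ncol(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # reconstruction from all components reproduces the centered/scaled data
  Z <- scale(as.matrix(X), center = p$center, scale = p$scale)
  expect_equal(p$scores %*% t(L), unclass(Z), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, j])), j], 0)
})

test_that("two perfectly correlated variables load on one component", {
  x <- rnorm(50)
  X <- data.frame(a = x, b = 2 * x)
  expect_warning(p <- pca_covariates(X, standardize = TRUE),
                 "Rank deficiency")
  expect_equal(p$variance_fraction, c(1, 0), tolerance = 1e-10)
})

test_that("grid aggregation uses half-open cells and averages correctly", {
  # 6x6 stack cells of 1 km, analysis cells of 3 km
  v <- matrix(1, 6, 6)
  st <- covariate_stack(list(
    const = raster_grid(v * 7, c(0, 6000), 1000),
    ramp = raster_grid(matrix(rep(1:6, each = 6), 6, 6), c(0, 6000), 1000)
  ))
  # fire exactly on a 3-km cell corner belongs to the upper-right cell
  cat0 <- fire_catalog(data.frame(id = "a", x = 3000, y = 3000, year = 2001,
                                  month = 7, size = 50, cause = "lightning"))
  g <- grid_aggregate(cat0, st, cell_size = 3000)
  expect_equal(nrow(g), 4)
  hit <- g[g$presence == 1, ]
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$cx, hit$cy), c(4500, 4500))
  expect_true(all(g$const == 7))
  # ramp layer varies along x: left cells average cols 1-3, right cols 4-6
  expect_equal(sort(unique(g$ramp)), c(2, 5))
})

test_that("presence assignment matches a brute-force point-in-cell oracle", {
  cfg <- california_like_config(seed = 55, n_fires = 300)
  cfg$grid <- list(n_rows = 40, n_cols = 40, cell_size = 15000,
                   origin = c(0, 600000))
  st <- gen_covariate_stack(cfg)
  cat0 <- gen_catalog(cfg)
  cs <- 30000
  g <- grid_aggregate(cat0, st, cell_size = cs)
  ncx <- 600000 / cs
  oracle <- rep(0L, nrow(g))
  for (i in seq_len(n_fires(cat0))) {
    px <- cat0$records$x[i]; py <- cat0$records$y[i]
    idx <- floor(py / cs) * ncx + floor(px / cs) + 1
    oracle[idx] <- 1L
  }
  expect_equal(g$presence, oracle)
})

test_that("logistic fit reduces to closed forms on toy data", {
  # intercept-only at presence rate 0.5 -> w0 = 0
  g <- tibble::tibble(cell_id = 1:100, cx = 0, cy = 0,
                      presence = rep(c(0L, 1L), 50))
  class(g) <- c("grid_dataset", class(g))
  f <- logistic_fit(g, variables = character(0))
  expect_equal(f$coefficients$estimate[1], 0, tolerance = 1e-8)

  # binary covariate: coefficient equals the log odds ratio
  n <- c(40, 60, 70, 30) # (x=0,y=0) (x=0,y=1) (x=1,y=0) (x=1,y=1)
  g2 <- tibble::tibble(
    cell_id = 1:200, cx = 0, cy = 0,
    presence = rep(c(0L, 1L, 0L, 1L), times = n),
    z = rep(c(0, 0, 1, 1), times = n)
  )
  class(g2) <- c("grid_dataset", class(g2))
  f2 <- logistic_fit(g2, "z")
  log_or <- log((n[4] * n[1]) / (n[3] * n[2]))
  expect_equal(unname(f2$coefficients$estimate[f2$coefficients$term == "z"]),
               log_or, tolerance = 1e-6)

  g3 <- g
  g3$presence <- 1L
  expect_error(logistic_fit(g3, character(0)),
               class = "firescape_fit_error")
})

test_that("separation is flagged, not silently ignored", {
  g <- tibble::tibble(cell_id = 1:40, cx = 0, cy = 0,
                      presence = rep(c(0L, 1L), each = 20),
                      z = c(rnorm(20, -5), rnorm(20, 5)))
  class(g) <- c("grid_dataset", class(g))
  expect_warning(f <- logistic_fit(g, "z"), "separation")
  expect_true(f$separation)
})
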