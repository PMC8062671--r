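test_that("Pareto MLE matches the closed-form Hill estimator", {
  x <- c(1, 2, 4, 8, 1.5, 3, 6, 12, 2.5, 5, 10, 20)
  fit <- fit_distribution(x, "pareto")
  beta <- min(x)
  alpha_hill <- length(x) / sum(log(x / beta))
  expect_equal(fit$scale, beta)
  expect_equal(fit$shape, alpha_hill, tolerance = 1e-12)
  # log-likelihood at the optimum agrees with direct evaluation of the pdf
  ll <- sum(log(fit$shape * fit$scale^fit$shape / x^(fit$shape + 1)))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("degenerate samples are refused", {
  expect_error(fit_distribution(rep(exp(1), 12), "lognormal"),
               class = "firescape_degenerate_error")
  expect_error(fit_distribution(c(-1, rexp(11)), "gamma"),
               class = "firescape_domain_error")
  expect_error(fit_distribution(rexp(5) + 1, "pareto"),
               class = "firescape_argument_error")
})

test_that("truncated-Pareto fit approaches the Pareto fit as H grows", {
  set.seed(71)
  x <- rpareto(2000, alpha = 1.1, beta = 10)
  plain <- fit_distribution(x, "pareto")
  huge_H <- fit_distribution(x, "truncated_pareto", H = 1e12 * max(x))
  expect_equal(huge_H$shape, plain$shape, tolerance = 1e-4)
  # with H at the sample max the conditional MLE differs (smaller shape)
  cond <- fit_distribution(x, "truncated_pareto")
  expect_lt(cond$shape, plain$shape)
  expect_equal(cond$H, max(x))
})

test_that("each family recovers its generating parameters at n = 5000", {
  n <- 5000
  cases <- list(
    list(family = "pareto", shape = 0.728,
         gen = function() rpareto(n, 0.728, 61.935)),
    list(family = "truncated_pareto", shape = 0.482,
         gen = function() rtpareto(n, 0.482, 52.627, 1e6)),
    list(family = "lognormal", shape = 4.79,
         gen = function() rlnorm(n, 4.79, 1.83)),
    list(family = "gamma", shape = 0.5,
         gen = function() rgamma(n, shape = 0.5, rate = 0.002)),
    list(family = "weibull", shape = 0.497,
         gen = function() rweibull(n, shape = 0.497, scale = 319.241))
  )
  n_rep <- 12
  for (cs in cases) {
    set.seed(2024)
    est <- replicate(n_rep, fit_distribution(cs$gen(), cs$family)$shape)
    mc_se <- sd(est) # the estimator's sampling SD, estimated by Monte Carlo
    expect_lt(abs(est[1] - cs$shape), 3 * mc_se,
              label = paste0(cs$family, " shape recovery"))
  }
})

test_that("goodness-of-fit statistics follow their closed forms", {
  # a Pareto(1, 1) CDF is 0.5 at x = 2: single-point KS and CvM
  f <- manual_fit("pareto", shape = 1, scale = 1, loglik = -10)
  gof <- goodness_of_fit(f, 2)
  expect_equal(gof$ks, 0.5)
  expect_equal(gof$cvm, 1 / 12)
  expect_equal(gof$aic, 24) # 2*2 - 2*(-10)
})

test_that("KS and CvM are invariant under monotone reparameterization", {
  set.seed(12)
  x <- rweibull(200, shape = 1.4, scale = 30)
  f1 <- fit_distribution(x, "weibull")
  # X^2 is Weibull(shape/2, scale^2); F values at x^2 coincide with F at x
  f2 <- manual_fit("weibull", shape = f1$shape / 2, scale = f1$scale^2,
                   loglik = f1$loglik, n = f1$n)
  g1 <- goodness_of_fit(f1, x)
  g2 <- goodness_of_fit(f2, x^2)
  expect_equal(g1$ks, g2$ks, tolerance = 1e-12)
  expect_equal(g1$cvm, g2$cvm, tolerance = 1e-10)
})

test_that("mean excess matches its closed forms", {
  # exponential: memorylessness makes e(u) constant at the mean
  set.seed(4)
  x <- rexp(30000, rate = 1 / 50)
  cur <- mean_excess_curve(x, min_exceedances = 500)
  expect_lt(max(abs(cur$e - 50)) / 50, 0.25)
  mid <- cur[cur$n_exceed >= 5000, ]
  expect_lt(max(abs(mid$e - 50)) / 50, 0.10)

  # Pareto alpha = 2: e(u) = u, slope 1/(alpha - 1) = 1
  set.seed(5)
  y <- rpareto(30000, alpha = 2, beta = 100)
  cur2 <- mean_excess_curve(y, min_exceedances = 1000)
  sl <- coef(lm(e ~ u, data = cur2))["u"]
  expect_lt(abs(sl - 1), 0.15)

  # single exceedance just below the maximum
  z <- c(1, 2, 3, 10)
  cur3 <- mean_excess_curve(z, min_exceedances = 1, thresholds = 10 - 1e-6)
  expect_equal(cur3$e, 10 - (10 - 1e-6), tolerance = 1e-9)
})

test_that("threshold selection finds constructed change points", {
  # exactly linear everywhere -> smallest candidate
  u <- seq(10, 1000, by = 10)
  lin <- tibble::tibble(u = u, e = 5 + 0.7 * u, n_exceed = rev(seq_along(u)))
  class(lin) <- c("mean_excess_curve", class(lin))
  sel <- select_threshold(lin, candidate_grid = c(100, 300, 500))
  expect_equal(sel$threshold, 100)

  # flat then slope 1 starting at u = 500 -> 500 within one grid step
  e <- ifelse(u < 500, 50, 50 + (u - 500))
  kink <- tibble::tibble(u = u, e = e, n_exceed = rev(seq_along(u)))
  class(kink) <- c("mean_excess_curve", class(kink))
  grid <- seq(100, 900, by = 50)
  sel2 <- select_threshold(kink, candidate_grid = grid)
  expect_lte(abs(sel2$threshold - 500), 50)

  expect_error(select_threshold(lin[1:2, ], candidate_grid = 2000),
               class = "firescape_selection_error")
})

test_that("spliced-tail catalogs recover the 500-acre change point", {
  # lognormal body below 500 acres, Pareto(alpha = 2) tail above it
  set.seed(99)
  n <- 20000
  is_tail <- runif(n) < 0.2
  x <- numeric(n)
  lo <- plnorm(10, 4.8, 1.0); hi <- plnorm(500, 4.8, 1.0)
  x[!is_tail] <- qlnorm(lo + runif(sum(!is_tail)) * (hi - lo), 4.8, 1.0)
  x[is_tail] <- rpareto(sum(is_tail), alpha = 2, beta = 500)
  cur <- mean_excess_curve(x, min_exceedances = 200)
  grid <- seq(100, 1500, by = 100)
  sel <- select_threshold(cur, candidate_grid = grid)
  expect_lte(abs(sel$threshold - 500), 100)
})

test_that("family comparison ranks deterministically and survives failures", {
  set.seed(31)
  x <- rlnorm(800, 4, 1.5)
  cmp <- compare_families(x)
  expect_equal(nrow(cmp), 5)
  expect_equal(cmp$family[which(cmp$rank_aic == 1)], "lognormal")
  # permutation invariance
  cmp2 <- compare_families(sample(x))
  expect_equal(cmp$rank_aic, cmp2$rank_aic)
  expect_equal(cmp$aic, cmp2$aic, tolerance = 1e-9)
  expect_error(compare_families(x, families = "pareto"),
               class = "firescape_argument_error")
})

test_that("log-size fitting restricts families and works on logs", {
  set.seed(8)
  x <- rlnorm(500, 5, 1.2)
  fit <- fit_distribution(x, "lognormal", log_transform = TRUE)
  expect_true(fit$log_transform)
  expect_error(fit_distribution(x, "pareto", log_transform = TRUE),
               class = "firescape_argument_error")
  cmp <- compare_families(x, c("gamma", "lognormal", "weibull"),
                          log_transform = TRUE)
  expect_equal(nrow(cmp), 3)
})
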