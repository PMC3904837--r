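# minimal stand-in fit objects for the pure-arithmetic operations
fake_fit <- function(spec, lnL, n_tip = 100) {
  k <- n_free(spec)
  p <- unpack_params(spec, rep(0.1, k))
  r <- net_diversification(p)
  structure(list(spec = spec, free = rep(0.1, k), params = p, lnL = lnL,
                 k = k, AIC = 2 * k - 2 * lnL,
                 r_temp = unname(r[["r_temp"]]),
                 r_trop = unname(r[["r_trop"]]), converged = TRUE,
                 n_tip = n_tip, tree_height = 10),
            class = "geosse_fit")
}

spec_k7 <- model_spec()
spec_k5 <- model_spec(speciation_equal = TRUE, extinction_equal = TRUE)
spec_k3 <- char_independent_spec()

test_that("AIC ranking sorts ascending and breaks ties by parsimony", {
  f7 <- fake_fit(spec_k7, -100)  # AIC 214
  f5 <- fake_fit(spec_k5, -101)  # AIC 212
  rk <- rank_models(list(f7, f5))
  expect_equal(rk$AIC, c(212, 214))
  expect_equal(rk$dAIC, c(0, 2))
  expect_equal(rk$k[1], 5)

  # exact AIC tie: fewer parameters ranks first
  g7 <- fake_fit(spec_k7, -100)    # AIC 214
  g5 <- fake_fit(spec_k5, -102)    # AIC 214
  rk2 <- rank_models(list(g7, g5))
  expect_equal(rk2$k, c(5, 7))

  rk3 <- rank_models(list(f7))
  expect_equal(rk3$dAIC, 0)
})

test_that("likelihood-ratio tests use the chi-square reference", {
  base <- fake_fit(spec_k5, -100)
  # statistic exactly 3.841 with df = 1
  full <- fake_fit(model_spec(speciation_equal = TRUE), -100 + 3.841 / 2)
  z <- lrt(base, full)
  expect_equal(z$df, 1)
  expect_equal(z$statistic, 3.841, tolerance = 1e-12)
  expect_equal(z$p, 0.05, tolerance = 1e-3)

  # equal likelihoods: statistic floored at 0, p = 1
  z0 <- lrt(fake_fit(spec_k3, -50), fake_fit(spec_k5, -50))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p, 1)

  # df = 2 reference value
  z2 <- lrt(fake_fit(spec_k3, -50), fake_fit(spec_k5, -50 + 0.05))
  expect_equal(z2$df, 2)
  expect_equal(z2$p, 0.9512294, tolerance = 1e-6)

  # non-nested pairs are rejected
  a <- fake_fit(model_spec(speciation_equal = TRUE), -50)
  b <- fake_fit(model_spec(extinction_equal = TRUE), -50)
  expect_error(lrt(a, b), "not nested")
  expect_error(lrt(full, base), "not nested")  # reversed direction
})

test_that("ML recovers equal-rates parameters from simulated data", {
  fx <- sim_fixture("eq300")
  ft <- fit_ml(fx$tree, fx$states, sampling_fractions(), spec_k3,
               starts = 2, seed = 1, rtol = 1e-7, atol = 1e-9)
  expect_true(ft$converged)
  expect_lt(abs(ft$params[["lambda_temp"]] - 0.25) / 0.25, 0.25)
  expect_lt(abs(ft$params[["mu_temp"]] - 0.1), 0.1)
  expect_lt(abs(ft$params[["d_temp"]] - 0.05), 0.08)
})

test_that("refitting from the optimum is idempotent", {
  fx <- sim_fixture("oot60")
  f <- sampling_fractions()
  ft <- fit_ml(fx$tree, fx$states, f, spec_k5, starts = 1, seed = 2,
               rtol = 1e-7, atol = 1e-9)
  ft2 <- fit_ml(fx$tree, fx$states, f, spec_k5, starts = 1,
                init = ft$free, rtol = 1e-7, atol = 1e-9)
  expect_equal(ft2$lnL, ft$lnL, tolerance = 1e-6)
})

test_that("richer models never fit worse than nested ones", {
  fx <- sim_fixture("oot100")
  f <- sampling_fractions()
  specs <- list(spec_k3,
                model_spec(biome_divergence = FALSE, dispersal_equal = TRUE),
                model_spec(dispersal_equal = TRUE),
                spec_k7)
  fits <- fit_model_set(fx$tree, fx$states, f, specs, seed = 3,
                        rtol = 1e-7, atol = 1e-9)
  for (i in seq_along(specs))
    for (j in seq_along(specs))
      if (biomesse:::is_nested_spec(specs[[i]], specs[[j]]))
        expect_lte(fits[[i]]$lnL, fits[[j]]$lnL + 1e-4)
  # AIC identity
  for (ft in fits) expect_equal(ft$AIC, 2 * ft$k - 2 * ft$lnL)
})

test_that("prior calibration follows the doubled-net-diversification rule", {
  fx <- sim_fixture("oot100")
  pr <- default_priors(fx$tree, fx$states, sampling_fractions(), seed = 4,
                       rtol = 1e-7, atol = 1e-9)
  ci <- pr$ci_fit
  r_hat <- ci$r_temp
  if (r_hat > 0) {
    expect_equal(pr$mean, 2 * r_hat)
    expect_equal(pr$rate, 1 / (2 * r_hat))
  } else {
    expect_equal(pr$mean, unname(ci$params[["lambda_temp"]]))
  }
})

test_that("the slice sampler reproduces an exponential target", {
  set.seed(6)
  rate <- 2
  draws <- slice_sample(function(x) dexp(x, rate, log = TRUE),
                        x0 = 0.5, n = 4000, w = 1 / rate)
  x <- draws[, 1]
  expect_lt(abs(mean(x) - 1 / rate), 0.04)
  probs <- seq(0.1, 0.9, by = 0.2)
  rel <- abs(quantile(x, probs) - qexp(probs, rate)) / qexp(probs, rate)
  expect_lt(max(rel), 0.12)
})

test_that("a dominating prior shrinks the posterior toward its mean", {
  fx <- sim_fixture("oot60")
  ml <- fit_ml(fx$tree, fx$states, sampling_fractions(), spec_k3,
               starts = 1, seed = 7, rtol = 1e-7, atol = 1e-9)
  prior_at <- function(rate)
    structure(list(rate = rate, mean = 1 / rate, ci_fit = ml),
              class = "prior_spec")
  weak <- run_mcmc(fx$tree, fx$states, sampling_fractions(), spec_k3,
                   prior_at(2), steps = 80, burnin = 20, seed = 8,
                   init = ml$free, rtol = 1e-6, atol = 1e-8)
  strong <- run_mcmc(fx$tree, fx$states, sampling_fractions(), spec_k3,
                     prior_at(500), steps = 80, burnin = 20, seed = 8,
                     init = ml$free, rtol = 1e-6, atol = 1e-8)
  # the tight prior (mean 0.002) pulls every rate far below the
  # diffuse-prior posterior, which tracks the ML fit
  expect_lt(mean(strong$draws[, "lambda"]),
            0.5 * mean(weak$draws[, "lambda"]))
  expect_true(all(colMeans(strong$draws) <= colMeans(weak$draws) + 1e-6))
})

test_that("MCMC rejects time-varying specs and empty summaries", {
  fx <- sim_fixture("oot60")
  pr <- structure(list(rate = 2, mean = 0.5, ci_fit = NULL),
                  class = "prior_spec")
  expect_error(run_mcmc(fx$tree, fx$states, sampling_fractions(),
                        model_spec(time_varying = TRUE), pr,
                        steps = 10, burnin = 0, seed = 1),
               "time-constant")
})

test_that("posterior summaries flag a significant rate difference", {
  # constant chain: zero-width interval at the value
  spec <- spec_k3
  draws <- matrix(rep(c(0.3, 0.1, 0.05), each = 50), nrow = 50,
                  dimnames = list(NULL, c("lambda", "mu", "d")))
  post <- structure(list(draws = draws, lnL = rep(-1, 50), spec = spec,
                         steps = 50, burnin = 0),
                    class = "geosse_posterior")
  s <- summarize_posterior(post)
  expect_equal(unname(s$table["lambda", ]), c(0.3, 0.3, 0.3))
  expect_false(s$significant)  # equal rates: difference identically 0

  spec2 <- model_spec(biome_divergence = FALSE, dispersal_equal = TRUE)
  draws2 <- cbind(lambda_temp = runif(50, 0.1, 0.2),
                  lambda_trop = runif(50, 0.5, 0.6),
                  mu_temp = runif(50, 0.05, 0.1),
                  mu_trop = runif(50, 0.01, 0.02),
                  d = runif(50, 0.01, 0.05))
  post2 <- structure(list(draws = draws2, lnL = rep(-1, 50), spec = spec2,
                          steps = 50, burnin = 0),
                     class = "geosse_posterior")
  s2 <- summarize_posterior(post2)
  expect_true(s2$significant)
  expect_gt(s2$derived["r_diff", "lower"], 0)
})
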