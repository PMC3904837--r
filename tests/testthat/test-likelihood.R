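test_that("tip initialisation carries the sampling fractions", {
  s <- tip_init("TROPICAL", sampling_fractions(1, 1, 1))
  expect_equal(unname(s$D), c(0, 1, 0))
  expect_equal(unname(s$E), c(0, 0, 0))
  s2 <- tip_init("TEMPERATE", sampling_fractions(0.84, 0.83, 0.85))
  expect_equal(unname(s2$D[1]), 0.84)
  expect_equal(unname(s2$E[1]), 0.16)
  expect_equal(unname(s2$D[2:3]), c(0, 0))
  s3 <- tip_init("WIDESPREAD", sampling_fractions(0.84, 0.83, 0.85))
  expect_equal(unname(s3$D[3]), 0.85)
})

test_that("propagation with all rates zero is the identity", {
  p <- geosse_params(0, 0, 0, 0, 0, 0, 0)
  s0 <- likelihood_state(0.2, 0.5, 0.1, 0.3, 0.1, 0.05)
  s1 <- propagate_branch(p, s0, 0, 7.3)
  expect_equal(s1$D, s0$D, tolerance = 1e-10)
  expect_equal(s1$E, s0$E, tolerance = 1e-10)
})

test_that("pure-death extinction probability matches 1 - exp(-mu t)", {
  for (mu in c(0.1, 0.5, 1.5)) {
    p <- geosse_params(0, 0, 0, 0, mu, 0, 0)
    for (t in c(0.5, 1, 2, 5)) {
      s <- propagate_branch(p, tip_init("TROPICAL"), 0, t)
      expect_equal(unname(s$E[2]), 1 - exp(-mu * t), tolerance = 1e-8)
    }
  }
})

test_that("single-region likelihood reduces to the closed-form birth-death", {
  set.seed(21)
  tr <- random_single_region_tree(25)
  root <- root_options("fixed-state", root_state = "TROPICAL")
  for (i in 1:3) {
    lam <- runif(1, 0.2, 0.6)
    mu <- runif(1, 0.05, 0.8) * lam
    f <- runif(1, 0.5, 1)
    ll <- geosse_loglik(tr, all_tropical(tr),
                        geosse_params(lam, lam, 0, mu, mu, 0, 0),
                        sampling_fractions(f, f, f), root = root)
    expect_equal(ll, bd_loglik_closed_form(tr, lam, mu, f),
                 tolerance = 1e-7)
  }
})

test_that("branch propagation matches an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  geosse_rhs <- function(t, y, p) {
    lamA <- p$sA; lamB <- p$sB
    EA <- y[1]; EB <- y[2]; EW <- y[3]
    DA <- y[4]; DB <- y[5]; DW <- y[6]
    list(c(
      p$xA - (lamA + p$dA + p$xA) * EA + p$dA * EW + lamA * EA^2,
      p$xB - (lamB + p$dB + p$xB) * EB + p$dB * EW + lamB * EB^2,
      -(lamA + lamB + p$sAB + p$xA + p$xB) * EW + p$xA * EB + p$xB * EA +
        lamA * EA * EW + lamB * EB * EW + p$sAB * EA * EB,
      -(lamA + p$dA + p$xA) * DA + p$dA * DW + 2 * lamA * DA * EA,
      -(lamB + p$dB + p$xB) * DB + p$dB * DW + 2 * lamB * DB * EB,
      -(lamA + lamB + p$sAB + p$xA + p$xB) * DW + p$xA * DB + p$xB * DA +
        lamA * (EA * DW + EW * DA) + lamB * (EB * DW + EW * DB) +
        p$sAB * (EA * DB + EB * DA)))
  }
  set.seed(55)
  for (i in 1:5) {
    v <- runif(7, 0.01, 0.6)
    p <- geosse_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7])
    f <- sampling_fractions(0.8, 0.9, 0.7)
    st <- sample(c("TEMPERATE", "TROPICAL", "WIDESPREAD"), 1)
    s0 <- tip_init(st, f)
    tt <- runif(1, 0.5, 8)
    got <- propagate_branch(p, s0, 0, tt)
    ref <- deSolve::ode(c(s0$E, s0$D), c(0, tt), geosse_rhs,
                        list(sA = v[1], sB = v[2], sAB = v[3], xA = v[4],
                             xB = v[5], dA = v[6], dB = v[7]),
                        rtol = 1e-10, atol = 1e-12)[2, -1]
    expect_equal(unname(c(got$E, got$D)), unname(ref), tolerance = 1e-6)
  }
})

test_that("node combination applies the cladogenetic modes", {
  p <- geosse_params(0, 0.2, 0, 0, 0, 0, 0)
  l <- likelihood_state(0, 0.5, 0)
  r <- likelihood_state(0, 0.5, 0)
  out <- combine_at_node(p, l, r)
  expect_equal(unname(out$D), c(0, 0.05, 0))

  # biome divergence: symmetrized cross-product of endemic daughters
  p2 <- geosse_params(0, 0, 0.1, 0, 0, 0, 0)
  out2 <- combine_at_node(p2,
                          likelihood_state(1, 1, 0),
                          likelihood_state(1, 1, 0))
  expect_equal(unname(out2$D[3]), 0.1 * 0.5 * (1 * 1 + 1 * 1))
  expect_equal(unname(out2$D[1:2]), c(0, 0))
  # one daughter per endemic state: only one assignment survives
  out2b <- combine_at_node(p2,
                           likelihood_state(1, 0, 0),
                           likelihood_state(0, 1, 0))
  expect_equal(unname(out2b$D[3]), 0.05)

  # zero is absorbing
  out3 <- combine_at_node(geosse_params(0.3, 0.4, 0.1, 0, 0, 0, 0),
                          likelihood_state(0, 0, 0),
                          likelihood_state(0, 0, 0))
  expect_equal(unname(out3$D), c(0, 0, 0))
})

test_that("zero slopes reproduce the time-constant likelihood", {
  fx <- sim_fixture("oot100")
  p <- geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12)
  ptv <- time_varying_params(0.2, 0.4, 0, 0, 0.08, 0.12, 0.04, 0.04, 0.12)
  ll1 <- geosse_loglik(fx$tree, fx$states, p)
  ll2 <- geosse_loglik(fx$tree, fx$states, ptv)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("time-varying rates use absolute ages and enforce positivity", {
  fx <- sim_fixture("oot100")
  h <- tree_height(fx$tree)
  # a slope that turns lambda negative within the tree height -> -Inf
  bad <- time_varying_params(0.2, 0.4, 0, -0.4 * 1.1 / h, 0.08,
                             0.12, 0.04, 0.04, 0.12)
  expect_equal(geosse_loglik(fx$tree, fx$states, bad), -Inf)
  # a valid negative slope changes the likelihood
  ok <- time_varying_params(0.2, 0.4, 0, -0.01, 0.08, 0.12, 0.04,
                            0.04, 0.12)
  ll <- geosse_loglik(fx$tree, fx$states, ok)
  expect_true(is.finite(ll))
  expect_false(isTRUE(all.equal(
    ll, geosse_loglik(fx$tree, fx$states,
                      geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04,
                                    0.12)))))
})

test_that("likelihood obeys the rate/time rescaling relation", {
  set.seed(9)
  tr <- ape::rcoal(6)
  states <- data.frame(species = tr$tip.label,
                       state = c("TROPICAL", "TEMPERATE", "WIDESPREAD",
                                 "TROPICAL", "TROPICAL", "TEMPERATE"))
  p <- geosse_params(0.3, 0.5, 0.1, 0.1, 0.05, 0.07, 0.12)
  ll1 <- geosse_loglik(tr, states, p)
  cc <- 2.5
  tr2 <- tr
  tr2$edge.length <- tr$edge.length / cc
  p2 <- do.call(geosse_params, as.list(unclass(p) * cc))
  ll2 <- geosse_loglik(tr2, states, p2)
  # each internal node contributes one rate factor; conditioning on
  # survival removes one, leaving (n - 2) log c
  n <- ape::Ntip(tr)
  expect_equal(ll2 - ll1, (n - 2) * log(cc), tolerance = 1e-7)
})

test_that("E stays within [0,1] and lnL finite across random rate draws", {
  set.seed(33)
  fx <- sim_fixture("oot60")
  for (i in 1:20) {
    p <- do.call(geosse_params, as.list(runif(7, 0, 0.8)))
    ll <- geosse_loglik(fx$tree, fx$states, p)
    expect_true(is.finite(ll) || ll == -Inf)
    s <- propagate_branch(p, tip_init("WIDESPREAD",
                                      sampling_fractions(0.8, 0.8, 0.8)),
                          0, 20)
    expect_true(all(s$E >= 0 & s$E <= 1))
  }
})

test_that("an observed state with zero sampling fraction is impossible", {
  fx <- sim_fixture("oot100")
  p <- geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12)
  f0 <- c(0, 1, 1)  # temperate tips unobservable
  expect_true("TEMPERATE" %in% fx$states$state)
  expect_equal(geosse_loglik(fx$tree, fx$states, p, f0), -Inf)
})

test_that("halving ODE tolerances leaves lnL stable", {
  fx <- sim_fixture("oot100")
  p <- geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12)
  ll1 <- geosse_loglik(fx$tree, fx$states, p, rtol = 1e-8, atol = 1e-10)
  ll2 <- geosse_loglik(fx$tree, fx$states, p, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(ll1 - ll2), 1e-6)
})

test_that("lnL in the generating rate has an interior maximum", {
  fx <- sim_fixture("oot100")
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  ll <- vapply(grid, function(lam)
    geosse_loglik(fx$tree, fx$states,
                  geosse_params(0.2, lam, 0.08, 0.12, 0.04, 0.04, 0.12)),
    numeric(1))
  best <- which.max(ll)
  expect_gt(best, 1)
  expect_lt(best, length(grid))
})

test_that("root treatments differ and are all finite", {
  fx <- sim_fixture("oot60")
  p <- geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12)
  ll_fj <- geosse_loglik(fx$tree, fx$states, p)
  ll_eq <- geosse_loglik(fx$tree, fx$states, p,
                         root = root_options("equal-weights"))
  ll_fx <- geosse_loglik(fx$tree, fx$states, p,
                         root = root_options("fixed-state",
                                             root_state = "TROPICAL"))
  ll_nc <- geosse_loglik(fx$tree, fx$states, p,
                         root = root_options(condition_on_survival = FALSE))
  expect_true(all(is.finite(c(ll_fj, ll_eq, ll_fx, ll_nc))))
  expect_false(isTRUE(all.equal(ll_fj, ll_eq)))
  expect_false(isTRUE(all.equal(ll_fj, ll_nc)))
})
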