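test_that("states unreachable without dispersal never appear", {
  sim <- simulate_geosse(geosse_params(0.3, 0.3, 0, 0.1, 0.1, 0, 0),
                         max_time = 15, root_state = "TROPICAL",
                         seed = 12)
  expect_true(all(sim$states$state == "TROPICAL"))
})

test_that("simulated trees are binary, ultrametric, and within the stop time", {
  sim <- simulate_geosse(geosse_params(0.2, 0.4, 0.08, 0.12, 0.04,
                                       0.04, 0.12),
                         max_time = 12, seed = 99)
  tr <- sim$tree
  expect_true(ape::is.binary(tr))
  depths <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  expect_lt(diff(range(depths)) / max(depths), 1e-9)
  expect_lte(max(depths), 12 + 1e-9)
  expect_true(all(tr$edge.length > 0))
  expect_equal(sort(sim$states$species), sort(tr$tip.label))
  # passes the same validation the likelihood requires
  expect_s3_class(validate_phylogeny(tr), "phylo")
})

test_that("simulation is reproducible given a seed", {
  p <- geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12)
  a <- simulate_geosse(p, max_time = 10, seed = 5)
  b <- simulate_geosse(p, max_time = 10, seed = 5)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$states, b$states)
  c <- simulate_geosse(p, max_time = 10, seed = 6)
  expect_false(identical(ape::write.tree(a$tree), ape::write.tree(c$tree)))
})

test_that("target-size band rejection and truth record work", {
  p <- geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12)
  sim <- simulate_geosse(p, max_time = 13, target_tips = 100,
                         tip_tol = 0.3, seed = 8)
  expect_gte(ape::Ntip(sim$tree), 70)
  expect_lte(ape::Ntip(sim$tree), 130)
  expect_equal(sim$truth$n_sampled, ape::Ntip(sim$tree))
  expect_gte(sim$truth$n_extant, sim$truth$n_sampled)
})

test_that("per-state thinning follows the binomial law", {
  set.seed(14)
  p <- geosse_params(0, 0.3, 0, 0, 0, 0, 0)  # pure birth, tropical only
  reps <- 300
  extant <- sampled <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- simulate_geosse(p, max_time = 12,
                         sampling = sampling_fractions(1, 0.5, 1),
                         condition = FALSE)
    extant[i] <- s$truth$n_extant
    sampled[i] <- s$truth$n_sampled
  }
  # conditional on extant counts, sampled ~ Binomial(extant, 0.5)
  z <- (sum(sampled) - 0.5 * sum(extant)) / sqrt(0.25 * sum(extant))
  expect_lt(abs(z), 3)
})

test_that("the out-of-tropics regime yields a tropical-rich tree", {
  cfg <- scenario_config("out_of_tropics")
  sim <- simulate_geosse(cfg$params, cfg$max_time, cfg$root_state,
                         cfg$sampling, target_tips = 300, tip_tol = 0.5,
                         seed = 9)
  counts <- table(factor(sim$states$state, levels = c("TEMPERATE",
                                                      "TROPICAL",
                                                      "WIDESPREAD")))
  expect_gt(counts[["TROPICAL"]], counts[["TEMPERATE"]])
})

test_that("fixtures are written deterministically", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  f1 <- make_fixture("equal_rates", seed = 3, dir = d1, target_tips = 60,
                     tip_tol = 0.6)
  f2 <- make_fixture("equal_rates", seed = 3, dir = d2, target_tips = 60,
                     tip_tol = 0.6)
  for (k in c("tree", "states", "truth"))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  tr <- read_newick(f1$tree)
  st <- read_state_table(f1$states, schema = "states")
  expect_setequal(tr$tip.label, st$species)
  truth <- jsonlite::read_json(f1$truth)
  expect_equal(truth$scenario, "equal_rates")
  expect_equal(truth$params$lambda_temp, 0.25)
  expect_error(make_fixture("no_such_scenario", 1, tempdir()))
})

test_that("time-varying simulation respects the thinning bound", {
  cfg <- scenario_config("time_increasing")
  sim <- simulate_geosse(cfg$params, max_time = 10, root_state = "TROPICAL",
                         target_tips = 50, tip_tol = 0.8, seed = 21)
  expect_true(ape::is.binary(sim$tree))
  ll <- geosse_loglik(sim$tree, sim$states, cfg$params)
  expect_true(is.finite(ll))
})
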