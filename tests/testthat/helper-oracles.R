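# Independent oracles and shared simulated fixtures.

# Closed-form constant-rate birth-death log-likelihood with sampling
# fraction f, in the same density convention as the pruning likelihood
# (one speciation-rate factor per internal node, survival conditioning
# lambda * G(root)^2). Derived from the logistic solution of the
# extinction ODE: with G = 1 - E, G' = rG - lambda G^2, G(0) = f, and
# D(t)/D(0) = (G(t)/G(0))^2 exp(-r t). Pure arithmetic; no ODE solver.
bd_loglik_closed_form <- function(tree, lambda, mu, f = 1,
                                  condition = TRUE) {
  r <- lambda - mu
  stopifnot(abs(r) > 1e-12)
  G <- function(t) r * f * exp(r * t) / (r + lambda * f * (exp(r * t) - 1))
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  ll <- n * log(f)
  for (i in seq_len(nrow(tree$edge))) {
    tp <- ages[tree$edge[i, 1]]
    tc <- ages[tree$edge[i, 2]]
    ll <- ll + 2 * (log(G(tp)) - log(G(tc))) - r * (tp - tc)
  }
  ll <- ll + (n - 1) * log(lambda)
  if (condition) ll <- ll - log(lambda * G(max(ages))^2)
  ll
}

random_single_region_tree <- function(n) ape::rcoal(n)

all_tropical <- function(tree) {
  data.frame(species = tree$tip.label, state = "TROPICAL",
             stringsAsFactors = FALSE)
}

# shared simulated datasets, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

sim_fixture <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  fx <- switch(name,
    # out-of-tropics regime at ~100 tips: quick likelihood-level checks
    oot100 = simulate_geosse(
      geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12),
      max_time = 13, target_tips = 100, tip_tol = 0.5, seed = 2024),
    # ~60 tips for the slow per-fit stages (sweep, pipeline)
    oot60 = simulate_geosse(
      geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12),
      max_time = 11, target_tips = 60, tip_tol = 0.5, seed = 77),
    # equal-rates data for recovery checks
    eq300 = simulate_geosse(
      geosse_params(0.25, 0.25, 0, 0.1, 0.1, 0.05, 0.05),
      max_time = 40, target_tips = 300, tip_tol = 0.4, seed = 31),
    # the documented ~500-tip out-of-tropics study condition
    oot500 = {
      cfg <- scenario_config("out_of_tropics")
      simulate_geosse(cfg$params, cfg$max_time, cfg$root_state,
                      cfg$sampling, target_tips = cfg$target_tips,
                      seed = 424242)
    },
    stop("unknown fixture ", name))
  .fixture_cache[[name]] <- fx
  fx
}
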