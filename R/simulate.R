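## Exact forward simulation of the two-biome GeoSSE event process.
##
## Events realized (matching the likelihood exactly):
##   temperate endemic:  speciate lambda_temp(t) -> two temperate daughters
##                       go extinct mu_temp
##                       expand range d_temp -> widespread
##   tropical endemic:   symmetric with _trop rates
##   widespread:         within-temperate speciation lambda_temp(t)
##                         -> daughters (TEMPERATE, WIDESPREAD)
##                       within-tropical speciation lambda_trop(t)
##                         -> daughters (TROPICAL, WIDESPREAD)
##                       biome divergence lambda_tt
##                         -> daughters (TEMPERATE, TROPICAL)
##                       contract in temperate (mu_temp) -> tropical
##                       contract in tropics (mu_trop) -> temperate
## Time-varying speciation is handled by thinning against a rate bound.

#' Simulate a phylogeny under the two-biome GeoSSE process
#'
#' Exact next-event (Gillespie) simulation from a single root lineage for
#' `max_time` Myr, followed by pruning of extinct lineages, per-state
#' Bernoulli thinning of extant tips by the sampling fractions, and
#' suppression of degree-2 nodes. The returned tree is ultrametric by
#' construction and the whole run is reproducible given `seed`.
#'
#' Runs in which the process dies out (or misses the target-size band,
#' when one is set) are retried up to `max_retries` times; the retry
#' count is recorded in the truth record because this conditions the
#' output on survival, matching the likelihood's default conditioning.
#'
#' @param params a [geosse_params()] or [time_varying_params()].
#' @param max_time stem age of the simulation in Myr.
#' @param root_state state of the initial lineage (default TROPICAL).
#' @param sampling a [sampling_fractions()] object used for tip thinning.
#' @param target_tips optional target number of sampled extant tips;
#'   runs outside `[target * (1 - tip_tol), target * (1 + tip_tol)]` are
#'   rejected and retried (simple fixed-time band rejection; this biases
#'   mildly toward typical-sized outcomes and is documented as such).
#' @param tip_tol relative half-width of the acceptance band.
#' @param seed integer seed.
#' @param max_retries retry cap before giving up.
#' @param condition if `TRUE` (default), reject and retry runs that die
#'   out or miss the size band. If `FALSE`, a single unconditioned
#'   realization is returned; its `tree` element is `NULL` when fewer
#'   than two sampled tips survive, but the extant/sampled counts in the
#'   truth record are always filled (useful for moment checks on the
#'   raw branching process).
#' @param build_tree set `FALSE` (with `condition = FALSE`) to skip
#'   phylogeny assembly and return counts and tip states only, which is
#'   much faster for large-replicate moment checks.
#' @return list with elements `tree` (phylo), `states` (data.frame
#'   species/state), and `truth` (generating parameters, root state,
#'   times, extant and sampled tip counts, retries, seed).
#' @export
simulate_geosse <- function(params, max_time, root_state = "TROPICAL",
                            sampling = sampling_fractions(),
                            target_tips = NULL, tip_tol = 0.4,
                            seed = NULL, max_retries = 1000,
                            condition = TRUE, build_tree = TRUE) {
  stopifnot(max_time > 0)
  p <- as_rate_vector(params)
  check_tv_positive(p, max_time)
  if (!is.null(seed)) set.seed(seed)
  root_i <- state_index(root_state)

  if (!build_tree && condition)
    stop("build_tree = FALSE requires condition = FALSE")
  for (attempt in seq_len(if (condition) max_retries else 1L)) {
    sim <- sim_once(p, max_time, root_i, build_tree)
    keep <- runif(sim$n_extant) <= as.numeric(sampling)[sim$tip_state]
    truth <- list(params = params, root_state = BIOME_STATES[root_i],
                  max_time = max_time, sampling = as.numeric(sampling),
                  n_extant = sim$n_extant, n_sampled = sum(keep),
                  retries = attempt - 1L, seed = seed)
    ok <- !is.null(sim$tree) && sum(keep) >= 2
    if (ok && condition && !is.null(target_tips)) {
      lo <- ceiling(target_tips * (1 - tip_tol))
      hi <- floor(target_tips * (1 + tip_tol))
      ok <- sum(keep) >= lo && sum(keep) <= hi
    }
    if (!ok) {
      if (condition) next
      return(list(tree = NULL, states = NULL, truth = truth))
    }
    drop <- sim$tree$tip.label[!keep]
    tree <- if (length(drop) > 0) ape::drop.tip(sim$tree, drop) else sim$tree
    tree$root.edge <- NULL
    st <- sim$tip_state[keep][match(tree$tip.label, sim$tree$tip.label[keep])]
    states <- data.frame(species = tree$tip.label,
                         state = BIOME_STATES[st],
                         stringsAsFactors = FALSE)
    return(list(tree = tree, states = states, truth = truth))
  }
  stop("simulation failed to meet the survival/size condition within ",
       max_retries, " retries")
}

## One realization including extinct lineages. `tree` is NULL if fewer
## than 2 extant tips survive or the root lineage never speciates;
## `tip_state` and `n_extant` always describe the extant lineages.
sim_once <- function(p, max_time, root_i, build_tree = TRUE) {
  sA0 <- p[1]; sB0 <- p[2]; sAB <- p[3]
  xA <- p[4]; xB <- p[5]; dA <- p[6]; dB <- p[7]
  rA <- p[8]; rB <- p[9]
  tv <- rA != 0 || rB != 0
  lamA_at <- function(age) sA0 + rA * age
  lamB_at <- function(age) sB0 + rB * age

  cap <- 256L
  parent <- integer(cap); birth <- numeric(cap); end <- numeric(cap)
  state <- integer(cap); kind <- integer(cap)  # 0 open, 1 internal, 2 extinct, 3 extant
  n_lin <- 1L
  parent[1] <- 0L; birth[1] <- 0; state[1] <- root_i; kind[1] <- 0L
  alive <- 1L
  # incremental per-state counts of living lineages
  cnt <- c(0L, 0L, 0L)
  cnt[root_i] <- 1L

  t <- 0
  while (t < max_time && length(alive) > 0) {
    age <- max_time - t
    # per-lineage rate bound: lambda(age') for age' in (0, age] is maximal
    # at an endpoint of the interval
    bA <- max(lamA_at(age), lamA_at(0))
    bB <- max(lamB_at(age), lamB_at(0))
    nA <- cnt[1L]; nB <- cnt[2L]; nW <- cnt[3L]
    R_bound <- nA * (bA + xA + dA) + nB * (bB + xB + dB) +
      nW * (bA + bB + sAB + xA + xB)
    if (R_bound <= 0) break
    t <- t + rexp(1, R_bound)
    if (t >= max_time) break
    age <- max_time - t
    lamA <- lamA_at(age); lamB <- lamB_at(age)
    # instantaneous category rates at the candidate event time
    rates <- c(A_spec = nA * lamA, A_ext = nA * xA, A_disp = nA * dA,
               B_spec = nB * lamB, B_ext = nB * xB, B_disp = nB * dB,
               W_specA = nW * lamA, W_specB = nW * lamB,
               W_div = nW * sAB, W_conA = nW * xA, W_conB = nW * xB)
    R <- sum(rates)
    if (tv && runif(1) > R / R_bound) next  # thinning rejection
    ev <- sample.int(11L, 1L, prob = rates)
    cat_state <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L)[ev]
    cand <- alive[state[alive] == cat_state]
    lin <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]

    if (ev %in% c(1L, 4L, 7L, 8L, 9L)) {
      # cladogenesis: close lineage, open two daughters
      daughters <- switch(as.character(ev),
                          "1" = c(1L, 1L), "4" = c(2L, 2L),
                          "7" = c(1L, 3L), "8" = c(2L, 3L),
                          "9" = c(1L, 2L))
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(birth) <- cap; length(end) <- cap
        length(state) <- cap; length(kind) <- cap
      }
      end[lin] <- t; kind[lin] <- 1L
      ids <- n_lin + 1:2
      parent[ids] <- lin; birth[ids] <- t; state[ids] <- daughters
      kind[ids] <- 0L
      n_lin <- n_lin + 2L
      alive <- c(setdiff(alive, lin), ids)
      cnt[cat_state] <- cnt[cat_state] - 1L
      cnt[daughters[1]] <- cnt[daughters[1]] + 1L
      cnt[daughters[2]] <- cnt[daughters[2]] + 1L
    } else if (ev %in% c(2L, 5L)) {
      end[lin] <- t; kind[lin] <- 2L
      alive <- setdiff(alive, lin)
      cnt[cat_state] <- cnt[cat_state] - 1L
    } else {
      new_state <- c(3L, 3L, 2L, 1L)[match(ev, c(3L, 6L, 10L, 11L))]
      state[lin] <- new_state   # range expansion or contraction
      cnt[cat_state] <- cnt[cat_state] - 1L
      cnt[new_state] <- cnt[new_state] + 1L
    }
  }
  if (length(alive) > 0) { end[alive] <- max_time; kind[alive] <- 3L }
  idx <- seq_len(n_lin)
  extant <- idx[kind[idx] == 3L]
  if (!build_tree || kind[1] != 1L || length(extant) < 2L)
    return(list(tree = NULL, tip_state = state[extant],
                n_extant = length(extant)))
  tips <- idx[kind[idx] %in% c(2L, 3L)]
  internals <- idx[kind[idx] == 1L]
  internals <- internals[order(end[internals])]  # root (earliest) first
  n_tip <- length(tips)
  node_id <- integer(n_lin)
  node_id[tips] <- seq_len(n_tip)
  node_id[internals] <- n_tip + seq_along(internals)
  children <- idx[-1]
  edge <- cbind(node_id[parent[children]], node_id[children])
  tree <- list(edge = edge,
               edge.length = end[children] - birth[children],
               tip.label = paste0("sp", seq_len(n_tip)),
               Nnode = length(internals))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  extinct <- tree$tip.label[which(kind[tips] == 2L)]
  if (length(extinct) > 0) {
    keep_map <- which(kind[tips] == 3L)
    tree2 <- ape::drop.tip(tree, extinct)
    st <- state[tips[keep_map]][match(tree2$tip.label,
                                      tree$tip.label[keep_map])]
    tree <- tree2
  } else {
    st <- state[tips]
  }
  tree$root.edge <- NULL
  list(tree = tree, tip_state = st, n_extant = length(extant))
}

#' Registry of documented simulation scenarios
#'
#' Parameter sets (events/lineage/Myr) used by [make_fixture()]:
#' \describe{
#'   \item{out_of_tropics}{higher tropical speciation, lower tropical
#'     extinction, more range expansion out of the tropics -- the regime
#'     supported for the global mammal phylogeny.}
#'   \item{equal_rates}{biome has no effect (character-independent).}
#'   \item{temperate_cradle}{both speciation and extinction higher in
#'     temperate regions (high-latitude turnover, Carnivora-like).}
#'   \item{time_increasing}{out-of-tropics regime with within-biome
#'     speciation increasing through time toward the present (negative
#'     slopes in the age parameterization lambda(t) = lambda_0 + r t).}
#' }
#'
#' @param scenario scenario name.
#' @param target_tips demanded number of sampled tips (default 500). The
#'   simulation stop time is rescaled by the scenario's dominant net
#'   diversification rate so the expected tree size tracks the demand,
#'   keeping size-band rejection cheap.
#' @return list: params, root_state, max_time, sampling, target_tips.
#' @export
scenario_config <- function(scenario = c("out_of_tropics", "equal_rates",
                                         "temperate_cradle",
                                         "time_increasing"),
                            target_tips = 500) {
  scenario <- match.arg(scenario)
  stopifnot(target_tips >= 20)
  # sampling fractions mirror a nearly complete supertree
  f <- sampling_fractions(0.84, 0.83, 0.85)
  cfg <- switch(scenario,
    out_of_tropics = list(
      params = geosse_params(0.2, 0.4, 0.08, 0.12, 0.04, 0.04, 0.12),
      root_state = "TROPICAL", max_time = 17.5, sampling = f,
      target_tips = 500),
    equal_rates = list(
      params = geosse_params(0.25, 0.25, 0, 0.1, 0.1, 0.05, 0.05),
      root_state = "TROPICAL", max_time = 42, sampling = f,
      target_tips = 500),
    temperate_cradle = list(
      params = geosse_params(0.4, 0.25, 0.05, 0.25, 0.1, 0.05, 0.05),
      root_state = "TEMPERATE", max_time = 40, sampling = f,
      target_tips = 500),
    time_increasing = list(
      params = time_varying_params(0.25, 0.45, -0.006, -0.01, 0.08,
                                   0.12, 0.04, 0.04, 0.12),
      root_state = "TROPICAL", max_time = 17, sampling = f,
      target_tips = 500))
  # dominant net diversification rate, for stop-time rescaling
  r_dom <- switch(scenario, out_of_tropics = 0.36, equal_rates = 0.15,
                  temperate_cradle = 0.15, time_increasing = 0.35)
  if (target_tips != 500) {
    cfg$max_time <- cfg$max_time - log(500 / target_tips) / r_dom
    stopifnot(cfg$max_time > 0)
    cfg$target_tips <- target_tips
  }
  cfg
}

#' Write a bundled synthetic dataset to disk
#'
#' Simulates one dataset under a named scenario and writes a Newick tree,
#' a biome state CSV, and a truth-record JSON, byte-identically for a
#' given seed.
#'
#' @param scenario one of the [scenario_config()] names.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param target_tips optional override of the scenario's target size.
#' @param tip_tol acceptance band half-width (see [simulate_geosse()]).
#' @return invisible list of written paths plus the simulation object.
#' @export
make_fixture <- function(scenario, seed, dir, target_tips = NULL,
                         tip_tol = 0.4) {
  # route the demanded size through the scenario sizing so the stop
  # time tracks it (otherwise the size band rejects almost every run)
  cfg <- scenario_config(scenario, target_tips = target_tips %||% 500)
  sim <- simulate_geosse(cfg$params, cfg$max_time,
                         root_state = cfg$root_state,
                         sampling = cfg$sampling,
                         target_tips = cfg$target_tips, tip_tol = tip_tol,
                         seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = file.path(dir, paste0(scenario, "_tree.nwk")),
                states = file.path(dir, paste0(scenario, "_states.csv")),
                truth = file.path(dir, paste0(scenario, "_truth.json")))
  write_newick(sim$tree, paths$tree)
  write.csv(sim$states, paths$states, row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$params <- as.list(unclass(truth$params))
  truth$scenario <- scenario
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(sim = sim)))
}
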