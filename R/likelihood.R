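#' Per-lineage likelihood state
#'
#' The pruning variables of the state-dependent birth-death likelihood:
#' `D_*` are probability densities of the observed subtree given the
#' lineage occupies each biome state, `E_*` the probabilities that a
#' lineage in each state leaves no sampled descendant at the present.
#' `log_comp` is a running log-scaling factor protecting the D values
#' from underflow; the effective density is `D * exp(log_comp)`.
#'
#' @param D_temp,D_trop,D_wide subtree densities (>= 0).
#' @param E_temp,E_trop,E_wide extinction probabilities in `[0, 1]`.
#' @param log_comp accumulated log-scaling factor.
#' @return object of class `likelihood_state`.
#' @export
likelihood_state <- function(D_temp = 0, D_trop = 0, D_wide = 0,
                             E_temp = 0, E_trop = 0, E_wide = 0,
                             log_comp = 0) {
  E <- c(E_temp, E_trop, E_wide)
  D <- c(D_temp, D_trop, D_wide)
  if (any(E < 0) || any(E > 1)) stop("E values must lie in [0, 1]")
  if (any(D < 0)) stop("D values must be >= 0")
  structure(list(D = setNames(D, BIOME_STATES),
                 E = setNames(E, BIOME_STATES),
                 log_comp = log_comp),
            class = "likelihood_state")
}

#' Initial likelihood state at a sampled tip
#'
#' The sampling fraction of the observed state enters directly: the D of
#' the observed state is `f_state`, other D are 0, and every E starts at
#' `1 - f` for its state (the probability that an extant lineage of that
#' state was not sampled).
#'
#' @param state one of TEMPERATE, TROPICAL, WIDESPREAD.
#' @param f a [sampling_fractions()] object.
#' @return a [likelihood_state()].
#' @export
tip_init <- function(state, f = sampling_fractions()) {
  i <- state_index(state)
  D <- c(0, 0, 0)
  D[i] <- as.numeric(f)[i]
  likelihood_state(D[1], D[2], D[3],
                   1 - f[[1]], 1 - f[[2]], 1 - f[[3]])
}

#' Propagate a likelihood state along a branch
#'
#' Numerically integrates the six coupled GeoSSE ODEs backward in time
#' from the younger to the older end of a branch, using an adaptive
#' Runge-Kutta scheme. The `log_comp` factor passes through unchanged;
#' rescaling is applied per branch inside [geosse_loglik()].
#'
#' @param params a [geosse_params()] or [time_varying_params()].
#' @param state0 the [likelihood_state()] at the younger end.
#' @param t_young,t_old branch endpoint ages in Myr (present = 0,
#'   `t_old > t_young >= 0`).
#' @param rtol,atol relative and absolute integration tolerances.
#' @return the [likelihood_state()] at the older end.
#' @export
propagate_branch <- function(params, state0, t_young, t_old,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state0, "likelihood_state"),
            t_young >= 0, t_old >= t_young)
  p <- as_rate_vector(params)
  check_tv_positive(p, t_old)
  y0 <- c(state0$E, state0$D)
  y <- geosse_branch_cpp(y0, t_young, t_old, p, rtol, atol)
  likelihood_state(y[4], y[5], y[6],
                   min(max(y[1], 0), 1), min(max(y[2], 0), 1),
                   min(max(y[3], 0), 1),
                   log_comp = state0$log_comp)
}

check_tv_positive <- function(p, t_max) {
  # lambda(t) = lambda0 + slope * t must be >= 0 on [0, t_max]
  if (p[1] + p[8] * t_max < 0 || p[2] + p[9] * t_max < 0)
    stop("negative time-varying speciation rate within [0, ", t_max, "]",
         call. = FALSE)
  invisible(TRUE)
}

#' Combine the likelihood states of two daughter lineages at a node
#'
#' Endemic states multiply the daughters' D by the within-biome
#' speciation rate. The widespread state sums the three cladogenetic
#' modes -- within-temperate (daughters TEMPERATE + WIDESPREAD),
#' within-tropical (TROPICAL + WIDESPREAD), and biome divergence
#' (TEMPERATE + TROPICAL) -- each symmetrized over the left/right
#' daughter assignment with a factor 1/2.
#'
#' @param params a [geosse_params()] or [time_varying_params()].
#' @param left,right daughter [likelihood_state()]s, both propagated to
#'   the node age.
#' @param node_age node age in Myr (used to evaluate time-varying
#'   speciation rates).
#' @return the [likelihood_state()] of the parent lineage at the node.
#' @export
combine_at_node <- function(params, left, right, node_age = 0) {
  stopifnot(inherits(left, "likelihood_state"),
            inherits(right, "likelihood_state"))
  p <- as_rate_vector(params)
  lamA <- p[1] + p[8] * node_age
  lamB <- p[2] + p[9] * node_age
  sAB <- p[3]
  Dl <- left$D; Dr <- right$D
  D <- c(lamA * Dl[1] * Dr[1],
         lamB * Dl[2] * Dr[2],
         0.5 * (lamA * (Dl[1] * Dr[3] + Dl[3] * Dr[1]) +
                lamB * (Dl[2] * Dr[3] + Dl[3] * Dr[2]) +
                sAB * (Dl[1] * Dr[2] + Dl[2] * Dr[1])))
  likelihood_state(D[1], D[2], D[3],
                   left$E[1], left$E[2], left$E[3],
                   log_comp = left$log_comp + right$log_comp)
}

#' Root treatment options for the likelihood
#'
#' @param root_mode how the three root-state D values are combined:
#'   `"likelihood-weighted"` (default) weights each state by its relative
#'   D value, `"equal-weights"` averages them, `"fixed-state"` uses
#'   `root_state` only. The data themselves do not determine this choice;
#'   the default matches common practice for state-dependent
#'   diversification software.
#' @param condition_on_survival divide by the probability that a root
#'   lineage in each state speciates and leaves two surviving sampled
#'   clades (weighted `lambda * (1 - E_root)^2`); default `TRUE`.
#' @param root_state required when `root_mode = "fixed-state"`.
#' @return object of class `root_options`.
#' @export
root_options <- function(root_mode = c("likelihood-weighted",
                                       "equal-weights", "fixed-state"),
                         condition_on_survival = TRUE, root_state = NULL) {
  root_mode <- match.arg(root_mode)
  if (root_mode == "fixed-state") {
    if (is.null(root_state)) stop("fixed-state root requires root_state")
    root_state <- BIOME_STATES[state_index(root_state)]
  }
  structure(list(root_mode = root_mode,
                 condition_on_survival = condition_on_survival,
                 root_state = root_state),
            class = "root_options")
}

#' GeoSSE log-likelihood of a tree and tip biome states
#'
#' Post-order pruning over the phylogeny: tip initialisation with
#' state-specific sampling fractions, ODE propagation along each branch,
#' cladogenetic combination at each node, and the chosen root treatment.
#' Time-varying speciation rates are evaluated at absolute ages (t = 0 at
#' present), both inside branch ODEs and at node combinations. Invalid
#' time-varying parameters (negative `lambda(t)` anywhere on the tree)
#' yield `-Inf` rather than clamping.
#'
#' @param tree a validated ultrametric [ape::phylo].
#' @param states data.frame (species, state) matched to the tips.
#' @param params a [geosse_params()] or [time_varying_params()].
#' @param f a [sampling_fractions()] object (entries in `[0, 1]`; a state
#'   observed at a tip with sampling fraction 0 makes the data
#'   impossible, giving `-Inf`).
#' @param root a [root_options()] object.
#' @param rtol,atol ODE integration tolerances.
#' @return the log-likelihood (finite or `-Inf`).
#' @export
geosse_loglik <- function(tree, states, params, f = sampling_fractions(),
                          root = root_options(), rtol = 1e-8,
                          atol = 1e-10) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- ape::Ntip(tree)
  if (is.data.frame(states)) {
    i <- match(tree$tip.label, states$species)
    if (anyNA(i))
      stop("tips without a biome state: ",
           paste(tree$tip.label[is.na(i)], collapse = ", "),
           " (use match_tree_and_states first)")
    st <- state_index(states$state[i])
  } else if (length(states) == n_tip) {
    st <- state_index(states[tree$tip.label] %||% states)
  } else stop("states must be a data.frame (species, state)")

  p <- as_rate_vector(params)
  fv <- as.numeric(f)
  if (any(fv < 0) || any(fv > 1)) stop("sampling fractions must lie in [0, 1]")

  ages <- node_ages(tree)
  height <- max(ages)
  # hard positivity constraint on time-varying speciation rates
  if (p[1] + p[8] * height < 0 || p[2] + p[9] * height < 0 ||
      p[1] < 0 || p[2] < 0)
    return(-Inf)

  tr <- ape::reorder.phylo(tree, "postorder")
  mode <- match(root$root_mode,
                c("likelihood-weighted", "equal-weights", "fixed-state")) - 1L
  rs <- if (mode == 2L) state_index(root$root_state) - 1L else 0L
  ll <- geosse_loglik_cpp(tr$edge, n_tip, ages, as.integer(st - 1L), fv, p,
                          mode, rs, isTRUE(root$condition_on_survival),
                          rtol, atol)
  ll
}
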