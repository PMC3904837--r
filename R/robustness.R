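#' Dispersal-ratio grid
#'
#' The grid covers rho = d_temp/d_trop from 0 to +Inf uniformly in
#' u = rho / (1 + rho) on `[0, 1]`, which is symmetric under
#' rho <-> 1/rho; the endpoints map to the one-way-dispersal submodels
#' and u = 0.5 (rho = 1, symmetric range expansion) is forced onto the
#' grid.
#'
#' @param n_grid number of grid values (default 150).
#' @return numeric vector of ratios, strictly increasing, containing 1.
#' @export
dispersal_ratio_grid <- function(n_grid = 150) {
  stopifnot(n_grid >= 3)
  u <- seq(0, 1, length.out = n_grid)
  u[which.min(abs(u - 0.5))] <- 0.5
  u <- sort(unique(u))
  u / (1 - u)  # u = 1 -> Inf
}

#' Robustness sweep over the dispersal ratio
#'
#' Refits the model across a grid of fixed ratios rho = d_temp/d_trop
#' (with a single free dispersal scale replacing the dispersal
#' constraint of `spec`), and records for each rho whether the sign of
#' the fitted net-diversification difference `r_trop - r_temp` matches
#' the baseline sign at rho = 1. Fits sweep outward from rho = 1,
#' warm-starting each fit from its neighbour's optimum (the profile
#' likelihood is continuous in rho).
#'
#' @inheritParams fit_ml
#' @param n_grid grid size (default 150).
#' @param starts optimizer starts per grid point (warm start counts as
#'   the first).
#' @return object of class `dispersal_sweep`: data.frame (rho, lnL,
#'   parameter estimates, r_diff, conserved, converged) plus baseline
#'   attributes.
#' @export
sweep_dispersal_ratio <- function(tree, states, f, spec, n_grid = 150,
                                  starts = 1, seed = NULL,
                                  root = root_options(), ...) {
  if (!is.null(spec$dispersal_ratio))
    stop("spec already carries a dispersal-ratio constraint")
  rhos <- dispersal_ratio_grid(n_grid)
  i0 <- which(rhos == 1)

  fit_at <- function(rho, init) {
    sp <- spec
    sp$dispersal_ratio <- rho
    sp$dispersal_equal <- FALSE
    tryCatch(fit_ml(tree, states, f, sp, starts = starts, seed = seed,
                    root = root, init = init, ...),
             error = function(e) NULL)
  }

  fits <- vector("list", length(rhos))
  fits[[i0]] <- fit_at(1, NULL)
  if (is.null(fits[[i0]])) stop("baseline fit at rho = 1 failed")
  # outward warm-started sweep
  if (i0 < length(rhos))
    for (i in (i0 + 1):length(rhos))
      fits[[i]] <- fit_at(rhos[i], fits[[i - 1]]$free %||% NULL)
  if (i0 > 1)
    for (i in (i0 - 1):1)
      fits[[i]] <- fit_at(rhos[i], fits[[i + 1]]$free %||% NULL)

  base_diff <- fits[[i0]]$r_trop - fits[[i0]]$r_temp
  if (base_diff == 0)
    stop("baseline net-diversification difference is exactly 0; trend undefined")
  base_sign <- sign(base_diff)

  rows <- lapply(seq_along(rhos), function(i) {
    ft <- fits[[i]]
    if (is.null(ft)) {
      warning("fit failed at rho = ", signif(rhos[i], 4),
              "; excluded from the interval computation")
      return(data.frame(rho = rhos[i], lnL = NA_real_, r_temp = NA_real_,
                        r_trop = NA_real_, r_diff = NA_real_,
                        conserved = NA, converged = FALSE))
    }
    d <- ft$r_trop - ft$r_temp
    data.frame(rho = rhos[i], lnL = ft$lnL, r_temp = ft$r_temp,
               r_trop = ft$r_trop, r_diff = d,
               conserved = sign(d) == base_sign, converged = ft$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- fits[[i0]]
  attr(out, "base_sign") <- base_sign
  attr(out, "spec") <- spec
  class(out) <- c("dispersal_sweep", "data.frame")
  out
}

#' Trend-conservation interval of a dispersal sweep
#'
#' The largest contiguous grid interval containing rho = 1 on which the
#' baseline sign of `r_trop - r_temp` is conserved. Endpoints are
#' reported as grid values; 0 and `Inf` mean conservation extends to the
#' one-way-dispersal limits.
#'
#' @param sweep a `dispersal_sweep`.
#' @return named numeric `c(rho_min, rho_max)`.
#' @export
trend_interval <- function(sweep) {
  stopifnot(inherits(sweep, "dispersal_sweep"))
  ok <- sweep$conserved
  i0 <- which(sweep$rho == 1)
  if (length(i0) != 1 || is.na(ok[i0]) || !ok[i0])
    stop("baseline rho = 1 point missing or not conserved")
  lo <- i0
  while (lo > 1 && isTRUE(ok[lo - 1])) lo <- lo - 1
  hi <- i0
  while (hi < length(ok) && isTRUE(ok[hi + 1])) hi <- hi + 1
  c(rho_min = sweep$rho[lo], rho_max = sweep$rho[hi])
}
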