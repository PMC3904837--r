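#' GeoSSE parameter set
#'
#' The seven rates of the two-biome geographic state speciation-extinction
#' process, all in events/lineage/Myr. Naming convention for dispersal
#' (important, because the meaning of the d_temp/d_trop ratio flips if
#' misread): `d_temp` is the rate of range expansion of a *temperate*
#' endemic into the tropics (temperate -> widespread), and `d_trop` the
#' rate of expansion of a tropical endemic into temperate regions
#' (tropical -> widespread). Rates are source-labelled.
#'
#' @param lambda_temp,lambda_trop within-biome speciation rates.
#' @param lambda_tt biome-divergence speciation rate (a widespread
#'   lineage splitting into one temperate and one tropical endemic).
#' @param mu_temp,mu_trop extinction rates of endemics, equal to the
#'   range-contraction rates of widespread lineages in each biome.
#' @param d_temp,d_trop range-expansion rates (see above).
#' @return object of class `geosse_params` (named numeric of length 7).
#' @export
geosse_params <- function(lambda_temp, lambda_trop, lambda_tt,
                          mu_temp, mu_trop, d_temp, d_trop) {
  p <- c(lambda_temp = lambda_temp, lambda_trop = lambda_trop,
         lambda_tt = lambda_tt, mu_temp = mu_temp, mu_trop = mu_trop,
         d_temp = d_temp, d_trop = d_trop)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all seven rates must be finite and >= 0")
  structure(p, class = "geosse_params")
}

#' Time-varying GeoSSE parameter set
#'
#' Within-biome speciation rates vary linearly with time,
#' `lambda(t) = lambda_0 + slope * t`, where `lambda_0` is the rate at
#' present and t is measured in Myr from the present into the past.
#' Extinction, dispersal and biome-divergence speciation are constant.
#' Negative slopes mean speciation *increasing* through time toward the
#' present. `lambda(t)` must stay nonnegative over the tree height; the
#' likelihood returns `-Inf` otherwise.
#'
#' @param lambda0_temp,lambda0_trop speciation rates at present.
#' @param slope_temp,slope_trop linear slopes (events/lineage/Myr per
#'   Myr); may be negative.
#' @inheritParams geosse_params
#' @return object of class `tv_geosse_params` (named numeric, length 9).
#' @export
time_varying_params <- function(lambda0_temp, lambda0_trop,
                                slope_temp, slope_trop, lambda_tt,
                                mu_temp, mu_trop, d_temp, d_trop) {
  p <- c(lambda_temp = lambda0_temp, lambda_trop = lambda0_trop,
         lambda_tt = lambda_tt, mu_temp = mu_temp, mu_trop = mu_trop,
         d_temp = d_temp, d_trop = d_trop,
         slope_temp = slope_temp, slope_trop = slope_trop)
  rates <- p[1:7]
  if (any(!is.finite(p)) || any(rates < 0))
    stop("rates must be finite and >= 0 (slopes may be negative)")
  structure(p, class = "tv_geosse_params")
}

## 9-vector for the compiled core: sA,sB,sAB,xA,xB,dA,dB,rA,rB
as_rate_vector <- function(params) {
  v <- unclass(params)
  if (inherits(params, "tv_geosse_params")) {
    c(v[["lambda_temp"]], v[["lambda_trop"]], v[["lambda_tt"]],
      v[["mu_temp"]], v[["mu_trop"]], v[["d_temp"]], v[["d_trop"]],
      v[["slope_temp"]], v[["slope_trop"]])
  } else if (inherits(params, "geosse_params")) {
    c(v, 0, 0)
  } else stop("params must be geosse_params or tv_geosse_params")
}

#' Define one diversification scenario (constraint pattern)
#'
#' A model spec is a pattern of equality/zero constraints on the seven
#' GeoSSE rates. The full model space crosses presence/absence of
#' biome-divergence speciation, equal vs free dispersal, and the four
#' lambda/mu equality patterns, giving 16 scenarios.
#'
#' @param biome_divergence if `FALSE`, `lambda_tt` is fixed at 0.
#' @param speciation_equal constrain `lambda_temp == lambda_trop`.
#' @param extinction_equal constrain `mu_temp == mu_trop`.
#' @param dispersal_equal constrain `d_temp == d_trop`.
#' @param time_varying add linear time dependence of the within-biome
#'   speciation rates (slopes follow the speciation equality pattern).
#' @param dispersal_ratio optional fixed ratio rho = d_temp/d_trop with a
#'   single free dispersal scale; used by the robustness sweep. `0` and
#'   `Inf` are the one-way-dispersal limits. Overrides
#'   `dispersal_equal`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(biome_divergence = TRUE, speciation_equal = FALSE,
                       extinction_equal = FALSE, dispersal_equal = FALSE,
                       time_varying = FALSE, dispersal_ratio = NULL) {
  if (!is.null(dispersal_ratio)) {
    stopifnot(length(dispersal_ratio) == 1, dispersal_ratio >= 0)
    dispersal_equal <- FALSE
  }
  structure(list(biome_divergence = biome_divergence,
                 speciation_equal = speciation_equal,
                 extinction_equal = extinction_equal,
                 dispersal_equal = dispersal_equal,
                 time_varying = time_varying,
                 dispersal_ratio = dispersal_ratio),
            class = "model_spec")
}

## names of the free parameters, in packing order
free_names <- function(spec) {
  nm <- if (spec$speciation_equal) "lambda" else
    c("lambda_temp", "lambda_trop")
  if (spec$biome_divergence) nm <- c(nm, "lambda_tt")
  nm <- c(nm, if (spec$extinction_equal) "mu" else c("mu_temp", "mu_trop"))
  nm <- c(nm, if (!is.null(spec$dispersal_ratio)) "d_scale"
          else if (spec$dispersal_equal) "d"
          else c("d_temp", "d_trop"))
  if (spec$time_varying)
    nm <- c(nm, if (spec$speciation_equal) "slope"
            else c("slope_temp", "slope_trop"))
  nm
}

#' Number of free parameters of a model spec
#' @param spec a [model_spec()].
#' @export
n_free <- function(spec) length(free_names(spec))

#' Short label for a model spec
#' @param spec a [model_spec()].
#' @export
model_label <- function(spec) {
  paste0(if (spec$biome_divergence) "lTT+" else "lTT0",
         " ", if (spec$speciation_equal) "lEq" else "lFree",
         " ", if (spec$extinction_equal) "mEq" else "mFree",
         " ", if (!is.null(spec$dispersal_ratio))
           sprintf("dRatio=%g", spec$dispersal_ratio)
         else if (spec$dispersal_equal) "dEq" else "dFree",
         if (spec$time_varying) " tv" else "")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", model_label(x), sprintf("(k = %d)\n", n_free(x)))
  invisible(x)
}

#' Enumerate the diversification model space
#'
#' Without dispersal constraint this is the full set of 16 scenarios:
#' 2 (biome divergence present/absent) x 2 (dispersal equal/free) x
#' 4 (lambda/mu equality patterns). With `constrain_dispersal = TRUE`
#' only the 8 scenarios with equal range-expansion rates are returned,
#' the reduced set used for small phylogenies.
#'
#' @param constrain_dispersal restrict to `d_temp == d_trop`.
#' @param time_varying generate time-varying variants instead of
#'   time-constant ones (normally applied only to the best time-constant
#'   structure, not crossed with the whole space).
#' @return list of [model_spec()] objects, deterministic in order.
#' @export
enumerate_models <- function(constrain_dispersal = FALSE,
                             time_varying = FALSE) {
  specs <- list()
  for (bd in c(TRUE, FALSE))
    for (de in if (constrain_dispersal) TRUE else c(FALSE, TRUE))
      for (se in c(FALSE, TRUE))
        for (ee in c(FALSE, TRUE))
          specs[[length(specs) + 1]] <-
            model_spec(biome_divergence = bd, speciation_equal = se,
                       extinction_equal = ee, dispersal_equal = de,
                       time_varying = time_varying)
  specs
}

#' Expand a free-parameter vector into a full GeoSSE parameter set
#'
#' @param spec a [model_spec()].
#' @param free numeric vector of length [n_free()] (rates >= 0; slopes
#'   sign-free).
#' @return [geosse_params()] or [time_varying_params()].
#' @export
unpack_params <- function(spec, free) {
  nm <- free_names(spec)
  if (length(free) != length(nm))
    stop("free vector has length ", length(free), ", expected ",
         length(nm))
  free <- setNames(as.numeric(free), nm)
  rate_nm <- setdiff(nm, c("slope", "slope_temp", "slope_trop"))
  if (any(free[rate_nm] < 0)) stop("rate entries must be >= 0")

  lt <- if (spec$speciation_equal) free[["lambda"]] else free[["lambda_temp"]]
  lr <- if (spec$speciation_equal) free[["lambda"]] else free[["lambda_trop"]]
  ltt <- if (spec$biome_divergence) free[["lambda_tt"]] else 0
  mt <- if (spec$extinction_equal) free[["mu"]] else free[["mu_temp"]]
  mr <- if (spec$extinction_equal) free[["mu"]] else free[["mu_trop"]]
  if (!is.null(spec$dispersal_ratio)) {
    rho <- spec$dispersal_ratio
    s <- free[["d_scale"]]
    if (is.infinite(rho)) { dt <- s; dr <- 0 }
    else { dr <- s; dt <- rho * s }
  } else if (spec$dispersal_equal) {
    dt <- dr <- free[["d"]]
  } else {
    dt <- free[["d_temp"]]; dr <- free[["d_trop"]]
  }
  if (spec$time_varying) {
    st <- if (spec$speciation_equal) free[["slope"]] else free[["slope_temp"]]
    sr <- if (spec$speciation_equal) free[["slope"]] else free[["slope_trop"]]
    time_varying_params(lt, lr, st, sr, ltt, mt, mr, dt, dr)
  } else {
    geosse_params(lt, lr, ltt, mt, mr, dt, dr)
  }
}

#' Collapse a full parameter set into a spec's free-parameter vector
#'
#' Inverse of [unpack_params()]; errors if the parameter set violates the
#' spec's constraints.
#'
#' @param spec a [model_spec()].
#' @param params a [geosse_params()] or [time_varying_params()].
#' @param tol tolerance for checking equality constraints.
#' @export
pack_params <- function(spec, params, tol = 1e-10) {
  v <- unclass(params)
  chk <- function(ok, what) if (!ok) stop("parameters violate spec: ", what)
  out <- c()
  if (spec$speciation_equal) {
    chk(abs(v[["lambda_temp"]] - v[["lambda_trop"]]) <= tol,
        "lambda_temp != lambda_trop")
    out <- c(out, lambda = v[["lambda_temp"]])
  } else out <- c(out, lambda_temp = v[["lambda_temp"]],
                  lambda_trop = v[["lambda_trop"]])
  if (spec$biome_divergence) out <- c(out, lambda_tt = v[["lambda_tt"]])
  else chk(v[["lambda_tt"]] <= tol, "lambda_tt != 0")
  if (spec$extinction_equal) {
    chk(abs(v[["mu_temp"]] - v[["mu_trop"]]) <= tol, "mu_temp != mu_trop")
    out <- c(out, mu = v[["mu_temp"]])
  } else out <- c(out, mu_temp = v[["mu_temp"]], mu_trop = v[["mu_trop"]])
  if (!is.null(spec$dispersal_ratio)) {
    rho <- spec$dispersal_ratio
    if (is.infinite(rho)) {
      chk(v[["d_trop"]] <= tol, "d_trop != 0 under rho = Inf")
      out <- c(out, d_scale = v[["d_temp"]])
    } else {
      chk(abs(v[["d_temp"]] - rho * v[["d_trop"]]) <= tol * max(1, rho),
          "d_temp != rho * d_trop")
      out <- c(out, d_scale = v[["d_trop"]])
    }
  } else if (spec$dispersal_equal) {
    chk(abs(v[["d_temp"]] - v[["d_trop"]]) <= tol, "d_temp != d_trop")
    out <- c(out, d = v[["d_temp"]])
  } else out <- c(out, d_temp = v[["d_temp"]], d_trop = v[["d_trop"]])
  if (spec$time_varying) {
    if (!inherits(params, "tv_geosse_params"))
      stop("time-varying spec requires tv_geosse_params")
    if (spec$speciation_equal) {
      chk(abs(v[["slope_temp"]] - v[["slope_trop"]]) <= tol,
          "slope_temp != slope_trop")
      out <- c(out, slope = v[["slope_temp"]])
    } else out <- c(out, slope_temp = v[["slope_temp"]],
                    slope_trop = v[["slope_trop"]])
  } else if (inherits(params, "tv_geosse_params")) {
    chk(abs(v[["slope_temp"]]) <= tol && abs(v[["slope_trop"]]) <= tol,
        "nonzero slopes for a time-constant spec")
  }
  out
}

#' Net diversification rates from a parameter set
#'
#' r = lambda - mu within each biome (speciation minus extinction);
#' for time-varying parameters the rate at present is used.
#'
#' @param params a [geosse_params()] or [time_varying_params()].
#' @return named numeric: r_temp, r_trop.
#' @export
net_diversification <- function(params) {
  v <- unclass(params)
  c(r_temp = v[["lambda_temp"]] - v[["mu_temp"]],
    r_trop = v[["lambda_trop"]] - v[["mu_trop"]])
}
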