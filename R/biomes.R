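#' Classify latitudinal ranges into biome states
#'
#' A species is TROPICAL if its latitudinal range lies within the tropic
#' lines at +/- `threshold` degrees, TEMPERATE if the range lies entirely
#' poleward of them, and WIDESPREAD if it straddles a tropic line.
#' Boundary convention (the measure-zero ties): a range with
#' `min_lat == threshold` (or `max_lat == -threshold`) counts as
#' TEMPERATE; a range merely touching a tropic line from inside counts as
#' TROPICAL.
#'
#' @param min_lat,max_lat numeric vectors of range limits in degrees,
#'   with `-90 <= min_lat <= max_lat <= 90`.
#' @param threshold positive tropic latitude in degrees (default 23.4,
#'   the tropic lines).
#' @return character vector of states.
#' @examples
#' classify_biome(-10, 15)      # TROPICAL
#' classify_biome(30, 50)       # TEMPERATE
#' classify_biome(10, 40)       # WIDESPREAD
#' @export
classify_biome <- function(min_lat, max_lat, threshold = 23.4) {
  stopifnot(length(threshold) == 1, threshold > 0)
  tab <- data.frame(species = seq_along(min_lat),
                    min_lat = min_lat, max_lat = max_lat)
  check_latitude_ranges(tab)
  # TEMPERATE checked first so degenerate ranges sitting exactly on a
  # tropic line resolve as temperate (closed-boundary convention)
  temperate <- min_lat >= threshold | max_lat <= -threshold
  tropical <- !temperate & min_lat >= -threshold & max_lat <= threshold
  ifelse(temperate, "TEMPERATE", ifelse(tropical, "TROPICAL", "WIDESPREAD"))
}

#' Classify a species latitude table into a biome state table
#'
#' @param latitudes data.frame with columns species, min_lat, max_lat
#'   (as returned by [read_state_table()] with the latitudes schema).
#' @inheritParams classify_biome
#' @return data.frame with columns species, state.
#' @export
classify_species <- function(latitudes, threshold = 23.4) {
  stopifnot(is.data.frame(latitudes),
            all(c("species", "min_lat", "max_lat") %in% names(latitudes)))
  data.frame(species = latitudes$species,
             state = classify_biome(latitudes$min_lat, latitudes$max_lat,
                                    threshold = threshold),
             stringsAsFactors = FALSE)
}

#' Sampling fractions per biome state
#'
#' Probabilities that an extant species of each state appears in the
#' phylogeny; they enter the likelihood through the tip initial
#' conditions.
#'
#' @param f_temp,f_trop,f_wide probabilities in (0, 1].
#' @return an object of class `sampling_fractions`: numeric vector
#'   (f_temp, f_trop, f_wide).
#' @export
sampling_fractions <- function(f_temp = 1, f_trop = 1, f_wide = 1) {
  f <- c(TEMPERATE = f_temp, TROPICAL = f_trop, WIDESPREAD = f_wide)
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    stop("sampling fractions must lie in (0, 1]")
  structure(f, class = "sampling_fractions")
}

#' Estimate sampling fractions from tree counts and described totals
#'
#' `f_state` = (number of tips in the state) / (described species in the
#' state).
#'
#' @param states data.frame with columns species, state (the tips present
#'   in the tree).
#' @param total_described named numeric vector of described species per
#'   state (names TEMPERATE, TROPICAL, WIDESPREAD); states absent from
#'   the tree may be omitted.
#' @return a [sampling_fractions()] object with the counts attached as
#'   attributes `tree_counts` and `described`.
#' @export
estimate_sampling_fractions <- function(states, total_described) {
  stopifnot(is.data.frame(states), "state" %in% names(states))
  counts <- table(factor(states$state, levels = BIOME_STATES))
  described <- setNames(rep(NA_real_, 3), BIOME_STATES)
  described[names(total_described)] <- total_described
  for (s in BIOME_STATES) {
    if (counts[[s]] > 0) {
      if (!is.finite(described[[s]]) || described[[s]] <= 0)
        stop("no described-species total for state ", s,
             " although it appears in the tree")
      if (described[[s]] < counts[[s]])
        stop("described total for ", s, " (", described[[s]],
             ") is below the tip count (", counts[[s]], ")")
    } else if (!is.finite(described[[s]])) {
      described[[s]] <- 1  # state absent from tree; fraction is inert
    }
  }
  f <- pmin(as.numeric(counts) / as.numeric(described), 1)
  f[as.numeric(counts) == 0] <- 1
  out <- sampling_fractions(f[1], f[2], f[3])
  attr(out, "tree_counts") <- as.numeric(counts)
  attr(out, "described") <- as.numeric(described)
  out
}

#' Described-species totals from proportions and a grand total
#'
#' Reproduces the workflow of extrapolating per-state described totals
#' from the proportions observed in a trait database times the total
#' number of described species, rounding half-up.
#'
#' @param proportions named numeric vector (states as names) summing to
#'   ~1.
#' @param grand_total total number of described species.
#' @return named numeric vector of per-state described counts.
#' @examples
#' described_counts_from_proportions(
#'   c(TEMPERATE = 0.25, TROPICAL = 0.52, WIDESPREAD = 0.23), 5416)
#' @export
described_counts_from_proportions <- function(proportions, grand_total) {
  stopifnot(all(names(proportions) %in% BIOME_STATES),
            grand_total > 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 0.01)
    warning("proportions sum to ", sum(proportions), ", not 1")
  floor(proportions * grand_total + 0.5)  # round half-up
}
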