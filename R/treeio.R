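#' Read and validate a dated phylogeny from a Newick file
#'
#' Reads a rooted, strictly binary, ultrametric tree with branch lengths in
#' Myr. Polytomies, missing or non-positive branch lengths, duplicated tip
#' labels, and departures from ultrametricity beyond the tolerance are
#' rejected: trees failing these checks cannot be used by the two-biome
#' diversification likelihood.
#'
#' @param path path to a Newick file (branch lengths required).
#' @param ultrametric_tol relative tolerance on root-to-tip path spread,
#'   as a fraction of tree height. Supertrees are numerically sloppy, so
#'   the default is permissive (1e-3); violations above it are errors (or
#'   warnings, see `on_nonultrametric`), below it are silently accepted.
#' @param on_nonultrametric `"error"` (default) or `"warn"`.
#' @return an [ape::phylo] object that has passed validation.
#' @export
read_newick <- function(path, ultrametric_tol = 1e-3,
                        on_nonultrametric = c("error", "warn")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure in '",
                                            path, "': ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure in '", path, "'")
  validate_phylogeny(tree, ultrametric_tol = ultrametric_tol,
                     on_nonultrametric = match.arg(on_nonultrametric))
}

#' Validate a phylogeny for diversification analysis
#'
#' @param tree an [ape::phylo] object.
#' @inheritParams read_newick
#' @return the tree, invisibly unchanged, if valid.
#' @export
validate_phylogeny <- function(tree, ultrametric_tol = 1e-3,
                               on_nonultrametric = c("error", "warn")) {
  on_nonultrametric <- match.arg(on_nonultrametric)
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (a basal polytomy reads as unrooted)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("all branches must carry a branch length")
  if (!ape::is.binary(tree))
    stop("tree contains polytomies; externally resolved binary trees are required")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0))
    stop("all branch lengths must be positive and finite")
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_len(ape::Ntip(tree))]
  height <- max(tip_depths)
  spread <- (max(tip_depths) - min(tip_depths)) / height
  if (spread > ultrametric_tol) {
    msg <- sprintf(
      "tree is not ultrametric: tip depth spread %.3g x height exceeds tolerance %.3g",
      spread, ultrametric_tol)
    if (on_nonultrametric == "error") stop(msg) else warning(msg)
  }
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @param digits digits for branch lengths (default preserves lengths to
#'   well below the 1e-9 relative round-trip guarantee).
#' @export
write_newick <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured in Myr from the present (t = 0 at the tips)
#' increasing into the past, the time coordinate used throughout.
#'
#' @param tree an [ape::phylo] object.
#' @return numeric vector over all node ids (tips first), in Myr.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(ape::Ntip(tree))])
  ages <- height - depths
  # extant tips sit at the present up to ultrametricity slack
  ages[abs(ages) < 1e-8 * height] <- 0
  ages
}

#' Tree height (root age) in Myr
#' @param tree an [ape::phylo] object.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Read a species table of latitudinal ranges or biome states
#'
#' Delimited text with a header. The `latitudes` schema needs columns
#' `species`, `min_lat`, `max_lat` (degrees); the `states` schema needs
#' `species`, `state` with states in TEMPERATE / TROPICAL / WIDESPREAD.
#'
#' @param path path to a CSV or TSV file.
#' @param schema `"auto"` (detect from columns), `"latitudes"`, or
#'   `"states"`.
#' @return a data.frame: either columns (species, min_lat, max_lat) or
#'   (species, state).
#' @export
read_state_table <- function(path, schema = c("auto", "latitudes", "states")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  if (!"species" %in% names(tab)) stop("missing 'species' column")
  if (schema == "auto") {
    schema <- if (all(c("min_lat", "max_lat") %in% names(tab)))
      "latitudes" else if ("state" %in% names(tab)) "states" else
        stop("cannot detect schema: need (min_lat, max_lat) or (state) columns")
  }
  if (anyDuplicated(tab$species))
    stop("duplicate species entries: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "))
  if (schema == "latitudes") {
    if (!all(c("min_lat", "max_lat") %in% names(tab)))
      stop("latitudes schema requires 'min_lat' and 'max_lat' columns")
    out <- tab[, c("species", "min_lat", "max_lat")]
    out$min_lat <- as.numeric(out$min_lat)
    out$max_lat <- as.numeric(out$max_lat)
    check_latitude_ranges(out)
    out
  } else {
    if (!"state" %in% names(tab))
      stop("states schema requires a 'state' column")
    out <- data.frame(species = tab$species,
                      state = BIOME_STATES[state_index(tab$state)],
                      stringsAsFactors = FALSE)
    out
  }
}

check_latitude_ranges <- function(tab) {
  bad <- !is.finite(tab$min_lat) | !is.finite(tab$max_lat) |
    tab$min_lat < -90 | tab$max_lat > 90 | tab$min_lat > tab$max_lat
  if (any(bad))
    stop("invalid latitudinal range for: ",
         paste(tab$species[bad], collapse = ", "))
  invisible(tab)
}

#' Match a phylogeny with a biome state table
#'
#' Tips without a state are either pruned (`policy = "drop"`, the
#' treatment applied to species lacking latitudinal data) or raise an
#' error. Pruning keeps the tree strictly binary by suppressing degree-2
#' nodes and summing their branch lengths, so root-to-tip depths of
#' retained tips are preserved exactly.
#'
#' @param tree an [ape::phylo] object.
#' @param states data.frame with columns species, state.
#' @param policy `"drop"` or `"error"`.
#' @return list with elements `tree`, `states` (in bijection with the
#'   tips), and `dropped` (character vector of pruned tip labels).
#' @export
match_tree_and_states <- function(tree, states, policy = c("drop", "error")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(states), all(c("species", "state") %in% names(states)))
  unmatched <- setdiff(tree$tip.label, states$species)
  if (length(unmatched) > 0 && policy == "error")
    stop("tips without a biome state: ", paste(unmatched, collapse = ", "))
  if (length(unmatched) > 0) {
    if (ape::Ntip(tree) - length(unmatched) < 2)
      stop("fewer than 2 tips would remain after dropping unmatched tips")
    tree <- ape::drop.tip(tree, unmatched)
  }
  states <- states[match(tree$tip.label, states$species), , drop = FALSE]
  rownames(states) <- NULL
  list(tree = tree, states = states, dropped = unmatched)
}
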