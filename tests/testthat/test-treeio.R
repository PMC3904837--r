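nwk_file <- function(text) {
  path <- tempfile(fileext = ".nwk")
  writeLines(text, path)
  path
}

test_that("valid Newick trees parse with correct structure", {
  tr <- read_newick(nwk_file("((A:1,B:1):1,(C:1.5,D:1.5):0.5);"))
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tree_height(tr), 2.0)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  ages <- node_ages(tr)
  expect_equal(ages[ape::Ntip(tr) + 1], 2.0)  # root age
})

test_that("malformed trees are rejected", {
  expect_error(read_newick(nwk_file("(A:1,B:1,C:1);")), "polytom")
  expect_error(read_newick(nwk_file("((A:1,B:2):1,C:2);"),
                           ultrametric_tol = 1e-6), "ultrametric")
  expect_error(read_newick(nwk_file("((A:1,B):1,C:2);")), "branch length")
  expect_error(read_newick(nwk_file("((A:0,B:0):1,C:1);")), "positive")
  expect_error(read_newick(nwk_file("((A:1,A:1):1,C:2);")), "duplicat")
  expect_error(read_newick(tempfile()), "not found")
})

test_that("near-ultrametric trees pass within tolerance, warn option works", {
  # 0.05% spread: below the default 1e-3 relative tolerance
  p <- nwk_file("((A:1,B:1.001):1,(C:1.5,D:1.5):0.5005);")
  expect_s3_class(read_newick(p), "phylo")
  p2 <- nwk_file("((A:1,B:2):1,C:2);")
  expect_warning(read_newick(p2, ultrametric_tol = 1e-6,
                             on_nonultrametric = "warn"), "ultrametric")
})

test_that("read-write-read round trip preserves topology and lengths", {
  set.seed(5)
  tr <- ape::rcoal(40)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  # label-indexed patristic distances are invariant to node renumbering
  d1 <- ape::cophenetic.phylo(tr)
  d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
  off <- upper.tri(d1)
  rel <- abs(d2[off] - d1[off]) / d1[off]
  expect_lt(max(rel), 1e-9)
})

test_that("state tables read under both schemas and reject bad input", {
  csv <- function(lines) {
    p <- tempfile(fileext = ".csv")
    writeLines(lines, p)
    p
  }
  lat <- read_state_table(csv(c("species,min_lat,max_lat",
                                "sp1,-10,15", "sp2,30,50")))
  expect_equal(lat$min_lat, c(-10, 30))
  st <- read_state_table(csv(c("species,state", "sp1,TROPICAL",
                               "sp2,temperate")))
  expect_equal(st$state, c("TROPICAL", "TEMPERATE"))
  expect_error(read_state_table(csv(c("species,min_lat,max_lat",
                                      "sp1,-10,15", "sp1,0,5"))),
               "duplicate")
  expect_error(read_state_table(csv(c("species,min_lat,max_lat",
                                      "sp1,-100,15"))), "invalid")
  expect_error(read_state_table(csv(c("species,min_lat,max_lat",
                                      "sp1,20,10"))), "invalid")
  expect_error(read_state_table(csv(c("name,state", "sp1,TROPICAL"))),
               "species")
})

test_that("matching drops stateless tips and preserves retained depths", {
  tr <- read_newick(nwk_file("((A:1,B:1):1,C:2);"))
  states <- data.frame(species = c("B", "C"),
                       state = c("TROPICAL", "TEMPERATE"))
  m <- match_tree_and_states(tr, states, policy = "drop")
  expect_equal(m$dropped, "A")
  expect_equal(ape::Ntip(m$tree), 2)
  # degree-2 node suppressed, branch lengths summed: (B:2,C:2)
  expect_equal(sort(m$tree$edge.length), c(2, 2))
  expect_setequal(m$tree$tip.label, c("B", "C"))
  expect_equal(m$states$species, m$tree$tip.label)
  expect_error(match_tree_and_states(tr, states, policy = "error"),
               "without a biome state")
})

test_that("matching is the identity when all tips have states", {
  set.seed(8)
  tr <- ape::rcoal(20)
  states <- data.frame(species = tr$tip.label,
                       state = sample(c("TROPICAL", "TEMPERATE",
                                        "WIDESPREAD"), 20, TRUE))
  m <- match_tree_and_states(tr, states)
  expect_length(m$dropped, 0)
  expect_identical(m$tree, tr)
})

test_that("pruning preserves root-to-tip depths of retained tips", {
  set.seed(13)
  tr <- ape::rcoal(30)
  depth0 <- setNames(ape::node.depth.edgelength(tr)[1:30], tr$tip.label)
  keep <- sample(tr$tip.label, 18)
  states <- data.frame(species = keep, state = "TROPICAL")
  m <- match_tree_and_states(tr, states)
  depth1 <- setNames(
    ape::node.depth.edgelength(m$tree)[seq_len(ape::Ntip(m$tree))],
    m$tree$tip.label)
  expect_equal(depth1[keep], depth0[keep], tolerance = 1e-12)
})
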