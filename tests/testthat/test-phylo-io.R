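test_that("read_newick accepts valid ultrametric trees, polytomies included", {
  tf <- write_table_fixture("((A:1,B:1):1,C:2);", ".nwk")
  tr <- read_newick(tf)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(levyshift:::tree_depth(tr), 2)

  star <- write_table_fixture("(A:1,B:1,C:1);", ".nwk")
  trs <- read_newick(star)
  expect_equal(ape::Ntip(trs), 3)
  expect_equal(trs$Nnode, 1)  # polytomy preserved
})

test_that("read_newick rejects non-ultrametric trees and missing lengths", {
  bad <- write_table_fixture("((A:1,B:2):1,C:2);", ".nwk")
  expect_error(read_newick(bad), "ultrametric")
  nolen <- write_table_fixture("((A,B),C);", ".nwk")
  expect_error(read_newick(nolen), "branch length")
})

test_that("expression tables are read with replicates and NA as absence", {
  tf <- write_table_fixture(c("species,tox1,tox2",
                              "A,0.1,0.9",
                              "A,0.2,0.8",
                              "B,NA,1"))
  tbl <- read_expression_table(tf)
  expect_equal(sum(tbl$species == "A"), 2)  # replicate rows kept
  expect_equal(tbl$tox1[tbl$species == "B"], 0)  # NA -> absent

  neg <- write_table_fixture(c("species,tox1", "A,-0.1"))
  expect_error(read_expression_table(neg), "negative")
  chr <- write_table_fixture(c("species,tox1", "A,abc"))
  expect_error(read_expression_table(chr), "row 1")
})

test_that("delimiter is sniffed for TSV input", {
  tf <- write_table_fixture(c("species\ttox1", "A\t0.5", "B\t0.2"), ".tsv")
  tbl <- read_expression_table(tf)
  expect_named(tbl, c("species", "tox1"))
  expect_equal(tbl$tox1, c(0.5, 0.2))
})

test_that("presence filter keeps toxins reaching the species fraction", {
  tbl <- toy_presence_table()
  out <- presence_filter(tbl, 0.5)
  expect_named(out, c("species", "X"))  # X in 2/4, Y in 1/4
  # presence counts species, not replicate rows
  tbl_rep <- tibble::add_row(tbl, species = "A", X = 0, Y = 0.4)
  out2 <- presence_filter(tbl_rep, 0.5)
  expect_named(out2, c("species", "X"))

  all_present <- tibble::tibble(species = c("A", "B"), X = c(1, 2),
                                Y = c(3, 4))
  expect_identical(presence_filter(all_present, 0.5), all_present)
  expect_error(presence_filter(tbl, 0.9), "presence fractions")
})

test_that("presence filter is idempotent", {
  tbl <- toy_presence_table()
  once <- presence_filter(tbl, 0.5)
  expect_identical(presence_filter(once, 0.5), once)
})

test_that("within-species variance scaling matches the hand computation", {
  tbl <- tibble::tibble(species = c("P", "P", "Q", "Q"),
                        tox = c(0.2, 0.4, 0.1, 0.1))
  tr <- scale_by_within_species_variance(tbl, "tox")
  # variances {0.02, 0}, average 0.01, divisor sqrt = 0.1
  expect_equal(attr(tr, "scaling_constant"), 0.1)
  expect_equal(tr$value[tr$species == "P"], 3.0)
  expect_equal(tr$value[tr$species == "Q"], 1.0)
  # alternative divisor reading is one flag away
  tr2 <- scale_by_within_species_variance(tbl, "tox", divisor = "variance")
  expect_equal(attr(tr2, "scaling_constant"), 0.01)
})

test_that("scaling falls back to constant 1 without usable replicates", {
  norep <- tibble::tibble(species = c("P", "Q"), tox = c(0.3, 0.1))
  expect_warning(tr <- scale_by_within_species_variance(norep, "tox"),
                 "no species has replicate")
  expect_equal(tr$value, c(0.3, 0.1))

  ident <- tibble::tibble(species = c("P", "P", "Q", "Q"),
                          tox = c(0.3, 0.3, 0.1, 0.1))
  expect_warning(tr2 <- scale_by_within_species_variance(ident, "tox"),
                 "zero")
  expect_equal(tr2$value, c(0.3, 0.1))
})

test_that("scaling commutes with relabeling of species", {
  tbl <- tibble::tibble(species = c("P", "P", "Q", "Q", "R"),
                        tox = c(0.2, 0.4, 0.1, 0.15, 0.6))
  tr <- scale_by_within_species_variance(tbl, "tox")
  perm <- c(P = "Q", Q = "R", R = "P")
  tbl2 <- dplyr::mutate(tbl, species = unname(perm[species]))
  tr2 <- scale_by_within_species_variance(tbl2, "tox")
  v1 <- setNames(tr$value, unname(perm[tr$species]))
  v2 <- setNames(tr2$value, tr2$species)
  expect_equal(v1[names(v2)], v2)
})

test_that("pruning to overlap preserves depth and sums through-branches", {
  tr <- tree_from_text("(((A:1,B:1):1,C:2):1,D:3);")
  trait <- trait_of(A = 1, B = 2, D = 0)
  out <- prune_to_overlap(tr, trait)
  expect_equal(sort(out$tree$tip.label), c("A", "B", "D"))
  expect_equal(levyshift:::tree_depth(out$tree), 3, tolerance = 1e-9)
  expect_equal(out$trait$species, out$tree$tip.label)

  same <- prune_to_overlap(tr, trait_of(A = 1, B = 2, C = 3, D = 4))
  expect_equal(ape::Ntip(same$tree), 4)
  expect_error(prune_to_overlap(tr, trait_of(X = 1, Y = 2, Z = 3)),
               "at least 3")
})
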