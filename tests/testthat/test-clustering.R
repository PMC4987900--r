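three_point_d <- function() {
  d <- matrix(c(0, 10, 100,
                10, 0, 100,
                100, 100, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d
}

test_that("dihedral-space structure distances aggregate circular arcs", {
  expect_equal(structure_distance(c(10, -50), c(10, -50))$distance, 0)
  one <- structure_distance(c(0, NA), c(120, 40))
  expect_equal(one$distance, 120)
  expect_equal(one$n_used, 1L)
  two <- structure_distance(c(0, 100), c(20, 140))
  expect_equal(two$distance, 30)  # mean of 20 and 40
  expect_equal(structure_distance(c(0, 100), c(20, 140), "rms")$distance,
               sqrt(mean(c(20, 40)^2)))
  expect_equal(structure_distance(c(0, 100), c(20, 140), "max")$distance, 40)
  expect_error(structure_distance(c(NA, 1), c(2, NA)), "no comparable")
})

test_that("the ensemble distance matrix is a valid circular metric table", {
  ens <- two_family_ensemble(seed = 51L, n = 3L)
  aln <- align_by_numbering(ens$structures)
  tor <- ensemble_torsions(ens$structures)
  sel <- parse_position_list(paste(min(LOOP_POSITIONS), "-",
                                   max(LOOP_POSITIONS), " phi psi",
                                   sep = ""))
  dm <- dihedral_distance_matrix(tor, aln, sel)
  expect_true(isSymmetric(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 6L))
  expect_true(all(dm$d >= 0 & dm$d <= 180))
  expect_equal(unname(dm$n_used[1L, 2L]), 2L * length(LOOP_POSITIONS))
})

test_that("pairs with no shared variables name the offending structures", {
  a <- set_resnos(build_chain("AGFS", label = "a"), 1:4)
  b <- set_resnos(build_chain("AGFS", label = "b"), 11:14)
  aln <- align_by_numbering(list(a, b))
  tor <- ensemble_torsions(list(a, b))
  expect_error(
    suppressWarnings(dihedral_distance_matrix(tor, aln)),
    "'a' and 'b'")
})

test_that("complete linkage follows the forced 3-point merge order", {
  tree <- linkage_complete(three_point_d())
  expect_equal(tree$height, c(10, 100))
  expect_equal(tree$merge[1L, ], c(-2L, -1L))
  res <- cut_tree(tree, radius = 60)
  expect_equal(unname(res$labels[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(res$labels["C"]), 2L)
  # radius beyond the root height: one cluster; below all heights: singletons
  expect_equal(length(cut_tree(tree, 101)$sizes), 1L)
  expect_equal(length(cut_tree(tree, 5)$sizes), 3L)
  # boundary: a merge at exactly the radius is refused
  expect_equal(length(cut_tree(tree, 100)$sizes), 2L)
})

test_that("equal distances yield a deterministic index-ordered tree", {
  d <- matrix(5, 4L, 4L); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tree <- linkage_complete(d)
  expect_equal(tree$height, rep(5, 3L))
  expect_equal(tree$merge[1L, ], c(-2L, -1L))
  tree2 <- linkage_complete(d)
  expect_identical(tree, tree2)
})

test_that("merge heights match the stats::hclust complete-linkage oracle", {
  set.seed(61)
  for (k in 1:5) {
    n <- 8L
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1L) / 2L, 1, 179)
    d <- d + t(d)
    tree <- linkage_complete(d)
    expect_equal(sort(tree$height), hclust_heights(d), tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone heights
  }
})

test_that("permuting structures permutes labels but not the partition", {
  ens <- two_family_ensemble(seed = 71L, n = 4L)
  aln <- align_by_numbering(ens$structures)
  tor <- ensemble_torsions(ens$structures)
  sel <- parse_position_list("4-9 phi psi")
  cut1 <- cut_tree(linkage_complete(
    dihedral_distance_matrix(tor, aln, sel)), 60)
  set.seed(73)
  perm <- sample(seq_along(ens$structures))
  aln_p <- align_by_numbering(ens$structures[perm])
  tor_p <- ensemble_torsions(ens$structures[perm])
  cut2 <- cut_tree(linkage_complete(
    dihedral_distance_matrix(tor_p, aln_p, sel)), 60)
  part <- function(cut) {
    unname(lapply(split(names(cut$labels), cut$labels), sort))
  }
  expect_setequal(part(cut1), part(cut2))
})

test_that("a two-family torsion ensemble is recovered at radius 60", {
  ens <- two_family_ensemble(seed = 42L, n = 10L, sd = 5)
  aln <- align_by_numbering(ens$structures)
  tor <- ensemble_torsions(ens$structures)
  sel <- parse_position_list("4-9 phi psi")
  dm <- dihedral_distance_matrix(tor, aln, sel)
  res <- cut_tree(linkage_complete(dm), radius = 60)
  expect_equal(length(res$sizes), 2L)
  # 100% purity: each cluster holds exactly one family
  tab <- table(ens$families[names(res$labels)], res$labels)
  expect_equal(sort(unname(apply(tab, 1L, max))), c(10L, 10L))
  expect_equal(sum(tab), 20L)
  expect_true(all(apply(tab, 2L, function(col) sum(col > 0L)) == 1L))
})

test_that("cluster ids are 1-based and ordered by decreasing size", {
  ens <- two_family_ensemble(seed = 81L, n = 3L)
  # drop one stateB structure so sizes differ: 3 vs 2
  keep <- c(1:3, 4:5)
  aln <- align_by_numbering(ens$structures[keep])
  tor <- ensemble_torsions(ens$structures[keep])
  res <- cut_tree(linkage_complete(dihedral_distance_matrix(
    tor, aln, parse_position_list("4-9 phi psi"))), 60)
  expect_equal(sort(unique(unname(res$labels))), c(1L, 2L))
  expect_equal(res$sizes, c(3L, 2L))
  expect_equal(unname(res$labels[1L]), 1L)  # biggest cluster is id 1
})

test_that("cluster families round-trip through the Structure list format", {
  ens <- two_family_ensemble(seed = 91L, n = 2L)
  aln <- align_by_numbering(ens$structures)
  tor <- ensemble_torsions(ens$structures)
  res <- cut_tree(linkage_complete(dihedral_distance_matrix(
    tor, aln, parse_position_list("4-9 phi psi"))), 60)
  txt <- emit_cluster_families(res, ens$entries)
  re <- parse_structure_list(txt)
  expect_equal(re$basename, ens$entries$basename)
  expect_equal(re$chain, ens$entries$chain)
  expect_setequal(unique(re$family), c("1", "2"))
})

test_that("the Newick export is a parseable ultrametric tree", {
  set.seed(101)
  n <- 6L
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1L) / 2L, 10, 170)
  d <- d + t(d)
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  tree <- linkage_complete(d)
  txt <- write_newick(tree)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, paste0("s", 1:n))
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
  # leaf depth equals the root merge height
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths[seq_len(n)]), max(tree$height),
               tolerance = 1e-8)
})
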