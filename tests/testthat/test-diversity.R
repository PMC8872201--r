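test_that("profile distances are Euclidean, symmetric and zero on duplicates", {
  x <- rbind(A = c(0, 0), B = c(3, 4), C = c(0, 0))
  d <- profile_distance(x, scale = FALSE)
  expect_equal(d["A", "B"], 5)
  expect_equal(d["A", "C"], 0)
  expect_identical(unclass(d), unclass(t(d)))
  expect_true(all(diag(d) == 0))
  expect_error(profile_distance(x[1, , drop = FALSE]), "at least 2")
})

test_that("scaling drops zero-variance columns with a note", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_message(d <- profile_distance(x, scale = TRUE), "zero-variance")
  expect_equal(dim(d), c(3L, 3L))
})

test_that("analytic self-cell completion fills the natural diagonal", {
  set.seed(2)
  inst <- random_pair_instance(n_markers = 60, n_chrom = 1, miss_prob = 0)
  g3 <- genotype_matrix(rbind(unclass(inst$genotypes),
                              C = sample(0:2, 60, replace = TRUE)),
                        sample_ids = c("A", "B", "C"),
                        marker_ids = inst$map$marker)
  sp <- splosh_matrix(g3, inst$map)
  done <- impute_self_cells(sp, "analytic")
  expect_true(all(diag(done) == attr(sp, "total_map_length")))
  d <- profile_distance(unclass(sp), scale = FALSE)
  expect_true(all(diag(impute_self_cells(d, "analytic")) == 0))
})

test_that("iterative low-rank completion recovers a deleted rank-1 diagonal", {
  set.seed(14)
  u <- runif(8, 1, 3)
  full <- tcrossprod(u)          # rank 1, all cells positive
  dimnames(full) <- list(paste0("S", 1:8), paste0("S", 1:8))
  holed <- full
  diag(holed) <- NA
  done <- impute_self_cells(holed, "iterative_pca", cells = "na", rank = 1L)
  expect_lt(max(abs(diag(done) - diag(full))), 1e-4)
})

test_that("PCA separates known geometry and reports bounded variance shares", {
  x <- rbind(A = c(0, 0, 0), B = c(0, 0, 0), C = c(10, 10, 0),
             D = c(10, 10, 0))
  p <- pca_scores(x, k = 2, scale = FALSE)
  expect_gt(abs(p$scores["A", 1] - p$scores["C", 1]), 1)
  expect_equal(p$explained[2], 0, tolerance = 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 100 + 1e-9)
  # duplicated samples score identically
  expect_equal(p$scores["A", ], p$scores["B", ])
  expect_error(pca_scores(rbind(c(1, NA), c(2, 3))), "non-finite")
})

test_that("component signs are fixed by the largest-magnitude loading", {
  set.seed(6)
  x <- matrix(rnorm(100), 20, 5)
  p <- pca_scores(x, k = 3, scale = TRUE)
  for (c in 1:3)
    expect_gt(p$loadings[which.max(abs(p$loadings[, c])), c], 0)
})

test_that("the three-taxon neighbor-joining branch lengths solve exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("additive five-taxon distances recover the generating topology", {
  set.seed(10)
  true <- ape::rtree(5)
  true$edge.length <- true$edge.length + 0.5   # keep branches comfortably positive
  d <- ape::cophenetic.phylo(true)
  tr <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_setequal(tr$tip.label, true$tip.label)
  expect_true(all(tr$edge.length >= 0))
})

test_that("distance exports round-trip in both formats and sanitize labels", {
  set.seed(19)
  x <- matrix(runif(12), 4, 3)
  rownames(x) <- c("GDR kale", "Vates", "Starbor", "Winnetou")
  d <- profile_distance(x, scale = FALSE)
  phy <- withr::local_tempfile(fileext = ".phy")
  export_distance(d, phy, "phylip_square")
  lines <- readLines(phy)
  expect_identical(trimws(lines[1]), "4")
  back <- read_phylip_distance(phy)
  expect_lt(max(abs(back - unclass(d))), 1e-9)
  expect_identical(rownames(back)[1], "GDR_kale")
  expect_true(file.exists(paste0(phy, ".labels.tsv")))
  nex <- withr::local_tempfile(fileext = ".nex")
  export_distance(d, nex, "nexus_distances")
  back2 <- read_nexus_distance(nex)
  expect_lt(max(abs(back2 - unclass(d))), 1e-9)
  rownames(x)[2] <- "GDR_kale"
  d2 <- profile_distance(x, scale = FALSE)
  expect_error(export_distance(d2, phy), "duplicate")
})
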