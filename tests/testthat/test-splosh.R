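toy_anchored <- function(ci, cj, pos = c(0, 10, 20, 30, 40)) {
  m <- genetic_map(data.frame(marker = paste0("m", seq_along(pos)),
                              chrom = "c1", pos_cM = pos))
  g <- genotype_matrix(rbind(ci, cj), sample_ids = c("A", "B"),
                       marker_ids = m$marker)
  list(g = g, m = m)
}

test_that("only opposite homozygotes are incompatible; missing never excludes sharing", {
  expect_identical(classify_compatibility(0, 2), "INCOMPATIBLE")
  expect_identical(classify_compatibility(2, 0), "INCOMPATIBLE")
  expect_identical(classify_compatibility(0, 1), "COMPATIBLE")
  expect_identical(classify_compatibility(1, 2), "COMPATIBLE")
  expect_identical(classify_compatibility(0, 0), "COMPATIBLE")
  expect_identical(classify_compatibility(NA, 2), "COMPATIBLE")
  expect_identical(classify_compatibility(NA, NA), "COMPATIBLE")
  expect_identical(classify_compatibility(NA, 2, missing_is_compatible = FALSE),
                   "INCOMPATIBLE")
})

test_that("segments are maximal compatible runs bounded by flanking incompatibles", {
  segs <- find_potential_segments(c(0, 1, 2, 0, 0), c(0, 0, 0, 2, 0),
                                  c(0, 10, 20, 30, 40))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$lower_cM, c(0, 30))
  expect_equal(segs$upper_cM, c(20, 40))
  expect_equal(segs$length_cM, c(20, 10))
  expect_equal(segs$n_markers, c(2L, 1L))
  # all compatible: one segment spanning the whole chromosome span
  all_ok <- find_potential_segments(c(0, 1, 0), c(0, 0, 1), c(5, 15, 45))
  expect_equal(nrow(all_ok), 1L)
  expect_equal(all_ok$length_cM, 40)
  # all incompatible: nothing
  none <- find_potential_segments(c(0, 0), c(2, 2), c(0, 30))
  expect_equal(nrow(none), 0L)
  expect_error(find_potential_segments(c(0, 1), c(0, 0, 1), c(0, 1, 2)),
               "mismatch")
})

test_that("pair values sum segment lengths above the inclusive threshold", {
  tt <- toy_anchored(c(0, 1, 2, 0, 0), c(0, 0, 0, 2, 0))
  vals <- vapply(c(30, 15, 0), function(th)
    splosh_pair(tt$g, tt$m, "A", "B", splosh_config(threshold_cM = th))$value,
    numeric(1))
  expect_equal(vals, c(0, 20, 30))
  # a segment of exactly threshold length counts (inclusive comparison)
  expect_equal(splosh_pair(tt$g, tt$m, "A", "B",
                           splosh_config(threshold_cM = 20))$value, 20)
  expect_error(splosh_pair(tt$g, tt$m, "A", "nope"), "unknown sample")
})

test_that("self-comparison with complete calls equals the total map length", {
  tt <- toy_anchored(c(0, 0, 2, 0, 2), c(2, 2, 0, 2, 0))
  cfg <- splosh_config(threshold_cM = 0)
  expect_equal(splosh_pair(tt$g, tt$m, "A", "A", cfg)$value, 40)
  # two fully inbred lines opposite-homozygous everywhere share nothing
  expect_equal(splosh_pair(tt$g, tt$m, "A", "B", cfg)$value, 0)
})

test_that("the matrix is symmetric, mirrors pair values and respects bounds", {
  set.seed(21)
  inst <- random_pair_instance(n_markers = 120, n_chrom = 2)
  extra <- genotype_matrix(
    rbind(unclass(inst$genotypes),
          C = sample(c(0:2, NA), 120, replace = TRUE)),
    sample_ids = c("A", "B", "C"), marker_ids = inst$map$marker)
  sp <- splosh_matrix(extra, inst$map)
  expect_identical(sp, t(sp))
  total <- attr(sp, "total_map_length")
  expect_true(all(sp >= 0 & sp <= total + 1e-9))
  for (i in 1:3) for (j in 1:3)
    expect_equal(sp[i, j],
                 splosh_pair(extra, inst$map, i, j)$value)
  expect_error(splosh_matrix(extra[1, ], inst$map), "at least 2")
})

test_that("replacing any call with missing never decreases the pair value", {
  set.seed(33)
  for (r in 1:20) {
    inst <- random_pair_instance(n_markers = 80, n_chrom = 2)
    g <- inst$genotypes
    base <- splosh_pair(g, inst$map, "A", "B")$value
    dos <- unclass(g)
    k <- sample(ncol(dos), 1)
    dos[1, k] <- NA
    g2 <- genotype_matrix(dos)
    expect_gte(splosh_pair(g2, inst$map, "A", "B")$value, base)
  }
})

test_that("strict mode breaks segments at long double-missing runs", {
  pos <- c(0, 10, 20, 30, 40, 50)
  tt <- toy_anchored(c(0, NA, NA, NA, 0, 0), c(0, NA, NA, NA, 0, 0), pos)
  lax <- splosh_pair(tt$g, tt$m, "A", "B", splosh_config(threshold_cM = 0))
  expect_equal(lax$value, 50)
  strict <- splosh_pair(tt$g, tt$m, "A", "B",
                        splosh_config(threshold_cM = 0,
                                      missing_breaker_run = 3))
  # the 3-marker missing run splits the chromosome into two bounded runs:
  # marker 1 bounded by [0, 10] and markers 5-6 bounded by [30, 50]
  expect_equal(sort(strict$segments$length_cM), c(10, 20))
})

test_that("percent-of-map conversion reports one decimal and guards the denominator", {
  expect_equal(splosh_percent(600, 1200), 50.0)
  expect_equal(splosh_percent(0, 777), 0.0)
  m <- genetic_map(data.frame(marker = c("a", "b"), chrom = "c1",
                              pos_cM = c(0, 120)))
  expect_equal(splosh_percent(60, map_summary(m)), 50.0)
  expect_error(splosh_percent(10, 0), "> 0")
})

test_that("splosh matrices round-trip through the delimited writer", {
  set.seed(9)
  inst <- random_pair_instance(n_markers = 60, n_chrom = 1)
  sp <- splosh_matrix(inst$genotypes, inst$map)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_splosh_matrix(sp, path)
  back <- read_splosh_matrix(path)
  expect_equal(back, unclass(sp)[,], ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(sp))
})
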