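test_that("AB-encoded tables are normalized to the 4-value call domain", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample,m1,m2,m3,m4,m5",
               "S1,AA,AB,BB,--,NC",
               "S2,BA,aa,bb,NA,AB"), path)
  g <- read_genotype_table(path)
  expect_s3_class(g, "genotype_matrix")
  expect_identical(unname(unclass(g)[1, ]), c(0L, 1L, 2L, NA, NA))
  expect_identical(unname(unclass(g)[2, ]), c(1L, 0L, 2L, NA, 1L))
  expect_identical(rownames(g), c("S1", "S2"))
})

test_that("nucleotide calls collapse via allele definitions, order-insensitive", {
  defs <- data.frame(marker = c("m1", "m2"),
                     allele_a = c("C", "A"), allele_b = c("T", "G"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Sample\tm1\tm2", "S1\tTC\tAA", "S2\tCC\tGG", "S3\tCT\tAG"),
             path)
  g <- read_genotype_table(path, encoding = "nucleotide", allele_defs = defs)
  # all 2-letter combinations of {C,T}: CC hom-A, TT hom-B, CT == TC het
  expect_identical(unname(unclass(g)[, "m1"]), c(1L, 0L, 1L))
  expect_identical(unname(unclass(g)[, "m2"]), c(0L, 2L, 1L))
})

test_that("nucleotide calls with alleles outside the definitions error with the marker id", {
  defs <- data.frame(marker = "m1", allele_a = "C", allele_b = "T")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Sample\tm1", "S1\tAG"), path)
  expect_error(read_genotype_table(path, encoding = "nucleotide",
                                   allele_defs = defs), "m1")
})

test_that("duplicate sample or marker ids are rejected by name", {
  expect_error(genotype_matrix(rbind(c(0, 1), c(1, 2)),
                               sample_ids = c("S1", "S1"),
                               marker_ids = c("m1", "m2")), "S1")
  expect_error(genotype_matrix(rbind(c(0, 1)), sample_ids = "S1",
                               marker_ids = c("m1", "m1")), "m1")
})

test_that("genotype table write/read round-trip is the identity and idempotent", {
  set.seed(42)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 5,
                dimnames = list(paste0("S", 1:5), paste0("m", 1:12)))
  g <- genotype_matrix(dos)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(g, path)
  g2 <- read_genotype_table(path)
  expect_identical(unclass(g2), unclass(g))
  # second round trip (normalize twice) changes nothing
  write_genotype_table(g2, path)
  expect_identical(unclass(read_genotype_table(path)), unclass(g))
})

test_that("column-oriented tables are transposed on request", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Marker\tS1\tS2", "m1\tAA\tBB", "m2\tAB\tAA"), path)
  g <- read_genotype_table(path, orientation = "columns")
  expect_identical(rownames(g), c("S1", "S2"))
  expect_identical(unname(unclass(g)["S1", ]), c(0L, 1L))
})

test_that("STRUCTURE export uses two allele rows per sample with -9 for missing", {
  g <- genotype_matrix(rbind(S1 = c(m1 = 0L, m2 = 1L, m3 = NA)))
  path <- withr::local_tempfile(fileext = ".str")
  write_structure_file(g, path)
  lines <- readLines(path)
  expect_identical(lines[2], "S1 1 1 -9")
  expect_identical(lines[3], "S1 1 2 -9")
  expect_error(write_structure_file(g[0, ], path), "empty")
})

test_that("STRUCTURE files re-read to the original genotype grid", {
  set.seed(7)
  dos <- matrix(sample(c(0:2, NA), 80, replace = TRUE), nrow = 8,
                dimnames = list(paste0("S", 1:8), paste0("m", 1:10)))
  g <- genotype_matrix(dos)
  path <- withr::local_tempfile(fileext = ".str")
  write_structure_file(g, path)
  expect_identical(unclass(read_structure_file(path)), unclass(g))
})

test_that("intensity tables reject negative values and align with genotypes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Sample\tm1\tm2", "S1\t0.5\t1.2", "S2\t-0.1\t0.3"), path)
  expect_error(read_intensity_table(path), "negative")
})
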