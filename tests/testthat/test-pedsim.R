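tiny_chroms <- function(n = 2, len = 100)
  data.frame(label = sprintf("C%02d", seq_len(n)), length_cM = len)

test_that("simulation is deterministic under the seed", {
  cfg <- sim_config(chromosomes = tiny_chroms(), markers_per_cM = 0.5,
                    subpopulations = data.frame(name = "p", n_founders = 6L,
                                                law = "beta", alpha = 1,
                                                beta = 1),
                    pedigree = ped_cross("kid", "p_F01", "p_F02"),
                    missing_rate = 0.05, seed = 99L)
  s1 <- simulate_pedigree(cfg)
  s2 <- simulate_pedigree(cfg)
  expect_identical(unclass(s1$genotypes), unclass(s2$genotypes))
  expect_identical(s1$truth$mosaics, s2$truth$mosaics)
})

test_that("a fixed allele frequency of 1 makes every founder HOM_B", {
  cfg <- sim_config(chromosomes = tiny_chroms(1, 50), markers_per_cM = 1,
                    subpopulations = data.frame(name = "p", n_founders = 4L,
                                                law = "fixed", p = 1),
                    missing_rate = 0, seed = 1L)
  fo <- simulate_founders(cfg)
  expect_true(all(unclass(fo$genotypes) == 2L))
})

test_that("founder heterozygosity matches the binomial expectation 2p(1-p)", {
  cfg <- sim_config(chromosomes = data.frame(label = "C01",
                                             length_cM = 1000),
                    markers_per_cM = 10,  # 10,001 markers
                    subpopulations = data.frame(name = "p", n_founders = 10L,
                                                law = "fixed", p = 0.5),
                    missing_rate = 0, seed = 5L)
  fo <- simulate_founders(cfg)
  het <- mean(unclass(fo$genotypes) == 1L)
  expect_lt(abs(het - 0.5), 0.02)
})

test_that("meiosis follows Haldane crossover counts and tiles the chromosome", {
  parent <- list(hap1 = list(breaks = 100, origin = 1L),
                 hap2 = list(breaks = 100, origin = 2L))
  set.seed(4)
  zero <- meiosis(parent, 0)
  expect_length(zero$origin, 1L)
  counts <- replicate(10000, {
    gam <- meiosis(parent, 100)
    expect_equal(gam$breaks[length(gam$breaks)], 100)
    length(gam$origin) - 1L
  })
  # 100 cM = 1 Morgan: mean crossover count 1
  expect_lt(abs(mean(counts) - 1), 0.05)
})

test_that("children carry one allele of each parent at every marker", {
  cfg <- sim_config(chromosomes = tiny_chroms(3, 80), markers_per_cM = 1,
                    subpopulations = data.frame(name = "p", n_founders = 2L,
                                                law = "beta", alpha = 0.5,
                                                beta = 0.5),
                    pedigree = ped_cross("kid", "p_F01", "p_F02"),
                    missing_rate = 0, error_rate = 0, seed = 12L)
  sim <- simulate_pedigree(cfg)
  dos <- unclass(sim$genotypes)
  kid <- dos["kid", ]
  for (parent in c("p_F01", "p_F02")) {
    opposite <- (kid == 0L & dos[parent, ] == 2L) |
      (kid == 2L & dos[parent, ] == 0L)
    expect_false(any(opposite))
  }
})

test_that("corruption touches calls only, never the recorded truth", {
  cfg <- sim_config(chromosomes = tiny_chroms(1, 60), markers_per_cM = 1,
                    subpopulations = data.frame(name = "p", n_founders = 2L,
                                                law = "beta", alpha = 1,
                                                beta = 1),
                    pedigree = ped_cross("kid", "p_F01", "p_F02"),
                    missing_rate = 1, seed = 3L)
  sim <- simulate_pedigree(cfg)
  expect_true(all(is.na(unclass(sim$genotypes))))
  mos <- sim$truth$mosaics$kid$C01
  expect_equal(mos$hap1$breaks[length(mos$hap1$breaks)], 60)
  expect_equal(mos$hap2$breaks[length(mos$hap2$breaks)], 60)
})

test_that("selfing a fully inbred line reproduces it exactly", {
  cfg <- sim_config(chromosomes = tiny_chroms(2, 70), markers_per_cM = 1,
                    subpopulations = data.frame(name = "p", n_founders = 1L,
                                                law = "fixed", p = 1),
                    pedigree = ped_self("kid", "p_F01"),
                    missing_rate = 0, seed = 8L)
  sim <- simulate_pedigree(cfg)
  dos <- unclass(sim$genotypes)
  expect_identical(unname(dos["kid", ]), unname(dos["p_F01", ]))
})

test_that("clone and parent-offspring pairs have the expected IBD states", {
  rp <- sim_relationship_pairs(2, chromosomes = tiny_chroms(2, 100),
                               markers_per_cM = 0.1, seed = 17L)
  pairs <- rp$pairs
  cl <- pairs[pairs$class == "clone", ][1, ]
  seg <- true_ibd_segments(rp$sim$truth, cl$id1, cl$id2)
  expect_true(all(seg$state == 2L))
  expect_equal(sum(seg$end_cM - seg$start_cM), 200)
  po <- pairs[pairs$class == "parent_offspring", ][1, ]
  seg <- true_ibd_segments(rp$sim$truth, po$id1, po$id2)
  expect_true(all(seg$state >= 1L))
  expect_equal(sum(seg$end_cM - seg$start_cM), 200)
  expect_error(true_ibd_segments(rp$sim$truth, "nope", cl$id1), "unknown")
})

test_that("full sibs share about three quarters of the genome IBD", {
  n_rep <- 500L
  ped <- do.call(rbind, lapply(seq_len(n_rep), function(k) rbind(
    ped_cross(sprintf("a%03d", k), sprintf("p_F%04d", 2 * k - 1),
              sprintf("p_F%04d", 2 * k)),
    ped_cross(sprintf("b%03d", k), sprintf("p_F%04d", 2 * k - 1),
              sprintf("p_F%04d", 2 * k)))))
  cfg <- sim_config(chromosomes = tiny_chroms(10, 100),
                    markers_per_cM = 0.01,  # truth needs no dense markers
                    subpopulations = data.frame(name = "p",
                                                n_founders = 2L * n_rep,
                                                law = "fixed", p = 0.5),
                    pedigree = ped, missing_rate = 0, seed = 23L)
  sim <- simulate_pedigree(cfg)
  frac <- vapply(seq_len(n_rep), function(k) {
    seg <- true_ibd_segments(sim$truth, sprintf("a%03d", k),
                             sprintf("b%03d", k))
    sum(seg$end_cM - seg$start_cM) / 1000
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.75), 0.02)
})

test_that("pedigrees referencing unresolved parents are rejected", {
  cfg <- sim_config(chromosomes = tiny_chroms(1, 50), markers_per_cM = 1,
                    subpopulations = data.frame(name = "p", n_founders = 2L,
                                                law = "fixed", p = 0.5),
                    pedigree = rbind(ped_cross("k1", "k2", "p_F01"),
                                     ped_cross("k2", "p_F01", "p_F02")),
                    seed = 1L)
  expect_error(simulate_pedigree(cfg), "unresolved")
})

test_that("simulator YAML configs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "chromosomes:",
    "  - {label: C01, length_cM: 100}",
    "  - {label: C02, length_cM: 50}",
    "markers_per_cM: 0.5",
    "subpopulations:",
    "  - {name: p, n_founders: 4, law: beta, alpha: 0.4, beta: 0.4}",
    "pedigree:",
    "  - {id: kid, parent1: p_F01, parent2: p_F02}",
    "missing_rate: 0.02",
    "seed: 11"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$chromosomes$length_cM, c(100, 50))
  expect_equal(cfg$seed, 11L)
  sim <- simulate_pedigree(cfg)
  expect_true("kid" %in% rownames(sim$genotypes))
})
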