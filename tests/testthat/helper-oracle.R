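# Independent brute-force shared-haplotype oracle: for every compatible
# marker, scan outward to the nearest incompatible marker in each
# direction (or the chromosome span end), collect the distinct bounded
# intervals, and sum those at least `threshold` long. Quadratic and
# structurally unrelated to the package's run-length scanner.
brute_splosh <- function(gi, gj, map, threshold = 30,
                         missing_compatible = TRUE) {
  total <- 0
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    p <- map$pos_cM[idx]
    a <- gi[idx]; b <- gj[idx]
    inc <- !is.na(a) & !is.na(b) & ((a == 0 & b == 2) | (a == 2 & b == 0))
    if (!missing_compatible) inc[is.na(a) | is.na(b)] <- TRUE
    comp <- which(!inc)
    if (length(comp) == 0L) next
    bounds <- t(vapply(comp, function(k) {
      before <- which(inc & seq_along(inc) < k)
      after <- which(inc & seq_along(inc) > k)
      c(if (length(before)) p[max(before)] else min(p),
        if (length(after)) p[min(after)] else max(p))
    }, numeric(2)))
    segs <- unique(bounds)
    lens <- segs[, 2] - segs[, 1]
    total <- total + sum(lens[lens >= threshold])
  }
  total
}

# Random unphased genotype pair + map instance for oracle comparisons.
random_pair_instance <- function(n_markers = sample(50:500, 1),
                                 n_chrom = sample(1:3, 1),
                                 miss_prob = 0.1) {
  chrom <- sort(sample(seq_len(n_chrom), n_markers, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(ii)
    sort(stats::runif(length(ii), 0, 100))))
  map <- genetic_map(data.frame(marker = paste0("m", seq_len(n_markers)),
                                chrom = paste0("chr", chrom),
                                pos_cM = pos))
  draw <- function() {
    g <- sample(0:2, n_markers, replace = TRUE)
    g[stats::runif(n_markers) < miss_prob] <- NA
    g
  }
  g <- genotype_matrix(rbind(draw(), draw()),
                       sample_ids = c("A", "B"), marker_ids = map$marker)
  list(genotypes = g, map = map)
}

# The QC demonstration panel: 6 markers x 10 samples where each marker
# exercises exactly one known combination of filter rules.
#   m1: 3/10 missing (fails MISSING_RATE only)
#   m2: all HOM_A (MONOMORPHIC and NO_TWO_HOM)
#   m3: only HOM_A and HET observed (NO_TWO_HOM)
#   m4: clean
#   m5: clean calls, Norm R SD 0.12 (NULL_ALLELE)
#   m6: clean
qc_fixture <- function() {
  calls <- cbind(
    m1 = c(0, 2, 1, 0, 2, 0, 2, NA, NA, NA),
    m2 = rep(0, 10),
    m3 = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    m4 = c(0, 2, 1, 0, 2, 1, 0, 2, 1, 0),
    m5 = c(0, 2, 1, 0, 2, 1, 0, 2, 1, 0),
    m6 = c(2, 0, 1, 2, 0, 1, 2, 0, 1, 2))
  g <- genotype_matrix(calls, sample_ids = paste0("S", 1:10))
  # constant Norm R everywhere except m5, whose values alternate enough to
  # give a standard deviation of 0.12 (> 0.09)
  intens <- matrix(1, 10, 6, dimnames = dimnames(g))
  m5vals <- rep(c(1 - 0.12, 1 + 0.12), 5)
  m5vals <- m5vals * 0.12 / stats::sd(m5vals)  # exact SD 0.12
  intens[, "m5"] <- 1 + (m5vals - mean(m5vals))
  list(genotypes = g, intensities = intens)
}
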