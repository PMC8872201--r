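#' Configuration for the diploid pedigree simulator
#'
#' Simulates unphased diploid SNP-array genotypes on a genetic map, with
#' subpopulation structure among founders, arbitrary pedigrees
#' (crosses, selfing, clones), recombination under the Haldane
#' (no-interference) model, and per-call genotyping error and missingness.
#' Founder-haplotype origin mosaics are recorded for every simulated
#' chromosome, so true identity-by-descent segments are available for any
#' sample pair.
#'
#' The defaults emulate a diversity panel of 72 varieties genotyped on a
#' dense array and anchored to a ~1205 cM genetic map: 19 chromosomes of
#' 63.4 cM, about 2.2 markers per cM (~2700 markers), three divergent
#' subpopulations of 24 founders each with per-marker allele frequencies
#' drawn from Beta(0.4, 0.4) independently per subpopulation, 1% missing
#' calls and no genotyping error.
#'
#' @param chromosomes data frame with columns `label`, `length_cM`.
#' @param markers_per_cM marker density; markers are laid out evenly from
#'   0 to the chromosome length inclusive
#'   (`round(length * density) + 1` markers per chromosome).
#' @param positions optional named list (by chromosome label) of explicit
#'   marker positions, overriding `markers_per_cM`.
#' @param subpopulations data frame with columns `name`, `n_founders`,
#'   `law` (`"beta"` or `"fixed"`), and `alpha`,`beta` or `p` as the law
#'   requires. Allele frequencies refer to allele B: under `law = "fixed"`
#'   with `p = 1` every founder is `HOM_B`.
#' @param pedigree data frame of cross instructions with columns `id`,
#'   `parent1`, `parent2`, `op` (`"cross"` or `"clone"`); see [ped_cross()],
#'   [ped_self()], [ped_clone()]. Parents must be defined before use
#'   (founders or earlier rows), which keeps the pedigree acyclic.
#' @param missing_rate,error_rate per-call corruption probabilities in
#'   \[0,1\].
#' @param sample_missing_rates optional named numeric vector overriding
#'   `missing_rate` for specific samples (e.g. outgroup-like samples with
#'   tens of percent missing calls).
#' @param samples optional character vector restricting the output
#'   genotype matrix to these ids (truth is kept for all simulated ids).
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(chromosomes = data.frame(
                         label = sprintf("C%02d", 1:19),
                         length_cM = rep(63.4, 19)),
                       markers_per_cM = 2.2,
                       positions = NULL,
                       subpopulations = data.frame(
                         name = c("curly", "lacinato", "collard"),
                         n_founders = 24L,
                         law = "beta", alpha = 0.4, beta = 0.4),
                       pedigree = NULL,
                       missing_rate = 0.01,
                       error_rate = 0,
                       sample_missing_rates = NULL,
                       samples = NULL,
                       seed = 1L) {
  stopifnot(all(c("label", "length_cM") %in% names(chromosomes)),
            all(chromosomes$length_cM >= 0),
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            all(c("name", "n_founders", "law") %in% names(subpopulations)))
  if (!is.null(pedigree))
    stopifnot(all(c("id", "parent1", "parent2", "op") %in% names(pedigree)))
  structure(list(chromosomes = chromosomes,
                 markers_per_cM = markers_per_cM,
                 positions = positions,
                 subpopulations = subpopulations,
                 pedigree = pedigree,
                 missing_rate = missing_rate,
                 error_rate = error_rate,
                 sample_missing_rates = sample_missing_rates,
                 samples = samples,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pedigree instruction helpers
#'
#' Build rows for the `pedigree` slot of [sim_config()]: a biparental
#' cross, a selfing (both parents the same individual), or a clone (an
#' exact copy, sharing both haplotype mosaics).
#'
#' @param id new sample id.
#' @param parent1,parent2,of parent ids (must exist before this row).
#' @return one-row data frame.
#' @export
ped_cross <- function(id, parent1, parent2)
  data.frame(id = id, parent1 = parent1, parent2 = parent2, op = "cross",
             stringsAsFactors = FALSE)

#' @rdname ped_cross
#' @export
ped_self <- function(id, of) ped_cross(id, of, of)

#' @rdname ped_cross
#' @export
ped_clone <- function(id, of)
  data.frame(id = id, parent1 = of, parent2 = NA_character_, op = "clone",
             stringsAsFactors = FALSE)

# marker layout for one chromosome
sim_positions <- function(cfg, label, length_cM) {
  if (!is.null(cfg$positions)) {
    p <- cfg$positions[[label]]
    if (is.null(p)) stop("no explicit positions for chromosome ", label)
    return(sort(as.numeric(p)))
  }
  n <- round(length_cM * cfg$markers_per_cM) + 1L
  if (n < 1L) stop("zero markers on chromosome ", label)
  seq(0, length_cM, length.out = max(n, 2L))
}

#' Simulate founder individuals
#'
#' Lays out markers on the configured chromosomes, draws per-marker allele
#' frequencies per subpopulation from the configured law, and gives each
#' founder two haplotypes with alleles drawn independently from those
#' frequencies. Deterministic under the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `haplotypes` (per chromosome, a 2*n_founders x
#'   n_markers 0/1 matrix; founder f owns rows 2f-1 and 2f), `genotypes`
#'   (founder [genotype_matrix]), `map` (the [genetic_map]), `founder_ids`,
#'   and `subpop` (named character vector).
#' @export
simulate_founders <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- cfg$chromosomes
  pos_list <- lapply(seq_len(nrow(chroms)), function(k)
    sim_positions(cfg, chroms$label[k], chroms$length_cM[k]))
  names(pos_list) <- chroms$label
  if (sum(lengths(pos_list)) == 0L) stop("zero markers configured")
  map <- genetic_map(data.frame(
    marker = unlist(lapply(chroms$label, function(cc)
      paste0(cc, "_", seq_along(pos_list[[cc]])))),
    chrom = rep(chroms$label, lengths(pos_list)),
    pos_cM = unlist(pos_list)), chrom_order = chroms$label)

  sp <- cfg$subpopulations
  founder_ids <- unlist(lapply(seq_len(nrow(sp)), function(s)
    sprintf("%s_F%0*d", sp$name[s], max(2L, nchar(sp$n_founders[s])),
            seq_len(sp$n_founders[s]))))
  subpop <- setNames(rep(sp$name, sp$n_founders), founder_ids)
  n_f <- length(founder_ids)

  haplotypes <- list()
  for (cc in chroms$label) {
    nm <- length(pos_list[[cc]])
    hap <- matrix(0L, nrow = 2L * n_f, ncol = nm)
    row0 <- 0L
    for (s in seq_len(nrow(sp))) {
      p <- switch(as.character(sp$law[s]),
                  beta = stats::rbeta(nm, sp$alpha[s], sp$beta[s]),
                  fixed = rep(sp$p[s], nm),
                  stop("unknown frequency law: ", sp$law[s]))
      nh <- 2L * sp$n_founders[s]
      hap[row0 + seq_len(nh), ] <-
        matrix(stats::rbinom(nh * nm, 1L, rep(p, each = nh)), nrow = nh)
      row0 <- row0 + nh
    }
    haplotypes[[cc]] <- hap
  }
  geno <- do.call(cbind, lapply(chroms$label, function(cc) {
    h <- haplotypes[[cc]]
    odd <- seq(1L, nrow(h), by = 2L)
    h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  }))
  list(haplotypes = haplotypes,
       genotypes = genotype_matrix(geno, sample_ids = founder_ids,
                                   marker_ids = map$marker),
       map = map, founder_ids = founder_ids, subpop = subpop)
}

# whole-chromosome mosaic for founder haplotype with global label `lab`
founder_mosaic <- function(lab, length_cM)
  list(breaks = length_cM, origin = lab)

# slice a mosaic to (from, to], right endpoints clipped at `to`
mosaic_slice <- function(mosaic, from, to) {
  first_end <- which(mosaic$breaks >= to)[1L]
  if (is.na(first_end)) first_end <- length(mosaic$breaks)
  idx <- which(mosaic$breaks > from)
  idx <- idx[idx <= first_end]
  list(breaks = pmin(mosaic$breaks[idx], to), origin = mosaic$origin[idx])
}

# concatenate mosaic pieces, merging adjacent intervals of equal origin
mosaic_concat <- function(pieces) {
  br <- unlist(lapply(pieces, `[[`, "breaks"))
  org <- unlist(lapply(pieces, `[[`, "origin"))
  keep <- c(org[-length(org)] != org[-1L], TRUE)
  list(breaks = br[keep], origin = org[keep])
}

#' One simulated meiosis on one chromosome
#'
#' Crossovers follow the Haldane (no-interference) model: the crossover
#' count is Poisson with mean `length_cM / 100` (centimorgans to Morgans)
#' and positions are uniform on the chromosome; the starting parental
#' haplotype is a fair coin. The gamete mosaic splices the two parental
#' mosaics at the crossover points and always tiles the chromosome
#' exactly. Uses the current RNG state.
#'
#' @param parent list of the parent's two chromosome mosaics (`hap1`,
#'   `hap2`), each `list(breaks, origin)` with right endpoints ending at
#'   `length_cM`.
#' @param length_cM chromosome length.
#' @return a gamete mosaic `list(breaks, origin)`.
#' @export
meiosis <- function(parent, length_cM) {
  n_x <- stats::rpois(1L, length_cM / 100)
  cur <- sample.int(2L, 1L)
  if (n_x == 0L) return(parent[[cur]])
  xpos <- sort(stats::runif(n_x, 0, length_cM))
  cuts <- c(0, xpos, length_cM)
  pieces <- vector("list", length(cuts) - 1L)
  for (k in seq_len(length(cuts) - 1L)) {
    pieces[[k]] <- mosaic_slice(parent[[cur]], cuts[k], cuts[k + 1L])
    cur <- 3L - cur
  }
  mosaic_concat(pieces)
}

#' Simulate a full pedigree with truth IBD
#'
#' Simulates founders ([simulate_founders()]), then produces every
#' pedigree child by one meiosis per parent per chromosome (clones copy
#' both mosaics). Genotypes are read off the mosaics at the marker
#' positions; genotyping error (a call replaced by a uniformly chosen
#' different non-missing call with probability `error_rate`) and
#' missingness (probability `missing_rate`, per sample overridable) are
#' applied afterwards. Truth mosaics are recorded before corruption.
#'
#' Randomness is split into deterministic substreams of the single
#' configuration seed (founders: `seed`; meiosis: `seed + 1`; corruption:
#' `seed + 2`), so founder genotypes do not change when the pedigree does.
#'
#' @param cfg a [sim_config()].
#' @return list of class `splosh_sim`: `genotypes` ([genotype_matrix] of
#'   all samples, or `cfg$samples`), `map` ([genetic_map]), `truth`
#'   (`sim_truth`), `founders` (the [simulate_founders()] result),
#'   `subpop` (named vector, founders only), `config`.
#' @export
simulate_pedigree <- function(cfg) {
  fo <- simulate_founders(cfg)
  chroms <- cfg$chromosomes
  mosaics <- list()
  for (f in seq_along(fo$founder_ids)) {
    id <- fo$founder_ids[f]
    mosaics[[id]] <- lapply(seq_len(nrow(chroms)), function(k)
      list(hap1 = founder_mosaic(2L * f - 1L, chroms$length_cM[k]),
           hap2 = founder_mosaic(2L * f, chroms$length_cM[k])))
    names(mosaics[[id]]) <- chroms$label
  }

  ped <- cfg$pedigree
  if (!is.null(ped) && nrow(ped) > 0L) {
    set.seed(cfg$seed + 1L)
    for (r in seq_len(nrow(ped))) {
      id <- ped$id[r]
      if (id %in% names(mosaics)) stop("duplicate pedigree id: ", id)
      p1 <- ped$parent1[r]
      if (!p1 %in% names(mosaics))
        stop("pedigree id ", id, " references unresolved parent ", p1,
             " (parents must be founders or earlier rows; cycles are invalid)")
      if (ped$op[r] == "clone") {
        mosaics[[id]] <- mosaics[[p1]]
      } else {
        p2 <- ped$parent2[r]
        if (!p2 %in% names(mosaics))
          stop("pedigree id ", id, " references unresolved parent ", p2,
               " (parents must be founders or earlier rows; cycles are invalid)")
        mosaics[[id]] <- lapply(seq_len(nrow(chroms)), function(k) {
          cc <- chroms$label[k]
          list(hap1 = meiosis(mosaics[[p1]][[cc]], chroms$length_cM[k]),
               hap2 = meiosis(mosaics[[p2]][[cc]], chroms$length_cM[k]))
        })
        names(mosaics[[id]]) <- chroms$label
      }
    }
  }

  truth <- structure(list(mosaics = mosaics, chromosomes = chroms),
                     class = "sim_truth")
  all_ids <- names(mosaics)
  geno <- genotypes_from_mosaics(truth, fo, all_ids)

  set.seed(cfg$seed + 2L)
  dos <- unclass(geno)
  if (cfg$error_rate > 0) {
    hit <- which(stats::runif(length(dos)) < cfg$error_rate & !is.na(dos))
    if (length(hit))
      dos[hit] <- (dos[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
  }
  rates <- rep(cfg$missing_rate, nrow(dos))
  names(rates) <- rownames(dos)
  if (!is.null(cfg$sample_missing_rates)) {
    ov <- cfg$sample_missing_rates
    rates[names(ov)] <- ov
  }
  for (i in seq_len(nrow(dos))) {
    if (rates[i] > 0)
      dos[i, stats::runif(ncol(dos)) < rates[i]] <- NA_integer_
  }
  geno <- genotype_matrix(dos)
  if (!is.null(cfg$samples)) geno <- geno[cfg$samples, , drop = FALSE]

  structure(list(genotypes = geno, map = fo$map, truth = truth,
                 founders = fo, subpop = fo$subpop, config = cfg),
            class = "splosh_sim")
}

# origin label at each position for one mosaic (vectorized)
origin_at <- function(mosaic, pos) {
  idx <- findInterval(pos, mosaic$breaks, left.open = TRUE) + 1L
  mosaic$origin[pmin(idx, length(mosaic$origin))]
}

# read genotypes off mosaics for the given sample ids (error-free)
genotypes_from_mosaics <- function(truth, founders, ids) {
  chroms <- truth$chromosomes
  map <- founders$map
  blocks <- lapply(chroms$label, function(cc) {
    idx <- which(map$chrom == cc)
    list(chrom = cc, pos = map$pos_cM[idx])
  })
  rows <- lapply(ids, function(id) {
    unlist(lapply(seq_along(blocks), function(k) {
      b <- blocks[[k]]
      mo <- truth$mosaics[[id]][[b$chrom]]
      hap <- founders$haplotypes[[b$chrom]]
      a1 <- hap[cbind(origin_at(mo$hap1, b$pos), seq_along(b$pos))]
      a2 <- hap[cbind(origin_at(mo$hap2, b$pos), seq_along(b$pos))]
      a1 + a2
    }))
  })
  genotype_matrix(do.call(rbind, rows), sample_ids = ids,
                  marker_ids = map$marker)
}

#' True identity-by-descent segments for a sample pair
#'
#' Overlays the four founder-origin mosaics of the pair and reports the
#' intervals where the two samples share at least one (state 1) or both
#' (state 2) founder-haplotype origins; adjacent intervals with the same
#' state are merged. Shared state is the size of the maximal matching
#' between the two origin pairs (multiset intersection).
#'
#' @param truth a `sim_truth` from [simulate_pedigree()].
#' @param i,j sample ids.
#' @return data frame: `chrom`, `start_cM`, `end_cM`, `state` (1 or 2);
#'   state-0 intervals are omitted.
#' @export
true_ibd_segments <- function(truth, i, j) {
  for (id in c(i, j))
    if (!id %in% names(truth$mosaics)) stop("unknown sample id: ", id)
  out <- lapply(seq_len(nrow(truth$chromosomes)), function(k) {
    cc <- truth$chromosomes$label[k]
    L <- truth$chromosomes$length_cM[k]
    mi <- truth$mosaics[[i]][[cc]]
    mj <- truth$mosaics[[j]][[cc]]
    cuts <- sort(unique(c(0, mi$hap1$breaks, mi$hap2$breaks,
                          mj$hap1$breaks, mj$hap2$breaks, L)))
    mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
    a1 <- origin_at(mi$hap1, mids); a2 <- origin_at(mi$hap2, mids)
    b1 <- origin_at(mj$hap1, mids); b2 <- origin_at(mj$hap2, mids)
    # multiset intersection size of {a1,a2} and {b1,b2}
    state <- integer(length(mids))
    for (t in seq_along(mids)) {
      a <- c(a1[t], a2[t]); b <- c(b1[t], b2[t])
      m <- 0L
      for (x in a) {
        hit <- match(x, b)
        if (!is.na(hit)) { m <- m + 1L; b <- b[-hit] }
      }
      state[t] <- m
    }
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(chrom = cc, start_cM = cuts[starts], end_cM = cuts[ends + 1L],
               state = r$values, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[res$state >= 1L, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Total true shared length above a segment-length threshold
#'
#' Merges adjacent state-1/state-2 intervals into maximal shared runs,
#' keeps runs at least `threshold_cM` long and sums their lengths — the
#' truth quantity a shared-haplotype estimate should dominate on
#' error-free data.
#'
#' @inheritParams true_ibd_segments
#' @param threshold_cM minimum run length in cM.
#' @return total length in cM.
#' @export
true_shared_length <- function(truth, i, j, threshold_cM = 30) {
  seg <- true_ibd_segments(truth, i, j)
  if (nrow(seg) == 0L) return(0)
  total <- 0
  for (cc in unique(seg$chrom)) {
    s <- seg[seg$chrom == cc, , drop = FALSE]
    s <- s[order(s$start_cM), , drop = FALSE]
    # merge touching/overlapping shared intervals regardless of state
    start <- s$start_cM[1L]; end <- s$end_cM[1L]
    lens <- numeric(0)
    if (nrow(s) > 1L) for (r in 2L:nrow(s)) {
      if (s$start_cM[r] <= end + 1e-9) end <- max(end, s$end_cM[r])
      else { lens <- c(lens, end - start); start <- s$start_cM[r]; end <- s$end_cM[r] }
    }
    lens <- c(lens, end - start)
    total <- total + sum(lens[lens >= threshold_cM])
  }
  total
}

#' Write simulation truth IBD as a BED-like table
#'
#' @param truth a `sim_truth`.
#' @param pairs data frame with columns `id1`, `id2`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_ibd <- function(truth, pairs, path) {
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    seg <- true_ibd_segments(truth, pairs$id1[r], pairs$id2[r])
    if (nrow(seg) == 0L) return(NULL)
    cbind(id1 = pairs$id1[r], id2 = pairs$id2[r], seg)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id1 = character(0), id2 = character(0),
                      chrom = character(0), start_cM = numeric(0),
                      end_cM = numeric(0), state = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a simulation with labelled relationship-class pairs
#'
#' Convenience design generator used for validating the shared-haplotype
#' statistic: for each of `n_per_class` families it creates a clone pair,
#' a parent–offspring pair, a full-sib pair, a half-sib pair and an
#' unrelated founder pair, all from a single founder population.
#'
#' @param n_per_class number of pairs per relationship class.
#' @param chromosomes,markers_per_cM,seed passed to [sim_config()].
#' @param p fixed founder allele frequency (default 0.5).
#' @param missing_rate,error_rate corruption rates (default 0).
#' @return list with `sim` (a `splosh_sim`) and `pairs` (data frame:
#'   `class`, `id1`, `id2`).
#' @export
sim_relationship_pairs <- function(n_per_class = 50L,
                                   chromosomes = data.frame(
                                     label = sprintf("C%02d", 1:10),
                                     length_cM = rep(100, 10)),
                                   markers_per_cM = 1,
                                   p = 0.5,
                                   missing_rate = 0, error_rate = 0,
                                   seed = 1L) {
  # founders per family: 2 (PO) + 2 (FS) + 3 (HS) + 2 (unrelated) + 1 (clone)
  n_f <- n_per_class * 10L
  ped <- list()
  pairs <- list()
  fid <- function(k) sprintf("pop_F%0*d", max(2L, nchar(n_f)), k)
  for (fam in seq_len(n_per_class)) {
    b <- (fam - 1L) * 10L
    po_c <- sprintf("po_child%03d", fam)
    fs1 <- sprintf("fs_a%03d", fam); fs2 <- sprintf("fs_b%03d", fam)
    hs1 <- sprintf("hs_a%03d", fam); hs2 <- sprintf("hs_b%03d", fam)
    cl <- sprintf("clone%03d", fam)
    ped[[fam]] <- rbind(
      ped_cross(po_c, fid(b + 1L), fid(b + 2L)),
      ped_cross(fs1, fid(b + 3L), fid(b + 4L)),
      ped_cross(fs2, fid(b + 3L), fid(b + 4L)),
      ped_cross(hs1, fid(b + 5L), fid(b + 6L)),
      ped_cross(hs2, fid(b + 5L), fid(b + 7L)),
      ped_clone(cl, fid(b + 10L)))
    pairs[[fam]] <- data.frame(
      class = c("clone", "parent_offspring", "full_sib", "half_sib",
                "unrelated"),
      id1 = c(fid(b + 10L), fid(b + 1L), fs1, hs1, fid(b + 8L)),
      id2 = c(cl, po_c, fs2, hs2, fid(b + 9L)),
      stringsAsFactors = FALSE)
  }
  cfg <- sim_config(
    chromosomes = chromosomes, markers_per_cM = markers_per_cM,
    subpopulations = data.frame(name = "pop", n_founders = n_f,
                                law = "fixed", p = p),
    pedigree = do.call(rbind, ped),
    missing_rate = missing_rate, error_rate = error_rate, seed = seed)
  list(sim = simulate_pedigree(cfg), pairs = do.call(rbind, pairs))
}

#' Read a simulator configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; `chromosomes`,
#' `subpopulations` and `pedigree` are given as lists of records.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  args <- list()
  if (!is.null(y$chromosomes)) args$chromosomes <- to_df(y$chromosomes)
  if (!is.null(y$subpopulations)) args$subpopulations <- to_df(y$subpopulations)
  if (!is.null(y$pedigree)) {
    ped <- to_df(y$pedigree)
    if (!"op" %in% names(ped)) ped$op <- "cross"
    if (!"parent2" %in% names(ped)) ped$parent2 <- NA_character_
    args$pedigree <- ped
  }
  for (k in c("markers_per_cM", "missing_rate", "error_rate", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$sample_missing_rates))
    args$sample_missing_rates <- unlist(y$sample_missing_rates)
  if (!is.null(y$samples)) args$samples <- unlist(y$samples)
  do.call(sim_config, args)
}
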