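#' End-to-end run configuration
#'
#' Describes one analysis run: either file inputs (genotype table, map,
#' optional Norm R intensities) or a simulation ([sim_config()]) —
#' exactly one of the two — plus the QC, shared-haplotype and ordination
#' settings, the dataset modes to produce, and an output directory.
#'
#' The three dataset modes mirror the standard array-diversity design:
#' `"filtered"` (all QC-passing SNPs), `"map"` (the QC-passing SNPs
#' anchored to the genetic map) and `"splosh"` (the pairwise
#' shared-haplotype matrix computed from the map dataset).
#'
#' @param genotypes,map,intensities input file paths (`intensities`
#'   optional).
#' @param simulate a [sim_config()] instead of file inputs.
#' @param encoding,allele_defs passed to [read_genotype_table()].
#' @param qc a [qc_config()].
#' @param splosh a [splosh_config()].
#' @param datasets subset of `c("filtered", "map", "splosh")`.
#' @param scale scale columns before distance/PCA (default TRUE).
#' @param impute_method diagonal completion method, see
#'   [impute_self_cells()].
#' @param splosh_distance `"profile"` (Euclidean distance between sharing
#'   profiles, the default) or `"complement"` (total map length minus the
#'   pairwise value).
#' @param k number of principal components to keep (default 2).
#' @param export_formats distance export formats, see [export_distance()].
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, map = NULL, intensities = NULL,
                       simulate = NULL,
                       encoding = "AB", allele_defs = NULL,
                       qc = qc_config(), splosh = splosh_config(),
                       datasets = c("filtered", "map", "splosh"),
                       scale = TRUE,
                       impute_method = c("analytic", "iterative_pca"),
                       splosh_distance = c("profile", "complement"),
                       k = 2L,
                       export_formats = c("phylip_square",
                                          "nexus_distances"),
                       out_dir = "haploshare_run", seed = 1L) {
  has_files <- !is.null(genotypes) || !is.null(map)
  if (is.null(simulate) && !(!is.null(genotypes) && !is.null(map)))
    stop("provide either genotype+map file paths or a simulate config")
  if (!is.null(simulate) && has_files)
    stop("provide file inputs or a simulate config, not both")
  structure(list(genotypes = genotypes, map = map,
                 intensities = intensities, simulate = simulate,
                 encoding = encoding, allele_defs = allele_defs,
                 qc = qc, splosh = splosh,
                 datasets = match.arg(datasets, several.ok = TRUE),
                 scale = isTRUE(scale),
                 impute_method = match.arg(impute_method),
                 splosh_distance = match.arg(splosh_distance),
                 k = as.integer(k),
                 export_formats = export_formats,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror [run_config()]; `qc`, `splosh` and `simulate`
#' are nested mappings whose keys mirror [qc_config()], [splosh_config()]
#' and [sim_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("genotypes", "map", "intensities",
                                  "encoding", "datasets", "scale",
                                  "impute_method", "splosh_distance", "k",
                                  "export_formats", "out_dir", "seed"))]
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$splosh)) args$splosh <- do.call(splosh_config, y$splosh)
  if (!is.null(y$simulate_file))
    args$simulate <- read_sim_config(file.path(dirname(path),
                                               y$simulate_file))
  do.call(run_config, args)
}

log_stage <- function(con, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf(...), collapse = " "))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full shared-haplotype diversity pipeline
#'
#' Orchestrates QC filtering, genetic-map anchoring, pairwise SPLoSH
#' computation and the ordination outputs for each requested dataset
#' mode, writing every artifact (tables, matrices, trees, exports) under
#' `cfg$out_dir` and logging per-stage counts. Every artifact set is
#' stamped with a configuration fingerprint and the seed via the
#' `MANIFEST.txt` written at the end, so a run can be recognized and
#' reproduced.
#'
#' @param cfg a [run_config()].
#' @return a `run_report`: input/retained/anchored marker counts, per-rule
#'   QC attrition, overall and max per-sample missing percentages, the
#'   SPLoSH threshold, the top-5 SPLoSH pairs, per-dataset explained
#'   variance, and the artifact file list.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(cfg$out_dir, "log.txt"), "w")
  on.exit(close(logcon))
  artifacts <- character(0)
  emit <- function(name) {
    artifacts[length(artifacts) + 1L] <<- name
    file.path(cfg$out_dir, name)
  }

  # -- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    log_stage(logcon, "simulate", "seed=%d", cfg$simulate$seed)
    sim <- simulate_pedigree(cfg$simulate)
    g <- sim$genotypes; m <- sim$map; intens <- NULL
    write_genotype_table(g, emit("genotypes_input.tsv"))
    write_genetic_map(m, emit("map_input.tsv"))
  } else {
    log_stage(logcon, "read", "genotypes=%s map=%s", cfg$genotypes, cfg$map)
    g <- read_genotype_table(cfg$genotypes, encoding = cfg$encoding,
                             allele_defs = cfg$allele_defs)
    m <- read_genetic_map(cfg$map)
    intens <- if (!is.null(cfg$intensities))
      read_intensity_table(cfg$intensities) else NULL
    sim <- NULL
  }
  log_stage(logcon, "input", "%d samples x %d markers", nrow(g), ncol(g))

  # -- QC --------------------------------------------------------------
  qc <- apply_qc(g, cfg$qc, intens)
  gf <- qc$genotypes
  pct_missing <- 100 * mean(is.na(unclass(gf)))
  sample_missing <- 100 * rowMeans(is.na(unclass(gf)))
  log_stage(logcon, "qc", "retained %d of %d markers; %.2f%% missing",
            qc$report$n_retained, qc$report$n_input, pct_missing)
  write_qc_report(qc$report, g, emit("qc_report.tsv"))
  write_genotype_table(gf, emit("genotypes_filtered.tsv"))
  write_structure_file(gf, emit("structure_filtered.str"))

  # -- map anchoring ---------------------------------------------------
  anchored <- subset_to_map(gf, m)
  gm <- anchored$genotypes
  msum <- map_summary(anchored$map)
  log_stage(logcon, "map", "%d markers anchored (%d unmapped); %.1f cM map",
            ncol(gm), length(anchored$unmapped), msum$total_length)
  write_genotype_table(gm, emit("genotypes_map.tsv"))
  write_genetic_map(anchored$map, emit("map_anchored.tsv"))

  # -- SPLoSH ----------------------------------------------------------
  sp <- splosh_matrix(gm, anchored$map, cfg$splosh)
  write_splosh_matrix(sp, emit("splosh_matrix.tsv"))
  ut <- upper.tri(sp)
  ord <- order(sp[ut], decreasing = TRUE)
  idx <- which(ut, arr.ind = TRUE)[ord, , drop = FALSE]
  top_n <- min(5L, nrow(idx))
  top_pairs <- data.frame(
    id1 = rownames(sp)[idx[seq_len(top_n), 1L]],
    id2 = rownames(sp)[idx[seq_len(top_n), 2L]],
    splosh_cM = sp[ut][ord][seq_len(top_n)],
    pct_of_map = splosh_percent(sp[ut][ord][seq_len(top_n)], msum),
    stringsAsFactors = FALSE)
  log_stage(logcon, "splosh",
            "threshold %.1f cM; top pair %s/%s = %.1f cM (%.1f%% of map)",
            cfg$splosh$threshold_cM, top_pairs$id1[1L], top_pairs$id2[1L],
            top_pairs$splosh_cM[1L], top_pairs$pct_of_map[1L])
  audit <- splosh_pair(gm, anchored$map, top_pairs$id1[1L],
                       top_pairs$id2[1L], cfg$splosh)
  write_segment_audit(audit$segments, emit("splosh_segments_top_pair.tsv"),
                      pair = c(top_pairs$id1[1L], top_pairs$id2[1L]))

  # -- per-dataset ordination -----------------------------------------
  datasets <- list()
  explained <- list()
  for (ds in cfg$datasets) {
    x <- switch(ds,
      filtered = impute_self_cells(
        profile_distance(encode_snp_features(gf), scale = cfg$scale),
        method = cfg$impute_method),
      map = impute_self_cells(
        profile_distance(encode_snp_features(gm), scale = cfg$scale),
        method = cfg$impute_method),
      splosh = impute_self_cells(sp, method = cfg$impute_method))
    p <- pca_scores(unclass(x), k = cfg$k, scale = cfg$scale)
    d <- if (ds == "splosh") {
      if (cfg$splosh_distance == "complement") {
        dm <- attr(sp, "total_map_length") - unclass(x)
        diag(dm) <- 0
        structure(dm, class = c("distance_matrix", "matrix", "array"))
      } else profile_distance(unclass(x), scale = cfg$scale)
    } else x
    write_pca_scores(p, emit(sprintf("pca_%s.tsv", ds)))
    tr <- nj_tree(d)
    ape::write.tree(tr, emit(sprintf("tree_%s.nwk", ds)))
    for (fmt in cfg$export_formats) {
      ext <- if (fmt == "phylip_square") "phy" else "nex"
      export_distance(d, emit(sprintf("distance_%s.%s", ds, ext)), fmt)
    }
    datasets[[ds]] <- list(distance = d, pca = p)
    explained[[ds]] <- p$explained
    log_stage(logcon, "dataset", "%s: PC1 %.1f%%, PC2 %.1f%%", ds,
              p$explained[1L],
              if (length(p$explained) > 1L) p$explained[2L] else NA_real_)
  }

  # -- manifest & report ----------------------------------------------
  stamp <- fnv1a32(paste(deparse(cfg), collapse = ""))
  writeLines(c(sprintf("config_hash: %s", stamp),
               sprintf("seed: %d", cfg$seed),
               sprintf("artifact: %s", artifacts)),
             file.path(cfg$out_dir, "MANIFEST.txt"))

  report <- structure(list(
    n_samples = nrow(g),
    n_markers_input = ncol(g),
    qc_rule_counts = qc$report$rule_counts,
    n_retained = qc$report$n_retained,
    n_map_anchored = ncol(gm),
    n_unmapped = length(anchored$unmapped),
    pct_missing = pct_missing,
    max_sample_missing = max(sample_missing),
    max_sample_missing_id = names(which.max(sample_missing)),
    total_map_length = msum$total_length,
    threshold_cM = cfg$splosh$threshold_cM,
    top_pairs = top_pairs,
    explained = explained,
    config_hash = stamp, seed = cfg$seed,
    out_dir = cfg$out_dir, artifacts = artifacts,
    datasets = datasets, splosh = sp, sim = sim),
    class = "run_report")
  log_stage(logcon, "done", "%d artifacts in %s", length(artifacts),
            cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("haploshare run [%s, seed %d]\n", x$config_hash, x$seed))
  cat(sprintf("  input:    %d samples x %d markers\n", x$n_samples,
              x$n_markers_input))
  cat(sprintf("  filtered: %d SNPs retained (%.2f%% missing, max %.1f%% in %s)\n",
              x$n_retained, x$pct_missing, x$max_sample_missing,
              x$max_sample_missing_id))
  cat(sprintf("  map:      %d SNPs anchored; map length %.1f cM\n",
              x$n_map_anchored, x$total_map_length))
  cat(sprintf("  splosh:   threshold %.1f cM; top pair %s/%s = %.1f cM (%.1f%%)\n",
              x$threshold_cM, x$top_pairs$id1[1], x$top_pairs$id2[1],
              x$top_pairs$splosh_cM[1], x$top_pairs$pct_of_map[1]))
  invisible(x)
}

#' Quantitative concordance of two dataset views
#'
#' Measures how similarly two dataset modes (e.g. SNP-based vs
#' shared-haplotype-based) place the samples: a Mantel correlation of the
#' two distance matrices with a permutation p-value, and the adjusted
#' Rand index between k-means clusterings of the first two principal
#' components of each view.
#'
#' @param d_a,d_b square distance matrices over the same samples.
#' @param pca_a,pca_b `pca_result`s over the same samples (only the first
#'   two score columns are used).
#' @param k number of k-means clusters (default 3).
#' @param permutations Mantel permutations (default 999).
#' @param seed seed controlling permutations and k-means restarts.
#' @return list: `mantel_r`, `mantel_p`, `ari`.
#' @export
compare_datasets <- function(d_a, d_b, pca_a, pca_b, k = 3L,
                             permutations = 999L, seed = 1L) {
  d_a <- as.matrix(unclass(d_a)); d_b <- as.matrix(unclass(d_b))
  if (!identical(rownames(d_a), rownames(d_b)))
    stop("the two datasets cover different sample sets")
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(d_a), stats::as.dist(d_b),
                      permutations = permutations)
  ka <- stats::kmeans(pca_a$scores[, 1:2], centers = k, nstart = 20L)
  kb <- stats::kmeans(pca_b$scores[, 1:2], centers = k, nstart = 20L)
  list(mantel_r = unname(mt$statistic), mantel_p = mt$signif,
       ari = mclust::adjustedRandIndex(ka$cluster, kb$cluster))
}

#' Best label-matching accuracy of a clustering
#'
#' Fraction of samples assigned to the right group under the best
#' one-to-one relabelling of cluster ids to true labels (exhaustive over
#' permutations; intended for small numbers of clusters).
#'
#' @param cluster integer/character cluster assignment.
#' @param truth true group labels, same length.
#' @return accuracy in \[0, 1\].
#' @export
cluster_accuracy <- function(cluster, truth) {
  cl <- as.integer(factor(cluster))
  tr <- as.integer(factor(truth))
  ks <- max(cl, tr)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- 0
  for (p in perms(seq_len(ks)))
    best <- max(best, mean(p[cl] == tr))
  best
}
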