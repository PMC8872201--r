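#' SNP quality-control configuration
#'
#' Thresholds for the four marker-level array QC rules:
#'
#' 1. `MISSING_RATE` — drop markers whose missing-call fraction is strictly
#'    greater than `max_missing_rate` (default 0.02, i.e. >2% missing).
#' 2. `NO_TWO_HOM` — drop markers at which the two homozygous classes are
#'    not both observed among non-missing calls.
#' 3. `MONOMORPHIC` — drop markers whose non-missing calls are all
#'    identical.
#' 4. `NULL_ALLELE` — drop markers whose Norm R intensity spread exceeds
#'    `normr_spread_threshold` (default 0.09); wide Norm R spread is the
#'    classic signature of a null (non-hybridizing) allele segregating at
#'    the locus. The spread statistic is pluggable: standard deviation
#'    (default) or interquartile range of the non-missing Norm R values.
#'
#' @param max_missing_rate fraction in \[0,1\], default 0.02.
#' @param normr_spread_threshold non-negative, default 0.09.
#' @param require_two_homozygous logical, default TRUE (rule 2 active).
#' @param require_polymorphic logical, default TRUE (rule 3 active).
#' @param normr_statistic `"sd"` (default) or `"iqr"`.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(max_missing_rate = 0.02,
                      normr_spread_threshold = 0.09,
                      require_two_homozygous = TRUE,
                      require_polymorphic = TRUE,
                      normr_statistic = c("sd", "iqr")) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            normr_spread_threshold >= 0)
  structure(list(max_missing_rate = max_missing_rate,
                 normr_spread_threshold = normr_spread_threshold,
                 require_two_homozygous = isTRUE(require_two_homozygous),
                 require_polymorphic = isTRUE(require_polymorphic),
                 normr_statistic = match.arg(normr_statistic)),
            class = "qc_config")
}

#' Per-marker call statistics
#'
#' @param g a non-empty [genotype_matrix].
#' @return data frame with one row per marker: `marker`, `missing_rate`,
#'   `n_hom_a`, `n_het`, `n_hom_b`, `n_missing`,
#'   `n_distinct_nonmissing_calls`. Class counts always sum to the sample
#'   count.
#' @export
snp_stats <- function(g) {
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
  dos <- unclass(g)
  n_hom_a <- colSums(dos == 0L, na.rm = TRUE)
  n_het <- colSums(dos == 1L, na.rm = TRUE)
  n_hom_b <- colSums(dos == 2L, na.rm = TRUE)
  n_missing <- colSums(is.na(dos))
  distinct <- (n_hom_a > 0L) + (n_het > 0L) + (n_hom_b > 0L)
  data.frame(marker = colnames(g),
             missing_rate = n_missing / nrow(g),
             n_hom_a = n_hom_a, n_het = n_het, n_hom_b = n_hom_b,
             n_missing = n_missing,
             n_distinct_nonmissing_calls = as.integer(distinct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply marker-level quality-control filters
#'
#' Evaluates the four QC rules of [qc_config()] as independent predicates:
#' every rule a marker fails is tagged, nothing is short-circuited, so the
#' attrition report is order-independent and reproducible. The
#' `NULL_ALLELE` rule needs a Norm R intensity matrix; when none is given
#' the rule is skipped and flagged as not evaluated in the report.
#'
#' @param g a [genotype_matrix].
#' @param cfg a [qc_config()].
#' @param intensities optional numeric samples x markers Norm R matrix with
#'   axes matching `g`.
#' @return list with `genotypes` (filtered [genotype_matrix]) and `report`
#'   (class `qc_report`): `retained` marker ids in input order, `dropped`
#'   named list of rule-tag vectors, `rule_counts`, `n_input`,
#'   `n_retained`, `null_allele_evaluated`.
#' @export
apply_qc <- function(g, cfg = qc_config(), intensities = NULL) {
  stats <- snp_stats(g)
  tags <- setNames(vector("list", ncol(g)), colnames(g))

  fail_miss <- stats$missing_rate > cfg$max_missing_rate
  fail_hom <- if (cfg$require_two_homozygous)
    stats$n_hom_a == 0L | stats$n_hom_b == 0L else logical(ncol(g))
  fail_mono <- if (cfg$require_polymorphic)
    stats$n_distinct_nonmissing_calls <= 1L else logical(ncol(g))

  fail_null <- logical(ncol(g))
  null_eval <- !is.null(intensities)
  if (null_eval) {
    if (!identical(dim(intensities), dim(g)) ||
        !identical(rownames(intensities), rownames(g)) ||
        !identical(colnames(intensities), colnames(g)))
      stop("intensity matrix axes do not align with the genotype matrix")
    spread <- apply(intensities, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(0)
      switch(cfg$normr_statistic,
             sd = stats::sd(v),
             iqr = stats::IQR(v))
    })
    fail_null <- spread > cfg$normr_spread_threshold
  }

  for (j in seq_len(ncol(g))) {
    t <- character(0)
    if (fail_miss[j]) t <- c(t, "MISSING_RATE")
    if (fail_hom[j]) t <- c(t, "NO_TWO_HOM")
    if (fail_mono[j]) t <- c(t, "MONOMORPHIC")
    if (fail_null[j]) t <- c(t, "NULL_ALLELE")
    tags[[j]] <- t
  }
  drop <- lengths(tags) > 0L
  report <- structure(list(
    retained = colnames(g)[!drop],
    dropped = tags[drop],
    rule_counts = c(MISSING_RATE = sum(fail_miss),
                    NO_TWO_HOM = sum(fail_hom),
                    MONOMORPHIC = sum(fail_mono),
                    NULL_ALLELE = sum(fail_null)),
    n_input = ncol(g),
    n_retained = sum(!drop),
    null_allele_evaluated = null_eval), class = "qc_report")
  list(genotypes = g[, !drop, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("SNP QC: retained %d of %d markers (%d dropped)\n",
              x$n_retained, x$n_input, x$n_input - x$n_retained))
  for (r in names(x$rule_counts))
    cat(sprintf("  %-13s %d\n", r, x$rule_counts[[r]]))
  if (!x$null_allele_evaluated)
    cat("  (NULL_ALLELE rule not evaluated: no intensity data)\n")
  invisible(x)
}

#' Write a QC attrition report as a delimited table
#'
#' One row per input marker with its status and the tags of every rule it
#' failed, plus a one-line summary comment on top.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param g the input [genotype_matrix] the report was computed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, g, path) {
  all_markers <- colnames(g)
  status <- ifelse(all_markers %in% report$retained, "retained", "dropped")
  tagtxt <- vapply(all_markers, function(mk) {
    t <- report$dropped[[mk]]
    if (is.null(t)) "" else paste(t, collapse = ";")
  }, "")
  pct_missing <- 100 * mean(is.na(unclass(g)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# retained %d of %d SNPs, %.2f%% missing data overall",
                     report$n_retained, report$n_input, pct_missing), con)
  utils::write.table(
    data.frame(marker = all_markers, status = status, rules_failed = tagtxt),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
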