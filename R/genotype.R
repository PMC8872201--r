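#' Construct a genotype matrix of unphased diploid calls
#'
#' The package-internal representation of an unphased diploid SNP call set:
#' an integer matrix with samples in rows and markers in columns, coded as
#' allele-B dosage. Every cell is one of `0` (homozygous for allele A,
#' `HOM_A`), `1` (heterozygous, `HET`), `2` (homozygous for allele B,
#' `HOM_B`) or `NA` (missing). All downstream code (QC, shared-haplotype
#' scanning, ordination) works on this 4-value domain; raw call encodings
#' are collapsed at read time.
#'
#' @param calls a samples x markers matrix, either integer dosage
#'   (0/1/2/NA) or character calls in `{"AA","AB","BA","BB"}` /
#'   `{"HOM_A","HET","HOM_B"}` with `NA` for missing.
#' @param sample_ids character vector of unique sample labels; defaults to
#'   `rownames(calls)`.
#' @param marker_ids character vector of unique marker labels; defaults to
#'   `colnames(calls)`.
#' @return an object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(rbind(S1 = c(m1 = "AA", m2 = "AB", m3 = "BB")))
#' genotype_calls(g)
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            marker_ids = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  if (is.character(calls)) {
    code <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L,
              HOM_A = 0L, HET = 1L, HOM_B = 2L)
    bad <- setdiff(unique(calls[!is.na(calls)]), names(code))
    if (length(bad) > 0L)
      stop("unrecognized genotype calls: ", paste(bad, collapse = ", "))
    m <- matrix(unname(code[calls]), nrow = nrow(calls))
  } else {
    m <- calls
    storage.mode(m) <- "integer"
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(m)))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(m) || length(marker_ids) != ncol(m))
    stop("id lengths do not match call matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  bad <- m[!is.na(m)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype dosages must be 0, 1, 2 or NA")
  dimnames(m) <- list(sample_ids, marker_ids)
  structure(m, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, class = c("genotype_matrix", "matrix", "array"))
}

#' Character view of genotype calls
#'
#' @param g a [genotype_matrix].
#' @return character matrix with cells in `{"HOM_A","HET","HOM_B"}` and `NA`
#'   for missing.
#' @export
genotype_calls <- function(g) {
  lev <- c("HOM_A", "HET", "HOM_B")
  out <- matrix(lev[unclass(g) + 1L], nrow = nrow(g), dimnames = dimnames(g))
  out
}

#' Numeric dosage features for ordination
#'
#' Recodes calls to an allele-B dosage table suitable for distance and PCA
#' computations: `HOM_A` -> 0, `HET` -> 1, `HOM_B` -> 2. Missing calls stay
#' `NA` (they are handled downstream by pairwise-complete distances or
#' imputation, never silently zeroed).
#'
#' @param g a [genotype_matrix].
#' @return numeric samples x markers matrix with `NA` for missing calls.
#' @export
encode_snp_features <- function(g) {
  out <- unclass(g)
  storage.mode(out) <- "double"
  out
}

sample_ids <- function(g) rownames(g)
marker_ids <- function(g) colnames(g)
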