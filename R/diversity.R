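#' Euclidean distance between sample profiles
#'
#' Computes the pairwise Euclidean distance matrix over the rows of a
#' numeric feature table. For a SPLoSH matrix the features are the
#' per-sample sharing profiles (each sample's row of SPLoSH values), so
#' two samples are close when they share haplotypes with the same set of
#' varieties. Columns can be standardized first; zero-variance columns are
#' dropped with a message since they cannot be scaled. Cells may be `NA`
#' (e.g. missing genotype dosages): distances then use the
#' pairwise-complete rescaling of [stats::dist()].
#'
#' @param x numeric samples x features matrix (or a `splosh_matrix`).
#' @param scale logical; standardize columns to unit variance first.
#' @return a symmetric `distance_matrix` (square numeric matrix, zero
#'   diagonal).
#' @export
profile_distance <- function(x, scale = TRUE) {
  x <- as.matrix(unclass(x))
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (scale) {
    v <- apply(x, 2L, stats::var, na.rm = TRUE)
    zero <- !is.na(v) & v == 0
    if (any(zero)) {
      message("dropping ", sum(zero), " zero-variance column(s) before scaling")
      x <- x[, !zero, drop = FALSE]
    }
    x <- base::scale(x)
  }
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  diag(d) <- 0
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Fill in the self-comparison cells of a pairwise matrix
#'
#' Pairwise sharing tools leave the diagonal (an individual against
#' itself) undefined. Two completion methods are provided:
#'
#' * `analytic`: self-sharing is complete, so a SPLoSH diagonal is set to
#'   the total map length and a distance diagonal to 0.
#' * `iterative_pca`: low-rank EM completion. Missing cells are
#'   initialized at the observed column means, then the matrix is
#'   repeatedly approximated by its rank-`rank` truncated SVD and the
#'   missing cells are replaced by the approximation, until successive
#'   imputed values change by less than `tol` (default 1e-6) or `max_iter`
#'   iterations (default 1000).
#'
#' @param s a `splosh_matrix` or `distance_matrix`, or a plain numeric
#'   matrix with `NA`s in the cells to complete.
#' @param method `"analytic"` (default) or `"iterative_pca"`.
#' @param cells which cells are treated as missing: `"diagonal"` (default)
#'   or `"na"` (every `NA` cell).
#' @param rank,tol,max_iter EM parameters for `iterative_pca`.
#' @return the completed matrix, same class as the input.
#' @export
impute_self_cells <- function(s, method = c("analytic", "iterative_pca"),
                              cells = c("diagonal", "na"),
                              rank = 2L, tol = 1e-6, max_iter = 1000L) {
  method <- match.arg(method)
  cells <- match.arg(cells)
  m <- unclass(s)
  miss <- if (cells == "diagonal") {
    mm <- matrix(FALSE, nrow(m), ncol(m)); diag(mm) <- TRUE; mm
  } else is.na(m)
  if (method == "analytic") {
    if (cells == "na" && any(is.na(m) & !diag(nrow(m))))
      stop("analytic completion only handles diagonal cells")
    fill <- if (inherits(s, "splosh_matrix")) {
      total <- attr(s, "total_map_length")
      if (is.null(total)) stop("splosh_matrix lacks total_map_length")
      total
    } else if (inherits(s, "distance_matrix")) 0
    else stop("analytic completion needs a splosh_matrix or distance_matrix")
    diag(m) <- fill
  } else {
    m[miss] <- NA
    mu <- colMeans(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
    prev <- m[miss]
    for (it in seq_len(max_iter)) {
      sv <- svd(m, nu = rank, nv = rank)
      approx <- sv$u %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
      m[miss] <- approx[miss]
      if (max(abs(m[miss] - prev)) < tol) break
      prev <- m[miss]
    }
  }
  attributes(m) <- attributes(unclass(s))
  class(m) <- class(s)
  m
}

#' Principal component analysis with explained-variance percentages
#'
#' Centered (and optionally column-standardized) PCA of a complete numeric
#' table via [stats::prcomp()]. Zero-variance columns are dropped before
#' scaling. Component signs are fixed deterministically: within each
#' component the loading of largest magnitude is made positive, so
#' repeated runs and platforms agree.
#'
#' @param x complete numeric samples x features matrix (impute first; see
#'   [impute_self_cells()]).
#' @param k number of components to keep (default `min(dim)` capped at 10).
#' @param scale logical; standardize columns (default TRUE).
#' @return object of class `pca_result`: `scores` (samples x k),
#'   `explained` (percent variance per kept component, non-increasing),
#'   `loadings`, `sdev` (all components).
#' @export
pca_scores <- function(x, k = NULL, scale = TRUE) {
  x <- as.matrix(unclass(x))
  if (any(!is.finite(x))) stop("input contains non-finite cells; impute first")
  if (scale) {
    v <- apply(x, 2L, stats::var)
    if (any(v == 0)) {
      message("dropping ", sum(v == 0), " zero-variance column(s) before scaling")
      x <- x[, v > 0, drop = FALSE]
    }
  }
  kmax <- min(nrow(x) - 1L, ncol(x))
  k <- min(k %||% min(kmax, 10L), kmax)
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  expl <- 100 * p$sdev^2 / sum(p$sdev^2)
  scores <- p$x[, seq_len(k), drop = FALSE]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    if (load[which.max(abs(load[, c])), c] < 0) {
      load[, c] <- -load[, c]
      scores[, c] <- -scores[, c]
    }
  }
  structure(list(scores = scores, explained = expl[seq_len(k)],
                 loadings = load, sdev = p$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n  explained (%):",
      paste(sprintf("%.1f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]). Negative
#' branch lengths, which NJ can produce on non-additive distances, are
#' clamped to zero with the deficit moved onto the sister branch so that
#' path lengths through the parent node are preserved.
#'
#' @param d a `distance_matrix` (square symmetric, >= 3 samples).
#' @return an [ape::as.phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(unclass(d))
  if (nrow(d) < 3L) stop("need at least 3 samples for a tree")
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative branches, shifting the deficit to the sister edge
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs) > 0L)
      tr$edge.length[sibs] <- tr$edge.length[sibs] + tr$edge.length[e] /
        length(sibs)
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Export a distance matrix for external phylogenetics tools
#'
#' Writes `phylip_square` (first line the number of taxa, then one row per
#' taxon: label followed by the full distance row) or `nexus_distances`
#' (TAXA block plus a DISTANCES block with `triangle=both`). Labels are
#' sanitized (whitespace to underscores); when any label changes, a
#' tab-delimited mapping file `<path>.labels.tsv` is written alongside.
#'
#' @param d a `distance_matrix` or square labelled numeric matrix.
#' @param path output path.
#' @param format `"phylip_square"` or `"nexus_distances"`.
#' @return `path`, invisibly.
#' @export
export_distance <- function(d, path,
                            format = c("phylip_square", "nexus_distances")) {
  format <- match.arg(format)
  d <- as.matrix(unclass(d))
  labels <- rownames(d)
  clean <- gsub("[[:space:]]+", "_", labels)
  if (anyDuplicated(clean))
    stop("duplicate labels after sanitization: ",
         paste(unique(clean[duplicated(clean)]), collapse = ", "))
  if (!identical(clean, labels))
    utils::write.table(data.frame(original = labels, sanitized = clean),
                       paste0(path, ".labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(d)
  fmt_row <- function(i) paste(sprintf("%.10g", d[i, ]), collapse = " ")
  if (format == "phylip_square") {
    writeLines(sprintf("%5d", n), con)
    for (i in seq_len(n))
      writeLines(paste(sprintf("%-12s", clean[i]), fmt_row(i)), con)
  } else {
    writeLines(c("#NEXUS", "", "BEGIN TAXA;",
                 sprintf("  DIMENSIONS NTAX=%d;", n),
                 paste0("  TAXLABELS ", paste(clean, collapse = " "), ";"),
                 "END;", "", "BEGIN DISTANCES;",
                 "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX"), con)
    for (i in seq_len(n))
      writeLines(paste("   ", clean[i], fmt_row(i)), con)
    writeLines(c("  ;", "END;"), con)
  }
  invisible(path)
}

#' Read distance matrices written by [export_distance()]
#'
#' @param path file path.
#' @return square numeric matrix with labels.
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  rows <- strsplit(trimws(lines[2:(n + 1L)]), "[ \t]+")
  labels <- vapply(rows, `[[`, "", 1L)
  d <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}

#' @rdname read_phylip_distance
#' @export
read_nexus_distance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1L]
  end <- which(trimws(lines) == ";" & seq_along(lines) > start)[1L]
  rows <- strsplit(trimws(lines[(start + 1L):(end - 1L)]), "[ \t]+")
  labels <- vapply(rows, `[[`, "", 1L)
  n <- length(labels)
  d <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}

#' Write PCA scores as a delimited table
#'
#' @param p a `pca_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca_scores <- function(p, path) {
  df <- data.frame(Sample = rownames(p$scores), p$scores,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# explained variance (%): ",
                    paste(sprintf("%.2f", p$explained), collapse = ", ")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
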