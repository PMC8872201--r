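#' Configuration for shared-haplotype (SPLoSH) computation
#'
#' @param threshold_cM minimum potential segment length, in centimorgans,
#'   for a segment to count towards the summed value. The comparison is
#'   inclusive: a segment of exactly `threshold_cM` counts. Default 30 cM.
#' @param missing_is_compatible logical, default TRUE. A missing call can
#'   never exhibit opposite homozygosity, so by default it does not break a
#'   segment — which is also why heavy missingness inflates SPLoSH values.
#' @param missing_breaker_run strict-mode sensitivity knob: a run of at
#'   least this many consecutive markers at which either sample is missing
#'   is treated as a segment breaker. Default `Inf` (off).
#' @return an object of class `splosh_config`.
#' @export
splosh_config <- function(threshold_cM = 30, missing_is_compatible = TRUE,
                          missing_breaker_run = Inf) {
  stopifnot(threshold_cM >= 0, missing_breaker_run >= 1)
  structure(list(threshold_cM = threshold_cM,
                 missing_is_compatible = isTRUE(missing_is_compatible),
                 missing_breaker_run = missing_breaker_run),
            class = "splosh_config")
}

#' Classify one unphased call pair as compatible or incompatible
#'
#' Two unphased diploid calls can lie on a shared haplotype if and only if
#' they share at least one allele. The only configuration that excludes
#' sharing is the opposite-homozygote pair (`HOM_A` vs `HOM_B`). A missing
#' call cannot exclude sharing and is compatible with everything (unless
#' `missing_is_compatible` is FALSE).
#'
#' @param call_i,call_j dosage-coded calls (0/1/2/`NA`); vectorized.
#' @param missing_is_compatible see [splosh_config()].
#' @return character vector of `"COMPATIBLE"` / `"INCOMPATIBLE"`.
#' @export
classify_compatibility <- function(call_i, call_j,
                                   missing_is_compatible = TRUE) {
  inc <- incompatible_calls(as.integer(call_i), as.integer(call_j),
                            missing_is_compatible)
  ifelse(inc, "INCOMPATIBLE", "COMPATIBLE")
}

# Logical vector: TRUE where the pair of calls breaks a shared haplotype.
incompatible_calls <- function(gi, gj, missing_is_compatible = TRUE) {
  inc <- (gi == 0L & gj == 2L) | (gi == 2L & gj == 0L)
  miss <- is.na(gi) | is.na(gj)
  inc[miss] <- !missing_is_compatible
  inc
}

# Apply the strict missing-run breaker: runs of >= k consecutive
# either-missing markers become incompatible.
apply_missing_breaker <- function(inc, miss, k) {
  if (!is.finite(k) || !any(miss)) return(inc)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= k)
  for (w in long) inc[starts[w]:ends[w]] <- TRUE
  inc
}

#' Enumerate potential shared-haplotype segments on one chromosome
#'
#' A potential segment is a maximal run of compatible markers. Its
#' potential length is bounded by the evidence against sharing: the lower
#' bound is the position of the nearest incompatible marker before the run
#' (or the chromosome span minimum if there is none) and the upper bound
#' the position of the nearest incompatible marker after it (or the span
#' maximum). Segments never cross chromosomes and always contain at least
#' one marker.
#'
#' @param calls_i,calls_j dosage-coded calls of the two samples, aligned
#'   with `positions` along one chromosome.
#' @param positions non-decreasing cM positions.
#' @param span numeric length-2 `(min, max)` of the chromosome's mapped
#'   extent; defaults to `range(positions)`.
#' @param chrom chromosome label recorded in the output.
#' @param cfg a [splosh_config()].
#' @return data frame of segments: `chrom`, `first_idx`, `last_idx`,
#'   `lower_cM`, `upper_cM`, `length_cM`, `n_markers`.
#' @export
find_potential_segments <- function(calls_i, calls_j, positions,
                                    span = range(positions), chrom = "chr",
                                    cfg = splosh_config()) {
  if (length(calls_i) != length(calls_j) ||
      length(calls_i) != length(positions))
    stop("calls and positions have mismatching lengths")
  if (is.unsorted(positions)) stop("positions must be non-decreasing")
  gi <- as.integer(calls_i); gj <- as.integer(calls_j)
  inc <- incompatible_calls(gi, gj, cfg$missing_is_compatible)
  inc <- apply_missing_breaker(inc, is.na(gi) | is.na(gj),
                               cfg$missing_breaker_run)
  segs <- segment_runs(inc, positions, span)
  data.frame(chrom = if (nrow(segs)) chrom else character(0),
             segs, stringsAsFactors = FALSE)
}

# Core run scanner shared by the exported segment/pair/matrix functions.
# inc: logical incompatibility vector; positions aligned; span = c(lo, hi).
segment_runs <- function(inc, positions, span) {
  if (length(inc) == 0L || all(inc))
    return(data.frame(first_idx = integer(0), last_idx = integer(0),
                      lower_cM = numeric(0), upper_cM = numeric(0),
                      length_cM = numeric(0), n_markers = integer(0)))
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  s <- starts[keep]; e <- ends[keep]
  lower <- ifelse(s > 1L, positions[pmax(s - 1L, 1L)], span[1L])
  upper <- ifelse(e < length(inc), positions[pmin(e + 1L, length(inc))],
                  span[2L])
  data.frame(first_idx = s, last_idx = e,
             lower_cM = lower, upper_cM = upper,
             length_cM = upper - lower, n_markers = e - s + 1L)
}

# Split an anchored genotype/map pair into per-chromosome index blocks.
# Returns list of list(chrom, idx, pos, span).
chromosome_blocks <- function(map) {
  lapply(intersect(map_chrom_order(map), unique(map$chrom)), function(cc) {
    idx <- which(map$chrom == cc)
    p <- map$pos_cM[idx]
    list(chrom = cc, idx = idx, pos = p, span = c(min(p), max(p)))
  })
}

# Summed potential length for one pair given precomputed blocks.
splosh_value_blocks <- function(gi, gj, blocks, cfg) {
  total <- 0
  for (b in blocks) {
    ii <- b$idx
    inc <- incompatible_calls(gi[ii], gj[ii], cfg$missing_is_compatible)
    if (is.finite(cfg$missing_breaker_run))
      inc <- apply_missing_breaker(inc, is.na(gi[ii]) | is.na(gj[ii]),
                                   cfg$missing_breaker_run)
    segs <- segment_runs(inc, b$pos, b$span)
    ok <- segs$length_cM >= cfg$threshold_cM
    if (any(ok)) total <- total + sum(segs$length_cM[ok])
  }
  total
}

#' Summed potential length of shared haplotypes for one sample pair
#'
#' Scans every chromosome of the anchored genotype matrix for maximal
#' compatible runs, bounds each run by the flanking incompatible markers
#' (or the chromosome span ends), and sums the potential lengths of all
#' runs at least `threshold_cM` long.
#'
#' @param g a [genotype_matrix] anchored to `m` (same markers, map order;
#'   see [subset_to_map()]).
#' @param m the matching [genetic_map].
#' @param i,j sample ids (or row indices).
#' @param cfg a [splosh_config()].
#' @return list with `value` (cM) and `segments` (data frame over all
#'   chromosomes, with a `counted` column marking segments passing the
#'   threshold).
#' @export
splosh_pair <- function(g, m, i, j, cfg = splosh_config()) {
  check_anchored(g, m)
  i <- resolve_sample(g, i); j <- resolve_sample(g, j)
  blocks <- chromosome_blocks(m)
  gi <- unclass(g)[i, ]; gj <- unclass(g)[j, ]
  segs <- do.call(rbind, lapply(blocks, function(b) {
    find_potential_segments(gi[b$idx], gj[b$idx], b$pos, b$span, b$chrom, cfg)
  }))
  segs$counted <- segs$length_cM >= cfg$threshold_cM
  list(value = sum(segs$length_cM[segs$counted]), segments = segs)
}

#' Pairwise SPLoSH matrix
#'
#' Computes the summed potential length of shared haplotypes for every
#' unordered sample pair once and mirrors it, giving a symmetric samples x
#' samples matrix in centimorgans. The diagonal is the self-comparison
#' (for a sample with no missing data it equals the sum of chromosome
#' spans that pass the threshold).
#'
#' @inheritParams splosh_pair
#' @return a numeric matrix of class `splosh_matrix` with attributes
#'   `threshold_cM` and `total_map_length`.
#' @export
splosh_matrix <- function(g, m, cfg = splosh_config()) {
  check_anchored(g, m)
  if (nrow(g) < 2L) stop("need at least 2 samples")
  blocks <- chromosome_blocks(m)
  dos <- unclass(g)
  n <- nrow(dos)
  out <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) {
    gi <- dos[i, ]
    for (j in i:n) {
      v <- splosh_value_blocks(gi, dos[j, ], blocks, cfg)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  total <- sum(vapply(blocks, function(b) diff(b$span), 0))
  structure(out, class = c("splosh_matrix", "matrix", "array"),
            threshold_cM = cfg$threshold_cM, total_map_length = total)
}

#' @export
print.splosh_matrix <- function(x, ...) {
  cat(sprintf(paste0("splosh_matrix: %d samples, threshold %.1f cM, ",
                     "map length %.1f cM\n"),
              nrow(x), attr(x, "threshold_cM"), attr(x, "total_map_length")))
  invisible(x)
}

#' Express a SPLoSH value as a percentage of the genetic map
#'
#' @param value SPLoSH value in cM.
#' @param summary a [map_summary()] (its `total_length` is the denominator)
#'   or a single positive number taken as the total map length in cM.
#' @return percentage, rounded to one decimal place.
#' @export
splosh_percent <- function(value, summary) {
  total <- if (is.list(summary)) summary$total_length else summary
  if (!is.numeric(total) || total <= 0) stop("total map length must be > 0")
  round(100 * value / total, 1)
}

#' Write / read a SPLoSH (or any square labelled) matrix
#'
#' Square delimited table with sample ids as both header and first column.
#'
#' @param x matrix with matching row/column names.
#' @param path file path.
#' @param delim delimiter, default tab.
#' @return `write_splosh_matrix`: `path` invisibly; `read_splosh_matrix`:
#'   the numeric matrix.
#' @export
write_splosh_matrix <- function(x, path, delim = "\t") {
  df <- data.frame(Sample = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_splosh_matrix
#' @export
read_splosh_matrix <- function(path, delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  tab <- utils::read.table(path, sep = delim, header = TRUE, row.names = 1,
                           check.names = FALSE, comment.char = "")
  as.matrix(tab)
}

#' Write a per-pair segment audit trail
#'
#' BED-like delimited table of the potential shared-haplotype segments of
#' one pair: chromosome, lower/upper bound (cM), potential length, marker
#' count, and whether the segment passed the threshold.
#'
#' @param segments segment data frame from [splosh_pair()].
#' @param path output path.
#' @param pair optional character length-2 of sample ids, recorded in a
#'   comment line.
#' @return `path`, invisibly.
#' @export
write_segment_audit <- function(segments, path, pair = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(pair))
    writeLines(sprintf("# pair: %s vs %s", pair[1], pair[2]), con)
  cols <- c("chrom", "lower_cM", "upper_cM", "length_cM", "n_markers",
            "counted")
  utils::write.table(segments[, intersect(cols, names(segments))], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_anchored <- function(g, m) {
  if (!identical(colnames(g), m$marker))
    stop("genotype matrix is not anchored to this map ",
         "(marker sets or order differ); run subset_to_map() first")
  invisible(TRUE)
}

resolve_sample <- function(g, i) {
  if (is.character(i)) {
    k <- match(i, rownames(g))
    if (is.na(k)) stop("unknown sample id: ", i)
    return(k)
  }
  if (i < 1L || i > nrow(g)) stop("sample index out of range: ", i)
  as.integer(i)
}
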