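#' Construct a genetic map
#'
#' A genetic map assigns each marker a chromosome label and a position in
#' centimorgans. Within a chromosome, markers are kept sorted by position;
#' markers at identical positions keep their input order (stable sort).
#' Chromosome order is first-appearance order unless given explicitly.
#'
#' @param entries data frame with columns `marker`, `chrom`, `pos_cM`.
#' @param chrom_order optional character vector fixing chromosome order.
#' @return an object of class `genetic_map`: the entry data frame sorted by
#'   (chromosome, position), with a `chrom_order` attribute.
#' @export
genetic_map <- function(entries, chrom_order = NULL) {
  stopifnot(all(c("marker", "chrom", "pos_cM") %in% names(entries)))
  entries$marker <- as.character(entries$marker)
  entries$chrom <- as.character(entries$chrom)
  entries$pos_cM <- as.numeric(entries$pos_cM)
  if (anyDuplicated(entries$marker))
    stop("duplicate marker ids in map: ",
         paste(unique(entries$marker[duplicated(entries$marker)]),
               collapse = ", "))
  if (any(!is.finite(entries$pos_cM) | entries$pos_cM < 0))
    stop("map positions must be finite and >= 0")
  chrom_order <- chrom_order %||% unique(entries$chrom)
  if (!all(entries$chrom %in% chrom_order))
    stop("chrom_order does not cover all chromosomes in the map")
  ord <- order(match(entries$chrom, chrom_order), entries$pos_cM)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, class = c("genetic_map", "data.frame"),
            chrom_order = chrom_order)
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  cat(sprintf("genetic_map: %d markers on %d chromosomes, total length %.1f cM\n",
              nrow(x), nrow(s$per_chromosome), s$total_length))
  invisible(x)
}

map_chrom_order <- function(m) attr(m, "chrom_order")

#' Anchor a genotype matrix onto a genetic map
#'
#' Builds the "map dataset": keeps only genotyped markers present in the
#' map and orders the columns by (chromosome, cM position), stable on
#' position ties. Markers absent from the map are reported, never silently
#' dropped.
#'
#' @param g a [genotype_matrix].
#' @param m a [genetic_map].
#' @return list with `genotypes` (the anchored [genotype_matrix]), `map`
#'   (the [genetic_map] restricted to the anchored markers, same order) and
#'   `unmapped` (character vector of genotyped marker ids not on the map).
#' @export
subset_to_map <- function(g, m) {
  shared <- intersect(colnames(g), m$marker)
  if (length(shared) == 0L) stop("no markers shared with map")
  sub <- m[m$marker %in% shared, , drop = FALSE]   # map order = (chrom, cM)
  anchored <- g[, sub$marker, drop = FALSE]
  sub_map <- genetic_map(as.data.frame(sub), chrom_order = map_chrom_order(m))
  list(genotypes = anchored,
       map = sub_map,
       unmapped = setdiff(colnames(g), m$marker))
}

#' Per-chromosome spans and total genetic map length
#'
#' Chromosome spans are measured between the extreme mapped marker
#' positions (the map knows nothing about physical chromosome ends), so a
#' single-marker chromosome has span 0. The total length, the sum of the
#' spans, is the denominator used when a shared-haplotype value is
#' expressed as a percentage of the genetic map.
#'
#' @param m a [genetic_map].
#' @param restrict_to optional character vector of marker ids; spans are
#'   then computed over the mapped markers in this set only.
#' @return list with `per_chromosome` (data frame: `chrom`, `n_markers`,
#'   `min_cM`, `max_cM`, `span_cM`) and `total_length` (numeric, cM).
#' @export
map_summary <- function(m, restrict_to = NULL) {
  entries <- as.data.frame(m)
  if (!is.null(restrict_to)) {
    entries <- entries[entries$marker %in% restrict_to, , drop = FALSE]
    if (nrow(entries) == 0L)
      stop("restriction shares no markers with the map")
  }
  chroms <- intersect(map_chrom_order(m), unique(entries$chrom))
  per <- do.call(rbind, lapply(chroms, function(cc) {
    p <- entries$pos_cM[entries$chrom == cc]
    data.frame(chrom = cc, n_markers = length(p),
               min_cM = min(p), max_cM = max(p), span_cM = max(p) - min(p),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_chromosome = per, total_length = sum(per$span_cM))
}
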