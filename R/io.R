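DEFAULT_MISSING_CODES <- c("--", "NC", "NA", "")

#' Read a genotype call table
#'
#' Reads a delimited text export of unphased diploid SNP calls (one header
#' row of marker ids, one row per sample with the sample id in the first
#' column) and normalizes the calls into the internal 4-value domain.
#' Two call dialects are supported:
#'
#' * `encoding = "AB"`: cells are `AA`, `AB`/`BA` or `BB` relative to the
#'   assay's A/B allele cluster labels.
#' * `encoding = "nucleotide"`: cells are two-letter nucleotide calls
#'   (e.g. `"TC"`); `allele_defs` must then give, per marker, which
#'   nucleotide is allele A and which is allele B. Heterozygotes are
#'   order-insensitive.
#'
#' Cells matching a configured missing code, and any token that cannot be
#' parsed under the chosen encoding, become `MISSING`; unparseable tokens
#' additionally raise a warning naming the offending values.
#'
#' @param path path to the delimited file.
#' @param encoding `"AB"` (default) or `"nucleotide"`.
#' @param allele_defs for nucleotide encoding, a data frame with columns
#'   `marker`, `allele_a`, `allele_b`.
#' @param orientation `"rows"` (samples in rows, the default) or
#'   `"columns"` (markers in rows; the table is transposed after reading).
#' @param delim field delimiter; `NULL` (default) sniffs tab/comma/semicolon
#'   from the header line.
#' @param missing_codes character vector of tokens treated as missing.
#' @return a [genotype_matrix].
#' @export
read_genotype_table <- function(path, encoding = c("AB", "nucleotide"),
                                allele_defs = NULL,
                                orientation = c("rows", "columns"),
                                delim = NULL,
                                missing_codes = DEFAULT_MISSING_CODES) {
  encoding <- match.arg(encoding)
  orientation <- match.arg(orientation)
  delim <- delim %||% sniff_delim(path)
  tab <- utils::read.table(path, sep = delim, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character(0), quote = "\"",
                           comment.char = "")
  m <- as.matrix(tab)
  if (orientation == "columns") m <- t(m)
  m[trimws(m) %in% missing_codes] <- NA_character_
  if (encoding == "AB") {
    dos <- normalize_ab_calls(m)
  } else {
    if (is.null(allele_defs))
      stop("nucleotide encoding requires allele_defs")
    dos <- normalize_nucleotide_calls(m, allele_defs)
  }
  genotype_matrix(dos, sample_ids = rownames(m), marker_ids = colnames(m))
}

normalize_ab_calls <- function(m) {
  code <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L)
  toks <- toupper(trimws(m))
  known <- is.na(toks) | toks %in% names(code)
  if (!all(known)) {
    bad <- unique(toks[!known])
    warning("unparseable genotype tokens set to missing: ",
            paste(utils::head(bad, 10), collapse = ", "))
    toks[!known] <- NA_character_
  }
  matrix(unname(code[toks]), nrow = nrow(m), dimnames = dimnames(m))
}

normalize_nucleotide_calls <- function(m, allele_defs) {
  stopifnot(all(c("marker", "allele_a", "allele_b") %in% names(allele_defs)))
  defs <- allele_defs
  rownames(defs) <- as.character(defs$marker)
  missing_defs <- setdiff(colnames(m), rownames(defs))
  if (length(missing_defs) > 0L)
    stop("no allele definitions for markers: ",
         paste(utils::head(missing_defs, 10), collapse = ", "))
  out <- matrix(NA_integer_, nrow = nrow(m), ncol = ncol(m),
                dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    a <- toupper(defs[colnames(m)[j], "allele_a"])
    b <- toupper(defs[colnames(m)[j], "allele_b"])
    toks <- toupper(trimws(m[, j]))
    ok <- !is.na(toks)
    al1 <- substr(toks, 1L, 1L)
    al2 <- substr(toks, 2L, 2L)
    valid <- ok & nchar(toks) == 2L & al1 %in% c(a, b) & al2 %in% c(a, b)
    alien <- ok & !valid & (nchar(toks) != 2L |
                              !(al1 %in% c(a, b, "-", "N")) |
                              !(al2 %in% c(a, b, "-", "N")))
    if (any(alien))
      stop(sprintf("marker %s: call(s) with allele absent from allele_defs: %s",
                   colnames(m)[j],
                   paste(unique(toks[alien]), collapse = ", ")))
    out[valid, j] <- (al1[valid] == b) + (al2[valid] == b)
  }
  out
}

#' Write a genotype matrix as an AB-encoded delimited table
#'
#' Inverse of [read_genotype_table()] for the AB dialect: header of marker
#' ids, one row per sample, cells `AA`/`AB`/`BB` and `--` for missing.
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, delim = "\t") {
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
  lev <- c("AA", "AB", "BB")
  chars <- matrix(lev[unclass(g) + 1L], nrow = nrow(g))
  chars[is.na(chars)] <- "--"
  df <- data.frame(Sample = rownames(g), chars, check.names = FALSE)
  names(df) <- c("Sample", colnames(g))
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample, per-marker Norm R intensity table
#'
#' Same layout as the genotype table (header of marker ids, sample id in
#' the first column), numeric non-negative cells, `NA` allowed.
#'
#' @inheritParams read_genotype_table
#' @return numeric samples x markers matrix.
#' @export
read_intensity_table <- function(path, orientation = c("rows", "columns"),
                                 delim = NULL) {
  orientation <- match.arg(orientation)
  delim <- delim %||% sniff_delim(path)
  tab <- utils::read.table(path, sep = delim, header = TRUE, row.names = 1,
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(tab)
  if (orientation == "columns") m <- t(m)
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity values")
  m
}

#' Read a genetic map table
#'
#' Three delimited columns: marker id, chromosome label, position in
#' centimorgans. A header row is detected (and skipped) when the third
#' field of the first line is non-numeric.
#'
#' @param path path to the map file.
#' @param delim field delimiter; `NULL` sniffs it.
#' @return a [genetic_map].
#' @export
read_genetic_map <- function(path, delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty map file: ", path)
  fields <- strsplit(lines, delim, fixed = TRUE)
  first <- fields[[1L]]
  has_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(trimws(first[3L]))))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop("map file has a header but no data rows")
  rows <- fields[start:length(fields)]
  lineno <- start:length(fields)
  nf <- lengths(rows)
  if (any(nf < 3L))
    stop("map line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 fields")
  marker <- trimws(vapply(rows, `[[`, "", 1L))
  chrom <- trimws(vapply(rows, `[[`, "", 2L))
  pos_chr <- trimws(vapply(rows, `[[`, "", 3L))
  pos <- suppressWarnings(as.numeric(pos_chr))
  if (anyNA(pos))
    stop("map line ", lineno[which(is.na(pos))[1L]],
         ": non-numeric position '", pos_chr[which(is.na(pos))[1L]], "'")
  if (any(pos < 0 | !is.finite(pos)))
    stop("map line ", lineno[which(pos < 0 | !is.finite(pos))[1L]],
         ": negative or non-finite position")
  genetic_map(data.frame(marker = marker, chrom = chrom, pos_cM = pos,
                         stringsAsFactors = FALSE))
}

#' Write a genetic map as a 3-column delimited table
#'
#' Inverse of [read_genetic_map()].
#'
#' @param m a [genetic_map].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(m, path, delim = "\t") {
  utils::write.table(as.data.frame(m), path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes in STRUCTURE two-rows-per-individual format
#'
#' Each sample occupies two consecutive rows (one allele per row), the
#' sample id in the first column, one column per marker. Alleles are coded
#' `1`/`2`; missing calls are `-9` on both rows. Heterozygotes are written
#' as `1` then `2`.
#'
#' @param g a [genotype_matrix]; must be non-empty.
#' @param path output path.
#' @param marker_row write a first header row of marker ids (default TRUE).
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(g, path, marker_row = TRUE) {
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
  dos <- unclass(g)
  # per-call allele pairs: 0 -> 1/1, 1 -> 1/2, 2 -> 2/2, NA -> -9/-9
  a1 <- ifelse(is.na(dos), -9L, ifelse(dos == 2L, 2L, 1L))
  a2 <- ifelse(is.na(dos), -9L, ifelse(dos == 0L, 1L, 2L))
  con <- file(path, "w")
  on.exit(close(con))
  if (marker_row)
    writeLines(paste(colnames(g), collapse = " "), con)
  for (i in seq_len(nrow(g))) {
    writeLines(paste(c(rownames(g)[i], a1[i, ]), collapse = " "), con)
    writeLines(paste(c(rownames(g)[i], a2[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a STRUCTURE two-rows-per-individual file back into genotypes
#'
#' @param path file written by [write_structure_file()].
#' @param marker_row whether the file starts with a marker-id header row.
#' @return a [genotype_matrix].
#' @export
read_structure_file <- function(path, marker_row = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  markers <- NULL
  if (marker_row) {
    markers <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
    lines <- lines[-1L]
  }
  if (length(lines) %% 2L != 0L)
    stop("STRUCTURE file must have two rows per individual")
  fields <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(fields, `[[`, "", 1L)
  odd <- seq(1L, length(fields), by = 2L)
  if (!identical(ids[odd], ids[odd + 1L]))
    stop("allele row pairs carry mismatching sample ids")
  alleles <- lapply(fields, function(f) as.integer(f[-1L]))
  nmark <- length(alleles[[1L]])
  if (is.null(markers)) markers <- paste0("M", seq_len(nmark))
  dos <- matrix(NA_integer_, nrow = length(odd), ncol = nmark,
                dimnames = list(ids[odd], markers))
  for (k in seq_along(odd)) {
    x1 <- alleles[[odd[k]]]
    x2 <- alleles[[odd[k] + 1L]]
    miss <- x1 == -9L | x2 == -9L
    d <- (x1 - 1L) + (x2 - 1L)
    d[miss] <- NA_integer_
    dos[k, ] <- d
  }
  genotype_matrix(dos)
}
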