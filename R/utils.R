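#' @keywords internal
"_PACKAGE"

# Guess the delimiter of a delimited text file from its first line.
# Candidates: tab, comma, semicolon. Ties go to the earliest candidate.
sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("empty file: ", path)
  counts <- vapply(c("\t", ",", ";"), function(d)
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) stop("could not detect a delimiter in ", path)
  c("\t", ",", ";")[which.max(counts)]
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only to
# stamp run artifacts with a configuration fingerprint.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # exact 32-bit modular multiply by the FNV prime 16777619: split h into
    # 16-bit halves so intermediate products stay below 2^53
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
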