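# Shared internals: alphabet, seeded evaluation, small helpers.

# The 20 standard amino acids, fixed column order for all score tables.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues legal in package sequences: 20 aa + X (unknown) + "-" (gap, aligned only).
LEGAL_RESIDUES <- c(AA20, "X", "-")

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so that
#' seeded package operations never perturb the session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific sub-seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587)
}

# FNV-1a 32-bit hash of a character scalar, rendered as 8 hex digits.
# Used to stamp output files with a config fingerprint (no digest dependency).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on 16-bit halves: h can exceed the bitwXor integer range
    h <- bitwXor(h %/% 65536, b %/% 65536) * 65536 +
      bitwXor(h %% 65536, b %% 65536)
    # exact 32-bit modular multiply via 16-bit limbs
    h <- ((h %/% 65536 * 16777619) %% 65536 * 65536 + h %% 65536 * 16777619) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Validate a residue string; 'where' names the offending record in errors.
check_residues <- function(seq, where = "sequence", allow_gap = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  legal <- if (allow_gap) LEGAL_RESIDUES else c(AA20, "X")
  bad <- setdiff(unique(chars), legal)
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue character(s) %s in %s",
                 paste(sQuote(bad), collapse = ", "), where))
  }
  invisible(seq)
}

# Random residue string from background frequencies (uniform by default).
random_residues <- function(n, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA20, n, replace = TRUE, prob = freqs), collapse = "")
}

# Split a residue string into a character vector.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Write a data.frame as TSV with optional comment header lines ("# ...").
write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}
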