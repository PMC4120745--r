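# FASTA and newick input/output, plus the packaged summary-table fixture loader.

#' Read a protein FASTA file
#'
#' Reads a multi-record amino-acid FASTA file. Sequence lines may be wrapped;
#' whitespace is stripped and letters are uppercased. Record order is
#' preserved. Only the 20 amino-acid letters plus `X` and the gap character
#' `-` are legal; anything else (including the `.` gap dialect) is an error
#' that names the offending line.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of residue strings; names are record ids
#'   (the header up to the first whitespace).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MKV"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA: line 1 does not start with '>'")
  }
  is_header <- startsWith(lines, ">")
  rec <- cumsum(is_header)
  ids <- character(max(rec))
  seqs <- character(max(rec))
  for (k in seq_len(max(rec))) {
    block <- lines[rec == k]
    header <- sub("^>", "", block[[1]])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("malformed FASTA header at line %d", which(rec == k)[1]))
    }
    body <- toupper(gsub("\\s", "", paste(block[-1], collapse = "")))
    first_line <- which(rec == k)[1]
    check_residues(body, where = sprintf("record '%s' (header line %d)", id, first_line))
    ids[k] <- id
    seqs[k] <- body
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a newick string into a tree
#'
#' Wraps [ape::read.tree()] with an explicit balanced-parentheses check that
#' reports the character position of the first imbalance. Internal node
#' labels are interpreted as integer percent bootstrap supports (the MEGA
#' convention) and stored in `tree$node.label`.
#'
#' @param text a newick string.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop(sprintf("newick parse error: unbalanced ')' at position %d", i))
  }
  if (depth != 0L) {
    stop(sprintf("newick parse error: %d unclosed '(' at end of string (length %d)",
                 depth, length(chars)))
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse error: ape could not parse the string")
  tree
}

#' Serialize a tree to newick
#'
#' Branch lengths are written with enough digits to round-trip to 1e-9;
#' internal node labels (supports) are written verbatim.
#'
#' @param tree a `"phylo"` object.
#' @return A newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}

#' Load the packaged subgroup/domain summary fixture
#'
#' Returns the bundled cell-for-cell transcription of the published Table 1:
#' one row per (subgroup, domain) pair across the 20 subgroups of the L2,
#' Jockey and CR1 lineages. Blank cells are `NA`, never 0. See
#' `inst/extdata/README.md` for provenance and the element-count
#' reconciliation.
#'
#' @return A data.frame with columns `subgroup_id`, `lineage`, `n_seqs`,
#'   `rt_identity_pct`, `type_subtype`, `domain_label`, `length_aa`,
#'   `aa_identity_pct`, `top_hit`, `probability_pct`, `n_copies`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_orf1_domains.tsv", package = "orf1evo")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged table fixture is missing; reinstall the package")
  }
  rows <- read_tsv(path)
  needed <- c("subgroup_id", "lineage", "n_seqs", "rt_identity_pct",
              "type_subtype", "domain_label", "length_aa", "aa_identity_pct",
              "top_hit", "probability_pct", "n_copies")
  if (!all(needed %in% names(rows))) stop("table fixture is corrupt: missing columns")
  pc <- c(rows$rt_identity_pct, rows$aa_identity_pct, rows$probability_pct)
  if (any(!is.na(pc) & (pc < 0 | pc > 100))) {
    stop("table fixture is corrupt: percentage outside [0, 100]")
  }
  rows$type_subtype[is.na(rows$type_subtype)] <- ""
  rows
}
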