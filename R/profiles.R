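# Domain profile library: position-specific score tables for the ORF1
# domains of Jockey-superfamily LINEs, plus plain-text (de)serialization.
#
# Each profile is a log-odds table over the 20 amino acids versus a
# background distribution. The packaged defaults are built from fixed
# consensus strings: the consensus residue gets probability `match_prob`
# at its position, the remaining mass is spread uniformly, and weights are
# log(p/background). RRM-family profiles carry the RNP2/RNP1 consensus-box
# coordinates needed to excise the inter-box region for clustering.

# Consensus strings for the packaged profiles. Invented, fixed sequences
# with the canonical sequence features of each family (zinc-coordinating
# C/H spacing for PHD/CCHC/zf, RNP boxes for the RRMs, heptad leucines for
# the coiled-coil and leucine zipper, a composite CC+RRM+CTD for Tnp22).
PROFILE_CONSENSUS <- list(
  PHD      = "VYCICGQPYDESRFMIECDECKDWFHGSCVGVDEEAGEIDLYFCPKCQAR",
  RRM      = paste0("TKLFVGNLPWSTTEEDLRELFSQYGEVVSAKVITDRETGRSRGFGFVEFA",
                    "TAEDAQKALEAMNGAELGGRALRVDFATER"),
  CCHC     = "QCYNCGKFGHIARNCP",
  Tnp22    = paste0("LEKLMEQLEELREKLAQLSEKVDELKSN",
                    "MKIYVSQIAEDVRPEDLYWLFRPYGHITDVYLPKNQRTMESRGVAYVKYE",
                    "DPRDAEDAMRHMDGGQIDGREVRLDWSTPKNK",
                    "APSGSWARVAQKPNPQTNKGGRPQKRPLEDSDEEVIAFSE"),
  Esterase = paste0("MKVAFLGDSNITQGAYVPGGKFEAHLQERLGDGYEVVNFGHSGATLLRKG",
                    "DGPYAERLDQAMESNPDLVIIELGGNDGLRGFPPQVIRENLRKMIDLVRS",
                    "NGAKPLLMQIRLPPNYGRRYNEAFSDIYPKLAKEYDVPLLPFFMEEVYLK",
                    "PQWMQDDGIHPNRDAQPFIA"),
  zf       = "FQCKLCNKKFSRSDHLSKHIRTHQNEKPFA",
  lz       = "LEDKVEELLSKNYHLENEVARLKKLVGE"
)

# RNP consensus boxes inside the RRM profile (located by motif search so the
# spans track the consensus string).
RNP2_MOTIF <- "LFVGNL"
RNP1_MOTIF <- "RGFGFVEF"

#' Build a domain profile from a consensus string
#'
#' @param name domain label.
#' @param consensus residue string (20-letter alphabet).
#' @param match_prob probability mass on the consensus residue per position;
#'   the rest is spread uniformly over the other 19 residues.
#' @param background background residue frequencies (length 20, sums to 1);
#'   uniform by default.
#' @param rnp2_span,rnp1_span optional 0-based half-open `c(start, end)`
#'   sub-intervals (RRM-type profiles only); `rnp2_span` must precede
#'   `rnp1_span`.
#' @return An object of class `"domain_profile"`: a list with `name`,
#'   `length`, `weights` (length x 20 log-odds matrix), `consensus`, and the
#'   RNP spans (possibly `NULL`).
#' @export
make_profile <- function(name, consensus, match_prob = 0.6,
                         background = NULL, rnp2_span = NULL, rnp1_span = NULL) {
  check_residues(consensus, where = sprintf("profile '%s' consensus", name),
                 allow_gap = FALSE)
  L <- nchar(consensus)
  if (L < 8L) stop("profile length must be >= 8")
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-8) {
    stop("background must be 20 frequencies summing to 1")
  }
  chars <- seq_chars(consensus)
  weights <- matrix(NA_real_, nrow = L, ncol = 20L, dimnames = list(NULL, AA20))
  off_prob <- (1 - match_prob) / 19
  for (i in seq_len(L)) {
    p <- rep(off_prob, 20)
    p[match(chars[i], AA20)] <- match_prob
    weights[i, ] <- log(p / background)
  }
  prof <- structure(
    list(name = name, length = L, weights = weights, consensus = consensus,
         rnp2_span = rnp2_span, rnp1_span = rnp1_span),
    class = "domain_profile")
  validate_profile(prof)
  prof
}

validate_profile <- function(profile) {
  stopifnot(inherits(profile, "domain_profile"))
  if (profile$length < 8L) stop("profile length must be >= 8")
  if (!all(is.finite(profile$weights))) stop("profile weights must be finite")
  spans <- list(rnp2 = profile$rnp2_span, rnp1 = profile$rnp1_span)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (!is.null(sp)) {
      if (length(sp) != 2L || sp[1] < 0L || sp[2] > profile$length || sp[1] >= sp[2]) {
        stop(nm, " span must be 0-based half-open within [0, length)")
      }
    }
  }
  if (!is.null(profile$rnp2_span) && !is.null(profile$rnp1_span) &&
      profile$rnp2_span[2] > profile$rnp1_span[1]) {
    stop("rnp2 span must end before rnp1 span starts")
  }
  invisible(profile)
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile '%s': %d positions%s>\n", x$name, x$length,
              if (!is.null(x$rnp2_span)) " (RNP boxes annotated)" else ""))
  invisible(x)
}

#' Consensus string of a profile (argmax residue per position)
#' @param profile a `"domain_profile"`.
#' @return A residue string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  paste(AA20[apply(profile$weights, 1L, which.max)], collapse = "")
}

#' The packaged default profile library
#'
#' Seven profiles: PHD, RRM (with RNP2/RNP1 box coordinates), CCHC, the
#' composite Tnp22 (coiled-coil + RRM + C-terminal domain, modeled as a
#' single entry as in the structure databases), Esterase, zf and lz.
#'
#' @param match_prob per-position consensus probability (default 0.6).
#' @return A named list of `"domain_profile"` objects.
#' @export
default_profile_library <- function(match_prob = 0.6) {
  lib <- lapply(names(PROFILE_CONSENSUS), function(nm) {
    cons <- PROFILE_CONSENSUS[[nm]]
    rnp2 <- rnp1 <- NULL
    if (nm == "RRM") {
      s2 <- as.integer(regexpr(RNP2_MOTIF, cons, fixed = TRUE))
      s1 <- as.integer(regexpr(RNP1_MOTIF, cons, fixed = TRUE))
      stopifnot(s2 > 0L, s1 > 0L)
      rnp2 <- c(s2 - 1L, s2 - 1L + nchar(RNP2_MOTIF))
      rnp1 <- c(s1 - 1L, s1 - 1L + nchar(RNP1_MOTIF))
    }
    make_profile(nm, cons, match_prob = match_prob,
                 rnp2_span = rnp2, rnp1_span = rnp1)
  })
  stats::setNames(lib, names(PROFILE_CONSENSUS))
}

#' Write / read a profile as a plain-text file
#'
#' Format: a header line `name <tab> length <tab> rnp2_start <tab> rnp2_end
#' <tab> rnp1_start <tab> rnp1_end` (spans `NA` when absent), then `length`
#' rows of 20 tab-separated log-odds values in the fixed residue order
#' `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param profile a `"domain_profile"`.
#' @param path file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `"domain_profile"`.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  sp <- function(x) if (is.null(x)) c(NA_integer_, NA_integer_) else x
  header <- paste(c(profile$name, profile$length,
                    sp(profile$rnp2_span), sp(profile$rnp1_span)),
                  collapse = "\t")
  rows <- apply(profile$weights, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 10), collapse = "\t")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 6L) stop("malformed profile header in ", path)
  L <- as.integer(hdr[2])
  if (length(lines) != L + 1L) stop("profile row count disagrees with header in ", path)
  weights <- do.call(rbind, lapply(lines[-1], function(ln) {
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])
  }))
  if (ncol(weights) != 20L) stop("profile rows must have 20 values in ", path)
  colnames(weights) <- AA20
  span <- function(a, b) {
    v <- suppressWarnings(as.integer(c(a, b)))
    if (anyNA(v)) NULL else v
  }
  prof <- structure(
    list(name = hdr[1], length = L, weights = weights,
         consensus = NULL,
         rnp2_span = span(hdr[3], hdr[4]), rnp1_span = span(hdr[5], hdr[6])),
    class = "domain_profile")
  prof$consensus <- profile_consensus(prof)
  validate_profile(prof)
  prof
}

#' Write or read a whole profile library directory
#'
#' One `<name>.profile` text file per profile.
#'
#' @param library named list of profiles.
#' @param dir directory path.
#' @return `write_profile_library()` returns `dir` invisibly;
#'   `read_profile_library()` returns a named list of profiles.
#' @export
write_profile_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in library) write_profile(p, file.path(dir, paste0(p$name, ".profile")))
  invisible(dir)
}

#' @rdname write_profile_library
#' @export
read_profile_library <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.profile$", full.names = TRUE))
  if (length(files) == 0L) stop("no .profile files found in ", dir)
  lib <- lapply(files, read_profile)
  stats::setNames(lib, vapply(lib, `[[`, "", "name"))
}
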