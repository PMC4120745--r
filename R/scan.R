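# Profile scanning of ORF1 regions: ungapped PSSM local matching with an
# empirical shuffle-null probability calibration, plus heptad-repeat
# coiled-coil detection. This is the package's desk-scale counterpart of a
# profile-database search: the decision rule downstream (take the top hit,
# accept at probability > 85%) is preserved while the scoring mechanism is
# a self-contained position-specific score table.

# Kyte-Doolittle hydropathy, used by the coiled-coil heuristic.
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3)

# Memoized null-score distributions, keyed by profile, scan length, null size
# and seed. Lives for the R session; keeps repeated annotation cheap.
.null_cache <- new.env(parent = emptyenv())

# Score every window of `idx` (residue indices, NA for X/gap) against W.
# Returns a numeric vector of window scores (empty if profile longer than seq).
window_scores <- function(idx, W) {
  L <- nrow(W)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  S <- numeric(n)
  for (i in seq_len(L)) {
    v <- W[i, ][idx[i:(i + n - 1L)]]
    v[is.na(v)] <- 0
    S <- S + v
  }
  S
}

#' Scan a sequence with one domain profile
#'
#' Scores every ungapped window of profile length and reports non-overlapping
#' score maxima (greedy, best first) above `score_floor`, in coordinate
#' order. Unknown residues (`X`) and gaps contribute zero.
#'
#' @param seq residue string.
#' @param profile a `"domain_profile"`.
#' @param score_floor minimum raw log-odds sum for a reported hit (default 0;
#'   random windows against the packaged profiles score well below 0).
#' @return A data.frame with columns `domain`, `start`, `end` (0-based
#'   half-open), `score`. Zero rows if the profile is longer than the
#'   sequence or nothing clears the floor.
#' @export
scan_profile <- function(seq, profile, score_floor = 0) {
  if (!nzchar(seq)) stop("seq must be non-empty")
  validate_profile(profile)
  idx <- match(seq_chars(seq), AA20)
  S <- window_scores(idx, profile$weights)
  empty <- data.frame(domain = character(0), start = integer(0),
                      end = integer(0), score = numeric(0))
  if (length(S) == 0L) return(empty)
  cand <- order(-S, seq_along(S))
  cand <- cand[S[cand] > score_floor]
  taken_start <- integer(0)
  L <- profile$length
  for (s in cand) {
    if (!any(abs(taken_start - s) < L)) taken_start <- c(taken_start, s)
  }
  if (length(taken_start) == 0L) return(empty)
  taken_start <- sort(taken_start)
  data.frame(domain = profile$name,
             start = taken_start - 1L,
             end = taken_start - 1L + L,
             score = S[taken_start])
}

# Max window score of each of n_null random background sequences of length
# scan_length, for one profile. Deterministic given seed.
null_max_scores <- function(profile, scan_length, n_null, seed, background = NULL) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  key <- paste(profile$name, fnv1a32(paste(signif(profile$weights, 8), collapse = ",")),
               scan_length, n_null, seed, fnv1a32(paste(background, collapse = ",")),
               sep = "|")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  L <- profile$length
  n <- scan_length - L + 1L
  out <- if (n < 1L) {
    rep(-Inf, n_null)
  } else {
    with_seed(seed, {
      idxmat <- matrix(sample.int(20L, n_null * scan_length, replace = TRUE,
                                  prob = background),
                       nrow = n_null, ncol = scan_length)
      S <- matrix(0, nrow = n_null, ncol = n)
      W <- profile$weights
      for (i in seq_len(L)) {
        S <- S + matrix(W[i, ][idxmat[, i:(i + n - 1L), drop = FALSE]],
                        nrow = n_null, ncol = n)
      }
      apply(S, 1L, max)
    })
  }
  .null_cache[[key]] <- out
  out
}

#' Calibrate a raw profile score to an empirical probability
#'
#' The null model is the maximum window score of `n_null` random background
#' sequences of the scanned length; the probability is the empirical
#' percentile of `score` among those null maxima, in percent. Monotone in
#' `score` for a fixed profile and seed, and deterministic given the seed.
#'
#' @param score raw log-odds window score.
#' @param profile the profile that produced the score.
#' @param scan_length length of the scanned sequence (the null sequences
#'   match it).
#' @param n_null number of null sequences (default 1000; fewer than 100 is
#'   refused as an unstable calibration).
#' @param seed integer seed for the null draw.
#' @param background background residue frequencies (uniform by default).
#' @return A percent in \[0, 100\].
#' @export
calibrate_probability <- function(score, profile, scan_length, n_null = 1000L,
                                  seed = 1L, background = NULL) {
  if (n_null < 100L) stop("n_null < 100 gives an unstable calibration; refused")
  nulls <- null_max_scores(profile, scan_length, n_null, seed, background)
  100 * mean(nulls < score)
}

#' Detect coiled-coil segments by heptad hydropathy contrast
#'
#' Slides a window over the sequence; for each of the 7 heptad registers the
#' score is the mean Kyte-Doolittle hydropathy at the `a`/`d` positions minus
#' the mean elsewhere, and the window takes the best register. Windows whose
#' score exceeds `threshold` are merged into segments.
#'
#' @param seq residue string.
#' @param window window length; must be >= 14 and a multiple of 7
#'   (default 21, three heptads).
#' @param threshold score needed to call a window coiled-coil (default 6.5:
#'   an ideal amphipathic heptad scores about 7.5 on the Kyte-Doolittle
#'   scale, while shuffles of the same residue composition stay below 6.5
#'   in about 99% of cases).
#' @return A data.frame with columns `start`, `end` (0-based half-open) and
#'   `score` (max window score in the segment). Zero rows if nothing crosses
#'   the threshold.
#' @export
detect_coiled_coil <- function(seq, window = 21L, threshold = 6.5) {
  if (window < 14L || window %% 7L != 0L) {
    stop("window must be >= 14 and a multiple of 7")
  }
  h <- KD_HYDROPATHY[seq_chars(seq)]
  h[is.na(h)] <- 0
  len <- length(h)
  n <- len - window + 1L
  empty <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  if (n < 1L) return(empty)
  offsets <- seq_len(window) - 1L
  best <- rep(-Inf, n)
  for (r in 0:6) {
    ad <- (offsets - r) %% 7L %in% c(0L, 3L)
    n_ad <- sum(ad)
    sc <- numeric(n)
    sc_all <- numeric(n)
    for (j in seq_len(window)) {
      v <- h[j:(j + n - 1L)]
      if (ad[j]) sc <- sc + v
      sc_all <- sc_all + v
    }
    contrast <- sc / n_ad - (sc_all - sc) / (window - n_ad)
    best <- pmax(best, contrast)
  }
  hit <- which(best > threshold)
  if (length(hit) == 0L) return(empty)
  # merge windows whose spans touch or overlap
  segs <- list()
  cur_s <- hit[1]
  cur_e <- hit[1] + window
  cur_sc <- best[hit[1]]
  for (s in hit[-1]) {
    if (s <= cur_e) {
      cur_e <- max(cur_e, s + window)
      cur_sc <- max(cur_sc, best[s])
    } else {
      segs[[length(segs) + 1L]] <- c(cur_s, cur_e, cur_sc)
      cur_s <- s; cur_e <- s + window; cur_sc <- best[s]
    }
  }
  segs[[length(segs) + 1L]] <- c(cur_s, cur_e, cur_sc)
  m <- do.call(rbind, segs)
  data.frame(start = as.integer(m[, 1] - 1L), end = as.integer(m[, 2] - 1L),
             score = m[, 3])
}

#' Annotate an ORF1 with a profile library
#'
#' Pools hits from all profiles, resolves overlaps by keeping the
#' higher-probability hit (ties: longer hit, then earlier start), flags each
#' surviving hit as accepted when its calibrated probability meets
#' `accept_threshold`, and returns hits sorted by start coordinate.
#'
#' @param seq ORF1 residue string (may be empty: empty annotation).
#' @param library named list of `"domain_profile"` objects.
#' @param accept_threshold probability (percent) needed for acceptance
#'   (default 85).
#' @param n_null,seed,background calibration controls, see
#'   [calibrate_probability()].
#' @param score_floor raw-score floor passed to [scan_profile()].
#' @return A data.frame with columns `domain`, `start`, `end`, `score`,
#'   `probability`, `accepted`.
#' @export
annotate_orf1 <- function(seq, library, accept_threshold = 85, n_null = 1000L,
                          seed = 1L, background = NULL, score_floor = 0) {
  if (length(library) == 0L) stop("profile library must be non-empty")
  empty <- data.frame(domain = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      probability = numeric(0), accepted = logical(0))
  if (is.null(seq) || !nzchar(seq)) return(empty)
  hits <- list()
  for (p in library) {
    h <- scan_profile(seq, p, score_floor = score_floor)
    if (nrow(h) == 0L) next
    nulls <- null_max_scores(p, nchar(seq), n_null, seed, background)
    h$probability <- vapply(h$score, function(s) 100 * mean(nulls < s), 0)
    hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L) return(empty)
  all_hits <- do.call(rbind, hits)
  ord <- order(-all_hits$probability, -(all_hits$end - all_hits$start),
               all_hits$start)
  kept <- logical(nrow(all_hits))
  for (i in ord) {
    overlap <- kept &
      all_hits$start < all_hits$end[i] & all_hits$end > all_hits$start[i]
    if (!any(overlap)) kept[i] <- TRUE
  }
  out <- all_hits[kept, , drop = FALSE]
  out$accepted <- out$probability >= accept_threshold
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
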