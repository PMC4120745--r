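# All-vs-all similarity clustering of extracted RRM units: Smith-Waterman
# scores (BLOSUM62) turned into z-score attractions against a shuffle null,
# thresholded connected components for clusters, and a small force-directed
# 2-D layout for visualization.

#' Extract RRM units for clustering
#'
#' For each element, takes the accepted RRM hits and excises the region
#' between the RNP2 and RNP1 consensus boxes (the only region shared by all
#' RRMs), projected onto hit coordinates. Elements with two RRMs yield two
#' records tagged `U` (upstream) and `D` (downstream) in coordinate order;
#' a single RRM yields one untagged record. Elements whose RRM profile
#' carries no RNP spans are skipped with a warning.
#'
#' @param orf1_seqs named character vector of ORF1 residue strings.
#' @param annotations named list of annotation data.frames parallel to
#'   `orf1_seqs`.
#' @param library profile library (provides the RNP spans of the RRM
#'   profile).
#' @return Named character vector of unit sequences; names are element ids
#'   with `_U`/`_D` (or `_R<k>` beyond two) tags where applicable.
#' @export
extract_rrm_units <- function(orf1_seqs, annotations, library) {
  prof <- library[["RRM"]]
  units <- character(0)
  for (id in names(orf1_seqs)) {
    ann <- annotations[[id]]
    if (is.null(ann)) next
    rrm <- ann[ann$accepted & ann$domain == "RRM", , drop = FALSE]
    if (nrow(rrm) == 0L) next
    if (is.null(prof) || is.null(prof$rnp2_span) || is.null(prof$rnp1_span)) {
      warning("RRM profile lacks RNP spans; skipping element ", id)
      next
    }
    rrm <- rrm[order(rrm$start), , drop = FALSE]
    tags <- if (nrow(rrm) == 1L) "" else if (nrow(rrm) == 2L) c("_U", "_D")
            else paste0("_R", seq_len(nrow(rrm)))
    for (k in seq_len(nrow(rrm))) {
      from <- rrm$start[k] + prof$rnp2_span[2] + 1L   # 1-based, after RNP2
      to <- rrm$start[k] + prof$rnp1_span[1]          # up to RNP1 start
      units[paste0(id, tags[k])] <- substr(orf1_seqs[[id]], from, to)
    }
  }
  units
}

#' All-vs-all similarity graph of sequence units
#'
#' Scores each pair by Smith-Waterman local alignment (BLOSUM62); the
#' attraction is the z-score of the observed score against a null of
#' `n_shuffle` scores obtained by shuffling one member (always the
#' lexicographically smaller id, which makes the weight symmetric by
#' construction), floored at zero. Zero-attraction edges are omitted.
#'
#' @param units named character vector of unit sequences (>= 2).
#' @param gap_open,gap_extend gap penalties (positive costs; defaults 10
#'   and 4).
#' @param n_shuffle null shuffles per pair (default 200).
#' @param seed integer seed (per-pair sub-seeds derive from it and from the
#'   pair ids, so results do not depend on input order).
#' @return An object of class `"similarity_graph"`: list with `nodes` and
#'   an `edges` data.frame (`a`, `b`, `weight`).
#' @export
all_vs_all_similarity <- function(units, gap_open = 10, gap_extend = 4,
                                  n_shuffle = 200L, seed = 1L) {
  if (length(units) < 2L) stop("need at least 2 units")
  if (is.null(names(units)) || anyDuplicated(names(units))) {
    stop("units must have unique names")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  subm <- get("BLOSUM62", envir = environment())
  ids <- sort(names(units))
  sw <- function(pattern, subjects) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(subjects),
      subject = Biostrings::AAString(pattern),
      type = "local", substitutionMatrix = subm,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  }
  edges <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- ids[i]; b <- ids[j]          # a < b: a's sequence is shuffled
      sa <- units[[a]]; sb <- units[[b]]
      obs <- sw(sb, sa)
      pair_seed <- derive_seed(seed, sum(utf8ToInt(paste0(a, "~", b))))
      shuffled <- with_seed(pair_seed, {
        vapply(seq_len(n_shuffle), function(k) {
          paste(sample(seq_chars(sa)), collapse = "")
        }, "")
      })
      nulls <- sw(sb, shuffled)
      z <- if (stats::sd(nulls) > 0) (obs - mean(nulls)) / stats::sd(nulls) else 0
      w <- max(0, z)
      if (w > 0) edges[[length(edges) + 1L]] <- data.frame(a = a, b = b, weight = w)
    }
  }
  structure(list(nodes = ids,
                 edges = if (length(edges) > 0L) do.call(rbind, edges)
                         else data.frame(a = character(0), b = character(0),
                                         weight = numeric(0))),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Force-directed 2-D layout of a similarity graph
#'
#' Attraction along edges proportional to weight, uniform pairwise
#' repulsion, damped updates from seeded random initial positions.
#' Visualization only; deterministic given the seed.
#'
#' @param graph a `"similarity_graph"`.
#' @param iterations update steps (>= 1; default 200).
#' @param seed integer seed for the initial placement.
#' @param k_attract,k_repel force constants.
#' @return A matrix of node coordinates (rows named by node, columns x/y).
#' @export
force_layout <- function(graph, iterations = 200L, seed = 1L,
                         k_attract = 0.05, k_repel = 0.05) {
  if (iterations < 1L) stop("iterations must be >= 1")
  n <- length(graph$nodes)
  pos <- with_seed(seed, matrix(stats::runif(2 * n, -1, 1), ncol = 2,
                                dimnames = list(graph$nodes, c("x", "y"))))
  if (n == 1L) return(pos)
  e <- graph$edges
  ia <- match(e$a, graph$nodes); ib <- match(e$b, graph$nodes)
  step <- 0.1
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1], pos[, 1], `-`)
    dy <- outer(pos[, 2], pos[, 2], `-`)
    d2 <- dx^2 + dy^2 + 1e-9
    fx <- rowSums(k_repel * dx / d2)
    fy <- rowSums(k_repel * dy / d2)
    if (nrow(e) > 0L) {
      ax <- (pos[ib, 1] - pos[ia, 1]) * e$weight * k_attract
      ay <- (pos[ib, 2] - pos[ia, 2]) * e$weight * k_attract
      for (r in seq_len(nrow(e))) {
        fx[ia[r]] <- fx[ia[r]] + ax[r]; fy[ia[r]] <- fy[ia[r]] + ay[r]
        fx[ib[r]] <- fx[ib[r]] - ax[r]; fy[ib[r]] <- fy[ib[r]] - ay[r]
      }
    }
    pos[, 1] <- pos[, 1] + step * fx
    pos[, 2] <- pos[, 2] + step * fy
    step <- step * 0.98
  }
  pos
}

#' Extract clusters from a similarity graph
#'
#' Connected components of the subgraph whose edges have weight at or above
#' `attraction_floor`; singleton components are kept. Cluster ids are
#' ordered by decreasing size, then by the lexicographically smallest
#' member, and the assignment is invariant to node input order.
#'
#' @param graph a `"similarity_graph"`.
#' @param attraction_floor minimum edge weight (default 3, i.e. z >= 3).
#' @return Named integer vector mapping node id to cluster id.
#' @export
extract_clusters <- function(graph, attraction_floor = 3) {
  nodes <- sort(graph$nodes)
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  e <- graph$edges[graph$edges$weight >= attraction_floor, , drop = FALSE]
  for (r in seq_len(nrow(e))) {
    ra <- find(match(e$a[r], nodes)); rb <- find(match(e$b[r], nodes))
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  comp <- split(nodes, roots)
  ord <- order(-lengths(comp), vapply(comp, function(g) sort(g)[1], ""))
  comp <- comp[ord]
  out <- integer(0)
  for (k in seq_along(comp)) out[comp[[k]]] <- k
  out[nodes]
}
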