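# Shared fixtures and independent oracles used across the suite.

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(orf1evo:::AA20, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else orf1evo:::with_seed(seed, draw())
}

# Brute-force window scores of a profile over a sequence (independent of the
# package's vectorized scan path).
brute_window_scores <- function(seq, profile) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- profile$length
  n <- length(chars) - L + 1L
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n), function(s) {
    sum(vapply(seq_len(L), function(i) {
      k <- match(chars[s + i - 1L], orf1evo:::AA20)
      if (is.na(k)) 0 else profile$weights[i, k]
    }, 0))
  }, 0)
}

# Exhaustive small-parsimony minimum: try every internal-node labeling of a
# binary rooting and count edges whose endpoints differ.
brute_fitch <- function(tree, labels) {
  rooted <- if (ape::is.rooted(tree) && ape::is.binary(tree)) tree
            else ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  lv <- unique(unname(labels))
  ntip <- length(rooted$tip.label)
  internal <- (ntip + 1L):(ntip + rooted$Nnode)
  grid <- expand.grid(rep(list(lv), length(internal)), stringsAsFactors = FALSE)
  state <- character(ntip + rooted$Nnode)
  state[seq_len(ntip)] <- labels[rooted$tip.label]
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    state[internal] <- unlist(grid[g, ], use.names = FALSE)
    ch <- sum(state[rooted$edge[, 1]] != state[rooted$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# Random tree with strictly positive branch lengths and its additive
# (path-length) distance matrix.
random_additive <- function(n_taxa) {
  t0 <- ape::rtree(n_taxa)
  t0$edge.length <- stats::runif(nrow(t0$edge), 0.05, 1)
  list(tree = t0, D = stats::cophenetic(t0))
}

split_set <- function(tree) sort(orf1evo:::tree_splits(tree))

# RRM..CCHC block straight off the simulator's ground-truth segment states
# (independent of the annotation path).
truth_block <- function(sim, id) {
  segs <- sim$truth$states[[id]]
  labs <- vapply(segs, `[[`, "", "label")
  rrm <- which(labs == "RRM")
  cchc <- which(labs == "CCHC")
  if (length(rrm) == 0L || length(cchc) == 0L) return(NA_character_)
  paste(vapply(segs[min(rrm):max(cchc)], `[[`, "", "seq"), collapse = "")
}

# Point-estimate (no bootstrap) ORF2 and ORF1 trees for a simulation, the
# ORF1 tree restricted to elements carrying the type-I block.
sim_trees <- function(sim, model = "kimura_aa") {
  el <- sim$elements
  concat <- stats::setNames(paste0(el$ape_seq, el$rt_seq), el$id)
  orf2 <- neighbor_joining(distance_matrix(concat, model))
  blocks <- vapply(el$id, function(id) truth_block(sim, id), "")
  names(blocks) <- el$id
  blocks <- blocks[!is.na(blocks)]
  orf1 <- if (length(blocks) >= 3L) {
    neighbor_joining(distance_matrix(blocks, model))
  } else NULL
  list(orf2 = orf2, orf1 = orf1, block_ids = names(blocks))
}

lineage_monophyletic <- function(tree, labels) {
  tips <- sort(tree$tip.label)
  splits <- orf1evo:::tree_splits(tree)
  all(vapply(unique(labels[tips]), function(L) {
    set <- tips[labels[tips] == L]
    length(set) <= 1L || length(set) >= length(tips) - 1L ||
      orf1evo:::split_key(set, tips) %in% splits
  }, TRUE))
}
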