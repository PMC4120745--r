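# Distance computation, neighbor joining, bootstrap bipartition support,
# Fitch small parsimony, and support/type-based subgroup delineation.
#
# NJ is implemented in-package so the tie-break (smallest lexicographic id
# pair) and negative-branch clamping are fixed and reproducible; trees are
# returned unrooted as ape "phylo" objects.

#' Percent pairwise identity of two aligned rows
#'
#' Columns with a gap in either row are excluded (pairwise deletion). A pair
#' with no comparable columns is reported missing (`NA`).
#'
#' @param a,b equal-length gapped residue strings.
#' @return Percent identity in \[0, 100\], or `NA`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  ca <- seq_chars(a); cb <- seq_chars(b)
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(NA_real_)
  100 * sum(ca[keep] == cb[keep]) / sum(keep)
}

#' Pairwise distance matrix from an alignment
#'
#' Distances derive from pairwise-deletion p-distances: `p` itself,
#' Poisson-corrected `-ln(1 - p)`, or the Kimura amino-acid correction
#' `-ln(1 - p - 0.2 p^2)` (the default; a closed-form surrogate for
#' matrix-based ML distances, monotone in p over its domain). Saturated
#' pairs (correction undefined) are set to `ceiling` and flagged in the
#' `"saturated"` attribute.
#'
#' @param aln named character vector of equal-length (gapped) rows; >= 2 rows.
#' @param model one of `"kimura_aa"`, `"poisson"`, `"p"`.
#' @param ceiling distance assigned to saturated pairs (default 5).
#' @return A symmetric numeric matrix with zero diagonal and `dimnames` from
#'   `names(aln)`; attribute `"saturated"` is a logical matrix.
#' @export
distance_matrix <- function(aln, model = c("kimura_aa", "poisson", "p"),
                            ceiling = 5) {
  model <- match.arg(model)
  n <- length(aln)
  if (n < 2L) stop("alignment must have at least 2 rows")
  if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
  ids <- names(aln)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idty <- pairwise_identity(aln[[i]], aln[[j]])
      if (is.na(idty)) {
        stop(sprintf("pairwise identity undefined for pair (%s, %s): no comparable columns",
                     ids[i], ids[j]))
      }
      p <- 1 - idty / 100
      d <- switch(model,
        p = p,
        poisson = if (p >= 1) NA_real_ else -log(1 - p),
        kimura_aa = {
          arg <- 1 - p - 0.2 * p^2
          if (arg <= 0) NA_real_ else -log(arg)
        })
      if (is.na(d)) { d <- ceiling; sat[i, j] <- sat[j, i] <- TRUE }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken by the smallest lexicographic pair of node ids (a node is
#' identified by the smallest leaf id in its subtree); negative estimated
#' branch lengths are clamped to 0. The result is unrooted (trifurcating
#' root node) and exact on additive matrices.
#'
#' @param dm symmetric distance matrix with taxon ids as dimnames (>= 3
#'   taxa).
#' @return An unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(dm) {
  D <- as.matrix(dm)
  ids <- rownames(D)
  n <- nrow(D)
  if (is.null(ids)) stop("distance matrix must carry taxon ids as dimnames")
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  frag <- ids                 # newick fragment per active node
  lab <- ids                  # tie-break id (min leaf id in subtree)
  fmt <- function(x) formatC(max(x, 0), format = "g", digits = 15)
  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(lab[cand[, 1]], lab[cand[, 2]])
    key2 <- pmax(lab[cand[, 1]], lab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newlab <- min(lab[i], lab[j])
    k <- setdiff(seq_len(n), c(i, j))
    newd <- (D[i, k] + D[j, k] - D[i, j]) / 2
    D <- rbind(cbind(D[k, k, drop = FALSE], newd), c(newd, 0))
    frag <- c(frag[k], newfrag)
    lab <- c(lab[k], newlab)
    n <- n - 1L
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  read_newick(nwk)
}

# Canonical keys for the non-trivial bipartitions (splits) of an unrooted
# tree: for each internal edge, the side NOT containing the alphabetically
# first leaf, sorted and joined with "|".
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) split_key(labs[ix], tips), "")
  keys <- keys[!is.na(keys)]
  unique(keys)
}

# Canonical key of one leaf set as a split of `all_tips`; NA for trivial
# splits (size < 2 on either side).
split_key <- function(side, all_tips) {
  side <- sort(side)
  if (all_tips[1] %in% side) side <- sort(setdiff(all_tips, side))
  if (length(side) < 2L || length(side) > length(all_tips) - 2L) return(NA_character_)
  paste(side, collapse = "|")
}

#' Bootstrap bipartition supports for an NJ tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, rebuilds, and reports for each
#' internal bipartition of the original tree the percent of replicate trees
#' containing it (integer percents in `tree$node.label`; the root gets an
#' empty label). Deterministic given `seed`.
#'
#' @param aln named character vector of equal-length rows.
#' @param model distance model, see [distance_matrix()].
#' @param n_reps bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return A `"phylo"` tree with supports in `node.label`.
#' @export
bootstrap_support <- function(aln, model = "kimura_aa", n_reps = 500L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  tree <- neighbor_joining(distance_matrix(aln, model))
  rows <- strsplit(aln, "", fixed = TRUE)
  m <- do.call(rbind, rows)
  rownames(m) <- names(aln)
  orig <- tree_splits(tree)
  counts <- stats::setNames(rep(0L, length(orig)), orig)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      baln <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      bt <- neighbor_joining(distance_matrix(baln, model))
      hit <- intersect(tree_splits(bt), orig)
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- round(100 * counts / n_reps)
  set_node_supports(tree, support)
}

# Write a split-key -> percent map onto tree$node.label (root label "").
set_node_supports <- function(tree, support_map) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_lab <- vapply(pp, function(ix) {
    key <- split_key(labs[ix], tips)
    if (is.na(key) || is.na(support_map[key])) "" else as.character(support_map[key])
  }, "")
  tree$node.label <- node_lab
  tree
}

# Support map (split key -> integer percent) read back off node labels.
node_support_map <- function(tree) {
  if (is.null(tree$node.label)) return(stats::setNames(integer(0), character(0)))
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) split_key(labs[ix], tips), "")
  vals <- suppressWarnings(as.integer(tree$node.label))
  ok <- !is.na(keys) & !is.na(vals)
  stats::setNames(vals[ok], keys[ok])
}

# Fitch change count on a rooted binary tree (edge matrix in postorder).
# `state` is an integer label index per tip, named by tip label.
fitch_count <- function(rooted, state_idx) {
  edge <- rooted$edge
  ntip <- length(rooted$tip.label)
  nnode <- rooted$Nnode
  sets <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) sets[[t]] <- state_idx[[rooted$tip.label[t]]]
  changes <- 0L
  po <- ape::reorder.phylo(rooted, "postorder")$edge
  # process children in postorder; combine at each parent sequentially
  for (r in seq_len(nrow(po))) {
    p <- po[r, 1]; ch <- po[r, 2]
    s <- sets[[ch]]
    if (is.null(sets[[p]])) {
      sets[[p]] <- s
    } else {
      inter <- intersect(sets[[p]], s)
      if (length(inter) == 0L) {
        sets[[p]] <- union(sets[[p]], s)
        changes <- changes + 1L
      } else {
        sets[[p]] <- inter
      }
    }
  }
  changes
}

# Root an unrooted tree on the first tip's pendant edge, giving a binary
# rooted tree suitable for a Fitch pass.
root_for_fitch <- function(tree) {
  if (ape::is.rooted(tree) && ape::is.binary(tree)) return(tree)
  ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
}

#' Fitch parsimony score of a leaf labeling
#'
#' Minimum number of label changes needed to explain the leaf labels on the
#' tree (two-pass Fitch on an arbitrary binary rooting; the count is
#' independent of the rooting).
#'
#' @param tree a `"phylo"` tree.
#' @param labels named character vector mapping every leaf to a label.
#' @return Integer change count.
#' @export
fitch_parsimony <- function(tree, labels) {
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "))
  }
  lv <- unique(labels[tree$tip.label])
  idx <- lapply(tree$tip.label, function(t) match(labels[[t]], lv))
  names(idx) <- tree$tip.label
  fitch_count(root_for_fitch(tree), idx)
}

#' Delineate subgroups from supports and ORF1 types
#'
#' Partitions the leaves into maximal clades whose bipartition support meets
#' `support_floor` and whose leaves all share one ORF1 (major, subtype)
#' label; leaves in no qualifying clade become singletons. With
#' `merge_same_type = TRUE`, groups sharing a type label are merged even if
#' not sisters (the published subgroups are sometimes non-monophyletic but
#' grouped by ORF1 structure).
#'
#' @param tree a `"phylo"` tree with bootstrap supports in `node.label`.
#' @param types named character vector mapping each leaf to its type label
#'   (e.g. `"IIA"`).
#' @param support_floor minimum percent support for a qualifying clade.
#' @param merge_same_type merge same-type non-sister groups (default FALSE).
#' @return Named character vector mapping each leaf to a group id (`"G1"`,
#'   `"G2"`, ... ordered by decreasing size then leaf name).
#' @export
delineate_subgroups <- function(tree, types, support_floor, merge_same_type = FALSE) {
  missing <- setdiff(tree$tip.label, names(types))
  if (length(missing) > 0L) stop("untyped leaf/leaves: ", paste(missing, collapse = ", "))
  smap <- node_support_map(tree)
  rooted <- phangorn::midpoint(ape::unroot(tree))
  ntip <- length(rooted$tip.label)
  kids <- split(rooted$edge[, 2], rooted$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(rooted$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under), use.names = FALSE)
  }
  all_tips <- sort(rooted$tip.label)
  groups <- list()
  walk <- function(node) {
    lv <- tips_under(node)
    if (length(lv) == 1L) { groups[[length(groups) + 1L]] <<- lv; return(invisible()) }
    key <- split_key(lv, all_tips)
    # trivial splits (whole tree / n-1 sets) count as fully supported
    sup <- if (is.na(key)) 100L else smap[key]
    if (!is.na(sup) && sup >= support_floor && length(unique(types[lv])) == 1L) {
      groups[[length(groups) + 1L]] <<- lv
    } else {
      for (ch in kids[[as.character(node)]]) walk(ch)
    }
  }
  walk(ntip + 1L)
  if (merge_same_type) {
    bytype <- split(groups, vapply(groups, function(g) types[[g[1]]], ""))
    groups <- lapply(bytype, function(gs) sort(unlist(gs)))
  }
  ord <- order(-lengths(groups), vapply(groups, function(g) sort(g)[1], ""))
  groups <- groups[ord]
  out <- character(0)
  for (k in seq_along(groups)) {
    out[groups[[k]]] <- paste0("G", k)
  }
  out[tree$tip.label]
  stats::setNames(out[tree$tip.label], tree$tip.label)
}
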