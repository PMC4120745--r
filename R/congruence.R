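# Horizontal ORF1 acquisition: compare lineage placement between the ORF2
# (APE+RT) tree and an ORF1-domain tree. A lineage that is monophyletic in
# the ORF2 tree but sits inside a foreign-lineage context of the ORF1 tree
# is reported as a transfer candidate. The embedding rule quantifies the
# visual inference of the source study; the permutation test is this
# package's own addition and is labeled as such in reports.

#' Detect cross-lineage ORF1 embeddings
#'
#' For each lineage `L` monophyletic in the ORF2 tree, the midpoint-rooted
#' ORF1 tree is searched for the smallest clade that contains all `L` leaves
#' and at least as many foreign leaves as `L` leaves. A candidate is emitted
#' when more than `majority` of those foreign leaves carry one single other
#' lineage label `H` *and* the span of `H` in the ORF1 tree itself contains
#' `L` leaves (so `H` is broken by the intrusion, which rules out ordinary
#' sister-lineage geometry). `n_embedding_positions` counts the maximal
#' `L`-only clades inside the host span; `delta_fitch` is the Fitch score
#' difference (ORF1 minus ORF2) of the full lineage labeling.
#'
#' @param orf2_tree,orf1_tree `"phylo"` trees on the same leaf set (the set
#'   restricted to elements that possess the ORF1 region used).
#' @param labels named character vector mapping each leaf to its lineage.
#' @param majority foreign-majority threshold (default 0.5, exclusive).
#' @return A data.frame with one row per candidate: `focal_lineage`,
#'   `host_lineage`, `focal_leaves` (comma-joined), `n_embedding_positions`,
#'   `delta_fitch`, `permutation_p` (NA; fill via [permutation_test()]).
#' @export
detect_embeddings <- function(orf2_tree, orf1_tree, labels, majority = 0.5) {
  l2 <- sort(orf2_tree$tip.label); l1 <- sort(orf1_tree$tip.label)
  if (!identical(l1, l2)) {
    off <- union(setdiff(l1, l2), setdiff(l2, l1))
    stop("trees disagree on leaves: ", paste(off, collapse = ", "))
  }
  missing <- setdiff(l1, names(labels))
  if (length(missing) > 0L) stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "))
  labels <- labels[l1]
  empty <- data.frame(focal_lineage = character(0), host_lineage = character(0),
                      focal_leaves = character(0), n_embedding_positions = integer(0),
                      delta_fitch = integer(0), permutation_p = numeric(0))
  splits2 <- tree_splits(orf2_tree)
  rooted1 <- phangorn::midpoint(ape::unroot(orf1_tree))
  ntip <- length(rooted1$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + rooted1$Nnode)
  parent[rooted1$edge[, 2]] <- rooted1$edge[, 1]
  kids <- split(rooted1$edge[, 2], rooted1$edge[, 1])
  clade_tips <- function(node) {
    if (node <= ntip) return(rooted1$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade_tips), use.names = FALSE)
  }
  df <- fitch_parsimony(orf1_tree, labels) - fitch_parsimony(orf2_tree, labels)
  out <- list()
  for (L in sort(unique(labels))) {
    Lset <- l1[labels == L]
    if (length(Lset) == length(l1)) next
    mono2 <- length(Lset) == 1L ||
      !is.na(key <- split_key(Lset, l1)) && key %in% splits2 ||
      length(Lset) == length(l1) - 1L
    if (!mono2) next
    node <- if (length(Lset) == 1L) match(Lset, rooted1$tip.label)
            else ape::getMRCA(rooted1, Lset)
    repeat {
      tips <- clade_tips(node)
      others <- setdiff(tips, Lset)
      if (length(others) >= length(Lset) || node == root) break
      node <- parent[node]
    }
    others <- setdiff(clade_tips(node), Lset)
    if (length(others) < length(Lset) || length(others) == 0L) next
    tab <- table(labels[others])
    H <- names(tab)[which.max(tab)]
    if (H == L || max(tab) <= majority * length(others)) next
    # host-span check: the host lineage must itself be broken by the focal
    Hset <- l1[labels == H]
    h_node <- if (length(Hset) == 1L) match(Hset, rooted1$tip.label)
              else ape::getMRCA(rooted1, Hset)
    h_tips <- clade_tips(h_node)
    if (!any(Lset %in% h_tips)) next
    # maximal focal-only clades inside the host span
    pure <- vapply(seq_len(ntip + rooted1$Nnode), function(nd) {
      tp <- clade_tips(nd); all(tp %in% Lset)
    }, TRUE)
    in_host <- vapply(seq_len(ntip + rooted1$Nnode), function(nd) {
      all(clade_tips(nd) %in% h_tips)
    }, TRUE)
    n_pos <- sum(vapply(seq_len(ntip + rooted1$Nnode), function(nd) {
      pure[nd] && in_host[nd] && (parent[nd] == 0L || !pure[parent[nd]])
    }, TRUE))
    out[[length(out) + 1L]] <- data.frame(
      focal_lineage = L, host_lineage = H,
      focal_leaves = paste(sort(Lset), collapse = ","),
      n_embedding_positions = max(1L, n_pos),
      delta_fitch = df, permutation_p = NA_real_)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Permutation test for lineage clustering in the ORF1 tree
#'
#' The statistic is the Fitch score of the binary labeling (focal lineage
#' vs. rest) on the ORF1 tree; small scores mean tight clustering. Labels
#' are shuffled uniformly across leaves; the p-value is
#' `(1 + #permutations with statistic <= observed) / (n_perm + 1)`.
#'
#' This quantification has no counterpart in the source analysis (which read
#' the pattern off the tree); it is reported as an auxiliary statistic only.
#'
#' @param orf1_tree a `"phylo"` tree.
#' @param labels named character vector of leaf lineages.
#' @param focal_lineage the lineage whose clustering is tested.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return The permutation p-value.
#' @export
permutation_test <- function(orf1_tree, labels, focal_lineage,
                             n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  tips <- orf1_tree$tip.label
  lab <- labels[tips]
  if (!focal_lineage %in% lab) stop("focal lineage absent from tree: ", focal_lineage)
  binary <- ifelse(lab == focal_lineage, "focal", "other")
  names(binary) <- tips
  rooted <- root_for_fitch(orf1_tree)
  to_idx <- function(b) {
    lv <- unique(b)
    stats::setNames(lapply(b, function(x) match(x, lv)), names(b))
  }
  obs <- fitch_count(rooted, to_idx(binary))
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      perm <- stats::setNames(sample(binary), tips)
      fitch_count(rooted, to_idx(perm)) <= obs
    }, TRUE))
  })
  (1 + hits) / (n_perm + 1)
}

#' Build the ORF1-domain tree
#'
#' Extracts the requested ORF1 region from each element, drops elements that
#' lack it (with a warning), and infers a bootstrap-supported NJ tree.
#' Extracted blocks are positionally homologous by construction (the package
#' pipeline has no indel process), so blocks whose length differs from the
#' modal length are excluded with a warning rather than aligned.
#'
#' @param orf1_seqs named character vector of ORF1 residue strings.
#' @param annotations named list of annotation data.frames
#'   (from [annotate_orf1()]), parallel to `orf1_seqs`.
#' @param region `"rrm_cchc_block"` (first accepted RRM through last
#'   accepted CCHC; requires both) or `"full_orf1"`.
#' @param model distance model, see [distance_matrix()].
#' @param n_boot bootstrap replicates (default 1000 for the ORF1 tree).
#' @param seed integer seed.
#' @return List with `tree` (a `"phylo"` with supports), `used` (leaf ids)
#'   and `excluded` (ids dropped, with reasons).
#' @export
build_orf1_tree <- function(orf1_seqs, annotations,
                            region = c("rrm_cchc_block", "full_orf1"),
                            model = "kimura_aa", n_boot = 1000L, seed = 1L) {
  region <- match.arg(region)
  blocks <- character(0)
  excluded <- character(0)
  for (id in names(orf1_seqs)) {
    seq <- orf1_seqs[[id]]
    if (region == "full_orf1") {
      if (nzchar(seq)) blocks[id] <- seq
      else excluded[id] <- "empty ORF1"
      next
    }
    ann <- annotations[[id]]
    acc <- ann[ann$accepted, , drop = FALSE]
    rrm <- acc[acc$domain == "RRM", , drop = FALSE]
    cchc <- acc[acc$domain == "CCHC", , drop = FALSE]
    if (nrow(rrm) == 0L || nrow(cchc) == 0L || max(cchc$end) <= min(rrm$start)) {
      excluded[id] <- "no RRM+CCHC block"
      next
    }
    blocks[id] <- substr(seq, min(rrm$start) + 1L, max(cchc$end))
  }
  if (length(blocks) > 0L) {
    lens <- nchar(blocks)
    modal <- as.integer(names(which.max(table(lens))))
    off <- names(blocks)[lens != modal]
    if (length(off) > 0L) {
      warning("excluding ", length(off), " element(s) with non-modal block length: ",
              paste(off, collapse = ", "))
      for (id in off) excluded[id] <- "non-modal block length"
      blocks <- blocks[lens == modal]
    }
  }
  if (length(excluded) > 0L && length(blocks) > 0L) {
    message("ORF1 tree: excluded ", length(excluded), " element(s) lacking the region")
  }
  if (length(blocks) < 3L) {
    return(list(tree = NULL, used = names(blocks), excluded = excluded))
  }
  tree <- bootstrap_support(blocks, model = model, n_reps = n_boot, seed = seed)
  list(tree = tree, used = names(blocks), excluded = excluded)
}
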