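# End-to-end orchestration: annotate -> classify -> trees -> clusters ->
# congruence -> summary, with config, per-stage logging and seed control.
# Every output file is stamped with the package version and a config hash;
# reruns with the same inputs, config and seed are byte-identical.

#' Pipeline run configuration
#'
#' @param accept_threshold domain acceptance probability, percent
#'   (default 85).
#' @param model distance model for trees (default `"kimura_aa"`).
#' @param n_boot_orf2 bootstrap replicates for the ORF2 (APE+RT) tree
#'   (default 500).
#' @param n_boot_orf1 bootstrap replicates for the ORF1-domain tree
#'   (default 1000).
#' @param support_floor percent support for subgroup delineation
#'   (default 70).
#' @param attraction_floor z-score floor for similarity clusters
#'   (default 3).
#' @param calib_n null-model size for probability calibration
#'   (default 1000).
#' @param n_perm permutations for the transfer-candidate test (default 999).
#' @param seed master integer seed for every stochastic stage.
#' @return A `"run_config"` list.
#' @export
run_config <- function(accept_threshold = 85, model = "kimura_aa",
                       n_boot_orf2 = 500L, n_boot_orf1 = 1000L,
                       support_floor = 70, attraction_floor = 3,
                       calib_n = 1000L, n_perm = 999L, seed = 1L) {
  stopifnot(accept_threshold >= 0, accept_threshold <= 100,
            support_floor >= 0, n_boot_orf2 >= 1, n_boot_orf1 >= 1,
            calib_n >= 100, n_perm >= 99)
  structure(list(accept_threshold = accept_threshold, model = model,
                 n_boot_orf2 = as.integer(n_boot_orf2),
                 n_boot_orf1 = as.integer(n_boot_orf1),
                 support_floor = support_floor,
                 attraction_floor = attraction_floor,
                 calib_n = as.integer(calib_n), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  fnv1a32(paste(names(config), vapply(config, function(x) paste(format(x), collapse = ","), ""),
                sep = "=", collapse = ";"))
}

stage_log <- function(stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%d out=%d%s", stage, n_in, n_out,
                  if (nzchar(note)) paste0(" ", note) else ""))
}

#' Run the full analysis pipeline
#'
#' Takes element sequences (ORF1/APE/RT regions plus lineage labels),
#' annotates ORF1 domains against the profile library, classifies
#' architectures, builds the bootstrap-supported ORF2 (APE+RT
#' concatenation) tree, delineates subgroups, clusters extracted RRM units,
#' builds the ORF1-domain tree and screens for cross-lineage ORF1
#' transfer, and writes a per-subgroup summary table. All stage outputs are
#' returned; set `out_dir` to also write them as stamped TSV/newick files.
#'
#' @param elements a data.frame with columns `id`, `lineage`, `orf1_seq`,
#'   `ape_seq`, `rt_seq` (as produced by [generate_dataset()]`$elements`),
#'   or an `"orf1_sim"` object.
#' @param library profile library (default packaged library).
#' @param config a `"run_config"`.
#' @param out_dir optional output directory.
#' @return A list with `annotations`, `classifications`, `orf2_tree`,
#'   `subgroups`, `rrm_units`, `similarity`, `clusters`, `layout`,
#'   `orf1_tree`, `transfer_candidates`, `summary`, `config`.
#' @export
run_pipeline <- function(elements, library = default_profile_library(),
                         config = run_config(), out_dir = NULL) {
  if (inherits(elements, "orf1_sim")) elements <- elements$elements
  needed <- c("id", "lineage", "orf1_seq", "ape_seq", "rt_seq")
  if (!all(needed %in% names(elements))) {
    stop("pipeline input failed: elements must have columns ",
         paste(needed, collapse = ", "))
  }
  ids <- elements$id
  orf1 <- stats::setNames(elements$orf1_seq, ids)
  lineage <- stats::setNames(elements$lineage, ids)

  # --- annotation -----------------------------------------------------------
  annotations <- lapply(ids, function(id) {
    ann <- annotate_orf1(orf1[[id]], library,
                         accept_threshold = config$accept_threshold,
                         n_null = config$calib_n,
                         seed = derive_seed(config$seed, 1L))
    ann
  })
  names(annotations) <- ids
  stage_log("annotate", length(ids), sum(vapply(annotations, nrow, 0L) > 0L))

  # --- classification -------------------------------------------------------
  classifications <- do.call(rbind, lapply(ids, function(id) {
    cc <- detect_coiled_coil(orf1[[id]])
    arch <- build_architecture(annotations[[id]], nchar(orf1[[id]]), cc)
    ty <- classify_orf1(arch)
    data.frame(id = id, lineage = lineage[[id]],
               signature = architecture_signature(arch),
               major = ty$major, subtype = ty$subtype,
               type = paste0(ty$major, ty$subtype),
               coverage = arch$coverage,
               context_override = ty$context_override, novel = ty$novel)
  }))
  rownames(classifications) <- NULL
  stage_log("classify", length(ids), nrow(classifications))

  # --- ORF2 (APE+RT) tree ---------------------------------------------------
  concat <- stats::setNames(paste0(elements$ape_seq, elements$rt_seq), ids)
  orf2_tree <- bootstrap_support(concat, model = config$model,
                                 n_reps = config$n_boot_orf2,
                                 seed = derive_seed(config$seed, 2L))
  stage_log("orf2_tree", length(ids), length(orf2_tree$tip.label))

  # --- subgroups ------------------------------------------------------------
  types <- stats::setNames(classifications$type, classifications$id)
  subgroups <- delineate_subgroups(orf2_tree, types, config$support_floor)
  stage_log("subgroups", length(ids), length(unique(subgroups)))

  # --- RRM clustering -------------------------------------------------------
  rrm_units <- extract_rrm_units(orf1, annotations, library)
  similarity <- NULL; clusters <- NULL; layout <- NULL
  if (length(rrm_units) >= 2L) {
    similarity <- all_vs_all_similarity(rrm_units,
                                        seed = derive_seed(config$seed, 3L))
    clusters <- extract_clusters(similarity, config$attraction_floor)
    layout <- force_layout(similarity, seed = derive_seed(config$seed, 4L))
  }
  stage_log("clusters", length(rrm_units),
            if (is.null(clusters)) 0L else length(unique(clusters)))

  # --- ORF1 tree and transfer screen ---------------------------------------
  orf1_fit <- build_orf1_tree(orf1, annotations, region = "rrm_cchc_block",
                              model = config$model, n_boot = config$n_boot_orf1,
                              seed = derive_seed(config$seed, 5L))
  candidates <- data.frame(focal_lineage = character(0), host_lineage = character(0),
                           focal_leaves = character(0),
                           n_embedding_positions = integer(0),
                           delta_fitch = integer(0), permutation_p = numeric(0))
  if (!is.null(orf1_fit$tree)) {
    used <- orf1_fit$used
    sub2 <- ape::keep.tip(orf2_tree, used)
    candidates <- detect_embeddings(sub2, orf1_fit$tree, lineage[used])
    if (nrow(candidates) > 0L) {
      candidates$permutation_p <- vapply(seq_len(nrow(candidates)), function(r) {
        permutation_test(orf1_fit$tree, lineage[used],
                         candidates$focal_lineage[r], n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 6L))
      }, 0)
    }
  }
  stage_log("congruence", length(orf1_fit$used), nrow(candidates))

  # --- summary table --------------------------------------------------------
  summary_df <- summarize_table1_style(elements, annotations, classifications,
                                       subgroups, library, config)
  stage_log("summary", length(unique(subgroups)), nrow(summary_df))

  out <- list(annotations = annotations, classifications = classifications,
              orf2_tree = orf2_tree, subgroups = subgroups,
              rrm_units = rrm_units, similarity = similarity,
              clusters = clusters, layout = layout,
              orf1_tree = orf1_fit$tree, orf1_tree_leaves = orf1_fit$used,
              transfer_candidates = candidates, summary = summary_df,
              config = config)
  if (!is.null(out_dir)) write_report_bundle(out, elements, out_dir)
  out
}

# Write every pipeline product as stamped text files.
write_report_bundle <- function(result, elements, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("orf1evo %s", as.character(utils::packageVersion("orf1evo"))),
           sprintf("config %s", config_hash(result$config)),
           sprintf("seed %d", result$config$seed))
  ann <- do.call(rbind, lapply(names(result$annotations), function(id) {
    a <- result$annotations[[id]]
    if (nrow(a) == 0L) return(NULL)
    cbind(element_id = id, a)
  }))
  if (is.null(ann)) {
    ann <- data.frame(element_id = character(0), domain = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      probability = numeric(0), accepted = logical(0))
  }
  write_tsv(ann, file.path(out_dir, "annotation.tsv"), hdr)
  write_tsv(result$classifications, file.path(out_dir, "classification.tsv"), hdr)
  writeLines(c(paste0("# ", hdr), write_newick(result$orf2_tree)),
             file.path(out_dir, "orf2_tree.nwk"))
  write_tsv(data.frame(id = names(result$subgroups),
                       subgroup = unname(result$subgroups)),
            file.path(out_dir, "subgroups.tsv"), hdr)
  if (!is.null(result$clusters)) {
    write_tsv(data.frame(unit = names(result$clusters),
                         cluster = unname(result$clusters)),
              file.path(out_dir, "rrm_clusters.tsv"), hdr)
    write_tsv(data.frame(unit = rownames(result$layout),
                         x = result$layout[, 1], y = result$layout[, 2]),
              file.path(out_dir, "rrm_layout.tsv"), hdr)
  }
  if (!is.null(result$orf1_tree)) {
    writeLines(c(paste0("# ", hdr), write_newick(result$orf1_tree)),
               file.path(out_dir, "orf1_tree.nwk"))
  }
  write_tsv(result$transfer_candidates,
            file.path(out_dir, "transfer_candidates.tsv"),
            c(hdr, "permutation_p is an auxiliary statistic of this package"))
  write_tsv(result$summary, file.path(out_dir, "summary.tsv"), hdr)
  invisible(out_dir)
}

# Mean over all unordered pairs; NA when fewer than 2 rows.
mean_pairwise_identity <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(NA_real_)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    vals <- c(vals, pairwise_identity(seqs[[i]], seqs[[j]]))
  }
  mean(vals, na.rm = TRUE)
}

# Majority-residue consensus of equal-length sequences.
majority_consensus <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(m, 2L, function(col) names(which.max(table(col)))), collapse = "")
}

#' Per-subgroup summary in the style of the published table
#'
#' For each subgroup: element count, mean pairwise RT identity (missing,
#' not 0, below 2 elements), modal type/subtype, and per accepted domain
#' the minimum observed length, mean pairwise amino-acid identity of the
#' domain instances, the calibrated probability of the subgroup consensus
#' against its profile, and the modal per-element copy number.
#'
#' @param elements element data.frame (see [run_pipeline()]).
#' @param annotations named list of annotation data.frames.
#' @param classifications classification data.frame.
#' @param subgroups named character vector id -> subgroup.
#' @param library profile library.
#' @param config a `"run_config"`.
#' @return A data.frame with one row per (subgroup, domain).
#' @export
summarize_table1_style <- function(elements, annotations, classifications,
                                   subgroups, library = default_profile_library(),
                                   config = run_config()) {
  rows <- list()
  rt <- stats::setNames(elements$rt_seq, elements$id)
  orf1 <- stats::setNames(elements$orf1_seq, elements$id)
  for (sg in sort(unique(subgroups))) {
    ids <- names(subgroups)[subgroups == sg]
    rt_id <- if (length(ids) >= 2L) mean_pairwise_identity(rt[ids]) else NA_real_
    ty <- classifications$type[match(ids, classifications$id)]
    ty_modal <- names(which.max(table(ty)))
    acc <- do.call(rbind, lapply(ids, function(id) {
      a <- annotations[[id]]
      a <- a[a$accepted, , drop = FALSE]
      if (nrow(a) == 0L) return(NULL)
      cbind(element_id = id, a)
    }))
    if (is.null(acc) || nrow(acc) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, n_seqs = length(ids), rt_identity_pct = rt_id,
        type_subtype = ty_modal, domain_label = "none",
        length_aa = NA_integer_, aa_identity_pct = NA_real_,
        probability_pct = NA_real_, n_copies = NA_integer_)
      next
    }
    for (dom in unique(acc$domain)) {
      d <- acc[acc$domain == dom, , drop = FALSE]
      inst <- vapply(seq_len(nrow(d)), function(r) {
        substr(orf1[[d$element_id[r]]], d$start[r] + 1L, d$end[r])
      }, "")
      cons <- majority_consensus(inst)
      hit <- scan_profile(cons, library[[dom]])
      prob <- if (nrow(hit) > 0L) {
        calibrate_probability(max(hit$score), library[[dom]], nchar(cons),
                              n_null = config$calib_n,
                              seed = derive_seed(config$seed, 1L))
      } else NA_real_
      copies <- table(table(d$element_id))
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, n_seqs = length(ids), rt_identity_pct = rt_id,
        type_subtype = ty_modal, domain_label = dom,
        length_aa = min(d$end - d$start),
        aa_identity_pct = if (nrow(d) >= 2L) mean_pairwise_identity(inst) else NA_real_,
        probability_pct = prob,
        n_copies = as.integer(names(which.max(copies))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics over the packaged table fixture
#'
#' Computes, from the fixture rows alone: the range of the domain
#' amino-acid identity column, the number of domain rows with probability
#' strictly below a threshold (missing probabilities excluded), the number
#' of distinct major types over a lineage filter, and the distinct
#' (major, subtype) structure counts per lineage via the classifier (with
#' the published context override).
#'
#' @param rows fixture rows from [load_table1_fixture()].
#' @param prob_threshold probability threshold in percent (default 85).
#' @return A list with `aa_identity_min`, `aa_identity_max`,
#'   `n_below_threshold`, `n_major_types_l2_cr1`, `distinct_structures_l2`,
#'   `distinct_structures_cr1`.
#' @export
fixture_statistics <- function(rows = load_table1_fixture(), prob_threshold = 85) {
  aa <- rows$aa_identity_pct[!is.na(rows$aa_identity_pct)]
  pr <- rows$probability_pct[!is.na(rows$probability_pct)]
  types <- classify_fixture(rows)
  labs <- vapply(types, function(x) paste0(x$major, x$subtype), "")
  lin <- stats::setNames(rows$lineage[!duplicated(rows$subgroup_id)],
                         rows$subgroup_id[!duplicated(rows$subgroup_id)])
  majors <- vapply(types, `[[`, "", "major")
  list(aa_identity_min = min(aa),
       aa_identity_max = max(aa),
       n_below_threshold = sum(pr < prob_threshold),
       n_major_types_l2_cr1 = length(unique(majors[lin[names(majors)] %in% c("L2", "CR1")])),
       distinct_structures_l2 = distinct_structures(labs, lin, "L2"),
       distinct_structures_cr1 = distinct_structures(labs, lin, "CR1"))
}
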