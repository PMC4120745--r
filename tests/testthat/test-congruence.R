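test_that("identical trees yield no transfer candidates", {
  tr <- read_newick("((a:1,b:1):1,((c:1,d:1):1,(e:1,f:1):1):1);")
  labs <- stats::setNames(c("L2", "L2", "CR1", "CR1", "Jockey", "Jockey"),
                          letters[1:6])
  out <- detect_embeddings(tr, tr, labs)
  expect_equal(nrow(out), 0L)
  expect_error(detect_embeddings(tr, read_newick("(a:1,b:1,c:1);"), labs),
               "disagree")
})

test_that("a two-position embedding is detected with the right count", {
  # ORF2: 4 CR1 leaves monophyletic beside 8 L2 leaves
  orf2 <- read_newick(paste0(
    "(((c1:1,c2:1):1,(c3:1,c4:1):1):2,",
    "((l1:1,l2:1):1,((l3:1,l4:1):1,((l5:1,l6:1):1,(l7:1,l8:1):1):1):1):2);"))
  # ORF1: the same CR1 leaves sit at two separate positions inside the L2 clade
  orf1 <- read_newick(paste0(
    "((l1:1,l2:1):3,(((c1:1,c2:1):1,(l3:1,l4:1):1):1,",
    "((c3:1,c4:1):1,((l5:1,l6:1):1,(l7:1,l8:1):1):1):1):3);"))
  labs <- stats::setNames(c(rep("CR1", 4), rep("L2", 8)),
                          c(paste0("c", 1:4), paste0("l", 1:8)))
  out <- detect_embeddings(orf2, orf1, labs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$focal_lineage, "CR1")
  expect_equal(out$host_lineage, "L2")
  expect_equal(out$focal_leaves, "c1,c2,c3,c4")
  expect_equal(out$n_embedding_positions, 2L)
  expect_gte(out$delta_fitch, 1L)
})

test_that("permutation test calibrates against Fitch clustering", {
  # a clean 10-leaf focal clade among 40 leaves: strongly non-random
  others <- orf1evo:::with_seed(3, ape::rtree(30, tip.label = paste0("o", 1:30)))
  focal_clade <- orf1evo:::with_seed(4, ape::rtree(10, tip.label = paste0("f", 1:10)))
  frag <- function(t) sub(";$", "", write_newick(t))
  tree <- read_newick(paste0("(", frag(others), ":1,", frag(focal_clade), ":1);"))
  tips <- paste0("o", 1:30)
  labs <- stats::setNames(c(rep("other", 30), rep("CR1", 10)), c(tips, paste0("f", 1:10)))
  p <- permutation_test(tree, labs, "CR1", n_perm = 999, seed = 4)
  expect_lte(p, 0.05)
  # single focal leaf: statistic is always 1, p is 1
  labs1 <- labs; labs1[labs1 == "CR1"] <- "other"; labs1[["f1"]] <- "CR1"
  expect_equal(permutation_test(tree, labs1, "CR1", n_perm = 99, seed = 4), 1)
  expect_error(permutation_test(tree, labs, "absent", n_perm = 999), "absent")
})

test_that("permutation p-values are valid (conservative) under random labels", {
  # the Fitch statistic is discrete, so p-values are conservative rather
  # than exactly uniform: P(p <= alpha) must not exceed alpha materially
  orf1evo:::with_seed(55, {
    ps <- vapply(1:100, function(k) {
      tr <- ape::rtree(12)
      labs <- stats::setNames(sample(rep(c("A", "B"), 6)), tr$tip.label)
      permutation_test(tr, labs, "A", n_perm = 199, seed = k)
    }, 0)
    for (alpha in c(0.05, 0.25, 0.5)) {
      margin <- 3 * sqrt(alpha * (1 - alpha) / length(ps))
      expect_lte(mean(ps <= alpha), alpha + margin)
    }
    # and they are not degenerate at 1
    expect_gt(stats::sd(ps), 0.05)
  })
})

test_that("the ORF1 tree builder extracts blocks and handles degenerate input", {
  lib <- default_profile_library()
  block <- paste0(lib$RRM$consensus, random_seq(8, seed = 61), lib$CCHC$consensus)
  seqs <- stats::setNames(rep(paste0(random_seq(20, seed = 62), block,
                                     random_seq(20, seed = 63)), 4),
                          paste0("e", 1:4))
  anns <- lapply(seqs, annotate_orf1, library = lib, n_null = 200, seed = 7)
  fit <- build_orf1_tree(seqs, anns, region = "rrm_cchc_block", n_boot = 10, seed = 2)
  # identical blocks: star-like tree with zero internal branch lengths
  expect_length(fit$used, 4L)
  internal <- fit$tree$edge[, 2] > length(fit$tree$tip.label)
  expect_true(all(fit$tree$edge.length[internal] < 1e-9))
  # an element without the block is excluded with a message, not an error
  seqs2 <- c(seqs, none = random_seq(120, seed = 64))
  anns2 <- c(anns, list(none = annotate_orf1(seqs2[["none"]], lib,
                                             n_null = 200, seed = 7)))
  expect_message(fit2 <- build_orf1_tree(seqs2, anns2, n_boot = 10, seed = 2),
                 "excluded")
  expect_false("none" %in% fit2$used)
})

test_that("simulated transfers are seen by the tree pair, absent ones are not", {
  # no transfer: lineages monophyletic in both trees, no candidates
  sim0 <- generate_dataset(simulation_config(n_taxa = 18, seed = 71))
  tr0 <- sim_trees(sim0)
  labs0 <- stats::setNames(sim0$elements$lineage, sim0$elements$id)
  expect_true(lineage_monophyletic(tr0$orf2, labs0))
  # when every lineage shares a type I root, the ORF1 tree covers all
  # elements and its lineages stay monophyletic without transfer
  archI <- c("RRM", "RRM", "CCHC", "CCHC", "CCHC")
  simI <- generate_dataset(simulation_config(
    n_taxa = 18, seed = 73,
    root_architectures = list(Jockey = archI, L2 = archI, CR1 = archI)))
  trI <- sim_trees(simI)
  labsI <- stats::setNames(simI$elements$lineage, simI$elements$id)
  expect_length(trI$block_ids, 18L)
  expect_true(lineage_monophyletic(trI$orf1, labsI))
  expect_equal(nrow(detect_embeddings(trI$orf2, trI$orf1, labsI)), 0L)
  # with a transfer: focal lineage monophyletic in ORF2 but broken in ORF1
  sim1 <- generate_dataset(simulation_config(
    n_taxa = 18, seed = 72,
    ht_events = list(list(donor = "Jockey", recipient_lineage = "L2"))))
  tr1 <- sim_trees(sim1)
  labs1 <- stats::setNames(sim1$elements$lineage, sim1$elements$id)
  out <- detect_embeddings(ape::keep.tip(tr1$orf2, tr1$block_ids), tr1$orf1,
                           labs1[tr1$block_ids])
  ht <- Filter(function(e) e$kind == "ht", sim1$truth$event_log)[[1]]
  expect_equal(nrow(out), 1L)
  expect_equal(out$focal_leaves, ht$branch)
  expect_equal(out$host_lineage, "Jockey")
})
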