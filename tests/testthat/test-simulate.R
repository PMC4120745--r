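test_that("Yule trees are deterministic, start as cherries, track e^(lambda t)", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_identical(write_newick(simulate_yule_tree(7, 1, seed = 4)),
                   write_newick(simulate_yule_tree(7, 1, seed = 4)))
  counts <- vapply(1:300, function(k) {
    n_lineages_at(simulate_yule_tree(64, 1, seed = 1000 + k), 1.5)
  }, 0L)
  expect_lt(abs(mean(counts) - exp(1.5)) / exp(1.5), 0.1)
})

test_that("protein evolution matches its closed-form substitution probability", {
  tr <- read_newick("(a:0.0001,b:0.8);")
  root <- random_seq(10000, seed = 90)
  leaves <- evolve_protein(tr, root, 0.5, seed = 91)
  pdiff <- mean(orf1evo:::seq_chars(leaves[["a"]]) !=
                orf1evo:::seq_chars(leaves[["b"]]))
  expected <- 19 / 20 * (1 - exp(-20 / 19 * 0.5 * 0.8))
  expect_lt(abs(pdiff - expected), 0.02)
  # zero rate: all leaves equal the root
  tr5 <- simulate_yule_tree(5, 1, seed = 92)
  frozen <- evolve_protein(tr5, "MKVRACDEFG", 0, seed = 93)
  expect_true(all(frozen == "MKVRACDEFG"))
})

test_that("sisters are on average more similar than non-sisters", {
  orf1evo:::with_seed(95, {
    sis <- c(); non <- c()
    for (k in 1:30) {
      tr <- read_newick("((a:0.2,b:0.2):0.4,(c:0.2,d:0.2):0.4);")
      lv <- evolve_protein(tr, random_seq(200), 0.5, seed = k)
      sis <- c(sis, pairwise_identity(lv[["a"]], lv[["b"]]))
      non <- c(non, pairwise_identity(lv[["a"]], lv[["c"]]))
    }
    expect_gt(mean(sis), mean(non))
  })
})

test_that("architecture evolution is inert at zero rates and replays exactly", {
  cfg <- simulation_config(n_taxa = 12, seed = 101)
  sim <- generate_dataset(cfg)
  for (lin in cfg$lineages) {
    ids <- sim$elements$id[sim$elements$lineage == lin]
    for (id in ids) {
      expect_identical(sim$truth$true_architectures[[id]],
                       cfg$root_architectures[[lin]])
    }
  }
  # event-log replay reproduces leaf architectures under events too
  cfg2 <- simulation_config(n_taxa = 15, seed = 102, phd_gain_rate = 1.2,
                            phd_loss_rate = 0.4, esterase_gain_rate = 0.3,
                            ht_events = list(list(donor = "Jockey",
                                                  recipient_lineage = "CR1")))
  sim2 <- generate_dataset(cfg2)
  expect_gt(length(sim2$truth$event_log), 1L)
  replayed <- replay_architectures(sim2$truth, cfg2)
  ids <- names(sim2$truth$true_architectures)
  expect_identical(replayed[ids], sim2$truth$true_architectures[ids])
})

test_that("PHD gain pressure on one lineage shifts its classifications only", {
  cfg <- simulation_config(n_taxa = 15, seed = 103,
                           phd_gain_rate = c(L2 = 8))
  sim <- generate_dataset(cfg)
  cls <- vapply(sim$elements$id, function(id) {
    ty <- classify_orf1(architecture(sim$truth$true_architectures[[id]], 0.5))
    paste0(ty$major, ty$subtype)
  }, "")
  lin <- stats::setNames(sim$elements$lineage, sim$elements$id)
  # L2 roots are Tnp22 (IIA); gained PHDs turn them into IIB/IIC
  expect_true(any(cls[lin == "L2"] %in% c("IIB", "IIC")))
  expect_true(all(cls[lin == "Jockey"] == "IB"))
  expect_true(all(cls[lin == "CR1"] == "IIIA"))
})

test_that("an explicit transfer rewrites recipient ORF1s but not ORF2", {
  cfg0 <- simulation_config(n_taxa = 12, seed = 104)
  sim0 <- generate_dataset(cfg0)
  recipients <- sim0$elements$id[sim0$elements$lineage == "L2"][1:2]
  # recipients must form a clade; take sisters from the lineage subtree
  l2_tree <- ape::keep.tip(sim0$tree, sim0$elements$id[sim0$elements$lineage == "L2"])
  pair <- NULL
  for (nd in (length(l2_tree$tip.label) + 1L):(length(l2_tree$tip.label) + l2_tree$Nnode)) {
    tips <- ape::extract.clade(l2_tree, nd)$tip.label
    if (length(tips) == 2L) { pair <- tips; break }
  }
  cfg1 <- simulation_config(n_taxa = 12, seed = 104,
                            ht_events = list(list(donor = "Jockey",
                                                  recipients = pair)))
  sim1 <- generate_dataset(cfg1)
  for (id in pair) {
    expect_identical(architecture_signature(sim1$truth$true_architectures[[id]]),
                     "RRMx2-CCHCx3")
  }
  # ORF2 regions untouched by the transfer
  expect_identical(sim1$elements$ape_seq, sim0$elements$ape_seq)
  expect_identical(sim1$elements$rt_seq, sim0$elements$rt_seq)
  expect_error(generate_dataset(simulation_config(
    n_taxa = 12, seed = 104,
    ht_events = list(list(donor = "Jockey", recipients = c("nope_t1", pair))))),
    "recipient")
})

test_that("dataset generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_taxa = 10, seed = 105,
                           ht_events = list(list(donor = "Jockey",
                                                 recipient_lineage = "L2",
                                                 n_recipients = c(2, 3))))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("lineage recovery from tree plus types reaches high adjusted Rand", {
  aris <- vapply(1:20, function(k) {
    sim <- generate_dataset(simulation_config(n_taxa = 15, seed = 200 + k))
    el <- sim$elements
    concat <- stats::setNames(paste0(el$ape_seq, el$rt_seq), el$id)
    bt <- bootstrap_support(concat, n_reps = 50, seed = k)
    types <- vapply(el$id, function(id) {
      ty <- classify_orf1(architecture(sim$truth$true_architectures[[id]], 0.5))
      paste0(ty$major, ty$subtype)
    }, "")
    part <- delineate_subgroups(bt, types, support_floor = 70)
    mclust::adjustedRandIndex(part[el$id], el$lineage)
  }, 0)
  expect_gte(mean(aris), 0.9)
})
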