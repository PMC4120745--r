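test_that("pairwise identity uses pairwise deletion and is symmetric", {
  expect_equal(pairwise_identity("MKVR", "MKVR"), 100)
  expect_equal(pairwise_identity("AC-T", "AG-T"), 2 / 3 * 100)
  expect_true(is.na(pairwise_identity("--", "AA")))
  expect_error(pairwise_identity("AC", "ACA"), "equal length")
  orf1evo:::with_seed(9, {
    for (k in 1:20) {
      a <- random_seq(50); b <- random_seq(50)
      expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    }
  })
})

test_that("distance corrections match closed forms and their ordering", {
  aln <- c(x = strrep("A", 100), y = paste0(strrep("A", 90), strrep("C", 10)))
  expect_equal(distance_matrix(aln, "p")["x", "y"], 0.1)
  expect_equal(distance_matrix(aln, "poisson")["x", "y"], -log(0.9),
               tolerance = 1e-12)
  expect_equal(distance_matrix(aln, "kimura_aa")["x", "y"],
               -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  expect_equal(unname(distance_matrix(aln, "kimura_aa")["x", "x"]), 0)
  # kimura >= poisson >= p across the working range of p
  for (p in seq(0.01, 0.84, by = 0.05)) {
    expect_gte(-log(1 - p - 0.2 * p^2), -log(1 - p))
    expect_gte(-log(1 - p), p)
  }
  # saturation: distance hits the ceiling and is flagged
  sat <- c(x = strrep("A", 100), y = strrep("C", 100))
  D <- distance_matrix(sat, "kimura_aa", ceiling = 7)
  expect_equal(D["x", "y"], 7)
  expect_true(attr(D, "saturated")["x", "y"])
})

test_that("3-taxon NJ solves the three-point equations", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  cd <- stats::cophenetic(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, ignore_attr = TRUE)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive trees exactly and ignores taxon order", {
  orf1evo:::with_seed(21, {
    for (k in 1:10) {
      ra <- random_additive(sample(6:10, 1))
      tr <- neighbor_joining(ra$D)
      expect_identical(split_set(tr), split_set(ape::unroot(ra$tree)))
      expect_equal(sort(stats::cophenetic(tr)[rownames(ra$D), colnames(ra$D)]),
                   sort(ra$D), tolerance = 1e-9, ignore_attr = TRUE)
      perm <- sample(rownames(ra$D))
      tr2 <- neighbor_joining(ra$D[perm, perm])
      expect_identical(split_set(tr2), split_set(tr))
    }
  })
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  orf1evo:::with_seed(22, {
    for (k in 1:5) {
      ra <- random_additive(8)
      noise <- matrix(stats::runif(64, 0, 0.01), 8, 8)
      noise <- (noise + t(noise)) / 2; diag(noise) <- 0
      D <- ra$D + noise
      expect_identical(split_set(neighbor_joining(D)),
                       split_set(ape::nj(D)))
    }
  })
})

test_that("bootstrap supports behave at the extremes and are seed-stable", {
  # one perfectly informative column pattern duplicated: every resample
  # yields the identical matrix and tree
  base <- c(a = "A", b = "A", c = "C", d = "C")
  aln <- vapply(base, function(s) strrep(s, 40), "")
  bt <- bootstrap_support(aln, model = "p", n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.integer(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  sim <- generate_dataset(simulation_config(n_taxa = 12, seed = 31))
  el <- sim$elements
  concat <- stats::setNames(paste0(el$ape_seq, el$rt_seq), el$id)
  b1 <- bootstrap_support(concat, n_reps = 500, seed = 1)
  b2 <- bootstrap_support(concat, n_reps = 500, seed = 2)
  m1 <- orf1evo:::node_support_map(b1); m2 <- orf1evo:::node_support_map(b2)
  expect_true(all(m1 >= 0 & m1 <= 100))
  shared <- intersect(names(m1), names(m2))
  expect_true(all(abs(m1[shared] - m2[shared]) < 10))
})

test_that("Fitch equals the exhaustive minimum and ignores rooting", {
  labs2 <- c(a = "x", b = "x", c = "y", d = "y", e = "y")
  tr <- read_newick("((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  expect_equal(fitch_parsimony(tr, labs2), 1L)
  expect_equal(fitch_parsimony(tr, stats::setNames(rep("z", 5), letters[1:5])), 0L)
  expect_error(fitch_parsimony(tr, labs2[-1]), "unlabeled")
  orf1evo:::with_seed(41, {
    for (k in 1:10) {
      t0 <- ape::unroot(ape::rtree(sample(5:8, 1)))
      labs <- stats::setNames(sample(c("A", "B", "C"), length(t0$tip.label), TRUE),
                              t0$tip.label)
      expect_equal(fitch_parsimony(t0, labs), brute_fitch(t0, labs))
      rerooted <- ape::root(t0, outgroup = sample(t0$tip.label, 1),
                            resolve.root = TRUE)
      expect_equal(fitch_parsimony(rerooted, labs), fitch_parsimony(t0, labs))
    }
  })
})

test_that("subgroup delineation recovers simulated lineages and honors the floor", {
  sim <- generate_dataset(simulation_config(n_taxa = 15, seed = 8))
  el <- sim$elements
  concat <- stats::setNames(paste0(el$ape_seq, el$rt_seq), el$id)
  bt <- bootstrap_support(concat, n_reps = 100, seed = 3)
  types <- stats::setNames(
    vapply(sim$truth$true_architectures[el$id], function(a) {
      ty <- classify_orf1(architecture(a, 0.5)); paste0(ty$major, ty$subtype)
    }, ""), el$id)
  part <- delineate_subgroups(bt, types, support_floor = 70)
  # the partition equals the simulated lineages
  expect_equal(length(unique(part)), 3L)
  for (g in unique(part)) {
    members <- names(part)[part == g]
    expect_equal(length(unique(el$lineage[match(members, el$id)])), 1L)
  }
  # an unreachable floor forces all singletons
  all_single <- delineate_subgroups(bt, types, support_floor = 101)
  expect_equal(length(unique(all_single)), length(el$id))
  # merging only fuses same-type non-sister groups
  merged <- delineate_subgroups(bt, types, support_floor = 101,
                                merge_same_type = TRUE)
  expect_equal(length(unique(merged)), length(unique(types)))
})
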