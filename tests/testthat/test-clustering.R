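lib <- default_profile_library()

make_units <- function(n_per_family, mut = 0.15, seed = 1) {
  # two families of mutated copies of two unrelated seed units
  orf1evo:::with_seed(seed, {
    seeds <- c(fam1 = random_seq(40), fam2 = random_seq(40))
    units <- character(0)
    for (f in names(seeds)) {
      for (k in seq_len(n_per_family)) {
        chars <- orf1evo:::seq_chars(seeds[[f]])
        flip <- which(stats::runif(40) < mut)
        for (p in flip) chars[p] <- sample(setdiff(orf1evo:::AA20, chars[p]), 1)
        units[paste0(f, "_", k)] <- paste(chars, collapse = "")
      }
    }
    units
  })
}

test_that("RRM units are excised between the RNP boxes and tagged U/D", {
  rrm <- lib$RRM
  seq1 <- paste0(random_seq(20, seed = 2), rrm$consensus,
                 random_seq(15, seed = 3), rrm$consensus, random_seq(20, seed = 4))
  seq2 <- paste0(random_seq(20, seed = 5), rrm$consensus, random_seq(20, seed = 6))
  seqs <- c(two = seq1, one = seq2)
  anns <- lapply(seqs, annotate_orf1, library = lib["RRM"], n_null = 200, seed = 2)
  units <- extract_rrm_units(seqs, anns, lib)
  expect_setequal(names(units), c("two_U", "two_D", "one"))
  # for an exact consensus hit the excised length is rnp1.start - rnp2.end
  expect_equal(unique(nchar(units)), rrm$rnp1_span[1] - rrm$rnp2_span[2])
  inner <- substr(rrm$consensus, rrm$rnp2_span[2] + 1, rrm$rnp1_span[1])
  expect_equal(unname(units["one"]), inner)
})

test_that("similarity attraction separates identity from noise", {
  u <- c(a = random_seq(40, seed = 11), b = random_seq(40, seed = 12))
  u["a2"] <- u[["a"]]
  g <- all_vs_all_similarity(u, n_shuffle = 100, seed = 3)
  w <- stats::setNames(g$edges$weight, paste(g$edges$a, g$edges$b))
  # the identical pair dominates every other pair
  expect_true("a a2" %in% names(w))
  expect_equal(unname(w["a a2"]), max(g$edges$weight))
  # independent random pairs almost never attract at the z >= 3 floor
  hits <- orf1evo:::with_seed(13, {
    vapply(1:20, function(k) {
      pair <- c(x = random_seq(40), y = random_seq(40))
      gg <- all_vs_all_similarity(pair, n_shuffle = 100, seed = k)
      nrow(gg$edges[gg$edges$weight >= 3, ])
    }, 0L)
  })
  expect_gte(mean(hits == 0L), 0.95)
})

test_that("cluster extraction finds simulated families and refines monotonically", {
  units <- make_units(6, seed = 21)
  g <- all_vs_all_similarity(units, n_shuffle = 100, seed = 4)
  cl <- extract_clusters(g, attraction_floor = 3)
  expect_equal(length(unique(cl)), 2L)
  for (f in c("fam1", "fam2")) {
    expect_equal(length(unique(cl[grep(f, names(cl))])), 1L)
  }
  # raising the floor never merges clusters
  lo <- extract_clusters(g, attraction_floor = 1)
  hi <- extract_clusters(g, attraction_floor = 6)
  same_hi <- utils::combn(names(cl), 2)[, apply(utils::combn(names(cl), 2), 2,
                  function(p) hi[[p[1]]] == hi[[p[2]]]), drop = FALSE]
  expect_true(all(apply(same_hi, 2, function(p) lo[[p[1]]] == lo[[p[2]]])))
  # empty edge set: every node its own cluster
  g0 <- structure(list(nodes = g$nodes,
                       edges = g$edges[0, ]), class = "similarity_graph")
  expect_equal(length(unique(extract_clusters(g0, 3))), length(g$nodes))
  # node input order does not matter
  g_rev <- structure(list(nodes = rev(g$nodes), edges = g$edges),
                     class = "similarity_graph")
  expect_identical(extract_clusters(g_rev, 3)[names(cl)], cl)
})

test_that("U and D units from distinct ancestral domains stay apart", {
  orf1evo:::with_seed(33, {
    anc_u <- random_seq(40); anc_d <- random_seq(40)
    units <- character(0)
    for (k in 1:8) {
      mut <- function(s) {
        ch <- orf1evo:::seq_chars(s)
        for (p in which(stats::runif(40) < 0.15)) {
          ch[p] <- sample(setdiff(orf1evo:::AA20, ch[p]), 1)
        }
        paste(ch, collapse = "")
      }
      units[paste0("el", k, "_U")] <- mut(anc_u)
      units[paste0("el", k, "_D")] <- mut(anc_d)
    }
    g <- all_vs_all_similarity(units, n_shuffle = 100, seed = 5)
    cl <- extract_clusters(g, 3)
    expect_equal(length(unique(cl[grep("_U$", names(cl))])), 1L)
    expect_equal(length(unique(cl[grep("_D$", names(cl))])), 1L)
    expect_false(cl[["el1_U"]] == cl[["el1_D"]])
  })
})

test_that("force layout is deterministic and separates disconnected cliques", {
  nodes <- c(paste0("p", 1:4), paste0("q", 1:4))
  edges <- rbind(
    do.call(rbind, lapply(utils::combn(1:4, 2, simplify = FALSE), function(ij) {
      data.frame(a = paste0("p", ij[1]), b = paste0("p", ij[2]), weight = 5)
    })),
    do.call(rbind, lapply(utils::combn(1:4, 2, simplify = FALSE), function(ij) {
      data.frame(a = paste0("q", ij[1]), b = paste0("q", ij[2]), weight = 5)
    })))
  g <- structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
  xy <- force_layout(g, iterations = 300, seed = 9)
  expect_identical(force_layout(g, iterations = 300, seed = 9), xy)
  cp <- colMeans(xy[1:4, ]); cq <- colMeans(xy[5:8, ])
  diam <- function(m) max(stats::dist(m))
  expect_gt(sqrt(sum((cp - cq)^2)), max(diam(xy[1:4, ]), diam(xy[5:8, ])))
  # single node: position unchanged by iteration
  g1 <- structure(list(nodes = "solo", edges = edges[0, ]),
                  class = "similarity_graph")
  expect_identical(force_layout(g1, iterations = 5, seed = 1),
                   force_layout(g1, iterations = 50, seed = 1))
})
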