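# Reticulate-evolution simulator: a tree-like ORF2 (Yule lineage trees on a
# backbone, Poisson amino-acid substitution) and a modular ORF1 (segmented
# domain+linker states with PHD gain/loss, esterase gain, and whole-ORF1
# cross-lineage transfer), with a replayable ground-truth event log for
# every pipeline stage.

LINEAGE_POOL <- c("Jockey", "L2", "CR1")

# Default root ORF1 architectures per lineage: a type I (two RRMs over three
# CCHC knuckles), a Tnp22-only type II, and a PHD-only type III.
DEFAULT_ROOT_ARCHITECTURES <- list(
  Jockey = c("RRM", "RRM", "CCHC", "CCHC", "CCHC"),
  L2     = "Tnp22",
  CR1    = "PHD")

#' Simulation configuration
#'
#' @param n_taxa total number of elements (split as evenly as possible
#'   across lineages).
#' @param n_lineages number of lineages (1-3 use the Jockey/L2/CR1 labels).
#' @param yule_rate per-lineage speciation rate of the Yule trees.
#' @param subst_rate expected substitutions per site per unit time.
#' @param lineage_height height each lineage tree is scaled to (time units).
#' @param stem_length backbone stem length between lineages (time units).
#' @param root_architectures named list: lineage -> ordered domain labels.
#' @param phd_gain_rate,phd_loss_rate,esterase_gain_rate per-branch event
#'   rates (per unit time); scalars, or vectors named by lineage.
#' @param ht_events `NULL`, or a list of transfer events, each a list with
#'   `donor` (lineage), and either `recipients` (leaf ids forming a clade)
#'   or `recipient_lineage` plus `n_recipients` (size range, default 3:5).
#' @param linker_len,terminal_linker_len inter-domain and terminal linker
#'   lengths (residues).
#' @param ape_len,rt_len lengths of the simulated APE and RT regions.
#' @param seed master integer seed; every stream derives from it.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(n_taxa = 20L, n_lineages = 3L, yule_rate = 1,
                              subst_rate = 0.5, lineage_height = 0.3,
                              stem_length = 0.3,
                              root_architectures = NULL,
                              phd_gain_rate = 0, phd_loss_rate = 0,
                              esterase_gain_rate = 0, ht_events = NULL,
                              linker_len = 10L, terminal_linker_len = 25L,
                              ape_len = 100L, rt_len = 150L, seed = 1L) {
  if (n_lineages < 1L || n_taxa < n_lineages) stop("need n_taxa >= n_lineages >= 1")
  if (any(c(yule_rate, subst_rate, phd_gain_rate, phd_loss_rate,
            esterase_gain_rate) < 0)) stop("rates must be >= 0")
  lineages <- if (n_lineages <= 3L) LINEAGE_POOL[seq_len(n_lineages)]
              else c(LINEAGE_POOL, paste0("Lin", 4:n_lineages))
  if (is.null(root_architectures)) {
    root_architectures <- lapply(seq_len(n_lineages), function(i) {
      DEFAULT_ROOT_ARCHITECTURES[[((i - 1L) %% 3L) + 1L]]
    })
    names(root_architectures) <- lineages
  }
  if (!all(lineages %in% names(root_architectures))) {
    stop("root_architectures must cover every lineage")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_lineages = as.integer(n_lineages),
                 lineages = lineages, yule_rate = yule_rate,
                 subst_rate = subst_rate, lineage_height = lineage_height,
                 stem_length = stem_length,
                 root_architectures = root_architectures,
                 phd_gain_rate = phd_gain_rate, phd_loss_rate = phd_loss_rate,
                 esterase_gain_rate = esterase_gain_rate,
                 ht_events = ht_events, linker_len = as.integer(linker_len),
                 terminal_linker_len = as.integer(terminal_linker_len),
                 ape_len = as.integer(ape_len), rt_len = as.integer(rt_len),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rate_for <- function(rate, lineage) {
  if (length(rate) == 1L && is.null(names(rate))) return(unname(rate))
  if (lineage %in% names(rate)) unname(rate[[lineage]]) else 0
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starts from one lineage at time 0; each lineage splits at rate
#' `yule_rate`; simulation runs until `n_taxa` lineages exist plus one
#' further exponential waiting time, so tips are contemporaneous. Branch
#' lengths are in time units; the stem before the first split is kept as
#' `root.edge`. Deterministic given `seed`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param yule_rate speciation rate.
#' @param seed integer seed.
#' @return A rooted, ultrametric `"phylo"` tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_taxa, yule_rate = 1, seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  with_seed(seed, {
    birth <- c(0)
    kids <- list()
    active <- 1L
    nid <- 1L
    t <- 0
    while (length(active) < n_taxa) {
      k <- length(active)
      t <- t + stats::rexp(1, k * yule_rate)
      sp <- active[sample.int(k, 1L)]
      a <- nid + 1L; b <- nid + 2L; nid <- nid + 2L
      birth[a] <- birth[b] <- t
      kids[[sp]] <- c(a, b)
      active <- c(setdiff(active, sp), a, b)
    }
    t_end <- t + stats::rexp(1, n_taxa * yule_rate)
    tip_label <- stats::setNames(paste0("t", seq_along(active)), sort(active))
    fmt <- function(x) formatC(x, format = "g", digits = 15)
    frag <- function(x) {
      if (is.null(kids[x][[1]])) return(tip_label[[as.character(x)]])
      ch <- kids[[x]]
      ends <- vapply(ch, function(c2) {
        if (is.null(kids[c2][[1]])) t_end else birth[kids[[c2]][1]]
      }, 0)
      sprintf("(%s:%s,%s:%s)",
              frag(ch[1]), fmt(ends[1] - birth[ch[1]]),
              frag(ch[2]), fmt(ends[2] - birth[ch[2]]))
    }
    tree <- read_newick(paste0(frag(1L), ";"))
    tree$root.edge <- birth[kids[[1L]][1]]
    tree
  })
}

#' Number of lineages alive at a time point
#'
#' Counts branches of a clock tree crossing time `t`, measured from the
#' origin (the start of the `root.edge` stem when present).
#'
#' @param tree a clock `"phylo"` tree from [simulate_yule_tree()].
#' @param t time from the origin.
#' @return Integer lineage count.
#' @export
n_lineages_at <- function(tree, t) {
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  s <- t - stem
  if (s < 0) return(1L)
  d <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  crossing <- sum(d[tree$edge[, 1]] <= s & s < d[tree$edge[, 2]])
  ended <- sum(seq_len(ntip) %in% tree$edge[, 2][s >= d[tree$edge[, 2]]])
  as.integer(crossing + ended)   # capped tips persist at the boundary
}

# Scale a tree so its root-to-tip height is `height`.
scale_tree_height <- function(tree, height) {
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * height / h
  tree$root.edge <- NULL
  tree
}

# One Markov substitution pass: Poisson event count, uniform positions,
# replacement uniform over the 19 other residues, applied sequentially.
mutate_seq <- function(seq, rate, t) {
  L <- nchar(seq)
  if (L == 0L || rate * t == 0) return(seq)
  nsub <- stats::rpois(1, rate * L * t)
  if (nsub == 0L) return(seq)
  chars <- seq_chars(seq)
  pos <- sample.int(L, nsub, replace = TRUE)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Evolve a protein along a tree
#'
#' Per-branch Poisson substitution counts at `subst_rate` per site per unit
#' time; replacements are uniform over the other 19 residues; no indels.
#'
#' @param tree a `"phylo"` tree with branch lengths in time units.
#' @param root_seq residue string at the root.
#' @param subst_rate substitutions per site per unit time.
#' @param seed integer seed.
#' @return Named character vector of leaf sequences.
#' @export
evolve_protein <- function(tree, root_seq, subst_rate, seed = 1L) {
  if (!nzchar(root_seq)) stop("root_seq must be non-empty")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    state <- list()
    out <- character(0)
    walk <- function(node, seq) {
      if (node <= ntip) { out[tree$tip.label[node]] <<- seq; return(invisible()) }
      for (e in kids[[as.character(node)]]) {
        walk(tree$edge[e, 2], mutate_seq(seq, subst_rate, tree$edge.length[e]))
      }
    }
    walk(ntip + 1L, root_seq)
    out
  })
}

# ---- segmented ORF1 states -------------------------------------------------

# A state is a list of segments list(label=, seq=); "linker" segments are
# unlabeled spacers, every other label is a domain.
state_arch <- function(state) {
  labs <- vapply(state, `[[`, "", "label")
  labs[labs != "linker"]
}

state_seq <- function(state) {
  paste(vapply(state, `[[`, "", "seq"), collapse = "")
}

# Root state for an ordered architecture; linkers drawn from background.
build_root_state <- function(arch_labels, library, linker_len, terminal_len) {
  state <- list(list(label = "linker", seq = random_residues(terminal_len)))
  for (i in seq_along(arch_labels)) {
    lab <- arch_labels[i]
    prof <- library[[lab]]
    if (is.null(prof)) stop("no profile for root domain ", lab)
    state[[length(state) + 1L]] <- list(label = lab, seq = prof$consensus)
    state[[length(state) + 1L]] <- list(
      label = "linker",
      seq = random_residues(if (i == length(arch_labels)) terminal_len else linker_len))
  }
  state
}

mutate_state <- function(state, rate, t) {
  lapply(state, function(s) list(label = s$label, seq = mutate_seq(s$seq, rate, t)))
}

# Apply architecture events along one branch; returns list(state, events).
branch_arch_events <- function(state, lineage, t, config, library) {
  events <- list()
  dom_idx <- function(st) which(vapply(st, `[[`, "", "label") != "linker")
  n_gain <- stats::rpois(1, rate_for(config$phd_gain_rate, lineage) * t)
  n_loss <- stats::rpois(1, rate_for(config$phd_loss_rate, lineage) * t)
  n_est <- stats::rpois(1, rate_for(config$esterase_gain_rate, lineage) * t)
  for (k in seq_len(n_gain)) {
    ins <- list(list(label = "PHD", seq = library$PHD$consensus),
                list(label = "linker", seq = random_residues(config$linker_len)))
    di <- dom_idx(state)
    at_n <- length(di) == 0L || stats::runif(1) < 0.5
    if (at_n) {
      state <- append(state, ins, after = 1L)   # after the leading linker
      pos <- 0L
    } else {
      slot <- di[sample.int(length(di), 1L)]
      state <- append(state, ins, after = slot)
      pos <- match(slot, di)
    }
    events[[length(events) + 1L]] <- list(kind = "phd_gain", position = pos)
  }
  for (k in seq_len(n_loss)) {
    di <- dom_idx(state)
    phd <- di[vapply(state[di], `[[`, "", "label") == "PHD"]
    if (length(phd) == 0L) next
    victim <- phd[sample.int(length(phd), 1L)]
    pos <- match(victim, di)
    state <- state[-victim]
    events[[length(events) + 1L]] <- list(kind = "phd_loss", position = pos)
  }
  for (k in seq_len(n_est)) {
    state <- append(state, list(list(label = "Esterase",
                                     seq = library$Esterase$consensus)),
                    after = length(state) - 1L)   # before the trailing linker
    events[[length(events) + 1L]] <- list(kind = "esterase_gain",
                                          position = length(dom_idx(state)))
  }
  list(state = state, events = events)
}

# Evolve segmented states down a rooted subtree; logs events keyed by the
# child clade's sorted leaf set. Returns list(node_states, leaf_states, log).
evolve_states_down <- function(tree, root_state, lineage, config, library) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_states <- vector("list", ntip + tree$Nnode)
  log <- list()
  clade_leaves <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[kids[[as.character(node)]], 2], clade_leaves),
           use.names = FALSE)
  }
  walk <- function(node, state) {
    node_states[[node]] <<- state
    if (node <= ntip) return(invisible())
    for (e in kids[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      ev <- branch_arch_events(state, lineage, t, config, library)
      for (rec in ev$events) {
        rec$lineage <- lineage
        rec$branch <- paste(sort(clade_leaves(child)), collapse = ",")
        log[[length(log) + 1L]] <<- rec
      }
      walk(child, mutate_state(ev$state, config$subst_rate, t))
    }
  }
  walk(ntip + 1L, root_state)
  leaf_states <- stats::setNames(node_states[seq_len(ntip)], tree$tip.label)
  list(node_states = node_states, leaf_states = leaf_states, log = log)
}

#' Evolve ORF1 architectures and sequences along a tree
#'
#' Each lineage's clade evolves independently from its configured root
#' architecture: PHD gain (N-terminal or downstream slot with equal odds),
#' PHD loss and esterase gain are Poisson events per branch; all segments
#' accumulate substitutions at `subst_rate`. Horizontal-transfer events
#' replace a recipient clade's entire ORF1 state with the donor lineage's
#' state at a donor node, after which the recipient clade re-evolves; every
#' event is appended to a replayable log.
#'
#' @param tree the full element tree (lineage clades must be monophyletic).
#' @param config a `"simulation_config"`.
#' @param lineages named character vector leaf -> lineage.
#' @param library profile library supplying domain consensus seeds.
#' @return A ground-truth list: `true_tree`, `true_lineages`,
#'   `true_architectures` (leaf -> label vector), `orf1_seqs`,
#'   `event_log`, and internal `states`.
#' @export
evolve_architecture <- function(tree, config, lineages,
                                library = default_profile_library()) {
  with_seed(derive_seed(config$seed, 11L), {
    log <- list()
    leaf_states <- list()
    subtrees <- list()
    runs <- list()
    for (lin in config$lineages) {
      leaves <- names(lineages)[lineages == lin]
      sub <- if (length(leaves) == length(tree$tip.label)) tree
             else ape::keep.tip(tree, leaves)
      subtrees[[lin]] <- sub
      root_state <- build_root_state(config$root_architectures[[lin]], library,
                                     config$linker_len, config$terminal_linker_len)
      run <- evolve_states_down(sub, root_state, lin, config, library)
      runs[[lin]] <- run
      leaf_states <- c(leaf_states, run$leaf_states)
      log <- c(log, run$log)
    }
    for (ev in config$ht_events %||% list()) {
      donor <- ev$donor
      if (!donor %in% config$lineages) stop("HT donor lineage unknown: ", donor)
      # recipients: explicit clade, or a random clade of the requested size
      if (!is.null(ev$recipients)) {
        recipients <- ev$recipients
        rec_lin <- unique(lineages[recipients])
        if (length(rec_lin) != 1L) stop("HT recipients must be one lineage")
      } else {
        rec_lin <- ev$recipient_lineage
        sub <- subtrees[[rec_lin]]
        ntip <- length(sub$tip.label)
        size_range <- ev$n_recipients %||% c(3L, 5L)
        sizes <- vapply((ntip + 1L):(ntip + sub$Nnode), function(nd) {
          length(ape::extract.clade(sub, nd)$tip.label)
        }, 0L)
        ok <- which(sizes >= size_range[1] & sizes <= size_range[2] & sizes < ntip)
        if (length(ok) == 0L) ok <- which(sizes < ntip)[which.min(abs(sizes[sizes < ntip] - size_range[1]))]
        nd <- (ntip + 1L):(ntip + sub$Nnode)
        pick <- nd[ok[sample.int(length(ok), 1L)]]
        recipients <- ape::extract.clade(sub, pick)$tip.label
      }
      if (!all(recipients %in% tree$tip.label)) {
        stop("HT recipient(s) not in tree: ",
             paste(setdiff(recipients, tree$tip.label), collapse = ", "))
      }
      # donor state: a random internal non-root node of the donor clade, so
      # recipients nest inside (not sister to) the donor lineage
      dsub <- subtrees[[donor]]
      dntip <- length(dsub$tip.label)
      cand <- if (dsub$Nnode > 1L) (dntip + 2L):(dntip + dsub$Nnode) else dntip + 1L
      dnode <- cand[sample.int(length(cand), 1L)]
      donor_state <- runs[[donor]]$node_states[[dnode]]
      # re-evolve the recipient clade from the donor state
      rsub <- subtrees[[rec_lin]]
      rtree <- if (length(recipients) == 1L) NULL
               else ape::extract.clade(rsub, ape::getMRCA(rsub, recipients))
      branch_key <- paste(sort(recipients), collapse = ",")
      # drop superseded events inside the replaced clade
      log <- Filter(function(rec) {
        !(rec$lineage == rec_lin &&
          all(strsplit(rec$branch, ",", fixed = TRUE)[[1]] %in% recipients))
      }, log)
      log[[length(log) + 1L]] <- list(
        kind = "ht", lineage = rec_lin, branch = branch_key,
        donor = donor, donor_arch = state_arch(donor_state))
      if (is.null(rtree)) {
        leaf_states[[recipients]] <- donor_state
      } else {
        rerun <- evolve_states_down(rtree, donor_state, rec_lin, config, library)
        leaf_states[rtree$tip.label] <- rerun$leaf_states
        log <- c(log, rerun$log)
      }
    }
    list(true_tree = tree,
         true_lineages = lineages,
         true_architectures = lapply(leaf_states, state_arch),
         orf1_seqs = vapply(leaf_states, state_seq, ""),
         event_log = log,
         states = leaf_states)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay an event log to leaf architectures
#'
#' Applies the logged gain/loss/transfer events along the true tree starting
#' from the configured root architectures, using only the log (no
#' sequences). Reproducing `true_architectures` exactly is the simulator's
#' core bookkeeping invariant.
#'
#' @param truth ground truth from [evolve_architecture()].
#' @param config the `"simulation_config"` used.
#' @return Named list of leaf label vectors.
#' @export
replay_architectures <- function(truth, config) {
  tree <- truth$true_tree
  lineages <- truth$true_lineages
  log <- truth$event_log
  apply_events <- function(arch, events) {
    for (ev in events) {
      if (ev$kind == "phd_gain") {
        arch <- if (ev$position == 0L) c("PHD", arch)
                else append(arch, "PHD", after = ev$position)
      } else if (ev$kind == "phd_loss") {
        # position indexes the removed domain in pre-removal domain order
        arch <- arch[-ev$position]
      } else if (ev$kind == "esterase_gain") {
        arch <- c(arch, "Esterase")
      } else if (ev$kind == "ht") {
        arch <- ev$donor_arch
      }
    }
    arch
  }
  out <- list()
  for (lin in config$lineages) {
    leaves <- names(lineages)[lineages == lin]
    sub <- if (length(leaves) == length(tree$tip.label)) tree
           else ape::keep.tip(tree, leaves)
    ntip <- length(sub$tip.label)
    kids <- split(seq_len(nrow(sub$edge)), sub$edge[, 1])
    clade_leaves <- function(node) {
      if (node <= ntip) return(sub$tip.label[node])
      unlist(lapply(sub$edge[kids[[as.character(node)]], 2], clade_leaves),
             use.names = FALSE)
    }
    # HT events re-seed a whole clade; handle them by branch key like others
    walk <- function(node, arch) {
      key <- paste(sort(clade_leaves(node)), collapse = ",")
      evs <- Filter(function(rec) rec$lineage == lin && rec$branch == key, log)
      for (ev in evs) arch <- apply_events(arch, list(ev))
      if (node <= ntip) { out[[sub$tip.label[node]]] <<- arch; return(invisible()) }
      for (e in kids[[as.character(node)]]) walk(sub$edge[e, 2], arch)
    }
    walk(ntip + 1L, config$root_architectures[[lin]])
  }
  out
}

#' Generate a full synthetic dataset
#'
#' Builds per-lineage Yule trees scaled to a common height, joins them on a
#' backbone, evolves APE and RT regions along the joined tree, evolves
#' segmented ORF1 states with the configured event rates and transfers, and
#' returns everything with ground truth. Fully reproducible from the config
#' seed.
#'
#' @param config a `"simulation_config"`.
#' @param library profile library used for domain consensus seeds.
#' @return An object of class `"orf1_sim"`: list with `config`, `tree`,
#'   `elements` (data.frame id/lineage/orf1_seq/ape_seq/rt_seq) and `truth`.
#' @export
generate_dataset <- function(config = simulation_config(),
                             library = default_profile_library()) {
  stopifnot(inherits(config, "simulation_config"))
  sizes <- diff(round(seq(0, config$n_taxa, length.out = config$n_lineages + 1L)))
  subtrees <- list()
  for (i in seq_len(config$n_lineages)) {
    lin <- config$lineages[i]
    n_i <- max(2L, sizes[i])
    sub <- simulate_yule_tree(n_i, config$yule_rate,
                              seed = derive_seed(config$seed, i))
    sub <- scale_tree_height(sub, config$lineage_height)
    sub$tip.label <- paste0(lin, "_t", seq_len(n_i))
    subtrees[[lin]] <- sub
  }
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  frags <- vapply(subtrees, function(s) sub(";$", "", write_newick(s)), "")
  nwk <- frags[1]
  for (i in seq_along(frags)[-1]) {
    nwk <- sprintf("(%s:%s,%s:%s)", nwk, fmt(config$stem_length),
                   frags[i], fmt(config$stem_length))
  }
  tree <- read_newick(paste0(nwk, ";"))
  lineages <- stats::setNames(sub("_t[0-9]+$", "", tree$tip.label), tree$tip.label)
  ape_root <- with_seed(derive_seed(config$seed, 101L), random_residues(config$ape_len))
  rt_root <- with_seed(derive_seed(config$seed, 102L), random_residues(config$rt_len))
  ape_seqs <- evolve_protein(tree, ape_root, config$subst_rate,
                             seed = derive_seed(config$seed, 103L))
  rt_seqs <- evolve_protein(tree, rt_root, config$subst_rate,
                            seed = derive_seed(config$seed, 104L))
  truth <- evolve_architecture(tree, config, lineages, library)
  ids <- tree$tip.label
  elements <- data.frame(
    id = ids, lineage = unname(lineages[ids]),
    orf1_seq = unname(truth$orf1_seqs[ids]),
    ape_seq = unname(ape_seqs[ids]), rt_seq = unname(rt_seqs[ids]),
    stringsAsFactors = FALSE)
  structure(list(config = config, tree = tree, elements = elements,
                 truth = truth),
            class = "orf1_sim")
}

#' @export
print.orf1_sim <- function(x, ...) {
  cat(sprintf("<orf1_sim: %d elements, %d lineages, seed %d, %d logged events>\n",
              nrow(x$elements), x$config$n_lineages, x$config$seed,
              length(x$truth$event_log)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `orf1.fasta`, `ape.fasta`, `rt.fasta`, `true_tree.nwk`,
#' `truth.tsv` (id, lineage, architecture signature) and `event_log.json`.
#' Two runs with the same config produce byte-identical files.
#'
#' @param sim an `"orf1_sim"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- sim$elements
  write_fasta(stats::setNames(el$orf1_seq, el$id), file.path(dir, "orf1.fasta"))
  write_fasta(stats::setNames(el$ape_seq, el$id), file.path(dir, "ape.fasta"))
  write_fasta(stats::setNames(el$rt_seq, el$id), file.path(dir, "rt.fasta"))
  writeLines(write_newick(sim$tree), file.path(dir, "true_tree.nwk"))
  truth_df <- data.frame(
    id = el$id, lineage = el$lineage,
    architecture = vapply(sim$truth$true_architectures[el$id],
                          architecture_signature, ""))
  write_tsv(truth_df, file.path(dir, "truth.tsv"),
            header_lines = sprintf("orf1evo simulation, seed %d", sim$config$seed))
  writeLines(jsonlite::toJSON(sim$truth$event_log, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "event_log.json"))
  invisible(dir)
}
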