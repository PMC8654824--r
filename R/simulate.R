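# Species-structured sequence simulator. A Yule species tree sets the
# between-species divergences; each species tip is replaced by a star of
# individuals with short pendant branches (within-species divergence);
# sequences evolve along the resulting tree under the Kimura 2-parameter
# substitution process. Confusable species pairs share their species-level
# sequence, so their interspecific divergence collapses to the
# within-species level.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults
#' describe a "clean" barcode library: well separated species with little
#' within-species variation.
#'
#' @param n_species number of species (>= 2).
#' @param individuals_per_species either a single count or a
#'   `c(min, max)` range sampled uniformly per species (default 5).
#' @param seq_length alignment length in bases (default 800).
#' @param kappa transition/transversion rate ratio, i.e. the rate of
#'   transitions relative to the *total* transversion rate (default 2;
#'   0.5 makes all three alternative bases equally likely).
#' @param inter_scale species-tree root-to-tip height in expected
#'   substitutions/site (default 0.2).
#' @param intra_scale upper bound of the uniform pendant length of each
#'   individual, in expected substitutions/site (default 0.005).
#' @param n_confusable_pairs number of species pairs generated with zero
#'   species-level divergence, emulating cryptic or confused taxa
#'   (default 0). Pairs are taken as species (1,2), (3,4), ...
#' @param missing_fraction per-locus probability that a sample is missing,
#'   used by the multi-locus benchmark (default 0).
#' @param min_split minimum depth (substitutions/site from the present) of
#'   any species split. The Yule process piles splits up near the present;
#'   flooring the shallowest splits keeps the simulated taxonomy
#'   identifiable at the configured within-species noise, which is what
#'   the "clean" benchmark promises by construction. Default
#'   `max(4 * intra_scale, 0.05 * inter_scale)`.
#' @param locus locus name attached to simulated alignments
#'   (default "SIM").
#' @param seed integer seed; every generator call is deterministic given
#'   the configuration (default 1).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 30L, individuals_per_species = 5L,
                       seq_length = 800L, kappa = 2,
                       inter_scale = 0.2, intra_scale = 0.005,
                       n_confusable_pairs = 0L, missing_fraction = 0,
                       min_split = NULL, locus = "SIM", seed = 1L) {
  stopifnot(n_species >= 2L, seq_length > 0L, kappa >= 0,
            inter_scale >= 0, intra_scale >= 0,
            n_confusable_pairs >= 0L,
            2L * n_confusable_pairs <= n_species,
            missing_fraction >= 0, missing_fraction < 1)
  if (is.null(min_split))
    min_split <- max(4 * intra_scale, 0.05 * inter_scale)
  structure(list(
    n_species = as.integer(n_species),
    individuals_per_species = as.integer(individuals_per_species),
    seq_length = as.integer(seq_length), kappa = kappa,
    inter_scale = inter_scale, intra_scale = intra_scale,
    n_confusable_pairs = as.integer(n_confusable_pairs),
    missing_fraction = missing_fraction, min_split = min_split,
    locus = locus, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

.sim_species_names <- function(n) sprintf("Simulated_sp%03d", seq_len(n))

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology with exponential waiting times, scaled so
#' that the root-to-tip height equals `inter_scale`; split depths
#' shallower than `min_split` are floored (see [sim_config()]).
#' Deterministic for a given configuration.
#'
#' @param cfg a [sim_config()].
#' @return an ultrametric `phylo` tree whose tips are species.
#' @export
simulate_species_tree <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_species
  # forward pure-birth: lineage k splits at total rate k
  parent <- c(0L)      # internal node parents; node 1 = root
  ntime <- c(0)        # internal node times (root at 0)
  active <- c(1L, 1L)  # parent node of each active lineage
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1L, k)
    idx <- sample.int(k, 1L)
    parent <- c(parent, active[idx])
    ntime <- c(ntime, t)
    m <- length(parent)
    active[idx] <- m
    active <- c(active, m)
  }
  t_end <- t + stats::rexp(1L, n)
  depth <- (t_end - ntime) / t_end * cfg$inter_scale
  # floor shallow splits, propagating so parents stay at least as deep
  for (m in rev(seq_along(depth))) {
    depth[m] <- max(depth[m], cfg$min_split)
    if (parent[m] > 0L) depth[parent[m]] <- max(depth[parent[m]], depth[m])
  }
  tip_parent <- active
  tip_names <- .sim_species_names(n)
  build <- function(node) {
    kids_int <- which(parent == node)
    kids_int <- kids_int[kids_int != node]
    kids_tip <- which(tip_parent == node)
    parts <- c(
      vapply(kids_int, function(m)
        paste0(build(m), ":", .nwk_num(depth[node] - depth[m])),
        character(1L)),
      vapply(kids_tip, function(i)
        paste0(tip_names[i], ":", .nwk_num(depth[node])), character(1L)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(1L), ";"))
}

#' Expand a species tree into an individual-level tree
#'
#' Replaces every species tip with a star of its individuals; pendant
#' branch lengths are drawn uniformly on `[0, intra_scale]`. Confusable
#' pairs are merged at the species level: both species' individuals hang
#' from the same point, so only the pendants separate them.
#'
#' @param species_tree a `phylo` from [simulate_species_tree()].
#' @param cfg a [sim_config()].
#' @return a `phylo` whose tips are individuals, with attributes
#'   `"species"` (named map tip -> species) and `"confusable"` (list of
#'   species pairs sharing a species-level sequence).
#' @export
simulate_individuals <- function(species_tree, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  n <- cfg$n_species
  sp <- .sim_species_names(n)
  ipr <- cfg$individuals_per_species
  k <- if (length(ipr) == 1L) rep(ipr, n)
       else sample(seq(ipr[1L], ipr[2L]), n, replace = TRUE)
  pairs <- list()
  host <- seq_len(n)  # species whose tip hosts each species' star
  if (cfg$n_confusable_pairs > 0L)
    for (p in seq_len(cfg$n_confusable_pairs)) {
      a <- 2L * p - 1L; b <- 2L * p
      pairs[[p]] <- c(sp[a], sp[b])
      host[b] <- a
    }
  drop <- setdiff(seq_len(n), unique(host))
  tr <- species_tree
  if (length(drop)) tr <- ape::drop.tip(tr, sp[drop])
  nwk <- ape::write.tree(tr)
  species_map <- character(0)
  for (h in unique(host)) {
    members <- which(host == h)
    labs <- unlist(lapply(members, function(i)
      sprintf("s%03d_%02d", i, seq_len(k[i]))))
    species_map[labs] <- rep(sp[members], k[members])
    pend <- if (cfg$intra_scale > 0)
      stats::runif(length(labs), 0, cfg$intra_scale)
      else rep(0, length(labs))
    star <- paste0("(", paste0(labs, ":", .nwk_num(pend), collapse = ","),
                   ")")
    nwk <- sub(paste0(sp[h], ":"), paste0(star, ":"), nwk, fixed = TRUE)
  }
  out <- ape::read.tree(text = nwk)
  attr(out, "species") <- species_map[out$tip.label]
  attr(out, "confusable") <- pairs
  out
}

# One K2P substitution step along a branch of length len (expected
# substitutions/site); x is an integer sequence over 1:4 = A,C,G,T.
.k2p_mutate <- function(x, len, kappa) {
  if (len <= 0) return(x)
  beta_t <- len / (2 * (kappa + 1))
  alpha_t <- kappa * len / (kappa + 1)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta_t) - 0.5 * exp(-2 * (alpha_t + beta_t))
  q_each <- 0.25 - 0.25 * exp(-4 * beta_t)
  p_same <- 1 - p_ts - 2 * q_each
  r <- stats::runif(length(x))
  partner <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  y <- x
  y[r >= p_same & r < p_same + p_ts] <-
    partner[x[r >= p_same & r < p_same + p_ts]]
  y[r >= p_same + p_ts & r < p_same + p_ts + q_each] <-
    tv1[x[r >= p_same + p_ts & r < p_same + p_ts + q_each]]
  y[r >= p_same + p_ts + q_each] <- tv2[x[r >= p_same + p_ts + q_each]]
  y
}

#' Evolve sequences along a tree
#'
#' Draws a uniform random root sequence and evolves it along every branch
#' under the Kimura 2-parameter substitution process (no indels), so the
#' tip sequences form a gap-free alignment. Expected pairwise K2P distance
#' between two tips equals their path length for long sequences.
#'
#' @param tree a `phylo` with branch lengths in expected
#'   substitutions/site; if it carries a `"species"` attribute (see
#'   [simulate_individuals()]) it is used for the species labels,
#'   otherwise tips are treated as one individual per species.
#' @param cfg a [sim_config()]; uses `seq_length`, `kappa`, `locus` and
#'   `seed`.
#' @return a [locus_alignment()].
#' @export
evolve_sequences <- function(tree, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  L <- cfg$seq_length
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- matrix(NA_integer_, ntip + nnode, L)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    seqs[ch, ] <- .k2p_mutate(seqs[p, ], tr$edge.length[e], cfg$kappa)
  }
  bases <- c("A", "C", "G", "T")
  tip_seqs <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L,
                    function(v) paste(bases[v], collapse = ""))
  species <- attr(tree, "species")
  if (is.null(species)) species <- setNames(tree$tip.label, tree$tip.label)
  locus_alignment(cfg$locus, tree$tip.label,
                  unname(species[tree$tip.label]), tip_seqs)
}

#' Simulate one barcode dataset
#'
#' Convenience wrapper chaining [simulate_species_tree()],
#' [simulate_individuals()] and [evolve_sequences()].
#'
#' @param cfg a [sim_config()].
#' @return list with `alignment` (a [locus_alignment()]), `species_tree`,
#'   `tree` (individual-level), `confusable` (list of merged species
#'   pairs) and `config`.
#' @export
simulate_barcode_dataset <- function(cfg) {
  sptree <- simulate_species_tree(cfg)
  itree <- simulate_individuals(sptree, cfg)
  aln <- evolve_sequences(itree, cfg)
  list(alignment = aln, species_tree = sptree, tree = itree,
       confusable = attr(itree, "confusable"), config = cfg)
}

#' Generate the benchmark suite
#'
#' Emits three datasets with known truth: `clean` (all species well
#' separated — every species has a barcoding gap, every Best Match query
#' is correct and every species is monophyletic, by construction),
#' `confusable` (as clean plus species pairs with zero species-level
#' divergence, whose members are expected to fail identification), and
#' `multilocus` (two loci evolved on the same individuals with random
#' per-locus sample dropout, for exercising concatenation).
#'
#' @param cfg a [sim_config()]; `n_confusable_pairs` (default 3 if unset)
#'   sizes the confusable dataset and `missing_fraction` (default 0.2 if
#'   unset) the dropout.
#' @return list of datasets, each as in [simulate_barcode_dataset()]
#'   (`multilocus` carries `alignments`, a list per locus), plus a `truth`
#'   entry per dataset.
#' @export
make_benchmark_suite <- function(cfg = sim_config()) {
  p <- if (cfg$n_confusable_pairs > 0L) cfg$n_confusable_pairs else 3L
  miss <- if (cfg$missing_fraction > 0) cfg$missing_fraction else 0.2

  clean_cfg <- cfg; clean_cfg$n_confusable_pairs <- 0L
  clean <- simulate_barcode_dataset(clean_cfg)
  clean$truth <- list(
    gap = setNames(rep(TRUE, cfg$n_species),
                   .sim_species_names(cfg$n_species)),
    monophyletic = setNames(rep(TRUE, cfg$n_species),
                            .sim_species_names(cfg$n_species)),
    bm_category = "CORRECT")

  conf_cfg <- cfg; conf_cfg$n_confusable_pairs <- p
  conf_cfg$seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1000L
  confusable <- simulate_barcode_dataset(conf_cfg)
  confusable$truth <- list(
    confusable_species = unlist(confusable$confusable),
    expected_bm = "members of confusable pairs may be AMBIGUOUS/INCORRECT")

  ml_cfg <- cfg; ml_cfg$n_confusable_pairs <- 0L
  ml_cfg$seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 2000L
  sptree <- simulate_species_tree(ml_cfg)
  itree <- simulate_individuals(sptree, ml_cfg)
  alns <- list()
  for (li in 1:2) {
    lc <- ml_cfg
    lc$locus <- paste0("LOC", li)
    lc$seed <- if (is.null(ml_cfg$seed)) NULL else ml_cfg$seed + 10L * li
    aln <- evolve_sequences(itree, lc)
    if (!is.null(lc$seed)) set.seed(lc$seed + 5L)
    keep <- aln$sample_id[stats::runif(length(aln$sample_id)) >= miss]
    if (length(keep) >= 2L) aln <- aln_subset(aln, keep)
    alns[[lc$locus]] <- aln
  }
  multilocus <- list(alignments = alns, tree = itree, config = ml_cfg,
                     truth = list(missing_fraction = miss,
                                  n_individuals = length(itree$tip.label)))
  list(clean = clean, confusable = confusable, multilocus = multilocus)
}
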