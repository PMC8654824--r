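# Independent oracles and fixture builders shared across tests. These are
# deliberately naive (per-site loops, O(n^2) scans) so they stay
# independent of the vectorised implementations they check.

# Site-by-site K2P / p-distance oracle.
bf_pair <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  sites <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% acgt) || !(b[i] %in% acgt)) next
    sites <- sites + 1L
    if (a[i] == b[i]) next
    pur <- c("A", "G")
    if ((a[i] %in% pur) == (b[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  k2p <- NA_real_
  if (sites > 0) {
    P <- ts / sites; Q <- tv / sites
    if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0)
      k2p <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  }
  p <- if (sites > 0) (ts + tv) / sites else NA_real_
  list(k2p = k2p, p = p, sites = sites)
}

# O(n^2) leave-one-out nearest-neighbour classifier (BM; finite threshold
# gives BCM). Returns a category per classifiable query, named by query.
bf_classify <- function(d, species, threshold = Inf) {
  n <- nrow(d)
  out <- character(0)
  for (i in seq_len(n)) {
    best <- Inf; best_sp <- character(0)
    for (j in seq_len(n)) {
      if (j == i || is.na(d[i, j])) next
      if (d[i, j] < best) { best <- d[i, j]; best_sp <- species[j] }
      else if (d[i, j] == best) best_sp <- union(best_sp, species[j])
    }
    if (!is.finite(best) && length(best_sp) == 0L) next   # unclassifiable
    cat_i <- if (best > threshold) "NO_MATCH"
      else if (all(best_sp == species[i])) "CORRECT"
      else if (species[i] %in% best_sp) "AMBIGUOUS"
      else "INCORRECT"
    out[rownames(d)[i]] <- cat_i
  }
  out
}

# Hand-assembled distance container for constructed matrix scenarios.
make_dm <- function(d, species, model = "K2P") {
  labels <- rownames(d)
  if (is.null(labels)) {
    labels <- paste0("q", seq_len(nrow(d)))
    dimnames(d) <- list(labels, labels)
  }
  sites <- matrix(100L, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(labels = labels,
                 species = stats::setNames(species, labels),
                 d = d, sites = sites, model = model),
            class = "barcode_dist")
}

# Symmetric matrix built from a vector of pairwise values filling the
# upper triangle in R's column-major order:
# (1,2), (1,3), (2,3), (1,4), (2,4), (3,4), ...
sym_from_upper <- function(n, values, labels = paste0("q", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- values
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# Random gapped alignment fixture with species structure.
random_alignment <- function(n_species = 4, k = 3, width = 60,
                             gap_frac = 0.1, locus = "ITS") {
  n <- n_species * k
  chars <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(chars, width, replace = TRUE)
    gaps <- runif(width) < gap_frac
    s[gaps] <- sample(c("-", "N"), sum(gaps), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  locus_alignment(locus,
                  sprintf("x%02d", seq_len(n)),
                  rep(sprintf("Genus_sp%02d", seq_len(n_species)),
                      each = k),
                  seqs)
}

# Random unrooted binary tree with strictly positive branch lengths and
# its additive (path-length) distance matrix.
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# Wrap a plain distance matrix for nj_build.
dm_from_matrix <- function(d, species = NULL) {
  if (is.null(species)) species <- rownames(d)
  make_dm(d, species, model = "p")
}

write_fasta_fixture <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]]))), path)
  path
}
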