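# Pairwise deletion: only columns where BOTH residues are unambiguous
# A/C/G/T are compared; gaps, N and IUPAC ambiguity codes are treated as
# missing for that pair. Transitions are A<->G and C<->T; every other
# difference among A,C,G,T is a transversion.

.k2p_from_counts <- function(sites, ts, tv) {
  if (sites == 0L) return(NA_real_)
  P <- ts / sites
  Q <- tv / sites
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)  # saturated: log undefined
  -0.5 * log(a1) - 0.25 * log(a2)
}

.pair_counts <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  c(sites = sum(ok), ts = ts, tv = sum(diff) - ts)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K2P distance over the sites at which both sequences carry an
#' unambiguous base (pairwise deletion). With transition proportion `P` and
#' transversion proportion `Q`,
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`.
#' The distance is undefined (`NA`) when no comparable sites remain or when a
#' log argument is non-positive (saturation).
#'
#' @param seq_a,seq_b aligned residue strings of equal length.
#' @return list with `distance` (non-negative number or `NA`) and `sites`
#'   (number of comparable sites used).
#' @export
#' @examples
#' pairwise_k2p("ACGT", "ACGA")  # one transversion over four sites
pairwise_k2p <- function(seq_a, seq_b) {
  ct <- .pair_counts(seq_a, seq_b)
  list(distance = .k2p_from_counts(ct[["sites"]], ct[["ts"]], ct[["tv"]]),
       sites = unname(ct[["sites"]]))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among comparable sites (pairwise
#' deletion, as in [pairwise_k2p()]). Undefined (`NA`) only when no
#' comparable sites remain.
#'
#' @inheritParams pairwise_k2p
#' @return list with `distance` and `sites`.
#' @export
pairwise_pdist <- function(seq_a, seq_b) {
  ct <- .pair_counts(seq_a, seq_b)
  d <- if (ct[["sites"]] == 0L) NA_real_ else
    (ct[["ts"]] + ct[["tv"]]) / ct[["sites"]]
  list(distance = d, sites = unname(ct[["sites"]]))
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all pairwise distances under the chosen model with pairwise
#' deletion. Undefined distances (no comparable sites, or saturation under
#' K2P) are stored as `NA`.
#'
#' @param aln a [locus_alignment()] with at least two records.
#' @param model `"K2P"` (default) or `"p"`.
#' @return an object of class `barcode_dist`: list with `labels`
#'   (sample ids), `species` (named character), `d` (symmetric numeric
#'   matrix, zero diagonal, `NA` = undefined), `sites` (symmetric integer
#'   matrix of comparable sites per pair) and `model`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p")) {
  model <- match.arg(model)
  n <- length(aln$sample_id)
  if (n < 2L) stop("need at least two records for a distance matrix")
  M <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  ind <- lapply(c("A", "C", "G", "T"), function(b) {
    m <- (M == b); storage.mode(m) <- "double"; m
  })
  names(ind) <- c("A", "C", "G", "T")
  valid <- ind$A + ind$C + ind$G + ind$T
  sites <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
        tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  tv <- sites - matches - ts
  if (model == "p") {
    d <- (ts + tv) / sites            # NaN where sites == 0
    d[sites == 0] <- NA_real_
  } else {
    P <- ts / sites
    Q <- tv / sites
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    d <- -0.5 * log(pmax(a1, 0)) - 0.25 * log(pmax(a2, 0))
    d[sites == 0 | a1 <= 0 | a2 <= 0] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(aln$sample_id, aln$sample_id)
  storage.mode(sites) <- "integer"
  dimnames(sites) <- dimnames(d)
  structure(
    list(labels = aln$sample_id,
         species = setNames(aln$species, aln$sample_id),
         d = d, sites = sites, model = model),
    class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat("Pairwise ", x$model, " distance matrix: ", length(x$labels),
      " samples, ", length(unique(x$species)), " species\n", sep = "")
  nu <- sum(is.na(x$d[upper.tri(x$d)]))
  if (nu) cat("  ", nu, " undefined pairwise distances\n", sep = "")
  invisible(x)
}

# Logical masks over the strict upper triangle of a barcode_dist.
.pair_masks <- function(dm) {
  same <- outer(dm$species, dm$species, `==`)
  ut <- upper.tri(dm$d)
  list(intra = ut & same, inter = ut & !same)
}

#' Intra- and interspecific distance ranges
#'
#' Extrema of the defined pairwise distances, split into intraspecific
#' (same species) and interspecific (different species) pairs. A range with
#' no defined pairs is reported as `NA` rather than zero.
#'
#' @param dm a [distance_matrix()] result.
#' @return named numeric vector
#'   `c(min_inter, max_inter, min_intra, max_intra)`.
#' @export
summarize_ranges <- function(dm) {
  m <- .pair_masks(dm)
  intra <- dm$d[m$intra]; intra <- intra[!is.na(intra)]
  inter <- dm$d[m$inter]; inter <- inter[!is.na(inter)]
  rng <- function(v, f) if (length(v)) f(v) else NA_real_
  c(min_inter = rng(inter, min), max_inter = rng(inter, max),
    min_intra = rng(intra, min), max_intra = rng(intra, max))
}

#' Write a distance matrix to disk
#'
#' Emits the square matrix as a tab-separated file with a header row, and
#' optionally a long-format table `(sample_a, sample_b, distance, sites)`
#' over unordered pairs.
#'
#' @param dm a [distance_matrix()] result.
#' @param path output path for the square matrix.
#' @param long_path optional output path for the long-format table.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, long_path = NULL) {
  utils::write.table(dm$d, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(long_path)) {
    ut <- which(upper.tri(dm$d), arr.ind = TRUE)
    long <- data.frame(sample_a = dm$labels[ut[, 1L]],
                       sample_b = dm$labels[ut[, 2L]],
                       distance = dm$d[ut], sites = dm$sites[ut],
                       stringsAsFactors = FALSE)
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
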