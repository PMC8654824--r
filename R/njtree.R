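# Neighbour joining (Saitou-Nei, Studier-Keppler Q criterion), written
# against the distance-matrix container used throughout the package.
# Deterministic tie-breaking: among pairs minimising Q, the lowest
# (row, column) index pair in the current cluster order is joined. Negative
# branch lengths are clamped to zero; the topology is unaffected.

.nwk_label <- function(x) {
  # quote labels that would collide with Newick syntax
  ifelse(grepl("[()\\[\\]:;, ']", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

.nwk_num <- function(x) sprintf("%.12g", x)

#' Build a neighbour-joining tree
#'
#' Agglomerates the samples of a distance matrix with the standard
#' neighbour-joining algorithm using the rate-corrected criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`. Branch lengths
#' follow the standard allocation; negative lengths are clamped to zero.
#' The matrix must be fully defined: undefined distances are refused
#' rather than imputed, because silent imputation could change which
#' species come out monophyletic (see [prune_undefined()]).
#'
#' @param dm a [distance_matrix()] result with at least three records and
#'   no undefined entries.
#' @return an unrooted `phylo` tree (ape) whose tip labels are the sample
#'   ids, with the species map attached as attribute `"species"`.
#' @export
nj_build <- function(dm) {
  D <- dm$d
  n <- nrow(D)
  if (n < 3L) stop("neighbour joining needs at least three records")
  na <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(na))
    stop("undefined distance between '", dm$labels[na[1L, 1L]], "' and '",
         dm$labels[na[1L, 2L]],
         "'; remove offending samples (see prune_undefined) before NJ")
  reprs <- .nwk_label(dm$labels)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    dnew <- 0.5 * (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j])
    repr_new <- paste0("(", reprs[i], ":", .nwk_num(vi), ",",
                       reprs[j], ":", .nwk_num(vj), ")")
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    reprs <- c(reprs[-c(i, j)], repr_new)
  }
  v1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", reprs[1L], ":", .nwk_num(v1), ",",
                reprs[2L], ":", .nwk_num(v2), ",",
                reprs[3L], ":", .nwk_num(v3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "species") <- dm$species[tree$tip.label]
  tree
}

#' Drop samples with undefined distances
#'
#' Greedily removes the sample involved in the most undefined pairwise
#' distances until the matrix is fully defined; used before [nj_build()],
#' which refuses undefined entries.
#'
#' @param dm a [distance_matrix()] result.
#' @return list with `dm` (pruned matrix) and `removed` (sample ids).
#' @export
prune_undefined <- function(dm) {
  removed <- character(0)
  while (TRUE) {
    na_count <- rowSums(is.na(dm$d))
    if (all(na_count == 0L)) break
    worst <- which.max(na_count)
    removed <- c(removed, dm$labels[worst])
    keep <- -worst
    dm$d <- dm$d[keep, keep, drop = FALSE]
    dm$sites <- dm$sites[keep, keep, drop = FALSE]
    dm$labels <- dm$labels[keep]
    dm$species <- dm$species[keep]
  }
  list(dm = dm, removed = removed)
}

#' Write a tree to a Newick file
#'
#' Tip labels are written as `sample_id|Genus_species` when a species map
#' is available (either attached to the tree by [nj_build()] or supplied),
#' so that species information survives the round trip.
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @param species optional named character vector (sample id -> species).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, species = attr(tree, "species")) {
  out <- tree
  if (!is.null(species))
    out$tip.label <- paste(tree$tip.label,
                           unname(species[tree$tip.label]), sep = "|")
  ape::write.tree(out, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Inverse of [write_newick()]: tip labels of the form
#' `sample_id|Genus_species` are split back into sample ids and an attached
#' species map.
#'
#' @param path path to a Newick file.
#' @return a `phylo` object, with attribute `"species"` when the labels
#'   carry species information.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick in ", path)
  if (all(grepl("|", tree$tip.label, fixed = TRUE))) {
    parts <- strsplit(tree$tip.label, "|", fixed = TRUE)
    tree$tip.label <- vapply(parts, `[[`, character(1L), 1L)
    attr(tree, "species") <- setNames(
      vapply(parts, `[[`, character(1L), 2L), tree$tip.label)
  }
  tree
}

#' Per-species monophyly on an unrooted tree
#'
#' A species with two or more individuals is scored monophyletic when some
#' edge of the unrooted tree separates exactly its individuals from all
#' other tips. Species represented by a single individual are trivially
#' monophyletic and are excluded from the denominator. Two independent
#' procedures are available: `"bipartition"` checks the leaf sets induced
#' by every internal edge, `"rooting"` reroots at an outgroup tip and
#' checks the rooted clade; they agree on every tree.
#'
#' @param tree a `phylo` object.
#' @param species named character vector mapping tip label to species;
#'   defaults to the map attached to the tree.
#' @param method `"bipartition"` (default) or `"rooting"`.
#' @return object of class `monophyly_report`: list with `table`
#'   (species, n_individuals, monophyletic), `pct_discriminated`
#'   (percentage of assessed species that are monophyletic) and
#'   `singletons`.
#' @export
species_monophyly <- function(tree, species = attr(tree, "species"),
                              method = c("bipartition", "rooting")) {
  method <- match.arg(method)
  if (is.null(species)) stop("no species map available for the tree")
  species <- species[tree$tip.label]
  if (anyNA(species)) stop("species map does not cover all tips")
  tab <- table(species)
  assessed <- names(tab)[tab >= 2L]
  singles <- names(tab)[tab < 2L]
  ntip <- length(tree$tip.label)

  if (method == "bipartition") {
    pp <- lapply(unclass(ape::prop.part(tree)), sort)
    all_tips <- seq_len(ntip)
    is_mono <- function(s) {
      tips <- unname(sort(which(species == s)))
      if (length(tips) == ntip) return(TRUE)
      any(vapply(pp, function(cl)
        identical(cl, tips) || identical(cl, setdiff(all_tips, tips)),
        logical(1L)))
    }
  } else {
    is_mono <- function(s) {
      tips <- tree$tip.label[species == s]
      if (length(tips) == ntip) return(TRUE)
      og <- setdiff(tree$tip.label, tips)[1L]
      rt <- ape::root(tree, outgroup = og, resolve.root = TRUE)
      ape::is.monophyletic(rt, tips)
    }
  }

  mono <- vapply(assessed, is_mono, logical(1L))
  out <- data.frame(species = assessed,
                    n_individuals = as.integer(tab[assessed]),
                    monophyletic = unname(mono), stringsAsFactors = FALSE)
  pct <- if (nrow(out)) 100 * sum(out$monophyletic) / nrow(out) else NA_real_
  structure(list(table = out, pct_discriminated = pct,
                 singletons = singles, method = method),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat("Species discrimination on NJ tree (", x$method, " test)\n", sep = "")
  cat("  ", sum(x$table$monophyletic), " of ", nrow(x$table),
      " assessed species monophyletic (",
      sprintf("%.2f%%", x$pct_discriminated), ")\n", sep = "")
  if (length(x$singletons))
    cat("  ", length(x$singletons), " singleton species not assessed\n",
        sep = "")
  invisible(x)
}
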