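#' Per-species barcoding-gap records
#'
#' For every species with at least two individuals, finds the maximum
#' intraspecific distance and the minimum distance to any heterospecific
#' individual, and flags a barcoding gap when the latter strictly exceeds
#' the former (the dot lies above the 1:1 line of a
#' max-intra vs min-inter scatter plot). Singleton species have no
#' intraspecific distance and are excluded; species whose relevant pairs
#' are all undefined are skipped. Both exclusions are recorded in
#' attributes `singletons` and `skipped`.
#'
#' @param dm a [distance_matrix()] result covering at least two species.
#' @return object of class `gap_records`: data frame with columns
#'   `species`, `n_individuals`, `max_intra`, `min_inter`, `has_gap`.
#' @export
species_gap_records <- function(dm) {
  sp <- dm$species
  if (length(unique(sp)) < 2L)
    stop("gap analysis needs at least two species")
  tab <- table(sp)
  assessed <- names(tab)[tab >= 2L]
  singletons <- names(tab)[tab < 2L]
  rows <- list()
  skipped <- character(0)
  for (s in assessed) {
    in_s <- sp == s
    dintra <- dm$d[in_s, in_s, drop = FALSE]
    dintra <- dintra[upper.tri(dintra)]
    dintra <- dintra[!is.na(dintra)]
    dinter <- dm$d[in_s, !in_s, drop = FALSE]
    dinter <- dinter[!is.na(dinter)]
    if (!length(dintra) || !length(dinter)) {
      skipped <- c(skipped, s)
      next
    }
    rows[[s]] <- data.frame(
      species = s, n_individuals = sum(in_s),
      max_intra = max(dintra), min_inter = min(dinter),
      has_gap = min(dinter) > max(dintra),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(species = character(0), n_individuals = integer(0),
                      max_intra = numeric(0), min_inter = numeric(0),
                      has_gap = logical(0))
  attr(out, "singletons") <- singletons
  attr(out, "skipped") <- skipped
  class(out) <- c("gap_records", "data.frame")
  out
}

#' Percentage of species showing a barcoding gap
#'
#' @param records a [species_gap_records()] result with at least one row.
#' @return percentage in `[0, 100]`.
#' @export
gap_percentage <- function(records) {
  if (nrow(records) == 0L) stop("no assessable species in gap records")
  100 * sum(records$has_gap) / nrow(records)
}

#' Scatter-plot table for the barcoding gap
#'
#' One row per assessed species with the coordinates used in a
#' max-intraspecific vs min-interspecific scatter plot (reference line
#' `y = x`).
#'
#' @param records a [species_gap_records()] result.
#' @return plain data frame with columns `species`, `max_intra`,
#'   `min_inter`, `has_gap`.
#' @export
scatter_table <- function(records) {
  data.frame(species = records$species, max_intra = records$max_intra,
             min_inter = records$min_inter, has_gap = records$has_gap,
             stringsAsFactors = FALSE)
}

#' Plot per-species gap records
#'
#' Max-intraspecific vs min-interspecific scatter with the 1:1 reference
#' line; dots above the line are species with a barcoding gap.
#'
#' @param x a [species_gap_records()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gap_records <- function(x, ...) {
  lim <- range(0, x$max_intra, x$min_inter)
  graphics::plot(x$max_intra, x$min_inter, xlim = lim, ylim = lim,
                 xlab = "maximum intraspecific distance",
                 ylab = "minimum interspecific distance",
                 pch = ifelse(x$has_gap, 19, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Histograms of intra- and interspecific distances
#'
#' Bins all defined intraspecific and interspecific pairwise distances on a
#' common grid `[0, max_distance]` with the given bin width. Overlap of the
#' two distributions indicates the absence of a global barcoding gap.
#'
#' @param dm a [distance_matrix()] result.
#' @param bin_width width of the histogram bins on the distance scale
#'   (default 0.01 substitutions/site).
#' @return object of class `distance_histogram`: list with `bin_edges`
#'   (length `k + 1`), `intra_counts`, `inter_counts` (length `k`) and
#'   `bin_width`.
#' @export
distance_histograms <- function(dm, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  m <- .pair_masks(dm)
  intra <- dm$d[m$intra]; intra <- intra[!is.na(intra)]
  inter <- dm$d[m$inter]; inter <- inter[!is.na(inter)]
  if (!length(intra) && !length(inter))
    stop("no defined pairwise distances to bin")
  top <- max(intra, inter, 0)
  edges <- seq(0, bin_width * max(1, ceiling(top / bin_width + 1e-9)),
               by = bin_width)
  if (max(edges) < top) edges <- c(edges, max(edges) + bin_width)
  bin_counts <- function(v) {
    if (!length(v)) return(integer(length(edges) - 1L))
    tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                  length(edges) - 1L),
             nbins = length(edges) - 1L)
  }
  structure(list(bin_edges = edges, intra_counts = bin_counts(intra),
                 inter_counts = bin_counts(inter), bin_width = bin_width),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat("Distance histogram: ", length(x$intra_counts), " bins of width ",
      x$bin_width, "\n  ", sum(x$intra_counts), " intraspecific / ",
      sum(x$inter_counts), " interspecific pairs\n", sep = "")
  invisible(x)
}

#' Histogram table for export
#'
#' @param h a [distance_histograms()] result.
#' @return data frame with columns `bin_start`, `bin_end`, `intra_count`,
#'   `inter_count`.
#' @export
histogram_table <- function(h) {
  k <- length(h$intra_counts)
  data.frame(bin_start = h$bin_edges[seq_len(k)],
             bin_end = h$bin_edges[seq_len(k) + 1L],
             intra_count = h$intra_counts, inter_count = h$inter_counts)
}
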