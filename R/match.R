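#' Best Close Match distance threshold
#'
#' The 95th percentile of all defined intraspecific pairwise distances,
#' computed empirically without interpolation: the smallest observed
#' distance `v` such that at least 95% of intraspecific distances are
#' `<= v`.
#'
#' @param dm a [distance_matrix()] result.
#' @param prob coverage probability (default 0.95).
#' @return object of class `bcm_threshold`: list with `value` and
#'   `n_intra_pairs`.
#' @export
#' @examples
#' # with intraspecific distances 0.00, 0.01, ..., 0.99 the threshold is 0.94
bcm_threshold <- function(dm, prob = 0.95) {
  m <- .pair_masks(dm)
  intra <- dm$d[m$intra]
  intra <- sort(intra[!is.na(intra)])
  if (!length(intra))
    stop("no defined intraspecific pairwise distances; ",
         "cannot set a Best Close Match threshold")
  v <- intra[ceiling(prob * length(intra))]
  structure(list(value = v, n_intra_pairs = length(intra)),
            class = "bcm_threshold")
}

#' @export
print.bcm_threshold <- function(x, ...) {
  cat("BCM threshold: ", format(x$value), " (from ", x$n_intra_pairs,
      " intraspecific distances)\n", sep = "")
  invisible(x)
}

# Shared leave-one-out classifier. threshold = Inf gives Best Match.
.match_verdicts <- function(dm, threshold) {
  n <- length(dm$labels)
  verdicts <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    di <- dm$d[i, -i]
    cand <- names(di)[!is.na(di)]
    if (!length(cand)) {
      excluded <- c(excluded, dm$labels[i])
      next
    }
    best <- min(di[cand])
    if (best > threshold) {
      verdicts[[i]] <- data.frame(
        query = dm$labels[i], species = unname(dm$species[i]),
        best_distance = best, best_species = NA_character_,
        category = "NO_MATCH", stringsAsFactors = FALSE)
      next
    }
    hits <- cand[di[cand] == best]
    hit_sp <- unique(unname(dm$species[hits]))
    own <- unname(dm$species[i])
    category <- if (identical(hit_sp, own)) "CORRECT"
      else if (own %in% hit_sp) "AMBIGUOUS" else "INCORRECT"
    verdicts[[i]] <- data.frame(
      query = dm$labels[i], species = own, best_distance = best,
      best_species = paste(sort(hit_sp), collapse = ","),
      category = category, stringsAsFactors = FALSE)
  }
  list(verdicts = do.call(rbind, c(verdicts, list(make.row.names = FALSE))),
       excluded = excluded)
}

.match_report <- function(method, res, threshold = NULL) {
  v <- res$verdicts
  if (is.null(v) || nrow(v) == 0L)
    stop("no query had a defined distance to any other sample")
  n <- nrow(v)
  pct <- function(cat) 100 * sum(v$category == cat) / n
  structure(
    list(method = method, threshold = threshold, verdicts = v,
         n_queries = n, excluded = res$excluded,
         pct_correct = pct("CORRECT"), pct_ambiguous = pct("AMBIGUOUS"),
         pct_incorrect = pct("INCORRECT"), pct_no_match = pct("NO_MATCH")),
    class = "match_report")
}

#' Best Match species identification
#'
#' Leave-one-out nearest-neighbour identification: every sequence is used
#' in turn as a query against all remaining sequences. The query is
#' `CORRECT` when all nearest neighbours (samples attaining the minimum
#' defined distance) are conspecific, `AMBIGUOUS` when they include the
#' query's species and at least one other, and `INCORRECT` when none
#' belongs to the query's species. Species represented by a single
#' sequence should be removed first (see [drop_singleton_species()]).
#' Queries with no defined distance to any other sample are excluded from
#' the percentages and listed in the report.
#'
#' @param dm a [distance_matrix()] result (at least two records).
#' @return object of class `match_report`: per-query verdict table plus
#'   `pct_correct`, `pct_ambiguous`, `pct_incorrect`, `pct_no_match`
#'   (always 0 for Best Match); percentages sum to 100 over classified
#'   queries.
#' @export
best_match <- function(dm) {
  if (length(dm$labels) < 2L) stop("need at least two records")
  .match_report("BM", .match_verdicts(dm, Inf))
}

#' Best Close Match species identification
#'
#' As [best_match()], but a query whose nearest defined neighbour lies
#' beyond the threshold — conventionally the 95th percentile of
#' intraspecific distances, see [bcm_threshold()] — is classified
#' `NO_MATCH` instead. With an infinite threshold the report equals the
#' Best Match report.
#'
#' @param dm a [distance_matrix()] result.
#' @param threshold a [bcm_threshold()] object, or a single number on the
#'   distance scale. Defaults to `bcm_threshold(dm)`.
#' @return a `match_report`; the four percentages (including
#'   `pct_no_match`) sum to 100.
#' @export
best_close_match <- function(dm, threshold = bcm_threshold(dm)) {
  if (length(dm$labels) < 2L) stop("need at least two records")
  thr <- if (inherits(threshold, "bcm_threshold")) threshold$value
         else as.numeric(threshold)
  .match_report("BCM", .match_verdicts(dm, thr), threshold = thr)
}

#' @export
print.match_report <- function(x, ...) {
  cat(if (x$method == "BM") "Best Match" else "Best Close Match",
      " identification over ", x$n_queries, " queries\n", sep = "")
  if (!is.null(x$threshold) && is.finite(x$threshold))
    cat("  threshold: ", format(x$threshold), "\n", sep = "")
  cat(sprintf("  correct %.2f%%  ambiguous %.2f%%  incorrect %.2f%%",
              x$pct_correct, x$pct_ambiguous, x$pct_incorrect))
  if (x$method == "BCM") cat(sprintf("  no-match %.2f%%", x$pct_no_match))
  cat("\n")
  if (length(x$excluded))
    cat("  ", length(x$excluded),
        " queries excluded (no defined distances)\n", sep = "")
  invisible(x)
}

#' @export
summary.match_report <- function(object, ...) {
  c(correct = object$pct_correct, ambiguous = object$pct_ambiguous,
    incorrect = object$pct_incorrect, no_match = object$pct_no_match)
}
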