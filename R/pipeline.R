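# Orchestration: run the whole evaluation (filters, distances, gap
# analysis, BM/BCM, NJ monophyly) over single loci and multi-locus
# combinations, and emit the three summary tables.

.default_combinations <- function(loci, exclude = "trnH-psbA") {
  loci <- setdiff(loci, exclude)
  if (length(loci) < 2L) return(list())
  combos <- list()
  for (k in 2:length(loci))
    combos <- c(combos, utils::combn(loci, k, simplify = FALSE))
  # ITS2 is a segment of ITS; the two are never combined with each other
  combos <- Filter(function(cc) !all(c("ITS", "ITS2") %in% cc), combos)
  combos
}

.eval_one <- function(aln, dist_model, tree_model, bin_width,
                      bcm_prob = 0.95) {
  ug <- ungapped_lengths(aln)
  dm <- distance_matrix(aln, model = dist_model)
  ranges <- summarize_ranges(dm)
  gaps <- species_gap_records(dm)
  hist <- distance_histograms(dm, bin_width = bin_width)

  ds <- drop_singleton_species(aln)
  bm <- bcm <- thr <- NULL
  if (length(ds$alignment$sample_id) >= 2L) {
    dm_match <- distance_matrix(ds$alignment, model = dist_model)
    thr <- bcm_threshold(dm_match, prob = bcm_prob)
    bm <- best_match(dm_match)
    bcm <- best_close_match(dm_match, thr)
  }

  dm_tree <- if (tree_model == dist_model) dm
             else distance_matrix(aln, model = tree_model)
  pruned <- prune_undefined(dm_tree)
  tree <- mono <- NULL
  if (length(pruned$dm$labels) >= 3L) {
    tree <- nj_build(pruned$dm)
    mono <- species_monophyly(tree)
  }

  list(alignment = aln, n_seq = length(aln$sample_id),
       n_species = length(unique(aln$species)),
       len_min = min(ug), len_max = max(ug), ranges = ranges,
       gap_records = gaps, gap_pct = gap_percentage(gaps),
       histogram = hist, threshold = thr, bm = bm, bcm = bcm,
       tree = tree, monophyly = mono,
       nj_excluded = pruned$removed,
       singletons_removed = ds$removed_species)
}

#' Evaluate barcode loci and their combinations
#'
#' Runs the full species-identification evaluation over a set of aligned
#' barcode loci: sampling filters, pairwise distances, per-species
#' barcoding-gap analysis, leave-one-out Best Match / Best Close Match
#' identification (on the singleton-free data), and neighbour-joining
#' monophyly scoring. Multi-locus barcodes are built by concatenating the
#' samples shared by all constituent loci.
#'
#' @param loci named list of [locus_alignment()] objects (names are locus
#'   names; unnamed entries use the alignment's own locus).
#' @param combinations list of character vectors of locus names to
#'   concatenate; `NULL` (default) evaluates every combination of the
#'   provided loci except those containing `combo_exclude` or both ITS
#'   and ITS2.
#' @param min_len,max_per_species,exempt_min_len sampling filters, see
#'   [apply_sampling_filters()]; set `min_len = 0` and
#'   `max_per_species = Inf` to disable.
#' @param combo_exclude loci left out of default combinations
#'   (default `"trnH-psbA"`, whose alignments are typically too sparse
#'   and indel-rich to concatenate).
#' @param dist_model distance model for ranges, gap analysis and BM/BCM
#'   (default `"K2P"`).
#' @param tree_model distance model for NJ trees (default `"p"`).
#' @param bin_width histogram bin width (default 0.01).
#' @return object of class `barcode_eval`: list with `barcodes`
#'   (per-barcode results), `filter_logs`, and the parameters used.
#' @export
barcode_eval <- function(loci, combinations = NULL,
                         min_len = 300L, max_per_species = 20L,
                         exempt_min_len = "ITS2",
                         combo_exclude = "trnH-psbA",
                         dist_model = c("K2P", "p"),
                         tree_model = c("p", "K2P"),
                         bin_width = 0.01) {
  dist_model <- match.arg(dist_model)
  tree_model <- match.arg(tree_model)
  if (length(loci) < 1L) stop("no locus alignments supplied")
  nm <- names(loci)
  if (is.null(nm)) nm <- rep("", length(loci))
  for (i in seq_along(loci))
    if (!nzchar(nm[i])) nm[i] <- loci[[i]]$locus
  names(loci) <- nm
  if (is.null(combinations))
    combinations <- .default_combinations(nm, combo_exclude)
  for (cc in combinations)
    if (!all(cc %in% nm))
      stop("combination ", paste(cc, collapse = "+"),
           " references loci not provided: ",
           paste(setdiff(cc, nm), collapse = ", "))

  filtered <- list()
  filter_logs <- list()
  for (l in nm) {
    f <- apply_sampling_filters(loci[[l]], min_len = min_len,
                                max_per_species = max_per_species,
                                exempt_min_len = exempt_min_len)
    filtered[[l]] <- f$alignment
    filter_logs[[l]] <- f$log
  }

  barcodes <- list()
  for (l in nm)
    barcodes[[l]] <- .eval_one(filtered[[l]], dist_model, tree_model,
                               bin_width)
  for (cc in combinations) {
    name <- paste(cc, collapse = "+")
    cat_aln <- concatenate(filtered[cc], name = name)
    barcodes[[name]] <- .eval_one(cat_aln, dist_model, tree_model,
                                  bin_width)
  }

  structure(list(barcodes = barcodes, filter_logs = filter_logs,
                 params = list(min_len = min_len,
                               max_per_species = max_per_species,
                               exempt_min_len = exempt_min_len,
                               dist_model = dist_model,
                               tree_model = tree_model,
                               bin_width = bin_width),
                 combinations = combinations),
            class = "barcode_eval")
}

#' Summary tables of an evaluation
#'
#' Builds the three report tables: sequence characteristics and distance
#' ranges per barcode; gap and NJ discrimination percentages; Best Match /
#' Best Close Match category percentages.
#'
#' @param x a [barcode_eval()] result.
#' @return list of three data frames: `characteristics`
#'   (`marker, n_seq, len_max, len_min, inter_range, intra_range`),
#'   `discrimination` (`marker, gap_pct, nj_pct`) and `matching`
#'   (`marker, bm_correct, bm_ambiguous, bm_incorrect, bcm_correct,
#'   bcm_ambiguous, bcm_incorrect, bcm_no_match`).
#' @export
report_tables <- function(x) {
  stopifnot(inherits(x, "barcode_eval"))
  fmt_rng <- function(lo, hi)
    if (is.na(lo)) NA_character_ else
      paste0(format(round(lo, 3)), "-", format(round(hi, 3)))
  rows1 <- rows2 <- rows3 <- list()
  for (nm in names(x$barcodes)) {
    b <- x$barcodes[[nm]]
    rows1[[nm]] <- data.frame(
      marker = nm, n_seq = b$n_seq, len_max = b$len_max,
      len_min = b$len_min,
      inter_range = fmt_rng(b$ranges[["min_inter"]],
                            b$ranges[["max_inter"]]),
      intra_range = fmt_rng(b$ranges[["min_intra"]],
                            b$ranges[["max_intra"]]),
      stringsAsFactors = FALSE)
    rows2[[nm]] <- data.frame(
      marker = nm, gap_pct = b$gap_pct,
      nj_pct = if (is.null(b$monophyly)) NA_real_
               else b$monophyly$pct_discriminated,
      stringsAsFactors = FALSE)
    rows3[[nm]] <- data.frame(
      marker = nm,
      bm_correct = if (is.null(b$bm)) NA_real_ else b$bm$pct_correct,
      bm_ambiguous = if (is.null(b$bm)) NA_real_ else b$bm$pct_ambiguous,
      bm_incorrect = if (is.null(b$bm)) NA_real_ else b$bm$pct_incorrect,
      bcm_correct = if (is.null(b$bcm)) NA_real_ else b$bcm$pct_correct,
      bcm_ambiguous = if (is.null(b$bcm)) NA_real_
                      else b$bcm$pct_ambiguous,
      bcm_incorrect = if (is.null(b$bcm)) NA_real_
                      else b$bcm$pct_incorrect,
      bcm_no_match = if (is.null(b$bcm)) NA_real_
                     else b$bcm$pct_no_match,
      stringsAsFactors = FALSE)
  }
  list(characteristics = do.call(rbind, c(rows1, list(make.row.names = FALSE))),
       discrimination = do.call(rbind, c(rows2, list(make.row.names = FALSE))),
       matching = do.call(rbind, c(rows3, list(make.row.names = FALSE))))
}

#' Write evaluation artifacts to a directory
#'
#' Emits the three summary tables as TSV, per-barcode verdict and gap
#' tables, and a JSON manifest of the run parameters.
#'
#' @param x a [barcode_eval()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "barcode_eval"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- report_tables(x)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(tb$characteristics, "table_characteristics.tsv")
  wt(tb$discrimination, "table_discrimination.tsv")
  wt(tb$matching, "table_matching.tsv")
  for (nm in names(x$barcodes)) {
    b <- x$barcodes[[nm]]
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    wt(scatter_table(b$gap_records), paste0("gap_", safe, ".tsv"))
    if (!is.null(b$bm))
      wt(b$bm$verdicts, paste0("bm_", safe, ".tsv"))
    if (!is.null(b$bcm))
      wt(b$bcm$verdicts, paste0("bcm_", safe, ".tsv"))
    if (!is.null(b$monophyly))
      wt(b$monophyly$table, paste0("monophyly_", safe, ".tsv"))
    if (!is.null(b$tree))
      write_newick(b$tree, file.path(dir, paste0("nj_", safe, ".nwk")))
  }
  manifest <- list(package_version = as.character(
                     utils::packageVersion("barcodeval")),
                   params = x$params,
                   barcodes = names(x$barcodes),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.barcode_eval <- function(x, ...) {
  tb <- report_tables(x)
  cat("Barcode evaluation over", length(x$barcodes), "barcode(s)\n")
  cat("  distance model:", x$params$dist_model,
      "| tree model:", x$params$tree_model, "\n\n")
  df <- merge(tb$discrimination,
              tb$matching[, c("marker", "bm_correct", "bcm_correct")],
              by = "marker", sort = FALSE)
  df[-1] <- lapply(df[-1], function(v) round(v, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.barcode_eval <- function(object, ...) report_tables(object)
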