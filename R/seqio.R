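#' @importFrom stats setNames
NULL

# Characters not counted when measuring the ungapped length of a sequence.
.GAPLIKE <- c("-", "N", "?", ".")

#' Construct a locus alignment
#'
#' A `locus_alignment` holds one gapped multiple-sequence alignment for a
#' single barcode locus, together with the species label of every sample.
#' All sequences must have identical (aligned) length and sample ids must be
#' unique within the alignment.
#'
#' @param locus single string naming the locus (e.g. `"ITS"`, `"matK"`).
#' @param sample_id character vector of unique sample identifiers.
#' @param species character vector of species labels (underscore-joined
#'   binomials such as `"Dendrobium_nobile"`), parallel to `sample_id`.
#' @param seqs character vector of aligned residue strings over
#'   `A,C,G,T`, IUPAC ambiguity codes, `N` and `-`; parallel to `sample_id`.
#'   Lowercase letters are uppercased and `U` is mapped to `T`.
#'
#' @return An object of class `locus_alignment`: a list with elements
#'   `locus`, `sample_id`, `species`, `seqs` and `width` (alignment columns).
#' @export
#' @examples
#' aln <- locus_alignment("ITS", c("s1", "s2"), c("Genus_a", "Genus_a"),
#'                        c("ACGT", "AC-T"))
#' aln$width
locus_alignment <- function(locus, sample_id, species, seqs) {
  stopifnot(is.character(locus), length(locus) == 1L, nzchar(locus))
  sample_id <- as.character(sample_id)
  species <- as.character(species)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  n <- length(sample_id)
  if (n < 1L) stop("alignment must contain at least one record")
  if (length(species) != n || length(seqs) != n)
    stop("sample_id, species and seqs must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(!nzchar(sample_id))) stop("empty sample_id")
  if (any(!nzchar(species))) stop("empty species label")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    bad <- sample_id[nchar(seqs) != nchar(seqs)[1L]][1L]
    stop("ragged alignment: record '", bad, "' has length ",
         nchar(seqs[sample_id == bad]), ", expected ", nchar(seqs)[1L])
  }
  if (w == 0L) stop("empty sequences")
  structure(
    list(locus = locus, sample_id = sample_id, species = species,
         seqs = setNames(seqs, sample_id), width = w),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment: ", x$locus, "\n", sep = "")
  cat("  ", length(x$sample_id), " sequences x ", x$width, " columns, ",
      length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

#' @export
length.locus_alignment <- function(x) length(x$sample_id)

# Subset an alignment to a set of sample ids (order preserved).
aln_subset <- function(aln, keep) {
  idx <- match(keep, aln$sample_id)
  if (anyNA(idx)) stop("unknown sample_id in subset")
  out <- aln
  out$sample_id <- aln$sample_id[idx]
  out$species <- aln$species[idx]
  out$seqs <- aln$seqs[idx]
  out
}

#' Ungapped sequence lengths
#'
#' Number of residues per record once alignment gaps (`-`, `.`), `N` and `?`
#' are removed; used by the minimum-length sampling filter.
#'
#' @param aln a [locus_alignment()].
#' @return named integer vector.
#' @export
ungapped_lengths <- function(aln) {
  chars <- strsplit(aln$seqs, "", fixed = TRUE)
  vapply(chars, function(s) sum(!s %in% .GAPLIKE), integer(1L),
         USE.NAMES = TRUE)
}

#' Read an aligned FASTA file
#'
#' Headers carry both the sample id and the species label, by default in the
#' form `>sample_id|Genus_species`. The field separator and field order are
#' configurable. Residues are uppercased and `U` is mapped to `T`.
#'
#' @param path path to a FASTA file containing a gapped alignment.
#' @param locus locus name to attach to the alignment.
#' @param sep single character separating header fields (default `"|"`).
#' @param fields order of the two header fields; either
#'   `c("sample", "species")` (default) or `c("species", "sample")`.
#' @return a [locus_alignment()].
#' @export
read_alignment <- function(path, locus, sep = "|",
                           fields = c("sample", "species")) {
  fields <- match.arg(paste(fields, collapse = ","),
                      c("sample,species", "species,sample"))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  headers <- names(x)
  parts <- strsplit(headers, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1L)) < 2L)
  if (length(bad))
    stop("unparseable FASTA header (record ", bad[1L], "): '",
         headers[bad[1L]], "' (expected two '", sep, "'-separated fields)")
  f1 <- vapply(parts, `[[`, character(1L), 1L)
  f2 <- vapply(parts, `[[`, character(1L), 2L)
  if (fields == "sample,species") {
    sample_id <- f1; species <- f2
  } else {
    sample_id <- f2; species <- f1
  }
  locus_alignment(locus, sample_id, species, as.character(x))
}

#' Write an alignment to FASTA
#'
#' Headers are emitted as `sample_id|Genus_species` (or the supplied
#' separator), so that [read_alignment()] on the output reproduces the input.
#' For a concatenated alignment the locus partition table can be written as a
#' tab-separated sidecar file.
#'
#' @param aln a [locus_alignment()] or [concat_alignment].
#' @param path output FASTA path.
#' @param sep header field separator (default `"|"`).
#' @param partitions_path optional path for the partition sidecar table
#'   (columns `locus`, `start`, `end`; 0-based half-open) when `aln` is a
#'   concatenation.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, sep = "|", partitions_path = NULL) {
  if (length(aln$sample_id) == 0L) stop("refusing to write empty alignment")
  x <- Biostrings::BStringSet(unname(aln$seqs))
  names(x) <- paste(aln$sample_id, aln$species, sep = sep)
  Biostrings::writeXStringSet(x, filepath = path)
  if (!is.null(partitions_path)) {
    if (is.null(aln$partitions))
      stop("alignment has no partition table")
    utils::write.table(aln$partitions, partitions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Apply dataset sampling filters
#'
#' Applies the two computational filters used when assembling a barcode
#' reference matrix: sequences whose ungapped length is below `min_len`
#' are removed (loci in `exempt_min_len`, by default ITS2, are exempt
#' because the locus itself is shorter than the cutoff), and species with
#' more than `max_per_species` individuals are truncated to the
#' `max_per_species` longest ungapped sequences, ties broken by sample id.
#'
#' @param aln a [locus_alignment()].
#' @param min_len minimum ungapped length in bases (default 300).
#' @param max_per_species maximum individuals retained per species
#'   (default 20).
#' @param exempt_min_len loci exempt from the length filter
#'   (default `"ITS2"`).
#' @return a list with elements `alignment` (the filtered
#'   [locus_alignment()]) and `log` (data frame with columns `sample_id`,
#'   `species`, `reason` — one row per removed record).
#' @export
apply_sampling_filters <- function(aln, min_len = 300L,
                                   max_per_species = 20L,
                                   exempt_min_len = "ITS2") {
  ug <- ungapped_lengths(aln)
  drop_len <- character(0)
  if (!aln$locus %in% exempt_min_len)
    drop_len <- aln$sample_id[ug < min_len]
  keep <- setdiff(aln$sample_id, drop_len)

  drop_cap <- character(0)
  sp <- aln$species[match(keep, aln$sample_id)]
  for (s in unique(sp)) {
    ids <- keep[sp == s]
    if (length(ids) > max_per_species) {
      # keep the longest ungapped sequences; ties resolved lexicographically
      ord <- order(-ug[ids], ids)
      drop_cap <- c(drop_cap, ids[ord][-seq_len(max_per_species)])
    }
  }
  keep <- setdiff(keep, drop_cap)
  if (length(keep) == 0L)
    stop("sampling filters removed every record from locus ", aln$locus)

  log <- data.frame(
    sample_id = c(drop_len, drop_cap),
    species = aln$species[match(c(drop_len, drop_cap), aln$sample_id)],
    reason = rep(c("min_len", "max_per_species"),
                 c(length(drop_len), length(drop_cap))),
    stringsAsFactors = FALSE)
  list(alignment = aln_subset(aln, keep), log = log)
}

#' Remove species represented by a single sequence
#'
#' Singleton species carry no intraspecific information and are removed
#' before Best Match / Best Close Match identification.
#'
#' @param aln a [locus_alignment()].
#' @return list with `alignment` (possibly zero-record; downstream
#'   operations reject empty input) and `removed_species` (character).
#' @export
drop_singleton_species <- function(aln) {
  tab <- table(aln$species)
  singles <- names(tab)[tab < 2L]
  keep <- aln$sample_id[!aln$species %in% singles]
  out <- aln
  out$sample_id <- aln$sample_id[aln$sample_id %in% keep]
  out$species <- aln$species[aln$sample_id %in% keep]
  out$seqs <- aln$seqs[aln$sample_id %in% keep]
  list(alignment = out, removed_species = singles)
}

#' Concatenate alignments across loci
#'
#' Builds a multi-locus supermatrix over the samples present in *every*
#' input locus (intersection join on `sample_id`), concatenating residues in
#' the given locus order and recording the column range of each locus as a
#' partition (0-based, half-open). A sample labelled with different species
#' at different loci is an error.
#'
#' @param alns list of two or more [locus_alignment()] objects.
#' @param name optional name for the combined barcode; default joins the
#'   locus names with `"+"`.
#' @return a `concat_alignment` (also a `locus_alignment`), with extra
#'   elements `loci` and `partitions`.
#' @export
concatenate <- function(alns, name = NULL) {
  if (length(alns) < 2L) stop("need at least two alignments to concatenate")
  loci <- vapply(alns, `[[`, character(1L), "locus")
  if (is.null(name)) name <- paste(loci, collapse = "+")
  shared <- Reduce(intersect, lapply(alns, `[[`, "sample_id"))
  if (length(shared) == 0L)
    stop("no sample is present in all of: ", paste(loci, collapse = ", "))
  sp <- lapply(alns, function(a) a$species[match(shared, a$sample_id)])
  for (k in seq_along(alns)[-1L]) {
    bad <- shared[sp[[k]] != sp[[1L]]]
    if (length(bad))
      stop("sample '", bad[1L], "' labelled '",
           sp[[1L]][shared == bad[1L]], "' in ", loci[1L], " but '",
           sp[[k]][shared == bad[1L]], "' in ", loci[k])
  }
  seq_parts <- lapply(alns, function(a) unname(a$seqs[match(shared, a$sample_id)]))
  seqs <- do.call(paste0, seq_parts)
  widths <- vapply(alns, `[[`, integer(1L), "width")
  ends <- cumsum(widths)
  partitions <- data.frame(locus = loci, start = c(0L, ends[-length(ends)]),
                           end = ends, stringsAsFactors = FALSE)
  out <- locus_alignment(name, shared, sp[[1L]], seqs)
  out$loci <- loci
  out$partitions <- partitions
  class(out) <- c("concat_alignment", "locus_alignment")
  out
}
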