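#' Construct a RAD/GBS locus
#'
#' A locus is a short multiple alignment of diploid consensus sequences
#' (IUPAC ambiguity codes for heterozygous sites) across the samples in
#' which it was recovered. Samples without data at a locus are simply
#' absent from its alignment.
#'
#' @param locus_id integer identifier, unique within a [locus_set()].
#' @param seqs named character vector: one upper-case sequence string per
#'   sample with data at this locus. All sequences must have equal length.
#' @return an object of class `rad_locus`.
#' @export
rad_locus <- function(locus_id, seqs) {
  if (length(seqs) == 0L) stop("locus ", locus_id, ": no sequences")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("locus ", locus_id, ": sequences must be named by sample id")
  if (anyDuplicated(names(seqs)))
    stop("locus ", locus_id, ": duplicated sample ids")
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("locus ", locus_id, ": ragged alignment (lengths ",
         paste(sort(len), collapse = ", "), ")")
  structure(list(locus_id = as.integer(locus_id),
                 seqs = toupper(seqs),
                 length = len),
            class = "rad_locus")
}

#' Construct a locus set
#'
#' The container all locus- and site-level filters operate on: an ordered
#' collection of loci plus a sample registry and an append-only provenance
#' log of the filters applied so far.
#'
#' @param loci list of [rad_locus()] objects with unique `locus_id`s.
#' @param samples either a character vector of sample ids or a data frame
#'   with columns `id`, and optionally `taxon`, `clade`, `lat`, `lon`.
#' @param provenance character vector describing how the set was produced.
#' @return an object of class `locus_set`.
#' @export
locus_set <- function(loci, samples = NULL, provenance = character()) {
  ids <- vapply(loci, function(l) l$locus_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicated locus ids")
  seen <- unique(unlist(lapply(loci, function(l) names(l$seqs))))
  if (is.null(samples)) samples <- seen
  if (is.character(samples))
    samples <- data.frame(id = samples, stringsAsFactors = FALSE)
  if (!"id" %in% names(samples)) stop("sample table must have an 'id' column")
  if (anyDuplicated(samples$id)) stop("duplicated sample ids in registry")
  unknown <- setdiff(seen, samples$id)
  if (length(unknown) > 0L)
    stop("loci contain samples absent from the registry: ",
         paste(unknown, collapse = ", "))
  structure(list(loci = loci, samples = samples, provenance = provenance),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  lens <- locus_lengths(x)
  cat("locus_set: ", length(x$loci), " loci, ", nrow(x$samples),
      " samples\n", sep = "")
  if (length(lens) > 0L)
    cat("  locus length: ", min(lens), "-", max(lens), " bp\n", sep = "")
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' @export
print.rad_locus <- function(x, ...) {
  cat("rad_locus ", x$locus_id, ": ", length(x$seqs), " samples x ",
      x$length, " bp\n", sep = "")
  invisible(x)
}

#' Number of loci in a locus set
#' @param ls a [locus_set()].
#' @return integer count.
#' @export
n_loci <- function(ls) length(ls$loci)

#' Alignment lengths of all loci
#' @param ls a [locus_set()].
#' @return integer vector of per-locus alignment lengths.
#' @export
locus_lengths <- function(ls) {
  vapply(ls$loci, function(l) l$length, integer(1))
}

#' Locus ids of a locus set
#' @param ls a [locus_set()].
#' @return integer vector.
#' @export
locus_ids <- function(ls) vapply(ls$loci, function(l) l$locus_id, integer(1))

#' Alignment of one locus as a character matrix
#'
#' @param locus a [rad_locus()].
#' @return character matrix, samples in rows, positions in columns.
#' @export
locus_matrix <- function(locus) {
  m <- do.call(rbind, strsplit(locus$seqs, "", fixed = TRUE))
  rownames(m) <- names(locus$seqs)
  m
}

# internal: keep a subset of loci, appending one provenance line
.subset_loci <- function(ls, keep, note) {
  locus_set(ls$loci[keep], samples = ls$samples,
            provenance = c(ls$provenance, note))
}

#' Read a sample metadata table
#'
#' Expects a CSV with columns `id`, `taxon`, `clade` and optionally
#' `lat`, `lon` (decimal degrees).
#'
#' @param path path to the CSV file.
#' @return data frame suitable as the `samples` registry of [locus_set()].
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("metadata must have an 'id' column")
  if (anyDuplicated(df$id)) stop("duplicated sample ids in metadata")
  df
}
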