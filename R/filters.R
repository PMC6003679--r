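# Locus- and site-level filters applied between assembly and analysis.
# All filters return a new locus_set with one provenance line appended
# and are idempotent.

#' Trim terminal alignment positions from every locus
#'
#' Short-read loci accumulate alignment error at their ends; trimming the
#' final bases of each locus after alignment removes most of it.
#'
#' @param ls a [locus_set()].
#' @param n number of terminal positions to remove from the 3' end of the
#'   alignment (default 5).
#' @return the trimmed [locus_set()].
#' @export
trim_edges <- function(ls, n = 5L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  if (n == 0L) return(.subset_loci(ls, seq_len(n_loci(ls)), "trim_edges(0)"))
  loci <- lapply(ls$loci, function(l) {
    if (l$length <= n)
      stop("locus ", l$locus_id, ": length ", l$length,
           " <= trim width ", n)
    rad_locus(l$locus_id, substr(l$seqs, 1L, l$length - n))
  })
  locus_set(loci, samples = ls$samples,
            provenance = c(ls$provenance, paste0("trim_edges(", n, ")")))
}

#' Count SNPs (variable columns) in one locus
#'
#' A column is variable when at least two distinct alleles are observed
#' among the non-missing characters after ambiguity expansion (a
#' heterozygous code contributes both of its alleles).
#'
#' @param locus a [rad_locus()].
#' @return integer number of variable columns.
#' @export
count_snps <- function(locus) {
  cnt <- .column_allele_counts(.allele_codes(locus_matrix(locus)))
  sum(colSums(cnt > 0L) >= 2L)
}

#' Remove loci with an excess of SNPs
#'
#' Loci with unusually many variable sites are more likely to be
#' under-merged paralog clusters than single loci; those with more than
#' `k` SNPs are excluded.
#'
#' @param ls a [locus_set()].
#' @param k maximum number of SNPs a retained locus may carry (default 10).
#' @return the filtered [locus_set()].
#' @export
filter_max_snps <- function(ls, k = 10L) {
  keep <- vapply(ls$loci, count_snps, integer(1)) <= k
  .subset_loci(ls, keep, paste0("filter_max_snps(", k, "): kept ",
                                sum(keep), "/", length(keep)))
}

#' Remove loci with widely shared heterozygous sites (paralog filter)
#'
#' A site heterozygous in many samples at once is the signature of
#' clustered paralogs rather than allelic variation. A locus is removed
#' when any of its columns carries an ambiguity code in more than
#' `max_samples` samples.
#'
#' @param ls a [locus_set()].
#' @param max_samples maximum number of samples allowed to share a
#'   heterozygous call at one site (default 4).
#' @return the filtered [locus_set()].
#' @export
filter_shared_hets <- function(ls, max_samples = 4L) {
  keep <- vapply(ls$loci, function(l) {
    het <- .column_het_counts(.allele_codes(locus_matrix(l)))
    all(het <= max_samples)
  }, logical(1))
  .subset_loci(ls, keep, paste0("filter_shared_hets(", max_samples,
                                "): kept ", sum(keep), "/", length(keep)))
}

#' Keep loci recovered in at least `m` samples (coverage tiers)
#'
#' The coverage-tier datasets (min4, min10, min20, min30) are nested
#' subsets produced by this filter at increasing `m`.
#'
#' @param ls a [locus_set()].
#' @param m minimum number of samples with data at a retained locus.
#' @return the filtered [locus_set()].
#' @export
filter_min_coverage <- function(ls, m) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  keep <- vapply(ls$loci, function(l) length(l$seqs) >= m, logical(1))
  .subset_loci(ls, keep, paste0("filter_min_coverage(", m, "): kept ",
                                sum(keep), "/", length(keep)))
}

#' Keep loci with adequate per-taxon coverage
#'
#' Retains loci for which every taxon has data for at least
#' `min(k, taxon size)` of its individuals — taxa with fewer than `k`
#' members must be completely covered.
#'
#' @param ls a [locus_set()].
#' @param assignment named character vector mapping every sample id in the
#'   registry to a taxon label.
#' @param k required individuals with data per taxon (default 4).
#' @return the filtered [locus_set()].
#' @export
filter_taxon_coverage <- function(ls, assignment, k = 4L) {
  ids <- ls$samples$id
  missing_assign <- setdiff(ids, names(assignment))
  if (length(missing_assign) > 0L)
    stop("samples not assigned to a taxon: ",
         paste(missing_assign, collapse = ", "))
  tax <- assignment[ids]
  sizes <- table(tax)
  need <- stats::setNames(pmin(as.integer(k), as.integer(sizes)),
                          names(sizes))
  keep <- vapply(ls$loci, function(l) {
    have <- table(factor(tax[match(names(l$seqs), ids)],
                         levels = names(need)))
    all(have >= need)
  }, logical(1))
  .subset_loci(ls, keep, paste0("filter_taxon_coverage(k=", k, "): kept ",
                                sum(keep), "/", length(keep)))
}

#' Count parsimony-informative sites in one locus
#'
#' A column is parsimony-informative when at least two distinct alleles
#' are each observed in at least two samples. A heterozygous sample
#' contributes each of its two alleles once, so allele occurrences are
#' counted over samples carrying the allele.
#'
#' @param locus a [rad_locus()].
#' @return integer count of parsimony-informative columns.
#' @export
count_parsimony_informative <- function(locus) {
  codes <- .allele_codes(locus_matrix(locus))
  nc <- ncol(codes$c1)
  carriers <- matrix(0L, nrow = 4L, ncol = nc)
  for (b in 1:4) {
    carriers[b, ] <- colSums((codes$c1 == b) | (codes$c2 == b), na.rm = TRUE)
  }
  sum(colSums(carriers >= 2L) >= 2L)
}

#' Keep loci with a minimum number of parsimony-informative sites
#'
#' @param ls a [locus_set()].
#' @param k minimum parsimony-informative site count (default 2).
#' @return the filtered [locus_set()].
#' @export
filter_min_pis <- function(ls, k = 2L) {
  keep <- vapply(ls$loci, count_parsimony_informative, integer(1)) >= k
  .subset_loci(ls, keep, paste0("filter_min_pis(", k, "): kept ",
                                sum(keep), "/", length(keep)))
}

#' Bundle of filter thresholds for one assembly tier
#'
#' @param min_sample_coverage minimum samples with data per locus
#'   (4/10/20/30 for the min4..min30 tiers).
#' @param max_snps_per_locus SNP-excess threshold (default 10).
#' @param max_shared_het_samples shared-heterozygosity threshold
#'   (default 4).
#' @param edge_trim_bases terminal bases trimmed per locus (default 5).
#' @param min_pis minimum parsimony-informative sites (default 0 = off).
#' @param per_taxon_min_individuals per-taxon coverage requirement
#'   (default 0 = off).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_sample_coverage = 4L,
                          max_snps_per_locus = 10L,
                          max_shared_het_samples = 4L,
                          edge_trim_bases = 5L,
                          min_pis = 0L,
                          per_taxon_min_individuals = 0L) {
  cfg <- list(min_sample_coverage = as.integer(min_sample_coverage),
              max_snps_per_locus = as.integer(max_snps_per_locus),
              max_shared_het_samples = as.integer(max_shared_het_samples),
              edge_trim_bases = as.integer(edge_trim_bases),
              min_pis = as.integer(min_pis),
              per_taxon_min_individuals = as.integer(per_taxon_min_individuals))
  if (any(unlist(cfg) < 0L)) stop("filter thresholds must be non-negative")
  if (cfg$min_sample_coverage < 1L) stop("min_sample_coverage must be >= 1")
  structure(cfg, class = "filter_config")
}

#' Apply a full filter configuration in canonical order
#'
#' Order: edge trim, SNP excess, shared-heterozygosity, minimum sample
#' coverage, then (when enabled) per-taxon coverage and minimum
#' parsimony-informative sites.
#'
#' @param ls a [locus_set()].
#' @param cfg a [filter_config()].
#' @param assignment sample-to-taxon map, required when
#'   `per_taxon_min_individuals > 0`.
#' @return the filtered [locus_set()].
#' @export
apply_filters <- function(ls, cfg, assignment = NULL) {
  if (cfg$edge_trim_bases > 0L) ls <- trim_edges(ls, cfg$edge_trim_bases)
  ls <- filter_max_snps(ls, cfg$max_snps_per_locus)
  ls <- filter_shared_hets(ls, cfg$max_shared_het_samples)
  ls <- filter_min_coverage(ls, cfg$min_sample_coverage)
  if (cfg$per_taxon_min_individuals > 0L) {
    if (is.null(assignment))
      stop("per-taxon coverage filter needs a sample-to-taxon assignment")
    ls <- filter_taxon_coverage(ls, assignment,
                                cfg$per_taxon_min_individuals)
  }
  if (cfg$min_pis > 0L) ls <- filter_min_pis(ls, cfg$min_pis)
  ls
}
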