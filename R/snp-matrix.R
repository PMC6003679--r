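#' Construct a SNP matrix
#'
#' @param sites data frame with columns `locus_id`, `pos` (1-based column
#'   within the locus alignment), `ref`, `alt`.
#' @param geno integer matrix, sites x samples, counting copies of the
#'   `alt` allele per diploid genotype (0, 1, 2 or `NA` for missing).
#' @param samples character vector of sample ids (column order of `geno`).
#' @return an object of class `snp_matrix`.
#' @export
snp_matrix <- function(sites, geno, samples) {
  stopifnot(nrow(sites) == nrow(geno), length(samples) == ncol(geno))
  colnames(geno) <- samples
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix: ", nrow(x$sites), " biallelic sites x ",
      length(x$samples), " samples (",
      length(unique(x$sites$locus_id)), " loci, missingness ",
      round(missingness(x), 3), ")\n", sep = "")
  invisible(x)
}

#' Number of sites in a SNP matrix
#' @param m a [snp_matrix()].
#' @return integer count.
#' @export
n_sites <- function(m) nrow(m$sites)

#' Extract biallelic SNPs from a locus set
#'
#' Scans every alignment column; ambiguity codes are decoded to diploid
#' allele pairs; columns with exactly two observed alleles become sites.
#' Columns with three or more observed alleles are dropped (the downstream
#' statistics are defined on biallelic patterns); the number dropped is
#' recorded in `attr(, "n_multiallelic")`. The reference allele at a site
#' is the lexicographically smallest observed allele — polarization
#' against an outgroup happens later, in the D-statistic.
#'
#' @param ls a [locus_set()].
#' @return a [snp_matrix()] whose genotypes count copies of the alternate
#'   allele; samples without data at a locus are `NA` across its sites.
#' @export
extract_snps <- function(ls) {
  ids <- ls$samples$id
  per_locus <- lapply(ls$loci, function(l) {
    codes <- .allele_codes(locus_matrix(l))
    cnt <- .column_allele_counts(codes)
    nall <- colSums(cnt > 0L)
    bi <- which(nall == 2L)
    multi <- sum(nall > 2L)
    if (length(bi) == 0L)
      return(list(sites = NULL, geno = NULL, multi = multi))
    row_idx <- match(ids, rownames(codes$c1))
    geno <- matrix(NA_integer_, nrow = length(bi), ncol = length(ids))
    ref <- character(length(bi))
    alt <- character(length(bi))
    for (j in seq_along(bi)) {
      col <- bi[j]
      obs <- which(cnt[, col] > 0L)
      ref[j] <- .BASES[obs[1]]
      alt[j] <- .BASES[obs[2]]
      g <- (codes$c1[, col] == obs[2]) + (codes$c2[, col] == obs[2])
      geno[j, ] <- as.integer(g[row_idx])
    }
    list(sites = data.frame(locus_id = l$locus_id, pos = bi,
                            ref = ref, alt = alt),
         geno = geno, multi = multi)
  })
  sites <- do.call(rbind, lapply(per_locus, `[[`, "sites"))
  geno <- do.call(rbind, lapply(per_locus, `[[`, "geno"))
  if (is.null(sites)) {
    sites <- data.frame(locus_id = integer(), pos = integer(),
                        ref = character(), alt = character())
    geno <- matrix(NA_integer_, nrow = 0L, ncol = length(ids))
  }
  m <- snp_matrix(sites, geno, ids)
  attr(m, "n_multiallelic") <- sum(vapply(per_locus, `[[`, numeric(1),
                                          "multi"))
  m
}

#' Subsample one SNP per locus (putatively unlinked set)
#'
#' SNPs on the same short locus are tightly linked; model-based clustering
#' assumes unlinked markers, so one site is drawn uniformly at random from
#' each locus.
#'
#' @param m a [snp_matrix()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [snp_matrix()] with exactly one site per represented locus.
#' @export
sample_unlinked_snps <- function(m, seed) {
  grp <- split(seq_len(n_sites(m)), m$sites$locus_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- vapply(grp, function(idx) {
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1))
  pick <- sort(unname(pick))
  snp_matrix(m$sites[pick, , drop = FALSE],
             m$geno[pick, , drop = FALSE], m$samples)
}

#' Fraction of missing entries
#'
#' For a SNP matrix, the fraction of `NA` genotypes; for a locus set, the
#' fraction of (sample, locus) sequence cells that are absent or masked
#' (`N`/`-`) relative to a complete sample x locus x position block.
#'
#' @param x a [snp_matrix()] or [locus_set()].
#' @return numeric fraction in \[0, 1\].
#' @export
missingness <- function(x) {
  if (inherits(x, "snp_matrix")) {
    if (length(x$geno) == 0L) stop("empty SNP matrix")
    return(mean(is.na(x$geno)))
  }
  if (inherits(x, "locus_set")) {
    if (n_loci(x) == 0L) stop("empty locus set")
    nsamp <- nrow(x$samples)
    total <- sum(locus_lengths(x)) * nsamp
    present <- sum(vapply(x$loci, function(l) {
      chars <- locus_matrix(l)
      sum(!(chars %in% c("N", "-")))
    }, numeric(1)))
    return(1 - present / total)
  }
  stop("missingness() expects a snp_matrix or locus_set")
}

# run RNG-dependent code under a seed without clobbering the caller's
# random state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a SNP matrix as a minimal VCF
#'
#' Sites are written 1-based with `CHROM` = `locus<id>` and `POS` = the
#' column of the site within its locus alignment; a `##source` header line
#' records provenance.
#'
#' @param m a [snp_matrix()].
#' @param path output file path.
#' @param source provenance string for the `##source` header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, source = "radmixr") {
  gt <- matrix("./.", nrow = n_sites(m), ncol = length(m$samples))
  gt[which(m$geno == 0L)] <- "0/0"
  gt[which(m$geno == 1L)] <- "0/1"
  gt[which(m$geno == 2L)] <- "1/1"
  body <- paste(paste0("locus", m$sites$locus_id), m$sites$pos, ".",
                m$sites$ref, m$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", source),
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(m$samples, collapse = "\t")),
               body), path)
  invisible(path)
}

#' Read a VCF into a SNP matrix
#'
#' Uses \pkg{vcfR} for parsing. Only biallelic SNP records are kept;
#' `CHROM` values of the form `locus<id>` populate the locus index, other
#' `CHROM` values are mapped to consecutive integer ids (one per CHROM, so
#' by-locus bootstrap resamples chromosomes).
#'
#' @param path VCF file path.
#' @return a [snp_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf() needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- !grepl(",", fix[, "ALT"]) &
    fix[, "REF"] %in% .BASES & fix[, "ALT"] %in% .BASES
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  chrom <- fix[, "CHROM"]
  lid <- suppressWarnings(as.integer(sub("^locus", "", chrom)))
  if (anyNA(lid)) lid <- as.integer(factor(chrom, levels = unique(chrom)))
  cnt <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  cnt[which(clean == "0/0")] <- 0L
  cnt[which(clean %in% c("0/1", "1/0"))] <- 1L
  cnt[which(clean == "1/1")] <- 2L
  snp_matrix(data.frame(locus_id = lid, pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"]),
             cnt, colnames(gt))
}
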