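# Quartet topology inference from SNP data.
#
# For each 4-set of samples, site-pattern counts over the jointly-called
# sites are arranged into the three 16 x 16 flattenings of the 4 x 4 x 4
# x 4 pattern tensor (one flattening per possible split). Under the
# multispecies coalescent the flattening matching the true split has rank
# <= 10, so each split is scored by the mass of its flattening beyond
# rank 10 (square root of the sum of squared singular values 11..16) and
# the minimal score wins. Robust to missing data: every quartet uses all
# sites where just its own four samples are called.

#' Enumerate all 4-subsets of a sample list
#'
#' @param samples character vector of >= 4 sample ids.
#' @return a `choose(n, 4)` x 4 character matrix, one quartet per row, in
#'   deterministic (combinatorial) order.
#' @export
enumerate_quartets <- function(samples) {
  n <- length(samples)
  if (n < 4L) stop("need at least 4 samples, got ", n)
  t(utils::combn(samples, 4L))
}

#' Resolve heterozygous genotypes to haploid base calls
#'
#' Each genotype is mapped to one base: homozygotes to their allele,
#' heterozygotes to one of their two alleles chosen uniformly at random
#' under `seed` (preserving allele frequencies in expectation, with a
#' deterministic audit trail).
#'
#' @param m a [snp_matrix()].
#' @param seed integer seed.
#' @return character matrix (sites x samples) of bases, `NA` for missing.
#' @export
resolve_heterozygotes <- function(m, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- matrix(NA_character_, nrow = n_sites(m), ncol = length(m$samples),
                dimnames = list(NULL, m$samples))
  ref <- m$sites$ref
  alt <- m$sites$alt
  for (j in seq_along(m$samples)) {
    g <- m$geno[, j]
    out[, j] <- ifelse(g == 0L, ref, alt)
    het <- which(g == 1L)
    if (length(het) > 0L)
      out[het, j] <- ifelse(stats::runif(length(het)) < 0.5,
                            ref[het], alt[het])
  }
  out
}

#' Site-pattern counts for one quartet
#'
#' @param m a [snp_matrix()], or a pre-resolved base matrix from
#'   [resolve_heterozygotes()] (used by tree building so all quartets
#'   share one resolution).
#' @param q character vector of 4 sample ids.
#' @param seed seed for heterozygote resolution when `m` is a
#'   [snp_matrix()].
#' @return a `quartet_counts` object: integer array `counts` of dimension
#'   4x4x4x4 (base index order A,C,G,T per sample in the order of `q`)
#'   and `n_sites`, the number of jointly-called sites.
#' @export
quartet_pattern_counts <- function(m, q, seed = 1L) {
  if (length(q) != 4L) stop("a quartet has exactly 4 samples")
  base_mat <- if (inherits(m, "snp_matrix")) {
    bad <- setdiff(q, m$samples)
    if (length(bad) > 0L)
      stop("samples not in matrix: ", paste(bad, collapse = ", "))
    resolve_heterozygotes(m, seed)[, q, drop = FALSE]
  } else {
    m[, q, drop = FALSE]
  }
  codes <- matrix(match(base_mat, .BASES), ncol = 4L)
  ok <- !is.na(codes[, 1]) & !is.na(codes[, 2]) &
    !is.na(codes[, 3]) & !is.na(codes[, 4])
  codes <- codes[ok, , drop = FALSE]
  counts <- array(0L, dim = c(4L, 4L, 4L, 4L))
  if (nrow(codes) > 0L) {
    flat <- (codes[, 1] - 1L) + 4L * (codes[, 2] - 1L) +
      16L * (codes[, 3] - 1L) + 64L * (codes[, 4] - 1L) + 1L
    tab <- tabulate(flat, nbins = 256L)
    counts <- array(tab, dim = c(4L, 4L, 4L, 4L))
  }
  structure(list(counts = counts, taxa = q, n_sites = nrow(codes)),
            class = "quartet_counts")
}

# score one flattening: mass beyond rank 10
.flattening_score <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  sqrt(sum(d[11:16]^2))
}

#' Infer the topology of one quartet from its pattern counts
#'
#' @param counts a `quartet_counts` object from [quartet_pattern_counts()].
#' @param tol two splits whose scores differ by less than `tol` (relative
#'   to the largest score, floor `1e-12`) are tied; a tie for the minimum
#'   marks the quartet unresolved.
#' @return a `quartet` object: `taxa`, `topology` (`"12|34"`, `"13|24"`,
#'   `"14|23"` referring to positions in `taxa`, or `NA` when unresolved),
#'   `split` (the two cherries by sample id), `scores` (named numeric of
#'   the three split scores), `n_sites`, `resolved`.
#' @export
infer_quartet <- function(counts, tol = 1e-9) {
  stopifnot(inherits(counts, "quartet_counts"))
  A <- counts$counts
  f <- A / max(1L, sum(A))
  # flattening rows indexed by the states of one side of the split
  m12 <- matrix(aperm(f, c(1, 2, 3, 4)), nrow = 16L)  # rows (s1,s2)
  m13 <- matrix(aperm(f, c(1, 3, 2, 4)), nrow = 16L)  # rows (s1,s3)
  m14 <- matrix(aperm(f, c(1, 4, 2, 3)), nrow = 16L)  # rows (s1,s4)
  scores <- c("12|34" = .flattening_score(m12),
              "13|24" = .flattening_score(m13),
              "14|23" = .flattening_score(m14))
  eps <- max(tol * max(scores, 1e-300), 1e-12)
  o <- order(scores)
  resolved <- counts$n_sites > 0L && (scores[o[2]] - scores[o[1]]) > eps
  topology <- if (resolved) names(scores)[o[1]] else NA_character_
  split <- NULL
  if (resolved) {
    pair <- switch(topology,
                   "12|34" = c(1L, 2L), "13|24" = c(1L, 3L),
                   "14|23" = c(1L, 4L))
    split <- list(counts$taxa[pair], counts$taxa[-pair])
  }
  structure(list(taxa = counts$taxa, topology = topology, split = split,
                 scores = scores, n_sites = counts$n_sites,
                 resolved = resolved),
            class = "quartet")
}

#' @export
print.quartet <- function(x, ...) {
  if (x$resolved) {
    cat(sprintf("quartet %s,%s | %s,%s  (n_sites = %d)\n",
                x$split[[1]][1], x$split[[1]][2],
                x$split[[2]][1], x$split[[2]][2], x$n_sites))
  } else {
    cat("quartet {", paste(x$taxa, collapse = ","),
        "} unresolved (n_sites = ", x$n_sites, ")\n", sep = "")
  }
  invisible(x)
}

#' Infer all quartets for a set of samples
#'
#' @param m a [snp_matrix()].
#' @param samples sample ids to use (default: all in `m`).
#' @param seed seed for the shared heterozygote resolution.
#' @return data frame with one row per quartet: taxa `t1..t4` (sorted),
#'   the two cherry members `a`, `b` and `c`, `d` of the chosen split
#'   (`NA` when unresolved), the three scores, and `n_sites`.
#' @export
infer_all_quartets <- function(m, samples = NULL, seed = 1L) {
  if (is.null(samples)) samples <- m$samples
  base_mat <- resolve_heterozygotes(m, seed)
  qs <- enumerate_quartets(samples)
  rows <- vector("list", nrow(qs))
  for (i in seq_len(nrow(qs))) {
    q <- infer_quartet(quartet_pattern_counts(base_mat, qs[i, ]))
    rows[[i]] <- data.frame(
      t1 = qs[i, 1], t2 = qs[i, 2], t3 = qs[i, 3], t4 = qs[i, 4],
      a = if (q$resolved) q$split[[1]][1] else NA_character_,
      b = if (q$resolved) q$split[[1]][2] else NA_character_,
      c = if (q$resolved) q$split[[2]][1] else NA_character_,
      d = if (q$resolved) q$split[[2]][2] else NA_character_,
      score_12_34 = q$scores[1], score_13_24 = q$scores[2],
      score_14_23 = q$scores[3], n_sites = q$n_sites,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
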