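# Brute-force oracles, written as naive loops independent of the package
# internals, plus small fixture builders.

ORACLE_IUPAC <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
                     T = c("T", "T"),
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

oracle_column_alleles <- function(chars) {
  out <- character()
  for (ch in chars) {
    if (ch %in% names(ORACLE_IUPAC)) out <- c(out, ORACLE_IUPAC[[ch]])
  }
  out
}

oracle_count_snps <- function(locus) {
  mat <- locus_matrix(locus)
  n <- 0L
  for (j in seq_len(ncol(mat))) {
    alleles <- oracle_column_alleles(mat[, j])
    if (length(unique(alleles)) >= 2L) n <- n + 1L
  }
  n
}

oracle_count_pis <- function(locus) {
  mat <- locus_matrix(locus)
  n <- 0L
  for (j in seq_len(ncol(mat))) {
    carriers <- list()
    for (i in seq_len(nrow(mat))) {
      ch <- mat[i, j]
      if (ch %in% names(ORACLE_IUPAC))
        for (a in unique(ORACLE_IUPAC[[ch]]))
          carriers[[a]] <- c(carriers[[a]], i)
    }
    n_common <- sum(vapply(carriers, function(x) length(x) >= 2L,
                           logical(1)))
    if (n_common >= 2L) n <- n + 1L
  }
  n
}

oracle_shared_het_ok <- function(locus, max_samples) {
  mat <- locus_matrix(locus)
  for (j in seq_len(ncol(mat))) {
    hets <- sum(mat[, j] %in% c("R", "Y", "S", "W", "K", "M"))
    if (hets > max_samples) return(FALSE)
  }
  TRUE
}

oracle_n_biallelic <- function(locus) {
  mat <- locus_matrix(locus)
  n <- 0L
  for (j in seq_len(ncol(mat))) {
    alleles <- oracle_column_alleles(mat[, j])
    if (length(unique(alleles)) == 2L) n <- n + 1L
  }
  n
}

oracle_taxon_ok <- function(locus, tax_of, k) {
  covered <- names(locus$seqs)
  ok <- TRUE
  for (taxon in unique(tax_of)) {
    members <- names(tax_of)[tax_of == taxon]
    need <- min(k, length(members))
    if (sum(members %in% covered) < need) ok <- FALSE
  }
  ok
}

# D-statistic by a literal per-site loop
oracle_d <- function(p1, p2, p3, p4) {
  num <- 0
  den <- 0
  for (j in seq_along(p1)) {
    abba <- (1 - p1[j]) * p2[j] * p3[j] * (1 - p4[j])
    baba <- p1[j] * (1 - p2[j]) * p3[j] * (1 - p4[j])
    num <- num + (abba - baba)
    den <- den + (abba + baba)
  }
  num / den
}

# random locus set with IUPAC codes and per-sample dropout
random_locus_set <- function(n_loci = 20, n_samples = 8, len = 30,
                             het_rate = 0.05, drop_rate = 0.2, seed = 1) {
  set.seed(seed)
  chars <- c("A", "C", "G", "T")
  hets <- c("R", "Y", "S", "W", "K", "M")
  samples <- paste0("s", seq_len(n_samples))
  loci <- lapply(seq_len(n_loci), function(i) {
    keep <- samples[runif(n_samples) >= drop_rate]
    if (length(keep) == 0L) keep <- samples[1]
    base <- sample(chars, len, replace = TRUE)
    seqs <- vapply(keep, function(s) {
      v <- base
      mut <- runif(len) < 0.15
      v[mut] <- sample(chars, sum(mut), replace = TRUE)
      hh <- runif(len) < het_rate
      v[hh] <- sample(hets, sum(hh), replace = TRUE)
      paste(v, collapse = "")
    }, character(1))
    rad_locus(i, seqs)
  })
  locus_set(loci, samples = samples)
}
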