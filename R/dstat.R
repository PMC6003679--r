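# Pooled-frequency ABBA-BABA D-statistics with by-locus bootstrap.
#
# For a four-group test (((P1, P2), P3), P4) with P4 the outgroup, each
# usable biallelic site contributes
#   ABBA = (1 - p1) * p2 * p3 * (1 - p4)
#   BABA = p1 * (1 - p2) * p3 * (1 - p4)
# where p_i is the derived-allele frequency in pool i, and
#   D = sum(ABBA - BABA) / sum(ABBA + BABA).
# Gene flow between P3 and P2 inflates ABBA (D > 0); between P3 and P1 it
# inflates BABA (D < 0). Significance comes from resampling whole loci
# with replacement: Z = |D| / sd(bootstrap D).

#' Define one four-group D-statistic test
#'
#' @param p1,p2,p3,p4 non-empty, disjoint character vectors of sample ids;
#'   `p4` is the outgroup pool.
#' @param label optional test label.
#' @param test_index optional integer index used in battery output.
#' @return an object of class `dstat_test`.
#' @export
dstat_test <- function(p1, p2, p3, p4, label = "", test_index = NA_integer_) {
  pools <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (any(lengths(pools) == 0L)) stop("all four pools must be non-empty")
  all_ids <- unlist(pools)
  if (anyDuplicated(all_ids)) stop("pools must be disjoint")
  structure(c(pools, list(label = label,
                          test_index = as.integer(test_index))),
            class = "dstat_test")
}

#' Per-pool derived-allele frequencies for one test
#'
#' A site is usable when every pool has at least one called allele. The
#' derived allele is the allele at minor frequency in the outgroup pool;
#' at an exact 50:50 outgroup tie the reference (lexicographically
#' smallest) allele is taken as derived — the `(1 - p4)` factor already
#' downweights polymorphic-outgroup sites symmetrically.
#'
#' @param m a [snp_matrix()].
#' @param test a [dstat_test()].
#' @return a `pooled_freqs` list with per-usable-site frequency vectors
#'   `p1..p4`, allele counts per pool, and the site's `locus_id`.
#' @export
pooled_frequencies <- function(m, test) {
  for (p in c("p1", "p2", "p3", "p4")) {
    bad <- setdiff(test[[p]], m$samples)
    if (length(bad) > 0L)
      stop("pool ", p, " samples not in matrix: ", paste(bad, collapse = ", "))
  }
  pool_stats <- lapply(c("p1", "p2", "p3", "p4"), function(p) {
    g <- m$geno[, test[[p]], drop = FALSE]
    called <- 2L * rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    list(n = called, f_alt = ifelse(called > 0L, alt / called, NA_real_))
  })
  names(pool_stats) <- c("p1", "p2", "p3", "p4")
  usable <- Reduce(`&`, lapply(pool_stats, function(s) s$n > 0L))
  idx <- which(usable)
  derived_is_alt <- pool_stats$p4$f_alt[idx] < 0.5
  freq <- lapply(pool_stats, function(s) {
    f <- s$f_alt[idx]
    ifelse(derived_is_alt, f, 1 - f)
  })
  structure(list(p1 = freq$p1, p2 = freq$p2, p3 = freq$p3, p4 = freq$p4,
                 n_alleles = vapply(pool_stats,
                                    function(s) s$n[idx],
                                    numeric(length(idx))),
                 locus_id = m$sites$locus_id[idx],
                 site_index = idx,
                 n_excluded = sum(!usable)),
            class = "pooled_freqs")
}

#' The D-statistic from pooled frequencies
#'
#' @param f a `pooled_freqs` object from [pooled_frequencies()], or a list
#'   with numeric vectors `p1..p4` of equal length.
#' @return list with `D`, `abba_sum`, `baba_sum` and per-site vectors
#'   `abba`, `baba`. When `sum(abba + baba)` is zero, `D` is `NA` and the
#'   condition is flagged via `defined = FALSE` (with a warning).
#' @export
d_statistic <- function(f) {
  if (length(f$p1) == 0L) stop("no informative sites")
  abba <- (1 - f$p1) * f$p2 * f$p3 * (1 - f$p4)
  baba <- f$p1 * (1 - f$p2) * f$p3 * (1 - f$p4)
  denom <- sum(abba) + sum(baba)
  if (denom == 0) {
    warning("ABBA + BABA mass is zero: D undefined")
    return(list(D = NA_real_, abba_sum = 0, baba_sum = 0,
                abba = abba, baba = baba, defined = FALSE))
  }
  list(D = (sum(abba) - sum(baba)) / denom,
       abba_sum = sum(abba), baba_sum = sum(baba),
       abba = abba, baba = baba, defined = TRUE)
}

#' D-statistic with by-locus bootstrap Z-score
#'
#' Loci (not sites) are resampled with replacement `n_boot` times; D is
#' recomputed on each replicate, `sd_boot` is the standard deviation of
#' the replicate Ds, and `Z = |D| / sd_boot`. A replicate whose resampled
#' loci carry zero ABBA+BABA mass is redrawn (counted in `n_redrawn`).
#'
#' @param m a [snp_matrix()] with a populated locus index.
#' @param test a [dstat_test()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param z_threshold significance threshold in bootstrap standard
#'   deviations (default 3.5).
#' @param keep_replicates keep the vector of replicate Ds for audit.
#' @return an object of class `dstat_result`.
#' @export
bootstrap_z <- function(m, test, n_boot = 1000L, seed = 1L,
                        z_threshold = 3.5, keep_replicates = FALSE) {
  f <- pooled_frequencies(m, test)
  d <- d_statistic(f)
  per_locus_a <- tapply(d$abba, f$locus_id, sum)
  per_locus_b <- tapply(d$baba, f$locus_id, sum)
  L <- length(per_locus_a)
  if (L < 2L) stop("need >= 2 loci with usable sites for the bootstrap")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- as.numeric(per_locus_a)
  b <- as.numeric(per_locus_b)
  Db <- numeric(n_boot)
  n_redrawn <- 0L
  for (r in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(L, L, replace = TRUE)
      num <- sum(a[idx]) - sum(b[idx])
      den <- sum(a[idx]) + sum(b[idx])
      if (den > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) stop("bootstrap cannot find mass")
    }
    Db[r] <- num / den
  }
  sd_boot <- stats::sd(Db)
  Z <- if (!d$defined) NA_real_
  else if (sd_boot > 0) abs(d$D) / sd_boot
  else if (d$D != 0) {
    warning("zero bootstrap SD with nonzero D: Z infinite")
    Inf
  } else 0
  structure(list(D = d$D, abba_sum = d$abba_sum, baba_sum = d$baba_sum,
                 sd_boot = sd_boot, Z = Z,
                 n_loci = L, n_sites = length(f$p1),
                 n_discordant_sites = d$abba_sum + d$baba_sum,
                 significant = isTRUE(Z > z_threshold),
                 z_threshold = z_threshold,
                 n_redrawn = n_redrawn,
                 replicates = if (keep_replicates) Db else NULL,
                 test = test),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  (ABBA %.2f / BABA %.2f, %d loci, %d sites)\n",
              x$D, x$abba_sum, x$baba_sum, x$n_loci, x$n_sites))
  cat(sprintf("Z = %.2f  (boot sd %.4f)%s\n", x$Z, x$sd_boot,
              if (isTRUE(x$significant))
                sprintf("  * |D| > %.1f SD from 0", x$z_threshold) else ""))
  invisible(x)
}

#' Run a battery of D-statistic tests
#'
#' One row per test; failures in individual tests are isolated, reported
#' in the `error` column and do not abort the battery.
#'
#' @param m a [snp_matrix()].
#' @param tests list of [dstat_test()] objects.
#' @param n_boot bootstrap replicates per test (default 1000).
#' @param seed integer seed; test `i` uses `seed + i - 1`.
#' @param z_threshold significance threshold (default 3.5).
#' @return data frame with columns `test_index`, `label`, `p1..p4`, `D`,
#'   `sd_boot`, `Z`, `n_loci`, `n_sites`, `n_discordant`, `significant`,
#'   `error`; mean loci and discordant-site mass across tests are attached
#'   as attributes `mean_n_loci` and `mean_discordant`.
#' @export
run_test_battery <- function(m, tests, n_boot = 1000L, seed = 1L,
                             z_threshold = 3.5) {
  rows <- lapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    ti <- if (is.na(t$test_index)) i - 1L else t$test_index
    base <- data.frame(test_index = ti, label = t$label,
                       p1 = paste(t$p1, collapse = ";"),
                       p2 = paste(t$p2, collapse = ";"),
                       p3 = paste(t$p3, collapse = ";"),
                       p4 = paste(t$p4, collapse = ";"),
                       stringsAsFactors = FALSE)
    res <- tryCatch(
      bootstrap_z(m, t, n_boot = n_boot, seed = seed + i - 1L,
                  z_threshold = z_threshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      cbind(base, data.frame(D = NA_real_, sd_boot = NA_real_, Z = NA_real_,
                             n_loci = NA_integer_, n_sites = NA_integer_,
                             n_discordant = NA_real_, significant = NA,
                             error = conditionMessage(res)))
    } else {
      cbind(base, data.frame(D = res$D, sd_boot = res$sd_boot, Z = res$Z,
                             n_loci = res$n_loci, n_sites = res$n_sites,
                             n_discordant = res$n_discordant_sites,
                             significant = res$significant,
                             error = NA_character_))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_n_loci") <- mean(out$n_loci, na.rm = TRUE)
  attr(out, "mean_discordant") <- mean(out$n_discordant, na.rm = TRUE)
  out
}
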