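# Shared simulation experiments, cached so several test files can reuse
# one run. Study conditions: 4-population tree, Ne = 5e4, 2000 loci of
# 75 bp, mu = 2e-8, 30% locus dropout; the D test pools all samples of
# P1/P2/P3 against the outgroup pool.

.sim_cache <- new.env(parent = emptyenv())

dstat_experiment <- function(gamma, seed, n_loci = 2000, n_boot = 1000,
                             with_hybrid = FALSE) {
  key <- paste("ds", gamma, seed, n_loci, n_boot, with_hybrid, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  d <- demography_dstat(gamma = gamma)
  sim <- simulate_loci(d, sim_config(n_loci = n_loci, seed = seed))
  ls <- sim$loci
  ids <- ls$samples$id
  pools <- lapply(c("P1", "P2", "P3", "O"), function(p)
    grep(paste0("^", p, "_"), ids, value = TRUE))
  names(pools) <- c("P1", "P2", "P3", "O")
  if (with_hybrid)
    ls <- simulate_hybrid(ls, pools$P1, pools$P3, seed = seed)
  m <- extract_snps(ls)
  diffuse <- bootstrap_z(
    m, dstat_test(pools$P1, pools$P2, pools$P3, pools$O),
    n_boot = n_boot, seed = seed)
  hybrid <- if (with_hybrid)
    bootstrap_z(m, dstat_test("F1", pools$P1, pools$P3, pools$O),
                n_boot = n_boot, seed = seed)
  else NULL
  out <- list(m = m, pools = pools, diffuse = diffuse, hybrid = hybrid)
  .sim_cache[[key]] <- out
  out
}

quartet_experiment <- function(seed, n_loci = 70) {
  key <- paste("qt", seed, n_loci, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- simulate_loci(demography_quartet(),
                       sim_config(n_loci = n_loci,
                                  missing_locus_rate = 0, seed = seed))
  m <- extract_snps(sim$loci)
  q <- infer_quartet(quartet_pattern_counts(
    m, c("A_1", "B_1", "C_1", "D_1"), seed = seed))
  .sim_cache[[key]] <- q
  q
}
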