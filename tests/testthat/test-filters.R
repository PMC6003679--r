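make_ls <- function(...) {
  seqs <- list(...)
  loci <- lapply(seq_along(seqs), function(i) rad_locus(i, seqs[[i]]))
  locus_set(loci)
}

test_that("trim_edges shortens every locus by exactly n and drops none", {
  l75 <- rad_locus(1, c(a = strrep("ACGTA", 15), b = strrep("TGCAT", 15)))
  ls <- locus_set(list(l75))
  out <- trim_edges(ls, 5)
  expect_equal(locus_lengths(out), 70L)
  expect_equal(unname(out$loci[[1]]$seqs["a"]), substr(strrep("ACGTA", 15), 1, 70))

  ls2 <- random_locus_set(n_loci = 15, len = 40, seed = 2)
  out2 <- trim_edges(ls2, 5)
  expect_equal(n_loci(out2), n_loci(ls2))
  expect_equal(locus_lengths(out2), locus_lengths(ls2) - 5L)

  same <- trim_edges(ls2, 0)
  expect_equal(lapply(same$loci, `[[`, "seqs"), lapply(ls2$loci, `[[`, "seqs"))
  short <- make_ls(c(a = "ACG", b = "ACG"))
  expect_error(trim_edges(short, 5), "locus 1")
})

test_that("SNP-excess filter keeps loci at the boundary and matches the oracle", {
  # 11 vs 10 variable columns out of 12
  v11 <- c(a = "AAAAAAAAAAAA", b = "CCCCCCCCCCCA")
  v10 <- c(a = "AAAAAAAAAAAA", b = "CCCCCCCCCCAA")
  ls <- make_ls(v11, v10)
  kept <- filter_max_snps(ls, 10)
  expect_equal(locus_ids(kept), 2L)

  ls2 <- random_locus_set(n_loci = 25, seed = 3)
  counts <- vapply(ls2$loci, oracle_count_snps, integer(1))
  for (k in c(0L, 2L, 5L)) {
    expect_equal(locus_ids(filter_max_snps(ls2, k)),
                 locus_ids(ls2)[counts <= k])
  }
  expect_equal(vapply(ls2$loci, count_snps, integer(1)), counts)
})

test_that("shared-heterozygosity filter removes loci above the sample bound", {
  five_hets <- c(a = "RAAA", b = "RAAA", c = "RAAA", d = "RAAA", e = "RAAA")
  four_hets <- c(a = "RAAA", b = "RAAA", c = "RAAA", d = "RAAA", e = "AAAA")
  ls <- make_ls(five_hets, four_hets)
  expect_equal(locus_ids(filter_shared_hets(ls, 4)), 2L)

  ls2 <- random_locus_set(n_loci = 30, het_rate = 0.3, seed = 4)
  ok <- vapply(ls2$loci, oracle_shared_het_ok, logical(1), max_samples = 2)
  expect_equal(locus_ids(filter_shared_hets(ls2, 2)), locus_ids(ls2)[ok])
})

test_that("coverage tiers nest and m=1 is the identity", {
  ls <- random_locus_set(n_loci = 40, n_samples = 12, drop_rate = 0.5,
                         seed = 5)
  expect_equal(locus_ids(filter_min_coverage(ls, 1)), locus_ids(ls))
  ids4 <- locus_ids(filter_min_coverage(ls, 4))
  ids10 <- locus_ids(filter_min_coverage(ls, 10))
  ids20 <- locus_ids(filter_min_coverage(ls, 12))
  expect_true(all(ids10 %in% ids4))
  expect_true(all(ids20 %in% ids10))
  three <- make_ls(c(a = "AC", b = "AC", c = "AC"))
  expect_equal(n_loci(filter_min_coverage(three, 4)), 0L)
})

test_that("per-taxon coverage honours the small-taxon rule and the census oracle", {
  tax <- c(s1 = "t1", s2 = "t1", s3 = "t1", s4 = "t1", s5 = "t1",
           s6 = "t2", s7 = "t2", s8 = "t2")
  # taxon t2 has 3 < k members: all three must be covered
  full <- rad_locus(1, setNames(rep("ACGT", 8), names(tax)))
  no_t2 <- rad_locus(2, setNames(rep("ACGT", 5), paste0("s", 1:5)))
  partial_t2 <- rad_locus(3, setNames(rep("ACGT", 7), paste0("s", 1:7)))
  ls <- locus_set(list(full, no_t2, partial_t2), samples = names(tax))
  expect_equal(locus_ids(filter_taxon_coverage(ls, tax, 4)), 1L)
  expect_error(filter_taxon_coverage(ls, tax[1:7], 4), "not assigned")

  ls2 <- random_locus_set(n_loci = 30, n_samples = 8, drop_rate = 0.4,
                          seed = 6)
  tax2 <- setNames(rep(c("x", "y"), each = 4), paste0("s", 1:8))
  ok <- vapply(ls2$loci, oracle_taxon_ok, logical(1), tax_of = tax2, k = 3)
  expect_equal(locus_ids(filter_taxon_coverage(ls2, tax2, 3)),
               locus_ids(ls2)[ok])
})

test_that("parsimony-informative counting matches canonical patterns and oracle", {
  expect_equal(count_parsimony_informative(
    rad_locus(1, c(a = "A", b = "A", c = "T", d = "T"))), 1L)
  expect_equal(count_parsimony_informative(
    rad_locus(1, c(a = "A", b = "A", c = "A", d = "T"))), 0L)
  ls <- random_locus_set(n_loci = 20, len = 10, seed = 7)
  expect_equal(vapply(ls$loci, count_parsimony_informative, integer(1)),
               vapply(ls$loci, oracle_count_pis, integer(1)))
  ge2 <- filter_min_pis(ls, 2)
  expect_equal(locus_ids(ge2),
               locus_ids(ls)[vapply(ls$loci, oracle_count_pis, integer(1)) >= 2])
})

test_that("filters are idempotent and independent filters commute", {
  ls <- random_locus_set(n_loci = 30, het_rate = 0.15, seed = 8)
  once <- filter_max_snps(ls, 4)
  twice <- filter_max_snps(once, 4)
  expect_equal(locus_ids(twice), locus_ids(once))
  hs1 <- filter_shared_hets(filter_max_snps(ls, 4), 2)
  hs2 <- filter_max_snps(filter_shared_hets(ls, 2), 4)
  expect_equal(locus_ids(hs1), locus_ids(hs2))
  cov_once <- filter_min_coverage(ls, 5)
  expect_equal(locus_ids(filter_min_coverage(cov_once, 5)),
               locus_ids(cov_once))
})

test_that("apply_filters runs the configured chain with provenance", {
  ls <- random_locus_set(n_loci = 30, len = 40, seed = 9)
  cfg <- filter_config(min_sample_coverage = 4, max_snps_per_locus = 8,
                       max_shared_het_samples = 4, edge_trim_bases = 5)
  out <- apply_filters(ls, cfg)
  expect_true(all(locus_lengths(out) == 35L))
  expect_true(length(out$provenance) >= 4L)
  expect_error(filter_config(min_sample_coverage = 0), ">= 1")
})
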