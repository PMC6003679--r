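freqs <- function(p1, p2, p3, p4, locus_id = seq_along(p1)) {
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, locus_id = locus_id),
            class = "pooled_freqs")
}

test_that("pooled frequencies polarize on the outgroup and drop empty-pool sites", {
  # site 1: fixed difference, p4 fixed ancestral; site 2: outgroup missing
  sites <- data.frame(locus_id = c(1L, 2L), pos = c(1L, 1L),
                      ref = "A", alt = "T")
  g <- rbind(c(0L, 2L, 2L, 0L, 0L),
             c(2L, 2L, 2L, NA, NA))
  m <- snp_matrix(sites, g, c("a", "b", "c", "o1", "o2"))
  t0 <- dstat_test("a", "b", "c", c("o1", "o2"))
  f <- pooled_frequencies(m, t0)
  expect_equal(length(f$p1), 1L)
  expect_equal(f$n_excluded, 1L)
  expect_equal(c(f$p1, f$p2, f$p3, f$p4), c(0, 1, 1, 0))
  expect_error(dstat_test("a", "a", "c", "o"), "disjoint")
})

test_that("pooled frequencies match a per-pool allele tally on random data", {
  set.seed(31)
  n <- 60L
  sites <- data.frame(locus_id = rep(1:15, each = 4), pos = rep(1:4, 15),
                      ref = "A", alt = "T")
  g <- matrix(sample(c(0:2, NA), n * 9, replace = TRUE), nrow = n)
  m <- snp_matrix(sites, g, paste0("s", 1:9))
  t0 <- dstat_test(c("s1", "s2"), c("s3", "s4"), c("s5", "s6"),
                   c("s7", "s8", "s9"))
  f <- pooled_frequencies(m, t0)
  pools <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8, 9))
  for (j in seq_along(f$site_index)) {
    row <- g[f$site_index[j], ]
    alt_freq <- vapply(pools, function(p) {
      x <- row[p]
      sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
    }, numeric(1))
    derived_alt <- alt_freq[4] < 0.5
    want <- if (derived_alt) alt_freq else 1 - alt_freq
    expect_equal(c(f$p1[j], f$p2[j], f$p3[j], f$p4[j]), want)
  }
})

test_that("D matches hand values and the per-site loop oracle at 1e-12", {
  pure_abba <- d_statistic(freqs(0, 1, 1, 0))
  expect_equal(pure_abba$D, 1)
  expect_equal(pure_abba$abba_sum, 1)
  cancel <- d_statistic(freqs(c(0, 1), c(1, 0), c(1, 1), c(0, 0)))
  expect_equal(cancel$D, 0)
  set.seed(32)
  for (rep in 1:5) {
    p <- matrix(runif(4 * 200), nrow = 4)
    d <- d_statistic(freqs(p[1, ], p[2, ], p[3, ], p[4, ]))
    expect_equal(d$D, oracle_d(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-12)
  }
})

test_that("zero discordant mass is flagged, not silently zero", {
  expect_warning(res <- d_statistic(freqs(0, 0, 0, 0)), "undefined")
  expect_true(is.na(res$D))
  expect_false(res$defined)
  expect_error(d_statistic(freqs(numeric(0), numeric(0), numeric(0),
                                 numeric(0))), "no informative sites")
})

test_that("degenerate bootstrap collapses to sd 0 with stable D", {
  # every locus has the same single-site pattern
  sites <- data.frame(locus_id = 1:6, pos = 1L, ref = "A", alt = "T")
  g <- matrix(rep(c(0L, 2L, 2L, 0L), each = 6), nrow = 6)
  m <- snp_matrix(sites, g, c("a", "b", "c", "o"))
  t0 <- dstat_test("a", "b", "c", "o")
  expect_warning(r <- bootstrap_z(m, t0, n_boot = 50, seed = 1), "infinite")
  expect_equal(r$D, 1)
  expect_equal(r$sd_boot, 0)
  expect_true(is.infinite(r$Z))
})

test_that("swapping P1 and P2 negates D and keeps |Z| (same seed)", {
  ex <- dstat_experiment(gamma = 0.2, seed = 101, n_loci = 400,
                         n_boot = 300)
  m <- ex$m
  p <- ex$pools
  fwd <- bootstrap_z(m, dstat_test(p$P1, p$P2, p$P3, p$O),
                     n_boot = 300, seed = 5)
  rev <- bootstrap_z(m, dstat_test(p$P2, p$P1, p$P3, p$O),
                     n_boot = 300, seed = 5)
  expect_equal(rev$D, -fwd$D, tolerance = 1e-12)
  expect_equal(rev$Z, fwd$Z, tolerance = 1e-12)
  expect_true(fwd$D >= -1 && fwd$D <= 1)
})

test_that("single-individual pools reduce to genotype frequencies 0, 1/2, 1", {
  ex <- dstat_experiment(gamma = 0, seed = 102, n_loci = 200, n_boot = 100)
  m <- ex$m
  p <- ex$pools
  t1 <- dstat_test(p$P1[1], p$P2[1], p$P3[1], p$O[1])
  f <- pooled_frequencies(m, t1)
  expect_true(all(unlist(f[c("p1", "p2", "p3", "p4")]) %in% c(0, 0.5, 1)))
  # per-individual oracle: frequency = genotype/2 polarized on outgroup
  cols <- match(c(p$P1[1], p$P2[1], p$P3[1], p$O[1]), m$samples)
  for (j in seq_len(min(25, length(f$site_index)))) {
    row <- m$geno[f$site_index[j], cols] / 2
    want <- if (row[4] < 0.5) row else 1 - row
    expect_equal(c(f$p1[j], f$p2[j], f$p3[j], f$p4[j]), unname(want))
  }
})

test_that("a battery row reproduces the single-test result and isolates failures", {
  ex <- dstat_experiment(gamma = 0.2, seed = 101, n_loci = 400,
                         n_boot = 300)
  p <- ex$pools
  tests <- list(dstat_test(p$P1, p$P2, p$P3, p$O, label = "diffuse"),
                dstat_test("absent_sample", p$P2, p$P3, p$O,
                           label = "broken"))
  tab <- suppressWarnings(run_test_battery(ex$m, tests, n_boot = 300,
                                           seed = 5))
  expect_equal(nrow(tab), 2L)
  single <- bootstrap_z(ex$m, tests[[1]], n_boot = 300, seed = 5)
  expect_equal(tab$D[1], single$D)
  expect_equal(tab$Z[1], single$Z)
  expect_true(is.na(tab$D[2]))
  expect_match(tab$error[2], "absent_sample")
  tab2 <- suppressWarnings(run_test_battery(ex$m, tests, n_boot = 300,
                                            seed = 5))
  expect_identical(tab$D, tab2$D)
})
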