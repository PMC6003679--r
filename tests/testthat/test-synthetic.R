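test_that("demography validates trees, Ne and pulse windows", {
  expect_error(demography("(A:10,B:20);", 100, 1L), "ultrametric")
  expect_error(demography("((A:10,B:10):10,C:20);", -5, 1L), "positive")
  bad_pulse <- data.frame(donor = "A", recipient = "B", time = 15,
                          gamma = 0.1)
  expect_error(demography("((A:10,B:10):10,C:20);", 100, 1L,
                          pulses = bad_pulse), "does not exist")
  expect_error(demography("((A:10,B:10):10,C:20);", 100, 1L,
                          pulses = data.frame(donor = "A", recipient = "B",
                                              time = 5, gamma = 1.5)),
               "gamma")
})

test_that("single-population diversity matches 4*Ne*mu within 3 SE", {
  d <- demography("(X:1);", Ne = 5e4, samples_per_pop = c(X = 2))
  cc <- sim_config(n_loci = 1500, mu = 2e-8, missing_locus_rate = 0,
                   seed = 81)
  sim <- simulate_loci(d, cc)
  m <- extract_snps(sim$loci)
  # per-locus heterozygosity over the 4 sampled alleles, vs theta = 0.004
  p <- rowSums(m$geno) / 4
  pi_by_locus <- tapply(2 * p * (1 - p) * 4 / 3, m$sites$locus_id, sum)
  all_loci <- rep(0, n_loci(sim$loci))
  all_loci[as.integer(names(pi_by_locus))] <- pi_by_locus
  per_site <- all_loci / cc$locus_length
  se <- sd(per_site) / sqrt(length(per_site))
  expect_lt(abs(mean(per_site) - 4 * 5e4 * 2e-8), 3 * se)
})

test_that("locus dropout matches the configured rate within binomial error", {
  d <- demography_dstat()
  cc <- sim_config(n_loci = 400, missing_locus_rate = 0.33, seed = 82)
  sim <- simulate_loci(d, cc)
  n_samp <- nrow(sim$loci$samples)
  present <- sum(vapply(sim$loci$loci, function(l) length(l$seqs),
                        integer(1)))
  rate <- 1 - present / (400 * n_samp)
  se <- sqrt(0.33 * 0.67 / (400 * n_samp))
  expect_lt(abs(rate - 0.33), 4 * se)
})

test_that("generators are bit-reproducible under a fixed seed", {
  d <- demography_dstat(gamma = 0.1)
  a <- simulate_loci(d, sim_config(n_loci = 40, seed = 83))
  b <- simulate_loci(d, sim_config(n_loci = 40, seed = 83))
  expect_identical(lapply(a$loci$loci, `[[`, "seqs"),
                   lapply(b$loci$loci, `[[`, "seqs"))
  h1 <- simulate_hybrid(a$loci, c("P1_1", "P1_2"), c("P3_1"), seed = 9)
  h2 <- simulate_hybrid(b$loci, c("P1_1", "P1_2"), c("P3_1"), seed = 9)
  expect_identical(lapply(h1$loci, `[[`, "seqs"),
                   lapply(h2$loci, `[[`, "seqs"))
  p1 <- simulate_posterior(1e-3, 1e-4, 50, seed = 4)
  p2 <- simulate_posterior(1e-3, 1e-4, 50, seed = 4)
  expect_identical(p1$draws, p2$draws)
  expect_equal(simulate_posterior(2e-3, 0, 10, seed = 1)$draws,
               rep(2e-3, 10))
})

test_that("an F1 hybrid is heterozygous at parental fixed differences", {
  la <- rad_locus(1, c(pa1 = "AAAA", pa2 = "AAAA",
                       pb1 = "TTTT", pb2 = "TTTT"))
  ls <- locus_set(list(la))
  h <- simulate_hybrid(ls, c("pa1", "pa2"), c("pb1", "pb2"), seed = 5)
  expect_equal(unname(h$loci[[1]]$seqs["F1"]), "WWWW")
  expect_error(simulate_hybrid(ls, character(0), "pb1"), "non-empty")
})

test_that("noiseless fabricated replicates round-trip through alignment", {
  truth <- matrix(c(0.7, 0.2, 0.1,
                    0.1, 0.7, 0.2,
                    0.2, 0.1, 0.7), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("s", 1:3), NULL))
  runs <- simulate_structure_runs(truth, n_reps = 5, noise_sd = 0,
                                  lnL_mean = -300, seed = 6)
  al <- align_replicates(runs)
  # without noise the average equals the reference replicate exactly ...
  expect_equal(unname(al$Q_mean), unname(runs[[1]]$Q), tolerance = 1e-12)
  # ... which is the truth up to its recorded column permutation
  perm1 <- attr(runs, "permutations")[[1]]
  expect_equal(unname(al$Q_mean), unname(truth[, perm1]),
               tolerance = 1e-12)
})

test_that("fabricated likelihood profiles peaked at K=3 recover best K = 3", {
  truth3 <- matrix(c(0.9, 0.05, 0.05,
                     0.05, 0.9, 0.05,
                     0.05, 0.05, 0.9,
                     0.3, 0.4, 0.3), 4, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), NULL))
  profile <- c(`2` = -2000, `3` = -1000, `4` = -980, `5` = -975)
  reps <- list()
  for (k in 2:5) {
    qk <- matrix(rep(1 / k, 4 * k), 4, k,
                 dimnames = list(paste0("s", 1:4), NULL))
    qk_truth <- if (k == 3) truth3 else qk
    runs <- simulate_structure_runs(qk_truth, n_reps = 4, noise_sd = 0.01,
                                    lnL_mean = profile[[as.character(k)]],
                                    lnL_sd = 2, K_label = k,
                                    seed = 90 + k)
    reps <- c(reps, runs)
  }
  kept <- convergence_filter(reps)$kept
  expect_gte(length(kept), 8L)
  ev <- evanno(kept)
  expect_equal(ev$best_K, 3L)
})

test_that("mean D rises with the admixture proportion gamma", {
  gammas <- c(0, 0.05, 0.1, 0.2)
  mean_D <- vapply(gammas, function(g) {
    mean(vapply(1:3, function(s)
      dstat_experiment(gamma = g, seed = 300 + s, n_loci = 800,
                       n_boot = 200)$diffuse$D, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_D) > -0.05))
  expect_gt(mean_D[4], mean_D[1])
})
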