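test_that("quartet enumeration matches the closed form and handles bounds", {
  expect_equal(nrow(enumerate_quartets(letters[1:4])), 1L)
  expect_error(enumerate_quartets(letters[1:3]), "at least 4")
  for (n in c(5L, 8L, 10L, 17L, 25L, 50L)) {
    expect_equal(nrow(enumerate_quartets(paste0("s", 1:n))),
                 n * (n - 1) * (n - 2) * (n - 3) / 24)
  }
  q10 <- enumerate_quartets(paste0("s", 1:10))
  expect_equal(nrow(q10), 210L)
  expect_equal(anyDuplicated(apply(q10, 1, paste, collapse = "|")), 0L)
})

test_that("pattern counts use jointly-called sites only and are local to the quartet", {
  sites <- data.frame(locus_id = 1:3, pos = 1L, ref = "A", alt = "T")
  g <- rbind(c(0L, 0L, 0L, 0L, 2L),    # all four called (constant A)
             c(0L, NA, 0L, 0L, 0L),    # b missing -> dropped
             c(2L, 2L, 0L, 0L, NA))    # informative, 5th sample missing
  m <- snp_matrix(sites, g, c("a", "b", "c", "d", "e"))
  ct <- quartet_pattern_counts(m, c("a", "b", "c", "d"))
  expect_equal(ct$n_sites, 2L)
  expect_equal(ct$counts[1, 1, 1, 1], 1L)   # AAAA
  expect_equal(ct$counts[4, 4, 1, 1], 1L)   # TTAA
  # joint-coverage census oracle
  joint <- sum(apply(!is.na(g[, 1:4]), 1, all))
  expect_equal(ct$n_sites, joint)
  # masking the unrelated fifth sample changes nothing
  g2 <- g
  g2[, 5] <- NA_integer_
  ct2 <- quartet_pattern_counts(snp_matrix(sites, g2, m$samples),
                                c("a", "b", "c", "d"))
  expect_identical(ct$counts, ct2$counts)
})

test_that("constant data ties all three splits and is flagged unresolved", {
  sites <- data.frame(locus_id = 1L, pos = 1L, ref = "A", alt = "T")
  g <- matrix(c(0L, 0L, 0L, 0L), nrow = 1)
  m <- snp_matrix(sites, g, c("a", "b", "c", "d"))
  q <- infer_quartet(quartet_pattern_counts(m, c("a", "b", "c", "d")))
  expect_false(q$resolved)
  expect_true(is.na(q$topology))
  expect_equal(length(unique(round(q$scores, 12))), 1L)
})

test_that("quartet scores permute with taxon relabeling", {
  ex <- dstat_experiment(gamma = 0, seed = 102, n_loci = 200, n_boot = 100)
  m <- ex$m
  q <- c(ex$pools$P1[1], ex$pools$P2[1], ex$pools$P3[1], ex$pools$O[1])
  base <- resolve_heterozygotes(m, seed = 3)
  s_abcd <- infer_quartet(quartet_pattern_counts(base, q))$scores
  s_acbd <- infer_quartet(quartet_pattern_counts(base,
                                                 q[c(1, 3, 2, 4)]))$scores
  # reordering to (a,c,b,d) swaps the 12|34 and 13|24 splits, fixes 14|23
  expect_equal(unname(s_acbd["12|34"]), unname(s_abcd["13|24"]))
  expect_equal(unname(s_acbd["13|24"]), unname(s_abcd["12|34"]))
  expect_equal(unname(s_acbd["14|23"]), unname(s_abcd["14|23"]))
})

test_that("simulated four-taxon data with a long internal branch resolves correctly", {
  hits <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    q <- quartet_experiment(seed = 200 + s)
    if (q$resolved &&
        setequal(q$split[[which(vapply(q$split, function(x)
          "A_1" %in% x, logical(1)))]], c("A_1", "B_1")))
      hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_seeds) - 1L)  # >= 11/12
})

test_that("star-tree simulations pick each resolution about a third of the time", {
  tally <- c("AB" = 0L, "AC" = 0L, "AD" = 0L, unres = 0L)
  n_seeds <- 90L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_loci(
      demography("(A:100000,B:100000,C:100000,D:100000);", Ne = 5e4,
                 samples_per_pop = 1L),
      sim_config(n_loci = 40, missing_locus_rate = 0, seed = 5000 + s))
    m <- extract_snps(sim$loci)
    q <- infer_quartet(quartet_pattern_counts(
      m, c("A_1", "B_1", "C_1", "D_1"), seed = s))
    if (!q$resolved) {
      tally["unres"] <- tally["unres"] + 1L
    } else {
      cherry <- q$split[[which(vapply(q$split, function(x)
        "A_1" %in% x, logical(1)))]]
      partner <- substr(setdiff(cherry, "A_1"), 1, 1)
      tally[paste0("A", partner)] <- tally[paste0("A", partner)] + 1L
    }
  }
  resolved <- sum(tally[1:3])
  # each resolution within a generous multinomial band around 1/3
  for (k in 1:3) {
    p <- tally[k] / resolved
    expect_gt(p, 1 / 3 - 4 * sqrt(2 / 9 / resolved))
    expect_lt(p, 1 / 3 + 4 * sqrt(2 / 9 / resolved))
  }
})
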