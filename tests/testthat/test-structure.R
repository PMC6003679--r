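flat_Q <- function(n, K) {
  matrix(rep(1 / K, n * K), n, K,
         dimnames = list(paste0("s", seq_len(n)), NULL))
}

rep_with_var <- function(K, id, v, mean_lnL = -500) {
  # trace with exact variance v (two points at +/- sqrt(v/2)*sqrt(2))
  trace <- mean_lnL + c(-1, 1) * sqrt(v / 2)
  structure_replicate(K, id, flat_Q(4, K), trace)
}

test_that("convergence filter excludes replicates above 100x the minimum variance", {
  reps <- list(rep_with_var(3, "r1", 1), rep_with_var(3, "r2", 50),
               rep_with_var(3, "r3", 150))
  out <- convergence_filter(reps)
  expect_equal(vapply(out$kept, function(r) r$replicate_id, character(1)),
               c("r1", "r2"))
  expect_equal(out$excluded[[1]]$replicate_id, "r3")
  same <- convergence_filter(list(rep_with_var(2, "a", 5),
                                  rep_with_var(2, "b", 5)))
  expect_equal(length(same$excluded), 0L)
})

test_that("zero minimum variance excludes every positive-variance replicate", {
  reps <- list(rep_with_var(2, "exact", 0), rep_with_var(2, "noisy", 1e-4))
  out <- convergence_filter(reps)
  expect_equal(out$kept[[1]]$replicate_id, "exact")
  expect_equal(length(out$kept), 1L)
})

test_that("randomized variance sets match a brute-force threshold scan", {
  set.seed(71)
  for (i in 1:5) {
    vs <- round(runif(8, 0.1, 300), 3)
    Ks <- sample(2:4, 8, replace = TRUE)
    reps <- lapply(seq_len(8), function(j)
      rep_with_var(Ks[j], paste0("r", j), vs[j]))
    out <- convergence_filter(reps)
    keep_oracle <- logical(8)
    for (j in 1:8) keep_oracle[j] <- vs[j] <= 100 * min(vs[Ks == Ks[j]])
    expect_equal(out$report$kept, keep_oracle)
    # the minimum-variance replicate per K always survives
    for (k in unique(Ks))
      expect_true(any(out$report$kept[Ks == k]))
  }
})

test_that("summary-mode filter works from per-replicate lnL alone", {
  mk <- function(id, lnL) structure_replicate(2, id, flat_Q(4, 2), lnL)
  reps <- list(mk("a", -500), mk("b", -500.1), mk("c", -9000))
  out <- convergence_filter(reps, mode = "summary")
  expect_false("c" %in% vapply(out$kept, `[[`, character(1),
                               "replicate_id"))
})

test_that("column-swapped replicates average back to either input", {
  Q <- matrix(c(0.9, 0.05, 0.05,
                0.05, 0.9, 0.05,
                0.05, 0.05, 0.9,
                0.4, 0.3, 0.3), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), NULL))
  r1 <- structure_replicate(3, 1, Q, -100)
  r2 <- structure_replicate(3, 2, Q[, c(3, 1, 2)], -100)
  al <- align_replicates(list(r1, r2))
  expect_equal(unname(al$Q_mean), unname(Q), tolerance = 1e-12)
  single <- align_replicates(list(r1))
  expect_equal(unname(single$Q_mean), unname(Q))
  expect_error(align_replicates(list(r1, structure_replicate(
    3, 3, Q[c(2, 1, 3, 4), ], -100))), "sample set")
})

test_that("alignment recovers known permutations at noise 0.01", {
  truth <- matrix(c(0.8, 0.1, 0.1,
                    0.1, 0.8, 0.1,
                    0.1, 0.1, 0.8,
                    0.6, 0.2, 0.2), 4, 3, byrow = TRUE,
                  dimnames = list(paste0("s", 1:4), NULL))
  runs <- simulate_structure_runs(truth, n_reps = 4, noise_sd = 0.01,
                                  lnL_mean = -500, seed = 2)
  al <- align_replicates(runs)
  tp <- attr(runs, "permutations")
  ref_map <- tp[[1]][al$permutations[[1]]]
  for (r in seq_along(runs))
    expect_equal(tp[[r]][al$permutations[[r]]], ref_map)
  expect_equal(unname(rowSums(al$Q_mean)), rep(1, 4), tolerance = 1e-9)
  # invariance: permuting any input's columns leaves the average unchanged
  runs2 <- runs
  runs2[[2]] <- structure_replicate(3, 2, runs[[2]]$Q[, c(2, 3, 1)],
                                    runs[[2]]$lnL_trace)
  al2 <- align_replicates(runs2)
  expect_equal(al2$Q_mean, al$Q_mean, tolerance = 1e-12)
})

test_that("Evanno table reproduces the hand-computed delta-K example", {
  Ls <- c(-100, -50, -45, -44)
  reps <- list()
  for (i in seq_along(Ls)) {
    for (r in 1:3) {
      reps[[length(reps) + 1L]] <- structure_replicate(
        i + 1L, r, flat_Q(4, i + 1L), Ls[i] + (r - 2))  # per-K sd = 1
    }
  }
  ev <- evanno(reps)
  expect_equal(ev$table$deltaK[ev$table$K == 3], 45)
  expect_equal(ev$best_K, 3L)
  expect_true(all(is.na(ev$table$deltaK[c(1, nrow(ev$table))])))
  expect_true(all(ev$table$deltaK >= 0, na.rm = TRUE))
  # replicate order invariance
  ev2 <- evanno(rev(reps))
  expect_equal(ev2$table, ev$table)
})

test_that("a flat likelihood profile gives an indeterminate best K", {
  reps <- list()
  for (k in 2:5) for (r in 1:2)
    reps[[length(reps) + 1L]] <- structure_replicate(
      k, r, flat_Q(4, k), -200 + (r - 1.5))
  ev <- evanno(reps)
  expect_true(is.na(ev$best_K))
})

test_that("replicate files parse from CSV and classic output dialects", {
  csv <- withr::local_tempfile(lines = c(
    "sample,cluster1,cluster2,lnL",
    "s1,0.9,0.1,-1234.5",
    "s2,0.2,0.8,-1234.5"))
  rep_csv <- read_structure_runs(csv, dialect = "csv")[[1]]
  expect_equal(rep_csv$K, 2L)
  expect_equal(rep_csv$lnL_mean, -1234.5)
  expect_equal(unname(rep_csv$Q["s1", ]), c(0.9, 0.1))

  classic <- withr::local_tempfile(lines = c(
    "STRUCTURE by Pritchard, Stephens and Donnelly",
    "2 populations assumed",
    "Estimated Ln Prob of Data   = -4321.0",
    "",
    "Inferred ancestry of individuals:",
    "        Label (%Miss) :  Inferred clusters",
    "  1      ind1    (0)  :  0.970 0.030",
    "  2      ind2    (0)  :  0.100 0.900",
    ""))
  rep_cl <- read_structure_runs(classic, dialect = "structure")[[1]]
  expect_equal(rep_cl$K, 2L)
  expect_equal(rep_cl$lnL_mean, -4321)
  expect_equal(unname(rep_cl$Q["ind2", ]), c(0.1, 0.9))
})
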