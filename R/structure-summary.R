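# Summarization of replicate Bayesian clustering runs: convergence
# filtering on log-likelihood variance, label alignment across replicates
# (cluster labels are arbitrary per run), averaged ancestry matrices, and
# Evanno's delta-K for choosing the number of clusters.

#' One replicate clustering run
#'
#' @param K number of clusters (>= 1).
#' @param replicate_id identifier of the replicate.
#' @param Q sample x K ancestry-fraction matrix; every row must sum to 1
#'   within 1e-6. Row names are sample ids.
#' @param lnL_trace numeric vector of post-burn-in log-likelihood values
#'   (may be a single summary value when only that is available).
#' @return an object of class `structure_replicate`.
#' @export
structure_replicate <- function(K, replicate_id, Q, lnL_trace) {
  Q <- as.matrix(Q)
  if (ncol(Q) != K) stop("Q must have K = ", K, " columns")
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("rows of Q must sum to 1 (tolerance 1e-6)")
  if (length(lnL_trace) == 0L) stop("lnL_trace must be non-empty")
  structure(list(K = as.integer(K), replicate_id = replicate_id, Q = Q,
                 lnL_trace = as.numeric(lnL_trace),
                 lnL_mean = mean(lnL_trace)),
            class = "structure_replicate")
}

#' Convergence filter on log-likelihood variance
#'
#' Per value of K, each replicate's log-likelihood variance is compared
#' with the minimum variance among replicates at that K; replicates whose
#' variance exceeds `factor` times the minimum are excluded. With
#' `mode = "trace"` (default) the variance is the within-run variance of
#' the lnL trace; with `mode = "summary"` — for runs where only a summary
#' lnL per replicate is available — each replicate's squared deviation of
#' mean lnL from the per-K median plays the role of its variance.
#'
#' @param reps list of [structure_replicate()] objects (any mix of K).
#' @param factor exclusion multiplier (default 100).
#' @param mode `"trace"` or `"summary"`.
#' @return list with elements `kept` and `excluded` (lists of replicates)
#'   and `report`, a data frame of per-replicate variances, thresholds and
#'   decisions.
#' @export
convergence_filter <- function(reps, factor = 100, mode = c("trace",
                                                            "summary")) {
  mode <- match.arg(mode)
  K <- vapply(reps, function(r) r$K, integer(1))
  v <- if (mode == "trace") {
    vapply(reps, function(r) {
      if (length(r$lnL_trace) < 2L) 0 else stats::var(r$lnL_trace)
    }, numeric(1))
  } else {
    mu <- vapply(reps, function(r) r$lnL_mean, numeric(1))
    med <- stats::ave(mu, K, FUN = stats::median)
    (mu - med)^2
  }
  thr <- stats::ave(v, K, FUN = min) * factor
  keep <- v <= thr
  report <- data.frame(
    K = K,
    replicate_id = vapply(reps, function(r) as.character(r$replicate_id),
                          character(1)),
    variance = v, threshold = thr, kept = keep,
    reason = ifelse(keep, "", sprintf("variance %.4g > %.4g", v, thr)),
    stringsAsFactors = FALSE)
  list(kept = reps[keep], excluded = reps[!keep], report = report)
}

# exact linear assignment by permutation enumeration (K <= 8), greedy
# above; maximizes sum of sim[k, perm[k]]
.best_permutation <- function(sim) {
  K <- nrow(sim)
  if (K <= 8L) {
    perms <- .all_permutations(K)
    scores <- apply(perms, 1L, function(p) sum(sim[cbind(seq_len(K), p)]))
    perms[which.max(scores), ]
  } else {
    perm <- integer(K)
    used <- logical(K)
    for (k in order(apply(sim, 1L, max), decreasing = TRUE)) {
      j <- order(sim[k, ], decreasing = TRUE)
      j <- j[!used[j]][1]
      perm[k] <- j
      used[j] <- TRUE
    }
    perm
  }
}

.all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L))
  sub <- .all_permutations(K - 1L)
  out <- matrix(0L, nrow = K * nrow(sub), ncol = K)
  r <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(K)) {
      out[r, ] <- append(sub[i, ], K, after = pos - 1L)
      r <- r + 1L
    }
  }
  out
}

#' Align replicate Q matrices and average them
#'
#' Cluster labels are arbitrary per replicate; each replicate's columns
#' are permuted to best match the first replicate (optimal assignment on
#' the column-similarity matrix `t(Q_ref) %*% Q_rep`), then the aligned
#' matrices are averaged.
#'
#' @param reps list of [structure_replicate()] objects, all with the same
#'   K and sample set (same row order).
#' @return list with `Q_mean` (averaged aligned matrix, rows summing to
#'   1), `permutations` (list of the column permutation applied to each
#'   replicate, `perm[j]` = reference column matched by input column j
#'   after inversion; see details), and `aligned` (the aligned Q
#'   matrices). The permutation reported for replicate r maps reference
#'   columns to replicate r's columns: `Q_rep[, perm]` aligns with the
#'   reference.
#' @export
align_replicates <- function(reps) {
  K <- unique(vapply(reps, function(r) r$K, integer(1)))
  if (length(K) != 1L) stop("all replicates must share one K")
  rn <- lapply(reps, function(r) rownames(r$Q))
  if (length(unique(vapply(rn, paste, character(1), collapse = "\r"))) != 1L)
    stop("all replicates must share one sample set (same order)")
  ref <- reps[[1]]$Q
  aligned <- vector("list", length(reps))
  perms <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    sim <- crossprod(ref, reps[[i]]$Q)      # K x K column similarity
    p <- .best_permutation(sim)             # ref column k <- input column p[k]
    perms[[i]] <- p
    aligned[[i]] <- reps[[i]]$Q[, p, drop = FALSE]
    colnames(aligned[[i]]) <- colnames(ref)
  }
  Q_mean <- Reduce(`+`, aligned) / length(aligned)
  list(Q_mean = Q_mean, permutations = perms, aligned = aligned)
}

#' Evanno delta-K table and best K
#'
#' Per K: the mean and SD of replicate mean log-likelihoods, the first
#' difference `L'(K) = L(K) - L(K-1)`, the absolute second difference
#' `|L''(K)| = |L(K+1) - 2 L(K) + L(K-1)|`, and
#' `deltaK = |L''(K)| / sd(K)`. The best K is the interior K maximizing
#' deltaK; when deltaK is zero or undefined everywhere the best K is
#' reported as `NA` (indeterminate).
#'
#' @param reps list of [structure_replicate()] objects covering >= 3
#'   consecutive K values with >= 2 replicates each (apply
#'   [convergence_filter()] first).
#' @return list with `table` (data frame of K, n_reps, mean_L, sd_L,
#'   Lprime, Lsecond, deltaK) and `best_K`.
#' @export
evanno <- function(reps) {
  Kv <- vapply(reps, function(r) r$K, integer(1))
  Ks <- sort(unique(Kv))
  if (length(Ks) < 3L) stop("need >= 3 K values for delta-K")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  mean_L <- vapply(Ks, function(k) {
    mean(vapply(reps[Kv == k], function(r) r$lnL_mean, numeric(1)))
  }, numeric(1))
  sd_L <- vapply(Ks, function(k) {
    x <- vapply(reps[Kv == k], function(r) r$lnL_mean, numeric(1))
    if (length(x) < 2L) NA_real_ else stats::sd(x)
  }, numeric(1))
  n <- length(Ks)
  Lprime <- c(NA, diff(mean_L))
  Lsecond <- rep(NA_real_, n)
  if (n >= 3L)
    Lsecond[2:(n - 1L)] <- abs(mean_L[3:n] - 2 * mean_L[2:(n - 1L)] +
                                 mean_L[1:(n - 2L)])
  deltaK <- ifelse(!is.na(Lsecond) & !is.na(sd_L) & sd_L > 0,
                   Lsecond / sd_L, NA_real_)
  tab <- data.frame(K = Ks,
                    n_reps = as.integer(table(factor(Kv, levels = Ks))),
                    mean_L = mean_L, sd_L = sd_L, Lprime = Lprime,
                    Lsecond = Lsecond, deltaK = deltaK)
  best_K <- if (all(is.na(deltaK)) || max(deltaK, na.rm = TRUE) == 0)
    NA_integer_
  else Ks[which.max(deltaK)]
  list(table = tab, best_K = best_K)
}

#' Read replicate clustering runs from files
#'
#' Two dialects. `"csv"`: columns `sample`, `cluster1..clusterK`, `lnL`
#' (the replicate's lnL trace is the unique values of `lnL`, typically a
#' single summary value). `"structure"`: the classic STRUCTURE output
#' file; the parser extracts K, the `Inferred ancestry of individuals`
#' block and the `Estimated Ln Prob of Data` line.
#'
#' @param paths character vector of file paths.
#' @param dialect `"csv"` or `"structure"`.
#' @return list of [structure_replicate()] objects.
#' @export
read_structure_runs <- function(paths, dialect = c("csv", "structure")) {
  dialect <- match.arg(dialect)
  lapply(seq_along(paths), function(i) {
    if (dialect == "csv") .read_structure_csv(paths[i], i)
    else .read_structure_classic(paths[i], i)
  })
}

.read_structure_csv <- function(path, id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qcols <- grep("^cluster", names(df))
  if (length(qcols) == 0L) stop(path, ": no cluster columns")
  Q <- as.matrix(df[, qcols])
  rownames(Q) <- df$sample
  trace <- if ("lnL" %in% names(df)) unique(df$lnL) else
    stop(path, ": no lnL column")
  structure_replicate(length(qcols), id, Q, trace)
}

.read_structure_classic <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  kline <- grep("populations assumed", lines, value = TRUE)[1]
  K <- as.integer(sub(".*?([0-9]+) populations assumed.*", "\\1", kline))
  lnl <- grep("Estimated Ln Prob of Data", lines, value = TRUE)[1]
  lnL <- as.numeric(sub(".*=\\s*", "", lnl))
  start <- grep("Inferred ancestry of individuals", lines)[1]
  if (is.na(start)) stop(path, ": no ancestry block")
  rows <- list()
  for (ln in lines[(start + 2L):length(lines)]) {
    if (!nzchar(trimws(ln))) break
    body <- sub(".*:", "", ln)
    head <- sub(":.*", "", ln)
    fields <- strsplit(trimws(head), "[[:space:]]+")[[1]]
    fr <- as.numeric(strsplit(trimws(body), "[[:space:]]+")[[1]])
    rows[[fields[2]]] <- fr[seq_len(K)]
  }
  Q <- do.call(rbind, rows)
  structure_replicate(K, id, Q, lnL)
}

#' Export an aligned average Q matrix in barplot-ready long format
#'
#' @param Q_mean averaged matrix from [align_replicates()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_q_long <- function(Q_mean, path) {
  long <- data.frame(sample = rep(rownames(Q_mean), ncol(Q_mean)),
                     cluster = rep(seq_len(ncol(Q_mean)),
                                   each = nrow(Q_mean)),
                     fraction = as.vector(Q_mean))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
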