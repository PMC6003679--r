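# Quartet amalgamation by recursive max-cut.
#
# A taxon set is split by the bipartition that (lexicographically)
# minimizes violated quartets and maximizes satisfied ones: a quartet
# ab|cd crossing the cut 2-2 is satisfied when {a,b} and {c,d} land on
# opposite sides, violated when the pairing is broken; quartets not
# crossing 2-2 are deferred to the recursion, where the far side is
# contracted to a single representative taxon. When the input is the
# complete induced quartet set of a binary tree, the only nontrivial
# zero-violation cuts are that tree's splits, so the recursion returns
# the tree exactly. Cut search is exhaustive up to 15 taxa per level and
# a multi-start single-move hill climb above.

.MAXCUT_EXHAUSTIVE_N <- 15L

# Best cut of taxa 1..n given quartet index matrix q (cols a,b,c,d = ab|cd)
# and weights w; returns logical side vector. `real` marks ordinary taxa
# (everything except the "@up" marker); each side needs >= 1 real taxon.
# When `marker` gives the index of "@up", the side not holding the marker
# must have >= 2 members — singleton far-sides carry no 2-2 quartets and
# would stall the recursion.
.best_cut <- function(n, q, w, real, marker = NA_integer_) {
  if (n <= .MAXCUT_EXHAUSTIVE_N) .best_cut_exhaustive(n, q, w, real, marker)
  else .best_cut_greedy(n, q, w, real, marker)
}

.cut_valid <- function(side, real, marker) {
  if (!any(side & real) || !any(!side & real)) return(FALSE)
  if (!is.na(marker)) {
    far <- if (side[marker]) sum(!side) else sum(side)
    if (far < 2L) return(FALSE)
  }
  TRUE
}

.best_cut_exhaustive <- function(n, q, w, real, marker = NA_integer_) {
  n_masks <- bitwShiftL(1L, n - 1L) - 1L
  masks <- seq_len(n_masks)          # taxon 1 fixed on side FALSE
  bit <- c(0L, bitwShiftL(1L, 0:(n - 2L)))
  sat <- numeric(n_masks)
  viol <- numeric(n_masks)
  if (nrow(q) > 0L) {
    for (i in seq_len(nrow(q))) {
      sa <- bitwAnd(masks, bit[q[i, 1]]) > 0L
      sb <- bitwAnd(masks, bit[q[i, 2]]) > 0L
      sc <- bitwAnd(masks, bit[q[i, 3]]) > 0L
      sd <- bitwAnd(masks, bit[q[i, 4]]) > 0L
      s <- (sa == sb) & (sc == sd) & (sa != sc)
      v <- ((sa + sb + sc + sd) == 2L) & !s
      sat <- sat + w[i] * s
      viol <- viol + w[i] * v
    }
  }
  real_bits <- sum(bit[real])
  side1_real <- bitwAnd(masks, real_bits) > 0L
  side0_real <- if (real[1]) rep(TRUE, n_masks)
  else bitwAnd(bitwNot(masks), real_bits) > 0L
  valid <- side1_real & side0_real
  if (!is.na(marker)) {
    size1 <- integer(n_masks)
    for (j in 2:n) size1 <- size1 + (bitwAnd(masks, bit[j]) > 0L)
    marker_on_1 <- if (marker == 1L) rep(FALSE, n_masks)
    else bitwAnd(masks, bit[marker]) > 0L
    far_size <- ifelse(marker_on_1, n - size1, size1)
    valid <- valid & far_size >= 2L
  }
  if (!any(valid)) stop("no valid cut (degenerate taxon set)")
  clean <- valid & viol == 0 & sat > 0
  best <- if (any(clean)) which(clean)[which.max(sat[clean])]
  else which(valid)[which.max((sat - viol)[valid])]
  mask <- masks[best]
  c(FALSE, bitwAnd(mask, bit[-1]) > 0L)
}

.best_cut_greedy <- function(n, q, w, real, marker = NA_integer_,
                             n_starts = 20L) {
  score_of <- function(side) {
    sa <- side[q[, 1]]; sb <- side[q[, 2]]
    sc <- side[q[, 3]]; sd <- side[q[, 4]]
    s <- (sa == sb) & (sc == sd) & (sa != sc)
    v <- ((sa + sb + sc + sd) == 2L) & !s
    sum(w * s) - sum(w * v)
  }
  best_side <- NULL
  best_score <- -Inf
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(n + nrow(q))
  for (st in seq_len(n_starts)) {
    side <- stats::runif(n) < 0.5
    if (!.cut_valid(side, real, marker)) {
      side <- rep(FALSE, n)
      side[which(real)[1:2]] <- c(TRUE, TRUE)
    }
    cur <- score_of(side)
    repeat {
      improved <- FALSE
      for (j in seq_len(n)) {
        cand <- side
        cand[j] <- !cand[j]
        if (!.cut_valid(cand, real, marker)) next
        sc <- score_of(cand)
        if (sc > cur) {
          side <- cand; cur <- sc; improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (cur > best_score) {
      best_score <- cur; best_side <- side
    }
  }
  best_side
}

# recursive fragment builder; taxa is a character vector that may include
# the marker "@up" (the contracted far side); q is a data frame with
# columns a,b,c,d (character, topology ab|cd) and weight, all members in
# taxa. Returns a rooted newick fragment over setdiff(taxa, "@up").
.grow_fragment <- function(taxa, q, counter) {
  S <- setdiff(taxa, "@up")
  if (length(S) == 1L) return(S)
  if (length(S) == 2L) return(paste0("(", S[1], ",", S[2], ")"))
  idx <- stats::setNames(seq_along(taxa), taxa)
  qm <- if (nrow(q) > 0L) cbind(idx[q$a], idx[q$b], idx[q$c], idx[q$d])
  else matrix(integer(), ncol = 4L)
  marker <- if ("@up" %in% taxa) which(taxa == "@up") else NA_integer_
  side <- .best_cut(length(taxa), qm, q$weight, taxa != "@up", marker)
  A <- taxa[side]
  B <- taxa[!side]
  if (is.na(marker)) {
    # top level: join the two side fragments at the root edge
    fa <- .grow_fragment(c(A, "@up"), .restrict_quartets(q, A), counter)
    fb <- .grow_fragment(c(B, "@up"), .restrict_quartets(q, B), counter)
    return(paste0("(", fa, ",", fb, ")"))
  }
  if ("@up" %in% B) { tmp <- A; A <- B; B <- tmp }   # attach side is A
  rep_name <- paste0("@rep", counter$i, "@")
  counter$i <- counter$i + 1L
  fb <- .grow_fragment(c(B, "@up"), .restrict_quartets(q, B), counter)
  qa <- .restrict_quartets(q, setdiff(A, "@up"), keep = "@up",
                           rep_name = rep_name)
  fa <- .grow_fragment(c(setdiff(A, "@up"), rep_name, "@up"), qa, counter)
  sub(rep_name, fb, fa, fixed = TRUE)
}

# keep quartets with >= 3 members in `inside` (plus optionally the marker
# `keep`); the single outside member is renamed to "@up" (or rep_name when
# it is neither inside nor `keep`)
.restrict_quartets <- function(q, inside, keep = NULL, rep_name = "@up") {
  members <- cbind(q$a, q$b, q$c, q$d)
  allowed <- c(inside, keep)
  inside_n <- matrix(members %in% allowed, ncol = 4L)
  n_in <- rowSums(inside_n)
  sel <- which(n_in >= 3L)
  if (length(sel) == 0L)
    return(data.frame(a = character(), b = character(), c = character(),
                      d = character(), weight = numeric()))
  members <- members[sel, , drop = FALSE]
  members[!inside_n[sel, , drop = FALSE]] <- rep_name
  out <- data.frame(a = members[, 1], b = members[, 2],
                    c = members[, 3], d = members[, 4],
                    weight = q$weight[sel], stringsAsFactors = FALSE)
  # drop quartets that collapsed (two members mapped to the same label)
  lab <- cbind(out$a, out$b, out$c, out$d)
  distinct <- apply(lab, 1L, function(r) length(unique(r)) == 4L)
  out <- out[distinct, , drop = FALSE]
  .aggregate_quartets(out)
}

# canonicalize ab|cd (sort within cherries and between them) and sum
# weights of duplicates
.aggregate_quartets <- function(q) {
  if (nrow(q) == 0L) return(q)
  p1 <- ifelse(q$a <= q$b, paste(q$a, q$b), paste(q$b, q$a))
  p2 <- ifelse(q$c <= q$d, paste(q$c, q$d), paste(q$d, q$c))
  key <- ifelse(p1 <= p2, paste(p1, p2), paste(p2, p1))
  agg <- tapply(q$weight, key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  data.frame(a = parts[, 1], b = parts[, 2], c = parts[, 3], d = parts[, 4],
             weight = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Amalgamate quartets into a supertree
#'
#' @param quartets either a data frame with character columns `a`, `b`,
#'   `c`, `d` (topology `ab|cd`) and optional `weight`, or the output of
#'   [infer_all_quartets()] (unresolved rows are dropped and contribute no
#'   weight).
#' @param conflict_report when `TRUE`, attach counts of input quartets
#'   satisfied/violated by the returned tree as attribute `"conflict"`
#'   (quadratic in taxa; intended for small trees).
#' @return an unrooted `phylo` tree over all taxa present in the input.
#' @export
supertree <- function(quartets, conflict_report = FALSE) {
  q <- quartets
  if (all(c("t1", "a") %in% names(q)))   # infer_all_quartets output
    q <- q[!is.na(q$a), c("a", "b", "c", "d")]
  if (!all(c("a", "b", "c", "d") %in% names(q)))
    stop("quartets must have columns a, b, c, d")
  if (is.null(q$weight)) q$weight <- rep(1, nrow(q))
  q <- .aggregate_quartets(q[, c("a", "b", "c", "d", "weight")])
  taxa <- sort(unique(c(q$a, q$b, q$c, q$d)))
  if (length(taxa) < 4L) stop("supertree needs at least 4 taxa")
  if (any(grepl("^@", taxa))) stop("taxon names may not start with '@'")
  counter <- new.env()
  counter$i <- 1L
  nwk <- paste0(.grow_fragment(taxa, q, counter), ";")
  tr <- ape::unroot(ape::read.tree(text = nwk))
  if (conflict_report) {
    ind <- induced_quartets(tr)
    key_in <- paste(q$a, q$b, q$c, q$d)
    key_tree <- paste(ind$a, ind$b, ind$c, ind$d)
    sat <- key_in %in% key_tree
    attr(tr, "conflict") <- list(n_input = nrow(q),
                                 satisfied = sum(q$weight[sat]),
                                 violated = sum(q$weight[!sat]))
  }
  tr
}

#' All quartets induced by a tree topology
#'
#' The inverse oracle for [supertree()]: every 4-subset of tips with the
#' resolution the tree implies (by the four-point condition on topological
#' distances).
#'
#' @param tree a `phylo` object.
#' @return data frame with canonical columns `a`, `b`, `c`, `d`
#'   (topology `ab|cd`) and `weight = 1`.
#' @export
induced_quartets <- function(tree) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  dm <- ape::cophenetic.phylo(tr)
  tips <- sort(tr$tip.label)
  qs <- enumerate_quartets(tips)
  a <- character(nrow(qs)); b <- a; cc <- a; dd <- a
  for (i in seq_len(nrow(qs))) {
    t4 <- qs[i, ]
    s <- c(dm[t4[1], t4[2]] + dm[t4[3], t4[4]],
           dm[t4[1], t4[3]] + dm[t4[2], t4[4]],
           dm[t4[1], t4[4]] + dm[t4[2], t4[3]])
    pair <- switch(which.min(s), c(1L, 2L), c(1L, 3L), c(1L, 4L))
    a[i] <- t4[pair[1]]; b[i] <- t4[pair[2]]
    rest <- t4[-pair]
    cc[i] <- rest[1]; dd[i] <- rest[2]
  }
  .aggregate_quartets(data.frame(a = a, b = b, c = cc, d = dd,
                                 weight = rep(1, nrow(qs)),
                                 stringsAsFactors = FALSE))
}

#' Quartet-supertree inference from a SNP matrix
#'
#' Infers every quartet with [infer_quartet()] under one shared
#' heterozygote resolution, then amalgamates the resolved quartets.
#'
#' @param m a [snp_matrix()].
#' @param samples tips to include (default all samples of `m`).
#' @param seed seed for heterozygote resolution.
#' @return an unrooted `phylo` tree.
#' @export
tree_from_snps <- function(m, samples = NULL, seed = 1L) {
  qt <- infer_all_quartets(m, samples = samples, seed = seed)
  supertree(qt)
}

# normalized split keys of a tree's internal edges (excluding trivial)
.tree_splits <- function(tree, anchor) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ntip <- length(labs)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= ntip - 1L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys[!is.na(keys)]
}

#' Quartet supertree with nonparametric bootstrap support
#'
#' Builds the full-data tree, then `n_boot` replicates in which loci are
#' resampled with replacement and one SNP is drawn at random from each
#' resampled locus (a putatively unlinked replicate alignment). Each
#' internal edge of the full-data tree is annotated (via `node.label`)
#' with the percentage of replicate trees containing that bipartition.
#' Replicates covering fewer than 4 samples are redrawn (logged in
#' `attr(, "n_redrawn")`).
#'
#' @param m a [snp_matrix()] with a populated locus index.
#' @param n_boot bootstrap replicates (default 100); `0` returns the
#'   full-data tree without support annotations.
#' @param seed integer seed.
#' @param samples tips to include (default all).
#' @return a `phylo` tree with integer percentage supports in
#'   `node.label`.
#' @export
bootstrap_tree_support <- function(m, n_boot = 100L, seed = 1L,
                                   samples = NULL) {
  if (is.null(samples)) samples <- m$samples
  full <- tree_from_snps(m, samples = samples, seed = seed)
  if (n_boot == 0L) return(full)
  anchor <- sort(samples)[1]
  keys_full <- .tree_splits(full, anchor)
  counts <- stats::setNames(numeric(length(keys_full)), keys_full)
  grp <- split(seq_len(n_sites(m)), m$sites$locus_id)
  L <- length(grp)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_redrawn <- 0L
  for (r in seq_len(n_boot)) {
    repeat {
      loci_idx <- sample.int(L, L, replace = TRUE)
      site_idx <- vapply(grp[loci_idx], function(s) {
        if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
      }, integer(1))
      mb <- snp_matrix(m$sites[site_idx, , drop = FALSE],
                       m$geno[site_idx, , drop = FALSE], m$samples)
      covered <- colSums(!is.na(mb$geno[, samples, drop = FALSE])) > 0L
      if (sum(covered) >= 4L) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) stop("bootstrap cannot cover 4 taxa")
    }
    tr <- tree_from_snps(mb, samples = samples[covered], seed = seed + r)
    kb <- .tree_splits(tr, anchor)
    hit <- keys_full %in% kb
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_boot)
  # map supports onto internal nodes of the full tree
  pp <- ape::prop.part(full)
  labs <- attr(pp, "labels")
  ntip <- length(labs)
  node_lab <- character(full$Nnode)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= ntip - 1L) {
      node_lab[i] <- "100"
    } else {
      key <- paste(sort(side), collapse = "|")
      node_lab[i] <- as.character(support[[key]])
    }
  }
  full$node.label <- node_lab
  attr(full, "n_redrawn") <- n_redrawn
  full
}
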