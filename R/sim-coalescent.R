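# Multispecies-coalescent simulator with pulse admixture.
#
# Per locus an independent genealogy is drawn under the structured
# coalescent on a species tree with branch lengths in generations:
# within a population of diploid size N, k haploid lineages coalesce at
# rate k(k-1)/(4N) per generation; at a speciation time the daughter
# populations' lineages merge into the parent; at an admixture pulse
# (donor, recipient, time, gamma), each lineage in the recipient moves
# (backwards in time) into the donor with probability gamma — the
# forward-time reading is that a fraction gamma of the recipient's genome
# traces to the donor. Mutations are Jukes-Cantor finite-sites at rate mu
# per site per generation (multiple hits tolerated; downstream SNP
# extraction keeps biallelic columns). Two haplotypes per diploid are
# collapsed to an IUPAC consensus, and whole loci drop out per sample at
# the missing-locus rate, emulating RAD/GBS missingness.

#' Specify a demography for the simulator
#'
#' @param tree newick string or `phylo`; tips are population names,
#'   branch lengths are in generations, and the tree must be ultrametric
#'   (all tips at the present).
#' @param Ne diploid effective size: a single value for all branches or a
#'   named vector over tip/internal-node labels (unnamed default via the
#'   `""` element or the single unnamed value).
#' @param samples_per_pop diploid samples per tip population: single
#'   value or named vector.
#' @param pulses `NULL` or a data frame with columns `donor`,
#'   `recipient`, `time` (generations) and `gamma` in \[0, 1\]; both
#'   populations must exist at the pulse time.
#' @return an object of class `demography`.
#' @export
demography <- function(tree, Ne, samples_per_pop, pulses = NULL) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("invalid newick tree")
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(ntip)]) - depth      # time before present
  if (any(abs(age[seq_len(ntip)]) > 1e-6 * max(age)))
    stop("species tree must be ultrametric (tips at time 0)")
  age[seq_len(ntip)] <- 0
  nnode <- phy$Nnode
  node_label <- c(phy$tip.label,
                  if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
                    phy$node.label
                  else paste0("anc", seq_len(nnode)))
  parent <- rep(NA_integer_, ntip + nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- which(is.na(parent))
  ne_of <- function(lab) {
    if (length(Ne) == 1L && is.null(names(Ne))) return(as.numeric(Ne))
    if (lab %in% names(Ne)) return(as.numeric(Ne[[lab]]))
    if ("" %in% names(Ne)) return(as.numeric(Ne[[""]]))
    stop("no Ne given for population '", lab, "'")
  }
  ne <- vapply(node_label, ne_of, numeric(1))
  if (any(ne <= 0)) stop("Ne must be positive")
  spp <- if (length(samples_per_pop) == 1L && is.null(names(samples_per_pop)))
    stats::setNames(rep(as.integer(samples_per_pop), ntip), phy$tip.label)
  else {
    miss <- setdiff(phy$tip.label, names(samples_per_pop))
    if (length(miss) > 0L)
      stop("no sample count for population(s): ", paste(miss, collapse = ", "))
    stats::setNames(as.integer(samples_per_pop[phy$tip.label]),
                    phy$tip.label)
  }
  if (!is.null(pulses)) {
    need <- c("donor", "recipient", "time", "gamma")
    if (!all(need %in% names(pulses)))
      stop("pulses needs columns donor, recipient, time, gamma")
    if (any(pulses$gamma < 0 | pulses$gamma > 1))
      stop("gamma must be in [0, 1]")
    for (i in seq_len(nrow(pulses))) {
      for (role in c("donor", "recipient")) {
        lab <- pulses[[role]][i]
        v <- match(lab, node_label)
        if (is.na(v)) stop("unknown population in pulse: ", lab)
        t_lo <- age[v]
        t_hi <- if (is.na(parent[v])) Inf else age[parent[v]]
        if (pulses$time[i] < t_lo || pulses$time[i] >= t_hi)
          stop("pulse at time ", pulses$time[i], ": population '", lab,
               "' does not exist then (alive ", t_lo, " to ", t_hi, ")")
      }
    }
  }
  structure(list(phy = phy, ntip = ntip, age = age, parent = parent,
                 root = root, node_label = node_label, ne = ne,
                 samples_per_pop = spp, pulses = pulses),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("demography: ", x$ntip, " populations, ",
      sum(x$samples_per_pop), " diploid samples\n", sep = "")
  cat("  root age ", max(x$age), " generations\n", sep = "")
  if (!is.null(x$pulses))
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("  pulse %s -> %s at %g gen, gamma = %g\n",
                  x$pulses$donor[i], x$pulses$recipient[i],
                  x$pulses$time[i], x$pulses$gamma[i]))
  invisible(x)
}

#' Simulator configuration
#'
#' @param n_loci number of independent loci (>= 1).
#' @param locus_length locus length in bp (default 75, the short-read
#'   regime these loci emulate).
#' @param mu mutation rate per site per generation (default 2e-8).
#' @param missing_locus_rate per-sample probability that a locus dropped
#'   out entirely (default 0.3).
#' @param seed integer seed; all downstream draws are reproducible.
#' @param store_genealogies keep per-locus gene trees (newick) in the
#'   truth record.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_loci, locus_length = 75L, mu = 2e-8,
                       missing_locus_rate = 0.3, seed = 1L,
                       store_genealogies = FALSE) {
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (missing_locus_rate < 0 || missing_locus_rate >= 1)
    stop("missing_locus_rate must be in [0, 1)")
  if (mu <= 0 || mu > 1) stop("mu must be in (0, 1]")
  structure(list(n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 mu = mu, missing_locus_rate = missing_locus_rate,
                 seed = as.integer(seed),
                 store_genealogies = isTRUE(store_genealogies)),
            class = "sim_config")
}

# one genealogy: returns parent/time arrays over gene-tree nodes;
# haploid tips 1..H in sample order
.sim_genealogy <- function(d) {
  H <- sum(2L * d$samples_per_pop)
  maxn <- 2L * H - 1L
  parent <- integer(maxn)
  ntime <- numeric(maxn)
  active <- seq_len(H)
  popv <- rep.int(match(rep(names(d$samples_per_pop),
                            2L * d$samples_per_pop), d$node_label), 1L)
  nxt <- H + 1L
  coalesce_until <- function(t0, t1) {
    t <- t0
    repeat {
      pops <- unique(popv)
      k <- vapply(pops, function(p) sum(popv == p), integer(1))
      rates <- k * (k - 1L) / (4 * d$ne[pops])
      R <- sum(rates)
      if (R == 0) return(t1)
      t_cand <- t + stats::rexp(1L, R)
      if (t_cand >= t1) return(t1)
      t <- t_cand
      p <- pops[sample.int(length(pops), 1L, prob = rates)]
      inpop <- which(popv == p)
      pair <- inpop[sample.int(length(inpop), 2L)]
      nid <- nxt
      nxt <<- nxt + 1L
      parent[active[pair]] <<- nid
      ntime[nid] <<- t
      active[pair[1]] <<- nid
      active <<- active[-pair[2]]
      popv <<- popv[-pair[2]]
      # pair[1] slot now carries the merged lineage, same pop
    }
  }
  events <- data.frame(time = numeric(), kind = character(),
                       id = integer(), stringsAsFactors = FALSE)
  internal <- which(!seq_along(d$age) %in% seq_len(d$ntip))
  ev <- data.frame(time = d$age[internal], kind = "speciation",
                   id = internal)
  if (!is.null(d$pulses) && nrow(d$pulses) > 0L) {
    ev <- rbind(ev, data.frame(time = d$pulses$time, kind = "pulse",
                               id = seq_len(nrow(d$pulses))))
  }
  ev <- ev[order(ev$time, ev$kind != "pulse"), , drop = FALSE]
  t_cur <- 0
  for (i in seq_len(nrow(ev))) {
    t_cur <- coalesce_until(t_cur, ev$time[i])
    if (ev$kind[i] == "speciation") {
      v <- ev$id[i]
      kids <- which(d$parent == v)
      popv[popv %in% kids] <- v
    } else {
      pu <- d$pulses[ev$id[i], ]
      don <- match(pu$donor, d$node_label)
      rec <- match(pu$recipient, d$node_label)
      movers <- which(popv == rec & stats::runif(length(popv)) < pu$gamma)
      if (length(movers) > 0L) popv[movers] <- don
    }
  }
  while (length(active) > 1L) {
    t_cur <- coalesce_until(t_cur, Inf)
    if (length(active) > 1L) stop("coalescent failed to finish")
  }
  list(parent = parent[seq_len(nxt - 1L)], time = ntime[seq_len(nxt - 1L)],
       root = nxt - 1L, H = H)
}

# Jukes-Cantor mutations on a genealogy -> integer base matrix for tips
.drop_mutations <- function(gen, L, mu) {
  n <- length(gen$parent)
  seqs <- matrix(0L, nrow = n, ncol = L)
  ord <- order(gen$time, decreasing = TRUE)   # parents before children
  seqs[gen$root, ] <- sample.int(4L, L, replace = TRUE)
  for (i in ord) {
    if (i == gen$root) next
    p <- gen$parent[i]
    s <- seqs[p, ]
    blen <- gen$time[p] - gen$time[i]
    nmut <- stats::rpois(1L, mu * L * blen)
    if (nmut > 0L) {
      pos <- sample.int(L, nmut, replace = TRUE)
      for (m in seq_len(nmut)) {
        s[pos[m]] <- sample.int(4L, 1L, prob = as.numeric(1:4 != s[pos[m]]))
      }
    }
    seqs[i, ] <- s
  }
  seqs[seq_len(gen$H), , drop = FALSE]
}

# genealogy arrays -> newick string (tip labels = haplotype names)
.genealogy_newick <- function(gen, tip_names) {
  lab <- character(length(gen$parent))
  lab[seq_len(gen$H)] <- tip_names
  kids <- split(seq_along(gen$parent)[-gen$root],
                gen$parent[-gen$root])
  build <- function(i) {
    if (i <= gen$H) return(paste0(lab[i], ":",
                                  gen$time[gen$parent[i]] - gen$time[i]))
    ch <- kids[[as.character(i)]]
    inner <- paste(vapply(ch, build, character(1)), collapse = ",")
    blen <- if (i == gen$root) 0 else gen$time[gen$parent[i]] - gen$time[i]
    paste0("(", inner, "):", blen)
  }
  paste0(build(gen$root), ";")
}

#' Simulate a RAD/GBS-like locus set under a demography
#'
#' @param d a [demography()].
#' @param c a [sim_config()].
#' @return list with `loci` (a [locus_set()] of diploid IUPAC consensus
#'   sequences; sample ids are `<population>_<i>`) and `truth` (the
#'   demography, the config, the sample-to-population map and, when
#'   requested, per-locus gene trees).
#' @export
simulate_loci <- function(d, c) {
  stopifnot(inherits(d, "demography"), inherits(c, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(c$seed)
  pops <- names(d$samples_per_pop)
  sample_ids <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(d$samples_per_pop[[p]]))))
  pop_of <- stats::setNames(rep(pops, d$samples_per_pop), sample_ids)
  hap_names <- paste0(rep(sample_ids, each = 2L), c(".1", ".2"))
  L <- c$locus_length
  loci <- vector("list", c$n_loci)
  trees <- if (c$store_genealogies) character(c$n_loci) else NULL
  for (l in seq_len(c$n_loci)) {
    gen <- .sim_genealogy(d)
    tipseq <- .drop_mutations(gen, L, c$mu)
    a1 <- tipseq[seq(1L, nrow(tipseq), by = 2L), , drop = FALSE]
    a2 <- tipseq[seq(2L, nrow(tipseq), by = 2L), , drop = FALSE]
    cons <- matrix(iupac_from_pair(.BASES[a1], .BASES[a2]),
                   nrow = nrow(a1))
    keep <- stats::runif(length(sample_ids)) >= c$missing_locus_rate
    if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
    seqs <- apply(cons[keep, , drop = FALSE], 1L, paste, collapse = "")
    names(seqs) <- sample_ids[keep]
    loci[[l]] <- rad_locus(l, seqs)
    if (c$store_genealogies) trees[l] <- .genealogy_newick(gen, hap_names)
  }
  samples <- data.frame(id = sample_ids, taxon = unname(pop_of),
                        clade = unname(pop_of), stringsAsFactors = FALSE)
  ls <- locus_set(loci, samples = samples,
                  provenance = paste0("simulate_loci(seed=", c$seed, ")"))
  list(loci = ls,
       truth = list(demography = d, config = c, pop_of = pop_of,
                    gene_trees = trees))
}

#' Add an F1 hybrid sample to a locus set
#'
#' At every locus covered by both parent pools, one parent with data is
#' drawn from each pool and one allele is taken from each (heterozygous
#' IUPAC codes resolved uniformly); the pair becomes the hybrid's diploid
#' consensus. At fixed differences between the pools the hybrid is
#' therefore always heterozygous.
#'
#' @param ls a [locus_set()].
#' @param parentA,parentB non-empty character vectors of sample ids (the
#'   two parent pools).
#' @param seed integer seed (same seed, same hybrid).
#' @param hybrid_id sample id for the new sample (default `"F1"`).
#' @return a [locus_set()] with the hybrid appended to covered loci.
#' @export
simulate_hybrid <- function(ls, parentA, parentB, seed = 1L,
                            hybrid_id = "F1") {
  if (length(parentA) == 0L || length(parentB) == 0L)
    stop("parent pools must be non-empty")
  if (hybrid_id %in% ls$samples$id) stop("hybrid id already in registry")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw_allele <- function(chars) {
    a1 <- .IUPAC_A1[chars]
    a2 <- .IUPAC_A2[chars]
    pick <- stats::runif(length(chars)) < 0.5
    ifelse(pick, a1, a2)
  }
  covered <- 0L
  loci <- lapply(ls$loci, function(l) {
    inA <- intersect(parentA, names(l$seqs))
    inB <- intersect(parentB, names(l$seqs))
    if (length(inA) == 0L || length(inB) == 0L) return(l)
    covered <<- covered + 1L
    pa <- inA[sample.int(length(inA), 1L)]
    pb <- inB[sample.int(length(inB), 1L)]
    ca <- strsplit(l$seqs[[pa]], "", fixed = TRUE)[[1]]
    cb <- strsplit(l$seqs[[pb]], "", fixed = TRUE)[[1]]
    hyb <- iupac_from_pair(draw_allele(ca), draw_allele(cb))
    seqs <- c(l$seqs, stats::setNames(paste(hyb, collapse = ""), hybrid_id))
    rad_locus(l$locus_id, seqs)
  })
  if (covered == 0L) stop("no locus covered by both parent pools")
  samples <- rbind(ls$samples,
                   stats::setNames(as.list(c(hybrid_id,
                                             rep(NA, ncol(ls$samples) - 1L))),
                                   names(ls$samples)))
  locus_set(loci, samples = samples,
            provenance = c(ls$provenance,
                           paste0("simulate_hybrid(", hybrid_id, ")")))
}

#' Fabricate replicate clustering runs around a known ancestry matrix
#'
#' Each replicate is the truth Q with columns randomly permuted, plus
#' truncated gaussian noise with row renormalization, and a lnL trace
#' drawn around the supplied per-replicate profile — a fixture generator
#' for the replicate-summarization stage with known label permutations.
#'
#' @param truth_Q sample x K matrix with rows summing to 1 (row names =
#'   sample ids).
#' @param n_reps number of replicates.
#' @param noise_sd standard deviation of the ancestry noise (>= 0).
#' @param lnL_mean mean of the log-likelihood trace.
#' @param lnL_sd within-trace standard deviation (default 1).
#' @param trace_length lnL trace length (default 50).
#' @param K_label K recorded on the replicates (default `ncol(truth_Q)`).
#' @param seed integer seed.
#' @return list of [structure_replicate()]s; the true column permutation
#'   of each (`perm[k]` = truth column placed at output column k) is
#'   attached as attribute `"permutations"`.
#' @export
simulate_structure_runs <- function(truth_Q, n_reps = 10L, noise_sd = 0.01,
                                    lnL_mean = -1000, lnL_sd = 1,
                                    trace_length = 50L,
                                    K_label = ncol(truth_Q), seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  truth_Q <- as.matrix(truth_Q)
  if (any(abs(rowSums(truth_Q) - 1) > 1e-6))
    stop("rows of truth_Q must sum to 1")
  K <- ncol(truth_Q)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- vector("list", n_reps)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(K)
    Q <- truth_Q[, perm, drop = FALSE]
    if (noise_sd > 0) {
      Q <- pmax(Q + matrix(stats::rnorm(length(Q), 0, noise_sd),
                           nrow = nrow(Q)), 0)
      Q <- Q / rowSums(Q)
    }
    colnames(Q) <- paste0("cluster", seq_len(K))
    trace <- stats::rnorm(trace_length, lnL_mean, lnL_sd)
    perms[[r]] <- perm
    reps[[r]] <- structure_replicate(K_label, r, Q, trace)
  }
  attr(reps, "permutations") <- perms
  reps
}

#' Fabricate a posterior sample around a known truth
#'
#' Positive-truncated normal (default) or log-normal draws around the
#' true value — a fixture generator for the unit-conversion stage.
#'
#' @param truth true tau or theta value (> 0, or 0 with `sd = 0`).
#' @param sd spread of the draws (>= 0; 0 gives constant draws).
#' @param n number of draws.
#' @param seed integer seed.
#' @param label,type passed to [posterior_sample()].
#' @param dist `"truncnorm"` or `"lognormal"` (log-sd = `sd/truth`).
#' @return a [posterior_sample()].
#' @export
simulate_posterior <- function(truth, sd, n = 1000L, seed = 1L,
                               label = "sim", type = "tau",
                               dist = c("truncnorm", "lognormal")) {
  dist <- match.arg(dist)
  if (sd < 0) stop("sd must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- if (sd == 0) rep(truth, n)
  else if (dist == "truncnorm") {
    x <- stats::rnorm(n, truth, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), truth, sd)
    x
  } else {
    stats::rlnorm(n, log(truth), sd / truth)
  }
  posterior_sample(label, type, draws)
}

#' Four-population demography for D-statistic experiments
#'
#' The default study conditions for the introgression experiments: an
#' asymmetric four-population tree (((P1,P2),P3),O) with equal diploid
#' size on every branch, split times of 1, 2 and 4 coalescent units (of
#' 2 Ne generations), and an optional P3 -> P2 admixture pulse midway
#' along the P2 branch.
#'
#' @param gamma admixture proportion of the pulse (0 disables it).
#' @param Ne diploid size on every branch (default 5e4).
#' @param n_per_pop diploid samples in each of P1, P2, P3 (default 4).
#' @param n_outgroup diploid samples in O (default 2).
#' @param donor,recipient pulse populations (defaults P3 -> P2).
#' @return a [demography()].
#' @export
demography_dstat <- function(gamma = 0, Ne = 5e4, n_per_pop = 4L,
                             n_outgroup = 2L, donor = "P3",
                             recipient = "P2") {
  t12 <- 2 * Ne          # 1 coalescent unit
  t123 <- 4 * Ne
  t_root <- 8 * Ne
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  nwk <- sprintf("(((P1:%s,P2:%s):%s,P3:%s):%s,O:%s);",
                 fmt(t12), fmt(t12), fmt(t123 - t12), fmt(t123),
                 fmt(t_root - t123), fmt(t_root))
  pulses <- if (gamma > 0)
    data.frame(donor = donor, recipient = recipient, time = t12 / 2,
               gamma = gamma)
  else NULL
  demography(nwk, Ne = Ne,
             samples_per_pop = c(P1 = n_per_pop, P2 = n_per_pop,
                                 P3 = n_per_pop, O = n_outgroup),
             pulses = pulses)
}

#' Balanced four-population demography for quartet experiments
#'
#' Symmetric tree ((A,B),(C,D)) with cherries diverging 1 coalescent unit
#' back and an internal branch of `internal_units` coalescent units
#' (default 4 — long enough that incomplete lineage sorting is rare), one
#' diploid per population.
#'
#' @param internal_units internal branch length in units of 2 Ne
#'   generations.
#' @param Ne diploid size on every branch (default 5e4).
#' @param n_per_pop diploids per population (default 1).
#' @return a [demography()].
#' @export
demography_quartet <- function(internal_units = 4, Ne = 5e4,
                               n_per_pop = 1L) {
  t1 <- 2 * Ne
  t2 <- t1 + internal_units * 2 * Ne
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  nwk <- sprintf("((A:%s,B:%s):%s,(C:%s,D:%s):%s);",
                 fmt(t1), fmt(t1), fmt(t2 - t1),
                 fmt(t1), fmt(t1), fmt(t2 - t1))
  demography(nwk, Ne = Ne,
             samples_per_pop = c(A = n_per_pop, B = n_per_pop,
                                 C = n_per_pop, D = n_per_pop))
}
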