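# End-to-end orchestration: simulate -> filter -> snps -> dstat /
# quartets / evanno / convert, driven by a single flat config, with a
# manifest recording seeds, a config hash, and per-stage record counts.

.filter_tiers <- list(min4 = 4L, min10 = 10L, min20 = 20L, min30 = 30L)

#' Run the analysis pipeline from a config
#'
#' The config is a YAML file (or an equivalent nested list) with a
#' `stages` vector naming what to run, in dependency order:
#' `simulate`, `filter`, `snps`, `dstat`, `quartets`, `evanno`,
#' `convert`. Stage blocks:
#' \describe{
#'   \item{simulate}{`preset` (`"dstat"` or `"quartet"`), `gamma`,
#'     `n_loci`, `missing_locus_rate`, `hybrid` (logical: add an F1
#'     between P1 and P3).}
#'   \item{input}{alternative to simulate: `loci` path and `dialect`.}
#'   \item{filter}{`tier` (min4/min10/min20/min30) or explicit
#'     thresholds (`max_snps`, `max_shared_hets`, `min_coverage`,
#'     `trim`).}
#'   \item{dstat}{`tests`: list of blocks with `p1..p4` (sample ids or
#'     population prefixes), `n_boot`, `z_threshold`.}
#'   \item{quartets}{`n_boot` for tree support (0 = no bootstrap).}
#'   \item{evanno}{`runs`: manifest CSV (columns `path`, optionally
#'     `dialect`).}
#'   \item{convert}{`trace`: MCMC trace table path; `generation_time`,
#'     `mutation_rate`: 95% CIs.}
#' }
#' Every written file is listed in `manifest.json` together with the
#' config hash, the seed, and per-stage record counts.
#'
#' @param config path to a YAML config or a named list.
#' @param out_dir output directory (default from the config's `out_dir`,
#'   required either way).
#' @param seed overrides the config's `seed` when given.
#' @return the output directory path, invisibly; the parsed manifest is
#'   attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L
  seed <- as.integer(seed)
  stages <- config$stages
  known <- c("simulate", "input", "filter", "snps", "dstat", "quartets",
             "evanno", "convert")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # validate stage dependencies before running anything
  needs_loci <- intersect(c("filter", "snps"), stages)
  if (length(needs_loci) > 0L &&
      !any(c("simulate", "input") %in% stages))
    stop("stages ", paste(needs_loci, collapse = "/"),
         " need a 'simulate' or 'input' stage")
  if (any(c("dstat", "quartets") %in% stages) && !"snps" %in% stages)
    stop("dstat/quartets need the 'snps' stage")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = stages, files = list(),
                   counts = list())
  if (!is.null(cfg_path)) {
    manifest$config_path <- cfg_path
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  } else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    manifest$config_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  emit <- function(name, path) manifest$files[[name]] <<- path
  count <- function(name, n) manifest$counts[[name]] <<- n
  ls <- NULL
  m <- NULL
  for (stage in stages) {
    if (stage == "simulate") {
      sc <- config$simulate
      preset <- if (is.null(sc$preset)) "dstat" else sc$preset
      gamma <- if (is.null(sc$gamma)) 0 else sc$gamma
      d <- switch(preset,
                  dstat = demography_dstat(gamma = gamma),
                  quartet = demography_quartet(),
                  stop("unknown simulate preset: ", preset))
      cc <- sim_config(
        n_loci = if (is.null(sc$n_loci)) 500L else sc$n_loci,
        missing_locus_rate = if (is.null(sc$missing_locus_rate)) 0.3
        else sc$missing_locus_rate,
        seed = seed)
      sim <- simulate_loci(d, cc)
      ls <- sim$loci
      if (isTRUE(sc$hybrid)) {
        pa <- grep("^P1_", ls$samples$id, value = TRUE)
        pb <- grep("^P3_", ls$samples$id, value = TRUE)
        ls <- simulate_hybrid(ls, pa, pb, seed = seed)
      }
      p <- file.path(out_dir, "simulated.loci")
      write_loci(ls, p)
      emit("simulated_loci", p)
      count("simulated_loci", n_loci(ls))
    } else if (stage == "input") {
      ic <- config$input
      dialect <- if (is.null(ic$dialect)) "loci" else ic$dialect
      ls <- read_loci(ic$loci, dialect = dialect)
      count("input_loci", n_loci(ls))
    } else if (stage == "filter") {
      fc <- config$filter
      cfg <- if (!is.null(fc$tier)) {
        tier <- .filter_tiers[[fc$tier]]
        if (is.null(tier)) stop("unknown filter tier: ", fc$tier)
        filter_config(min_sample_coverage = tier)
      } else {
        filter_config(
          min_sample_coverage = if (is.null(fc$min_coverage)) 4L
          else fc$min_coverage,
          max_snps_per_locus = if (is.null(fc$max_snps)) 10L
          else fc$max_snps,
          max_shared_het_samples = if (is.null(fc$max_shared_hets)) 4L
          else fc$max_shared_hets,
          edge_trim_bases = if (is.null(fc$trim)) 5L else fc$trim)
      }
      ls <- apply_filters(ls, cfg)
      p <- file.path(out_dir, "filtered.loci")
      write_loci(ls, p)
      emit("filtered_loci", p)
      count("filtered_loci", n_loci(ls))
      pc <- file.path(out_dir, "filter_counts.csv")
      utils::write.csv(data.frame(step = ls$provenance), pc,
                       row.names = FALSE)
      emit("filter_counts", pc)
    } else if (stage == "snps") {
      m <- extract_snps(ls)
      p <- file.path(out_dir, "snps.vcf")
      write_vcf(m, p, source = paste0("radmixr pipeline seed=", seed,
                                      "; ", paste(ls$provenance,
                                                  collapse = "; ")))
      emit("snps_vcf", p)
      count("snp_sites", n_sites(m))
    } else if (stage == "dstat") {
      dc <- config$dstat
      expand_pool <- function(x) {
        hits <- unlist(lapply(x, function(p) {
          exact <- m$samples[m$samples == p]
          if (length(exact) > 0L) return(exact)
          grep(paste0("^", p, "_"), m$samples, value = TRUE)
        }))
        unique(hits)
      }
      tests <- lapply(seq_along(dc$tests), function(i) {
        t <- dc$tests[[i]]
        dstat_test(expand_pool(t$p1), expand_pool(t$p2),
                   expand_pool(t$p3), expand_pool(t$p4),
                   label = if (is.null(t$label)) "" else t$label,
                   test_index = i - 1L)
      })
      n_boot <- if (is.null(dc$n_boot)) 1000L else dc$n_boot
      zt <- if (is.null(dc$z_threshold)) 3.5 else dc$z_threshold
      tab <- run_test_battery(m, tests, n_boot = n_boot, seed = seed,
                              z_threshold = zt)
      p <- file.path(out_dir, "dstat.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      emit("dstat", p)
      count("dstat_tests", nrow(tab))
    } else if (stage == "quartets") {
      qc <- config$quartets
      n_boot <- if (is.null(qc$n_boot)) 0L else qc$n_boot
      tr <- bootstrap_tree_support(m, n_boot = n_boot, seed = seed)
      p <- file.path(out_dir, "supertree.nwk")
      ape::write.tree(tr, p)
      emit("supertree", p)
      count("tree_tips", length(tr$tip.label))
    } else if (stage == "evanno") {
      ec <- config$evanno
      runs <- utils::read.csv(ec$runs, stringsAsFactors = FALSE)
      dialect <- if (is.null(runs$dialect)) "csv" else runs$dialect[1]
      reps <- read_structure_runs(runs$path, dialect = dialect)
      kept <- convergence_filter(reps)$kept
      ev <- evanno(kept)
      p <- file.path(out_dir, "evanno.csv")
      utils::write.csv(ev$table, p, row.names = FALSE)
      emit("evanno", p)
      count("evanno_best_K", ev$best_K)
    } else if (stage == "convert") {
      vc <- config$convert
      priors <- rate_priors(
        generation_time = if (is.null(vc$generation_time)) c(8, 16)
        else unlist(vc$generation_time),
        mutation_rate = if (is.null(vc$mutation_rate)) c(5e-8, 5e-7)
        else unlist(vc$mutation_rate))
      samples <- read_mcmc_trace(vc$trace)
      tab <- convert_posterior_table(samples, priors, seed = seed)
      p <- file.path(out_dir, "converted.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      emit("converted", p)
      count("converted_params", nrow(tab))
    }
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  out <- out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}
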