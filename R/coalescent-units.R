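# Conversion of multispecies-coalescent parameters to natural units.
#
# tau (divergence, expected substitutions/site) and theta (= 4 Ne mu,
# substitutions/site) are dimensionless in sequence units; converting to
# years and individuals requires a per-generation per-site mutation rate
# mu and a generation time g:
#   time = (tau / mu) generations * g years/generation
#   Ne   = theta / (4 mu) diploid individuals.
# Uncertainty in mu and g is propagated by Monte Carlo with gamma priors
# parameterized by their central 95% interval.

#' Gamma parameters matching a central 95% interval
#'
#' Finds the `(shape, rate)` of the gamma distribution whose 2.5% and
#' 97.5% quantiles equal `lo` and `hi`. The quantile ratio
#' `q(0.975)/q(0.025)` is strictly decreasing in the shape, so the shape
#' is found by monotone root finding on the log scale and the rate then
#' follows from either quantile.
#'
#' @param lo,hi interval bounds, `0 < lo < hi`.
#' @param level interval mass (default 0.95, equal-tailed).
#' @return named numeric vector `c(shape, rate)`; the reproduced
#'   quantiles match `lo`/`hi` to within 1e-6 relative error.
#' @export
gamma_from_ci <- function(lo, hi, level = 0.95) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  p_lo <- (1 - level) / 2
  p_hi <- 1 - p_lo
  target <- hi / lo
  ratio <- function(log_shape) {
    s <- exp(log_shape)
    stats::qgamma(p_hi, shape = s, rate = 1) /
      stats::qgamma(p_lo, shape = s, rate = 1) - target
  }
  sol <- tryCatch(
    stats::uniroot(ratio, lower = log(1e-3), upper = log(1e12),
                   extendInt = "downX", tol = 1e-14),
    error = function(e) stop("gamma_from_ci: root find failed for (",
                             lo, ", ", hi, "): ", conditionMessage(e)))
  shape <- exp(sol$root)
  rate <- stats::qgamma(p_lo, shape = shape, rate = 1) / lo
  got_lo <- stats::qgamma(p_lo, shape, rate)
  got_hi <- stats::qgamma(p_hi, shape, rate)
  if (abs(got_lo - lo) / lo > 1e-6 || abs(got_hi - hi) / hi > 1e-6)
    stop("gamma_from_ci: solution check failed for (", lo, ", ", hi, ")")
  c(shape = shape, rate = rate)
}

#' Priors on generation time and mutation rate
#'
#' Each prior is either a gamma distribution given by its central 95%
#' interval or a point mass given by a single value (used for closed-form
#' checks).
#'
#' @param generation_time interval `c(lo, hi)` in years (default
#'   `c(8, 16)`) or a single fixed value.
#' @param mutation_rate interval `c(lo, hi)` per site per generation
#'   (default `c(5e-8, 5e-7)`) or a single fixed value.
#' @return an object of class `rate_priors`.
#' @export
rate_priors <- function(generation_time = c(8, 16),
                        mutation_rate = c(5e-8, 5e-7)) {
  mk <- function(x, what) {
    if (length(x) == 1L) {
      if (x <= 0) stop(what, " must be positive")
      list(fixed = x)
    } else if (length(x) == 2L) {
      g <- gamma_from_ci(x[1], x[2])
      list(shape = g[["shape"]], rate = g[["rate"]], ci = x)
    } else stop(what, " must be length 1 (fixed) or 2 (95% CI)")
  }
  structure(list(generation_time = mk(generation_time, "generation_time"),
                 mutation_rate = mk(mutation_rate, "mutation_rate")),
            class = "rate_priors")
}

.draw_prior <- function(prior, n) {
  if (!is.null(prior$fixed)) rep(prior$fixed, n)
  else stats::rgamma(n, shape = prior$shape, rate = prior$rate)
}

#' A posterior sample of tau or theta
#'
#' @param label node or population label.
#' @param type `"tau"` (divergence, substitutions/site) or `"theta"`
#'   (4 Ne mu, substitutions/site).
#' @param draws numeric vector of posterior draws (`theta` strictly
#'   positive, `tau` non-negative).
#' @return an object of class `posterior_sample`.
#' @export
posterior_sample <- function(label, type = c("tau", "theta"), draws) {
  type <- match.arg(type)
  if (length(draws) == 0L) stop("draws must be non-empty")
  if (type == "theta" && any(draws <= 0)) stop("theta draws must be > 0")
  if (type == "tau" && any(draws < 0)) stop("tau draws must be >= 0")
  structure(list(label = label, type = type, draws = as.numeric(draws)),
            class = "posterior_sample")
}

#' Convert a tau or theta posterior to natural units
#'
#' Per Monte-Carlo iteration one posterior draw, one mutation rate and
#' (for tau) one generation time are drawn independently;
#' `time = (tau/mu) * g` or `Ne = theta/(4 mu)` is computed, and the mean
#' and equal-tailed 95% interval of the resulting sample are reported in
#' millions of years (tau) or thousands of individuals (theta).
#'
#' @param s a [posterior_sample()].
#' @param priors a [rate_priors()].
#' @param n_mc Monte-Carlo iterations (default 10000).
#' @param seed integer seed.
#' @return an object of class `converted_estimate`: `label`, `type`,
#'   `unit`, `mean`, `ci` (2.5/97.5 percentiles), `n_mc`.
#' @export
convert_posterior <- function(s, priors, n_mc = 10000L, seed = 1L) {
  stopifnot(inherits(s, "posterior_sample"), inherits(priors, "rate_priors"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- if (length(s$draws) == 1L) rep(s$draws, n_mc)
  else sample(s$draws, n_mc, replace = TRUE)
  mu <- .draw_prior(priors$mutation_rate, n_mc)
  if (s$type == "tau") {
    g <- .draw_prior(priors$generation_time, n_mc)
    vals <- (x / mu) * g / 1e6        # Myr
    unit <- "Myr"
  } else {
    vals <- x / (4 * mu) / 1e3        # thousands of individuals
    unit <- "thousands"
  }
  structure(list(label = s$label, type = s$type, unit = unit,
                 mean = mean(vals),
                 ci = stats::quantile(vals, c(0.025, 0.975), names = FALSE),
                 n_mc = n_mc),
            class = "converted_estimate")
}

#' @export
print.converted_estimate <- function(x, ...) {
  cat(sprintf("%s %s: %.2f %s (95%% CI %.2f-%.2f)\n", x$type, x$label,
              x$mean, x$unit, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Convert a table of posterior samples
#'
#' @param samples list of [posterior_sample()] objects.
#' @param priors a [rate_priors()].
#' @param n_mc,seed passed to [convert_posterior()]; sample `i` uses
#'   `seed + i - 1`.
#' @return data frame shaped like a parameter table: `type`, `parameter`,
#'   `mean`, `ci_low`, `ci_high` (Myr for tau rows, thousands of
#'   individuals for theta rows).
#' @export
convert_posterior_table <- function(samples, priors, n_mc = 10000L,
                                    seed = 1L) {
  rows <- lapply(seq_along(samples), function(i) {
    ce <- convert_posterior(samples[[i]], priors, n_mc = n_mc,
                            seed = seed + i - 1L)
    data.frame(type = if (ce$type == "tau") "Tau" else "Ne",
               parameter = ce$label, mean = ce$mean,
               ci_low = ce$ci[1], ci_high = ce$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a coalescent-sampler trace table
#'
#' Expects the common MCMC trace format: one column per parameter, one
#' row per draw, TSV or CSV. Columns whose names start with `tau` or
#' `theta` become posterior samples of the corresponding type.
#'
#' @param path trace file path.
#' @param sep field separator (default tab).
#' @return list of [posterior_sample()] objects.
#' @export
read_mcmc_trace <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  out <- list()
  for (nm in names(df)) {
    low <- tolower(nm)
    type <- if (startsWith(low, "tau")) "tau"
    else if (startsWith(low, "theta")) "theta"
    else next
    label <- sub("^(tau|theta)[._ ]*", "", low)
    if (!nzchar(label)) label <- nm
    out[[nm]] <- posterior_sample(label, type, df[[nm]])
  }
  if (length(out) == 0L) stop("no tau/theta columns found in ", path)
  out
}
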