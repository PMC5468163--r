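#' Genomic cline function
#'
#' Maps an individual's hybrid index `h` (fraction of the genome inherited
#' from the eastern parental population) to the locus-specific probability
#' `Phi` that a gene copy derives from the eastern parent:
#' `Phi = h + 2 h (1 - h) (alpha + beta (2 h - 1))`, truncated to [0, 1].
#' `alpha` shifts the cline center (positive = excess eastern ancestry),
#' `beta` its rate. With `alpha = beta = 0`, `Phi = h`: the neutral
#' genomewide expectation.
#'
#' @param h hybrid index in [0, 1].
#' @param alpha cline center parameter.
#' @param beta cline rate parameter.
#' @return `Phi` in [0, 1]; vectorised over all arguments.
#' @export
cline_function <- function(h, alpha, beta) {
  phi <- h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1))
  pmin(1, pmax(0, phi))
}

#' Fit Bayesian genomic clines to an admixed population
#'
#' Joint MCMC estimation (Metropolis-within-Gibbs) of per-individual hybrid
#' indices `h`, per-locus cline parameters `alpha` and `beta`, and parental
#' allele frequencies, from diploid genotypes. The admixed genotype
#' likelihood is `Binomial(2, Phi p_e + (1 - Phi) p_w)` with `Phi` from
#' [cline_function()]; parental genotypes enter as per-locus binomial allele
#' counts, anchoring the orientation (population 1 = east, so `h` is the
#' eastern fraction and positive `alpha` means excess eastern ancestry).
#' Missing genotypes contribute no likelihood.
#'
#' Priors: `h ~ U(0,1)`, `p ~ Beta(1,1)`; the locus effects are hierarchical,
#' `alpha_i ~ N(0, sd_alpha^2)` and `beta_i ~ N(0, sd_beta^2)` with the two
#' scales themselves estimated (conjugate inverse-gamma hyperpriors, Gibbs
#' updates). Estimating the scales is not optional sophistication: with a
#' fixed wide prior on `alpha` the marginal posterior of the genomewide
#' hybrid-index level drifts off-center, because at off-center `h` the
#' per-locus `alpha` values are less data-constrained and the extra
#' posterior volume outweighs the prior cost. Random-walk proposals are
#' reflected at bounds and adapt toward 20-50% acceptance during burn-in
#' only; a joint proposal along the (h level, mean alpha) ridge keeps the
#' weakly identified direction mixing.
#'
#' @param admixed [genotype_matrix()] of the admixed samples.
#' @param parentals [genotype_matrix()] of the parental samples (disjoint
#'   from `admixed`); locus sets must be shared.
#' @param pm [population_map()] covering the parental samples.
#' @param n_iter,burnin,thin MCMC controls (defaults 25000 / 2500 / 5).
#' @param sd_alpha,sd_beta initial (and, with `hierarchical = FALSE`, fixed)
#'   prior standard deviations for alpha and beta.
#' @param hierarchical estimate the locus-effect prior scales (default TRUE).
#' @param ess_floor warn when any reported parameter's effective sample size
#'   falls below this (default 50).
#' @param seed integer seed; fixed seed gives identical posterior summaries.
#' @param keep_chains keep the thinned posterior draws in the returned object.
#' @return an object of class `cline_fit` with components `h` (data.frame:
#'   individual, mean, lower, upper), `loci` (data.frame: locus_id, medians
#'   and 95% equal-tail intervals for alpha and beta, `gamma_quantile`),
#'   `diagnostics` (acceptance rates, minimum ESS per block), and the call
#'   settings. `Phi` is not stored: it is derivable via [predict.cline_fit()].
#' @export
fit_genomic_clines <- function(admixed, parentals, pm,
                               n_iter = 25000L, burnin = 2500L, thin = 5L,
                               sd_alpha = 1, sd_beta = 0.5,
                               hierarchical = TRUE,
                               ess_floor = 50, seed = 1L,
                               keep_chains = FALSE) {
  shared <- intersect(locus_ids(admixed), locus_ids(parentals))
  if (length(shared) == 0) stopf("admixed and parental genotype matrices share no loci")
  if (length(intersect(sample_ids(admixed), sample_ids(parentals))) > 0) {
    stopf("admixed and parental sample sets must be disjoint")
  }
  adm <- subset_loci(admixed, shared)
  par <- subset_loci(parentals, shared)
  check_popmap(par, pm)
  gw <- par$genotypes[sample_ids(par) %in% pop_samples(pm, "west"), , drop = FALSE]
  ge <- par$genotypes[sample_ids(par) %in% pop_samples(pm, "east"), , drop = FALSE]
  cw <- colSums(gw, na.rm = TRUE); nw <- 2L * colSums(!is.na(gw))
  ce <- colSums(ge, na.rm = TRUE); ne <- 2L * colSums(!is.na(ge))
  G <- adm$genotypes
  G[is.na(G)] <- -1L
  res <- with_seed(seed, .cline_mcmc_cpp(G, as.integer(cw), as.integer(nw),
                                         as.integer(ce), as.integer(ne),
                                         as.integer(n_iter), as.integer(burnin),
                                         as.integer(thin),
                                         sd_alpha, sd_beta, 50L, hierarchical))
  qs <- function(m, probs) t(apply(m, 2, stats::quantile, probs = probs, names = FALSE))
  hq <- qs(res$h, c(0.025, 0.975))
  aq <- qs(res$alpha, c(0.025, 0.5, 0.975))
  bq <- qs(res$beta, c(0.025, 0.5, 0.975))
  alpha_med <- aq[, 2]
  gq <- gamma_quantiles(alpha_med)
  h_tab <- data.frame(individual = sample_ids(adm),
                      mean = colMeans(res$h),
                      lower = hq[, 1], upper = hq[, 2],
                      stringsAsFactors = FALSE)
  loci_tab <- data.frame(locus_id = shared,
                         alpha_median = alpha_med,
                         alpha_lower = aq[, 1], alpha_upper = aq[, 3],
                         beta_median = bq[, 2],
                         beta_lower = bq[, 1], beta_upper = bq[, 3],
                         gamma_quantile = gq,
                         stringsAsFactors = FALSE)
  min_ess <- c(h = min(apply(res$h, 2, ess)),
               alpha = min(apply(res$alpha, 2, ess)),
               beta = min(apply(res$beta, 2, ess)))
  # beta is typically shrunk to ~0 by its hierarchical scale, where its
  # slow-moving chain is harmless; only h and alpha gate the warning
  if (any(min_ess[c("h", "alpha")] < ess_floor)) {
    warnf("minimum effective sample size below %g (h: %.0f, alpha: %.0f); consider longer chains",
          ess_floor, min_ess["h"], min_ess["alpha"])
  }
  out <- list(h = h_tab, loci = loci_tab,
              diagnostics = list(accept = res$accept, min_ess = min_ess,
                                 n_draws = nrow(res$h)),
              settings = list(n_iter = n_iter, burnin = burnin, thin = thin,
                              sd_alpha = sd_alpha, sd_beta = sd_beta,
                              seed = seed))
  if (keep_chains) out$chains <- res[c("h", "alpha", "beta")]
  class(out) <- "cline_fit"
  out
}

# CDF position of each locus's median alpha under a normal fitted to the
# genomewide median-alpha distribution (parametric locus-effect quantiles).
gamma_quantiles <- function(alpha_med, empirical = FALSE) {
  if (empirical) {
    n <- length(alpha_med)
    return(rank(alpha_med, ties.method = "average") / (n + 1))
  }
  s <- stats::sd(alpha_med)
  if (is.na(s) || s == 0) return(rep(0.5, length(alpha_med)))
  stats::pnorm(alpha_med, mean(alpha_med), s)
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline_fit: %d admixed individuals, %d loci, %d posterior draws\n",
              nrow(x$h), nrow(x$loci), x$diagnostics$n_draws))
  cat(sprintf("  mean hybrid index %.3f (range %.3f-%.3f)\n",
              mean(x$h$mean), min(x$h$mean), max(x$h$mean)))
  cat(sprintf("  median alpha range [%.3f, %.3f]; median beta range [%.3f, %.3f]\n",
              min(x$loci$alpha_median), max(x$loci$alpha_median),
              min(x$loci$beta_median), max(x$loci$beta_median)))
  invisible(x)
}

#' @export
summary.cline_fit <- function(object, ...) {
  calls <- classify_excess_ancestry(object)
  out <- list(n_individuals = nrow(object$h), n_loci = nrow(object$loci),
              h_mean = mean(object$h$mean),
              alpha_range = range(object$loci$alpha_median),
              beta_range = range(object$loci$beta_median),
              n_excess_east = sum(calls$excess == "east"),
              n_excess_west = sum(calls$excess == "west"),
              accept = object$diagnostics$accept,
              min_ess = object$diagnostics$min_ess)
  class(out) <- "summary.cline_fit"
  out
}

#' @export
print.summary.cline_fit <- function(x, ...) {
  cat(sprintf("Genomic cline fit: %d individuals x %d loci\n", x$n_individuals, x$n_loci))
  cat(sprintf("  mean hybrid index: %.3f\n", x$h_mean))
  cat(sprintf("  median alpha in [%.3f, %.3f]; median beta in [%.3f, %.3f]\n",
              x$alpha_range[1], x$alpha_range[2], x$beta_range[1], x$beta_range[2]))
  cat(sprintf("  excess-ancestry outliers: %d east, %d west\n",
              x$n_excess_east, x$n_excess_west))
  cat(sprintf("  acceptance rates: h %.2f, alpha %.2f, beta %.2f, p %.2f\n",
              x$accept["h"], x$accept["alpha"], x$accept["beta"], x$accept["p"]))
  cat(sprintf("  min ESS: h %.0f, alpha %.0f, beta %.0f\n",
              x$min_ess["h"], x$min_ess["alpha"], x$min_ess["beta"]))
  invisible(x)
}

#' @export
coef.cline_fit <- function(object, ...) {
  m <- cbind(alpha = object$loci$alpha_median, beta = object$loci$beta_median)
  rownames(m) <- object$loci$locus_id
  m
}

#' Predicted ancestry probabilities from a cline fit
#'
#' Evaluates [cline_function()] at the posterior summaries: `Phi[j, i]` is
#' the probability that a gene copy of individual `j` at locus `i` derives
#' from the eastern parental population.
#'
#' @param object a `cline_fit`.
#' @param h hybrid indices at which to evaluate; defaults to the posterior
#'   mean hybrid index of each fitted individual.
#' @param ... unused.
#' @return matrix of `Phi`, `length(h)` rows by number of loci.
#' @export
predict.cline_fit <- function(object, h = NULL, ...) {
  if (is.null(h)) h <- object$h$mean
  phi <- outer(h, seq_len(nrow(object$loci)), function(hh, i) {
    cline_function(hh, object$loci$alpha_median[i], object$loci$beta_median[i])
  })
  rownames(phi) <- if (is.null(names(h)) && length(h) == nrow(object$h))
    object$h$individual else names(h)
  colnames(phi) <- object$loci$locus_id
  phi
}

#' Plot fitted genomic clines
#'
#' Draws `Phi(h)` for every locus over `h` in [0, 1] (grey), highlighting
#' excess-ancestry outlier loci (east in blue, west in red) against the
#' neutral diagonal `Phi = h`.
#'
#' @param x a `cline_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cline_fit <- function(x, ...) {
  hgrid <- seq(0, 1, length.out = 101)
  phi <- sapply(seq_len(nrow(x$loci)), function(i) {
    cline_function(hgrid, x$loci$alpha_median[i], x$loci$beta_median[i])
  })
  calls <- classify_excess_ancestry(x)
  col <- ifelse(calls$excess == "east", "#2166AC",
                ifelse(calls$excess == "west", "#B2182B", "grey70"))
  graphics::matplot(hgrid, phi, type = "l", lty = 1, col = col,
                    xlab = "hybrid index (h)",
                    ylab = expression(Phi ~ "(eastern ancestry probability)"), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Classify excess-ancestry outlier loci
#'
#' A locus shows excess eastern ancestry when its 95% equal-tail interval for
#' `alpha` excludes 0, its median `alpha` is positive, and that median lies
#' above the 97.5th percentile of the genomewide median-alpha distribution
#' (the central-95% reading of "tails of the 95th quantile"); western excess
#' is symmetric below the 2.5th percentile.
#'
#' @param fit a `cline_fit`.
#' @param quantile width of the central region of the median-alpha
#'   distribution used for the tail rule (default 0.95).
#' @return data.frame: `locus_id`, `excess` in `{east, west, none}`,
#'   `is_gamma_outlier` (from [gamma_outliers()] at its default `n = 0.1`).
#' @export
classify_excess_ancestry <- function(fit, quantile = 0.95) {
  stopifnot(inherits(fit, "cline_fit"))
  am <- fit$loci$alpha_median
  lo_q <- stats::quantile(am, (1 - quantile) / 2, names = FALSE)
  hi_q <- stats::quantile(am, 1 - (1 - quantile) / 2, names = FALSE)
  excl0 <- fit$loci$alpha_lower > 0 | fit$loci$alpha_upper < 0
  excess <- rep("none", length(am))
  excess[excl0 & am > 0 & am > hi_q] <- "east"
  excess[excl0 & am < 0 & am < lo_q] <- "west"
  data.frame(locus_id = fit$loci$locus_id,
             excess = excess,
             is_gamma_outlier = gamma_outliers(fit),
             stringsAsFactors = FALSE)
}

#' Strong introgression outliers by locus-effect gamma-quantiles
#'
#' Flags loci whose gamma-quantile (CDF position of the median `alpha` under
#' a normal fitted to the genomewide median-alpha distribution) falls outside
#' the central `1 - n` region: `q < n/2` or `q > 1 - n/2`, default `n = 0.1`
#' (outside the central 90%).
#'
#' @param fit a `cline_fit` (needs >= 10 loci).
#' @param n tail mass, default 0.1.
#' @return logical vector, one flag per locus; no flags when the median-alpha
#'   distribution has zero variance.
#' @export
gamma_outliers <- function(fit, n = 0.1) {
  stopifnot(inherits(fit, "cline_fit"))
  if (nrow(fit$loci) < 10L) stopf("gamma-quantile outliers need at least 10 loci")
  if (stats::sd(fit$loci$alpha_median) == 0) {
    return(rep(FALSE, nrow(fit$loci)))
  }
  q <- fit$loci$gamma_quantile
  q < n / 2 | q > 1 - n / 2
}
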