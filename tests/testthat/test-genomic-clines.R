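test_that("cline_function has its fixed points, boundary behaviour and truncation", {
  h <- seq(0, 1, 0.05)
  # alpha = beta = 0: Phi = h (the neutral expectation)
  expect_equal(cline_function(h, 0, 0), h)
  # boundaries absorb any alpha, beta
  expect_equal(cline_function(0, 3, -2), 0)
  expect_equal(cline_function(1, -3, 2), 1)
  # direct evaluation
  expect_equal(cline_function(0.5, 0.5, 0), 0.75)
  expect_equal(cline_function(0.5, 0, 1), 0.5)  # beta inert at h = 0.5
  # truncation to [0, 1]
  expect_true(all(cline_function(h, 5, 0) <= 1))
  expect_true(all(cline_function(h, -5, 0) >= 0))
})

# compact admixed/parental fixture with strongly informative loci so short
# chains suffice; planted alpha at the first `n_planted` loci
cline_fixture <- function(n_loci = 120, n_adm = 16, planted_alpha = 0,
                          n_planted = 0, h_values = NULL, seed = 1) {
  withr::with_seed(seed, {
    p_w <- runif(n_loci, 0, 0.25)
    p_e <- runif(n_loci, 0.75, 1)
    ids <- sprintf("L%03d", seq_len(n_loci))
    truth <- data.frame(locus_id = ids, p_west = p_w, p_east = p_e,
                        alpha_true = rep(0, n_loci), beta_true = 0,
                        selection = "neutral", stringsAsFactors = FALSE)
    class(truth) <- c("sim_truth", "data.frame")
    if (n_planted > 0) truth$alpha_true[seq_len(n_planted)] <- planted_alpha
    samples <- c(sprintf("w%02d", 1:16), sprintf("e%02d", 1:16))
    g <- matrix(NA_integer_, 32, n_loci, dimnames = list(samples, ids))
    for (i in seq_len(n_loci)) {
      g[, i] <- rbinom(32, 2, rep(c(p_w[i], p_e[i]), each = 16))
    }
    meta <- data.frame(locus_id = ids, chrom = ids, pos = 1L, ref = "A",
                       alt = "T", stringsAsFactors = FALSE)
    list(truth = truth,
         parentals = genotype_matrix(g, meta),
         pm = population_map(samples, rep(c("west", "east"), each = 16)),
         admixed = simulate_admixed(truth, n_adm, h_values = h_values,
                                    seed = seed + 1))
  })
}

test_that("cline fit recovers planted alpha signs and is seed-deterministic", {
  fx <- cline_fixture(n_loci = 120, planted_alpha = 1.5, n_planted = 8, seed = 5)
  fit <- fit_genomic_clines(fx$admixed, fx$parentals, fx$pm,
                            n_iter = 5000, burnin = 1500, thin = 5, seed = 9)
  expect_s3_class(fit, "cline_fit")
  expect_gte(sum(fit$loci$alpha_median[1:8] > 0), 7)
  expect_true(all(fit$h$lower <= fit$h$mean & fit$h$mean <= fit$h$upper))
  expect_true(all(fit$loci$alpha_lower <= fit$loci$alpha_median &
                  fit$loci$alpha_median <= fit$loci$alpha_upper))
  expect_true(all(fit$h$mean >= 0 & fit$h$mean <= 1))
  # determinism
  fit2 <- fit_genomic_clines(fx$admixed, fx$parentals, fx$pm,
                             n_iter = 5000, burnin = 1500, thin = 5, seed = 9)
  expect_identical(fit$loci, fit2$loci)
  expect_identical(fit$h, fit2$h)
  # methods behave
  expect_output(print(fit), "cline_fit")
  expect_output(print(summary(fit)), "hybrid index")
  expect_equal(dim(coef(fit)), c(120L, 2L))
  phi <- predict(fit, h = c(0, 0.5, 1))
  expect_equal(dim(phi), c(3L, 120L))
  expect_equal(unname(phi[1, ]), rep(0, 120))
  expect_equal(unname(phi[3, ]), rep(1, 120))
})

test_that("swapping east and west labels negates the cline centers", {
  fx <- cline_fixture(n_loci = 100, planted_alpha = 1.5, n_planted = 6, seed = 7)
  fit <- fit_genomic_clines(fx$admixed, fx$parentals, fx$pm,
                            n_iter = 5000, burnin = 1500, thin = 5, seed = 3)
  pm_swap <- population_map(fx$pm$sample,
                            c(west = "east", east = "west")[fx$pm$population])
  fit_swap <- fit_genomic_clines(fx$admixed, fx$parentals, pm_swap,
                                 n_iter = 5000, burnin = 1500, thin = 5, seed = 4)
  # hybrid index flips and alpha (approximately) negates
  expect_equal(fit_swap$h$mean, 1 - fit$h$mean, tolerance = 0.05)
  expect_lt(mean((fit_swap$loci$alpha_median + fit$loci$alpha_median)^2), 0.1)
  calls <- classify_excess_ancestry(fit)
  calls_swap <- classify_excess_ancestry(fit_swap)
  east_loci <- calls$locus_id[calls$excess == "east"]
  expect_true(all(calls_swap$excess[calls_swap$locus_id %in% east_loci] %in%
                  c("west", "none")))
})

test_that("errors on disjoint loci and overlapping samples", {
  fx <- cline_fixture(n_loci = 20, seed = 2)
  other <- fx$parentals
  colnames(other$genotypes) <- paste0("X", seq_len(20))
  other$locus_meta$locus_id <- paste0("X", seq_len(20))
  expect_error(fit_genomic_clines(fx$admixed, other, fx$pm), "share no loci")
  expect_error(fit_genomic_clines(fx$parentals, fx$parentals, fx$pm), "disjoint")
})

# a hand-built cline_fit for classifier unit tests (no MCMC)
fake_fit <- function(alpha_med, alpha_lo = alpha_med - 0.1,
                     alpha_hi = alpha_med + 0.1) {
  n <- length(alpha_med)
  structure(list(
    h = data.frame(individual = "a", mean = 0.5, lower = 0.4, upper = 0.6),
    loci = data.frame(locus_id = sprintf("L%04d", seq_len(n)),
                      alpha_median = alpha_med,
                      alpha_lower = alpha_lo, alpha_upper = alpha_hi,
                      beta_median = 0, beta_lower = -0.1, beta_upper = 0.1,
                      gamma_quantile = hybridclines:::gamma_quantiles(alpha_med),
                      stringsAsFactors = FALSE),
    diagnostics = list(accept = c(h = .3, alpha = .3, beta = .3, p = .3),
                       min_ess = c(h = 100, alpha = 100, beta = 100),
                       n_draws = 1),
    settings = list()), class = "cline_fit")
}

test_that("excess-ancestry classification applies the interval and tail rules", {
  am <- c(rnorm(96, 0, 0.05), 1.2, 1.4, -1.2, -1.4)
  am <- withr::with_seed(4, sample(am))  # shuffle positions
  fit <- fake_fit(am)
  calls <- classify_excess_ancestry(fit)
  expect_equal(calls$excess[am > 1], rep("east", 2))
  expect_equal(calls$excess[am < -1], rep("west", 2))
  # interval including zero always gives none, however extreme the median
  fit2 <- fake_fit(am, alpha_lo = pmin(am - 0.1, -0.01),
                   alpha_hi = pmax(am + 0.1, 0.01))
  expect_true(all(classify_excess_ancestry(fit2)$excess == "none"))
  # east calls require positive medians above the upper tail
  expect_true(all(fit$loci$alpha_median[calls$excess == "east"] >
                  quantile(am, 0.975)))
})

test_that("gamma-quantile outliers flag the tails of the fitted distribution", {
  am <- withr::with_seed(8, rnorm(1000))
  fit <- fake_fit(am)
  flags <- gamma_outliers(fit, n = 0.1)
  expect_lt(abs(mean(flags) - 0.1), 0.02)
  # flagged loci are the extremes
  expect_true(all(abs(am[flags]) > min(abs(am[!flags]))))
  # degenerate distribution: no flags
  fit0 <- fake_fit(rep(0.3, 50))
  expect_true(all(!gamma_outliers(fit0)))
  expect_error(gamma_outliers(fake_fit(rnorm(5))), "at least 10")
})
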