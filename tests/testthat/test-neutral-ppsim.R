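# Frozen Monte-Carlo expectations from an established coalescent simulator
# (msprime 1.4.2, 20,000 replicates, branch-mode statistics), for three
# isolation-model parameter sets (theta_w, theta_e, theta_anc, tau). Values
# are mean within-population branch diversity and between-population branch
# divergence; the analytic expectations are E[dxy] = 2 tau + theta_anc and,
# within population i, the truncated-coalescent form below (which tends to
# theta_i as tau grows).
msprime_ref <- data.frame(
  theta_w = c(0.0592, 0.1, 0.02), theta_e = c(0.217, 0.1, 0.05),
  theta_anc = c(0.0615, 0.1, 0.03), tau = c(0.00578, 0.05, 0.1),
  pi_w = c(0.061002, 0.100199, 0.019927),
  pi_e = c(0.069737, 0.100307, 0.049632),
  dxy = c(0.072989, 0.199803, 0.229963))

# exact E[2 * pairwise coalescence time] within a population under isolation:
# coalesce at rate 2/theta until tau, else move to the ancestral population
pi_within_expected <- function(theta, theta_anc, tau) {
  r <- 2 / theta
  p_esc <- exp(-r * tau)
  2 * ((1 / r) * (1 - p_esc) - tau * p_esc + p_esc * (tau + theta_anc / 2))
}

test_that("genealogy simulator matches analytic and msprime expectations", {
  n_rep <- 1500
  for (k in seq_len(nrow(msprime_ref))) {
    ref <- msprime_ref[k, ]
    piw <- pie <- dv <- numeric(n_rep)
    set.seed(100 + k)
    for (i in seq_len(n_rep)) {
      g <- simulate_isolation_genealogy(4, 4, ref$theta_w, ref$theta_e,
                                        ref$theta_anc, ref$tau)
      pt <- g$pair_time
      w <- 1:4; e <- 5:8
      piw[i] <- mean(2 * pt[w, w][upper.tri(pt[w, w])])
      pie[i] <- mean(2 * pt[e, e][upper.tri(pt[e, e])])
      dv[i] <- mean(2 * pt[w, e])
    }
    se <- function(x) sd(x) / sqrt(n_rep)
    # analytic targets
    expect_lt(abs(mean(dv) - (2 * ref$tau + ref$theta_anc)), 3 * se(dv))
    expect_lt(abs(mean(piw) - pi_within_expected(ref$theta_w, ref$theta_anc, ref$tau)),
              3 * se(piw))
    expect_lt(abs(mean(pie) - pi_within_expected(ref$theta_e, ref$theta_anc, ref$tau)),
              3 * se(pie))
    # independent-simulator targets (frozen msprime means; allow both MC errors)
    expect_lt(abs(mean(dv) - ref$dxy), 4 * se(dv))
    expect_lt(abs(mean(piw) - ref$pi_w), 4 * se(piw))
    expect_lt(abs(mean(pie) - ref$pi_e), 4 * se(pie))
  }
  # long-isolation limit: within-population diversity approaches theta
  expect_lt(abs(pi_within_expected(0.01, 0.05, 1) - 0.01), 1e-8)
})

test_that("JC69 mutation layer matches the saturation-corrected divergence", {
  # between-population observed difference probability for one lineage per
  # population: distance 2T with T = tau + Exp(2/theta_anc), so
  # E[p_diff] = 3/4 (1 - exp(-8 tau / 3) / (1 + 4 theta_anc / 3))
  th_anc <- 0.3; tau <- 0.2
  expected <- 0.75 * (1 - exp(-8 * tau / 3) / (1 + 4 * th_anc / 3))
  set.seed(42)
  L <- 100
  diffs <- replicate(400, {
    g <- simulate_isolation_genealogy(1, 1, 0.1, 0.1, th_anc, tau)
    sites <- hybridclines:::jc69_mutate(g, L)$sites
    sum(sites[1, ] != sites[2, ]) / L
  })
  expect_lt(abs(mean(diffs) - expected), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("simulate_neutral_locus is deterministic, bounded, and errors on zero theta", {
  a <- simulate_neutral_locus(0.0592, 0.217, 0.0615, 0.00578, 10, 10, seed = 7)
  b <- simulate_neutral_locus(0.0592, 0.217, 0.0615, 0.00578, 10, 10, seed = 7)
  expect_identical(a, b)
  expect_false(a$skipped)
  expect_true(a$fst >= 0 && a$fst <= 1)
  expect_true(a$dxy >= 0 && a$dxy <= 1)
  expect_error(simulate_neutral_locus(0, 0.2, 0.1, 0.01, 4, 4), "theta_west")
  expect_error(simulate_neutral_locus(0.1, 0.2, 0, 0.01, 4, 4), "theta_anc")
})

test_that("panmixia gives an exchangeable null: relabeling leaves FST unchanged", {
  # tau = 0 and equal theta across demes is one population; the labeled FST
  # distribution must match the FST computed after random relabeling
  set.seed(11)
  n_loc <- 1200
  fst_lab <- numeric(0); fst_rel <- numeric(0)
  for (i in seq_len(n_loc)) {
    r <- simulate_neutral_locus(0.15, 0.15, 0.15, 0, 8, 8, L = 50)
    if (r$skipped) next
    fst_lab <- c(fst_lab, r$fst)
    # relabel: pool the counts and split at random
    alleles <- rep(c(1L, 0L), c(r$count_w + r$count_e, 16 - r$count_w - r$count_e))
    alleles <- sample(alleles)
    fst_rel <- c(fst_rel, wc_fst(sum(alleles[1:8]), 8, sum(alleles[9:16]), 8))
  }
  ks <- suppressWarnings(ks.test(fst_lab, fst_rel))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(fst_lab) - mean(fst_rel)), 3 * sd(fst_lab) / sqrt(length(fst_lab)))
})

test_that("median null FST increases with divergence time", {
  set.seed(13)
  med <- vapply(c(0.005, 0.05, 0.5), function(tau) {
    f <- replicate(400, {
      r <- simulate_neutral_locus(0.1, 0.1, 0.1, tau, 10, 10, L = 100)
      if (r$skipped) NA_real_ else r$fst
    })
    median(f, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("build_null_distribution respects counts, coverage draws, and determinism", {
  post <- make_pseudo_posterior(n_rows = 4, jitter_cv = 0.1, seed = 2)
  cfg <- neutral_sim_config(loci_per_sample = 25, locus_length = 100,
                            coverage_west = c(6L, 8L, 10L),
                            coverage_east = c(10L, 12L), seed = 5)
  nd <- build_null_distribution(post, cfg)
  expect_s3_class(nd, "null_distribution")
  expect_equal(nd$n_simulated, 100)
  expect_lte(length(nd$fst), 100)
  expect_equal(length(nd$fst) + sum(nd$n_skipped), 100)
  expect_true(all(nd$fst >= 0 & nd$fst <= 1))
  expect_true(all(nd$dxy >= 0 & nd$dxy <= 1))
  expect_true(all(nd$posterior_row %in% 1:4))
  nd2 <- build_null_distribution(post, cfg)
  expect_identical(nd, nd2)
})

test_that("compare_binned bins correctly and flags planted excess", {
  set.seed(3)
  null_vals <- rbeta(4000, 1, 8)          # mass near 0
  emp <- c(rbeta(900, 1, 8), runif(100, 0.55, 0.95))  # planted high tail
  bc <- compare_binned(emp, null_vals)
  expect_equal(nrow(bc), 10)
  expect_equal(bc$bin_lo, seq(0, 0.9, 0.1))
  expect_equal(sum(bc$n_empirical), length(emp))
  expect_equal(sum(bc$n_simulated), length(null_vals))
  high <- bc$bin_lo >= 0.6 & bc$n_empirical > 0
  expect_true(all(bc$p_value[high] < 0.05))
  # empty bin in both distributions -> p = 1
  bc2 <- compare_binned(c(0.05, 0.15), c(0.04, 0.12))
  expect_true(all(bc2$p_value[bc2$n_empirical == 0 & bc2$n_simulated == 0] == 1))
  expect_error(compare_binned(numeric(0), null_vals), "non-empty")
})

test_that("compare_binned type-I error is controlled under the null", {
  # empirical vectors drawn from the same distribution as the null: across
  # seeds, at most ~10% of bins reject at 0.05
  set.seed(21)
  null_vals <- rbeta(3000, 1.2, 6)
  n_sig <- 0; n_bins <- 0
  for (s in 1:20) {
    emp <- sample(null_vals, 600, replace = TRUE)
    bc <- compare_binned(emp, null_vals)
    n_sig <- n_sig + sum(bc$p_value < 0.05)
    n_bins <- n_bins + nrow(bc)
  }
  expect_lte(n_sig / n_bins, 0.10)
})

test_that("false-positive estimation is the capped simulated/empirical ratio", {
  # fixture: simulated fraction 0.001, empirical fraction 0.005 in (0.6, 1]
  sim <- c(rep(0.1, 999), 0.7)
  emp <- c(rep(0.1, 995), rep(0.7, 5))
  expect_equal(estimate_false_positive_rate(emp, sim, 0.6, 1), 0.2)
  # identical distributions -> ~1; zero simulated mass -> 0; no empirical -> NA
  expect_equal(estimate_false_positive_rate(emp, emp, 0.6, 1), 1)
  expect_equal(estimate_false_positive_rate(emp, rep(0.1, 100), 0.6, 1), 0)
  expect_true(is.na(estimate_false_positive_rate(rep(0.1, 10), sim, 0.6, 1)))
})
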