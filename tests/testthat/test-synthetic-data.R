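test_that("parental simulator has correct shape, labels, and determinism", {
  sim <- simulate_divergent_parentals(60, n_west = 5, n_east = 7,
                                      divergent_fraction = 0.1, seed = 4)
  expect_equal(dim(sim$genotypes), c(12L, 60L))
  expect_equal(sum(sim$popmap$population == "west"), 5)
  expect_equal(sum(sim$truth$selection == "divergent"), 6)
  expect_true(all(sim$truth$p_west >= 0 & sim$truth$p_west <= 1))
  # divergent_fraction = 0: all neutral
  sim0 <- simulate_divergent_parentals(30, n_west = 4, n_east = 4,
                                       divergent_fraction = 0, seed = 4)
  expect_true(all(sim0$truth$selection == "neutral"))
  # byte-identical under the same seed
  a <- simulate_divergent_parentals(25, n_west = 4, n_east = 4, seed = 99)
  b <- simulate_divergent_parentals(25, n_west = 4, n_east = 4, seed = 99)
  expect_identical(a, b)
  expect_error(simulate_divergent_parentals(10, n_west = 0), "at least one")
})

test_that("planted divergent loci have elevated FST", {
  sim <- simulate_divergent_parentals(800, divergent_fraction = 0.1,
                                      divergence_boost = 0.5, seed = 17)
  st <- compute_locus_stats(sim$genotypes, sim$popmap)
  div <- sim$truth$selection == "divergent"
  expect_gt(mean(st$fst[div], na.rm = TRUE), mean(st$fst[!div], na.rm = TRUE))
  # truth frequencies are pushed further apart at planted loci
  gap <- abs(sim$truth$p_east - sim$truth$p_west)
  expect_gt(mean(gap[div]), mean(gap[!div]))
})

test_that("admixed simulator respects the cline model", {
  n_loci <- 400
  truth <- data.frame(locus_id = sprintf("L%03d", 1:n_loci),
                      p_west = rep(0, n_loci), p_east = rep(1, n_loci),
                      alpha_true = 0, beta_true = 0, selection = "neutral",
                      stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")
  # alpha = beta = 0, h = 0.5, fixed parental difference: allele freq 0.5
  gm <- simulate_admixed(truth, 40, h_values = rep(0.5, 40), seed = 6)
  expect_equal(mean(gm$genotypes) / 2, 0.5, tolerance = 0.02)
  # h = 1: pure eastern sampling
  gm1 <- simulate_admixed(truth, 10, h_values = rep(1, 10), seed = 6)
  expect_true(all(gm1$genotypes == 2L))
  # planted positive alpha shifts the eastern-ancestry fraction above 0.5
  truth2 <- truth
  truth2$alpha_true[1] <- 1.5
  gm2 <- simulate_admixed(truth2, 500, h_values = rep(0.5, 500), seed = 8)
  frac <- mean(gm2$genotypes[, 1]) / 2
  expect_gt(frac, 0.5)
  expect_equal(frac, cline_function(0.5, 1.5, 0), tolerance = 0.05)
  expect_error(simulate_admixed(truth, 5, h_values = rep(0.5, 4)), "length")
})

test_that("neutral clines pass the regression slope check", {
  # with alpha = beta = 0 and h on a grid, the per-individual eastern-allele
  # fraction regresses on h_true with slope ~ 1
  n_loci <- 600
  truth <- data.frame(locus_id = sprintf("L%03d", 1:n_loci),
                      p_west = rep(0, n_loci), p_east = rep(1, n_loci),
                      alpha_true = 0, beta_true = 0, selection = "neutral",
                      stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")
  h <- seq(0.1, 0.9, length.out = 25)
  gm <- simulate_admixed(truth, 25, h_values = h, seed = 10)
  frac <- rowMeans(gm$genotypes) / 2
  slope <- coef(lm(frac ~ h))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
})

test_that("null admixed populations mix parental alleles evenly", {
  fx <- make_gm(p_w = rep(0, 50), p_e = rep(1, 50), n_w = 12, n_e = 12, seed = 2)
  reps <- simulate_null_admixed(fx$gm, fx$pm, seed = 3)
  # paper-mirroring defaults
  expect_length(reps, 5)
  expect_equal(nrow(reps[[1]]$genotypes), 21)
  # reciprocally fixed loci: expected null-admixed frequency 0.5
  allg <- do.call(rbind, lapply(reps, function(r) r$genotypes))
  expect_equal(mean(allg) / 2, 0.5, tolerance = 0.02)
  # convergence to the parental mean as n_admixed grows
  fx2 <- make_gm(p_w = c(0.1, 0.4), p_e = c(0.9, 0.8), n_w = 20, n_e = 20, seed = 5)
  big <- simulate_null_admixed(fx2$gm, fx2$pm, n_admixed = 800,
                               n_replicates = 1, seed = 6)[[1]]
  obs_w <- colMeans(fx2$gm$genotypes[1:20, ]) / 2
  obs_e <- colMeans(fx2$gm$genotypes[21:40, ]) / 2
  expect_equal(unname(colMeans(big$genotypes) / 2),
               unname((obs_w + obs_e) / 2), tolerance = 0.03)
  # all-missing parental data is a named error
  g <- fx$gm$genotypes
  g[1:12, 3] <- NA
  expect_error(simulate_null_admixed(genotype_matrix(g, fx$gm$locus_meta),
                                     fx$pm, seed = 1), "L003")
})

test_that("pseudo-posterior has the right center, spread and degenerate case", {
  # jitter_cv = 0: identical rows at the supplied values
  p0 <- make_pseudo_posterior(jitter_cv = 0, n_rows = 5, seed = 1)
  expect_equal(unique(p0$theta_east), 0.217)
  expect_equal(unique(p0$theta_west), 0.0592)
  expect_equal(unique(p0$theta_anc), 0.0615)
  expect_equal(unique(p0$tau), 0.00578)
  # sample mean within 3 SE of the center at the default row count
  p1 <- make_pseudo_posterior(n_rows = 375, jitter_cv = 0.1, seed = 8)
  for (col in names(p1)) {
    center <- c(theta_west = 0.0592, theta_east = 0.217,
                theta_anc = 0.0615, tau = 0.00578)[col]
    se <- sd(p1[[col]]) / sqrt(375)
    expect_lt(abs(mean(p1[[col]]) - center), 3 * se)
  }
  expect_true(all(as.matrix(p1) > 0))
})

test_that("gene annotation generator links loci and plants enrichment", {
  ids <- sprintf("L%04d", 1:400)
  div <- rep(FALSE, 400); div[1:40] <- TRUE
  ann <- generate_gene_annotations(ids, n_genes = 1200, divergent = div,
                                   enrichment_factor = 8, seed = 3)
  # every locus has exactly one up and one down gene
  cnt <- table(ann$gene_links$locus_id)
  expect_true(all(cnt == 2))
  expect_setequal(unique(ann$gene_links$side), c("up", "down"))
  expect_named(ann$candidate_sets,
               c("venom", "reproduction", "coloration", "nuc_mt", "nuc_oxphos"))
  # enriched sets over-represent divergent-linked genes; the negative
  # control does not (compare proportions)
  div_genes <- unique(ann$gene_links$gene_id[ann$gene_links$locus_id %in% ids[div]])
  prop <- vapply(ann$candidate_sets, function(s) mean(s %in% div_genes), numeric(1))
  base <- mean(ann$background %in% div_genes)
  expect_gt(prop["venom"], base)
  expect_gt(prop["nuc_mt"], base)
  expect_lt(abs(prop["coloration"] - base), 0.15)
  # determinism
  ann2 <- generate_gene_annotations(ids, n_genes = 1200, divergent = div,
                                    enrichment_factor = 8, seed = 3)
  expect_identical(ann, ann2)
})
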