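#' Simulate two parental populations with planted divergent loci
#'
#' Generates a synthetic SNP panel for two parental lineages diverged under
#' the neutral two-population isolation coalescent (via
#' [simulate_neutral_locus()]): per locus, a genealogy for a pseudo-sample of
#' alleles is simulated at the supplied theta/tau, one polymorphic biallelic
#' site is retained, and its per-population allele frequencies become the
#' locus's true frequencies. A fraction of loci is then planted as
#' "divergent": their parental frequencies are shifted apart symmetrically
#' toward fixation (`p +/- boost * min(p, 1 - p)`, clipped to [0, 1]), a
#' simple scheme monotone in the boost. Diploid genotypes are drawn
#' binomially from the (possibly shifted) true frequencies.
#'
#' Defaults are a desk-scale parental design (24 + 24 diploids) at posterior
#' mean parameters typical of a deeply structured rattlesnake-like system:
#' `theta_east = 0.217`, `theta_west = 0.0592`, `theta_anc = 0.0615`,
#' `tau = 0.00578` (per-site mutational units).
#'
#' @param n_loci number of polymorphic loci to produce.
#' @param n_west,n_east diploid sample sizes (default 24 each).
#' @param theta_west,theta_east,theta_anc,tau isolation-model parameters.
#' @param divergent_fraction fraction of loci planted as divergent.
#' @param divergence_boost frequency-shift intensity in [0, 1].
#' @param pseudo_sample alleles per population in the frequency-generating
#'   coalescent sample (default 50).
#' @param locus_length sites per simulated locus (default 190).
#' @param seed integer seed (byte-identical output for equal seeds).
#' @return list with `genotypes` (a [genotype_matrix()]), `popmap` (a
#'   [population_map()]) and `truth` (a `sim_truth` data.frame: `locus_id`,
#'   `p_west`, `p_east` — alternate-allele truth frequencies — `alpha_true`,
#'   `beta_true`, `selection` in `{neutral, divergent}`).
#' @export
simulate_divergent_parentals <- function(n_loci, n_west = 24L, n_east = 24L,
                                         theta_west = 0.0592,
                                         theta_east = 0.217,
                                         theta_anc = 0.0615, tau = 0.00578,
                                         divergent_fraction = 0.05,
                                         divergence_boost = 0.5,
                                         pseudo_sample = 50L,
                                         locus_length = 190L, seed = 1L) {
  if (n_west < 1 || n_east < 1) stopf("need at least one diploid per population")
  stopifnot(divergent_fraction >= 0, divergent_fraction <= 1,
            divergence_boost >= 0)
  with_seed(seed, {
    p_w <- p_e <- numeric(n_loci)
    for (i in seq_len(n_loci)) {
      repeat {
        res <- simulate_neutral_locus(theta_west, theta_east, theta_anc, tau,
                                      pseudo_sample, pseudo_sample,
                                      locus_length)
        if (!res$skipped) break
      }
      # truth = alternate-allele frequency; the simulator reports reference
      # (first-sampled-base) counts, so complement
      p_w[i] <- 1 - res$count_w / res$n_w
      p_e[i] <- 1 - res$count_e / res$n_e
    }
    n_div <- round(divergent_fraction * n_loci)
    divergent <- rep(FALSE, n_loci)
    if (n_div > 0) divergent[sample.int(n_loci, n_div)] <- TRUE
    if (any(divergent)) {
      up_east <- p_e[divergent] >= p_w[divergent]
      shift <- function(p, up) {
        d <- divergence_boost * pmin(p, 1 - p)
        pmin(1, pmax(0, ifelse(up, p + d, p - d)))
      }
      p_e[divergent] <- shift(p_e[divergent], up_east)
      p_w[divergent] <- shift(p_w[divergent], !up_east)
    }
    ids <- sprintf("locus%04d", seq_len(n_loci))
    samples <- c(sprintf("w%02d", seq_len(n_west)),
                 sprintf("e%02d", seq_len(n_east)))
    g <- matrix(NA_integer_, n_west + n_east, n_loci,
                dimnames = list(samples, ids))
    for (i in seq_len(n_loci)) {
      g[, i] <- stats::rbinom(n_west + n_east, 2,
                              rep(c(p_w[i], p_e[i]), c(n_west, n_east)))
    }
    meta <- data.frame(locus_id = ids, chrom = sprintf("contig%04d", seq_len(n_loci)),
                       pos = 100L, ref = "A", alt = "T", stringsAsFactors = FALSE)
    truth <- data.frame(locus_id = ids, p_west = p_w, p_east = p_e,
                        alpha_true = 0, beta_true = 0,
                        selection = ifelse(divergent, "divergent", "neutral"),
                        stringsAsFactors = FALSE)
    attr(truth, "seed") <- seed
    class(truth) <- c("sim_truth", "data.frame")
    list(genotypes = genotype_matrix(g, meta),
         popmap = population_map(samples,
                                 rep(c("west", "east"), c(n_west, n_east))),
         truth = truth)
  })
}

#' Simulate an admixed population under planted genomic clines
#'
#' Generative inverse of the cline model: for individual `j` with hybrid
#' index `h_j` and locus `i`, the eastern-ancestry probability is
#' `Phi_ij = cline_function(h_j, alpha_true_i, beta_true_i)`; each of the two
#' gene copies is eastern with probability `Phi_ij` and the allele is then
#' drawn from that parent's true frequency. Genotype = sum of the two
#' copies.
#'
#' @param truth `sim_truth` from [simulate_divergent_parentals()] (its
#'   `alpha_true` / `beta_true` columns may be edited to plant cline
#'   outliers).
#' @param n_admixed number of admixed diploids (default 21).
#' @param h_values hybrid indices, length `n_admixed`, each in [0, 1];
#'   default a uniform grid on [0.2, 0.8], mimicking a broadly admixed zone.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with samples `adm01`, `adm02`, ...
#' @export
simulate_admixed <- function(truth, n_admixed = 21L, h_values = NULL,
                             seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(h_values)) h_values <- seq(0.2, 0.8, length.out = n_admixed)
  if (length(h_values) != n_admixed) stopf("`h_values` must have length %d", n_admixed)
  if (any(h_values < 0 | h_values > 1)) stopf("hybrid indices must lie in [0, 1]")
  with_seed(seed, {
    n_loci <- nrow(truth)
    g <- matrix(NA_integer_, n_admixed, n_loci,
                dimnames = list(sprintf("adm%02d", seq_len(n_admixed)),
                                truth$locus_id))
    for (j in seq_len(n_admixed)) {
      phi <- cline_function(h_values[j], truth$alpha_true, truth$beta_true)
      east1 <- stats::runif(n_loci) < phi
      east2 <- stats::runif(n_loci) < phi
      p1 <- ifelse(east1, truth$p_east, truth$p_west)
      p2 <- ifelse(east2, truth$p_east, truth$p_west)
      g[j, ] <- (stats::runif(n_loci) < p1) + (stats::runif(n_loci) < p2)
    }
    meta <- data.frame(locus_id = truth$locus_id,
                       chrom = sprintf("contig%04d", seq_len(n_loci)),
                       pos = 100L, ref = "A", alt = "T", stringsAsFactors = FALSE)
    genotype_matrix(g, meta)
  })
}

#' Simulate null admixed populations by random parental-allele draws
#'
#' Builds replicate "null" admixed populations containing no locus-specific
#' introgression signal: per individual and locus, each of the two alleles is
#' obtained by first choosing a parental population uniformly at random and
#' then sampling one observed (non-missing) allele from that population at
#' that locus. Running the cline fit on such data benchmarks the
#' excess-ancestry classifier's false-positive behaviour.
#'
#' @param parental_gm [genotype_matrix()] holding the parental samples.
#' @param pm [population_map()] for the parental samples.
#' @param n_admixed individuals per replicate (default 21).
#' @param n_replicates number of replicates (default 5).
#' @param seed integer seed.
#' @return list of `n_replicates` [genotype_matrix()] objects.
#' @export
simulate_null_admixed <- function(parental_gm, pm, n_admixed = 21L,
                                  n_replicates = 5L, seed = 1L) {
  check_popmap(parental_gm, pm)
  gw <- parental_gm$genotypes[sample_ids(parental_gm) %in% pop_samples(pm, "west"), , drop = FALSE]
  ge <- parental_gm$genotypes[sample_ids(parental_gm) %in% pop_samples(pm, "east"), , drop = FALSE]
  n_w <- 2 * colSums(!is.na(gw)); n_e <- 2 * colSums(!is.na(ge))
  bad <- which(n_w == 0 | n_e == 0)
  if (length(bad) > 0) {
    stopf("all-missing parental data at locus/loci: %s",
          paste(utils::head(locus_ids(parental_gm)[bad], 5), collapse = ", "))
  }
  f_w <- colSums(gw, na.rm = TRUE) / n_w  # observed alt-allele fractions
  f_e <- colSums(ge, na.rm = TRUE) / n_e
  n_loci <- ncol(parental_gm$genotypes)
  meta <- parental_gm$locus_meta
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      g <- matrix(NA_integer_, n_admixed, n_loci,
                  dimnames = list(sprintf("null%02d", seq_len(n_admixed)),
                                  locus_ids(parental_gm)))
      for (j in seq_len(n_admixed)) {
        east1 <- stats::runif(n_loci) < 0.5
        east2 <- stats::runif(n_loci) < 0.5
        p1 <- ifelse(east1, f_e, f_w)
        p2 <- ifelse(east2, f_e, f_w)
        g[j, ] <- (stats::runif(n_loci) < p1) + (stats::runif(n_loci) < p2)
      }
      genotype_matrix(g, meta)
    })
  })
}

#' Pseudo-posterior sample set around supplied parameter values
#'
#' Stand-in for a posterior from a species-tree analysis: rows drawn from
#' independent log-normal distributions centered (in mean) at the supplied
#' values with coefficient of variation `jitter_cv`. `jitter_cv = 0` yields
#' identical rows. Defaults are the desk-scale isolation-model means used
#' throughout the package.
#'
#' @param theta_west,theta_east,theta_anc,tau central parameter values.
#' @param n_rows number of posterior rows (default 375).
#' @param jitter_cv coefficient of variation of each column (default 0.1).
#' @param seed integer seed.
#' @return a [posterior_sample_set()].
#' @export
make_pseudo_posterior <- function(theta_west = 0.0592, theta_east = 0.217,
                                  theta_anc = 0.0615, tau = 0.00578,
                                  n_rows = 375L, jitter_cv = 0.1, seed = 1L) {
  stopifnot(jitter_cv >= 0, n_rows >= 1)
  vals <- c(theta_west, theta_east, theta_anc, tau)
  with_seed(seed, {
    if (jitter_cv == 0) {
      m <- matrix(rep(vals, each = n_rows), n_rows)
    } else {
      sdlog <- sqrt(log(1 + jitter_cv^2))
      m <- vapply(vals, function(v) {
        if (v == 0) rep(0, n_rows)
        else stats::rlnorm(n_rows, meanlog = log(v) - sdlog^2 / 2, sdlog = sdlog)
      }, numeric(n_rows))
      if (n_rows == 1L) m <- matrix(m, 1)
    }
    posterior_sample_set(m[, 1], m[, 2], m[, 3], m[, 4])
  })
}

#' Generate a synthetic locus-to-gene map with planted candidate enrichment
#'
#' Links every locus to one upstream and one downstream gene drawn from a
#' synthetic gene universe, then builds named candidate gene sets in which
#' genes linked to divergent-labelled loci are over-represented by
#' `enrichment_factor` (sets marked `enriched = FALSE` are sampled
#' uniformly, providing negative controls). With `enrichment_factor = 1`,
#' membership is independent of the selection label.
#'
#' @param locus_ids character vector of locus ids.
#' @param n_genes size of the gene universe.
#' @param candidate_specs data.frame with columns `name`, `size`, `enriched`
#'   (logical). Default: five sets of 40 genes named after classic candidate
#'   axes (venom, reproduction, coloration, nuc_mt, nuc_oxphos), all
#'   enriched except `coloration` (the negative control).
#' @param enrichment_factor sampling-weight multiplier for divergent-linked
#'   genes in enriched sets (default 5).
#' @param divergent logical vector aligned with `locus_ids` marking the loci
#'   whose linked genes should be over-represented; default none.
#' @param seed integer seed.
#' @return list: `gene_links` (data.frame `locus_id`, `gene_id`, `side`,
#'   `evalue`), `candidate_sets` (named list of character vectors),
#'   `background` (all linked genes).
#' @export
generate_gene_annotations <- function(locus_ids, n_genes = 2000L,
                                      candidate_specs = NULL,
                                      enrichment_factor = 5,
                                      divergent = NULL, seed = 1L) {
  n_loci <- length(locus_ids)
  if (is.null(divergent)) divergent <- rep(FALSE, n_loci)
  stopifnot(length(divergent) == n_loci, enrichment_factor > 0)
  if (is.null(candidate_specs)) {
    candidate_specs <- data.frame(
      name = c("venom", "reproduction", "coloration", "nuc_mt", "nuc_oxphos"),
      size = 40L,
      enriched = c(TRUE, TRUE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- sprintf("gene%05d", seq_len(n_genes))
  with_seed(seed, {
    up <- sample(genes, n_loci, replace = n_loci > n_genes)
    down <- sample(genes, n_loci, replace = n_loci > n_genes)
    gene_links <- data.frame(
      locus_id = rep(locus_ids, 2L),
      gene_id = c(up, down),
      side = rep(c("up", "down"), each = n_loci),
      evalue = signif(10^stats::runif(2 * n_loci, -30, -5), 3),
      stringsAsFactors = FALSE)
    background <- unique(gene_links$gene_id)
    div_genes <- unique(gene_links$gene_id[gene_links$locus_id %in% locus_ids[divergent]])
    sets <- lapply(seq_len(nrow(candidate_specs)), function(k) {
      w <- rep(1, length(background))
      if (candidate_specs$enriched[k]) {
        w[background %in% div_genes] <- enrichment_factor
      }
      sample(background, min(candidate_specs$size[k], length(background)),
             prob = w)
    })
    names(sets) <- candidate_specs$name
    list(gene_links = gene_links, candidate_sets = sets,
         background = background)
  })
}
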