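#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 p (1 - p) n / (n - 1)` with
#' `p = ref_count / n`: the average pairwise difference over all pairs of the
#' `n` sampled alleles. Equals 1 at a site with one allele of each kind in a
#' sample of two, and 0 at a monomorphic site.
#'
#' @param ref_count count of one designated allele (which one is irrelevant;
#'   the statistic is allele-symmetric).
#' @param n total number of non-missing alleles sampled; must be >= 2 for a
#'   defined value (`NA` returned otherwise).
#' @return per-site diversity in [0, 1].
#' @export
site_pi <- function(ref_count, n) {
  p <- ref_count / n
  out <- 2 * p * (1 - p) * n / (n - 1)
  out[n < 2] <- NA_real_
  out
}

#' Weir-Cockerham FST for two populations from allele counts
#'
#' Variance-components estimator theta-hat of Weir & Cockerham (1984) in the
#' haploid-sample (allele-count) form, for two populations at a biallelic
#' site, with negative estimates clamped to zero (the lower bound indicative
#' of panmixia). Returns exactly 1 for reciprocally fixed populations.
#'
#' The allele-count form treats each sampled allele as the sampling unit,
#' which is the natural contract for RAD allele counts with missingness;
#' genotype-aware implementations can differ in the third decimal.
#'
#' @param count_w,count_e counts of the designated allele in the western and
#'   eastern samples.
#' @param n_w,n_e total non-missing allele counts per population; `NA` is
#'   returned when either is < 2.
#' @return clamped FST in [0, 1].
#' @export
wc_fst <- function(count_w, n_w, count_e, n_e) {
  p1 <- count_w / n_w
  p2 <- count_e / n_e
  r <- 2
  nbar <- (n_w + n_e) / r
  nc <- (n_w + n_e - (n_w^2 + n_e^2) / (n_w + n_e)) / (r - 1)
  pbar <- (count_w + count_e) / (n_w + n_e)
  # among- and within-population mean squares over alleles
  msp <- (n_w * (p1 - pbar)^2 + n_e * (p2 - pbar)^2) / (r - 1)
  msg <- (n_w * p1 * (1 - p1) + n_e * p2 * (1 - p2)) / (n_w - 1 + n_e - 1)
  denom <- msp + (nc - 1) * msg
  theta <- ifelse(denom == 0, ifelse(msp == 0, NA_real_, 1), (msp - msg) / denom)
  # a monomorphic site across both samples carries no information: define 0
  theta[msp == 0 & msg == 0] <- 0
  out <- pmin(1, pmax(theta, 0))
  out[n_w < 2 | n_e < 2] <- NA_real_
  out
}

#' Per-site absolute divergence (dxy)
#'
#' The probability that two alleles, one drawn from each population, differ:
#' `p_w (1 - p_e) + p_e (1 - p_w)`. Unlike FST it does not depend on
#' within-population diversity; reciprocally fixed sites give exactly 1.
#'
#' @param p_w,p_e frequencies of the same designated allele in the two
#'   populations.
#' @return dxy in [0, 1]; symmetric in its arguments.
#' @export
site_dxy <- function(p_w, p_e) {
  p_w * (1 - p_e) + p_e * (1 - p_w)
}

#' Per-locus diversity and differentiation table
#'
#' Applies [site_pi()], [wc_fst()] and [site_dxy()] to the parental samples
#' at every locus, on non-missing alleles only. Admixed samples are excluded.
#' `delta_pi` is `pi_east - pi_west`: positive at loci more diverse in the
#' eastern population. Loci unusable in either parental population (fewer
#' than 2 non-missing alleles) keep their row with `NA` statistics; a message
#' reports how many.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] with at least two samples in each parental
#'   population.
#' @return data.frame with one row per locus: `locus_id`, `n_west`, `n_east`
#'   (non-missing allele counts), `p_west`, `p_east` (reference-allele
#'   frequencies), `pi_west`, `pi_east`, `delta_pi`, `fst`, `dxy`,
#'   `missing_fraction`.
#' @export
compute_locus_stats <- function(gm, pm) {
  check_popmap(gm, pm)
  gw <- gm$genotypes[sample_ids(gm) %in% pop_samples(pm, "west"), , drop = FALSE]
  ge <- gm$genotypes[sample_ids(gm) %in% pop_samples(pm, "east"), , drop = FALSE]
  n_w <- 2 * colSums(!is.na(gw))
  n_e <- 2 * colSums(!is.na(ge))
  alt_w <- colSums(gw, na.rm = TRUE)
  alt_e <- colSums(ge, na.rm = TRUE)
  ref_w <- n_w - alt_w
  ref_e <- n_e - alt_e
  p_w <- ifelse(n_w > 0, ref_w / n_w, NA_real_)
  p_e <- ifelse(n_e > 0, ref_e / n_e, NA_real_)
  pi_w <- site_pi(ref_w, n_w)
  pi_e <- site_pi(ref_e, n_e)
  fst <- wc_fst(ref_w, n_w, ref_e, n_e)
  dxy <- ifelse(n_w >= 2 & n_e >= 2, site_dxy(p_w, p_e), NA_real_)
  miss <- colMeans(is.na(rbind(gw, ge)))
  out <- data.frame(locus_id = locus_ids(gm),
                    n_west = n_w, n_east = n_e,
                    p_west = p_w, p_east = p_e,
                    pi_west = pi_w, pi_east = pi_e,
                    delta_pi = pi_e - pi_w,
                    fst = fst, dxy = dxy,
                    missing_fraction = miss,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n_bad <- sum(is.na(out$fst))
  if (n_bad > 0) {
    message(sprintf("%d locus/loci unusable in a parental population (NA statistics)", n_bad))
  }
  out
}
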