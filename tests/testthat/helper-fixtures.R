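# Shared fixture builders. Everything is generated in code; nothing binary.

# tiny VCF with controllable records
write_test_vcf <- function(path, records,
                           samples = c("s1", "s2", "s3")) {
  head <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(head, records), path)
  path
}

vcf_rec <- function(chrom, pos, id, ref, alt, qual, gts) {
  paste(c(chrom, pos, id, ref, alt, qual, "PASS", ".", "GT", gts),
        collapse = "\t")
}

# small deterministic genotype matrix: freqs chosen per population
make_gm <- function(p_w, p_e, n_w = 10, n_e = 10, seed = 1) {
  n_loci <- length(p_w)
  ids <- sprintf("L%03d", seq_len(n_loci))
  samples <- c(sprintf("w%02d", seq_len(n_w)), sprintf("e%02d", seq_len(n_e)))
  g <- withr::with_seed(seed, {
    m <- matrix(NA_integer_, n_w + n_e, n_loci)
    for (i in seq_len(n_loci)) {
      m[, i] <- stats::rbinom(n_w + n_e, 2,
                              rep(c(p_w[i], p_e[i]), c(n_w, n_e)))
    }
    m
  })
  dimnames(g) <- list(samples, ids)
  meta <- data.frame(locus_id = ids, chrom = sprintf("c%03d", seq_len(n_loci)),
                     pos = 1L, ref = "A", alt = "T", stringsAsFactors = FALSE)
  list(gm = genotype_matrix(g, meta),
       pm = population_map(samples, rep(c("west", "east"), c(n_w, n_e))))
}

# independent Weir-Cockerham oracle: variance components a (among) and b
# (within) written directly from the published haploid-sample equations,
# structured differently from the package implementation (explicit n_c,
# per-population sums).
wc_fst_oracle <- function(count_w, n_w, count_e, n_e) {
  p <- c(count_w / n_w, count_e / n_e)
  n <- c(n_w, n_e)
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar_terms <- sum(n * p * (1 - p)) / sum(n - 1)  # within-pop mean squares
  msp <- (r - 1) * nbar * s2 / (r - 1)
  a <- (msp - hbar_terms) / nc  # among-population variance component
  b <- hbar_terms               # within-population component
  theta <- a / (a + b)
  if (!is.finite(theta)) return(NA_real_)
  max(0, min(1, theta))
}

# brute-force pi oracle: average difference over all allele pairs
site_pi_oracle <- function(ref_count, n) {
  alleles <- rep(c(1L, 0L), c(ref_count, n - ref_count))
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# one-sided hypergeometric enrichment p by explicit tail summation
enrich_p_oracle <- function(a, b, c_, d) {
  # P(X >= a) where X ~ Hypergeom(m = a+b candidates, n = c_+d others,
  # k = a+c_ outlier draws)
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  num <- sum(choose(m, xs[xs >= a]) * choose(n, k - xs[xs >= a]))
  den <- sum(choose(m, xs) * choose(n, k - xs))
  num / den
}
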