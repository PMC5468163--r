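#' Thin to one SNP per contig and apply a minor-allele-frequency floor
#'
#' Reduced-representation loci carry several SNPs in tight linkage; analyses
#' downstream assume independent markers, so a single SNP is kept per contig.
#' SNPs whose overall minor allele frequency (across all non-missing alleles
#' in all samples) falls below `maf_min` are then removed: such variants
#' carry almost no ancestry information.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] (used only for validation; the MAF is
#'   computed over all samples).
#' @param maf_min minor allele frequency floor, default 0.05.
#' @param seed integer seed for the per-contig draw.
#' @param choose how to pick the SNP within a contig: `"random"` (seeded
#'   uniform draw, the default) or `"first"` (lowest position).
#' @return A filtered [genotype_matrix()]; retained loci keep their original
#'   relative order. Applying the filter twice equals applying it once.
#' @export
filter_snps <- function(gm, pm = NULL, maf_min = 0.05, seed = 1L,
                        choose = c("random", "first")) {
  choose <- match.arg(choose)
  if (!is.null(pm)) check_popmap(gm, pm, require_parentals = FALSE)
  meta <- gm$locus_meta
  keep <- with_seed(seed, {
    vapply(split(seq_len(nrow(meta)), meta$chrom), function(ix) {
      if (length(ix) == 1L) return(ix)
      if (choose == "first") ix[which.min(meta$pos[ix])]
      else ix[sample.int(length(ix), 1L)]
    }, integer(1))
  })
  keep <- sort(unname(keep))
  g <- gm$genotypes[, keep, drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  n <- 2 * colSums(!is.na(g))
  p_alt <- ifelse(n > 0, alt / n, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  keep2 <- which(!is.na(maf) & maf >= maf_min)
  if (length(keep2) == 0) stopf("no SNPs survive the MAF >= %g filter", maf_min)
  subset_loci(genotype_matrix(g, meta[keep, , drop = FALSE]), keep2)
}
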