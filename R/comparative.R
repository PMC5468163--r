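#' Correlate parental divergence with introgression
#'
#' Pearson correlations (with two-sided p-values) between the magnitude of
#' the cline center parameter `|alpha|` and each divergence statistic: FST,
#' dxy, `|delta_pi|` and the Mahalanobis distance. Absolute values are used
#' for `alpha` and `delta_pi` because both are signed by direction, while
#' the hypothesis concerns strength of the signal.
#'
#' @param stats table from [compute_locus_stats()].
#' @param fit a `cline_fit` over (a subset of) the same loci.
#' @param md Mahalanobis distances aligned with `stats` (from
#'   [mahalanobis_distances()]); optional.
#' @param fst_min optional FST threshold; when non-`NULL`, an additional set
#'   of rows restricted to loci with `fst > fst_min` is reported.
#' @return data.frame: `pair`, `r`, `p_value`, `n` (complete loci used);
#'   `NA` entries when fewer than 3 complete pairs.
#' @export
correlate_divergence_introgression <- function(stats, fit, md = NULL,
                                               fst_min = NULL) {
  stopifnot(inherits(fit, "cline_fit"))
  ix <- match(fit$loci$locus_id, stats$locus_id)
  if (all(is.na(ix))) stopf("no shared loci between stats and cline fit")
  abs_alpha <- abs(fit$loci$alpha_median)
  cols <- list(fst = stats$fst[ix], dxy = stats$dxy[ix],
               abs_delta_pi = abs(stats$delta_pi[ix]))
  if (!is.null(md)) cols$md <- md[ix]
  one <- function(y, x, label) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(pair = label, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(pair = label, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(cols), function(nm) {
    one(abs_alpha, cols[[nm]], paste0("abs_alpha~", nm))
  }))
  if (!is.null(fst_min)) {
    keep <- !is.na(stats$fst[ix]) & stats$fst[ix] > fst_min
    sub <- do.call(rbind, lapply(names(cols), function(nm) {
      one(abs_alpha[keep], cols[[nm]][keep],
          paste0("abs_alpha~", nm, "|fst>", fst_min))
    }))
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out
}

#' Gene-overlap significance by resampling
#'
#' Tests whether two gene sets (e.g. genes linked to divergence outliers and
#' genes linked to introgression outliers) share more genes than expected by
#' chance given a common background. Each resample draws `|genes_a|` and
#' `|genes_b|` genes uniformly without replacement from the background and
#' counts their intersection; the p-value uses the +1 correction
#' `(1 + #{null >= observed}) / (n_resamples + 1)` and so never returns 0.
#' The overlap is also called significant when the observed count exceeds
#' the 95th quantile of the null overlap distribution.
#'
#' @param genes_a,genes_b character vectors (subsets of `background`).
#' @param background character vector: all genes linked to any analysed locus.
#' @param n_resamples number of resampled datasets, default 1000.
#' @param seed integer seed.
#' @return list of class `overlap_result`: `observed_overlap`,
#'   `null_overlaps`, `p_value`, `exceeds_q95`, `n_resamples`.
#' @export
overlap_resampling_test <- function(genes_a, genes_b, background,
                                    n_resamples = 1000L, seed = 1L) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  background <- unique(background)
  if (!all(genes_a %in% background) || !all(genes_b %in% background)) {
    stopf("gene sets must be subsets of the background")
  }
  if (length(genes_a) > length(background) || length(genes_b) > length(background)) {
    stopf("gene set larger than background")
  }
  observed <- length(intersect(genes_a, genes_b))
  null_overlaps <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      a <- sample(background, length(genes_a))
      b <- sample(background, length(genes_b))
      length(intersect(a, b))
    }, numeric(1))
  })
  p <- (1 + sum(null_overlaps >= observed)) / (n_resamples + 1)
  structure(list(observed_overlap = observed,
                 null_overlaps = null_overlaps,
                 p_value = p,
                 exceeds_q95 = observed > stats::quantile(null_overlaps, 0.95,
                                                          names = FALSE),
                 n_resamples = n_resamples),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: observed %d vs null mean %.2f (%d resamples); p = %.4g%s\n",
              x$observed_overlap, mean(x$null_overlaps), x$n_resamples,
              x$p_value, if (x$exceeds_q95) " [> 95th null quantile]" else ""))
  invisible(x)
}

#' Candidate gene-set enrichment by Fisher's exact test
#'
#' Tests whether outlier-linked genes are enriched for a named candidate set
#' over the gene background, using the exact hypergeometric test on the 2x2
#' table (gene in candidate set?) x (gene in outlier set?). One-sided
#' (enrichment) by default; the sample odds ratio uses a 0.5 continuity
#' correction when any cell is zero.
#'
#' @param outlier_genes character vector of genes linked to outlier loci.
#' @param candidate character vector: the candidate gene set. May be a named
#'   list element; the name is picked up via `set_name`.
#' @param background character vector: the gene universe.
#' @param set_name label for the output row.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return data.frame of class `enrichment_result` with the 2x2 counts
#'   (`n_cand_out`, `n_cand_bg`, `n_other_out`, `n_other_bg`), `odds_ratio`
#'   and `fisher_p`; `NA` row (with a warning) for an empty candidate set.
#' @export
candidate_enrichment_test <- function(outlier_genes, candidate, background,
                                      set_name = "candidate",
                                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  candidate <- unique(candidate)
  outlier_genes <- unique(outlier_genes)
  if (!all(candidate %in% background) || !all(outlier_genes %in% background)) {
    stopf("candidate and outlier gene sets must be subsets of the background")
  }
  if (length(candidate) == 0) {
    warnf("empty candidate set '%s'; returning NA result", set_name)
    return(data.frame(set_name = set_name, n_cand_out = NA_integer_,
                      n_cand_bg = NA_integer_, n_other_out = NA_integer_,
                      n_other_bg = NA_integer_, odds_ratio = NA_real_,
                      fisher_p = NA_real_, stringsAsFactors = FALSE))
  }
  a <- length(intersect(candidate, outlier_genes))
  b <- length(setdiff(candidate, outlier_genes))
  c_ <- length(setdiff(outlier_genes, candidate))
  d <- length(background) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  structure(data.frame(set_name = set_name, n_cand_out = a, n_cand_bg = b,
                       n_other_out = c_, n_other_bg = d,
                       odds_ratio = or, fisher_p = p,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Exact binomial test of ancestry-direction symmetry
#'
#' Given counts of outlier loci with excess eastern vs western ancestry,
#' tests the null that each direction is equally likely: a two-sided exact
#' binomial test (summing the probabilities of all outcomes no more likely
#' than the observed one) of `count_east` successes in
#' `count_east + count_west` trials against 0.5. Symmetric in its arguments.
#'
#' @param count_east,count_west non-negative locus counts, not both zero.
#' @return the two-sided p-value.
#' @export
ancestry_symmetry_test <- function(count_east, count_west) {
  stopifnot(count_east >= 0, count_west >= 0, count_east + count_west > 0)
  stats::binom.test(count_east, count_east + count_west, p = 0.5)$p.value
}
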