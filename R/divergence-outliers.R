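#' Mahalanobis distance of each locus from the multivariate centroid
#'
#' Distance of each locus's statistic vector (by default FST, dxy, delta_pi —
#' delta_pi entering signed, so loci extreme in either direction score high)
#' from the mean vector, scaled by the sample covariance over complete rows:
#' `sqrt((x - mu)' S^-1 (x - mu))`. Rows with any missing statistic get `NA`.
#' A near-singular covariance is ridged by `1e-8 * trace(S) / ncol` with a
#' warning; if still singular an error is raised.
#'
#' @param stats data.frame from [compute_locus_stats()].
#' @param columns statistic columns to use; default `c("fst","dxy","delta_pi")`.
#' @return numeric vector of distances, one per row of `stats`.
#' @export
mahalanobis_distances <- function(stats, columns = c("fst", "dxy", "delta_pi")) {
  x <- as.matrix(stats[, columns, drop = FALSE])
  complete <- stats::complete.cases(x)
  if (sum(complete) < length(columns) + 1L) {
    stopf("need at least %d complete rows for a %d-column Mahalanobis distance",
          length(columns) + 1L, length(columns))
  }
  xc <- x[complete, , drop = FALSE]
  mu <- colMeans(xc)
  S <- stats::cov(xc)
  md2 <- tryCatch(stats::mahalanobis(xc, mu, S),
                  error = function(e) NULL)
  if (is.null(md2) || rcond_ok(S) < 1e-12) {
    eps <- 1e-8 * sum(diag(S)) / ncol(S)
    warnf("near-singular covariance; applying ridge epsilon = %g", eps)
    S <- S + diag(eps, ncol(S))
    md2 <- tryCatch(stats::mahalanobis(xc, mu, S),
                    error = function(e) stopf("covariance singular even after ridging"))
  }
  out <- rep(NA_real_, nrow(x))
  out[complete] <- sqrt(pmax(md2, 0))
  out
}

rcond_ok <- function(S) tryCatch(1 / kappa(S, exact = TRUE), error = function(e) 0)

#' Classify divergence outliers from Mahalanobis distances
#'
#' A locus is a statistical outlier if its distance strictly exceeds the
#' empirical 95th quantile of the genomic distance distribution, and a strong
#' outlier above the 99th. The retained set additionally requires
#' `fst > fst_floor` (default 0.2), removing high-distance loci whose
#' signal is low relative differentiation — e.g. balancing selection — rather
#' than elevated divergence.
#'
#' @param md numeric vector from [mahalanobis_distances()].
#' @param stats the matching [compute_locus_stats()] table.
#' @param q_outlier,q_strong outlier quantiles (type-7 empirical), defaults
#'   0.95 and 0.99.
#' @param fst_floor FST retention floor, default 0.2.
#' @return data.frame: `locus_id`, `md`, `is_outlier`, `is_strong`,
#'   `passes_fst_floor`, `retained`.
#' @export
classify_divergence_outliers <- function(md, stats, q_outlier = 0.95,
                                         q_strong = 0.99, fst_floor = 0.2) {
  stopifnot(length(md) == nrow(stats))
  qs <- stats::quantile(md, c(q_outlier, q_strong), na.rm = TRUE, type = 7,
                        names = FALSE)
  is_outlier <- !is.na(md) & md > qs[1]
  is_strong <- !is.na(md) & md > qs[2]
  passes <- !is.na(stats$fst) & stats$fst > fst_floor
  data.frame(locus_id = stats$locus_id,
             md = md,
             is_outlier = is_outlier,
             is_strong = is_strong,
             passes_fst_floor = passes,
             retained = is_outlier & passes,
             stringsAsFactors = FALSE)
}
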