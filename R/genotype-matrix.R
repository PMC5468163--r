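#' Genotype matrix container
#'
#' A `genotype_matrix` holds diploid biallelic genotypes for a set of samples
#' at a set of SNPs (one SNP per RAD locus after filtering). Genotypes are
#' coded as the count of the VCF alternate allele (0, 1, 2) with `NA` for
#' missing calls. Allele orientation with respect to the two parental
#' lineages is never baked into storage; it is attached downstream from
#' parental allele frequencies.
#'
#' @param genotypes integer matrix, samples in rows, loci in columns, values
#'   in `{0, 1, 2, NA}`. Row names are sample ids, column names locus ids.
#' @param locus_meta data.frame with one row per locus and columns
#'   `locus_id`, `chrom` (contig of origin), `pos` (1-based, VCF convention),
#'   `ref`, `alt`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, locus_meta) {
  if (!is.matrix(genotypes)) stopf("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes))) {
    stopf("`genotypes` must carry sample ids (rownames) and locus ids (colnames)")
  }
  if (anyDuplicated(rownames(genotypes))) stopf("duplicate sample ids")
  if (anyDuplicated(colnames(genotypes))) stopf("duplicate locus ids")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stopf("genotype codes must be 0, 1, 2 or NA")
  need <- c("locus_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(locus_meta))) {
    stopf("`locus_meta` must have columns %s", paste(need, collapse = ", "))
  }
  locus_meta <- as.data.frame(locus_meta)[, need]
  if (!identical(as.character(locus_meta$locus_id), colnames(genotypes))) {
    stopf("`locus_meta$locus_id` must match genotype column names in order")
  }
  rownames(locus_meta) <- NULL
  structure(list(genotypes = genotypes, locus_meta = locus_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

sample_ids <- function(gm) rownames(gm$genotypes)
locus_ids <- function(gm) colnames(gm$genotypes)

# subset a genotype_matrix by loci (logical/integer/character index)
subset_loci <- function(gm, idx) {
  g <- gm$genotypes[, idx, drop = FALSE]
  if (is.character(idx)) {
    meta <- gm$locus_meta[match(idx, gm$locus_meta$locus_id), , drop = FALSE]
  } else {
    meta <- gm$locus_meta[idx, , drop = FALSE]
  }
  genotype_matrix(g, meta)
}

subset_samples <- function(gm, ids) {
  genotype_matrix(gm$genotypes[ids, , drop = FALSE], gm$locus_meta)
}

#' Population map
#'
#' Assigns each sample to one of the populations `west`, `east` or `admixed`.
#'
#' @param sample character vector of sample ids.
#' @param population character vector, one of `"west"`, `"east"`, `"admixed"`.
#' @return data.frame of class `population_map`.
#' @export
population_map <- function(sample, population) {
  population <- as.character(population)
  ok <- population %in% c("west", "east", "admixed")
  if (!all(ok)) stopf("unknown population label(s): %s",
                      paste(unique(population[!ok]), collapse = ", "))
  if (anyDuplicated(sample)) stopf("duplicate sample ids in population map")
  structure(data.frame(sample = as.character(sample), population = population,
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

pop_samples <- function(pm, pop) pm$sample[pm$population == pop]

# check every sample of gm has an assignment; >=2 samples in each parental pop
check_popmap <- function(gm, pm, require_parentals = TRUE) {
  missing_samples <- setdiff(sample_ids(gm), pm$sample)
  if (length(missing_samples) > 0) {
    stopf("samples without population assignment: %s",
          paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  if (require_parentals) {
    for (p in c("west", "east")) {
      if (sum(sample_ids(gm) %in% pop_samples(pm, p)) < 2) {
        stopf("need at least 2 '%s' samples for population statistics", p)
      }
    }
  }
  invisible(TRUE)
}
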