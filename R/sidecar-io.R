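#' Read a population map from a two-column TSV
#'
#' File format: tab-delimited, two columns `sample` and `population`
#' (header optional, detected), population one of `west`, `east`, `admixed`.
#'
#' @param path TSV path.
#' @return a [population_map()].
#' @export
read_population_map <- function(path) {
  tab <- read_tsv_checked(path, 2L, c("sample", "population"))
  population_map(tab[[1]], tab[[2]])
}

#' Read locus-to-gene link, candidate gene-set and posterior-sample tables
#'
#' The three sidecar tables accompanying a SNP panel:
#' * gene links: TSV with columns `locus_id`, `gene_id`, `side` (`up`/`down`),
#'   `evalue` — the nearest annotated gene up- and downstream of each locus,
#'   typically from a BLAST-style orthology search (consumed pre-computed);
#' * candidate sets: TSV with columns `set_name`, `gene_id` — named a priori
#'   gene sets for enrichment testing;
#' * posterior samples: TSV with header `theta_west`, `theta_east`,
#'   `theta_anc`, `tau` — posterior draws of the per-site population mutation
#'   parameters and the divergence time (in expected substitutions per site)
#'   of the two-population isolation model, used to parameterise neutral
#'   posterior-predictive simulation.
#'
#' @param gene_links_path,candidate_sets_path,posterior_path file paths.
#' @param locus_ids optional character vector of known locus ids; gene links
#'   referencing loci outside this set raise an error naming the offenders.
#' @return list with elements `gene_links` (data.frame), `candidate_sets`
#'   (named list of character vectors) and `posterior` (data.frame of class
#'   `posterior_sample_set`).
#' @export
read_sidecar_tables <- function(gene_links_path, candidate_sets_path,
                                posterior_path, locus_ids = NULL) {
  gl <- read_gene_links(gene_links_path, locus_ids)
  cs <- read_candidate_sets(candidate_sets_path)
  ps <- read_posterior_samples(posterior_path)
  list(gene_links = gl, candidate_sets = cs, posterior = ps)
}

#' @rdname read_sidecar_tables
#' @export
read_gene_links <- function(gene_links_path, locus_ids = NULL) {
  tab <- read_tsv_checked(gene_links_path, 4L,
                          c("locus_id", "gene_id", "side", "evalue"))
  names(tab) <- c("locus_id", "gene_id", "side", "evalue")
  bad_side <- !tab$side %in% c("up", "down")
  if (any(bad_side)) {
    stopf("gene links: invalid side at line(s) %s (must be 'up' or 'down')",
          paste(utils::head(which(bad_side) + 1L, 5), collapse = ", "))
  }
  tab$evalue <- as.numeric(tab$evalue)
  if (!is.null(locus_ids)) {
    unknown <- setdiff(tab$locus_id, locus_ids)
    if (length(unknown) > 0) {
      stopf("gene links reference unknown locus id(s): %s",
            paste(utils::head(unknown, 10), collapse = ", "))
    }
  }
  tab
}

#' @rdname read_sidecar_tables
#' @export
read_candidate_sets <- function(candidate_sets_path) {
  first <- readLines(candidate_sets_path, n = 1L)
  if (length(first) == 0L) {
    warnf("candidate set file '%s' is empty; no sets loaded", candidate_sets_path)
    return(list())
  }
  tab <- read_tsv_checked(candidate_sets_path, 2L, c("set_name", "gene_id"))
  names(tab) <- c("set_name", "gene_id")
  sets <- lapply(split(tab$gene_id, tab$set_name), function(g) unique(g))
  if (any(lengths(sets) == 0)) stopf("candidate set with no genes")
  sets
}

#' @rdname read_sidecar_tables
#' @export
read_posterior_samples <- function(posterior_path) {
  tab <- utils::read.delim(posterior_path, stringsAsFactors = FALSE)
  need <- c("theta_west", "theta_east", "theta_anc", "tau")
  if (!all(need %in% names(tab))) {
    stopf("posterior table must have header columns %s", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  posterior_sample_set(tab$theta_west, tab$theta_east, tab$theta_anc, tab$tau)
}

#' Construct a posterior sample set
#'
#' Rows of (theta_west, theta_east, theta_anc, tau) parameterising the
#' neutral two-population isolation coalescent; typically posterior draws
#' from a species-tree analysis of the parental populations.
#'
#' @param theta_west,theta_east per-site population mutation parameters of
#'   the two parental populations.
#' @param theta_anc same, for the ancestral population.
#' @param tau divergence time in expected substitutions per site.
#' @return data.frame of class `posterior_sample_set`.
#' @export
posterior_sample_set <- function(theta_west, theta_east, theta_anc, tau) {
  tab <- data.frame(theta_west = as.numeric(theta_west),
                    theta_east = as.numeric(theta_east),
                    theta_anc = as.numeric(theta_anc),
                    tau = as.numeric(tau))
  if (nrow(tab) < 1L) stopf("posterior sample set must have at least one row")
  if (any(is.na(as.matrix(tab)))) stopf("posterior sample set contains NA")
  if (any(as.matrix(tab) < 0)) stopf("theta and tau must be non-negative")
  class(tab) <- c("posterior_sample_set", "data.frame")
  tab
}

# strict TSV reader: every row must have exactly n_cols fields; header row
# (matching expected names) is consumed if present.
read_tsv_checked <- function(path, n_cols, expected_header) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("empty table: '%s'", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (identical(tolower(trimws(parts[[1]])), expected_header)) start <- 2L
  out <- vector("list", n_cols)
  if (length(lines) < start) stopf("no data rows in '%s'", path)
  for (i in seq(start, length(parts))) {
    if (length(parts[[i]]) != n_cols) {
      stopf("malformed row at line %d of '%s': expected %d fields, found %d",
            i, path, n_cols, length(parts[[i]]))
    }
  }
  body <- parts[seq(start, length(parts))]
  tab <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(tab) <- expected_header
  tab
}
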