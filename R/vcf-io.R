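#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (v4.x) and returns a [genotype_matrix()] of alternate-allele
#' counts. Only biallelic SNP records (single-base REF and ALT) whose QUAL
#' exceeds `qual_min` are retained. Missing genotype calls, including
#' half-missing calls such as `./1`, are stored as `NA`. Records with missing
#' QUAL are dropped unless `qual_min` is `-Inf`.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @param qual_min QUAL threshold; records are kept when `QUAL > qual_min`.
#'   The conventional hard filter for RADseq variant calls is 30.
#' @return A [genotype_matrix()]. Locus ids are taken from the VCF ID column
#'   where present, otherwise `chrom:pos`.
#' @export
read_vcf_genotypes <- function(vcf_path, qual_min = 30) {
  if (!file.exists(vcf_path)) stopf("cannot read VCF: no such file '%s'", vcf_path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(vcf_path),
    error = function(e) stopf("failed to parse VCF '%s': %s", vcf_path, conditionMessage(e))
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  qual <- rr$QUAL
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  is_snp <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  pass_qual <- if (is.infinite(qual_min) && qual_min < 0) {
    rep(TRUE, length(qual))
  } else {
    !is.na(qual) & qual > qual_min
  }
  keep <- which(is_snp & pass_qual)
  if (length(keep) == 0) {
    stopf("no biallelic SNP records with QUAL > %s in '%s'", qual_min, vcf_path)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF '%s' has no GT field", vcf_path)
  gt <- gt[keep, , drop = FALSE]
  ids <- rownames(vcf)[keep]
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(chrom[blank], ":", pos[blank])
  geno <- apply(gt, c(1, 2), gt_to_alt_count)
  geno <- t(geno)  # samples x loci
  colnames(geno) <- ids
  meta <- data.frame(locus_id = ids, chrom = chrom, pos = pos,
                     ref = ref[keep], alt = alt1[keep],
                     stringsAsFactors = FALSE)
  genotype_matrix(geno, meta)
}

# "0/1", "0|1", "1/1", "./.", ".", "./1" -> alt-allele count or NA
gt_to_alt_count <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_integer_)
  al <- strsplit(g, "[/|]")[[1]]
  if (any(al == ".") || length(al) != 2) return(NA_integer_)
  sum(al == "1")
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT genotypes; round-trips through
#' [read_vcf_genotypes()] (with `qual_min = -Inf`) to identical genotype
#' codes and locus ids. All records are written with QUAL 99.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path) {
  meta <- gm$locus_meta
  g <- gm$genotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hybridclines",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (i in seq_len(nrow(meta))) {
    gt <- ifelse(is.na(g[, i]), "./.", code[as.character(g[, i])])
    writeLines(paste(c(meta$chrom[i], meta$pos[i], meta$locus_id[i],
                       meta$ref[i], meta$alt[i], "99", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
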