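#' Read and write tab-delimited study files
#'
#' All tabular interchange formats are tab-delimited text with a header
#' row: summary statistics (`snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pvalue`; column names configurable on
#' read), phenotype tables, score tables, and locus definitions
#' (BED-like: `chrom`, `start`, `end`, `locus_id`, `lead_p`).
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(snp_id = "SNP", pvalue = "P")`.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @name cpep_io
NULL

#' @rdname cpep_io
#' @export
read_sumstats <- function(path, col_map = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(d)[names(d) == col_map[[canon]]] <- canon
    }
  }
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "pvalue")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop_cpep("Sumstats file lacks column(s): ", fmt_ids(miss))
  d$chrom <- as.character(d$chrom)
  d
}

#' @rdname cpep_io
#' @param sumstats Tibble of summary statistics.
#' @export
write_sumstats <- function(sumstats, path) {
  readr::write_tsv(sumstats, path)
  invisible(sumstats)
}

#' @rdname cpep_io
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname cpep_io
#' @param phenotypes Phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(phenotypes)
}

#' @rdname cpep_io
#' @param loci Loci tibble from [designate_loci()].
#' @export
write_loci_bed <- function(loci, path) {
  loci |>
    dplyr::transmute(.data$chrom, start = .data$start, end = .data$end,
                     .data$locus_id, .data$lead_p) |>
    readr::write_tsv(path)
  invisible(loci)
}

#' Write / read a dosage matrix as delimited text
#'
#' Plain-text dosage interchange: first column `individual_id`, one
#' column per SNP.
#'
#' @param dosage Numeric matrix (individuals x SNPs).
#' @param path File path.
#' @return The matrix (reader) or input invisibly (writer).
#' @export
write_dosage_matrix <- function(dosage, path) {
  d <- as_tibble(as.data.frame(dosage), rownames = "individual_id")
  readr::write_tsv(d, path)
  invisible(dosage)
}

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write / read genotype dosages as VCF
#'
#' Writes a minimal VCFv4.2 file with a `DS` (dosage) FORMAT field, one
#' sample column per individual, and reads it back (preferring `DS`,
#' falling back to `GT` allele counts). Reading uses the `vcfR` package
#' when available.
#'
#' @param genotypes A list with `dosage` and `snp_meta` as returned by
#'   [simulate_genotypes()].
#' @param path Output path (plain text; use a `.vcf` extension).
#' @return The input invisibly (writer); for the reader, a list with
#'   `dosage` and `snp_meta`.
#' @export
write_dosage_vcf <- function(genotypes, path) {
  meta <- genotypes$snp_meta
  dos <- genotypes$dosage
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(meta)), function(i) {
    paste(c(meta$chrom[i], meta$pos[i], meta$snp_id[i],
            meta$other_allele[i], meta$effect_allele[i], ".", "PASS",
            ".", "DS", format(dos[, i], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(genotypes)
}

#' @rdname write_dosage_vcf
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_cpep("Reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  meta <- tibble(
    snp_id = vcfR::getID(v),
    chrom = as.character(vcfR::getCHROM(v)),
    pos = vcfR::getPOS(v),
    effect_allele = vcfR::getALT(v),
    other_allele = vcfR::getREF(v)
  )
  dosage <- t(ds)
  colnames(dosage) <- meta$snp_id
  list(dosage = dosage, snp_meta = meta)
}

#' Write / read a GRM in a delimited, binary-free format
#'
#' Two files: `<stem>.ids` (one individual id per line) and
#' `<stem>.grm.tsv` (the matrix, tab-delimited, no header).
#'
#' @param grm Symmetric GRM matrix with ids as dimnames.
#' @param stem Path stem for the two output files.
#' @return The GRM (reader) or input invisibly (writer).
#' @export
write_grm <- function(grm, stem) {
  writeLines(rownames(grm), paste0(stem, ".ids"))
  utils::write.table(grm, paste0(stem, ".grm.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(grm)
}

#' @rdname write_grm
#' @export
read_grm <- function(stem) {
  ids <- readLines(paste0(stem, ".ids"))
  m <- as.matrix(utils::read.table(paste0(stem, ".grm.tsv"), sep = "\t"))
  dimnames(m) <- list(ids, ids)
  m
}

#' Record synthetic ground truth as YAML
#'
#' @param truth A [synthetic_truth()] object.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(
    list(
      hla_locus = truth$hla_locus,
      h2_true = truth$h2_true,
      regression_truth = as.list(truth$regression_truth),
      causal_effects = purrr::transpose(as.list(truth$causal_effects))
    ),
    path
  )
  invisible(truth)
}
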