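#' Write genotypes as a minimal VCFv4.2
#'
#' Emits CHROM/POS/REF/ALT plus per-sample GT fields (`0/0`, `0/1`, `1/1`,
#' `./.` for missing).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  gm <- genotypes
  gt_str <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
  ok <- !is.na(gm$dosage)
  gt[ok] <- gt_str[gm$dosage[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$dosage)), collapse = "\t"))
  body <- apply(cbind(gm$sites$supercontig, gm$sites$position,
                      site_id(gm$sites$supercontig, gm$sites$position),
                      gm$sites$ref, gm$sites$alt, ".", ".", ".", "GT", gt),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a VCF via vcfR and converts GT fields to alternate-allele dosage
#' (count of non-reference alleles; missing genotypes become NA).
#'
#' @param path VCF file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) {
    g <- gsub("|", "/", gt[, j], fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    dosage[, j] <- vapply(parts, function(p) {
      if (length(p) == 0 || any(p == ".") || anyNA(p)) NA_integer_
      else sum(p != "0")
    }, integer(1))
  }
  fix <- vcfR::getFIX(v)
  sites <- data.frame(supercontig = fix[, "CHROM"],
                      position = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  genotype_matrix(dosage, sites)
}

#' Write / read the phenotype table
#'
#' Tab-delimited, one row per individual: `sample`, `population`, one
#' column per insecticide.
#'
#' @param phenotypes phenotype table.
#' @param path TSV file.
#' @return `path` / the phenotype table.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(out)))
    stopf("phenotype TSV needs 'sample' and 'population' columns")
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write / read the depth-count matrix
#'
#' Tab-delimited: amplicon metadata columns (`amplicon_id`, `gene_id`,
#' `length`, and any others present) followed by one count column per
#' sample.
#'
#' @param depths a [depth_matrix()].
#' @param path TSV file.
#' @return `path` / a [depth_matrix()].
#' @export
write_depths_tsv <- function(depths, path) {
  stopifnot(inherits(depths, "depth_matrix"))
  utils::write.table(cbind(depths$amplicons, as.data.frame(depths$counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depths_tsv
#' @export
read_depths_tsv <- function(path) {
  if (!file.exists(path)) stopf("depth file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(
    c("amplicon_id", "gene_id", "supercontig", "start", "end", "pool",
      "length"), names(tab))
  counts <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  depth_matrix(counts, tab[, meta_cols, drop = FALSE])
}

#' Write amplicon intervals as BED
#'
#' BED is 0-based half-open; the amplicon table is 1-based inclusive, so
#' starts are shifted down by one.
#'
#' @param amplicons amplicon table (see [simulate_amplicons()]).
#' @param path BED file.
#' @return `path` / an amplicon table (1-based inclusive).
#' @export
write_amplicons_bed <- function(amplicons, path) {
  bed <- data.frame(chrom = amplicons$supercontig,
                    start = amplicons$start - 1L, end = amplicons$end,
                    name = amplicons$amplicon_id,
                    score = amplicons$pool %||% 0L,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_amplicons_bed
#' @export
read_amplicons_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:5] <- c("supercontig", "start", "end", "amplicon_id", "pool")
  data.frame(amplicon_id = bed$amplicon_id,
             gene_id = sub("_amp[0-9]+$", "", bed$amplicon_id),
             supercontig = bed$supercontig,
             start = bed$start + 1L, end = bed$end, pool = bed$pool,
             length = bed$end - bed$start, stringsAsFactors = FALSE)
}

#' Write the panel gene table as TSV
#'
#' One row per exon (`gene_id`, `supercontig`, `strand`, `exon_start`,
#' `exon_end`), readable by [read_panel_tsv()].
#'
#' @param panel a [gene_panel()].
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  rows <- lapply(panel$genes, function(g)
    data.frame(gene_id = g$gene_id, supercontig = g$supercontig,
               strand = g$strand, exon_start = g$exons[, 1],
               exon_end = g$exons[, 2], stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Cq table
#'
#' Tab-delimited with columns `sample`, `gene`, `role`
#' (`target`/`reference`), `replicate`, `cq`.
#'
#' @param path TSV file.
#' @return data frame suitable for [qpcr_fold_change()].
#' @export
read_qpcr_tsv <- function(path) {
  if (!file.exists(path)) stopf("qPCR file not found: %s", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "role", "replicate", "cq")
  if (!all(need %in% names(out)))
    stopf("qPCR TSV needs columns: %s", paste(need, collapse = ", "))
  out
}
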