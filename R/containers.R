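#' Genotype matrix container
#'
#' Per-site, per-individual alternate-allele dosage (0/1/2, NA missing)
#' together with the site table (supercontig, 1-based position, reference
#' and alternate alleles).
#'
#' @param dosage integer matrix, sites x samples; rownames are set to
#'   `supercontig:position`, colnames are sample IDs.
#' @param sites data frame with columns `supercontig`, `position`, `ref`,
#'   `alt` (rows aligned with `dosage`).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(sites),
            all(c("supercontig", "position", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(dosage))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stopf("dosage values must be 0/1/2 or NA")
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- site_id(sites$supercontig, sites$position)
  rownames(sites) <- NULL
  structure(list(dosage = dosage, sites = sites), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d SNPs x %d samples (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read-depth matrix container
#'
#' Per-amplicon, per-sample read counts plus amplicon metadata. Derived
#' RPKM / ZRPKM / SVD-ZRPKM layers are computed on demand by [rpkm()],
#' [zrpkm()] and [svd_denoise()] (see [cnv_scan()]).
#'
#' @param counts non-negative integer matrix, amplicons x samples.
#' @param amplicons data frame with at least `amplicon_id`, `gene_id`,
#'   `length` (bp); rows aligned with `counts`.
#' @return object of class `depth_matrix`.
#' @export
depth_matrix <- function(counts, amplicons) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(amplicons),
            all(c("amplicon_id", "gene_id", "length") %in% names(amplicons)),
            nrow(amplicons) == nrow(counts))
  if (any(counts < 0)) stopf("negative read counts")
  storage.mode(counts) <- "integer"
  rownames(counts) <- amplicons$amplicon_id
  rownames(amplicons) <- NULL
  structure(list(counts = counts, amplicons = amplicons),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("Depth matrix: %d amplicons (%d genes) x %d samples, mean depth %.0fx\n",
              nrow(x$counts), length(unique(x$amplicons$gene_id)),
              ncol(x$counts), mean(x$counts)))
  invisible(x)
}

#' @export
dim.depth_matrix <- function(x) dim(x$counts)
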