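#' Annotate one SNP against the gene panel
#'
#' Resolves region (exon/intron/flank/intergenic), and for exonic sites with
#' a coding sequence available, the codon number (counted 5'->3' in gene
#' orientation across the concatenated exons), position within the codon,
#' reference and alternate codons in gene orientation, translated amino
#' acids, and the coding effect. For genes on the minus strand the supplied
#' alleles (which follow the supercontig's plus strand, as in a VCF) are
#' complemented before substitution, so emitted codons are always in gene
#' orientation. If the supplied reference allele disagrees with the coding
#' sequence the annotation is flagged (`ref_mismatch`), never silently
#' accepted; the coding sequence is taken as authoritative for the codon.
#'
#' @param panel a [gene_panel()].
#' @param supercontig,position site coordinates (1-based).
#' @param ref,alt reference and alternate alleles on the supercontig plus
#'   strand; `alt` may contain several alleles separated by commas, giving
#'   one annotation row per alternate.
#' @return data frame with one row per (overlapping gene, alternate allele):
#'   columns `supercontig`, `position`, `ref`, `alt`, `gene_id`, `region`,
#'   `codon_number`, `position_in_codon`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `effect` (`synonymous`, `nonsynonymous`,
#'   `stop_gained`, `stop_lost`, or NA outside annotatable exons) and
#'   `ref_mismatch`.
#' @export
annotate_snp <- function(panel, supercontig, position, ref, alt) {
  stopifnot(inherits(panel, "gene_panel"))
  ref <- toupper(ref); alts <- toupper(strsplit(alt, ",", fixed = TRUE)[[1]])
  if (!all(strsplit(paste0(ref, paste(alts, collapse = "")), "")[[1]] %in%
           c("A", "C", "G", "T")))
    stopf("alleles must be over A/C/G/T at %s:%d", supercontig, position)
  cls <- classify_site(panel, supercontig, position)
  rows <- list()
  for (i in seq_len(nrow(cls))) {
    for (a in alts) {
      row <- data.frame(
        supercontig = supercontig, position = as.integer(position),
        ref = ref, alt = a, gene_id = cls$gene_id[i], region = cls$region[i],
        codon_number = NA_integer_, position_in_codon = NA_integer_,
        ref_codon = NA_character_, alt_codon = NA_character_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        effect = NA_character_, ref_mismatch = FALSE,
        stringsAsFactors = FALSE)
      g <- if (!is.na(cls$gene_id[i])) panel$genes[[cls$gene_id[i]]] else NULL
      if (!is.null(g) && cls$region[i] == "exon" && !is.null(g[["cds"]])) {
        idx <- cds_index(g, position) - g$cds_offset
        if (!is.na(idx) && idx >= 1L) {
          codon_number <- (idx - 1L) %/% 3L + 1L
          pos_in_codon <- (idx - 1L) %% 3L + 1L
          codon <- codon_at(panel, g$gene_id, codon_number)
          ref_or <- if (g$strand == "+") ref else complement_base(ref)
          alt_or <- if (g$strand == "+") a else complement_base(a)
          expected <- substr(codon, pos_in_codon, pos_in_codon)
          alt_codon <- codon
          substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_or
          ref_aa <- translate_codon(codon)
          alt_aa <- translate_codon(alt_codon)
          effect <-
            if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*") "stop_gained"
            else if (ref_aa == "*") "stop_lost"
            else "nonsynonymous"
          row$codon_number <- codon_number
          row$position_in_codon <- pos_in_codon
          row$ref_codon <- codon; row$alt_codon <- alt_codon
          row$ref_aa <- ref_aa; row$alt_aa <- alt_aa
          row$effect <- effect
          row$ref_mismatch <- !identical(expected, ref_or)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Annotate a table of SNP sites
#'
#' Vector interface over [annotate_snp()].
#'
#' @param panel a [gene_panel()].
#' @param sites data frame with columns `supercontig`, `position`, `ref`,
#'   `alt` (comma-separated alternates allowed).
#' @return row-bound annotation table (one row per site x gene x alternate).
#' @export
annotate_snps <- function(panel, sites) {
  stopifnot(all(c("supercontig", "position", "ref", "alt") %in% names(sites)))
  out <- lapply(seq_len(nrow(sites)), function(i)
    annotate_snp(panel, sites$supercontig[i], sites$position[i],
                 sites$ref[i], sites$alt[i]))
  do.call(rbind, out)
}

#' Summarize coding effects over an annotated SNP set
#'
#' Counts synonymous / nonsynonymous (and stop-affecting) exonic SNPs and
#' their percentages. A site with two alternate alleles of differing effect
#' contributes once to each effect class and is flagged. Percentages are
#' reported to one decimal (half-up).
#'
#' @param annotations output of [annotate_snps()].
#' @param merge_stops fold `stop_gained`/`stop_lost` into `nonsynonymous`
#'   (default FALSE).
#' @return data frame with columns `effect`, `count`, `pct`; attributes
#'   `n_effect_snps` (denominator), `multi_effect_sites` (site IDs whose
#'   alternates disagree) and `empty` (TRUE when there was nothing to count,
#'   in which case percentages are reported as 0).
#' @export
summarize_effects <- function(annotations, merge_stops = FALSE) {
  ann <- annotations[!is.na(annotations$effect), , drop = FALSE]
  eff_levels <- c("synonymous", "nonsynonymous", "stop_gained", "stop_lost")
  if (merge_stops && nrow(ann)) {
    ann$effect[ann$effect %in% c("stop_gained", "stop_lost")] <- "nonsynonymous"
    eff_levels <- c("synonymous", "nonsynonymous")
  }
  # one vote per (site, gene, effect): multi-allelic sites with equal-effect
  # alternates count once; differing effects count once per effect
  key <- unique(ann[c("supercontig", "position", "gene_id", "effect")])
  sid <- site_id(key$supercontig, key$position)
  multi <- unique(sid[duplicated(paste(sid, key$gene_id))])
  n <- nrow(key)
  counts <- table(factor(key$effect, levels = eff_levels))
  pct <- if (n > 0) round_half_up(100 * as.numeric(counts) / n, 1) else
    rep(0, length(counts))
  out <- data.frame(effect = names(counts), count = as.integer(counts),
                    pct = pct, stringsAsFactors = FALSE)
  attr(out, "n_effect_snps") <- n
  attr(out, "multi_effect_sites") <- multi
  attr(out, "empty") <- n == 0
  out
}
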