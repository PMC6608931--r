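#' Gene panel model
#'
#' A `gene_panel` holds the targeted-sequencing gene panel: the supercontigs
#' (unplaced assembly scaffolds) the genes live on, one model per gene
#' (strand, ordered exon intervals in supercontig coordinates, optionally the
#' coding sequence assembled 5'->3' in gene orientation), and the flanking
#' window length sequenced on either side of each gene. It is the coordinate
#' authority for all downstream SNP annotation. All external coordinates are
#' 1-based inclusive.
#'
#' @param genes list of gene models, each a list with elements `gene_id`,
#'   `supercontig`, `strand` (`"+"` or `"-"`), `exons` (two-column matrix of
#'   1-based inclusive start/end, sorted, non-overlapping), and optionally
#'   `cds` (coding sequence in gene orientation) and `cds_offset` (bases to
#'   trim from the 5' end of the concatenated exons before codon numbering,
#'   default 0).
#' @param supercontigs data frame with columns `name` and `length`.
#' @param flank_length flanking window in bp on each side of a gene span
#'   (default 150).
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(genes, supercontigs, flank_length = 150L) {
  stopifnot(is.list(genes), is.data.frame(supercontigs))
  if (!all(c("name", "length") %in% names(supercontigs)))
    stopf("supercontigs needs columns 'name' and 'length'")
  if (anyDuplicated(supercontigs$name))
    stopf("duplicate supercontig names")
  if (any(supercontigs$length < 0)) stopf("negative supercontig length")
  flank_length <- as.integer(flank_length)
  if (flank_length < 0) stopf("flank_length must be >= 0")

  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate gene ID: %s", ids[duplicated(ids)][1])

  genes <- lapply(genes, function(g) {
    g$cds_offset <- as.integer(g$cds_offset %||% 0L)
    if (!is_one_string(g$gene_id)) stopf("gene_id must be a string")
    if (!g$strand %in% c("+", "-"))
      stopf("gene %s: strand must be '+' or '-'", g$gene_id)
    sc <- match(g$supercontig, supercontigs$name)
    if (is.na(sc))
      stopf("gene %s: unknown supercontig '%s'", g$gene_id, g$supercontig)
    ex <- g$exons
    if (is.data.frame(ex)) ex <- as.matrix(ex)
    storage.mode(ex) <- "integer"
    if (is.null(dim(ex)) || ncol(ex) != 2)
      stopf("gene %s: exons must be a 2-column matrix", g$gene_id)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 2] < ex[, 1]))
      stopf("gene %s: exon end before start", g$gene_id)
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
      stopf("gene %s: overlapping exons", g$gene_id)
    if (any(ex[, 1] < 1) || any(ex[, 2] > supercontigs$length[sc]))
      stopf("exon outside supercontig bounds in gene %s", g$gene_id)
    colnames(ex) <- c("start", "end")
    g$exons <- ex
    if (!is.null(g[["cds"]])) {
      g[["cds"]] <- toupper(g[["cds"]])
      exlen <- sum(ex[, 2] - ex[, 1] + 1L)
      if (nchar(g[["cds"]]) != exlen)
        stopf("gene %s: coding sequence length %d != total exon length %d",
              g$gene_id, nchar(g[["cds"]]), exlen)
      if ((exlen - g$cds_offset) %% 3L != 0L)
        stopf("gene %s: CDS length after offset not divisible by 3", g$gene_id)
    }
    g
  })
  names(genes) <- ids

  structure(
    list(supercontigs = supercontigs, genes = genes,
         flank_length = flank_length),
    class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel: %d genes on %d supercontigs (flank %d bp)\n",
              length(x$genes), nrow(x$supercontigs), x$flank_length))
  n_cds <- sum(vapply(x$genes, function(g) !is.null(g[["cds"]]), logical(1)))
  cat(sprintf("  coding sequence available for %d genes\n", n_cds))
  invisible(x)
}

# total exon length of one gene model
exon_length <- function(gene) sum(gene$exons[, 2] - gene$exons[, 1] + 1L)

# gene span (outermost exon bounds) on the supercontig
gene_span <- function(gene) c(min(gene$exons[, 1]), max(gene$exons[, 2]))

#' Load a gene panel from a TSV gene table
#'
#' Reads a 5-column table (`gene_id`, `supercontig`, `strand`, `exon_start`,
#' `exon_end`; one row per exon, 1-based inclusive). Supercontig lengths come
#' from `supercontig_lengths` when supplied, otherwise each supercontig is
#' given a length just beyond its outermost annotated exon plus the flank.
#' Coding sequences may be supplied as a FASTA of supercontig sequences
#' (exons are cut out and stitched 5'->3' in gene orientation) via
#' `supercontig_fasta`.
#'
#' @param path TSV file with a header line.
#' @param flank_length flanking window in bp (default 150).
#' @param supercontig_lengths optional named vector of supercontig lengths.
#' @param supercontig_fasta optional FASTA path with supercontig sequences.
#' @return A [gene_panel()].
#' @export
read_panel_tsv <- function(path, flank_length = 150L,
                           supercontig_lengths = NULL,
                           supercontig_fasta = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "supercontig", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(tab)))
    stopf("panel TSV needs columns: %s", paste(need, collapse = ", "))
  seqs <- NULL
  if (!is.null(supercontig_fasta)) {
    ss <- Biostrings::readDNAStringSet(supercontig_fasta)
    seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  by_gene <- split(tab, factor(tab$gene_id, levels = unique(tab$gene_id)))
  genes <- lapply(by_gene, function(d) {
    if (length(unique(d$supercontig)) != 1 || length(unique(d$strand)) != 1)
      stopf("gene %s: inconsistent supercontig/strand across exon rows",
            d$gene_id[1])
    g <- list(gene_id = d$gene_id[1], supercontig = d$supercontig[1],
              strand = d$strand[1],
              exons = cbind(start = d$exon_start, end = d$exon_end))
    if (!is.null(seqs) && g$supercontig %in% names(seqs)) {
      ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
      pieces <- substring(seqs[[g$supercontig]], ex[, 1], ex[, 2])
      cds <- paste(pieces, collapse = "")
      if (g$strand == "-") cds <- revcomp(cds)
      g[["cds"]] <- cds
    }
    g
  })
  sc_names <- unique(tab$supercontig)
  if (is.null(supercontig_lengths)) {
    lens <- vapply(sc_names, function(s) {
      max(tab$exon_end[tab$supercontig == s]) + as.integer(flank_length) + 1000L
    }, numeric(1))
  } else {
    if (!all(sc_names %in% names(supercontig_lengths)))
      stopf("supercontig_lengths missing some supercontigs")
    lens <- supercontig_lengths[sc_names]
  }
  gene_panel(genes, data.frame(name = sc_names, length = as.integer(lens)),
             flank_length = flank_length)
}

#' Load a gene panel from GFF3
#'
#' Uses exon features grouped by their `Parent` (or `ID`) attribute.
#' Requires the rtracklayer package.
#'
#' @inheritParams read_panel_tsv
#' @param path GFF3 file.
#' @return A [gene_panel()].
#' @export
read_panel_gff3 <- function(path, flank_length = 150L,
                            supercontig_lengths = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("GFF3 loading requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr$type <- tolower(as.character(gr$type))
  ex <- gr[gr$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stopf("no exon features in %s", path)
  parent <- ex$Parent
  if (is.list(parent))  # GFF3 Parent is multi-valued in general
    parent <- vapply(parent, function(p) paste(p, collapse = ","), character(1))
  if (is.null(parent) || all(is.na(parent) | parent == ""))
    parent <- as.character(ex$ID)
  d <- data.frame(gene_id = as.character(parent),
                  supercontig = as.character(ex$seqnames),
                  strand = as.character(ex$strand),
                  exon_start = ex$start,
                  exon_end = ex$end,
                  stringsAsFactors = FALSE)
  d$strand[!d$strand %in% c("+", "-")] <- "+"
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_panel_tsv(tmp, flank_length = flank_length,
                 supercontig_lengths = supercontig_lengths)
}

#' Classify a genomic site against the panel
#'
#' Labels a supercontig position as exon, intron or flank of each gene whose
#' window it falls in, or intergenic. Overlapping genes each contribute a row
#' (first row follows panel gene order, used for reporting).
#'
#' @param panel a [gene_panel()].
#' @param supercontig supercontig name (must exist in the panel).
#' @param position 1-based position.
#' @return data frame with columns `supercontig`, `position`, `gene_id`
#'   (NA for intergenic) and `region` (one of `"exon"`, `"intron"`,
#'   `"flank"`, `"intergenic"`).
#' @export
classify_site <- function(panel, supercontig, position) {
  stopifnot(inherits(panel, "gene_panel"))
  position <- as.integer(position)
  if (position < 1) stopf("position must be >= 1")
  if (!supercontig %in% panel$supercontigs$name)
    stopf("unknown supercontig '%s'", supercontig)
  rows <- list()
  for (g in panel$genes) {
    if (g$supercontig != supercontig) next
    span <- gene_span(g)
    region <- NULL
    if (position >= span[1] && position <= span[2]) {
      inx <- any(position >= g$exons[, 1] & position <= g$exons[, 2])
      region <- if (inx) "exon" else "intron"
    } else if (position >= span[1] - panel$flank_length &&
               position <= span[2] + panel$flank_length) {
      region <- "flank"
    }
    if (!is.null(region))
      rows[[length(rows) + 1L]] <-
        data.frame(supercontig = supercontig, position = position,
                   gene_id = g$gene_id, region = region,
                   stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(supercontig = supercontig, position = position,
                      gene_id = NA_character_, region = "intergenic",
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# 1-based index of a supercontig position within the concatenated exons of a
# gene, measured 5'->3' in gene orientation; NA when not exonic.
cds_index <- function(gene, position) {
  ex <- gene$exons
  lens <- ex[, 2] - ex[, 1] + 1L
  hit <- which(position >= ex[, 1] & position <= ex[, 2])
  if (length(hit) == 0) return(NA_integer_)
  plus_idx <- sum(lens[seq_len(hit - 1L)]) + (position - ex[hit, 1]) + 1L
  if (gene$strand == "+") plus_idx else sum(lens) - plus_idx + 1L
}

#' Look up a codon of a gene
#'
#' Returns the `codon_number`-th codon of the coding sequence (gene
#' orientation, after the CDS frame offset).
#'
#' @param panel a [gene_panel()].
#' @param gene_id gene identifier in the panel.
#' @param codon_number 1-based codon index.
#' @return A 3-character codon string.
#' @export
codon_at <- function(panel, gene_id, codon_number) {
  g <- panel$genes[[gene_id]]
  if (is.null(g)) stopf("gene '%s' not in panel", gene_id)
  if (is.null(g[["cds"]])) stopf("gene '%s' has no coding sequence", gene_id)
  start <- g$cds_offset + 3L * (codon_number - 1L) + 1L
  if (start + 2L > nchar(g[["cds"]]))
    stopf("gene '%s' has no codon %d", gene_id, codon_number)
  substr(g[["cds"]], start, start + 2L)
}
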