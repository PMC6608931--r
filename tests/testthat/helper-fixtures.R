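# Fixtures and independent oracles used across test files. Oracles are
# deliberately naive (enumeration / brute force) and share no code with the
# package internals they check.

# ---- panel fixtures ------------------------------------------------------

# small two-gene panel: one plus-strand, one minus-strand gene with known CDS
toy_panel <- function(flank = 150L) {
  gene_panel(
    list(
      list(gene_id = "GPLUS", supercontig = "sc1", strand = "+",
           exons = cbind(start = c(1000L, 1300L), end = c(1098L, 1398L)),
           cds = paste(rep("GCTTTAAAC", 22), collapse = "")),
      list(gene_id = "GMINUS", supercontig = "sc1", strand = "-",
           exons = cbind(start = c(2000L, 2200L), end = c(2089L, 2301L)),
           cds = paste(rep("ATGGCA", 32), collapse = ""))),
    data.frame(name = "sc1", length = 5000L), flank_length = flank)
}

# gene whose CDS places a chosen codon at a chosen number; returns the panel
# and the supercontig positions of that codon's three bases
panel_with_codon <- function(gene_id, codon, codon_number, strand = "+",
                             n_exons = 6L) {
  n_codons <- codon_number + 2L
  cds <- paste(c(rep("GCT", codon_number - 1L), codon,
                 rep("GCT", n_codons - codon_number)), collapse = "")
  len <- nchar(cds)
  # split the CDS into n_exons chunks (multiples of 1 bp, contiguous here
  # with 50 bp introns)
  bounds <- round(seq(0, len, length.out = n_exons + 1L))
  ex_len <- diff(bounds)
  starts <- 1000L + cumsum(c(0L, head(ex_len, -1) + 50L))
  ends <- starts + ex_len - 1L
  exons <- cbind(start = starts, end = ends)
  panel <- gene_panel(
    list(list(gene_id = gene_id, supercontig = "scX", strand = strand,
              exons = exons, cds = cds)),
    data.frame(name = "scX", length = max(ends) + 2000L), flank_length = 150L)
  # supercontig positions of the codon bases, gene orientation
  idx <- (codon_number - 1L) * 3L + 1:3
  pos <- vapply(idx, function(i) oracle_supercontig_pos(exons, strand, i),
                integer(1))
  list(panel = panel, positions = pos, cds = cds)
}

# interval-arithmetic oracle: supercontig position of the i-th CDS base
# (gene orientation) given exons and strand
oracle_supercontig_pos <- function(exons, strand, i) {
  bases <- unlist(lapply(seq_len(nrow(exons)),
                         function(e) seq(exons[e, 1], exons[e, 2])))
  if (strand == "-") bases <- rev(bases)
  as.integer(bases[i])
}

# brute-force region classification by scanning every interval
oracle_classify <- function(panel, sc, pos) {
  labs <- character(0); genes <- character(0)
  for (g in panel$genes) {
    if (g$supercontig != sc) next
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    lab <- NA_character_
    for (e in seq_len(nrow(g$exons)))
      if (pos >= g$exons[e, 1] && pos <= g$exons[e, 2]) lab <- "exon"
    if (is.na(lab) && pos >= span[1] && pos <= span[2]) lab <- "intron"
    if (is.na(lab) && pos >= span[1] - panel$flank_length &&
        pos <= span[2] + panel$flank_length) lab <- "flank"
    if (!is.na(lab)) { labs <- c(labs, lab); genes <- c(genes, g$gene_id) }
  }
  if (length(labs) == 0) return(data.frame(gene_id = NA_character_,
                                           region = "intergenic"))
  data.frame(gene_id = genes, region = labs, stringsAsFactors = FALSE)
}

# ---- association oracles -------------------------------------------------

# exhaustive two-sided Fisher p: sum hypergeometric probabilities of all
# tables with the observed margins whose probability <= observed
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form trend test through the independent base-R implementation
oracle_catt_p <- function(counts3x2) {
  x <- counts3x2[, 1]; n <- rowSums(counts3x2)
  keep <- n > 0
  stats::prop.trend.test(x[keep], n[keep], score = (0:2)[keep])$p.value
}

# permutation oracle for the trend statistic
oracle_catt_perm <- function(dosage, phenotype, n_perm = 1e4, seed = 42) {
  set.seed(seed)
  stat_of <- function(ph) {
    m <- table(factor(dosage, 0:2), factor(ph, c("resistant", "susceptible")))
    catt(matrix(as.integer(m), 3, 2))$statistic
  }
  obs <- stat_of(phenotype)
  perm <- replicate(n_perm, stat_of(sample(phenotype)))
  mean(perm >= obs - 1e-12)
}

# ---- misc ----------------------------------------------------------------

# brute-force best 2-partition of loadings minimizing total within-group
# variance (1-D: contiguous splits of the sorted values suffice)
oracle_two_partition <- function(a) {
  o <- order(a)
  best <- NULL; best_ss <- Inf
  for (cut in 1:(length(a) - 1)) {
    g1 <- a[o[1:cut]]; g2 <- a[o[(cut + 1):length(a)]]
    ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (ss < best_ss) { best_ss <- ss; best <- names(g2) }
  }
  best  # the upper (larger-loading) group
}

small_cohort_config <- function(...) {
  sim_config(n_genes = 15L, amplicons_per_gene = 5L, n_neutral_snps = 60L,
             ...)
}
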