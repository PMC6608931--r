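#' Carrier 2x2 table for one SNP
#'
#' Cross-tabulates phenotype (resistant / susceptible) against carrier
#' status, where a carrier is an individual with at least one alternate
#' allele (dosage >= 1, the dominant coding matching the pipeline's
#' sensitivity/specificity definitions). Individuals with missing dosage are
#' excluded per site and counted.
#'
#' @param dosage integer vector of alternate-allele dosages (0/1/2, NA
#'   missing), one per individual.
#' @param phenotype character/factor vector, values `"resistant"` /
#'   `"susceptible"`, aligned with `dosage`.
#' @return 2x2 integer matrix, rows `resistant`/`susceptible`, columns
#'   `carrier`/`reference`, with attribute `n_missing`.
#' @export
carrier_table <- function(dosage, phenotype) {
  stopifnot(length(dosage) == length(phenotype))
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% c("resistant", "susceptible")))
    stopf("phenotype labels must be 'resistant' or 'susceptible'")
  keep <- !is.na(dosage)
  if (!any(keep)) stopf("all individuals missing at this site")
  carrier <- factor(ifelse(dosage[keep] >= 1, "carrier", "reference"),
                    levels = c("carrier", "reference"))
  pheno <- factor(phenotype[keep], levels = c("resistant", "susceptible"))
  tab <- table(pheno, carrier)
  out <- matrix(as.integer(tab), 2, 2,
                dimnames = list(c("resistant", "susceptible"),
                                c("carrier", "reference")))
  attr(out, "n_missing") <- sum(!keep)
  out
}

#' Two-sided Fisher exact test on a carrier table
#'
#' Two-sided p-value summing hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's. A table with a zero margin carries no information and returns
#' p = 1 with a flag.
#'
#' @param table 2x2 count matrix (e.g. from [carrier_table()]).
#' @return p-value with attribute `degenerate` (TRUE when a margin was 0).
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(structure(1.0, degenerate = TRUE))
  p <- stats::fisher.test(table)$p.value
  structure(min(p, 1.0), degenerate = FALSE)
}

#' Carrier-based sensitivity, specificity and AUC
#'
#' Sensitivity = resistant carriers / resistant; specificity = susceptible
#' reference-only / susceptible; AUC = their average (the panel pipeline's
#' informativeness score, not a ROC integral).
#'
#' @param table 2x2 matrix from [carrier_table()].
#' @return named numeric vector `sensitivity`, `specificity`, `auc`.
#' @export
sens_spec_auc <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  rs <- rowSums(table)
  if (any(rs == 0)) stopf("empty phenotype group")
  sens <- table["resistant", "carrier"] / rs["resistant"]
  spec <- table["susceptible", "reference"] / rs["susceptible"]
  c(sensitivity = unname(sens), specificity = unname(spec),
    auc = unname((sens + spec) / 2))
}

#' Cochran-Armitage trend test (co-dominant model)
#'
#' Trend test over the 3x2 genotype table with scores 0/1/2 on alternate
#' allele dosage. The statistic is the squared standardized trend in the
#' resistant fraction across dosage categories, referred to chi-squared with
#' 1 df. Monomorphic sites (a single occupied dosage category, or zero score
#' variance) return statistic 0 and p = 1 with a flag.
#'
#' @param genotype_counts 3x2 matrix: rows dosage 0/1/2, columns
#'   resistant/susceptible counts.
#' @return list with `statistic` (>= 0) and `p`, plus `degenerate` flag.
#' @export
catt <- function(genotype_counts) {
  m <- as.matrix(genotype_counts)
  stopifnot(nrow(m) == 3, ncol(m) == 2, all(m >= 0))
  s <- c(0, 1, 2)
  n_i <- rowSums(m)            # individuals per dosage category
  N <- sum(n_i)
  if (any(colSums(m) == 0) || N == 0)
    return(list(statistic = 0, p = 1.0, degenerate = TRUE))
  x_i <- m[, 1]                # resistant per dosage category
  R <- sum(x_i)
  pbar <- R / N
  denom <- pbar * (1 - pbar) * (sum(n_i * s^2) - sum(n_i * s)^2 / N)
  if (denom <= 0 || sum(n_i > 0) < 2)
    return(list(statistic = 0, p = 1.0, degenerate = TRUE))
  T_ <- sum(s * (x_i - n_i * pbar))
  stat <- T_^2 / denom
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# 3x2 dosage x phenotype counts for one site
genotype_counts <- function(dosage, phenotype) {
  keep <- !is.na(dosage)
  tab <- table(factor(dosage[keep], levels = 0:2),
               factor(as.character(phenotype)[keep],
                      levels = c("resistant", "susceptible")))
  matrix(as.integer(tab), 3, 2,
         dimnames = list(dosage = 0:2, phenotype = c("resistant", "susceptible")))
}

#' Per-SNP association scan for one insecticide
#'
#' Computes, for every site in the genotype matrix, the carrier-table Fisher
#' exact p, sensitivity/specificity/AUC, and the co-dominant
#' Cochran-Armitage trend test, then marks cascade membership:
#' Data Set 1 = all scanned SNPs; Data Set 2 = in-gene (exonic) SNPs with
#' Fisher p <= `fisher_alpha`; Data Set 3 = the Data Set 2 subset with CATT
#' p <= `catt_alpha`. Thresholds are inclusive. A Benjamini-Hochberg
#' adjusted Fisher p is emitted for information only; the cascade uses raw
#' thresholds.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a phenotype table (see [simulate_phenotypes()]).
#' @param insecticide column of `phenotypes` to use (e.g. `"permethrin"`).
#' @param annotations optional annotation table from [annotate_snps()];
#'   without it region/gene columns are NA and Data Set 2 cannot retain
#'   anything.
#' @param fisher_alpha Fisher threshold for Data Set 2 (default 0.10).
#' @param catt_alpha CATT threshold for Data Set 3 (default 0.05).
#' @return An `assoc_result` data frame, one row per SNP, sorted genomically,
#'   with columns `site`, `supercontig`, `position`, `gene_id`, `region`,
#'   `effect`, `n_missing`, `fisher_p`, `fisher_bh`, `sensitivity`,
#'   `specificity`, `auc`, `catt_stat`, `catt_p`, `ds1`, `ds2`, `ds3`.
#' @export
assoc_scan <- function(genotypes, phenotypes, insecticide,
                       annotations = NULL, fisher_alpha = 0.10,
                       catt_alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!insecticide %in% names(phenotypes))
    stopf("phenotype table has no column '%s'", insecticide)
  pheno <- phenotypes[[insecticide]][match(colnames(genotypes$dosage),
                                           phenotypes$sample)]
  if (anyNA(pheno)) stopf("phenotype missing for some samples")
  sites <- genotypes$sites
  n <- nrow(sites)
  res <- data.frame(
    site = site_id(sites$supercontig, sites$position),
    supercontig = sites$supercontig, position = sites$position,
    gene_id = NA_character_, region = NA_character_, effect = NA_character_,
    n_missing = NA_integer_, fisher_p = NA_real_, fisher_bh = NA_real_,
    sensitivity = NA_real_, specificity = NA_real_, auc = NA_real_,
    catt_stat = NA_real_, catt_p = NA_real_,
    ds1 = TRUE, ds2 = FALSE, ds3 = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    dos <- genotypes$dosage[i, ]
    tab <- carrier_table(dos, pheno)
    res$n_missing[i] <- attr(tab, "n_missing")
    res$fisher_p[i] <- as.numeric(fisher_exact(tab))
    ssa <- sens_spec_auc(tab)
    res$sensitivity[i] <- ssa["sensitivity"]
    res$specificity[i] <- ssa["specificity"]
    res$auc[i] <- ssa["auc"]
    ct <- catt(genotype_counts(dos, pheno))
    res$catt_stat[i] <- ct$statistic
    res$catt_p[i] <- ct$p
  }
  res$fisher_bh <- stats::p.adjust(res$fisher_p, method = "BH")
  if (!is.null(annotations)) {
    # choose one annotation row per site: exon > intron > flank > intergenic,
    # then panel gene order (first row wins for reporting)
    pri <- match(annotations$region,
                 c("exon", "intron", "flank", "intergenic"))
    ord <- order(pri, seq_len(nrow(annotations)))
    ann <- annotations[ord, , drop = FALSE]
    key <- paste(ann$supercontig, ann$position)
    idx <- match(paste(res$supercontig, res$position), key)
    res$gene_id <- ann$gene_id[idx]
    res$region <- ann$region[idx]
    res$effect <- ann$effect[idx]
  }
  in_gene <- !is.na(res$region) & res$region == "exon" & !is.na(res$gene_id)
  res$ds2 <- in_gene & res$fisher_p <= fisher_alpha
  res$ds3 <- res$ds2 & res$catt_p <= catt_alpha
  res <- res[order(res$supercontig, res$position), ]
  rownames(res) <- NULL
  structure(res, insecticide = insecticide, fisher_alpha = fisher_alpha,
            catt_alpha = catt_alpha,
            class = c("assoc_result", "data.frame"))
}

#' @export
print.assoc_result <- function(x, ...) {
  if (is.null(attr(x, "insecticide"))) return(NextMethod())  # plain subset
  cat(sprintf(
    "Association scan (%s): %d SNPs; Data Set 2: %d (Fisher p <= %.2f, in gene); Data Set 3: %d (CATT p <= %.2f)\n",
    attr(x, "insecticide") %||% "?", nrow(x), sum(x$ds2),
    attr(x, "fisher_alpha") %||% 0.10, sum(x$ds3),
    attr(x, "catt_alpha") %||% 0.05))
  NextMethod()
}

#' Data Set 2: in-gene SNPs passing the Fisher filter, AUC-sorted
#'
#' Retains SNPs located in genes (exonic under the panel model, so flanking
#' and intron SNPs are disregarded) with Fisher p <= the threshold, sorted
#' by descending AUC; ties broken by genomic order.
#'
#' @param result an [assoc_scan()] result.
#' @return the retained rows, AUC-sorted. May be empty.
#' @export
build_dataset2 <- function(result) {
  keep <- result[result$ds2, , drop = FALSE]
  keep <- keep[order(-keep$auc, keep$supercontig, keep$position), ]
  rownames(keep) <- NULL
  keep
}

#' Data Set 3: the Data Set 2 subset passing the trend-test filter
#'
#' @param result an [assoc_scan()] result (Data Set 2 filtering and CATT are
#'   already recorded in it).
#' @return rows with `ds3` set, sorted by ascending CATT p; attribute
#'   `snps_per_gene` gives the per-gene SNP counts.
#' @export
build_dataset3 <- function(result) {
  keep <- result[result$ds3, , drop = FALSE]
  keep <- keep[order(keep$catt_p, keep$supercontig, keep$position), ]
  rownames(keep) <- NULL
  tab <- table(keep$gene_id)
  attr(keep, "snps_per_gene") <-
    data.frame(gene_id = names(tab), n_snps = as.integer(tab),
               stringsAsFactors = FALSE)
  keep
}

#' Shared SNPs across insecticide comparisons
#'
#' Intersection of per-comparison SNP lists and the shared percentage
#' relative to the number of distinct SNPs across comparisons.
#'
#' @param site_lists named list of character vectors of site IDs (one per
#'   insecticide comparison).
#' @return list with `n_total` (distinct sites), `n_shared`, `pct_shared`
#'   (0-100), and `shared` (the site IDs).
#' @export
shared_snp_summary <- function(site_lists) {
  stopifnot(is.list(site_lists), length(site_lists) >= 2)
  shared <- Reduce(intersect, site_lists)
  total <- unique(unlist(site_lists))
  list(n_total = length(total), n_shared = length(shared),
       pct_shared = if (length(total)) 100 * length(shared) / length(total)
       else 0,
       shared = shared)
}

#' Carrier frequencies per population and phenotype group
#'
#' For each requested SNP: the carrier frequency (fraction of individuals
#' with at least one alternate allele) per population, among resistant and
#' among susceptible individuals, and their difference
#' (resistant - susceptible), reported to two decimals. Empty populations
#' yield NaN and are flagged.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table with `sample`, `population` and the
#'   insecticide column.
#' @param insecticide phenotype column to split resistant/susceptible on.
#' @param sites optional character vector of site IDs (default: all).
#' @return data frame, one row per SNP: `site`, one `freq_<population>`
#'   column per population, `freq_resistant`, `freq_susceptible`,
#'   `difference`.
#' @export
population_frequencies <- function(genotypes, phenotypes, insecticide,
                                   sites = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samp <- colnames(genotypes$dosage)
  idx <- match(samp, phenotypes$sample)
  pop <- phenotypes$population[idx]
  pheno <- phenotypes[[insecticide]][idx]
  all_sites <- site_id(genotypes$sites$supercontig, genotypes$sites$position)
  rows <- if (is.null(sites)) seq_along(all_sites) else match(sites, all_sites)
  if (anyNA(rows)) stopf("unknown site requested")
  pops <- unique(pop)
  carrier_freq <- function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NaN)
    mean(d >= 1)
  }
  out <- lapply(rows, function(i) {
    d <- genotypes$dosage[i, ]
    per_pop <- vapply(pops, function(p) carrier_freq(d[pop == p]), numeric(1))
    fr <- carrier_freq(d[pheno == "resistant"])
    fs <- carrier_freq(d[pheno == "susceptible"])
    c(stats::setNames(per_pop, paste0("freq_", pops)),
      freq_resistant = fr, freq_susceptible = fs,
      difference = round_half_up(fr - fs, 2))
  })
  out <- as.data.frame(do.call(rbind, out))
  cbind(data.frame(site = all_sites[rows], stringsAsFactors = FALSE), out)
}
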