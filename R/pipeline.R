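#' Cross-tabulate phenotypes for two insecticides
#'
#' Counts of the four phenotype combinations (resistant/susceptible to each
#' insecticide) over individuals with both labels present; individuals
#' missing a label are excluded and counted.
#'
#' @param phenotypes phenotype table with both insecticide columns.
#' @param insecticides the two columns to cross (default malathion,
#'   permethrin).
#' @return 2x2 integer matrix (rows: first insecticide R/S, columns: second
#'   insecticide R/S) with attribute `n_excluded`.
#' @export
phenotype_crosstab <- function(phenotypes,
                               insecticides = c("malathion", "permethrin")) {
  stopifnot(length(insecticides) == 2,
            all(insecticides %in% names(phenotypes)))
  a <- phenotypes[[insecticides[1]]]
  b <- phenotypes[[insecticides[2]]]
  keep <- !is.na(a) & !is.na(b)
  lev <- c("resistant", "susceptible")
  tab <- table(factor(a[keep], lev), factor(b[keep], lev))
  out <- matrix(as.integer(tab), 2, 2,
                dimnames = stats::setNames(list(lev, lev), insecticides))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Reconstruct the phenotype crosstab from printed marginals
#'
#' Inclusion-exclusion on reported totals: given the cohort size, the
#' per-insecticide resistant counts and the both-resistant count, the
#' remaining three cells are determined (e.g. resistant to the first but
#' susceptible to the second = first-resistant minus both-resistant).
#' Errors if the marginals are inconsistent (a negative cell).
#'
#' @param n_total cohort size.
#' @param n_a_resistant,n_b_resistant resistant counts per insecticide.
#' @param n_both_resistant count resistant to both.
#' @param insecticides dimnames labels.
#' @return 2x2 integer matrix as in [phenotype_crosstab()].
#' @export
crosstab_from_marginals <- function(n_total, n_a_resistant, n_b_resistant,
                                    n_both_resistant,
                                    insecticides = c("malathion",
                                                     "permethrin")) {
  rr <- n_both_resistant
  rs <- n_a_resistant - n_both_resistant
  sr <- n_b_resistant - n_both_resistant
  ss <- n_total - rr - rs - sr
  if (min(rr, rs, sr, ss) < 0) stopf("inconsistent marginals")
  lev <- c("resistant", "susceptible")
  matrix(as.integer(c(rr, sr, rs, ss)), 2, 2,
         dimnames = stats::setNames(list(lev, lev), insecticides))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> annotate -> associate (per insecticide) -> CNV ->
#' DAPC/snpzip, writing every input and report as TSV under `out_dir`:
#' the panel table, genotype VCF, phenotype and depth TSVs, the annotation
#' table, one association report per insecticide (Data Set flags included),
#' the population frequency table for nonsynonymous Data Set 3 SNPs, the
#' per-gene CNV report, the DAPC loadings and selected structural SNPs, and
#' the phenotype crosstab. Deterministic given `seed`: re-running into a
#' fresh directory reproduces every file byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param svd_k singular components removed in the CNV stage (default
#'   `"auto"`, see [cnv_scan()]).
#' @param fisher_alpha,catt_alpha,t_alpha,max_missing cascade thresholds.
#' @param group_by insecticide whose phenotype defines the DAPC grouping
#'   (default permethrin).
#' @return list with the in-memory stage results (`cohort`, `annotations`,
#'   `assoc` per insecticide, `cnv`, `dapc`, `structural_snps`, `crosstab`)
#'   and `files` (named vector of written paths), invisibly.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1,
                         svd_k = "auto", fisher_alpha = 0.10,
                         catt_alpha = 0.05,
                         t_alpha = 0.05, max_missing = 0.05,
                         group_by = "permethrin") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  files <- c()
  tsv <- function(x, name) {
    utils::write.table(x, fp(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[name] <<- fp(name)
  }

  cohort <- simulate_cohort(config, seed)
  write_panel_tsv(cohort$panel, fp("panel.tsv")); files["panel.tsv"] <- fp("panel.tsv")
  write_genotype_vcf(cohort$genotypes, fp("genotypes.vcf"))
  files["genotypes.vcf"] <- fp("genotypes.vcf")
  write_phenotypes_tsv(cohort$phenotypes, fp("phenotypes.tsv"))
  files["phenotypes.tsv"] <- fp("phenotypes.tsv")
  write_depths_tsv(cohort$depths, fp("depths.tsv"))
  files["depths.tsv"] <- fp("depths.tsv")
  write_amplicons_bed(cohort$amplicons, fp("amplicons.bed"))
  files["amplicons.bed"] <- fp("amplicons.bed")

  ann <- annotate_snps(cohort$panel, cohort$genotypes$sites)
  tsv(ann, "annotations.tsv")

  insecticides <- names(config$resistant_frac)
  assoc <- list()
  ds3_sites <- list()
  for (ins in insecticides) {
    res <- assoc_scan(cohort$genotypes, cohort$phenotypes, ins,
                      annotations = ann, fisher_alpha = fisher_alpha,
                      catt_alpha = catt_alpha)
    assoc[[ins]] <- res
    tsv(as.data.frame(res), sprintf("association_%s.tsv", ins))
    ds3_sites[[ins]] <- build_dataset3(res)$site
  }
  shared <- shared_snp_summary(lapply(assoc, function(r) r$site[r$ds2]))

  # population frequencies for nonsynonymous Data Set 3 SNPs, per insecticide
  for (ins in insecticides) {
    d3 <- build_dataset3(assoc[[ins]])
    nsyn <- d3$site[!is.na(d3$effect) & d3$effect == "nonsynonymous"]
    if (length(nsyn)) {
      pf <- population_frequencies(cohort$genotypes, cohort$phenotypes, ins,
                                   sites = nsyn)
      tsv(pf, sprintf("population_frequencies_%s.tsv", ins))
    }
  }

  cnv <- cnv_scan(cohort$depths, cohort$phenotypes, insecticides[1],
                  svd_k = svd_k, t_alpha = t_alpha)
  tsv(as.data.frame(cnv), "cnv_genes.tsv")

  pruned <- prune_snps(cohort$genotypes, max_missing = max_missing)
  dapc <- dapc_fit(pruned, cohort$phenotypes[[group_by]],
                   n_pcs = xval_retain(pruned, cohort$phenotypes[[group_by]],
                                       candidates = c(1, 5, 10, 25, 50),
                                       reps = 30, seed = seed))
  sel <- snpzip_select(dapc$loadings)
  tsv(data.frame(site = names(dapc$loadings), loading = dapc$loadings,
                 structural = names(dapc$loadings) %in% sel,
                 stringsAsFactors = FALSE), "dapc_loadings.tsv")
  tsv(data.frame(site = sel, loading = as.numeric(attr(sel, "loadings")),
                 stringsAsFactors = FALSE), "structural_snps.tsv")

  xt <- phenotype_crosstab(cohort$phenotypes, insecticides)
  tsv(data.frame(combination = c("RR", "RS", "SR", "SS"),
                 count = as.integer(c(xt[1, 1], xt[1, 2], xt[2, 1],
                                      xt[2, 2]))), "crosstab.tsv")

  invisible(list(cohort = cohort, annotations = ann, assoc = assoc,
                 shared = shared, cnv = cnv, dapc = dapc,
                 structural_snps = sel, crosstab = xt, files = files))
}
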