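test_that("carrier tables code dominance and missingness correctly", {
  tab <- carrier_table(c(2, 1, 0, 0), c("resistant", "resistant",
                                        "susceptible", "susceptible"))
  expect_equal(unclass(tab)[1:4], c(2L, 0L, 0L, 2L))  # [[2,0],[0,2]]
  expect_equal(attr(tab, "n_missing"), 0L)

  tab2 <- carrier_table(c(1, NA, 0, 2, 0),
                        c("resistant", "resistant", "susceptible",
                          "resistant", "susceptible"))
  expect_equal(sum(tab2), 4L)
  expect_equal(attr(tab2, "n_missing"), 1L)

  tab3 <- carrier_table(c(rep(1, 10), rep(0, 10)),
                        c(rep("resistant", 10), rep("susceptible", 10)))
  expect_equal(unname(tab3["resistant", "carrier"]), 10L)
  expect_equal(unname(tab3["susceptible", "reference"]), 10L)
  expect_error(carrier_table(c(NA, NA), c("resistant", "susceptible")),
               "all individuals missing")
})

test_that("Fisher p-values match enumeration and handle degenerate margins", {
  no_carriers <- matrix(c(0L, 0L, 10L, 10L), 2, 2,
                        dimnames = list(c("resistant", "susceptible"),
                                        c("carrier", "reference")))
  p <- fisher_exact(no_carriers)
  expect_equal(as.numeric(p), 1.0)
  expect_true(attr(p, "degenerate"))

  perfect5 <- matrix(c(5L, 0L, 0L, 5L), 2, 2,
                     dimnames = dimnames(no_carriers))
  # direct hypergeometric: C(5,5)C(5,0)/C(10,5) doubled by symmetry = 2/252
  expect_equal(as.numeric(fisher_exact(perfect5)), 2 / 252,
               tolerance = 1e-12)

  set.seed(3)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 4), 2, 2,
                  dimnames = dimnames(no_carriers))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(as.numeric(fisher_exact(tab)), oracle_fisher(tab),
                 tolerance = 1e-7)
  }
})

test_that("sensitivity, specificity and AUC follow the carrier definitions", {
  dn <- list(c("resistant", "susceptible"), c("carrier", "reference"))
  perfect <- matrix(c(10L, 0L, 0L, 10L), 2, 2, dimnames = dn)
  expect_equal(unname(sens_spec_auc(perfect)), c(1, 1, 1))

  none <- matrix(c(0L, 0L, 10L, 10L), 2, 2, dimnames = dn)
  expect_equal(unname(sens_spec_auc(none)), c(0, 1, 0.5))

  # 60/90 resistant carriers; 28/35 susceptible reference-only
  t3 <- matrix(c(60L, 7L, 30L, 28L), 2, 2, dimnames = dn)
  got <- sens_spec_auc(t3)
  expect_equal(unname(got), c(60 / 90, 28 / 35, (60 / 90 + 28 / 35) / 2))
  expect_equal(round(unname(got), 3), c(0.667, 0.8, 0.733))

  empty <- matrix(c(0L, 1L, 0L, 1L), 2, 2, dimnames = dn)
  expect_error(sens_spec_auc(empty), "empty phenotype group")
})

test_that("trend test matches the closed-form oracle and null behavior", {
  # strong trend: all resistant at dosage 2, all susceptible at dosage 0
  strong <- matrix(c(0L, 0L, 10L, 10L, 0L, 0L), 3, 2)
  expect_lt(catt(strong)$p, 1e-4)

  flat <- matrix(c(5L, 5L, 5L, 5L, 5L, 5L), 3, 2)
  expect_equal(catt(flat)$statistic, 0)
  expect_equal(catt(flat)$p, 1.0)

  mono <- matrix(c(10L, 0L, 0L, 5L, 0L, 0L), 3, 2)
  expect_true(catt(mono)$degenerate)
  expect_equal(catt(mono)$p, 1.0)

  set.seed(14)
  for (i in 1:60) {
    m <- matrix(rpois(6, 5), 3, 2)
    if (any(colSums(m) == 0)) next
    got <- catt(m)
    if (got$degenerate) next
    expect_equal(got$p, oracle_catt_p(m), tolerance = 1e-6)
  }
})

test_that("trend test agrees with a permutation oracle", {
  # cohort-sized table so the chi-squared reference is adequate
  set.seed(21)
  dosage <- c(rep(0, 50), rep(1, 45), rep(2, 30))
  pheno <- sample(c(rep("resistant", 80), rep("susceptible", 45)))
  m <- table(factor(dosage, 0:2), factor(pheno, c("resistant", "susceptible")))
  p_asy <- catt(matrix(as.integer(m), 3, 2))$p
  p_perm <- oracle_catt_perm(dosage, pheno, n_perm = 4000)
  se <- sqrt(max(p_perm, 0.01) * (1 - max(p_perm, 0.01)) / 4000)
  expect_lt(abs(p_asy - p_perm), 4 * se + 0.02)
})

test_that("the Data Set cascade filters with inclusive thresholds", {
  mk <- function(fisher_p, region, catt_p, pos) {
    data.frame(site = paste0("s:", pos), supercontig = "s", position = pos,
               gene_id = "G", region = region, effect = NA,
               n_missing = 0L, fisher_p = fisher_p, fisher_bh = fisher_p,
               sensitivity = 0.5, specificity = 0.5, auc = 0.5 + pos / 1000,
               catt_stat = 1, catt_p = catt_p,
               ds1 = TRUE, ds2 = region == "exon" & fisher_p <= 0.10,
               ds3 = region == "exon" & fisher_p <= 0.10 & catt_p <= 0.05,
               stringsAsFactors = FALSE)
  }
  res <- rbind(mk(0.10, "exon", 0.05, 1),    # boundary: retained in DS2+DS3
               mk(0.05, "intron", 0.01, 2),  # intron: excluded
               mk(0.101, "exon", 0.01, 3),   # just over Fisher threshold
               mk(0.01, "exon", 0.051, 4))   # just over CATT threshold
  class(res) <- c("assoc_result", "data.frame")
  d2 <- build_dataset2(res)
  expect_setequal(d2$position, c(1, 4))
  expect_equal(d2$position, c(4, 1))  # descending AUC
  d3 <- build_dataset3(res)
  expect_equal(d3$position, 1)
  expect_equal(attr(d3, "snps_per_gene")$n_snps, 1L)
})

test_that("cascade is monotone in its thresholds on a simulated scan", {
  co <- simulate_cohort(small_cohort_config(), seed = 31)
  ann <- annotate_snps(co$panel, co$genotypes$sites)
  loose <- assoc_scan(co$genotypes, co$phenotypes, "permethrin", ann,
                      fisher_alpha = 0.10, catt_alpha = 0.05)
  tight <- assoc_scan(co$genotypes, co$phenotypes, "permethrin", ann,
                      fisher_alpha = 0.05, catt_alpha = 0.01)
  expect_true(all(tight$site[tight$ds2] %in% loose$site[loose$ds2]))
  expect_true(all(tight$site[tight$ds3] %in% loose$site[loose$ds3]))
  # nesting DS3 within DS2 within DS1
  expect_true(all(loose$ds3[loose$ds3] & loose$ds2[loose$ds3]))
  expect_true(all(loose$ds2 | !loose$ds3))
})

test_that("null cohorts give approximately uniform association p-values", {
  cfg <- sim_config(
    n_genes = 60L, n_neutral_snps = 500L,
    causal_snps = data.frame(insecticide = character(0), effect = numeric(0),
                             base_freq = numeric(0)),
    duplications = data.frame(gene_id = NA_character_, copy_ratio = NA_real_,
                              carrier_frac_resistant = 0,
                              carrier_frac_susceptible = 0),
    missing_rate = 0)
  panel <- simulate_panel(cfg, seed = 41)
  gs <- simulate_genotypes(panel, cfg, seed = 41)
  ph <- simulate_phenotypes(gs, cfg, seed = 42)
  res <- assoc_scan(gs$genotypes, ph, "permethrin")
  # Fisher type-I error at alpha = 0.10 stays at or below nominal
  # (the exact test is conservative on discrete tables)
  rate <- mean(res$fisher_p <= 0.10)
  expect_lt(rate, 0.10 + 3 * sqrt(0.1 * 0.9 / nrow(res)))
  # CATT p-values approximately uniform
  ks <- suppressWarnings(ks.test(res$catt_p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("population frequencies and differences are reported correctly", {
  # 7 carriers of 19 in one population -> 0.37
  sites <- data.frame(supercontig = "s", position = 1L, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  dos <- matrix(c(rep(1L, 7), rep(0L, 12)), 1)
  colnames(dos) <- sprintf("TXU_%02d", 1:19)
  gm <- genotype_matrix(dos, sites)
  ph <- data.frame(sample = colnames(dos), population = "TXU",
                   permethrin = rep(c("resistant", "susceptible"),
                                    c(10, 9)), stringsAsFactors = FALSE)
  pf <- population_frequencies(gm, ph, "permethrin")
  expect_equal(round(pf$freq_TXU, 2), 0.37)

  # 0.81 resistant vs 0.32 susceptible -> difference 0.49
  n_r <- 100; n_s <- 100
  dos2 <- matrix(c(rep(1L, 81), rep(0L, 19), rep(1L, 32), rep(0L, 68)), 1)
  colnames(dos2) <- sprintf("P_%03d", 1:200)
  gm2 <- genotype_matrix(dos2, sites)
  ph2 <- data.frame(sample = colnames(dos2), population = "P",
                    permethrin = rep(c("resistant", "susceptible"),
                                     c(n_r, n_s)), stringsAsFactors = FALSE)
  pf2 <- population_frequencies(gm2, ph2, "permethrin")
  expect_equal(pf2$freq_resistant, 0.81)
  expect_equal(pf2$freq_susceptible, 0.32)
  expect_equal(pf2$difference, 0.49)

  # all carriers -> frequency 1 everywhere
  dos3 <- matrix(rep(2L, 200), 1); colnames(dos3) <- colnames(dos2)
  pf3 <- population_frequencies(genotype_matrix(dos3, sites), ph2,
                                "permethrin")
  expect_equal(pf3$freq_P, 1)
  expect_equal(pf3$difference, 0)
})

test_that("shared-SNP summaries report intersection percentages", {
  s <- shared_snp_summary(list(mal = c("a", "b", "c"), perm = c("b", "c", "d")))
  expect_equal(s$n_shared, 2L)
  expect_equal(s$n_total, 4L)
  expect_equal(s$pct_shared, 50)
  expect_setequal(s$shared, c("b", "c"))
})
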