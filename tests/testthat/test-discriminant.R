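mk_gm <- function(dosage) {
  n <- nrow(dosage)
  genotype_matrix(dosage,
                  data.frame(supercontig = "s", position = seq_len(n),
                             ref = "A", alt = "T", stringsAsFactors = FALSE))
}

test_that("pruning drops monomorphic and high-missingness SNPs inclusively", {
  n <- 125
  d <- rbind(fixed_alt = rep(2L, n),              # monomorphic, non-reference
             fixed_ref = rep(0L, n),              # monomorphic
             miss7 = c(rep(NA, 7), rep(0:1, 59)), # 7/125 = 5.6% > 5%
             miss6 = c(rep(NA, 6), rep(0:1, length.out = 119)),  # 4.8%
             ok = rep(c(0L, 1L, 2L), length.out = n))
  colnames(d) <- sprintf("i%03d", 1:n)
  pr <- prune_snps(mk_gm(d), max_missing = 0.05)
  kept <- rownames(pr$dosage)
  expect_setequal(kept, c("s:4", "s:5"))  # miss6 and ok survive
  expect_setequal(attr(pr, "dropped_monomorphic"), c("s:1", "s:2"))
  expect_setequal(attr(pr, "dropped_missing"), "s:3")
  expect_error(prune_snps(mk_gm(d[1:2, , drop = FALSE])), "no SNPs left")
})

test_that("DAPC separates constructed clusters and finds the planted SNP", {
  set.seed(6)
  n <- 60
  labels <- rep(c("resistant", "susceptible"), each = n / 2)
  # two clusters separated across 20 SNPs: structure dominates PC1
  sep <- t(vapply(1:20, function(i)
    rbinom(n, 2, ifelse(labels == "resistant", 0.95, 0.05)), numeric(n)))
  noise <- matrix(sample(0:2, 30 * n, TRUE), 30, n)
  gm <- mk_gm(rbind(sep, noise))
  fit <- dapc_fit(gm, labels, n_pcs = 2)
  expect_equal(fit$reassignment_rate, 1.0)
  expect_equal(sum(fit$loadings^2), 1, tolerance = 1e-10)
  # the separating block carries the weight
  top20 <- order(-abs(fit$loadings))[1:20]
  expect_gte(sum(top20 <= 20), 18)

  # one strongly discriminating SNP among noise: top |loading| once enough
  # PCs are retained to span the discriminating direction
  planted <- rbinom(n, 2, ifelse(labels == "resistant", 0.95, 0.05))
  gm2 <- mk_gm(rbind(noise, planted))
  fit2 <- dapc_fit(gm2, labels, n_pcs = 25)
  expect_equal(which.max(abs(fit2$loadings)), 31L, ignore_attr = TRUE)
  expect_gte(fit2$reassignment_rate, 0.9)

  expect_error(dapc_fit(gm, labels, n_pcs = n), "n_pcs")
  expect_error(dapc_fit(gm, rep("a", n), 2), "2 classes")
})

test_that("random labels give chance-level held-out assignment", {
  set.seed(7)
  n <- 80
  gm <- mk_gm(matrix(sample(0:2, 60 * n, TRUE), 60, n))
  labels <- sample(rep(c("resistant", "susceptible"), each = n / 2))
  res <- xval_retain(gm, labels, candidates = c(1, 5, 10), folds = 5,
                     reps = 20, seed = 3)
  succ <- attr(res, "success")
  expect_true(all(abs(succ - 0.5) < 0.2))
})

test_that("cross-validation retains one PC when signal lives on PC1", {
  set.seed(8)
  n <- 100
  labels <- rep(c("resistant", "susceptible"), each = n / 2)
  base <- ifelse(labels == "resistant", 1.7, 0.3)
  # 40 SNPs all driven by one latent axis aligned with the labels
  d <- t(vapply(1:40, function(i) rbinom(n, 2, plogis(base - 1)),
                numeric(n)))
  storage.mode(d) <- "integer"
  gm <- mk_gm(d)
  picked <- xval_retain(gm, labels, candidates = c(1, 5, 10, 20), folds = 5,
                        reps = 15, seed = 4)
  expect_equal(as.integer(picked), 1L)

  # deterministic under a fixed seed
  picked2 <- xval_retain(gm, labels, candidates = c(1, 5, 10, 20), folds = 5,
                         reps = 15, seed = 4)
  expect_identical(as.integer(picked), as.integer(picked2))
})

test_that("snpzip selection matches a brute-force 2-partition", {
  loads <- c(a = 0.9, b = 0.85, c = 0.01, d = 0.02, e = 0.03)
  sel <- snpzip_select(loads)
  expect_setequal(as.character(sel), c("a", "b"))
  expect_setequal(as.character(sel), oracle_two_partition(abs(loads)))
  expect_identical(as.character(sel)[1], "a")  # descending |loading|

  single <- c(big = 0.99, s1 = 0.01, s2 = 0.012, s3 = 0.008)
  expect_identical(as.character(snpzip_select(single)), "big")

  flat <- c(x = 0.2, y = 0.2, z = 0.2)
  sel_flat <- snpzip_select(flat)
  expect_length(sel_flat, 0)
  expect_true(attr(sel_flat, "degenerate"))
})

test_that("selection is invariant to SNP order and axis sign", {
  set.seed(9)
  n <- 80
  labels <- rep(c("resistant", "susceptible"), each = n / 2)
  noise <- matrix(sample(0:2, 50 * n, TRUE), 50, n)
  planted <- rbind(ifelse(labels == "resistant", 2L, 0L),
                   ifelse(labels == "resistant", 0L, 2L))
  d <- rbind(noise, planted)
  gm <- mk_gm(d)
  fit <- dapc_fit(gm, labels, n_pcs = 4)
  sel <- sort(as.character(snpzip_select(fit$loadings)))

  perm <- sample(nrow(d))
  gm_p <- genotype_matrix(d[perm, , drop = FALSE],
                          data.frame(supercontig = "s", position = perm,
                                     ref = "A", alt = "T",
                                     stringsAsFactors = FALSE))
  fit_p <- dapc_fit(gm_p, labels, n_pcs = 4)
  expect_identical(sort(as.character(snpzip_select(fit_p$loadings))), sel)

  # sign flip of the axis leaves |loadings| and the selection unchanged
  expect_identical(sort(as.character(snpzip_select(-fit$loadings))), sel)
})

test_that("selected set recovers planted structure better than chance", {
  # signal restricted to a known 10-SNP subset: those SNPs differ in
  # frequency between the groups, the other 490 are exchangeable
  set.seed(10)
  n <- 125
  labels <- rep(c("resistant", "susceptible"), c(80, 45))
  neutral <- t(vapply(1:490, function(i) rbinom(n, 2, runif(1, 0.1, 0.5)),
                      numeric(n)))
  signal <- t(vapply(1:10, function(i)
    rbinom(n, 2, ifelse(labels == "resistant", 0.8, 0.15)), numeric(n)))
  gm <- mk_gm(rbind(signal, neutral))
  truth <- rownames(gm$dosage)[1:10]
  pruned <- prune_snps(gm)
  n_pcs <- xval_retain(pruned, labels, candidates = c(10, 25, 50, 80),
                       reps = 6, seed = 2)
  fit <- dapc_fit(pruned, labels, n_pcs = n_pcs)
  sel <- as.character(snpzip_select(fit$loadings))
  expect_gte(length(intersect(sel, truth)) / 10, 0.8)
  jac <- length(intersect(sel, truth)) / length(union(sel, truth))
  # permutation null for the Jaccard of a random same-size selection
  null_j <- replicate(2000, {
    r <- sample(names(fit$loadings), length(sel))
    length(intersect(r, truth)) / length(union(r, truth))
  })
  expect_lt(mean(null_j >= jac), 0.01)
})

test_that("shared-signal cohorts yield nested selections across labels", {
  # both insecticides driven by the same causal SNPs; the permethrin
  # selection should be contained in the malathion one (constructed case)
  set.seed(12)
  cfg <- sim_config(
    n_genes = 30L, n_neutral_snps = 120L,
    causal_snps = data.frame(
      insecticide = c("permethrin", "malathion", "malathion"),
      effect = log(10), base_freq = 0.3),
    missing_rate = 0)
  panel <- simulate_panel(cfg, seed = 13)
  gs <- simulate_genotypes(panel, cfg, seed = 13)
  # give malathion the permethrin causal SNP too: shared signal
  gs$truth$insecticide <- c("permethrin", "malathion", "malathion")
  extra <- gs$truth[1, ]; extra$insecticide <- "malathion"
  gs$truth <- rbind(gs$truth, extra)
  ph <- simulate_phenotypes(gs, cfg, seed = 14)
  pruned <- prune_snps(gs$genotypes)
  sel_p <- as.character(snpzip_select(
    dapc_fit(pruned, ph$permethrin, 50)$loadings))
  sel_m <- as.character(snpzip_select(
    dapc_fit(pruned, ph$malathion, 50)$loadings))
  shared_causal <- gs$truth$site[1]
  expect_true(shared_causal %in% sel_p)
  expect_true(shared_causal %in% sel_m)
})
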