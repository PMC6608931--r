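#' Prune a genotype matrix for discriminant analysis
#'
#' Drops SNPs that are monomorphic in the cohort (no variation among
#' non-missing calls, including sites fixed for the alternate allele, i.e.
#' different from the reference but invariant here) and SNPs with more than
#' `max_missing` missing data (inclusive boundary: exactly 5\% is kept).
#'
#' @param genotypes a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @return pruned [genotype_matrix()] with attributes `dropped_monomorphic`
#'   and `dropped_missing` (site IDs).
#' @export
prune_snps <- function(genotypes, max_missing = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  miss_frac <- rowMeans(is.na(d))
  mono <- apply(d, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) == 0 || length(unique(r)) == 1
  })
  ids <- site_id(genotypes$sites$supercontig, genotypes$sites$position)
  keep <- !mono & miss_frac <= max_missing
  if (!any(keep)) stopf("no SNPs left after pruning")
  out <- genotype_matrix(d[keep, , drop = FALSE],
                         genotypes$sites[keep, , drop = FALSE])
  attr(out, "dropped_monomorphic") <- ids[mono]
  attr(out, "dropped_missing") <- ids[!mono & miss_frac > max_missing]
  out
}

# samples x SNPs numeric matrix: mean-imputed, centered, unit-scaled
dosage_design <- function(genotypes) {
  X <- t(genotypes$dosage)
  n_imputed <- sum(is.na(X))
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[!nas, j])
  }
  X <- scale(X)
  attr(X, "n_imputed") <- n_imputed
  X
}

#' Discriminant analysis of principal components (two groups)
#'
#' Centers and unit-scales the dosage matrix (residual missingness
#' mean-imputed and recorded), takes the leading `n_pcs` principal
#' components, and fits a linear discriminant on them. With two phenotype
#' classes there is a single discriminant axis; per-SNP loadings are
#' obtained by back-projecting the axis through the PC rotation and
#' normalizing to unit length. The reassignment rate classifies the
#' training samples with the fitted discriminant.
#'
#' @param genotypes a (pruned) [genotype_matrix()].
#' @param labels two-class factor/character vector, one per sample.
#' @param n_pcs number of principal components retained (>= 1, less than
#'   the number of samples).
#' @return object of class `dapc_result`: list with `n_pcs`, `loadings`
#'   (named per-SNP vector), `scores` (per-sample discriminant scores),
#'   `assignment` (predicted labels), `reassignment_rate`, `n_imputed`.
#' @export
dapc_fit <- function(genotypes, labels, n_pcs) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2) stopf("labels must have exactly 2 classes")
  n_pcs <- as.integer(n_pcs)
  n <- ncol(genotypes$dosage)
  if (n_pcs < 1) stopf("n_pcs must be >= 1")
  if (n_pcs >= n) stopf("n_pcs must be < number of samples (%d)", n)
  X <- dosage_design(genotypes)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  S <- pc$x[, seq_len(k), drop = FALSE]
  fit <- MASS::lda(S, grouping = labels)
  w <- fit$scaling[, 1]
  loadings <- drop(pc$rotation[, seq_len(k), drop = FALSE] %*% w)
  loadings <- loadings / sqrt(sum(loadings^2))
  names(loadings) <- site_id(genotypes$sites$supercontig,
                             genotypes$sites$position)
  pred <- stats::predict(fit, S)
  scores <- drop(S %*% w)
  names(scores) <- rownames(X)
  structure(
    list(n_pcs = k, loadings = loadings, scores = scores,
         assignment = pred$class,
         reassignment_rate = mean(pred$class == labels),
         n_imputed = attr(X, "n_imputed"),
         labels = labels),
    class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf(
    "DAPC: %d PC(s) retained, 1 discriminant axis over %d SNPs; training reassignment %.1f%%\n",
    x$n_pcs, length(x$loadings), 100 * x$reassignment_rate))
  invisible(x)
}

#' Cross-validated choice of retained principal components
#'
#' Repeated stratified hold-out: each repetition holds out 1/`folds` of
#' every class, fits the PCA + discriminant on the remainder for every
#' candidate number of PCs, and scores held-out assignment success. Returns
#' the candidate maximizing mean held-out success; ties go to the fewest
#' PCs.
#'
#' @param genotypes a (pruned) [genotype_matrix()].
#' @param labels two-class labels per sample.
#' @param candidates integer vector of candidate PC counts.
#' @param folds hold-out denominator (default 5; every class needs at least
#'   `folds` members).
#' @param reps repetitions (default 30).
#' @param seed RNG seed.
#' @return chosen number of PCs, with attribute `success` (mean held-out
#'   success per candidate).
#' @export
xval_retain <- function(genotypes, labels, candidates = 1:10, folds = 5,
                        reps = 30, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2) stopf("labels must have exactly 2 classes")
  if (folds < 2) stopf("folds must be >= 2")
  if (any(table(labels) < folds))
    stopf("every class needs at least %d members", folds)
  set.seed(seed)
  X <- dosage_design(genotypes)
  n <- nrow(X)
  candidates <- sort(unique(as.integer(candidates)))
  candidates <- candidates[candidates >= 1 & candidates < n]
  succ <- matrix(NA_real_, reps, length(candidates))
  for (r in seq_len(reps)) {
    test_idx <- unlist(lapply(levels(labels), function(lv) {
      members <- which(labels == lv)
      sample(members, max(1, floor(length(members) / folds)))
    }))
    train <- setdiff(seq_len(n), test_idx)
    # rescale within the training split, project the held-out samples
    mu <- colMeans(X[train, , drop = FALSE])
    Xtr <- sweep(X[train, , drop = FALSE], 2, mu)
    Xte <- sweep(X[test_idx, , drop = FALSE], 2, mu)
    pc <- stats::prcomp(Xtr, center = FALSE, scale. = FALSE)
    for (ci in seq_along(candidates)) {
      k <- min(candidates[ci], ncol(pc$x), length(train) - 2L)
      Str <- pc$x[, seq_len(k), drop = FALSE]
      Ste <- Xte %*% pc$rotation[, seq_len(k), drop = FALSE]
      fit <- tryCatch(MASS::lda(Str, grouping = labels[train]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred <- stats::predict(fit, Ste)$class
      succ[r, ci] <- mean(pred == labels[test_idx])
    }
  }
  mean_succ <- colMeans(succ, na.rm = TRUE)
  best <- candidates[which.max(mean_succ)]  # which.max takes first = fewest
  structure(best, success = stats::setNames(mean_succ, candidates))
}

#' Variance-threshold choice of retained principal components
#'
#' Returns the number of leading principal components needed to reach a
#' cumulative variance fraction (default 0.9), capped so the subsequent
#' discriminant fit keeps a margin of samples beyond dimensions. This is
#' the standard retention heuristic when between-group signal is spread
#' over many independent loci, where held-out assignment success is too
#' flat for cross-validation to resolve (see [xval_retain()] for the
#' cross-validated alternative).
#'
#' @param genotypes a (pruned) [genotype_matrix()].
#' @param threshold cumulative variance fraction to reach (default 0.9).
#' @return integer number of PCs.
#' @export
retain_by_variance <- function(genotypes, threshold = 0.9) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            threshold > 0, threshold <= 1)
  X <- dosage_design(genotypes)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= threshold)[1]
  max(1L, min(as.integer(k), nrow(X) - 15L))
}

#' snpzip-style structural SNP selection
#'
#' Splits the absolute discriminant loadings into two groups by Ward
#' clustering and returns the group with the larger mean absolute loading
#' (the "structural" SNPs contributing most to between-phenotype
#' structure), ordered by descending absolute loading. If all loadings are
#' equal there is no structure to cut and an empty, flagged selection is
#' returned.
#'
#' @param loadings named numeric vector of per-SNP loadings (>= 2 SNPs),
#'   e.g. from [dapc_fit()].
#' @return character vector of selected site IDs (descending |loading|),
#'   with attributes `loadings` (their absolute loadings) and `degenerate`.
#' @export
snpzip_select <- function(loadings) {
  if (length(loadings) < 2) stopf("need >= 2 SNPs")
  a <- abs(loadings)
  if (max(a) - min(a) < .Machine$double.eps^0.5)
    return(structure(character(0), degenerate = TRUE))
  hc <- stats::hclust(stats::dist(a), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  top <- if (mean(a[grp == 1]) >= mean(a[grp == 2])) 1 else 2
  sel <- names(a)[grp == top]
  sel <- sel[order(-a[sel])]
  structure(sel, loadings = a[sel], degenerate = FALSE)
}
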