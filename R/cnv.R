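#' RPKM normalization of an amplicon read-count matrix
#'
#' reads / (amplicon length in kb x sample total mapped reads in millions).
#' Doubling every count in a sample leaves its RPKM unchanged.
#'
#' @param counts amplicons x samples non-negative count matrix.
#' @param lengths amplicon lengths in bp (one per row of `counts`).
#' @param totals per-sample total mapped reads; defaults to column sums.
#' @return RPKM matrix, same shape as `counts`.
#' @export
rpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(counts >= 0))
  if (any(lengths <= 0)) stopf("zero-length amplicon")
  if (any(totals <= 0)) stopf("sample with zero total reads")
  sweep(counts / (lengths / 1000), 2, totals / 1e6, "/")
}

#' Per-amplicon z-scores (ZRPKM)
#'
#' Standardizes each amplicon's RPKM across samples (mean 0, sd 1).
#' Zero-variance amplicons cannot be standardized; they are returned as NA
#' rows and flagged (attribute `constant_rows`), and the SVD stage drops
#' them.
#'
#' @param rpkm_mat RPKM matrix (amplicons x samples), at least 2 samples.
#' @return ZRPKM matrix with attribute `constant_rows` (row indices).
#' @export
zrpkm <- function(rpkm_mat) {
  rpkm_mat <- as.matrix(rpkm_mat)
  if (ncol(rpkm_mat) < 2) stopf("ZRPKM needs at least 2 samples")
  mu <- rowMeans(rpkm_mat)
  sd_ <- apply(rpkm_mat, 1, stats::sd)
  const <- which(sd_ == 0 | !is.finite(sd_))
  z <- (rpkm_mat - mu) / sd_
  if (length(const)) z[const, ] <- NA_real_
  attr(z, "constant_rows") <- const
  z
}

#' SVD denoising of a ZRPKM matrix
#'
#' Removes systematic batch structure by zeroing the `k` largest singular
#' components and reconstructing (the targeted-sequencing CNV approach:
#' run-to-run biases dominate the top components, leaving copy-number signal
#' in the residual). `k = 0` is the identity. Constant (NA) rows from
#' [zrpkm()] are dropped before the SVD and returned as zeros.
#'
#' @param zrpkm_mat ZRPKM matrix (amplicons x samples).
#' @param k number of leading singular components to zero; must be smaller
#'   than the matrix rank bound `min(dim)`.
#' @return denoised matrix, same shape; attribute `singular_values` holds
#'   the full singular value spectrum (scree) of the input.
#' @export
svd_denoise <- function(zrpkm_mat, k) {
  zrpkm_mat <- as.matrix(zrpkm_mat)
  k <- as.integer(k)
  if (k < 0) stopf("k must be >= 0")
  drop_rows <- which(apply(zrpkm_mat, 1, function(r) anyNA(r)))
  keep <- setdiff(seq_len(nrow(zrpkm_mat)), drop_rows)
  m <- zrpkm_mat[keep, , drop = FALSE]
  if (k >= min(dim(m)))
    stopf("k = %d >= rank bound %d", k, min(dim(m)))
  out <- matrix(0, nrow(zrpkm_mat), ncol(zrpkm_mat),
                dimnames = dimnames(zrpkm_mat))
  if (k == 0) {
    out[keep, ] <- m
    sv <- svd(m, nu = 0, nv = 0)$d
  } else {
    s <- svd(m)
    d <- s$d
    d[seq_len(k)] <- 0
    out[keep, ] <- s$u %*% (d * t(s$v))
    sv <- s$d
  }
  attr(out, "singular_values") <- sv
  attr(out, "dropped_rows") <- drop_rows
  out
}

#' Group-level CNV determination per gene
#'
#' Jointly denoises the cohort's depth matrix
#' (RPKM -> ZRPKM -> SVD residual), averages the residual signal over each
#' gene's amplicons per sample, and compares phenotype groups: fold change =
#' mean resistant gene-level RPKM / mean susceptible gene-level RPKM, a
#' Welch t-test on the denoised gene signals, an mRMR rank over genes with
#' phenotype as the target, and a determination of `duplicated` (resistant
#' group mean signal above susceptible) or `deleted` (below). Every gene
#' gets exactly one determination; an exact tie is called `duplicated` and
#' flagged. Genes whose t-test p <= `t_alpha` with a `duplicated`
#' determination are the candidate amplified genes.
#'
#' @param depths a [depth_matrix()] (counts + amplicon metadata).
#' @param phenotypes phenotype table.
#' @param insecticide phenotype column to group by.
#' @param svd_k singular components removed. The default `"auto"` removes
#'   the components standing far above the bulk of the spectrum (singular
#'   value above both twice the median and half the leading value, at least
#'   1, capped at 10): run/batch structure dominates the scree on targeted
#'   panels while localized copy-number signal does not. A fixed integer is
#'   accepted; the scree is returned either way so the choice can be
#'   inspected.
#' @param t_alpha significance threshold for the t-test flag (default 0.05).
#' @return A `cnv_result` data frame, one row per gene: `gene_id`,
#'   `n_amplicons`, `mean_rpkm_resistant`, `mean_rpkm_susceptible`,
#'   `fold_change`, `t_p`, `mrmr_rank`, `determination`, `significant`,
#'   `tie`. Attribute `singular_values` carries the scree.
#' @export
cnv_scan <- function(depths, phenotypes, insecticide, svd_k = "auto",
                     t_alpha = 0.05) {
  stopifnot(inherits(depths, "depth_matrix"))
  pheno <- phenotypes[[insecticide]][match(colnames(depths$counts),
                                           phenotypes$sample)]
  if (anyNA(pheno)) stopf("phenotype missing for some samples")
  if (sum(pheno == "resistant") < 2 || sum(pheno == "susceptible") < 2)
    stopf("both phenotype groups need >= 2 samples")
  rp <- rpkm(depths$counts, depths$amplicons$length)
  z <- zrpkm(rp)
  if (identical(svd_k, "auto")) {
    sv <- attr(svd_denoise(z, 0), "singular_values")
    cut <- max(2 * stats::median(sv), 0.5 * sv[1])
    svd_k <- max(1L, min(10L, sum(sv > cut)))
  }
  dz <- svd_denoise(z, svd_k)
  genes <- unique(depths$amplicons$gene_id)
  res_idx <- pheno == "resistant"
  sig <- matrix(NA_real_, length(genes), ncol(depths$counts),
                dimnames = list(genes, colnames(depths$counts)))
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    amp <- which(depths$amplicons$gene_id == g)
    if (length(amp) == 0) {
      warnf("gene %s has no amplicons; skipped", g)
      next
    }
    sig[gi, ] <- colMeans(dz[amp, , drop = FALSE])
    g_rpkm <- colMeans(rp[amp, , drop = FALSE])
    m_r <- mean(g_rpkm[res_idx]); m_s <- mean(g_rpkm[!res_idx])
    fc <- m_r / m_s
    a <- sig[gi, res_idx]; b <- sig[gi, !res_idx]
    t_p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1.0)
    tie <- isTRUE(all.equal(mean(a), mean(b)))
    det <- if (mean(a) > mean(b) || tie) "duplicated" else "deleted"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, n_amplicons = length(amp),
      mean_rpkm_resistant = m_r, mean_rpkm_susceptible = m_s,
      fold_change = fc, t_p = t_p, mrmr_rank = NA_integer_,
      determination = det, significant = FALSE, tie = tie,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rk <- mrmr_rank(t(sig[out$gene_id, , drop = FALSE]), pheno)
  out$mrmr_rank <- rk[out$gene_id]
  out$significant <- out$determination == "duplicated" & out$t_p <= t_alpha
  rownames(out) <- NULL
  structure(out, insecticide = insecticide, svd_k = svd_k, t_alpha = t_alpha,
            singular_values = attr(dz, "singular_values"),
            class = c("cnv_result", "data.frame"))
}

#' @export
print.cnv_result <- function(x, ...) {
  if (is.null(attr(x, "insecticide"))) return(NextMethod())  # plain subset
  cat(sprintf(
    "CNV scan (%s, k = %d components removed): %d genes, %d duplicated with t-test p <= %.2f\n",
    attr(x, "insecticide") %||% "?", attr(x, "svd_k") %||% NA,
    nrow(x), sum(x$significant), attr(x, "t_alpha") %||% 0.05))
  NextMethod()
}

# mutual information of two discrete vectors (natural log)
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# tercile discretization; constant features collapse to one bin (MI = 0)
discretize_terciles <- function(v) {
  qs <- unique(stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE))
  findInterval(v, qs, left.open = TRUE)
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking (MID difference form)
#' of continuous features against a categorical target, with mutual
#' information computed on tercile-discretized features. Rank 1 is selected
#' first (highest relevance); each next pick maximizes relevance minus mean
#' redundancy with the already-selected set. Deterministic; ties break by
#' column order. Constant features have zero relevance and sink to the
#' bottom.
#'
#' @param features samples x features numeric matrix (>= 2 features).
#' @param target factor/character vector, one value per sample.
#' @return named integer vector of ranks (1 = most relevant), one per
#'   feature column.
#' @export
mrmr_rank <- function(features, target) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stopf("mRMR needs >= 2 features")
  stopifnot(nrow(features) == length(target))
  disc <- apply(features, 2, discretize_terciles)
  y <- as.factor(target)
  p <- ncol(features)
  rel <- vapply(seq_len(p), function(j) mutual_information(disc[, j], y),
                numeric(1))
  mi_cache <- matrix(NA_real_, p, p)
  selected <- integer(0)
  remaining <- seq_len(p)
  for (step in seq_len(p)) {
    if (length(selected) == 0) {
      score <- rel[remaining]
    } else {
      red <- vapply(remaining, function(j) {
        mean(vapply(selected, function(k) {
          if (is.na(mi_cache[j, k])) {
            mi <- mutual_information(disc[, j], disc[, k])
            mi_cache[j, k] <<- mi; mi_cache[k, j] <<- mi
          }
          mi_cache[j, k]
        }, numeric(1)))
      }, numeric(1))
      score <- rel[remaining] - red
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  ranks <- integer(p)
  ranks[selected] <- seq_len(p)
  names(ranks) <- colnames(features)
  ranks
}

#' qPCR relative copy-number fold change (delta-delta Cq)
#'
#' Computes, per (sample, gene), the triplicate-mean quantification cycles
#' for the target gene and the single-copy reference gene, the delta-delta
#' Cq against the susceptible control sample, and the fold change
#' 2^(-ddCq). A fold change >= `fold_threshold` (default 1.5) is taken as
#' support for increased copy number.
#'
#' @param cq data frame with columns `sample`, `gene`, `role` (`"target"` /
#'   `"reference"`), `replicate`, `cq` (positive cycles).
#' @param control name of the control (calibrator) sample present in `cq`.
#' @param fold_threshold amplification call threshold (default 1.5,
#'   inclusive).
#' @return data frame: `sample`, `gene`, `mean_cq_target`,
#'   `mean_cq_reference`, `ddcq`, `fold_change`, `amplified`.
#' @export
qpcr_fold_change <- function(cq, control, fold_threshold = 1.5) {
  need <- c("sample", "gene", "role", "replicate", "cq")
  if (!all(need %in% names(cq)))
    stopf("Cq table needs columns: %s", paste(need, collapse = ", "))
  if (any(cq$cq <= 0)) stopf("Cq values must be positive")
  if (!control %in% cq$sample) stopf("control sample '%s' not in Cq table", control)
  mean_cq <- function(samp, gene, role) {
    v <- cq$cq[cq$sample == samp & cq$gene == gene & cq$role == role]
    if (length(v) == 0)
      stopf("missing %s well for sample %s, gene %s", role, samp, gene)
    mean(v)
  }
  combos <- unique(cq[cq$sample != control, c("sample", "gene")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$sample[i]; g <- combos$gene[i]
    mt <- mean_cq(s, g, "target"); mr <- mean_cq(s, g, "reference")
    ct <- mean_cq(control, g, "target"); cr <- mean_cq(control, g, "reference")
    ddcq <- (mt - mr) - (ct - cr)
    fc <- 2^(-ddcq)
    data.frame(sample = s, gene = g, mean_cq_target = mt,
               mean_cq_reference = mr, ddcq = ddcq, fold_change = fc,
               amplified = fc >= fold_threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
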