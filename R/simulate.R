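#' Simulation configuration for a synthetic amplicon-panel cohort
#'
#' Defines the study conditions the generator emulates: ~125 unrelated
#' individuals from 8 southern-U.S. collection populations (one individual
#' per full-sibling family, so no kinship model), a ~122-gene detoxification
#' panel tiled by overlapping ~200 bp amplicons in two primer pools,
#' unbalanced bottle-bioassay phenotypes (malathion 90/125 resistant,
#' permethrin 106/125), planted causal SNPs acting on the log-odds of
#' resistance, planted gene duplications visible as >= 1.5x read depth in
#' carriers, and per-run/per-pool depth biases with negative-binomial
#' overdispersion.
#'
#' @param populations data frame `name`, `size`, `treated`. Default mirrors
#'   the study's collection table (sizes summing to 125).
#' @param n_genes,amplicons_per_gene,amplicon_length panel geometry
#'   (defaults 122 genes, ~10 amplicons each of 200 bp, jointly ~1255
#'   amplicons in two pools).
#' @param n_neutral_snps neutral SNP count (default 500).
#' @param neutral_freq_range allele-frequency spectrum for neutral SNPs
#'   (uniform draw, default 0.05-0.5).
#' @param causal_snps data frame `insecticide`, `effect` (log odds-ratio per
#'   alternate allele copy), `base_freq`. Default: one permethrin and one
#'   malathion causal SNP with odds ratio 8.
#' @param resistant_frac named marginal resistant fractions per insecticide
#'   (defaults 90/125 malathion, 106/125 permethrin).
#' @param duplications data frame `gene_id` (NA = pick at random),
#'   `copy_ratio` (>= 1), `carrier_frac_resistant`,
#'   `carrier_frac_susceptible`. Default: one 1.5x duplication carried by
#'   40\% of resistant and 5\% of susceptible samples.
#' @param mean_depth mean per-amplicon coverage (default 100x; the study
#'   reports 50x or more).
#' @param depth_dispersion negative-binomial size parameter (default 50).
#' @param sample_log_sd,run_size,run_log_sd,pool_log_sd depth-bias model:
#'   lognormal per-sample scale, sequencing-run block size (8-12 samples
#'   per chip; default 10) with lognormal run factors, and a lognormal
#'   run x primer-pool interaction.
#' @param missing_rate genotype missingness (default 0.02).
#' @param pop_freq_sd between-population allele-frequency jitter (drift;
#'   default 0 = none).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(
    populations = data.frame(
      name = c("AZU", "HCT", "HCU", "NOT", "NOU", "TXT", "TXU", "WCU"),
      size = c(7L, 16L, 14L, 13L, 17L, 19L, 19L, 20L),
      treated = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    n_genes = 122L, amplicons_per_gene = 10L, amplicon_length = 200L,
    n_neutral_snps = 500L, neutral_freq_range = c(0.05, 0.5),
    causal_snps = data.frame(
      insecticide = c("permethrin", "malathion"),
      effect = log(8), base_freq = 0.4, stringsAsFactors = FALSE),
    resistant_frac = c(malathion = 90 / 125, permethrin = 106 / 125),
    duplications = data.frame(
      gene_id = NA_character_, copy_ratio = 1.5,
      carrier_frac_resistant = 0.4, carrier_frac_susceptible = 0.05,
      stringsAsFactors = FALSE),
    mean_depth = 100, depth_dispersion = 50,
    sample_log_sd = 0.25, run_size = 10L, run_log_sd = 0.3,
    pool_log_sd = 0.15, missing_rate = 0.02, pop_freq_sd = 0) {
  stopifnot(all(populations$size > 0), n_genes >= 1,
            amplicons_per_gene >= 1, amplicon_length >= 50)
  if (any(duplications$copy_ratio < 1, na.rm = TRUE))
    stopf("copy_ratio must be >= 1")
  probs <- c(causal_snps$base_freq, duplications$carrier_frac_resistant,
             duplications$carrier_frac_susceptible, missing_rate,
             resistant_frac, neutral_freq_range)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  structure(
    list(populations = populations,
         n_individuals = sum(populations$size),
         n_genes = as.integer(n_genes),
         amplicons_per_gene = as.integer(amplicons_per_gene),
         amplicon_length = as.integer(amplicon_length),
         n_neutral_snps = as.integer(n_neutral_snps),
         neutral_freq_range = neutral_freq_range,
         causal_snps = causal_snps, resistant_frac = resistant_frac,
         duplications = duplications, mean_depth = mean_depth,
         depth_dispersion = depth_dispersion, sample_log_sd = sample_log_sd,
         run_size = as.integer(run_size), run_log_sd = run_log_sd,
         pool_log_sd = pool_log_sd, missing_rate = missing_rate,
         pop_freq_sd = pop_freq_sd),
    class = "sim_config")
}

random_cds <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a gene panel
#'
#' Generates a panel with the configured number of genes spread over
#' supercontigs (about 1.6 genes per supercontig, as in the study's 122
#' genes on 78 supercontigs), each with 2-6 exons separated by short
#' (< 100 bp) introns, random strand, and a random coding sequence whose
#' length is a multiple of 3.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return a [gene_panel()].
#' @export
simulate_panel <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n_sc <- max(1L, round(config$n_genes * 78 / 122))
  sc_of_gene <- sort(rep_len(seq_len(n_sc), config$n_genes))
  sc_names <- sprintf("sc%03d", seq_len(n_sc))
  genes <- vector("list", config$n_genes)
  sc_cursor <- stats::setNames(rep(1000L, n_sc), sc_names)
  for (i in seq_len(config$n_genes)) {
    scn <- sc_names[sc_of_gene[i]]
    n_ex <- sample(2:6, 1)
    ex_len <- sample(90:240, n_ex, replace = TRUE)
    excess <- sum(ex_len) %% 3L
    ex_len[n_ex] <- ex_len[n_ex] - excess  # CDS length divisible by 3
    introns <- sample(40:99, n_ex - 1, replace = TRUE)
    start <- sc_cursor[[scn]]
    starts <- start + cumsum(c(0L, ex_len[-n_ex] + introns))
    ends <- starts + ex_len - 1L
    sc_cursor[[scn]] <- max(ends) + 2L * 150L + 400L
    genes[[i]] <- list(
      gene_id = sprintf("GENE%03d", i), supercontig = scn,
      strand = sample(c("+", "-"), 1),
      exons = cbind(start = starts, end = ends),
      cds = random_cds(sum(ex_len)))
  }
  supercontigs <- data.frame(
    name = sc_names,
    length = as.integer(sc_cursor + 1000L), stringsAsFactors = FALSE)
  gene_panel(genes, supercontigs, flank_length = 150L)
}

#' Simulate the amplicon design for a panel
#'
#' Tiles each gene's span plus flanks with overlapping fixed-length
#' amplicons, alternating between two primer pools.
#'
#' @param panel a [gene_panel()].
#' @param config a [sim_config()].
#' @return amplicon table: `amplicon_id`, `gene_id`, `supercontig`, `start`,
#'   `end` (1-based inclusive), `pool`, `length`.
#' @export
simulate_amplicons <- function(panel, config = sim_config()) {
  rows <- lapply(panel$genes, function(g) {
    span <- gene_span(g)
    lo <- max(1L, span[1] - panel$flank_length)
    hi <- span[2] + panel$flank_length
    k <- config$amplicons_per_gene
    starts <- unique(round(seq(lo, max(lo, hi - config$amplicon_length + 1),
                               length.out = k)))
    data.frame(
      amplicon_id = sprintf("%s_amp%02d", g$gene_id, seq_along(starts)),
      gene_id = g$gene_id, supercontig = g$supercontig,
      start = as.integer(starts),
      end = as.integer(starts + config$amplicon_length - 1L),
      pool = rep_len(1:2, length(starts)),
      length = config$amplicon_length, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# supercontig position of the idx-th base (gene orientation) of a gene's CDS
supercontig_pos <- function(gene, idx) {
  lens <- gene$exons[, 2] - gene$exons[, 1] + 1L
  plus_idx <- if (gene$strand == "+") idx else sum(lens) - idx + 1L
  cum <- cumsum(lens)
  ex <- which(plus_idx <= cum)[1]
  offset_in_ex <- plus_idx - c(0L, cum)[ex] - 1L
  gene$exons[ex, 1] + offset_in_ex
}

#' Simulate genotypes for the cohort
#'
#' Places SNP sites at random exonic positions of the panel (reference
#' alleles consistent with each gene's coding sequence), draws
#' population-specific allele frequencies, and samples Hardy-Weinberg
#' genotypes per individual, with MCAR missingness. Causal sites from the
#' configuration are planted first and recorded in the returned truth.
#'
#' @param panel a [gene_panel()] (e.g. [simulate_panel()]).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `populations`
#'   (per-sample population labels) and `truth` (data frame of causal
#'   sites: `site`, `insecticide`, `effect`).
#' @export
simulate_genotypes <- function(panel, config = sim_config(), seed = 1) {
  set.seed(seed)
  pops <- config$populations
  pop_of <- rep(pops$name, pops$size)
  samples <- sprintf("%s_%02d", pop_of,
                     unlist(lapply(pops$size, seq_len)))
  n <- length(samples)
  n_causal <- nrow(config$causal_snps)
  n_snps <- config$n_neutral_snps + n_causal

  gene_ids <- names(panel$genes)
  used <- character(0)
  sites <- vector("list", n_snps)
  for (i in seq_len(n_snps)) {
    repeat {
      g <- panel$genes[[sample(gene_ids, 1)]]
      idx <- sample.int(nchar(g[["cds"]]), 1)
      pos <- supercontig_pos(g, idx)
      key <- site_id(g$supercontig, pos)
      if (!key %in% used) break
    }
    used <- c(used, key)
    base <- substr(g[["cds"]], idx, idx)
    ref <- if (g$strand == "+") base else complement_base(base)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    sites[[i]] <- data.frame(supercontig = g$supercontig,
                             position = as.integer(pos),
                             ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)

  base_freq <- c(config$causal_snps$base_freq,
                 stats::runif(config$n_neutral_snps,
                              config$neutral_freq_range[1],
                              config$neutral_freq_range[2]))
  dosage <- matrix(NA_integer_, n_snps, n)
  for (i in seq_len(n_snps)) {
    for (p in seq_len(nrow(pops))) {
      f <- base_freq[i]
      if (config$pop_freq_sd > 0)
        f <- min(1, max(0, f + stats::rnorm(1, 0, config$pop_freq_sd)))
      cols <- which(pop_of == pops$name[p])
      dosage[i, cols] <- stats::rbinom(length(cols), 2, f)
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < config$missing_rate
    dosage[miss] <- NA_integer_
  }
  colnames(dosage) <- samples
  truth <- if (n_causal > 0)
    data.frame(site = site_id(sites$supercontig, sites$position)[seq_len(n_causal)],
               insecticide = config$causal_snps$insecticide,
               effect = config$causal_snps$effect, stringsAsFactors = FALSE)
  else data.frame(site = character(0), insecticide = character(0),
                  effect = numeric(0))

  ord <- order(sites$supercontig, sites$position)
  gm <- genotype_matrix(dosage[ord, , drop = FALSE],
                        sites[ord, , drop = FALSE])
  list(genotypes = gm,
       populations = stats::setNames(pop_of, samples), truth = truth)
}

#' Simulate bottle-bioassay phenotypes
#'
#' Logistic model on causal alternate-allele dosages: for each insecticide
#' the log-odds of resistance are an intercept (calibrated so the marginal
#' resistant fraction matches the configured target given the cohort's mean
#' causal dosage) plus the causal effects. Missing causal dosages enter at
#' the cohort mean. This stands in for the bottle-bioassay outcome; the
#' assay-level classification rule itself is [simulate_bioassay_family()].
#'
#' @param sim output of [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return phenotype table: data frame `sample`, `population`, one column
#'   per insecticide with `"resistant"`/`"susceptible"`, plus attribute
#'   `intercepts`.
#' @export
simulate_phenotypes <- function(sim, config = sim_config(), seed = 1) {
  set.seed(seed)
  gm <- sim$genotypes
  samples <- colnames(gm$dosage)
  ids <- rownames(gm$dosage)
  out <- data.frame(sample = samples,
                    population = unname(sim$populations[samples]),
                    stringsAsFactors = FALSE)
  intercepts <- c()
  for (ins in names(config$resistant_frac)) {
    target <- config$resistant_frac[[ins]]
    causal <- sim$truth[sim$truth$insecticide == ins, , drop = FALSE]
    eta <- rep(0, length(samples))
    mean_term <- 0
    for (j in seq_len(nrow(causal))) {
      if (!causal$site[j] %in% ids) stopf("causal site missing from genotypes")
      d <- gm$dosage[causal$site[j], ]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      eta <- eta + causal$effect[j] * d
      mean_term <- mean_term + causal$effect[j] * mean(d)
    }
    b0 <- logit(target) - mean_term
    pr <- inv_logit(b0 + eta)
    out[[ins]] <- ifelse(stats::runif(length(samples)) < pr,
                         "resistant", "susceptible")
    intercepts[ins] <- b0
  }
  attr(out, "intercepts") <- intercepts
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Bottle-bioassay family classification
#'
#' Simulates mortality of one full-sibling family in the CDC bottle
#' bioassay and applies the classification rule: resistant if at most 80\%
#' of mosquitoes are dead at the diagnostic time (30 min for permethrin,
#' 45 min for malathion), susceptible if more than 80\% are dead.
#'
#' @param p_death per-mosquito probability of death by the diagnostic time.
#' @param n_mosquitoes mosquitoes in the bottle (typically 10-20; default
#'   20).
#' @param diagnostic_time minutes, recorded in the result (default 30).
#' @param seed optional RNG seed.
#' @return list: `n_dead`, `percent_dead`, `phenotype`, `diagnostic_time`.
#' @export
simulate_bioassay_family <- function(p_death, n_mosquitoes = 20,
                                     diagnostic_time = 30, seed = NULL) {
  if (n_mosquitoes <= 0) stopf("n_mosquitoes must be positive")
  stopifnot(p_death >= 0, p_death <= 1)
  if (!is.null(seed)) set.seed(seed)
  dead <- stats::rbinom(1, n_mosquitoes, p_death)
  pct <- 100 * dead / n_mosquitoes
  list(n_dead = dead, percent_dead = pct,
       phenotype = if (pct <= 80) "resistant" else "susceptible",
       diagnostic_time = diagnostic_time)
}

#' Simulate per-amplicon read depths
#'
#' Negative-binomial counts with mean = base depth x lognormal amplicon
#' bias x lognormal per-sample scale x sequencing-run factor x run-by-pool
#' factor x copy ratio (for duplication carriers, on the duplicated gene's
#' amplicons only). Runs are consecutive blocks of `run_size` samples
#' (sequencing chips); the run and run-by-pool factors are the systematic
#' batch structure the SVD stage is meant to remove.
#'
#' @param amplicons amplicon table from [simulate_amplicons()].
#' @param phenotypes phenotype table (used to enrich duplication carriers
#'   among resistant samples per the configuration).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list: `depths` (a [depth_matrix()]) and `truth` (data frame
#'   `gene_id`, `copy_ratio` plus attribute `carriers`, a named list of
#'   carrier sample IDs per duplicated gene).
#' @export
simulate_depths <- function(amplicons, phenotypes, config = sim_config(),
                            seed = 1) {
  set.seed(seed)
  samples <- phenotypes$sample
  n <- length(samples)
  n_amp <- nrow(amplicons)
  dup <- config$duplications
  dup <- dup[!is.na(dup$copy_ratio) & dup$copy_ratio > 0, , drop = FALSE]
  genes <- unique(amplicons$gene_id)
  carriers <- list()
  copy <- matrix(1, n_amp, n)
  if (nrow(dup) > 0) {
    for (j in seq_len(nrow(dup))) {
      g <- dup$gene_id[j]
      if (is.na(g)) g <- sample(setdiff(genes, names(carriers)), 1)
      res <- phenotypes$sample[phenotypes[[names(config$resistant_frac)[1]]] ==
                                 "resistant"]
      sus <- setdiff(samples, res)
      car <- c(res[stats::runif(length(res)) < dup$carrier_frac_resistant[j]],
               sus[stats::runif(length(sus)) < dup$carrier_frac_susceptible[j]])
      carriers[[g]] <- car
      amp_rows <- which(amplicons$gene_id == g)
      copy[amp_rows, match(car, samples)] <- dup$copy_ratio[j]
    }
  }
  amp_bias <- stats::rlnorm(n_amp, 0, 0.4)
  sample_factor <- stats::rlnorm(n, 0, config$sample_log_sd)
  run_of <- (seq_len(n) - 1L) %/% config$run_size + 1L
  n_runs <- max(run_of)
  run_factor <- stats::rlnorm(n_runs, 0, config$run_log_sd)
  pool_run <- matrix(stats::rlnorm(n_runs * 2, 0, config$pool_log_sd),
                     n_runs, 2)
  mu <- config$mean_depth * (amp_bias %o% (sample_factor * run_factor[run_of]))
  mu <- mu * pool_run[cbind(rep(run_of, each = n_amp),
                            rep(amplicons$pool, n))]
  mu <- mu * copy
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$depth_dispersion),
                   n_amp, n, dimnames = list(amplicons$amplicon_id, samples))
  truth <- data.frame(gene_id = as.character(names(carriers)),
                      copy_ratio = dup$copy_ratio[seq_along(carriers)],
                      stringsAsFactors = FALSE)
  attr(truth, "carriers") <- carriers
  list(depths = depth_matrix(counts, amplicons), truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Runs the four generators in sequence (panel, amplicon design, genotypes,
#' phenotypes, depths) under seeds derived from one master seed, returning
#' every matrix plus the ground truth needed to score recovery.
#'
#' @param config a [sim_config()].
#' @param seed master seed; stage seeds are `seed`, `seed + 1`, ....
#' @return object of class `ir_cohort`: list `panel`, `amplicons`,
#'   `genotypes`, `phenotypes`, `depths`, `truth` (list `causal`,
#'   `duplications`, `intercepts`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  panel <- simulate_panel(config, seed)
  amplicons <- simulate_amplicons(panel, config)
  gsim <- simulate_genotypes(panel, config, seed + 1L)
  pheno <- simulate_phenotypes(gsim, config, seed + 2L)
  dsim <- simulate_depths(amplicons, pheno, config, seed + 3L)
  structure(
    list(panel = panel, amplicons = amplicons, genotypes = gsim$genotypes,
         phenotypes = pheno, depths = dsim$depths,
         truth = list(causal = gsim$truth, duplications = dsim$truth,
                      intercepts = attr(pheno, "intercepts"))),
    class = "ir_cohort")
}

#' @export
print.ir_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d samples, %d SNPs, %d genes / %d amplicons\n",
    ncol(x$genotypes$dosage), nrow(x$genotypes$dosage),
    length(x$panel$genes), nrow(x$depths$counts)))
  cat(sprintf("  causal SNPs: %d; duplicated genes: %d\n",
              nrow(x$truth$causal), nrow(x$truth$duplications)))
  invisible(x)
}
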