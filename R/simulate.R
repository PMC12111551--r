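#' Simulation configuration for the synthetic cross-disorder screen
#'
#' Bundles every knob of the synthetic-data generator: an LD-blocked SNP
#' panel, two independent case-control cohorts (trait A, cancer-like; trait
#' B, autoimmune-like), planted per-SNP effect classes, a gene annotation
#' and per-cohort expression matrices driven by a latent immune-infiltration
#' factor.
#'
#' Defaults describe the regime the screen is designed for: large
#' biobank-scale case-control GWAS (50,000 cases and 50,000 controls per
#' trait), strong local LD (adjacent-SNP correlation 0.9 within a block),
#' common variants (MAF 0.05--0.5) and a strong infiltration factor
#' (loading 0.9) in four tumor expression cohorts of 500 samples each.
#'
#' @param seed integer seed; identical config + seed reproduces every
#'   generated object exactly.
#' @param n_snps number of SNPs on the (single) synthetic chromosome.
#' @param n_blocks number of LD blocks; SNPs are split into contiguous
#'   blocks of near-equal size and are independent across blocks.
#' @param block_rho target correlation between *adjacent SNP genotypes*
#'   within a block, in `[0, 1)`; correlation decays as
#'   `block_rho^distance`.
#' @param maf_range length-2 numeric in (0, 0.5]; each block draws one MAF
#'   uniformly from this range.
#' @param n_cases_a,n_controls_a,n_cases_b,n_controls_b sample sizes of the
#'   two (independent, non-overlapping) GWAS cohorts.
#' @param planted_effects list of [planted_effect()] objects.
#' @param chrom_length chromosome length in bp; positions are drawn
#'   uniformly without replacement and sorted.
#' @param n_genes number of genes in the synthetic annotation.
#' @param n_samples_expr samples per expression cohort.
#' @param n_cohorts number of expression cohorts (the four immune-cold
#'   cancer types by default).
#' @param infiltration_loading loading in `[0, 1]` of marker and driven genes
#'   on the latent infiltration factor.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [planted_effect()], [simulate_ld_genotypes()],
#'   [simulate_pair_sumstats()], [simulate_expression()]
#' @export
simulation_config <- function(seed = 1L,
                              n_snps = 600L,
                              n_blocks = 40L,
                              block_rho = 0.9,
                              maf_range = c(0.05, 0.5),
                              n_cases_a = 50000L, n_controls_a = 50000L,
                              n_cases_b = 50000L, n_controls_b = 50000L,
                              planted_effects = list(),
                              chrom_length = 2.5e8,
                              n_genes = 200L,
                              n_samples_expr = 500L,
                              n_cohorts = 4L,
                              infiltration_loading = 0.9) {
  counts <- c(n_snps = n_snps, n_blocks = n_blocks,
              n_cases_a = n_cases_a, n_controls_a = n_controls_a,
              n_cases_b = n_cases_b, n_controls_b = n_controls_b,
              chrom_length = chrom_length, n_genes = n_genes,
              n_samples_expr = n_samples_expr, n_cohorts = n_cohorts)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all counts must be positive", call. = FALSE)
  if (n_blocks > n_snps)
    stop("n_blocks must not exceed n_snps", call. = FALSE)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (block_rho < 0 || block_rho >= 1)
    stop("block_rho must be in [0, 1)", call. = FALSE)
  if (infiltration_loading < 0 || infiltration_loading > 1)
    stop("infiltration_loading must be in [0, 1]", call. = FALSE)
  if (chrom_length < n_snps)
    stop("chrom_length must allow n_snps distinct positions", call. = FALSE)
  for (pe in planted_effects) {
    if (!inherits(pe, "planted_effect"))
      stop("planted_effects must be a list of planted_effect()", call. = FALSE)
    if (pe$snp_index < 1L || pe$snp_index > n_snps)
      stop("planted snp_index out of range", call. = FALSE)
  }
  idx <- vapply(planted_effects, `[[`, integer(1), "snp_index")
  if (anyDuplicated(idx))
    stop("duplicate planted snp_index", call. = FALSE)
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 n_blocks = as.integer(n_blocks), block_rho = block_rho,
                 maf_range = maf_range,
                 n_cases_a = n_cases_a, n_controls_a = n_controls_a,
                 n_cases_b = n_cases_b, n_controls_b = n_controls_b,
                 planted_effects = planted_effects,
                 chrom_length = chrom_length, n_genes = as.integer(n_genes),
                 n_samples_expr = as.integer(n_samples_expr),
                 n_cohorts = as.integer(n_cohorts),
                 infiltration_loading = infiltration_loading),
            class = "sim_config")
}

#' Planted per-SNP effect
#'
#' Declares the true log-odds effects of one SNP on the two traits. Classes
#' encode the patterns the screen must separate: `opposite` (the antagonistic
#' pattern the pipeline hunts for), `concordant` (same direction -- cancelled
#' by the sign flip), `heterogeneous` (opposite but incompatible magnitudes
#' -- removed by the Q test), `a_only`/`b_only` (single-trait), and `null`.
#'
#' @param snp_index 1-based index into the simulated SNP panel.
#' @param class one of `"null"`, `"opposite"`, `"concordant"`,
#'   `"heterogeneous"`, `"a_only"`, `"b_only"`.
#' @param beta_a,beta_b true log odds ratios on traits A (cancer-like) and B
#'   (autoimmune-like), on the original, unflipped scale.
#' @return object of class `planted_effect`.
#' @export
planted_effect <- function(snp_index, class, beta_a = 0, beta_b = 0) {
  class <- match.arg(class, c("null", "opposite", "concordant",
                              "heterogeneous", "a_only", "b_only"))
  ok <- switch(class,
    null         = beta_a == 0 && beta_b == 0,
    opposite     = beta_a * beta_b < 0,
    concordant   = beta_a * beta_b > 0,
    heterogeneous = beta_a != 0 && beta_b != 0,
    a_only       = beta_a != 0 && beta_b == 0,
    b_only       = beta_a == 0 && beta_b != 0)
  if (!ok)
    stop("betas inconsistent with class '", class, "'", call. = FALSE)
  structure(list(snp_index = as.integer(snp_index), class = class,
                 beta_a = beta_a, beta_b = beta_b),
            class = "planted_effect")
}

#' Plant one effect per LD block
#'
#' Convenience constructor that places causal SNPs at the centre of
#' successive LD blocks, one per class entry. Used to set up recovery
#' experiments where each planted locus should surface as exactly one lead
#' SNP.
#'
#' @param config a [simulation_config()] (its `planted_effects` are ignored).
#' @param classes character vector of effect classes, one block each (must
#'   not exceed `n_blocks`).
#' @param beta absolute log-odds effect size for non-null classes.
#' @param het_ratio for class `"heterogeneous"`, |beta_b|/|beta_a|.
#' @return list of [planted_effect()] suitable for `planted_effects`.
#' @export
plant_block_effects <- function(config, classes, beta = 0.15, het_ratio = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (length(classes) > config$n_blocks)
    stop("more classes than blocks", call. = FALSE)
  blocks <- block_index(config$n_snps, config$n_blocks)
  lapply(seq_along(classes), function(i) {
    idx <- which(blocks == i)
    mid <- idx[ceiling(length(idx) / 2)]
    switch(classes[i],
      null         = planted_effect(mid, "null"),
      opposite     = planted_effect(mid, "opposite",  beta, -beta),
      concordant   = planted_effect(mid, "concordant", beta,  beta),
      heterogeneous = planted_effect(mid, "heterogeneous", beta / het_ratio,
                                     -beta * het_ratio),
      a_only       = planted_effect(mid, "a_only", beta, 0),
      b_only       = planted_effect(mid, "b_only", 0, beta),
      stop("unknown class ", classes[i], call. = FALSE))
  })
}

# contiguous block membership, sizes differing by at most 1
block_index <- function(n_snps, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_snps))
}

#' Simulate LD-structured genotype dosages and a SNP map
#'
#' Haplotypes follow a first-order Markov allele-copying process per LD
#' block: the first allele is Bernoulli(MAF) and each subsequent allele
#' copies its left neighbour with probability `block_rho`, otherwise it is
#' a fresh Bernoulli(MAF) draw (MAF is constant within a block). The
#' correlation between SNP genotypes at within-block distance d is then
#' exactly `block_rho^d` in population -- `block_rho` for adjacent pairs --
#' and 0 across blocks. Dosages are the sum of two independent haplotypes,
#' in {0, 1, 2}.
#'
#' SNPs carrying a planted effect are assigned non-palindromic allele pairs
#' so that downstream palindrome-ambiguity filtering can never silently drop
#' a planted locus.
#'
#' @param config a [simulation_config()].
#' @param n_individuals rows of the dosage matrix (the LD reference size).
#' @return list with `genotypes` (n_individuals x n_snps integer matrix,
#'   columns named by rsid) and `snp_map` (data.frame: rsid, chrom, pos,
#'   effect_allele, other_allele, maf, block).
#' @export
simulate_ld_genotypes <- function(config, n_individuals = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_individuals < 2L)
    stop("n_individuals must be at least 2", call. = FALSE)
  snp_map <- simulate_snp_map(config)
  block_maf <- attr(snp_map, "block_maf")
  set.seed(config$seed + 10L)
  m <- config$n_snps
  blocks <- snp_map$block

  geno <- matrix(0L, n_individuals, m)
  rho <- config$block_rho
  for (b in seq_len(config$n_blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    p <- block_maf[b]
    dose <- matrix(0L, n_individuals, k)
    for (hap in 1:2) {
      fresh <- matrix(runif(n_individuals * k) < p, n_individuals, k)
      x <- fresh
      if (k > 1L && rho > 0) {
        copy <- matrix(runif(n_individuals * k) < rho, n_individuals, k)
        for (j in 2:k)
          x[, j] <- ifelse(copy[, j], x[, j - 1], fresh[, j])
      }
      dose <- dose + x
    }
    geno[, idx] <- dose
  }
  colnames(geno) <- snp_map$rsid
  list(genotypes = geno, snp_map = snp_map)
}

#' Simulate the SNP map alone
#'
#' Draws the SNP panel (ids, positions, allele pairs, per-block MAFs)
#' without materializing genotypes; useful for large analytic-mode
#' simulations where the LD reference is not needed. Identical to the
#' `snp_map` element of [simulate_ld_genotypes()] for the same config.
#'
#' @param config a [simulation_config()].
#' @return data.frame: rsid, chrom, pos, effect_allele, other_allele, maf,
#'   block.
#' @export
simulate_snp_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  blocks <- block_index(m, config$n_blocks)
  block_maf <- runif(config$n_blocks, config$maf_range[1], config$maf_range[2])
  pos <- sort(sample.int(config$chrom_length, m))
  planted_idx <- vapply(config$planted_effects, `[[`, integer(1), "snp_index")

  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("A", "T"), c("C", "G"))
  pick <- sample.int(6L, m, replace = TRUE)
  # planted SNPs: redraw palindromic pairs (rows 5-6) from the 4 safe pairs
  if (length(planted_idx))
    pick[planted_idx] <- sample.int(4L, length(planted_idx), replace = TRUE)
  flip <- runif(m) < 0.5
  snp_map <- data.frame(rsid = sprintf("rs%06d", seq_len(m)), chrom = "1",
                        pos = pos,
                        effect_allele = ifelse(flip, pairs[pick, 2],
                                               pairs[pick, 1]),
                        other_allele = ifelse(flip, pairs[pick, 1],
                                              pairs[pick, 2]),
                        maf = block_maf[blocks], block = blocks,
                        stringsAsFactors = FALSE)
  attr(snp_map, "block_maf") <- block_maf
  snp_map
}

# effective sample size of a case-control study
n_eff <- function(cases, controls) 4 / (1 / cases + 1 / controls)

# analytic SE of a per-SNP log-odds estimate at effect-allele frequency p
analytic_se <- function(p, cases, controls) {
  1 / sqrt(2 * n_eff(cases, controls) * p * (1 - p))
}

# true marginal effects: propagate planted causal betas through within-block
# empirical LD (r * sqrt(var_c / var_j) * beta_c); without genotypes only the
# causal SNP itself carries signal.
marginal_betas <- function(beta_true, genotypes, snp_map) {
  out <- beta_true
  causal <- which(beta_true != 0)
  if (!length(causal) || is.null(genotypes)) return(out)
  out <- numeric(length(beta_true))
  for (c in causal) {
    idx <- which(snp_map$block == snp_map$block[c])
    g_c <- genotypes[, c]
    v_c <- stats::var(g_c)
    if (v_c == 0) stop("planted effect on monomorphic SNP", call. = FALSE)
    r <- suppressWarnings(cor(genotypes[, idx, drop = FALSE], g_c))
    v_j <- apply(genotypes[, idx, drop = FALSE], 2, stats::var)
    contrib <- ifelse(v_j > 0, r * sqrt(v_c / v_j) * beta_true[c], 0)
    out[idx] <- out[idx] + contrib
  }
  out
}

sumstats_one_trait <- function(genotypes, snp_map, beta_true, cases, controls,
                               mode, swap_fraction, flip_fraction) {
  m <- nrow(snp_map)
  if (mode == "analytic") {
    eaf <- if (is.null(genotypes)) snp_map$maf else colMeans(genotypes) / 2
    if (any(eaf[beta_true != 0] %in% c(0, 1)))
      stop("planted effect on monomorphic SNP", call. = FALSE)
    eaf_se <- pmin(pmax(eaf, 1e-6), 1 - 1e-6)
    se <- analytic_se(eaf_se, cases, controls)
    bmar <- marginal_betas(beta_true, genotypes, snp_map)
    beta <- rnorm(m, bmar, se)
  } else { # explicit phenotype simulation, score-test estimates
    if (is.null(genotypes))
      stop("phenotype mode requires genotypes", call. = FALSE)
    n <- cases + controls
    if (nrow(genotypes) != n)
      stop("phenotype mode needs one genotype row per subject", call. = FALSE)
    eaf <- colMeans(genotypes) / 2
    if (any(eaf[beta_true != 0] %in% c(0, 1)))
      stop("planted effect on monomorphic SNP", call. = FALSE)
    causal <- which(beta_true != 0)
    eta <- qlogis(cases / n) +
      if (length(causal))
        as.vector(scale(genotypes[, causal, drop = FALSE], scale = FALSE) %*%
                    beta_true[causal])
      else 0
    y <- rbinom(n, 1L, plogis(eta))
    phat <- mean(y)
    gc <- scale(genotypes, scale = FALSE)
    ss <- colSums(gc^2)
    info_fisher <- pmax(phat * (1 - phat) * ss, 1e-12)
    score <- as.vector(crossprod(gc, y - phat))
    beta <- score / info_fisher
    se <- 1 / sqrt(info_fisher)
  }
  p <- 2 * pnorm(-abs(beta / se))
  out <- data.frame(rsid = snp_map$rsid, chrom = snp_map$chrom,
                    pos = snp_map$pos,
                    effect_allele = snp_map$effect_allele,
                    other_allele = snp_map$other_allele,
                    eaf = eaf, info = runif(m, 0.9, 1),
                    beta = beta, se = se, p = p,
                    stringsAsFactors = FALSE)
  # optional allele-encoding perturbations to exercise harmonization
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  u <- runif(m)
  swap <- u < swap_fraction
  if (any(swap)) {
    tmp <- out$effect_allele[swap]
    out$effect_allele[swap] <- out$other_allele[swap]
    out$other_allele[swap] <- tmp
    out$beta[swap] <- -out$beta[swap]
    out$eaf[swap] <- 1 - out$eaf[swap]
  }
  flip <- u >= swap_fraction & u < swap_fraction + flip_fraction
  if (any(flip)) {
    out$effect_allele[flip] <- unname(comp[out$effect_allele[flip]])
    out$other_allele[flip] <- unname(comp[out$other_allele[flip]])
  }
  out
}

#' Simulate a pair of GWAS summary-statistic tables
#'
#' Draws per-SNP effect estimates for two independent case-control cohorts
#' (trait A, cancer-like; trait B, autoimmune-like) around the planted true
#' log-odds effects. In the default `"analytic"` mode each estimate is drawn
#' as beta-hat ~ Normal(beta_marginal, se^2) with
#' `se = 1/sqrt(2 * n_eff * p * (1 - p))`, `n_eff = 4/(1/cases + 1/controls)`,
#' and beta_marginal propagated through the empirical within-block LD of the
#' supplied genotypes. In `"phenotype"` mode binary outcomes are drawn from a
#' logistic model (intercept set to hit the configured case fraction) and
#' per-SNP estimates come from the one-step score statistic.
#'
#' @param genotypes dosage matrix from [simulate_ld_genotypes()] (may be
#'   `NULL` in analytic mode, in which case the configured MAFs are used and
#'   LD is ignored).
#' @param snp_map SNP map from [simulate_ld_genotypes()].
#' @param config a [simulation_config()].
#' @param mode `"analytic"` (default) or `"phenotype"`.
#' @param swap_fraction,flip_fraction fraction of SNPs (trait B only) whose
#'   allele encoding is perturbed -- effect/other swapped (with beta and EAF
#'   adjusted accordingly) or strand-complemented -- to exercise downstream
#'   harmonization. Defaults 0.
#' @return list with elements `a` and `b`, each a summary-statistic
#'   data.frame with columns rsid, chrom, pos, effect_allele, other_allele,
#'   eaf, info, beta, se, p.
#' @export
simulate_pair_sumstats <- function(genotypes, snp_map, config,
                                   mode = c("analytic", "phenotype"),
                                   swap_fraction = 0, flip_fraction = 0) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  m <- nrow(snp_map)
  beta_a <- beta_b <- numeric(m)
  for (pe in config$planted_effects) {
    beta_a[pe$snp_index] <- pe$beta_a
    beta_b[pe$snp_index] <- pe$beta_b
  }
  set.seed(config$seed + 1L)
  a <- sumstats_one_trait(genotypes, snp_map, beta_a,
                          config$n_cases_a, config$n_controls_a, mode, 0, 0)
  set.seed(config$seed + 2L)
  b <- sumstats_one_trait(genotypes, snp_map, beta_b,
                          config$n_cases_b, config$n_controls_b, mode,
                          swap_fraction, flip_fraction)
  list(a = a, b = b)
}

#' Simulate a synthetic gene annotation
#'
#' Tiles `n_genes` non-overlapping gene bodies along the synthetic
#' chromosome (1-based inclusive coordinates) so that nearest-gene mapping
#' and enrichment have a universe to work against.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns chrom, start, end, strand, gene_id,
#'   symbol.
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- config$n_genes
  slot <- config$chrom_length / n
  width <- pmax(1, round(runif(n, 0.1, 0.6) * slot))
  start <- round((seq_len(n) - 1) * slot + runif(n, 0, 0.3) * slot) + 1
  end <- pmin(start + width - 1, config$chrom_length)
  data.frame(chrom = "1", start = start, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             gene_id = sprintf("ENSG%08d", seq_len(n)),
             symbol = sprintf("G%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Simulate immune gene list and pathway gene sets
#'
#' Builds an immune-gene membership list containing the designated immune
#' genes plus random fillers, and a collection of pathway gene sets across
#' named databases, some labelled with immune-related keywords and seeded
#' with the driven genes.
#'
#' @param genes gene annotation from [simulate_gene_annotation()].
#' @param immune_genes character vector of symbols to place on the immune
#'   list.
#' @param driven_genes symbols seeded into the immune-keyword pathways.
#' @param n_pathways_per_db pathways per database.
#' @param databases database tags.
#' @param seed integer seed.
#' @return list with `immune` (a gene_set) and `pathways` (list of
#'   gene_sets, each tagged with a `database` attributeed field).
#' @export
simulate_gene_sets <- function(genes, immune_genes, driven_genes = character(),
                               n_pathways_per_db = 12L,
                               databases = c("Reactome", "WikiPathway",
                                             "KEGG", "Hallmark"),
                               seed = 1L) {
  set.seed(seed + 4L)
  universe <- genes$symbol
  immune <- gene_set("immune_list", "synthetic immune-related genes",
                     unique(c(immune_genes,
                              sample(universe, min(30L, length(universe))))))
  imm_names <- c("T-cell receptor signaling", "Interferon alpha response",
                 "Cytokine signaling", "Natural killer cell cytotoxicity",
                 "Inflammatory response", "Leukocyte migration")
  other_names <- c("Oxidative phosphorylation", "Lipid metabolism",
                   "DNA repair", "Cell cycle checkpoints", "Axon guidance",
                   "Ribosome biogenesis", "Glycolysis", "Protein secretion")
  pathways <- list()
  for (db in databases) {
    for (i in seq_len(n_pathways_per_db)) {
      immune_themed <- i <= 2L
      nm <- if (immune_themed) sample(imm_names, 1) else sample(other_names, 1)
      nm <- paste0(nm, " (", db, " ", i, ")")
      members <- sample(universe, sample(10:25, 1))
      if (immune_themed) members <- unique(c(driven_genes, members))
      gs <- gene_set(nm, db, members, database = db)
      pathways[[length(pathways) + 1L]] <- gs
    }
  }
  list(immune = immune, pathways = pathways)
}

#' Simulate per-cohort tumor expression matrices with a latent
#' infiltration factor
#'
#' Each cohort gets one latent immune-infiltration factor per sample;
#' marker genes and driven genes load on it with `infiltration_loading`,
#' all other genes are independent Gaussian noise. Every gene row is then
#' Z-scored across samples (mean 0, SD 1), matching the normalization of
#' the expression inputs the prioritization step expects.
#'
#' @param config a [simulation_config()].
#' @param driven_genes symbols of genes driven by the factor (the planted
#'   "true targets").
#' @param marker_genes symbols of the infiltration marker genes.
#' @param genes optional symbol universe; defaults to `G001..` plus any
#'   driven/marker symbols not already present.
#' @param cohorts cohort labels.
#' @return named list of numeric matrices (genes x samples), one per cohort.
#' @export
simulate_expression <- function(config, driven_genes, marker_genes,
                                genes = NULL,
                                cohorts = NULL) {
  stopifnot(inherits(config, "sim_config"))
  loading <- config$infiltration_loading
  if (loading < 0 || loading > 1)
    stop("infiltration_loading must be in [0, 1]", call. = FALSE)
  if (is.null(genes))
    genes <- unique(c(sprintf("G%03d", seq_len(config$n_genes)),
                      marker_genes))
  if (!all(driven_genes %in% genes) || !all(marker_genes %in% genes))
    stop("driven and marker genes must be subsets of the gene universe",
         call. = FALSE)
  if (is.null(cohorts))
    cohorts <- paste0("cohort", seq_len(config$n_cohorts))
  set.seed(config$seed + 5L)
  n <- config$n_samples_expr
  loads <- ifelse(genes %in% c(driven_genes, marker_genes), loading, 0)
  out <- lapply(cohorts, function(cc) {
    f <- rnorm(n)
    eps <- matrix(rnorm(length(genes) * n), length(genes), n)
    x <- loads %o% f + sqrt(1 - loads^2) * eps
    x <- t(scale(t(x))) # row z-score
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    dimnames(x) <- list(genes, paste0(cc, "_s", seq_len(n)))
    x
  })
  names(out) <- cohorts
  out
}

#' Simulate eQTL records for lead SNPs
#'
#' Produces one cis-eQTL record per (SNP, gene) pair with a Z-score whose
#' sign encodes the planted regulatory direction relative to the SNP's
#' effect allele.
#'
#' @param snp_map SNP map rows for the SNPs of interest.
#' @param genes character vector of gene symbols, parallel to `snp_map`.
#' @param z eQTL Z-scores relative to each SNP's effect allele.
#' @return data.frame with columns rsid, gene, effect_allele, other_allele,
#'   z, p.
#' @export
simulate_eqtl <- function(snp_map, genes, z) {
  stopifnot(nrow(snp_map) == length(genes), length(z) == length(genes))
  data.frame(rsid = snp_map$rsid, gene = genes,
             effect_allele = snp_map$effect_allele,
             other_allele = snp_map$other_allele,
             z = z, p = 2 * pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}
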