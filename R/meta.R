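#' Screening thresholds for the cross-disorder scan
#'
#' Collects every threshold of the screen: per-trait inclusion p < 1e-3 for
#' both disorders, combined genome-wide significance p < 5e-8,
#' heterogeneity exclusion at Cochran's Q p < 0.05, the QC bounds, the LD
#' r-squared defining lead SNPs (0.1), the 1 Mb block-merge distance, and
#' the Spearman rho > 0.5 prioritization cutoff.
#'
#' @param p_trait_max per-trait association p-value ceiling (exclusive).
#' @param p_meta_max combined meta-analysis p-value ceiling (exclusive).
#' @param p_het_min minimum heterogeneity p (records with `p_het <`
#'   this value are excluded).
#' @param maf_min,info_min QC thresholds (inclusive, see
#'   [apply_qc_filters()]).
#' @param r2_lead LD r-squared at or above which a SNP is absorbed into a
#'   lead SNP's clump.
#' @param merge_distance maximum distance (bp) between LD-block spans
#'   merged into a single region.
#' @param rho_min Spearman correlation threshold (strict >) for expression
#'   prioritization.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(p_trait_max = 1e-3, p_meta_max = 5e-8,
                          p_het_min = 0.05, maf_min = 0.005, info_min = 0.3,
                          r2_lead = 0.1, merge_distance = 1e6,
                          rho_min = 0.5) {
  probs <- c(p_trait_max = p_trait_max, p_meta_max = p_meta_max,
             p_het_min = p_het_min)
  if (any(probs <= 0) || any(probs > 1))
    stop("p-value thresholds must be in (0, 1]", call. = FALSE)
  if (maf_min < 0 || maf_min > 0.5 || info_min < 0 || info_min > 1)
    stop("invalid QC thresholds", call. = FALSE)
  if (r2_lead < 0 || r2_lead > 1 || rho_min < -1 || rho_min > 1)
    stop("correlation thresholds out of range", call. = FALSE)
  if (merge_distance < 0) stop("merge_distance must be >= 0", call. = FALSE)
  structure(list(p_trait_max = p_trait_max, p_meta_max = p_meta_max,
                 p_het_min = p_het_min, maf_min = maf_min,
                 info_min = info_min, r2_lead = r2_lead,
                 merge_distance = merge_distance, rho_min = rho_min),
            class = "screen_config")
}

#' Fixed-effect inverse-variance-weighted meta-analysis of two studies
#'
#' Combines per-SNP estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = (w_a*beta_a + w_b*beta_b) / (w_a + w_b)`,
#' `se_meta = (w_a + w_b)^(-1/2)`, `z = beta_meta/se_meta`, and a two-sided
#' p-value from the normal tail. The tail is evaluated in log space, so
#' `mlog10p` (-log10 p) stays accurate far below the smallest normalized
#' double; `p` itself underflows gracefully.
#'
#' All arguments are vectorized.
#'
#' @param beta_a,se_a cancer-trait estimates and standard errors.
#' @param beta_b_flipped,se_b sign-flipped autoimmune estimates and
#'   standard errors.
#' @return data.frame with columns beta_meta, se_meta, z, p_meta, mlog10p.
#' @export
ivw_meta <- function(beta_a, se_a, beta_b_flipped, se_b) {
  if (any(se_a <= 0) || any(se_b <= 0))
    stop("standard errors must be positive", call. = FALSE)
  w_a <- 1 / se_a^2
  w_b <- 1 / se_b^2
  beta_meta <- (w_a * beta_a + w_b * beta_b_flipped) / (w_a + w_b)
  se_meta <- 1 / sqrt(w_a + w_b)
  z <- beta_meta / se_meta
  log_tail <- pnorm(-abs(z), log.p = TRUE) + log(2)
  data.frame(beta_meta = beta_meta, se_meta = se_meta, z = z,
             p_meta = pmin(exp(log_tail), 1),
             mlog10p = -log_tail / log(10))
}

#' Cochran's Q heterogeneity test for two studies
#'
#' `Q = w_a*(beta_a - beta_meta)^2 + w_b*(beta_b - beta_meta)^2` with
#' `w_i = 1/se_i^2`; under homogeneity Q is chi-squared with k - 1 = 1
#' degree of freedom. Computed on the same (flipped) scale as the
#' meta-analysis.
#'
#' @inheritParams ivw_meta
#' @param beta_meta combined estimate from [ivw_meta()]; recomputed when
#'   omitted.
#' @return data.frame with columns q and p_het.
#' @export
cochran_q <- function(beta_a, se_a, beta_b_flipped, se_b, beta_meta = NULL) {
  if (any(se_a <= 0) || any(se_b <= 0))
    stop("standard errors must be positive", call. = FALSE)
  if (is.null(beta_meta))
    beta_meta <- ivw_meta(beta_a, se_a, beta_b_flipped, se_b)$beta_meta
  q <- (beta_a - beta_meta)^2 / se_a^2 + (beta_b_flipped - beta_meta)^2 / se_b^2
  data.frame(q = q, p_het = pchisq(q, df = 1, lower.tail = FALSE))
}

sign_char <- function(x) ifelse(x > 0, "+", ifelse(x < 0, "-", "0"))

#' Screen a harmonized trait pair for opposite-effect variants
#'
#' Applies the full per-pair screen in fixed order: (1) keep SNPs with
#' original-trait p below `p_trait_max` in *both* disorders; (2) run the
#' IVW meta-analysis and Cochran's Q on the survivors (trait B on the
#' flipped scale); (3) exclude heterogeneous SNPs (`p_het < p_het_min`) and
#' keep combined genome-wide-significant SNPs (`p_meta < p_meta_max`).
#' Because trait B was sign-flipped before meta-analysis, every retained
#' SNP had opposite allelic effects on the two disorders on their original
#' scales.
#'
#' @param pair a [harmonize_pair()] result whose `b` table has been passed
#'   through [flip_sign()] (enforced).
#' @param config a [screen_config()].
#' @return data.frame of retained records: rsid, chrom, pos, effect_allele,
#'   other_allele, beta_a, se_a, p_a, beta_b_flipped, se_b, p_b, beta_meta,
#'   se_meta, z, p_meta, mlog10p, q, p_het, direction (two characters, the
#'   allelic effect signs on the ORIGINAL trait scales). Attribute
#'   `"screen_log"` carries the per-stage counts.
#' @export
screen_pair <- function(pair, config = screen_config()) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (!isTRUE(attr(pair$b, "sign_flipped")))
    stop("trait B must be sign-flipped (flip_sign) before screening",
         call. = FALSE)
  a <- pair$a
  b <- pair$b
  n_input <- nrow(a)
  keep <- a$p < config$p_trait_max & b$p < config$p_trait_max
  n_fail_trait <- sum(!keep)
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]

  if (nrow(a)) {
    m <- ivw_meta(a$beta, a$se, b$beta, b$se)
    h <- cochran_q(a$beta, a$se, b$beta, b$se, m$beta_meta)
  } else {
    m <- data.frame(beta_meta = numeric(), se_meta = numeric(),
                    z = numeric(), p_meta = numeric(), mlog10p = numeric())
    h <- data.frame(q = numeric(), p_het = numeric())
  }
  fail_het <- h$p_het < config$p_het_min
  fail_meta <- m$p_meta >= config$p_meta_max
  keep2 <- !fail_het & !fail_meta
  out <- data.frame(rsid = a$rsid, chrom = a$chrom, pos = a$pos,
                    effect_allele = a$effect_allele,
                    other_allele = a$other_allele,
                    beta_a = a$beta, se_a = a$se, p_a = a$p,
                    beta_b_flipped = b$beta, se_b = b$se, p_b = b$p,
                    m, h,
                    direction = paste0(sign_char(a$beta),
                                       sign_char(-b$beta)),
                    stringsAsFactors = FALSE)[keep2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen_log") <- data.frame(
    stage = c("input", "fail_trait_p", "meta_tested", "fail_het",
              "fail_meta_p", "retained"),
    n = c(n_input, n_fail_trait, nrow(a), sum(fail_het),
          sum(fail_meta & !fail_het), nrow(out)),
    stringsAsFactors = FALSE)
  out
}

#' @rdname screen_pair
#' @param x a table returned by [screen_pair()].
#' @export
screen_log <- function(x) attr(x, "screen_log")
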