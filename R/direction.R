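#' Align eQTL effect direction to the cancer-risk allele
#'
#' For each lead SNP / nearest-gene pair, defines the cancer-risk allele as
#' the effect allele when the cancer beta is positive, otherwise the other
#' allele, then harmonizes the eQTL record's alleles to that risk allele
#' (negating the eQTL Z on an allele swap, relabelling strand complements
#' and re-checking) and classifies by the sign of the harmonized Z:
#' `risk_allele_increases_expression`, `risk_allele_decreases_expression`,
#' or `unresolvable` (palindromic allele pairs -- strand orientation cannot
#' be verified -- incompatible allele sets, a gene mismatch, or Z = 0),
#' with the reason logged.
#'
#' @param leads data.frame with columns rsid, gene (the nearest gene),
#'   effect_allele, other_allele and beta_cancer (cancer-scale effect of
#'   the effect allele; a Z-score works too, only the sign is used).
#' @param eqtls data.frame of eQTL records with columns rsid, gene,
#'   effect_allele, other_allele, z (see [simulate_eqtl()] or
#'   [load_fixture()]).
#' @return the leads table with columns risk_allele, eqtl_z_risk (Z
#'   harmonized to the risk allele), classification and reason.
#' @export
align_direction <- function(leads, eqtls) {
  need <- c("rsid", "gene", "effect_allele", "other_allele", "beta_cancer")
  miss <- setdiff(need, names(leads))
  if (length(miss))
    stop("leads missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(leads)
  risk <- ifelse(leads$beta_cancer > 0, leads$effect_allele,
                 leads$other_allele)
  nonrisk <- ifelse(leads$beta_cancer > 0, leads$other_allele,
                    leads$effect_allele)
  zr <- rep(NA_real_, n)
  classification <- rep("unresolvable", n)
  reason <- rep("", n)
  key <- paste(eqtls$rsid, toupper(eqtls$gene))
  idx <- match(paste(leads$rsid, toupper(leads$gene)), key)
  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) { reason[i] <- "no_eqtl_record"; next }
    ea <- eqtls$effect_allele[j]; oa <- eqtls$other_allele[j]
    if (is_palindromic(leads$effect_allele[i], leads$other_allele[i]) ||
        is_palindromic(ea, oa)) {
      reason[i] <- "palindromic_ambiguous"; next
    }
    z <- eqtls$z[j]
    if (ea == risk[i] && oa == nonrisk[i]) {
    } else if (ea == nonrisk[i] && oa == risk[i]) {
      z <- -z
    } else if (unname(COMPLEMENT[ea]) == risk[i] &&
               unname(COMPLEMENT[oa]) == nonrisk[i]) {
    } else if (unname(COMPLEMENT[ea]) == nonrisk[i] &&
               unname(COMPLEMENT[oa]) == risk[i]) {
      z <- -z
    } else {
      reason[i] <- "incompatible_alleles"; next
    }
    zr[i] <- z
    if (z > 0) classification[i] <- "risk_allele_increases_expression"
    else if (z < 0) classification[i] <- "risk_allele_decreases_expression"
    else reason[i] <- "zero_z"
  }
  cbind(leads,
        data.frame(risk_allele = risk, eqtl_z_risk = zr,
                   classification = classification, reason = reason,
                   stringsAsFactors = FALSE))
}
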