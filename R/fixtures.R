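# Registry of the bundled study tables. Each entry: file name, required
# columns and their types. The fig3b fixture transcribes the printed effect
# alleles and direction signs; its Z magnitudes and other alleles are
# synthetic placeholders (the published figure's numeric panel is not
# machine-readable), hence the _synthetic file name.
FIXTURE_SCHEMAS <- list(
  table1 = list(
    file = "table1.tsv",
    cols = c(gene = "character", immport = "integer", enrichr = "integer",
             category = "character")),
  sample_sizes = list(
    file = "sample_sizes.tsv",
    cols = c(trait = "character", abbrev = "character", class = "character",
             cases = "integer", controls = "integer")),
  subtype_sizes = list(
    file = "subtype_sizes.tsv",
    cols = c(subtype = "character", parent = "character", cases = "integer",
             controls = "integer")),
  lead_counts = list(
    file = "lead_counts.tsv",
    cols = c(analysis = "character", n_leads = "integer")),
  headline_counts = list(
    file = "headline_counts.tsv",
    cols = c(quantity = "character", value = "integer")),
  fig3b_direction = list(
    file = "fig3b_direction_synthetic.tsv",
    cols = c(rsid = "character", gene = "character",
             cancer_effect_allele = "character",
             cancer_other_allele = "character",
             cancer_z = "numeric", cancer_p = "numeric",
             eqtl_effect_allele = "character",
             eqtl_other_allele = "character",
             eqtl_z = "numeric", eqtl_p = "numeric"))
)

#' Load a bundled study table
#'
#' The package ships machine-readable transcriptions of the study's printed
#' tables: `"table1"` (the 32 immune-related nearest genes with their
#' ImmPort/Enrichr flags), `"sample_sizes"` (cases/controls of the 4 cancer
#' and 7 autoimmune GWAS), `"subtype_sizes"` (the nested ER+/ER-/high-grade
#' serous subtype GWAS), `"lead_counts"` (independent lead SNPs per
#' cancer analysis), `"headline_counts"` (the headline totals), and
#' `"fig3b_direction"` (lead-SNP/eQTL direction records for the five
#' prioritized genes; directions and effect alleles transcribed, Z
#' magnitudes and other alleles synthetic).
#'
#' @param name fixture name (see above).
#' @param path optional override of the bundled file (schema still
#'   validated -- used for tamper tests).
#' @return data.frame validated against the fixture's column schema.
#' @export
load_fixture <- function(name, path = NULL) {
  if (!name %in% names(FIXTURE_SCHEMAS))
    stop("unknown fixture: ", name, call. = FALSE)
  schema <- FIXTURE_SCHEMAS[[name]]
  if (is.null(path))
    path <- system.file("extdata", "fixtures", schema$file,
                        package = "pleioscan", mustWork = TRUE)
  x <- data.table::fread(path, header = TRUE, sep = "\t",
                         data.table = FALSE, showProgress = FALSE)
  miss <- setdiff(names(schema$cols), names(x))
  if (length(miss))
    stop("fixture ", name, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- x[names(schema$cols)]
  for (col in names(schema$cols)) {
    want <- schema$cols[[col]]
    v <- x[[col]]
    ok <- switch(want,
      character = is.character(v),
      integer = (is.integer(v) || (is.numeric(v) && all(v == round(v)))),
      numeric = is.numeric(v))
    if (!isTRUE(ok))
      stop("fixture ", name, " column '", col, "' fails schema (expected ",
           want, ")", call. = FALSE)
    if (want == "integer") x[[col]] <- as.integer(v)
  }
  x
}

#' Split the fig3b direction fixture into lead and eQTL inputs
#'
#' Reshapes [load_fixture]`("fig3b_direction")` into the two tables
#' [align_direction()] consumes.
#'
#' @return list with data.frames `leads` (rsid, gene, effect_allele,
#'   other_allele, beta_cancer) and `eqtls` (rsid, gene, effect_allele,
#'   other_allele, z, p).
#' @export
fig3b_direction_inputs <- function() {
  f <- load_fixture("fig3b_direction")
  list(
    leads = data.frame(rsid = f$rsid, gene = f$gene,
                       effect_allele = f$cancer_effect_allele,
                       other_allele = f$cancer_other_allele,
                       beta_cancer = f$cancer_z, stringsAsFactors = FALSE),
    eqtls = data.frame(rsid = f$rsid, gene = f$gene,
                       effect_allele = f$eqtl_effect_allele,
                       other_allele = f$eqtl_other_allele,
                       z = f$eqtl_z, p = f$eqtl_p, stringsAsFactors = FALSE))
}

#' Recompute and verify the study's headline count arithmetic
#'
#' Exercises the integer identities that tie the bundled tables together:
#' the seven per-analysis lead counts sum to the total; unique leads split
#' into single-pair plus multi-pair; the 32-gene table decomposes by
#' ImmPort/Enrichr flags with inclusion--exclusion; and the case/control
#' sums over the four overall cancer GWAS and seven autoimmune GWAS
#' reproduce the headline totals (subtype GWAS are nested subsets and are
#' excluded from the sums).
#'
#' @return data.frame: check, computed, expected, pass (all comparisons
#'   exact).
#' @export
verify_counts <- function() {
  t1 <- load_fixture("table1")
  sizes <- load_fixture("sample_sizes")
  leads <- load_fixture("lead_counts")
  head_ct <- load_fixture("headline_counts")
  exp_of <- function(q) head_ct$value[head_ct$quantity == q]

  checks <- list(
    c("sum_of_per_analysis_lead_counts", sum(leads$n_leads),
      exp_of("total_lead_snps")),
    c("unique_leads_single_plus_multi",
      exp_of("single_pair_lead_snps") + exp_of("multi_pair_lead_snps"),
      exp_of("unique_lead_snps")),
    c("table1_rows", nrow(t1), exp_of("immune_related_genes")),
    c("table1_immport_flags", sum(t1$immport), exp_of("immport_genes")),
    c("table1_enrichr_flags", sum(t1$enrichr), exp_of("enrichr_genes")),
    c("table1_both_flags", sum(t1$immport & t1$enrichr),
      exp_of("both_methods_genes")),
    c("table1_inclusion_exclusion",
      sum(t1$immport) + sum(t1$enrichr) - sum(t1$immport & t1$enrichr),
      nrow(t1)),
    c("cancer_case_total", sum(sizes$cases[sizes$class == "cancer"]),
      exp_of("cancer_cases")),
    c("cancer_control_total", sum(sizes$controls[sizes$class == "cancer"]),
      exp_of("cancer_controls")),
    c("autoimmune_case_total",
      sum(sizes$cases[sizes$class == "autoimmune"]),
      exp_of("autoimmune_cases")),
    c("autoimmune_control_total",
      sum(sizes$controls[sizes$class == "autoimmune"]),
      exp_of("autoimmune_controls"))
  )
  out <- data.frame(
    check = vapply(checks, `[`, character(1), 1),
    computed = as.integer(vapply(checks, `[`, character(1), 2)),
    expected = as.integer(vapply(checks, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  out$pass <- out$computed == out$expected
  out
}
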