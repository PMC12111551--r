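CANONICAL_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "info", "beta", "se", "p")
MANDATORY_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited file with header (gzip transparently
#' supported) into typed records. Non-canonical column names are handled via
#' `column_map`. Malformed rows -- non-ACGT single-base alleles, `se <= 0`,
#' `p` outside `(0, 1]`, `eaf`/`info` outside `[0, 1]` -- are rejected and
#' counted by reason; duplicate rsids are resolved by keeping the record
#' with the smallest p-value. A missing `p` column is recomputed as
#' `2 * pnorm(-|beta/se|)`. Chromosome labels are normalized by stripping a
#' leading "chr"; positions are 1-based.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `info`, `beta`, `se`, `p`) to the column names used in the file.
#' @return data.frame of records with attribute `"read_log"` (data.frame of
#'   reason / n_removed), retrievable via [read_log()].
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) stop("empty summary-statistics file: ", path,
                           call. = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(dt))
    if (length(bad))
      stop("column_map refers to absent columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (canon in names(column_map))
      names(dt)[names(dt) == column_map[[canon]]] <- canon
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(dt))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(CANONICAL_COLS, names(dt))) dt[[col]] <- NA_real_
  dt <- dt[CANONICAL_COLS]

  dt$rsid <- as.character(dt$rsid)
  dt$chrom <- sub("^chr", "", as.character(dt$chrom))
  dt$pos <- as.integer(dt$pos)
  dt$effect_allele <- toupper(as.character(dt$effect_allele))
  dt$other_allele <- toupper(as.character(dt$other_allele))
  for (col in c("eaf", "info", "beta", "se", "p"))
    dt[[col]] <- suppressWarnings(as.numeric(dt[[col]]))

  log <- list()
  drop <- function(bad, reason) {
    log[[reason]] <<- sum(bad, na.rm = TRUE)
    !bad | is.na(bad)
  }
  bases <- c("A", "C", "G", "T")
  keep <- dt$effect_allele %in% bases & dt$other_allele %in% bases
  log[["non_snp_allele"]] <- sum(!keep)
  dt <- dt[keep, , drop = FALSE]
  keep <- drop(!is.finite(dt$beta) | !is.finite(dt$se), "missing_beta_se")
  dt <- dt[keep & !is.na(dt$beta) & !is.na(dt$se), , drop = FALSE]
  keep <- drop(dt$se <= 0, "nonpositive_se")
  dt <- dt[keep, , drop = FALSE]
  keep <- drop(!is.na(dt$p) & (dt$p <= 0 | dt$p > 1), "p_out_of_range")
  dt <- dt[keep, , drop = FALSE]
  keep <- drop(!is.na(dt$eaf) & (dt$eaf < 0 | dt$eaf > 1), "eaf_out_of_range")
  dt <- dt[keep, , drop = FALSE]
  keep <- drop(!is.na(dt$info) & (dt$info < 0 | dt$info > 1),
               "info_out_of_range")
  dt <- dt[keep, , drop = FALSE]
  if (nrow(dt) == 0L)
    stop("no well-formed records in ", path, call. = FALSE)

  dt$p[is.na(dt$p)] <- 2 * pnorm(-abs(dt$beta[is.na(dt$p)] /
                                        dt$se[is.na(dt$p)]))

  # duplicate rsids: keep the smallest p (ties: first occurrence)
  if (anyDuplicated(dt$rsid)) {
    ord <- order(dt$rsid, dt$p)
    dt <- dt[ord, , drop = FALSE]
    dup <- duplicated(dt$rsid)
    log[["duplicate_rsid"]] <- sum(dup)
    dt <- dt[!dup, , drop = FALSE]
    dt <- dt[order(dt$chrom, dt$pos), , drop = FALSE]
  } else log[["duplicate_rsid"]] <- 0L
  rownames(dt) <- NULL
  attr(dt, "read_log") <- data.frame(reason = names(log),
                                     n_removed = unlist(log, use.names = FALSE),
                                     stringsAsFactors = FALSE)
  dt
}

#' @rdname read_sumstats
#' @param x a table returned by [read_sumstats()].
#' @export
read_log <- function(x) attr(x, "read_log")

#' Write a summary-statistics table
#'
#' Tab-delimited with the canonical header
#' `rsid chrom pos effect_allele other_allele eaf info beta se p`; full
#' float precision so a write/read round trip is lossless.
#'
#' @param x summary-statistics data.frame.
#' @param path output path (".gz" suffix compresses).
#' @export
write_sumstats <- function(x, path) {
  x <- x[intersect(CANONICAL_COLS, names(x))]
  for (col in names(x)) { # 17 significant digits round-trip any double
    if (is.double(x[[col]])) {
      v <- sprintf("%.17g", x[[col]])
      v[is.na(x[[col]])] <- NA_character_
      x[[col]] <- v
    }
  }
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Apply the study QC filters
#'
#' Excludes records with minor allele frequency below `maf_min` or
#' imputation quality below `info_min`. Both boundaries are inclusive
#' (a record at exactly the threshold is retained), and records lacking
#' `eaf` or `info` pass the corresponding filter -- some source GWAS do not
#' report these metrics.
#'
#' @param records table from [read_sumstats()].
#' @param maf_min minimum minor-allele frequency (default 0.005).
#' @param info_min minimum imputation quality (default 0.3).
#' @return filtered data.frame with attribute `"qc_report"` (data.frame of
#'   filter / n_removed), retrievable via [qc_report()].
#' @export
apply_qc_filters <- function(records, maf_min = 0.005, info_min = 0.3) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_info <- !is.na(records$info) & records$info < info_min
  out <- records[!fail_maf & !fail_info, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "read_log") <- attr(records, "read_log")
  attr(out, "qc_report") <- data.frame(
    filter = c("maf", "info"),
    n_removed = c(sum(fail_maf), sum(fail_info)),
    stringsAsFactors = FALSE)
  out
}

#' @rdname apply_qc_filters
#' @param x a table returned by [apply_qc_filters()].
#' @export
qc_report <- function(x) attr(x, "qc_report")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Harmonize two summary-statistic tables to a shared effect allele
#'
#' Joins trait A and trait B on (rsid, chrom, pos) and re-expresses trait
#' B's effect on trait A's effect allele: swapped effect/other alleles
#' negate B's beta and reflect its EAF; reverse-complement allele pairs are
#' relabelled (strand flip) and re-checked. Palindromic SNPs (A/T, C/G)
#' whose EAF falls inside the ambiguity window on either side -- or is
#' missing -- are dropped as strand-unresolvable; outside the window their
#' orientation is inferred from EAF agreement. Unresolvable allele sets are
#' dropped. All drops are logged by reason.
#'
#' @param table_a,table_b QC-filtered tables ([apply_qc_filters()]).
#' @param ambiguity_window EAF window (lo, hi) inside which palindromic
#'   SNPs are considered unresolvable; default (0.4, 0.6).
#' @return object of class `harmonized_pair`: list with data.frames `a` and
#'   `b` (row-aligned, identical effect alleles), and `log` (drop reasons),
#'   plus per-SNP flags `strand_flipped` and `allele_swapped`.
#' @export
harmonize_pair <- function(table_a, table_b, ambiguity_window = c(0.4, 0.6)) {
  key_a <- paste(table_a$rsid, table_a$chrom, table_a$pos)
  key_b <- paste(table_b$rsid, table_b$chrom, table_b$pos)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L)
    stop("no overlapping SNPs between the two tables", call. = FALSE)
  a <- table_a[match(common, key_a), , drop = FALSE]
  b <- table_b[match(common, key_b), , drop = FALSE]

  n <- nrow(a)
  swap <- strand <- logical(n)
  drop_reason <- character(n)

  same <- b$effect_allele == a$effect_allele & b$other_allele == a$other_allele
  swapped <- b$effect_allele == a$other_allele &
    b$other_allele == a$effect_allele
  comp_ea <- unname(COMPLEMENT[b$effect_allele])
  comp_oa <- unname(COMPLEMENT[b$other_allele])
  comp_same <- comp_ea == a$effect_allele & comp_oa == a$other_allele
  comp_swapped <- comp_ea == a$other_allele & comp_oa == a$effect_allele
  pal <- is_palindromic(a$effect_allele, a$other_allele)

  in_window <- function(f) !is.na(f) & f > ambiguity_window[1] &
    f < ambiguity_window[2]
  pal_ambiguous <- pal & (is.na(a$eaf) | is.na(b$eaf) |
                            in_window(a$eaf) | in_window(b$eaf))
  drop_reason[pal_ambiguous] <- "palindromic_ambiguous"

  # palindromic, unambiguous: labels can't distinguish swap from strand
  # flip, so orient by EAF agreement
  pal_ok <- pal & !pal_ambiguous
  pal_swap <- pal_ok & abs(b$eaf - a$eaf) > abs((1 - b$eaf) - a$eaf)

  unresolvable <- !pal & !(same | swapped | comp_same | comp_swapped)
  drop_reason[unresolvable & drop_reason == ""] <- "incompatible_alleles"

  do_swap <- (!pal & (swapped | comp_swapped)) | pal_swap
  do_strand <- !pal & (comp_same | comp_swapped)
  keep <- drop_reason == ""

  b$beta[do_swap] <- -b$beta[do_swap]
  b$eaf[do_swap] <- 1 - b$eaf[do_swap]
  b$effect_allele[keep] <- a$effect_allele[keep]
  b$other_allele[keep] <- a$other_allele[keep]

  log <- table(drop_reason[drop_reason != ""])
  log <- data.frame(reason = names(log), n_removed = as.integer(log),
                    stringsAsFactors = FALSE)
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  structure(list(a = a, b = b,
                 strand_flipped = do_strand[keep],
                 allele_swapped = do_swap[keep],
                 log = log),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("harmonized pair:", nrow(x$a), "shared SNPs (",
      sum(x$allele_swapped), "allele-swapped,",
      sum(x$strand_flipped), "strand-flipped )\n")
  if (nrow(x$log)) {
    cat("dropped:\n")
    print(x$log, row.names = FALSE)
  }
  invisible(x)
}

#' Reverse the sign of the autoimmune effect estimates
#'
#' Multiplies the beta coefficients of an autoimmune-disease table by -1
#' while keeping the effect allele, standard errors and p-values unchanged,
#' so that variants with opposite allelic effects on the two disorders
#' become concordant and can reach combined significance under the
#' fixed-effect model. The flip is recorded in an attribute and applying it
#' twice is an error; a cancer-role table is returned unchanged.
#'
#' @param table summary-statistics data.frame (harmonized).
#' @param trait_role `"autoimmune"` (flip) or `"cancer"` (no-op).
#' @return the table, with attribute `"sign_flipped"` set for autoimmune.
#' @export
flip_sign <- function(table, trait_role = c("autoimmune", "cancer")) {
  trait_role <- match.arg(trait_role)
  if (trait_role == "cancer") return(table)
  if (isTRUE(attr(table, "sign_flipped")))
    stop("sign already flipped for this table", call. = FALSE)
  table$beta <- -table$beta
  attr(table, "sign_flipped") <- TRUE
  table
}
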