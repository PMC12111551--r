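#' Squared-correlation LD matrix from genotype dosages
#'
#' r-squared is the squared Pearson correlation of dosages across the
#' reference individuals. Monomorphic SNPs get 0 off-diagonal (unit
#' diagonal) and are flagged in the `"monomorphic"` attribute.
#'
#' @param genotypes individuals x SNPs dosage matrix with SNP ids as column
#'   names.
#' @param snp_ids subset of columns to use (default all).
#' @return symmetric r-squared matrix with unit diagonal and SNP-id
#'   dimnames.
#' @export
compute_r2 <- function(genotypes, snp_ids = colnames(genotypes)) {
  if (nrow(genotypes) < 2L)
    stop("need at least two individuals", call. = FALSE)
  g <- genotypes[, snp_ids, drop = FALSE]
  if (anyNA(g)) {
    all_missing <- colSums(!is.na(g)) == 0L
    if (any(all_missing))
      stop("all-missing SNP(s): ",
           paste(snp_ids[all_missing], collapse = ", "), call. = FALSE)
  }
  sds <- apply(g, 2, stats::sd, na.rm = TRUE)
  mono <- sds == 0
  r2 <- matrix(0, ncol(g), ncol(g), dimnames = list(snp_ids, snp_ids))
  if (any(!mono)) {
    r <- suppressWarnings(cor(g[, !mono, drop = FALSE],
                              use = "pairwise.complete.obs"))
    r2[!mono, !mono] <- r^2
  }
  diag(r2) <- 1
  attr(r2, "monomorphic") <- snp_ids[mono]
  r2
}

#' Greedy LD clumping of screened meta-analysis records
#'
#' plink/FUMA-style: repeatedly take the unassigned SNP with the smallest
#' meta-analysis p-value as a lead (ties broken by smaller position, then
#' lexicographic rsid) and absorb every unassigned same-chromosome SNP with
#' `r2 >= r2_lead` into its clump. After exhaustion, clumps whose member
#' spans lie within `merge_distance` of each other on the same chromosome
#' are merged into a single region (locus) while each clump's lead is
#' retained as a distinct lead SNP; leads therefore satisfy pairwise
#' `r2 < r2_lead`.
#'
#' @param meta records from [screen_pair()] (already restricted to
#'   combined-significant SNPs).
#' @param ld r-squared matrix from [compute_r2()] (dimnames = rsids).
#' @param config a [screen_config()].
#' @param pair_label label of the (cancer, autoimmune) pair, carried
#'   through to the output.
#' @param missing_ld `"drop"` (default, with a warning) or `"error"` for
#'   SNPs absent from the LD matrix.
#' @return data.frame of lead SNPs: pair, lead_rsid, chrom, pos, p_meta,
#'   locus_id, locus_start, locus_end, n_members, members
#'   (comma-separated rsids of the lead's clump).
#' @export
ld_clump <- function(meta, ld, config = screen_config(), pair_label = "pair",
                     missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  present <- meta$rsid %in% rownames(ld)
  if (any(!present)) {
    msg <- paste0(sum(!present), " SNP(s) absent from the LD matrix")
    if (missing_ld == "error") stop(msg, call. = FALSE)
    warning(msg, ", dropped", call. = FALSE)
    meta <- meta[present, , drop = FALSE]
  }
  n <- nrow(meta)
  empty <- data.frame(pair = character(), lead_rsid = character(),
                      chrom = character(), pos = integer(),
                      p_meta = numeric(), locus_id = integer(),
                      locus_start = integer(), locus_end = integer(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  # p_meta underflows to 0 for very strong signals; the log-space tail
  # (mlog10p) breaks those ties before the positional tie-break
  mlp <- if ("mlog10p" %in% names(meta)) meta$mlog10p else -log10(meta$p_meta)
  ord <- order(meta$p_meta, -mlp, meta$pos, meta$rsid)
  assigned <- logical(n)
  leads <- integer(0)
  members <- list()
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    mem <- i
    same_chr <- which(!assigned & meta$chrom == meta$chrom[i])
    if (length(same_chr)) {
      r2 <- ld[meta$rsid[same_chr], meta$rsid[i]]
      absorb <- same_chr[r2 >= config$r2_lead]
      assigned[absorb] <- TRUE
      mem <- c(mem, absorb)
    }
    leads <- c(leads, i)
    members[[length(members) + 1L]] <- mem
  }

  span_start <- vapply(members, function(m) min(meta$pos[m]), numeric(1))
  span_end <- vapply(members, function(m) max(meta$pos[m]), numeric(1))
  chrom <- meta$chrom[leads]

  # merge clump spans within merge_distance on the same chromosome
  k <- length(leads)
  locus <- integer(k)
  next_locus <- 0L
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sel <- sel[order(span_start[sel])]
    cur_end <- -Inf
    for (j in sel) {
      if (span_start[j] - cur_end > config$merge_distance) {
        next_locus <- next_locus + 1L
        cur_end <- span_end[j]
      } else cur_end <- max(cur_end, span_end[j])
      locus[j] <- next_locus
    }
  }
  locus_start <- tapply(span_start, locus, min)[as.character(locus)]
  locus_end <- tapply(span_end, locus, max)[as.character(locus)]

  out <- data.frame(pair = pair_label, lead_rsid = meta$rsid[leads],
                    chrom = chrom, pos = meta$pos[leads],
                    p_meta = meta$p_meta[leads], locus_id = locus,
                    locus_start = as.integer(locus_start),
                    locus_end = as.integer(locus_end),
                    n_members = lengths(members),
                    members = vapply(members, function(m)
                      paste(meta$rsid[m], collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Deduplicate lead SNPs across trait-pair analyses
#'
#' Uniqueness is keyed on rsid identity (not LD). Reports, per unique lead,
#' the pairs in which it appeared, and the headline counts: total leads
#' with multiplicity, unique leads, and the split into leads found in a
#' single pair versus multiple pairs.
#'
#' @param leads either one data.frame of [ld_clump()] outputs (row-bound,
#'   with a `pair` column) or a list of such data.frames.
#' @return list with `unique` (data.frame: lead_rsid, chrom, pos,
#'   best_p_meta, n_pairs, pairs) and `summary` (named list: n_total,
#'   n_unique, n_single_pair, n_multi_pair).
#' @export
dedupe_leads <- function(leads) {
  if (is.list(leads) && !is.data.frame(leads))
    leads <- do.call(rbind, leads)
  if (nrow(leads) == 0L)
    return(list(unique = leads,
                summary = list(n_total = 0L, n_unique = 0L,
                               n_single_pair = 0L, n_multi_pair = 0L)))
  sp <- split(seq_len(nrow(leads)), leads$lead_rsid)
  uniq <- data.frame(
    lead_rsid = names(sp),
    chrom = vapply(sp, function(i) leads$chrom[i[1]], character(1)),
    pos = vapply(sp, function(i) leads$pos[i[1]], numeric(1)),
    best_p_meta = vapply(sp, function(i) min(leads$p_meta[i]), numeric(1)),
    n_pairs = vapply(sp, function(i) length(unique(leads$pair[i])),
                     integer(1)),
    pairs = vapply(sp, function(i)
      paste(sort(unique(leads$pair[i])), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  uniq <- uniq[order(uniq$chrom, uniq$pos), , drop = FALSE]
  rownames(uniq) <- NULL
  list(unique = uniq,
       summary = list(n_total = nrow(leads),
                      n_unique = nrow(uniq),
                      n_single_pair = sum(uniq$n_pairs == 1L),
                      n_multi_pair = sum(uniq$n_pairs > 1L)))
}
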