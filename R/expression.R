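#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), on
#' pairwise-complete observations. Returns `NA` with a warning when fewer
#' than three complete pairs remain or when either vector has zero rank
#' variance (constant input).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Spearman's rho (between -1 and 1), or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 complete pairs; rho undefined", call. = FALSE)
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector; rho undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

#' Default marker-symbol alias map
#'
#' The infiltration markers are usually named by their protein aliases;
#' expression matrices index HGNC symbols, so CD11B resolves to ITGAM and
#' CD45 to PTPRC.
#' @export
marker_aliases <- function() c(CD11B = "ITGAM", CD45 = "PTPRC")

resolve_marker <- function(marker, rows, aliases) {
  if (marker %in% rows) return(marker)
  if (marker %in% names(aliases) && aliases[[marker]] %in% rows)
    return(aliases[[marker]])
  NA_character_
}

#' Candidate-by-marker Spearman correlations across expression cohorts
#'
#' One correlation cell per (gene, marker, cohort) where both rows exist;
#' combinations missing a candidate row are recorded explicitly with `NA`
#' rho. Markers are mandatory in every cohort (after alias resolution).
#'
#' @param candidates character vector of candidate gene symbols.
#' @param markers infiltration marker names (default CD4, CD8A, CD11B,
#'   CD45).
#' @param cohorts named list of genes x samples matrices
#'   ([simulate_expression()] / [read_expression()]).
#' @param aliases named character vector resolving marker aliases; see
#'   [marker_aliases()].
#' @return data.frame: gene, marker, cohort, rho, n_samples, missing.
#' @export
correlation_matrix <- function(candidates,
                               markers = c("CD4", "CD8A", "CD11B", "CD45"),
                               cohorts, aliases = marker_aliases()) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  rows <- lapply(names(cohorts), function(cc) {
    m <- cohorts[[cc]]
    resolved <- vapply(markers, resolve_marker, character(1),
                       rows = rownames(m), aliases = aliases)
    if (anyNA(resolved))
      stop("marker(s) absent from cohort ", cc, ": ",
           paste(markers[is.na(resolved)], collapse = ", "), call. = FALSE)
    do.call(rbind, lapply(candidates, function(g) {
      present <- g %in% rownames(m)
      do.call(rbind, lapply(seq_along(markers), function(j) {
        rho <- if (present) spearman_rho(m[g, ], m[resolved[j], ])
               else NA_real_
        data.frame(gene = g, marker = markers[j], cohort = cc, rho = rho,
                   n_samples = if (present) ncol(m) else 0L,
                   missing = !present, stringsAsFactors = FALSE)
      }))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prioritize genes by the all-cohorts correlation rule
#'
#' A gene is prioritized iff in EVERY cohort its maximum Spearman rho over
#' the markers strictly exceeds `rho_min`; genes missing from any cohort
#' are never prioritized. The per-cohort maxima are returned as an audit
#' trail.
#'
#' @param cells correlation table from [correlation_matrix()].
#' @param config a [screen_config()] (uses `rho_min`, default 0.5).
#' @return data.frame with one row per gene: gene, the per-cohort max-rho
#'   columns (`max_rho_<cohort>`), and logical `prioritized`.
#' @export
prioritize_genes <- function(cells, config = screen_config()) {
  cohorts <- unique(cells$cohort)
  genes <- unique(cells$gene)
  max_rho <- sapply(cohorts, function(cc)
    vapply(genes, function(g) {
      r <- cells$rho[cells$gene == g & cells$cohort == cc]
      if (!length(r) || all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
    }, numeric(1)))
  max_rho <- matrix(max_rho, nrow = length(genes),
                    dimnames = list(genes, cohorts))
  prioritized <- apply(max_rho, 1, function(r)
    all(!is.na(r)) && all(r > config$rho_min))
  out <- data.frame(gene = genes, max_rho, prioritized = prioritized,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  names(out)[seq_along(cohorts) + 1L] <- paste0("max_rho_", cohorts)
  out[order(-out$prioritized, out$gene), , drop = FALSE]
}

#' Read / write an expression matrix
#'
#' TSV, genes x samples, first column the gene symbol.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (anyDuplicated(dt[[1]]))
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname read_expression
#' @param x genes x samples matrix.
#' @export
write_expression <- function(x, path) {
  dt <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
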