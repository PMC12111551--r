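#' Named gene collection
#'
#' @param name set name (e.g. a pathway).
#' @param description free text (the database tag for pathway sets).
#' @param members character vector of gene symbols; de-duplicated and
#'   case-normalized to upper case.
#' @param database optional database tag for pathway collections.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, description = "", members, database = NA_character_) {
  members <- unique(toupper(as.character(members)))
  structure(list(name = name, description = description,
                 members = members, database = database),
            class = "gene_set")
}

#' Read / write GMT-like gene-set files
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @param database database tag attached to every set read (optional).
#' @return `read_gmt`: list of [gene_set()].
#' @export
read_gmt <- function(path, database = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene)",
           call. = FALSE)
    gene_set(f[1], f[2], f[-(1:2)], database = database)
  })
}

#' @rdname read_gmt
#' @param sets list of [gene_set()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED-like gene annotation table
#'
#' Tab-delimited with header; 1-based inclusive coordinates and columns
#' `chrom start end strand gene_id symbol`.
#'
#' @param path file path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  g <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         showProgress = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "symbol")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(g$start > g$end)) stop("gene with start > end", call. = FALSE)
  g$chrom <- sub("^chr", "", as.character(g$chrom))
  g
}

#' Map SNPs to their nearest gene
#'
#' Distance is 0 for a position inside a gene body (1-based inclusive),
#' otherwise `min(|pos - start|, |pos - end|)`. Ties are broken by smaller
#' distance to the gene start, then lexicographic symbol, so assignments
#' are deterministic. SNPs on chromosomes with no annotated gene are
#' reported with `NA` gene and flagged.
#'
#' @param snps data.frame with columns rsid (or lead_rsid), chrom, pos.
#' @param genes gene annotation data.frame ([read_gene_table()] /
#'   [simulate_gene_annotation()]).
#' @return data.frame: rsid, chrom, pos, gene (symbol), gene_id, distance.
#' @export
nearest_gene <- function(snps, genes) {
  rsid <- if ("rsid" %in% names(snps)) snps$rsid else snps$lead_rsid
  chrom <- sub("^chr", "", as.character(snps$chrom))
  n <- length(rsid)
  gene <- gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(n)) {
    gi <- by_chr[[chrom[i]]]
    if (is.null(gi)) next
    pos <- snps$pos[i]
    inside <- pos >= genes$start[gi] & pos <= genes$end[gi]
    d <- ifelse(inside, 0, pmin(abs(pos - genes$start[gi]),
                                abs(pos - genes$end[gi])))
    d_start <- abs(pos - genes$start[gi])
    ord <- order(d, d_start, genes$symbol[gi])
    best <- gi[ord[1]]
    gene[i] <- genes$symbol[best]
    gene_id[i] <- genes$gene_id[best]
    distance[i] <- d[ord[1]]
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)), " SNP(s) on chromosomes without genes",
            call. = FALSE)
  data.frame(rsid = rsid, chrom = chrom, pos = snps$pos, gene = gene,
             gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Flag nearest genes present on an immune gene list
#'
#' @param nearest data.frame from [nearest_gene()].
#' @param immune_list a [gene_set()] (e.g. the ImmPort-style curated list).
#' @return the input with a logical `immune` column; one row per input SNP
#'   so gene-to-lead provenance is preserved.
#' @export
immune_overlap <- function(nearest, immune_list) {
  stopifnot(inherits(immune_list, "gene_set"))
  nearest$immune <- toupper(nearest$gene) %in% immune_list$members
  nearest$immune[is.na(nearest$gene)] <- FALSE
  nearest
}

#' Hypergeometric pathway overrepresentation
#'
#' For each set, the probability of observing at least `k` query genes in a
#' set of size `K` when `n` genes are drawn from a universe of `N`:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed by exact tail
#' summation. Results are ranked by p ascending with
#' Benjamini--Hochberg adjustment across all tested sets.
#'
#' @param query character vector of query gene symbols.
#' @param pathway_sets list of [gene_set()] (with `database` tags for
#'   downstream top-10 selection).
#' @param universe_size N; defaults to the number of genes in `universe`.
#' @param universe optional character vector defining the universe; sets
#'   and query are intersected with it when supplied.
#' @return data.frame ranked by p: set_name, database, k, K, n, N, p,
#'   p_adj, driver_genes (comma-separated overlapping symbols).
#' @export
hypergeom_enrich <- function(query, pathway_sets, universe_size = NULL,
                             universe = NULL) {
  query <- unique(toupper(query))
  if (!length(query)) stop("empty query", call. = FALSE)
  if (!is.null(universe)) {
    universe <- unique(toupper(universe))
    query <- intersect(query, universe)
    if (is.null(universe_size)) universe_size <- length(universe)
  }
  if (is.null(universe_size))
    stop("supply universe or universe_size", call. = FALSE)
  N <- universe_size
  n <- length(query)
  if (n > N) stop("query larger than universe", call. = FALSE)
  rows <- lapply(pathway_sets, function(s) {
    members <- if (is.null(universe)) s$members
               else intersect(s$members, universe)
    K <- length(members)
    if (K > N) stop("set larger than universe: ", s$name, call. = FALSE)
    drivers <- intersect(query, members)
    k <- length(drivers)
    data.frame(set_name = s$name, database = s$database, k = k, K = K,
               n = n, N = N, p = hyper_tail(k, K, n, N),
               driver_genes = paste(sort(drivers), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set_name", "database", "k", "K", "n", "N", "p", "p_adj",
          "driver_genes")]
}

# exact upper tail P(X >= k), X ~ Hypergeom(N, K, n), by direct summation
hyper_tail <- function(k, K, n, N) {
  if (k > min(K, n)) stop("k exceeds min(K, n)", call. = FALSE)
  if (k <= 0) return(1)
  sum(dhyper(k:min(K, n), K, N - K, n))
}

#' Default immune-related pathway keywords
#'
#' Case-insensitive substrings used to classify a pathway name as
#' immune-related, standing in for the manual curation step.
#' @export
immune_keywords <- function() {
  c("interferon", "tcr", "bcr", "cytokine", "inflammat", "immun",
    "leukocyte", "t-cell", "t cell", "natural killer", "dendritic")
}

#' Select driver genes of immune-related pathways among top-ranked results
#'
#' Within each database tag, takes the `top_n` sets by rank (ascending raw
#' hypergeometric p), retains those whose names match any immune keyword
#' (case-insensitive substring), and returns the union of their driver
#' genes.
#'
#' @param results data.frame from [hypergeom_enrich()] (must carry
#'   `database` tags).
#' @param keywords character vector of keywords; see [immune_keywords()].
#' @param top_n sets considered per database (default 10).
#' @return character vector: union of driver genes of the retained sets.
#' @export
select_immune_pathway_genes <- function(results,
                                        keywords = immune_keywords(),
                                        top_n = 10L) {
  if (!"database" %in% names(results) || all(is.na(results$database)))
    stop("enrichment results carry no database tags", call. = FALSE)
  genes <- character(0)
  for (db in unique(results$database)) {
    top <- head(results[results$database %in% db, , drop = FALSE], top_n)
    hit <- Reduce(`|`, lapply(keywords, function(k)
      grepl(k, top$set_name, ignore.case = TRUE)), rep(FALSE, nrow(top)))
    drivers <- top$driver_genes[hit]
    genes <- c(genes, unlist(strsplit(drivers[nzchar(drivers)], ",",
                                      fixed = TRUE)))
  }
  sort(unique(genes))
}
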