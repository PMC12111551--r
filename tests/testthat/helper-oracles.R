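# Independent oracles, deliberately written as plain step-by-step loops so
# they share no code path with the package implementation.

# greedy clump oracle: literal transcription of the procedure
brute_clump <- function(p, pos, chrom, rsid, r2, r2_lead) {
  mlp <- -log10(ifelse(p == 0, .Machine$double.xmin, p))
  unassigned <- seq_along(p)
  leads <- list()
  while (length(unassigned) > 0) {
    best <- unassigned[1]
    for (i in unassigned) {
      if (p[i] < p[best] ||
          (p[i] == p[best] && mlp[i] > mlp[best]) ||
          (p[i] == p[best] && mlp[i] == mlp[best] && pos[i] < pos[best]) ||
          (p[i] == p[best] && mlp[i] == mlp[best] && pos[i] == pos[best] &&
           rsid[i] < rsid[best])) best <- i
    }
    members <- best
    for (i in setdiff(unassigned, best)) {
      if (chrom[i] == chrom[best] && r2[i, best] >= r2_lead)
        members <- c(members, i)
    }
    leads[[length(leads) + 1]] <- list(lead = best, members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  leads
}

# exhaustive nearest-gene scan
brute_nearest <- function(pos, chrom, genes) {
  best <- NA_integer_
  best_key <- NULL
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    d <- if (pos >= genes$start[i] && pos <= genes$end[i]) 0
         else min(abs(pos - genes$start[i]), abs(pos - genes$end[i]))
    key <- list(d, abs(pos - genes$start[i]), genes$symbol[i])
    if (is.na(best) ||
        d < best_key[[1]] ||
        (d == best_key[[1]] && key[[2]] < best_key[[2]]) ||
        (d == best_key[[1]] && key[[2]] == best_key[[2]] &&
         key[[3]] < best_key[[3]])) {
      best <- i
      best_key <- key
    }
  }
  if (is.na(best)) NA_character_ else genes$symbol[best]
}

# random symmetric r^2 matrix with unit diagonal
random_r2 <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# small harmonized + flipped pair built from two raw tables
make_screen_pair <- function(ta, tb) {
  pair <- harmonize_pair(ta, tb)
  pair$b <- flip_sign(pair$b, "autoimmune")
  pair
}

# minimal well-formed summary-statistic table
toy_sumstats <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(rsid = sprintf("rs%d", seq_len(n)), chrom = "1",
             pos = seq_len(n) * 1000L,
             effect_allele = rep(c("A", "C"), length.out = n),
             other_allele = rep(c("G", "T"), length.out = n),
             eaf = runif(n, 0.1, 0.45), info = runif(n, 0.8, 1),
             beta = rnorm(n, 0, 0.05), se = runif(n, 0.01, 0.03),
             p = NA_real_, stringsAsFactors = FALSE) |>
    transform(p = 2 * pnorm(-abs(beta / se)))
}
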