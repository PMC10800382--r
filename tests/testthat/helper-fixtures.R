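# shared fixtures, built in code at test time

make_panel <- function(n_samples = 50, n_snps = 20, seed = 1,
                       maf_range = c(0.2, 0.5), chr = "1") {
  set.seed(seed)
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  g <- sapply(maf, function(f) rbinom(n_samples, 2, f))
  # guarantee polymorphism
  for (j in seq_len(n_snps)) if (var(g[, j]) == 0) g[1, j] <- 2 - g[1, j]
  meta <- data.frame(snp = sprintf("rs%04d", seq_len(n_snps)), chr = chr,
                     bp = seq_len(n_snps) * 1000L,
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  geno_panel(g, meta)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent greedy-pruning oracle working from an explicit r2 matrix
prune_oracle <- function(r2, window, step, thr) {
  M <- nrow(r2)
  alive <- rep(TRUE, M)
  for (s in seq(1, M, by = step)) {
    e <- min(s + window - 1, M)
    if (e <= s) next
    for (i in s:e) {
      if (!alive[i]) next
      for (j in seq_len(e - i) + i) {
        if (alive[j] && r2[i, j] > thr) alive[j] <- FALSE
      }
    }
  }
  which(alive)
}

aspus_ref_p <- function(stat_obs, stat_null) {
  (1 + sum(stat_null >= stat_obs)) / (length(stat_null) + 1)
}
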