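# Fixture writers and independent oracles shared across the test files.
# All fixtures are built in code at test time.

write_airr_fixture <- function(path, cdr3 = c("CASSLGQAYEQYF", "CASSIRSSYEQYF",
                                              "CASRDRVGNTIYF"),
                               v = c("TRBV19*01", "TRBV5-1*01", "TRBV28*01"),
                               count = c(5L, 3L, 2L)) {
  write.table(data.frame(junction_aa = cdr3, v_call = v,
                         duplicate_count = count, productive = "T"),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_immunoseq_fixture <- function(path, cdr3, v, count) {
  write.table(data.frame(aminoAcid = cdr3, vGeneName = v, templates = count),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_contigs_fixture <- function(path, df) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# random clonotype table for property loops
random_tcrs <- function(n, seed, n_v = 4) {
  withr::with_seed(seed, {
    lens <- sample(8:16, n, replace = TRUE)
    data.frame(
      cdr3b = vapply(lens, function(L) {
        paste0("C", paste(sample(epispec:::AA20, L - 2, replace = TRUE),
                          collapse = ""), "F")
      }, character(1)),
      v_gene = paste0("TRBV", sample.int(n_v, n, replace = TRUE)),
      count = sample.int(50, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

# ---- independent oracles -------------------------------------------------

# one-sided (enrichment) Fisher exact p for table [[a, b], [c, d]] by
# direct enumeration of hypergeometric point probabilities over the tail
oracle_fisher_greater <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  amax <- min(r1, c1)
  ks <- a:amax
  sum(exp(lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)))
}

# AUROC by brute-force concordant-pair counting with ties counted half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exact one-sided Mann-Whitney p (alternative: x stochastically greater)
# by full enumeration of group assignments; requires no ties
oracle_mw_greater <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  u_obs <- sum(rank(all_v)[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(all_v), n)
  r_all <- rank(all_v)
  u_all <- colSums(matrix(r_all[combs], nrow = n)) - n * (n + 1) / 2
  mean(u_all >= u_obs)
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# oracle scorer: flags clonotypes whose CDR3 is in a known specific set
oracle_scorer <- function(specific_cdr3b) {
  force(specific_cdr3b)
  function(tcrs) as.numeric(tcrs$cdr3b %in% specific_cdr3b)
}
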