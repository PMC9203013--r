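# Independent brute-force oracles for the exact tests used by the package.
# They enumerate the full null distribution and never call the code paths
# they check.

# Two-sided exact binomial p at p0 = 1/2: sum the probabilities of all
# outcomes no more likely than the observed one.
oracle_binom_two_sided <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Two-sided Fisher exact p for a 2x2 table: enumerate the hypergeometric
# support at fixed margins.
oracle_fisher_two_sided <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sided exact Wilcoxon rank-sum p (no ties): enumerate every assignment
# of the pooled ranks to group A and apply the standard doubling rule on
# the Mann-Whitney statistic U.
oracle_wilcox_two_sided <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - na * (na + 1) / 2)
  if (u_obs > na * nb / 2) p <- mean(u_all >= u_obs) else p <- mean(u_all <= u_obs)
  min(1, 2 * p)
}

# Closed-form per-gene paired t p-value, written independently of the
# package's vectorised pipeline.
oracle_paired_t_p <- function(d) {
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(t_stat), n - 1)
}

# A small protein-groups fixture in the MaxQuant dialect, written to a
# temporary TSV. `rows` is a data.frame with the literal cell values.
write_maxquant_fixture <- function(rows, path = tempfile(fileext = ".txt")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

maxquant_rows <- function() {
  data.frame(
    `Protein IDs` = c("P1", "P2;P9", "P3"),
    `Majority protein IDs` = c("P1", "P2", "P3"),
    `Gene names` = c("alpha", "beta", "gamma"),
    Peptides = c(5L, 3L, 8L),
    `Razor + unique peptides` = c(5L, 3L, 8L),
    `Unique peptides` = c(4L, 2L, 7L),
    Score = c(120.5, 88.1, 301.2),
    Reverse = c("", "", ""),
    `Potential contaminant` = c("", "", ""),
    `Only identified by site` = c("", "", ""),
    `LFQ intensity CON1` = c(1000, 0, 2500.5),
    `LFQ intensity SAM1` = c(1500, 300, 0),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

# Pair matrix built directly from log2 values (one gene per row of each
# matrix), convenience for hand-constructed cases.
pm_from_log2 <- function(log_con, log_sam, genes = NULL) {
  log_con <- rbind(log_con); log_sam <- rbind(log_sam)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(log_con)))
  con <- 2^log_con; sam <- 2^log_sam
  con[is.na(log_con)] <- 0; sam[is.na(log_sam)] <- 0
  rownames(con) <- rownames(sam) <- genes
  pair_matrix(con, sam)
}
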