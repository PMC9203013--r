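test_that("predictor thresholds are strict and jointly required", {
  seqs <- c(P1 = paste(rep("A", 30), collapse = ""))
  pred <- data.frame(protein = "P1", position = 15,
                     ann = c(0.6, 0.6, 0.5, 0.6),
                     pssm = c(0.85, 0.85, 0.85, 0.85),
                     svm = c(0.3, 0.3, 0.3, 0.3),
                     consensus = c(0.95, 0.9, 0.95, 0.91))
  sites <- import_predictions(pred, seqs)
  expect_identical(sites$passes, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(nchar(sites$window[1]), 13L)
})

test_that("windows pad at termini and error beyond the sequence", {
  seqs <- c(P1 = "MKVRSYSLP")
  pred <- data.frame(protein = "P1", position = 2, ann = 1, pssm = 1,
                     svm = 1, consensus = 1)
  sites <- import_predictions(pred, seqs)
  expect_identical(sites$window, "-----MKVRSYSL")
  pred$position <- 99
  expect_error(import_predictions(pred, seqs), "P1")
  pred$protein <- "P2"; pred$position <- 2
  expect_warning(s2 <- import_predictions(pred, seqs), "no sequence")
  expect_identical(s2$window, "")
})

test_that("the consensus scanner finds mode-I-like sites and only those", {
  expect_identical(scan_consensus("AAARSYSLPAAA"), 7L)
  expect_identical(scan_consensus(paste(rep("A", 50), collapse = "")), integer(0))
  expect_error(scan_consensus("AAXZA"), "non-amino-acid")
  # R/K accepted at -3 or -4; proline at +2 required
  expect_identical(scan_consensus("AKAASAPAA"), 5L)   # K at -3
  expect_identical(scan_consensus("AAAASAPAA"), integer(0))
  expect_identical(scan_consensus("AARASAAAA"), integer(0))
})

test_that("scanner hits on a planted fixture equal the planted positions", {
  sim <- simulate_experiment(experiment_config(
    n_proteins = 1000, motif_rate_spiked = 0.7, motif_rate_background = 0.4,
    seed = 37))
  sites <- scan_sites(sim$sequences)
  planted <- sim$truth[!is.na(sim$truth$motif_position), c("protein", "motif_position")]
  found <- sites[c("protein", "position")]
  expect_equal(nrow(found), nrow(planted))
  merged <- merge(planted, found, by = "protein")
  expect_equal(merged$motif_position, merged$position)
})

test_that("Aurora-context annotation follows the R/KxS/T rule at -2", {
  expect_true(annotate_aurora_context("AAKVSLSAAAAAA"))
  expect_false(annotate_aurora_context("AAAVSLSAAAAAA"))  # no basic residue
  expect_false(annotate_aurora_context("AAKVALSAAAAAA"))  # no S/T at -2
  expect_true(annotate_aurora_context("--KVSLSAAAAAA"))   # pad only at -6/-5
  expect_false(annotate_aurora_context("----SLSAAAAAA"))  # padded -4
  # Borealin-like configuration: phospho-site with S at -2 in an R-x-S context
  expect_true(annotate_aurora_context("AARVSLSLPAAAA"))
})

test_that("directional binomial p-values match enumeration and printed anchors", {
  expect_equal(direction_binom_test(10, 10)$p_value, 1.0)
  expect_equal(direction_binom_test(9, 1)$p_value, 0.021484375, tolerance = 1e-9)
  expect_equal(direction_binom_test(9, 1)$p_value, oracle_binom_two_sided(9, 10))
  # brute-force agreement across all splits with n <= 20
  for (n in c(5, 12, 20)) {
    for (k in 0:n) {
      expect_equal(direction_binom_test(k, n - k)$p_value,
                   oracle_binom_two_sided(k, n), tolerance = 1e-12)
    }
  }
})

test_that("directional enrichment partitions genes by passing sites", {
  tab <- data.frame(gene = sprintf("g%d", 1:8),
                    log_ratio = c(1, 2, 0.5, -1, -0.2, 0.3, -0.6, 1.2))
  sites <- data.frame(protein = c("g1", "g2", "g4", "g9"),
                      passes = c(TRUE, TRUE, FALSE, TRUE))
  enr <- directional_enrichment(tab, sites)
  # passing sites on g1, g2 (g4 fails, g9 unquantified): 2 up / 0 down
  expect_equal(enr$n_with_up, 2); expect_equal(enr$n_with_down, 0)
  expect_equal(enr$n_without_up, 3); expect_equal(enr$n_without_down, 3)
  expect_equal(enr$p_without, 1)
  tab$log_ratio[3] <- 0
  expect_warning(directional_enrichment(tab, sites), "exactly 0")
})

test_that("fold-change bins are contiguous, near-equal and deterministic", {
  tab <- data.frame(gene = sprintf("g%02d", 1:10), log_ratio = 10:1 / 10)
  bins <- bin_by_fold_change(tab, n_bins = 5)
  expect_equal(as.vector(table(bins)), rep(2L, 5))
  expect_identical(names(bins)[bins == 1], c("g01", "g02"))
  # remainder goes to the top bins; sizes differ by at most one
  tab13 <- data.frame(gene = sprintf("g%02d", 1:13), log_ratio = 13:1)
  b13 <- bin_by_fold_change(tab13, 5)
  expect_equal(as.vector(table(b13)), c(3L, 3L, 3L, 2L, 2L))
  expect_equal(sort(names(b13)), sort(tab13$gene))
  # identical log ratios at a boundary: assignment stable across runs
  tie <- data.frame(gene = sprintf("g%02d", 1:10), log_ratio = c(5:2, 1, 1, 1, 1, 0, -1))
  expect_identical(bin_by_fold_change(tie, 5), bin_by_fold_change(tie[sample(10), ], 5))
  expect_error(bin_by_fold_change(tab[1:3, ], 5), "fewer genes")
  groups <- bin_groups(bins)
  expect_identical(unname(groups[c("g01", "g05", "g10")]),
                   c("top20", "mid60", "bottom20"))
})

test_that("positional composition counts windows with padding excluded", {
  sites <- data.frame(protein = "P1", position = 7,
                      center_residue = "S", window = "AAAAAASAAAAAA",
                      passes = TRUE, stringsAsFactors = FALSE)
  comp <- positional_composition(sites)
  expect_equal(sum(comp$counts["A", ]), 12)
  expect_equal(comp$counts["S", "0"], 1)
  expect_equal(sum(comp$counts), 13)
  # N-terminal site: left overhang drops out of the position denominators
  nterm <- data.frame(protein = "P1", position = 2, center_residue = "S",
                      window = "-----MKSAAAAA", passes = TRUE)
  cn <- positional_composition(nterm)
  expect_equal(unname(colSums(cn$counts)), c(0, 0, 0, 0, 0, rep(1, 8)))
  # a 3-site fixture equals the hand-tallied table
  three <- data.frame(protein = c("a", "b", "c"), position = 7,
                      center_residue = "S",
                      window = c("RRRRRRSPPPPPP", "KKKKKKSPPPPPP", "RRRRRRTPPPPPP"),
                      passes = TRUE)
  ct <- positional_composition(three)
  expect_equal(unname(ct$counts["R", "-6"]), 2)
  expect_equal(unname(ct$counts["K", "-1"]), 1)
  expect_equal(unname(ct$counts["S", "0"]), 2)
  expect_equal(unname(ct$counts["T", "0"]), 1)
  expect_equal(unname(ct$counts["P", "6"]), 3)
  # permutation invariance to site order
  ct2 <- positional_composition(three[c(3, 1, 2), ])
  expect_identical(ct$counts, ct2$counts)
})

test_that("composition significance matches the hypergeometric enumeration", {
  mk <- function(a_at_p1, n) {
    m <- matrix(0L, 20, 13, dimnames = list(coseda:::AA_ALPHABET,
                                            as.character(-6:6)))
    m["A", "1"] <- a_at_p1
    m["G", "1"] <- n - a_at_p1
    structure(list(counts = m, n_sites = n), class = "composition_counts")
  }
  top <- mk(30, 100); rest <- mk(10, 100)
  res <- composition_significance(top, rest)
  cell <- res[res$position == 1 & res$residue == "A", ]
  expect_equal(cell$p_value,
               oracle_fisher_two_sided(matrix(c(30, 70, 10, 90), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_identical(cell$direction, "over")
  # identical groups: p = 1 everywhere, nothing flagged
  same <- composition_significance(top, top)
  expect_true(all(same$p_value == 1))
  expect_false(any(same$flag))
})

test_that("a planted compositional bias is flagged over and under", {
  # synthetic stand-in for a residue-by-position count table: the top group
  # is enriched for S at -2, S at 0 and K at -1, depleted for P at +2
  set.seed(101)
  base <- matrix(10L, 20, 13, dimnames = list(coseda:::AA_ALPHABET,
                                              as.character(-6:6)))
  top <- base; rest <- base * 3L
  top["S", "-2"] <- 80L; top["S", "0"] <- 150L; top["K", "-1"] <- 70L
  top["P", "2"] <- 1L
  rest["S", "0"] <- 90L; rest["P", "2"] <- 120L
  tc <- structure(list(counts = top, n_sites = max(colSums(top))),
                  class = "composition_counts")
  rc <- structure(list(counts = rest, n_sites = max(colSums(rest))),
                  class = "composition_counts")
  res <- composition_significance(tc, rc, alpha = 0.01)
  pick <- function(p, r) res[res$position == p & res$residue == r, ]
  expect_true(pick(-2, "S")$flag && pick(-2, "S")$direction == "over")
  expect_true(pick(0, "S")$flag && pick(0, "S")$direction == "over")
  expect_true(pick(-1, "K")$flag && pick(-1, "K")$direction == "over")
  expect_true(pick(2, "P")$flag && pick(2, "P")$direction == "under")
})

test_that("count matrices round-trip and conserve per-position totals", {
  sim <- simulate_experiment(experiment_config(n_proteins = 60, n_spiked_up = 5,
                                               n_spiked_down = 2,
                                               motif_rate_background = 0.8,
                                               seed = 41))
  sites <- scan_sites(sim$sequences)
  comp <- positional_composition(sites)
  f <- tempfile(fileext = ".tsv")
  export_count_matrix(comp, f)
  back <- read_count_matrix(f)
  expect_equal(back$counts, comp$counts)
  expect_equal(back$n_sites, comp$n_sites)
  expect_true(all(colSums(back$counts) <= back$n_sites))
  # empty counts: header-only round trip
  none <- positional_composition(sites[0, ])
  export_count_matrix(none, f)
  expect_equal(sum(read_count_matrix(f)$counts), 0)
})
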