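test_that("accession collapsing removes single-peptide records and keeps the top score", {
  rec <- maxquant_rows()
  rec <- rbind(rec, rec[1, ])
  rec$`Gene names`[4] <- "alpha"
  rec$Score <- c(100, 200, 300, 80)     # alpha appears twice: 100 vs 80
  rec$Peptides <- c(5L, 1L, 8L, 4L)     # beta has a single peptide
  path <- write_maxquant_fixture(rec)
  parsed <- read_protein_groups(path, "maxquant")
  collapsed <- collapse_accessions(parsed)
  expect_setequal(collapsed$gene_name, c("alpha", "gamma"))
  expect_equal(collapsed$score[collapsed$gene_name == "alpha"], 100)
  # input order does not affect the result
  shuffled <- parsed[c(3, 1, 4, 2), ]
  attr(shuffled, "replicates") <- attr(parsed, "replicates")
  expect_identical(collapse_accessions(shuffled), collapsed)
  # all-unique, all >= 2 peptides: identity up to ordering
  clean <- read_protein_groups(write_maxquant_fixture(maxquant_rows()), "maxquant")
  expect_equal(nrow(collapse_accessions(clean)), nrow(clean))
})

test_that("zero-set partition follows the one-arm-zero rule", {
  # g1: detected only in sample arms -> zero set
  # g2: both arms in 3 pairs -> testable with 3 pairs
  # g3: (c>0, s=0) in pair 1, both arms in pairs 2-3 -> testable with 2 pairs
  # g4: never detected -> undetected
  con <- rbind(c(0, 0, 0), c(4, 4, 4), c(4, 4, 4), c(0, 0, 0))
  sam <- rbind(c(5, 5, 0), c(6, 6, 6), c(0, 6, 6), c(0, 0, 0))
  rownames(con) <- rownames(sam) <- paste0("g", 1:4)
  part <- partition_zero_set(pair_matrix(con, sam))
  expect_identical(part$zero_set, "g1")
  expect_identical(part$undetected, "g4")
  expect_setequal(rownames(part$testable$con), c("g2", "g3"))
  fit <- cosed_diff(pair_matrix(con, sam))
  expect_equal(fit$table$n_pairs[fit$table$gene == "g2"], 3)
  expect_equal(fit$table$n_pairs[fit$table$gene == "g3"], 2)
})

test_that("replicate QC flags scale shifts and degenerate pairs", {
  sim <- simulate_experiment(experiment_config(n_proteins = 300,
                                               missing_rate = 0, seed = 3))
  pm <- sim$matrix
  qc <- replicate_qc(pm)
  expect_true(all(qc$flag == "ok"))
  # an exactly duplicated arm gives slope 1
  pm_dup <- pair_matrix(pm$con, pm$con)
  qc_dup <- replicate_qc(pm_dup)
  expect_true(all(abs(qc_dup$slope - 1) < 1e-8))
  expect_true(all(qc_dup$flag == "ok"))
  # one pair scaled by 100 in both arms: its median shifts by log2(100)
  con2 <- pm$con; sam2 <- pm$sam
  con2[, 1] <- con2[, 1] * 100; sam2[, 1] <- sam2[, 1] * 100
  qc2 <- replicate_qc(pair_matrix(con2, sam2))
  expect_equal(qc2$median_both[1] - median(qc2$median_both[-1]), log2(100),
               tolerance = 0.2)
  expect_identical(qc2$flag[1], "flagged")
  # an empty pair is insufficient
  con3 <- cbind(pm$con, 0); sam3 <- cbind(pm$sam, 0)
  expect_identical(replicate_qc(pair_matrix(con3, sam3))$flag[7], "insufficient")
})

test_that("the paired t-test matches the closed-form Student oracle", {
  d <- c(0.5, 1.0, 1.5, 2.0)
  pm <- pm_from_log2(rep(10, 4), 10 + d)
  fit <- cosed_diff(pm)
  expect_equal(fit$table$log_ratio, mean(d))
  expect_equal(fit$table$p_value, oracle_paired_t_p(d), tolerance = 1e-12)
  expect_equal(fit$table$p_value, 0.03046629, tolerance = 1e-6)
  # and the t statistic behind it is 3.873 on 3 df
  expect_equal(mean(d) / (sd(d) / 2), 3.872983, tolerance = 1e-6)
})

test_that("replicate support below the minimum yields class insufficient", {
  pm <- pm_from_log2(rbind(c(10, NA, NA), c(10, 10, 10)),
                     rbind(c(11, NA, NA), c(11, 11, 11)))
  fit <- cosed_diff(pm, min_pairs = 2)
  expect_identical(fit$table$class[fit$table$n_pairs == 1], "insufficient")
  expect_true(is.na(fit$table$p_value[fit$table$n_pairs == 1]))
})

test_that("zero-variance differences are degenerate, not significant", {
  pm <- pm_from_log2(c(10, 11, 12), c(11, 12, 13))  # all differences exactly 1
  fit <- cosed_diff(pm)
  expect_true(fit$table$degenerate)
  expect_true(is.na(fit$table$p_value))
  expect_identical(fit$table$class, "unchanged")
})

test_that("volcano classification applies strict thresholds exactly as printed", {
  expect_identical(classify_volcano(log2(1.6), 0.04), "increased")
  expect_identical(classify_volcano(log2(1.5), 0.01), "unchanged")  # boundary
  expect_identical(classify_volcano(log2(0.5), 0.01), "decreased")
  expect_identical(classify_volcano(log2(1 / 1.5), 0.01), "unchanged")
  expect_identical(classify_volcano(log2(2), 0.05), "unchanged")    # p boundary
  expect_identical(classify_volcano(log2(2), NA_real_), "unchanged")
})

test_that("swapping arms negates log ratios and preserves p-values", {
  sim <- simulate_experiment(experiment_config(n_proteins = 150, seed = 17))
  fit <- cosed_diff(sim$matrix)
  swapped <- cosed_diff(pair_matrix(sim$matrix$sam, sim$matrix$con))
  expect_equal(swapped$table$log_ratio, -fit$table$log_ratio)
  expect_equal(swapped$table$p_value, fit$table$p_value)
})

test_that("paired p-values are invariant to per-pair shifts common to both arms", {
  sim <- simulate_experiment(experiment_config(n_proteins = 100,
                                               missing_rate = 0.2, seed = 19))
  shift <- c(3, -1, 0.5, 2, -2, 1)
  con2 <- sweep(sim$matrix$con, 2, 2^shift, `*`)
  sam2 <- sweep(sim$matrix$sam, 2, 2^shift, `*`)
  fit <- cosed_diff(sim$matrix)
  fit2 <- cosed_diff(pair_matrix(con2, sam2))
  expect_equal(fit2$table$p_value, fit$table$p_value, tolerance = 1e-10)
  expect_equal(fit2$table$log_ratio, fit$table$log_ratio, tolerance = 1e-10)
})

test_that("unpaired mode is exposed and differs from paired on paired-structured data", {
  pm <- pm_from_log2(c(10, 12, 14), c(10.6, 12.4, 14.5))
  paired <- cosed_diff(pm, mode = "paired")
  unpaired <- cosed_diff(pm, mode = "unpaired")
  expect_equal(paired$table$log_ratio, unpaired$table$log_ratio)
  expect_lt(paired$table$p_value, unpaired$table$p_value)
  expect_equal(unpaired$table$p_value,
               t.test(c(10.6, 12.4, 14.5), c(10, 12, 14), var.equal = TRUE)$p.value)
})

test_that("null p-values are approximately uniform (KS test)", {
  sim <- simulate_experiment(experiment_config(
    n_proteins = 2000, spike_fold_change = 1, n_spiked_up = 0,
    n_spiked_down = 0, missing_rate = 0.2, seed = 23))
  fit <- cosed_diff(sim$matrix)
  p <- fit$table$p_value[!is.na(fit$table$p_value)]
  expect_gt(length(p), 1500)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the volcano table is ordered, complete and reproducible", {
  sim <- simulate_experiment(experiment_config(n_proteins = 200, seed = 29))
  fit <- cosed_diff(sim$matrix)
  vt <- volcano_table(fit)
  expect_true(all(diff(vt$logratio) <= 0))
  counts <- attr(vt, "class_counts")
  expect_equal(sum(counts), nrow(vt))
  # spiked-up proteins concentrate at the top of the ordering
  up_genes <- sim$truth$gene[sim$truth$direction == "up"]
  top_half <- vt$gene[seq_len(nrow(vt) %/% 2)]
  in_top <- sum(up_genes %in% top_half)
  in_bottom <- sum(up_genes %in% vt$gene) - in_top
  expect_gt(in_top, in_bottom)
  # no hidden randomness
  expect_identical(vt, volcano_table(cosed_diff(sim$matrix)))
})

test_that("fit methods expose coefficients, summaries and plots", {
  sim <- simulate_experiment(experiment_config(n_proteins = 80, seed = 31))
  fit <- cosed_diff(sim$matrix)
  expect_named(coef(fit), fit$table$gene)
  s <- summary(fit)
  expect_equal(unname(s$counts["detected"]), fit$n_detected)
  expect_output(print(fit), "Differential co-sedimentation")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
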