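test_that("invalid configurations are rejected with the offending field named", {
  expect_error(experiment_config(missing_rate = 1.3), "missing_rate")
  expect_error(experiment_config(spike_fold_change = 0), "spike_fold_change")
  expect_error(experiment_config(n_proteins = 10, n_spiked_up = 8, n_spiked_down = 5),
               "n_spiked_up")
  expect_error(experiment_config(motif_rate_spiked = -0.1), "motif_rate_spiked")
  expect_error(experiment_config(seed = 2^31), "seed")
})

test_that("the same configuration and seed reproduce identical outputs", {
  cfg <- experiment_config(n_proteins = 120, seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$tables, b$tables)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(a$matrix, b$matrix)
  # a different seed changes the draw
  c2 <- simulate_experiment(experiment_config(n_proteins = 120, seed = 12))
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("a unit spike fold change simulates a global null", {
  sim <- simulate_experiment(experiment_config(n_proteins = 60, n_spiked_up = 5,
                                               n_spiked_down = 5,
                                               spike_fold_change = 1, seed = 5))
  expect_true(all(sim$truth$fold_change == 1))
  expect_true(all(log2(sim$truth$fold_change) == 0))
})

test_that("injected missingness matches its nominal rate within 3 binomial SE", {
  n <- 5000; k <- 6; rate <- 0.2
  sim <- simulate_experiment(experiment_config(
    n_proteins = n, n_replicate_pairs = k, missing_rate = rate,
    n_spiked_up = 0, n_spiked_down = 0, seed = 7))
  cells <- c(sim$matrix$con, sim$matrix$sam)
  observed <- mean(cells == 0)
  se <- sqrt(rate * (1 - rate) / length(cells))
  expect_lt(abs(observed - rate), 3 * se)
})

test_that("simulated intensities are natural-scale with zeros only from missingness", {
  sim <- simulate_experiment(experiment_config(n_proteins = 200,
                                               missing_rate = 0, seed = 2))
  expect_true(all(sim$matrix$con > 0))
  expect_true(all(sim$matrix$sam > 0))
})

test_that("ground-truth lookup returns recorded values and rejects unknowns", {
  sim <- simulate_experiment(experiment_config(n_proteins = 50, n_spiked_up = 5,
                                               n_spiked_down = 5, seed = 9))
  up <- sim$truth$protein[sim$truth$direction == "up"][1]
  null_p <- sim$truth$protein[sim$truth$direction == "null"][1]
  expect_identical(ground_truth_lookup(sim$truth, up)$direction, "up")
  expect_identical(ground_truth_lookup(sim$truth, null_p)$fold_change, 1)
  expect_error(ground_truth_lookup(sim$truth, "NOSUCH"), "not found")
})

test_that("planted motifs sit at their recorded positions and follow the consensus", {
  sim <- simulate_experiment(experiment_config(n_proteins = 80,
                                               motif_rate_spiked = 1,
                                               motif_rate_background = 0.5,
                                               seed = 21))
  with_motif <- which(!is.na(sim$truth$motif_position))
  expect_gt(length(with_motif), 0)
  for (i in with_motif) {
    s <- sim$sequences[[sim$truth$protein[i]]]
    p <- sim$truth$motif_position[i]
    expect_identical(substring(s, p, p), "S")
    expect_identical(substring(s, p + 2, p + 2), "P")
    expect_true(substring(s, p - 3, p - 3) %in% c("R", "K"))
  }
})

test_that("phenotype simulation honours its rates and degenerate settings", {
  ph0 <- simulate_phenotype(n_per_group = 200, median_shift = 0,
                            mono_rate_a = 0, mono_rate_b = 0.3, seed = 4)
  expect_identical(ph0$counts["A", "monooriented"], 0L)
  a <- ph0$intensities$intensity[ph0$intensities$group == "A"]
  b <- ph0$intensities$intensity[ph0$intensities$group == "B"]
  # no shift: expected percent change of medians is 0; check it is small
  # relative to sampling noise on 200 log-normal draws
  expect_lt(abs(100 * (median(a) - median(b)) / median(a)), 25)

  ph <- simulate_phenotype(n_per_group = 1000, median_shift = 0.5,
                           mono_rate_a = 0.05, mono_rate_b = 0.3, seed = 8)
  frac_b <- ph$counts["B", "monooriented"] / 1000
  expect_lt(abs(frac_b - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_error(simulate_phenotype(mono_rate_a = 1.5), "mono_rate_a")
  expect_error(simulate_phenotype(median_shift = 1.2), "median_shift")
})
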