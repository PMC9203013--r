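#' Configuration for a synthetic co-sedimentation experiment
#'
#' Builds and validates the parameter set used by [simulate_experiment()].
#' The defaults describe the experimental design the pipeline targets: six
#' paired biological replicates (control vs 14-3-3-inhibited microtubule
#' fractions), a few thousand detectable proteins of which a small set
#' genuinely changes microtubule binding, and enough zero-inflated
#' missingness that roughly 42% of proteins are quantifiable in at least two
#' replicate pairs.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_replicate_pairs Number of paired replicates (control + sample).
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of the per-protein
#'   baseline log2 intensity (LFQ-like scale).
#' @param replicate_noise_sd SD (log2 units) of both the shared per-pair
#'   effect and the independent per-measurement noise.
#' @param missing_rate Probability that any single intensity cell is replaced
#'   by 0 ("not detected"). With the default 0.52 a protein is detected in
#'   both arms of a pair with probability (1 - 0.52)^2 = 0.23, which puts the
#'   expected fraction quantifiable in >= 2 of 6 pairs near 42%.
#' @param missing_mode `"mcar"` (default) drops cells completely at random;
#'   `"intensity"` makes low-abundance proteins proportionally more likely to
#'   be missing while keeping the average rate at `missing_rate`.
#' @param n_spiked_up,n_spiked_down Numbers of proteins whose sample-arm
#'   intensity is multiplied, respectively divided, by `spike_fold_change`.
#' @param spike_fold_change True fold change of the spiked proteins (> 0).
#'   1.0 simulates a global null.
#' @param motif_rate_spiked,motif_rate_background Probability that a
#'   spiked-up protein (respectively any other protein) carries a planted
#'   mode-I-like 14-3-3 consensus motif in its sequence.
#' @param seed Integer seed (< 2^31); the single source of randomness.
#' @return An object of class `experiment_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
experiment_config <- function(n_proteins = 3564L,
                              n_replicate_pairs = 6L,
                              baseline_log2_mean = 25,
                              baseline_log2_sd = 2,
                              replicate_noise_sd = 0.7,
                              missing_rate = 0.52,
                              missing_mode = c("mcar", "intensity"),
                              n_spiked_up = 47L,
                              n_spiked_down = 20L,
                              spike_fold_change = 4,
                              motif_rate_spiked = 0.6,
                              motif_rate_background = 0.35,
                              seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  chk_count <- function(x, field, min = 0L) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
      .stopf("invalid '%s': must be a single integer >= %d", field, min)
    as.integer(x)
  }
  chk_prob <- function(x, field) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
      .stopf("invalid '%s': must be a probability in [0, 1]", field)
    as.numeric(x)
  }
  chk_pos <- function(x, field) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
      .stopf("invalid '%s': must be a single positive number", field)
    as.numeric(x)
  }
  cfg <- list(
    n_proteins = chk_count(n_proteins, "n_proteins", 1L),
    n_replicate_pairs = chk_count(n_replicate_pairs, "n_replicate_pairs", 1L),
    baseline_log2_mean = as.numeric(baseline_log2_mean),
    baseline_log2_sd = chk_pos(baseline_log2_sd, "baseline_log2_sd"),
    replicate_noise_sd = chk_pos(replicate_noise_sd, "replicate_noise_sd"),
    missing_rate = chk_prob(missing_rate, "missing_rate"),
    missing_mode = missing_mode,
    n_spiked_up = chk_count(n_spiked_up, "n_spiked_up"),
    n_spiked_down = chk_count(n_spiked_down, "n_spiked_down"),
    spike_fold_change = chk_pos(spike_fold_change, "spike_fold_change"),
    motif_rate_spiked = chk_prob(motif_rate_spiked, "motif_rate_spiked"),
    motif_rate_background = chk_prob(motif_rate_background, "motif_rate_background"),
    seed = if (is.numeric(seed) && length(seed) == 1L && !is.na(seed) &&
                 seed >= 2^31)
             .stopf("invalid 'seed': must be below 2^31")
           else chk_count(seed, "seed", 0L)
  )
  if (!is.numeric(baseline_log2_mean) || length(baseline_log2_mean) != 1L ||
      is.na(baseline_log2_mean))
    .stopf("invalid 'baseline_log2_mean': must be a single number")
  if (cfg$n_spiked_up + cfg$n_spiked_down > cfg$n_proteins)
    .stopf("invalid 'n_spiked_up'/'n_spiked_down': %d + %d exceeds n_proteins = %d",
           cfg$n_spiked_up, cfg$n_spiked_down, cfg$n_proteins)
  structure(cfg, class = "experiment_config")
}

# Plant a mode-I-like motif (basic residue at -3, phospho-S at 0, P at +2)
# at a random internal position. Filler residues come from `alphabet`.
.plant_motif <- function(seq_chars, alphabet) {
  n <- length(seq_chars)
  center <- sample(5:(n - 3), 1L)
  seq_chars[center - 3L] <- sample(c("R", "K"), 1L)
  seq_chars[center] <- "S"
  seq_chars[center + 2L] <- "P"
  list(chars = seq_chars, position = center)
}

#' Simulate a paired microtubule co-sedimentation experiment
#'
#' Generates per-replicate protein-groups tables, protein sequences and a
#' ground-truth record with the statistical structure the downstream
#' analysis assumes. Each protein gets a log-normal baseline intensity; for
#' every replicate pair the control and sample (inhibitor-treated) arms share
#' the baseline plus a common pair effect, with independent measurement
#' noise on top. Spiked proteins have their sample-arm intensity multiplied
#' (up) or divided (down) by the configured fold change. Intensities are
#' formed on the natural scale as `2^log2draw`, and zeros arise only from
#' the missingness mechanism, mirroring the convention that an intensity of
#' 0 means "not detected" rather than a measured value.
#'
#' Sequences are drawn from an alphabet that excludes serine and threonine
#' except inside planted motifs, so a consensus-scanner hit identifies a
#' planted motif exactly; motif presence is correlated with the spiked-up
#' direction via `motif_rate_spiked` vs `motif_rate_background`.
#'
#' A handful of decoy ("REV__") and contaminant ("CON__") rows are appended
#' to each table so that standard-flag filtering is exercised end to end;
#' these carry no ground truth.
#'
#' @param config An [experiment_config()] object.
#' @return A list of class `cosed_simulation`:
#'   \describe{
#'     \item{tables}{named list of per-replicate-pair protein-groups
#'       data frames in the MaxQuant-style dialect read by
#'       [read_protein_groups()].}
#'     \item{matrix}{the corresponding [pair_matrix()] (truth-aligned,
#'       decoys/contaminants excluded).}
#'     \item{sequences}{named character vector of amino-acid sequences.}
#'     \item{truth}{data frame with columns `protein`, `gene`, `direction`
#'       (`"up"`/`"down"`/`"null"`), `fold_change`, `motif_position` (NA when
#'       no motif was planted).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    config <- do.call(experiment_config, as.list(config))
  n <- config$n_proteins
  k <- config$n_replicate_pairs

  set.seed(config$seed)
  protein <- sprintf("P%05d", seq_len(n))
  gene <- sprintf("G%04d", seq_len(n))

  direction <- rep("null", n)
  spiked <- sample.int(n, config$n_spiked_up + config$n_spiked_down)
  idx_up <- spiked[seq_len(config$n_spiked_up)]
  idx_down <- setdiff(spiked, idx_up)
  direction[idx_up] <- "up"
  direction[idx_down] <- "down"
  fold_change <- ifelse(direction == "up", config$spike_fold_change,
                        ifelse(direction == "down", 1 / config$spike_fold_change, 1))

  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  # sequences: alphabet without S/T outside planted motifs, so that scanner
  # hits coincide exactly with the planted ground truth
  alphabet <- setdiff(AA_ALPHABET, c("S", "T"))
  motif_p <- ifelse(direction == "up", config$motif_rate_spiked,
                    config$motif_rate_background)
  has_motif <- runif(n) < motif_p
  seq_len_i <- sample(200:600, n, replace = TRUE)
  motif_position <- rep(NA_integer_, n)
  sequences <- character(n)
  for (i in seq_len(n)) {
    chars <- sample(alphabet, seq_len_i[i], replace = TRUE)
    if (has_motif[i]) {
      planted <- .plant_motif(chars, alphabet)
      chars <- planted$chars
      motif_position[i] <- planted$position
    }
    sequences[i] <- paste(chars, collapse = "")
  }
  names(sequences) <- protein

  peptides <- sample(2:30, n, replace = TRUE)
  score <- round(runif(n, 10, 320), 2)

  con <- matrix(0, n, k, dimnames = list(gene, as.character(seq_len(k))))
  sam <- con
  for (j in seq_len(k)) {
    # deterministic per-pair sub-stream derived from the global seed
    set.seed((config$seed + 7919L * j) %% .Machine$integer.max)
    pair_effect <- rnorm(1, 0, config$replicate_noise_sd)
    log_con <- baseline + pair_effect + rnorm(n, 0, config$replicate_noise_sd)
    log_sam <- baseline + pair_effect + log2(fold_change) +
      rnorm(n, 0, config$replicate_noise_sd)
    cj <- 2^log_con
    sj <- 2^log_sam
    if (config$missing_rate > 0) {
      p <- rep(config$missing_rate, n)
      if (config$missing_mode == "intensity") {
        w <- plogis(-(baseline - config$baseline_log2_mean) / config$baseline_log2_sd)
        p <- pmin(1, config$missing_rate * w / mean(w))
      }
      cj[runif(n) < p] <- 0
      sj[runif(n) < p] <- 0
    }
    con[, j] <- cj
    sam[, j] <- sj
  }

  pm <- pair_matrix(con, sam)

  # decoy / contaminant rows exercising the standard-flag filter
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  n_rev <- 10L; n_con <- 5L
  extra <- data.frame(
    id = c(sprintf("REV__Q%05d", seq_len(n_rev)), sprintf("CON__Q%05d", seq_len(n_con))),
    gene = c(sprintf("REVG%d", seq_len(n_rev)), sprintf("CONG%d", seq_len(n_con))),
    reverse = c(rep("+", n_rev), rep("", n_con)),
    contam = c(rep("", n_rev), rep("+", n_con)),
    stringsAsFactors = FALSE
  )
  extra_int <- matrix(round(2^rnorm((n_rev + n_con) * 2 * k, 20, 2), 1),
                      nrow = n_rev + n_con)

  tables <- vector("list", k)
  names(tables) <- sprintf("pair%d", seq_len(k))
  for (j in seq_len(k)) {
    tab <- data.frame(
      `Protein IDs` = c(protein, extra$id),
      `Majority protein IDs` = c(protein, extra$id),
      `Gene names` = c(gene, extra$gene),
      Peptides = c(peptides, rep(3L, n_rev + n_con)),
      `Razor + unique peptides` = c(peptides, rep(3L, n_rev + n_con)),
      `Unique peptides` = c(pmax(1L, peptides - 1L), rep(2L, n_rev + n_con)),
      Score = c(score, rep(50, n_rev + n_con)),
      Reverse = c(rep("", n), extra$reverse),
      `Potential contaminant` = c(rep("", n), extra$contam),
      `Only identified by site` = rep("", n + n_rev + n_con),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    tab[[sprintf("LFQ intensity CON%d", j)]] <- c(con[, j], extra_int[, 2L * j - 1L])
    tab[[sprintf("LFQ intensity SAM%d", j)]] <- c(sam[, j], extra_int[, 2L * j])
    tables[[j]] <- tab
  }

  truth <- data.frame(protein = protein, gene = gene, direction = direction,
                      fold_change = fold_change, motif_position = motif_position,
                      stringsAsFactors = FALSE)

  structure(list(tables = tables, matrix = pm, sequences = sequences,
                 truth = truth, config = config),
            class = "cosed_simulation")
}

#' @export
print.cosed_simulation <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic co-sedimentation experiment\n")
  cat(sprintf("  %d proteins x %d replicate pairs (seed %d)\n",
              cfg$n_proteins, cfg$n_replicate_pairs, cfg$seed))
  cat(sprintf("  spiked: %d up, %d down at fold change %.3g; missing rate %.2f (%s)\n",
              cfg$n_spiked_up, cfg$n_spiked_down, cfg$spike_fold_change,
              cfg$missing_rate, cfg$missing_mode))
  cat(sprintf("  motifs planted in %d sequences\n", sum(!is.na(x$truth$motif_position))))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes the per-replicate protein-groups tables as TSV (the same dialect
#' [read_protein_groups()] reads), the sequences as FASTA, the combined pair
#' matrix as tidy TSV, and the ground truth as a TSV sidecar.
#'
#' @param sim A `cosed_simulation` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "cosed_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(sim$tables)) {
    f <- file.path(dir, paste0("proteinGroups_", nm, ".txt"))
    write.table(sim$tables[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  fa <- file.path(dir, "sequences.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$sequences), fa)
  mt <- file.path(dir, "pair_matrix.tsv")
  write_pair_matrix(sim$matrix, mt)
  tr <- file.path(dir, "ground_truth.tsv")
  write.table(sim$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, fa, mt, tr))
}

#' Look up the simulated ground truth for one protein
#'
#' @param truth The `truth` data frame of a `cosed_simulation`.
#' @param protein A protein accession (or simulated gene symbol).
#' @return A list with `direction`, `fold_change` and `motif_position`.
#' @export
ground_truth_lookup <- function(truth, protein) {
  i <- match(protein, truth$protein)
  if (is.na(i)) i <- match(protein, truth$gene)
  if (is.na(i)) .stopf("protein '%s' not found in ground truth", protein)
  list(direction = truth$direction[i],
       fold_change = truth$fold_change[i],
       motif_position = truth$motif_position[i])
}

#' Simulate per-oocyte signal intensities and orientation counts
#'
#' Emulates the inputs of the downstream phenotype statistics: per-oocyte
#' fluorescence intensities for two genotype groups where group B's
#' distribution is group A's scaled by `1 - median_shift`, and a 2x2 table
#' of bi- vs mono-oriented centromere counts drawn binomially.
#'
#' @param n_per_group Oocytes per group.
#' @param median_shift Fractional reduction of group B's intensities
#'   (0.82 reproduces a "82% reduction in median" scenario).
#' @param mono_rate_a,mono_rate_b Mono-orientation probabilities of the two
#'   genotypes.
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the group-A intensities
#'   (arbitrary fluorescence units).
#' @return A list with `intensities` (data frame: `group`, `intensity`) and
#'   `counts` (2x2 integer matrix, rows `A`/`B`, columns
#'   `bioriented`/`monooriented`).
#' @export
simulate_phenotype <- function(n_per_group = 40L, median_shift = 0.82,
                               mono_rate_a = 0.05, mono_rate_b = 0.30,
                               seed = 1L, meanlog = log(1000), sdlog = 0.5) {
  for (nm in c("mono_rate_a", "mono_rate_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      .stopf("invalid '%s': must be a probability in [0, 1]", nm)
  }
  if (!is.numeric(median_shift) || median_shift < 0 || median_shift >= 1)
    .stopf("invalid 'median_shift': must be a fraction in [0, 1)")
  if (n_per_group < 1) .stopf("invalid 'n_per_group': must be >= 1")
  n_per_group <- as.integer(n_per_group)
  set.seed(seed)
  a <- exp(rnorm(n_per_group, meanlog, sdlog))
  b <- exp(rnorm(n_per_group, meanlog, sdlog)) * (1 - median_shift)
  intensities <- data.frame(
    group = rep(c("A", "B"), each = n_per_group),
    intensity = c(a, b), stringsAsFactors = FALSE
  )
  mono_a <- rbinom(1, n_per_group, mono_rate_a)
  mono_b <- rbinom(1, n_per_group, mono_rate_b)
  counts <- matrix(c(n_per_group - mono_a, mono_a,
                     n_per_group - mono_b, mono_b),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("bioriented", "monooriented")))
  list(intensities = intensities, counts = counts)
}
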