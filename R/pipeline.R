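# End-to-end orchestration: a declarative config drives simulation or
# ingestion, the differential fit, motif annotation and enrichment, optional
# network enrichment, and a consolidated plain-text report. Identical config
# and seed give an identical bundle.

#' Build a pipeline run configuration
#'
#' All entries can also be supplied through a YAML file (see
#' [read_pipeline_config()]); explicit arguments override file values.
#'
#' @param input_dir Directory with protein-groups TSVs and a FASTA; when
#'   NULL the run starts from a simulated experiment.
#' @param dialect Protein-groups dialect for ingestion.
#' @param simulation List of [experiment_config()] overrides for simulated
#'   runs.
#' @param mode Differential test mode, `"paired"` or `"unpaired"`.
#' @param min_pairs Minimum doubly-detected pairs.
#' @param fc_up,fc_down,alpha Volcano thresholds.
#' @param n_bins Fold-change bins for the composition analysis.
#' @param composition_alpha Per-cell significance threshold.
#' @param edges_path Optional edge TSV; enables the network stage.
#' @param n_permutations Permutations for the network null.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory; NULL disables file output.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, dialect = "maxquant",
                            simulation = list(), mode = "paired",
                            min_pairs = 2, fc_up = 1.5, fc_down = 1 / 1.5,
                            alpha = 0.05, n_bins = 5,
                            composition_alpha = 0.01, edges_path = NULL,
                            n_permutations = 1000, seed = 1L,
                            out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) .stopf("invalid 'alpha': must be in (0, 1)")
  if (composition_alpha <= 0 || composition_alpha >= 1)
    .stopf("invalid 'composition_alpha': must be in (0, 1)")
  if (fc_up <= 0 || fc_down <= 0) .stopf("fold-change thresholds must be positive")
  structure(list(input_dir = input_dir, dialect = dialect,
                 simulation = simulation, mode = mode, min_pairs = min_pairs,
                 fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 n_bins = n_bins, composition_alpha = composition_alpha,
                 edges_path = edges_path, n_permutations = n_permutations,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys are `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  message(sprintf("[%s] done in %.2fs", name, as.numeric(Sys.time() - t0, "secs")))
  res
}

#' Run the whole analysis pipeline
#'
#' Chains the stages: input (simulation or ingestion) -> replicate QC ->
#' differential fit -> motif scan and directional enrichment -> fold-change
#' binning and positional composition -> optional network enrichment ->
#' report. When `out_dir` is set, every stage's table is written as TSV
#' alongside a plain-text summary and the resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cosed_run` with elements `fit`, `qc`, `sites`,
#'   `enrichment`, `bins`, `composition`, `composition_tests`, `network`
#'   (NULL without an edge table), `summary` (named numeric vector of
#'   headline counts), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input_dir)) {
    sim <- .stage("simulate", {
      sim_cfg <- do.call(experiment_config,
                         c(config$simulation,
                           if (is.null(config$simulation$seed))
                             list(seed = config$seed)))
      simulate_experiment(sim_cfg)
    })
    pm <- sim$matrix
    sequences <- sim$sequences
  } else {
    ing <- .stage("ingest", {
      files <- sort(list.files(config$input_dir, "^proteinGroups.*\\.txt$",
                               full.names = TRUE))
      if (!length(files)) .stopf("no proteinGroups*.txt under %s", config$input_dir)
      recs <- lapply(files, read_protein_groups, dialect = config$dialect)
      recs <- lapply(recs, filter_standard_flags, quiet = TRUE)
      recs <- lapply(recs, collapse_accessions)
      mats <- lapply(recs, build_pair_matrix)
      genes <- sort(unique(unlist(lapply(mats, function(m) rownames(m$con)))))
      con <- do.call(cbind, lapply(mats, function(m) {
        out <- matrix(0, length(genes), length(m$pairs),
                      dimnames = list(genes, m$pairs))
        out[rownames(m$con), ] <- m$con
        out
      }))
      sam <- do.call(cbind, lapply(mats, function(m) {
        out <- matrix(0, length(genes), length(m$pairs),
                      dimnames = list(genes, m$pairs))
        out[rownames(m$sam), ] <- m$sam
        out
      }))
      acc2gene <- unlist(lapply(recs, function(r) {
        lead <- vapply(strsplit(r$protein_ids, ";", fixed = TRUE),
                       function(p) p[[1]], character(1))
        setNames(gene_key(r), lead)
      }))
      list(pm = pair_matrix(con, sam),
           acc2gene = acc2gene[!duplicated(names(acc2gene))],
           fasta = list.files(config$input_dir, "\\.fa(sta)?$",
                              full.names = TRUE))
    })
    pm <- ing$pm
    sequences <- if (length(ing$fasta)) read_fasta(ing$fasta[1]) else NULL
    sim <- NULL
  }

  qc <- .stage("qc", replicate_qc(pm))
  fit <- .stage("differential", cosed_diff(pm, min_pairs = config$min_pairs,
                                           mode = config$mode,
                                           fc_up = config$fc_up,
                                           fc_down = config$fc_down,
                                           alpha = config$alpha))
  sites <- enrichment <- bins <- composition <- comp_tests <- NULL
  if (!is.null(sequences)) {
    sites <- .stage("motif", {
      s <- scan_sites(sequences)
      # the fit is keyed by gene; translate FASTA accessions to gene symbols
      if (!is.null(sim)) {
        s$protein <- sim$truth$gene[match(s$protein, sim$truth$protein)]
      } else if (length(ing$acc2gene)) {
        hit <- s$protein %in% names(ing$acc2gene)
        s$protein[hit] <- unname(ing$acc2gene[s$protein[hit]])
      }
      s
    })
    enrichment <- .stage("enrichment",
                         suppressWarnings(directional_enrichment(fit, sites)))
    tested <- fit$table[!is.na(fit$table$p_value), ]
    if (nrow(tested) >= config$n_bins) {
      bins <- bin_by_fold_change(tested, config$n_bins)
      groups <- if (config$n_bins == 5) bin_groups(bins)
                else setNames(as.character(bins), names(bins))
      composition <- suppressWarnings(positional_composition(sites, groups))
      nonzero <- vapply(composition, function(x) x$n_sites > 0, logical(1))
      if (config$n_bins == 5 && all(c("top20", "mid60", "bottom20") %in%
                                      names(composition)[nonzero])) {
        rest <- composition$mid60
        rest$counts <- rest$counts + composition$bottom20$counts
        rest$n_sites <- rest$n_sites + composition$bottom20$n_sites
        comp_tests <- composition_significance(composition$top20, rest,
                                               alpha = config$composition_alpha)
      }
    }
  }
  network <- NULL
  if (!is.null(config$edges_path)) {
    network <- .stage("network", {
      edges <- read_edge_table(config$edges_path)
      increased <- fit$table$gene[fit$table$class == "increased"]
      background <- fit$table$gene[!is.na(fit$table$p_value)]
      edge_enrichment(increased, background, edges,
                      n_permutations = config$n_permutations,
                      seed = config$seed)
    })
  }

  cl <- table(factor(fit$table$class,
                     c("increased", "decreased", "unchanged", "insufficient")))
  summary_counts <- c(
    detected = fit$n_detected,
    quantifiable = sum(fit$table$class != "insufficient"),
    increased = unname(cl[["increased"]]),
    decreased = unname(cl[["decreased"]]),
    unchanged = unname(cl[["unchanged"]]),
    zero_set = length(fit$zero_set),
    with_sites = if (is.null(sites)) NA_integer_
                 else length(unique(sites$protein[sites$passes]))
  )
  run <- structure(list(fit = fit, qc = qc, sites = sites,
                        enrichment = enrichment, bins = bins,
                        composition = composition,
                        composition_tests = comp_tests, network = network,
                        summary = summary_counts, config = config,
                        truth = if (is.null(sim)) NULL else sim$truth),
                   class = "cosed_run")
  if (!is.null(config$out_dir)) write_report(run, config$out_dir)
  run
}

#' @export
print.cosed_run <- function(x, ...) {
  cat("Pipeline run summary\n")
  print(x$summary)
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' Write the consolidated report bundle of a run
#'
#' Writes the volcano table, QC table, site table, enrichment counts,
#' per-group count matrices and network result as TSV, plus `summary.txt`
#' with the headline counts and provenance (seed, package version, config)
#' and the resolved configuration as YAML. Regenerating the report from the
#' same run reproduces identical files.
#'
#' @param run A `cosed_run` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "cosed_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    f <- file.path(dir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, f)
  }
  wt(volcano_table(run$fit, all = TRUE), "volcano.tsv")
  wt(as.data.frame(run$qc), "replicate_qc.tsv")
  if (!is.null(run$sites)) wt(run$sites, "sites.tsv")
  if (!is.null(run$composition_tests))
    wt(run$composition_tests, "composition_tests.tsv")
  if (!is.null(run$composition)) {
    for (g in names(run$composition)) {
      f <- file.path(dir, sprintf("composition_%s.tsv", g))
      export_count_matrix(run$composition[[g]], f)
      paths <- c(paths, f)
    }
  }
  if (!is.null(run$enrichment))
    wt(data.frame(partition = c("with_sites", "without_sites"),
                  n_up = c(run$enrichment$n_with_up, run$enrichment$n_without_up),
                  n_down = c(run$enrichment$n_with_down, run$enrichment$n_without_down),
                  p = c(run$enrichment$p_with, run$enrichment$p_without)),
       "enrichment.tsv")
  if (!is.null(run$network))
    wt(data.frame(observed = run$network$observed_edges,
                  expected = run$network$expected_edges,
                  empirical_p = run$network$empirical_p,
                  n_permutations = run$network$n_permutations,
                  seed = run$network$seed),
       "network.tsv")
  smry <- file.path(dir, "summary.txt")
  lines <- c("pipeline run summary",
             sprintf("%-14s %s", names(run$summary), run$summary),
             "",
             sprintf("seed: %d", run$config$seed),
             sprintf("package version: %s",
                     as.character(utils::packageVersion("coseda"))))
  if (!is.null(run$enrichment))
    lines <- c(lines,
               sprintf("enrichment with sites: %d up / %d down (p = %s)",
                       run$enrichment$n_with_up, run$enrichment$n_with_down,
                       format(run$enrichment$p_with, digits = 4)),
               sprintf("enrichment without sites: %d up / %d down (p = %s)",
                       run$enrichment$n_without_up, run$enrichment$n_without_down,
                       format(run$enrichment$p_without, digits = 4)))
  writeLines(lines, smry)
  cfgf <- file.path(dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(run$config), function(x)
    if (is.null(x)) NA else x), cfgf)
  invisible(c(paths, smry, cfgf))
}

#' Reproduce the published summary numbers from supplementary tables
#'
#' Runs the reproduction pipeline against a directory of the study's
#' supplementary tables, which the user must supply (they are not shipped
#' with the package): `S1` (quantifiable-protein result sheet), the raw
#' per-replicate protein-groups tables (any files matching `S[2-7]*`),
#' `S8` (positional residue counts per fold-change group), `S10`
#' (per-oocyte GFP signal intensities by genotype) and `S11`
#' (bi-/mono-orientation counts). Files may be `.xlsx` or `.tsv`/`.txt`
#' exports with the original column layouts.
#'
#' @param dir Directory containing the tables, named by their supplementary
#'   number (e.g. `S1.xlsx`, `S2.tsv`, ...).
#' @return A list with whichever of these could be computed: `n_detected`,
#'   `n_quantifiable`, `n_increased`, `n_decreased`,
#'   `percent_reduction_s163a`, `percent_reduction_s161a`,
#'   `mono_rate_control`, `mono_rate_rnai`, `composition_flags`.
#' @export
reproduce_supplementary <- function(dir) {
  if (!dir.exists(dir)) .stopf("supplementary-data directory not found: %s", dir)
  find <- function(stem) {
    f <- list.files(dir, sprintf("^%s[^0-9]", stem), full.names = TRUE,
                    ignore.case = TRUE)
    if (length(f)) f[1] else NULL
  }
  out <- list()

  raw <- unlist(lapply(sprintf("S%d", 2:7), find))
  if (length(raw)) {
    recs <- lapply(raw, read_protein_groups, dialect = "maxquant")
    recs <- lapply(recs, filter_standard_flags, quiet = TRUE)
    recs <- lapply(recs, collapse_accessions)
    mats <- lapply(recs, build_pair_matrix)
    genes <- sort(unique(unlist(lapply(mats, function(m) rownames(m$con)))))
    assemble <- function(arm) do.call(cbind, lapply(mats, function(m) {
      o <- matrix(0, length(genes), length(m$pairs),
                  dimnames = list(genes, m$pairs))
      o[rownames(m[[arm]]), ] <- m[[arm]]
      o
    }))
    fit <- cosed_diff(pair_matrix(assemble("con"), assemble("sam")))
    out$n_detected <- fit$n_detected
    out$n_quantifiable <- sum(fit$table$class != "insufficient")
  }

  s1 <- find("S1")
  if (!is.null(s1)) {
    recs <- read_protein_groups(s1, dialect = "supplementary")
    fit <- cosed_diff(build_pair_matrix(recs))
    cl <- table(fit$table$class)
    out$n_quantifiable_s1 <- sum(fit$table$class != "insufficient")
    out$n_increased <- sum(fit$table$class == "increased")
    out$n_decreased <- sum(fit$table$class == "decreased")
  }

  s8 <- find("S8")
  if (!is.null(s8)) {
    groups <- .read_s8_counts(s8)
    rest <- groups$mid
    rest$counts <- rest$counts + groups$bottom$counts
    rest$n_sites <- rest$n_sites + groups$bottom$n_sites
    out$composition_flags <- composition_significance(groups$top, rest)
  }

  s10 <- find("S10")
  if (!is.null(s10)) {
    df <- .read_any_table(s10)
    .require_columns(df, c("genotype", "intensity"), "S10 table")
    wt <- df$intensity[grepl("^(wt|wild)", df$genotype, ignore.case = TRUE)]
    for (mut in c("S163A", "S161A")) {
      v <- df$intensity[grepl(mut, df$genotype, ignore.case = TRUE)]
      if (length(wt) && length(v))
        out[[sprintf("percent_reduction_%s", tolower(mut))]] <-
          compare_intensities(wt, v)$percent_change
    }
  }

  s11 <- find("S11")
  if (!is.null(s11)) {
    df <- .read_any_table(s11)
    .require_columns(df, c("genotype", "bioriented", "monooriented"), "S11 table")
    ctrl <- grepl("control|no.?sh", df$genotype, ignore.case = TRUE)
    rnai <- grepl("RNAi", df$genotype, ignore.case = TRUE) &
      !grepl("wt|S16", df$genotype, ignore.case = TRUE)
    if (any(ctrl) && any(rnai)) {
      m <- rbind(c(sum(df$bioriented[ctrl]), sum(df$monooriented[ctrl])),
                 c(sum(df$bioriented[rnai]), sum(df$monooriented[rnai])))
      bt <- biorientation_test(m)
      out$mono_rate_control <- 100 * bt$mono_freq[1]
      out$mono_rate_rnai <- 100 * bt$mono_freq[2]
      out$biorientation_p <- bt$p_value
    }
  }
  out
}

.read_any_table <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE))
    as.data.frame(readxl::read_excel(path))
  else read.delim(path, stringsAsFactors = FALSE)
}

# S8 layout: one row per residue per group, columns = positions 1..13
# (position 7 = the phospho-site), with a group column naming top/mid/bottom
# (groups 2-4 are the middle quintiles and are pooled).
.read_s8_counts <- function(path) {
  df <- .read_any_table(path)
  .require_columns(df, c("group", "residue"), "S8 table")
  pos_cols <- names(df)[!(names(df) %in% c("group", "residue"))]
  if (length(pos_cols) != 13) .stopf("S8 table must have 13 position columns")
  mk <- function(rows) {
    m <- matrix(0L, length(AA_ALPHABET), 13,
                dimnames = list(AA_ALPHABET, as.character(-6:6)))
    sub <- df[rows, , drop = FALSE]
    m[sub$residue, ] <- as.matrix(sub[pos_cols])
    structure(list(counts = m, n_sites = max(colSums(m))),
              class = "composition_counts")
  }
  grp <- tolower(as.character(df$group))
  top <- mk(grepl("top|^1$", grp))
  bottom <- mk(grepl("bottom|^5$", grp))
  mid_rows <- which(!(grepl("top|^1$", grp) | grepl("bottom|^5$", grp)))
  mid <- mk(mid_rows)
  # several middle groups may repeat residues; re-aggregate
  if (length(mid_rows)) {
    m <- matrix(0L, length(AA_ALPHABET), 13,
                dimnames = list(AA_ALPHABET, as.character(-6:6)))
    sub <- df[mid_rows, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      m[sub$residue[i], ] <- m[sub$residue[i], ] + as.integer(sub[i, pos_cols])
    mid <- structure(list(counts = m, n_sites = max(colSums(m))),
                     class = "composition_counts")
  }
  list(top = top, mid = mid, bottom = bottom)
}
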