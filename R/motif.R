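# 14-3-3 binding-site annotation and sequence-context statistics: importing
# predictor output, a simple consensus scanner as a documented stand-in for
# the external predictor, directional enrichment among differential classes,
# fold-change binning, and positional residue composition around predicted
# phospho-sites.

WINDOW_HALF <- 6L   # positions -6..+6 around the phospho-S/T
WINDOW_PAD <- "-"   # marks overhangs beyond the protein termini

#' Extract the 13-residue window around a site
#'
#' @param sequence Amino-acid sequence.
#' @param position 1-based index of the phospho-S/T.
#' @return A 13-character string (positions -6..+6, center at character 7);
#'   overhangs beyond the termini are padded with `-`.
#' @export
extract_window <- function(sequence, position) {
  n <- nchar(sequence)
  if (position < 1 || position > n)
    .stopf("position %d outside sequence of length %d", position, n)
  idx <- (position - WINDOW_HALF):(position + WINDOW_HALF)
  chars <- ifelse(idx < 1 | idx > n, WINDOW_PAD,
                  substring(sequence, pmax(idx, 1), pmax(idx, 1)))
  paste(chars, collapse = "")
}

#' Read a 14-3-3 site predictor output table
#'
#' @param path TSV with columns `protein`, `position`, `ann`, `pssm`, `svm`,
#'   `consensus` (per-site scores of the three prediction methods and their
#'   consensus).
#' @return The table as a data frame.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("protein", "position", "ann", "pssm", "svm", "consensus"),
                   "predictor table")
  df
}

#' Annotate candidate 14-3-3 binding sites
#'
#' Applies the confidence thresholds to predictor scores (a site passes only
#' when all four scores are strictly above their thresholds: consensus 0.9,
#' ANN 0.55, PSSM 0.80, SVM 0.25 by default) and extracts the 13-residue
#' sequence window around each site from the supplied sequences.
#'
#' @param predictions Data frame from [read_predictions()] (columns
#'   `protein`, `position`, `ann`, `pssm`, `svm`, `consensus`).
#' @param sequences Named character vector of protein sequences
#'   (see [read_fasta()]). Sites on proteins without a sequence are kept
#'   with an empty window and a warning.
#' @param thresholds Named list of strict lower bounds.
#' @return Data frame of class `predicted_sites`: `protein`, `position`,
#'   `center_residue`, `window`, the four scores, `passes`,
#'   `aurora_context`.
#' @export
import_predictions <- function(predictions, sequences,
                               thresholds = list(consensus = 0.9, ann = 0.55,
                                                 pssm = 0.80, svm = 0.25)) {
  .require_columns(predictions,
                   c("protein", "position", "ann", "pssm", "svm", "consensus"),
                   "predictor table")
  n <- nrow(predictions)
  window <- character(n)
  missing_seq <- !(predictions$protein %in% names(sequences))
  if (any(missing_seq))
    .warnf("no sequence for %d site(s) (e.g. '%s'); windows left empty",
           sum(missing_seq), predictions$protein[missing_seq][1])
  for (i in seq_len(n)) {
    if (missing_seq[i]) { window[i] <- ""; next }
    s <- sequences[[predictions$protein[i]]]
    if (predictions$position[i] > nchar(s) || predictions$position[i] < 1)
      .stopf("site position %d beyond sequence of protein '%s' (length %d)",
             predictions$position[i], predictions$protein[i], nchar(s))
    window[i] <- extract_window(s, predictions$position[i])
  }
  center <- ifelse(window == "", NA_character_, substring(window, 7, 7))
  passes <- predictions$consensus > thresholds$consensus &
    predictions$ann > thresholds$ann &
    predictions$pssm > thresholds$pssm &
    predictions$svm > thresholds$svm
  out <- data.frame(protein = predictions$protein,
                    position = as.integer(predictions$position),
                    center_residue = center, window = window,
                    score_ann = predictions$ann, score_pssm = predictions$pssm,
                    score_svm = predictions$svm,
                    score_consensus = predictions$consensus,
                    passes = passes, stringsAsFactors = FALSE)
  out$aurora_context <- vapply(out$window, annotate_aurora_context, logical(1))
  class(out) <- c("predicted_sites", "data.frame")
  out
}

#' Scan a sequence for mode-I-like 14-3-3 consensus candidates
#'
#' A deliberately simple pattern scanner used where no external predictor
#' output is available: it reports every serine/threonine with a basic
#' residue (R/K) at position -3 or -4 and a proline at +2, the canonical
#' mode-I arrangement. It is a documented stand-in, not a re-implementation
#' of the published ANN/PSSM/SVM predictor.
#'
#' @param sequence Uppercase amino-acid sequence.
#' @param basic_offsets Offsets at which an R/K is required (any one
#'   suffices).
#' @param proline_offset Offset at which a proline is required.
#' @return Integer vector of 1-based phospho-site positions.
#' @export
scan_consensus <- function(sequence, basic_offsets = c(-3L, -4L),
                           proline_offset = 2L) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad))
    .stopf("non-amino-acid character '%s' at position %d", chars[bad][1],
           which(bad)[1])
  n <- length(chars)
  hits <- integer(0)
  for (p in which(chars %in% c("S", "T"))) {
    up <- p + basic_offsets
    up <- up[up >= 1]
    pro <- p + proline_offset
    if (pro > n) next
    if (any(chars[up] %in% c("R", "K")) && chars[pro] == "P")
      hits <- c(hits, p)
  }
  hits
}

#' Sites found by the consensus scanner, in predicted-sites form
#'
#' Convenience wrapper running [scan_consensus()] over a sequence set and
#' returning the same table shape as [import_predictions()] (scores NA,
#' `passes = TRUE`).
#'
#' @param sequences Named character vector of sequences.
#' @param ... Passed to [scan_consensus()].
#' @return A `predicted_sites` data frame.
#' @export
scan_sites <- function(sequences, ...) {
  hits <- lapply(sequences, scan_consensus, ...)
  protein <- rep(names(hits), lengths(hits))
  position <- unlist(hits, use.names = FALSE)
  if (is.null(position)) position <- integer(0)
  window <- vapply(seq_along(position), function(i)
    extract_window(sequences[[protein[i]]], position[i]), character(1))
  out <- data.frame(protein = protein, position = position,
                    center_residue = substring(window, 7, 7), window = window,
                    score_ann = NA_real_, score_pssm = NA_real_,
                    score_svm = NA_real_, score_consensus = NA_real_,
                    passes = TRUE, stringsAsFactors = FALSE)
  out$aurora_context <- vapply(out$window, annotate_aurora_context, logical(1))
  class(out) <- c("predicted_sites", "data.frame")
  out
}

#' Does a site window carry an Aurora-kinase consensus at -2?
#'
#' TRUE when the residue at window position -2 is S or T and the residue two
#' positions upstream of that (window -4) is R or K — the R/KxS/T
#' arrangement by which Aurora B phosphorylates the serine two residues
#' N-terminal to the 14-3-3 binding phospho-site. Padded positions yield
#' FALSE.
#'
#' @param window 13-character window string from [extract_window()].
#' @return Logical scalar.
#' @export
annotate_aurora_context <- function(window) {
  if (is.na(window) || nchar(window) != 13) return(FALSE)
  minus2 <- substring(window, 5, 5)
  minus4 <- substring(window, 3, 3)
  minus2 %in% c("S", "T") && minus4 %in% c("R", "K")
}

#' Two-sided exact binomial test of an up/down split against 50:50
#'
#' @param n_up,n_down Non-negative counts.
#' @return List: `n_up`, `n_down`, `prop_up`, `p_value`.
#' @export
direction_binom_test <- function(n_up, n_down) {
  n <- n_up + n_down
  p <- if (n == 0) NA_real_ else binom.test(n_up, n, 0.5)$p.value
  list(n_up = n_up, n_down = n_down,
       prop_up = if (n == 0) NA_real_ else n_up / n, p_value = p)
}

#' Directional enrichment of motif-bearing proteins
#'
#' Splits all quantified proteins by whether they carry at least one passing
#' predicted 14-3-3 site and, within each partition, tests the split of
#' proteins that increased (log2 ratio > 0) versus decreased (< 0)
#' microtubule binding against the 50:50 expected under no 14-3-3
#' regulation, with a two-sided exact binomial test. The direction uses the
#' sign of the log ratio over all quantified proteins, not the volcano
#' classes.
#'
#' @param fit A `cosed_diff` object, or a data frame with columns `gene` and
#'   `log_ratio`.
#' @param sites A `predicted_sites` data frame; `protein` must match the
#'   fit's gene keys.
#' @return List of class `cosed_enrichment` with the 2x2 counts
#'   (`n_with_up`, `n_with_down`, `n_without_up`, `n_without_down`) and the
#'   two binomial p-values (`p_with`, `p_without`).
#' @export
directional_enrichment <- function(fit, sites) {
  tab <- if (inherits(fit, "cosed_diff")) fit$table else fit
  tab <- tab[!is.na(tab$log_ratio), ]
  if ("p_value" %in% names(tab)) tab <- tab[!is.na(tab$p_value), ]
  zero <- tab$log_ratio == 0
  if (any(zero)) {
    .warnf("dropping %d gene(s) with log ratio exactly 0", sum(zero))
    tab <- tab[!zero, ]
  }
  with_sites <- unique(sites$protein[sites$passes])
  has <- tab$gene %in% with_sites
  up <- tab$log_ratio > 0
  res_with <- direction_binom_test(sum(has & up), sum(has & !up))
  res_without <- direction_binom_test(sum(!has & up), sum(!has & !up))
  structure(list(n_with_up = res_with$n_up, n_with_down = res_with$n_down,
                 n_without_up = res_without$n_up,
                 n_without_down = res_without$n_down,
                 p_with = res_with$p_value, p_without = res_without$p_value),
            class = "cosed_enrichment")
}

#' @export
print.cosed_enrichment <- function(x, ...) {
  f <- function(u, d, p, lab) {
    n <- u + d
    cat(sprintf("  %-13s %4d up (%2.0f%%) / %4d down (%2.0f%%)  binomial p = %s\n",
                lab, u, if (n) 100 * u / n else NA, d,
                if (n) 100 * d / n else NA,
                if (is.na(p)) "NA" else format(p, digits = 3)))
  }
  cat("Directional enrichment vs 50:50\n")
  f(x$n_with_up, x$n_with_down, x$p_with, "with sites:")
  f(x$n_without_up, x$n_without_down, x$p_without, "without sites:")
  invisible(x)
}

#' Bin genes by fold change
#'
#' Ranks genes by log2 ratio, descending (ties broken by gene name so the
#' assignment is deterministic), and splits them into `n_bins` contiguous
#' groups of near-equal size; when the count does not divide evenly the
#' remainder goes to the top bins, so bin sizes differ by at most one.
#'
#' @param fit A `cosed_diff` object or a data frame with `gene` and
#'   `log_ratio` (genes with undefined ratios are dropped).
#' @param n_bins Number of bins (default 5, i.e. quintiles).
#' @return Named integer vector: bin index (1 = largest increase) per gene.
#' @export
bin_by_fold_change <- function(fit, n_bins = 5) {
  tab <- if (inherits(fit, "cosed_diff")) fit$table else fit
  tab <- tab[!is.na(tab$log_ratio), ]
  n <- nrow(tab)
  if (n < n_bins) .stopf("fewer genes (%d) than bins (%d)", n, n_bins)
  ord <- order(-tab$log_ratio, tab$gene)
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  setNames(rep(seq_len(n_bins), sizes), tab$gene[ord])
}

#' Collapse quintile bins to top / mid / bottom groups
#'
#' With the default 5 bins: bin 1 is the top 20% (increase under
#' inhibition), bins 2-4 the middle 60%, bin 5 the bottom 20%.
#'
#' @param bins Output of [bin_by_fold_change()] with 5 bins.
#' @return Named character vector: `"top20"`, `"mid60"` or `"bottom20"` per
#'   gene.
#' @export
bin_groups <- function(bins) {
  if (max(bins) != 5) .stopf("top/mid/bottom grouping expects 5 bins, got %d", max(bins))
  setNames(c("top20", "mid60", "mid60", "mid60", "bottom20")[bins], names(bins))
}

#' Positional residue composition around predicted sites
#'
#' Counts each of the 20 amino acids at each window position (-6..+6) over
#' all passing sites, optionally split by a gene grouping. Padded overhang
#' positions are excluded, so per-position totals can be smaller than the
#' number of sites.
#'
#' @param sites A `predicted_sites` data frame (only rows with
#'   `passes = TRUE` and a non-empty window are counted; every passing site
#'   contributes one window).
#' @param groups Optional named character vector mapping gene/protein to a
#'   group label (e.g. from [bin_groups()]); sites on unmapped proteins are
#'   ignored.
#' @return If `groups` is NULL, one `composition_counts` object: a list
#'   with `counts` (20 x 13 matrix, rows residues, columns positions
#'   `-6`..`+6`) and `n_sites`. Otherwise a named list of such objects, one
#'   per group (empty groups yield zero counts with a warning).
#' @export
positional_composition <- function(sites, groups = NULL) {
  use <- sites$passes & !is.na(sites$window) & sites$window != ""
  sites <- sites[use, , drop = FALSE]
  count_one <- function(windows) {
    m <- matrix(0L, length(AA_ALPHABET), 2 * WINDOW_HALF + 1,
                dimnames = list(AA_ALPHABET, as.character(-WINDOW_HALF:WINDOW_HALF)))
    for (w in windows) {
      chars <- strsplit(w, "")[[1]]
      for (j in seq_along(chars)) {
        if (chars[j] %in% AA_ALPHABET) m[chars[j], j] <- m[chars[j], j] + 1L
      }
    }
    structure(list(counts = m, n_sites = length(windows)),
              class = "composition_counts")
  }
  if (is.null(groups)) return(count_one(sites$window))
  out <- lapply(split(sites$window, factor(groups[sites$protein],
                                           levels = unique(groups))),
                count_one)
  empty <- names(out)[vapply(out, function(x) x$n_sites == 0, logical(1))]
  if (length(empty))
    .warnf("group(s) with zero sites: %s", paste(empty, collapse = ", "))
  out
}

#' @export
print.composition_counts <- function(x, ...) {
  cat(sprintf("Positional composition over %d site window(s)\n", x$n_sites))
  print(x$counts)
  invisible(x)
}

#' Per-cell significance of compositional differences
#'
#' For every (position, residue) cell, compares the residue's frequency at
#' that position between two composition groups with a two-sided Fisher
#' exact test on the 2x2 table (residue vs any other residue, group vs
#' group). Positions with a zero denominator in either group are skipped.
#' No multiple-testing correction is applied by default (the raw p
#' threshold is part of the procedure); `correct = "BH"` adds adjusted
#' values.
#'
#' @param top,rest `composition_counts` objects (e.g. the top-20% group and
#'   everything else).
#' @param alpha Significance threshold for the flag (default 0.01).
#' @param correct `"none"` (default) or `"BH"`.
#' @return Data frame: `position` (-6..+6), `residue`, counts and
#'   denominators in both groups, `p_value` (plus `q_value` with BH),
#'   `direction` (`"over"` when the residue is more frequent in `top`),
#'   `flag` (p < alpha).
#' @export
composition_significance <- function(top, rest, alpha = 0.01,
                                     correct = c("none", "BH")) {
  correct <- match.arg(correct)
  stopifnot(inherits(top, "composition_counts"),
            inherits(rest, "composition_counts"))
  if (top$n_sites == 0 || rest$n_sites == 0)
    .stopf("both composition groups must contain at least one site")
  pos_lab <- colnames(top$counts)
  denom_top <- colSums(top$counts)
  denom_rest <- colSums(rest$counts)
  rows <- list()
  for (j in seq_along(pos_lab)) {
    if (denom_top[j] == 0 || denom_rest[j] == 0) next
    for (aa in AA_ALPHABET) {
      a <- top$counts[aa, j]; b <- denom_top[j] - a
      cc <- rest$counts[aa, j]; d <- denom_rest[j] - cc
      p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        position = as.integer(pos_lab[j]), residue = aa,
        count_top = a, denom_top = unname(denom_top[j]),
        count_rest = cc, denom_rest = unname(denom_rest[j]),
        p_value = p,
        direction = if (a / denom_top[j] > cc / denom_rest[j]) "over"
                    else if (a / denom_top[j] < cc / denom_rest[j]) "under"
                    else "equal",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (correct == "BH") out$q_value <- p.adjust(out$p_value, "BH")
  out$flag <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Write / read a position-count matrix
#'
#' Writes the residue-by-position counts in a TRANSFAC-like layout: one row
#' per position (labelled -6..+6), one column per residue, preceded by the
#' number of sites in a comment header. Reading a written file reproduces
#' the counts.
#'
#' @param counts A `composition_counts` object.
#' @param path Output (input) path.
#' @return `export_count_matrix`: the path, invisibly;
#'   `read_count_matrix`: a `composition_counts` object.
#' @export
export_count_matrix <- function(counts, path) {
  stopifnot(inherits(counts, "composition_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_sites=%d", counts$n_sites), con)
  df <- data.frame(PO = colnames(counts$counts), t(counts$counts),
                   check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname export_count_matrix
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- readLines(path, n = 1)
  n_sites <- as.integer(sub("^# n_sites=", "", header))
  df <- read.delim(path, skip = 1, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, AA_ALPHABET, drop = FALSE]))
  colnames(m) <- as.character(df$PO)
  storage.mode(m) <- "integer"
  structure(list(counts = m, n_sites = n_sites), class = "composition_counts")
}
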