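# The core estimator: per-gene paired (or unpaired) t-tests on log2
# intensity ratios between inhibitor-treated and control microtubule
# fractions, with the field's conventions for zeros ("not detected"),
# minimum replicate support and volcano classification.

#' Collapse protein-group records to one record per gene
#'
#' Applies the standard pre-test reduction: records supported by a single
#' peptide are removed first (one peptide cannot confidently identify an
#' accession), then, where several accessions map to the same gene (isoform
#' or transcript duplicates), only the highest-scored record is kept. The
#' result is independent of input order: ties on score are broken by lead
#' accession.
#'
#' @param records Data frame of protein-group records
#'   (see [read_protein_groups()]).
#' @param min_peptides Minimum peptide count; records strictly below it are
#'   dropped. Records with an unknown peptide count (supplementary dialect)
#'   are kept.
#' @return The collapsed records, one row per gene, sorted by gene key.
#' @export
collapse_accessions <- function(records, min_peptides = 2) {
  keep <- is.na(records$peptides_total) | records$peptides_total >= min_peptides
  rec <- records[keep, , drop = FALSE]
  gene <- gene_key(rec)
  score <- ifelse(is.na(rec$score), -Inf, rec$score)
  lead <- vapply(strsplit(rec$protein_ids, ";", fixed = TRUE),
                 function(p) p[[1]], character(1))
  ord <- order(gene, -score, lead)
  rec <- rec[ord, , drop = FALSE]
  gene <- gene[ord]
  rec <- rec[!duplicated(gene), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "replicates") <- attr(records, "replicates")
  rec
}

#' Partition genes into testable and zero-set
#'
#' A replicate pair contributes to a gene's test only when both arms were
#' detected (intensity > 0). A gene whose every detected pair has exactly
#' one zero arm cannot be given a ratio at all; such genes are removed from
#' the statistical analysis and listed separately (the "zero set").
#'
#' @param pm A [pair_matrix()].
#' @return A list: `testable` (`pair_matrix` of genes with >= 1
#'   doubly-detected pair), `zero_set` (gene names detected only with
#'   one-arm zeros), `undetected` (gene names with no detection at all).
#' @export
partition_zero_set <- function(pm) {
  stopifnot(inherits(pm, "pair_matrix"))
  detected <- rowSums(pm$con > 0 | pm$sam > 0) > 0
  n_both <- rowSums(pm$con > 0 & pm$sam > 0)
  genes <- rownames(pm$con)
  testable <- genes[detected & n_both > 0]
  list(
    testable = if (length(testable)) subset_genes(pm, testable) else NULL,
    zero_set = genes[detected & n_both == 0],
    undetected = genes[!detected]
  )
}

#' Replicate-pair quality control
#'
#' Summarises each replicate pair's log2 intensity distributions (median and
#' IQR of both arms over doubly-detected genes) and the least-squares line
#' of best fit of log2(sample) against log2(control). A pair is flagged when
#' its combined-arm median deviates from the cross-pair median by more than
#' `median_threshold` log2 units, or its slope falls outside `slope_range`.
#' Pairs with fewer than `min_genes` doubly-detected genes are flagged
#' `"insufficient"`.
#'
#' @param pm A [pair_matrix()].
#' @param median_threshold Allowed deviation of a pair's median (log2 units).
#' @param slope_range Acceptable slope interval of sample-vs-control fit.
#' @param min_genes Minimum doubly-detected genes for a meaningful summary.
#' @return Data frame of class `cosed_qc`, one row per replicate pair:
#'   `pair`, `n_genes`, `median_con`, `median_sam`, `iqr_con`, `iqr_sam`,
#'   `median_both`, `slope`, `intercept`, `flag`
#'   (`"ok"`/`"flagged"`/`"insufficient"`).
#' @export
replicate_qc <- function(pm, median_threshold = 2, slope_range = c(0.5, 2),
                         min_genes = 10) {
  stopifnot(inherits(pm, "pair_matrix"))
  k <- length(pm$pairs)
  out <- data.frame(pair = pm$pairs, n_genes = integer(k),
                    median_con = NA_real_, median_sam = NA_real_,
                    iqr_con = NA_real_, iqr_sam = NA_real_,
                    median_both = NA_real_, slope = NA_real_,
                    intercept = NA_real_, flag = "insufficient",
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    both <- pm$con[, j] > 0 & pm$sam[, j] > 0
    out$n_genes[j] <- sum(both)
    if (sum(both) < min_genes) next
    lc <- log2(pm$con[both, j]); ls <- log2(pm$sam[both, j])
    out$median_con[j] <- median(lc); out$median_sam[j] <- median(ls)
    out$iqr_con[j] <- IQR(lc); out$iqr_sam[j] <- IQR(ls)
    out$median_both[j] <- median(c(lc, ls))
    fit <- stats::lsfit(lc, ls)
    out$intercept[j] <- fit$coefficients[[1]]
    out$slope[j] <- fit$coefficients[[2]]
    out$flag[j] <- "ok"
  }
  usable <- out$flag == "ok"
  if (any(usable)) {
    center <- median(out$median_both[usable])
    dev <- abs(out$median_both - center) > median_threshold
    bad_slope <- out$slope < slope_range[1] | out$slope > slope_range[2]
    out$flag[usable & (dev | bad_slope)] <- "flagged"
  }
  class(out) <- c("cosed_qc", "data.frame")
  out
}

#' @export
print.cosed_qc <- function(x, ...) {
  cat("Replicate-pair QC\n")
  print.data.frame(cbind(x[c("pair", "n_genes")],
                         round(x[c("median_con", "median_sam", "slope")], 3),
                         flag = x$flag), row.names = FALSE)
  invisible(x)
}

#' Volcano classification of a tested gene
#'
#' Applies the strict fold-change and significance thresholds: `increased`
#' when the natural-scale fold change exceeds `fc_up` and p < `alpha`;
#' `decreased` when it is below `fc_down` and p < `alpha`; otherwise
#' `unchanged`. An undefined p-value always yields `unchanged`.
#'
#' @param log_ratio Numeric vector of log2 fold changes.
#' @param p_value Numeric vector of p-values (NA allowed).
#' @param fc_up,fc_down Natural-scale fold-change thresholds (default 1.5
#'   and 1/1.5, i.e. 0.6667).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector: `"increased"`, `"decreased"` or `"unchanged"`.
#' @export
classify_volcano <- function(log_ratio, p_value, fc_up = 1.5,
                             fc_down = 1 / 1.5, alpha = 0.05) {
  fc <- 2^log_ratio
  out <- rep("unchanged", length(log_ratio))
  sig <- !is.na(p_value) & p_value < alpha
  out[sig & fc > fc_up] <- "increased"
  out[sig & fc < fc_down] <- "decreased"
  out[is.na(log_ratio)] <- "unchanged"
  out
}

#' Fit the differential microtubule-binding model
#'
#' The central estimator of the package. For every gene with at least
#' `min_pairs` replicate pairs detected in both arms, computes the log2
#' ratio `mean(log2 sample) - mean(log2 control)` over the usable pairs and
#' a two-tailed t-test p-value: in `paired` mode a one-sample t on the
#' per-pair log2 differences, in `unpaired` mode a two-sample Student t on
#' the two arms. Pairs where exactly one arm is 0 are dropped from that
#' gene's test (never imputed); genes detected only in such pairs form the
#' zero set and are listed, not tested. No multiple-testing correction is
#' applied to the classification (the raw p threshold is part of the
#' procedure); Benjamini-Hochberg q-values are emitted as an extra column.
#'
#' @param pm A [pair_matrix()] (raw; the zero partition is applied
#'   internally).
#' @param min_pairs Minimum doubly-detected pairs for testing (default 2).
#' @param mode `"paired"` (default) or `"unpaired"`.
#' @param fc_up,fc_down,alpha Classification thresholds, see
#'   [classify_volcano()].
#' @return An object of class `cosed_diff`: a list with
#'   \describe{
#'     \item{table}{data frame, one row per testable gene: `gene`,
#'       `n_pairs`, `log_sam`, `log_con`, `log_ratio`, `p_value`, `q_value`,
#'       `class` (`increased`/`decreased`/`unchanged`/`insufficient`),
#'       `degenerate` (TRUE when all differences were identical, leaving p
#'       undefined).}
#'     \item{zero_set}{genes removed from testing because every detected
#'       pair had a zero arm.}
#'     \item{n_detected}{number of genes detected at all.}
#'     \item{mode, min_pairs, thresholds, call}{fit metadata.}
#'   }
#' @examples
#' sim <- simulate_experiment(experiment_config(n_proteins = 300, seed = 42))
#' fit <- cosed_diff(sim$matrix)
#' summary(fit)
#' @export
cosed_diff <- function(pm, min_pairs = 2, mode = c("paired", "unpaired"),
                       fc_up = 1.5, fc_down = 1 / 1.5, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "pair_matrix"))
  part <- partition_zero_set(pm)
  tm <- part$testable
  genes <- if (is.null(tm)) character(0) else rownames(tm$con)
  n <- length(genes)
  tab <- data.frame(gene = genes, n_pairs = integer(n), log_sam = NA_real_,
                    log_con = NA_real_, log_ratio = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    class = "insufficient", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    both <- tm$con[i, ] > 0 & tm$sam[i, ] > 0
    lc <- log2(tm$con[i, both]); ls <- log2(tm$sam[i, both])
    tab$n_pairs[i] <- sum(both)
    tab$log_sam[i] <- mean(ls)
    tab$log_con[i] <- mean(lc)
    tab$log_ratio[i] <- mean(ls) - mean(lc)
    if (sum(both) < min_pairs) next
    if (mode == "paired") {
      d <- ls - lc
      if (sd(d) == 0) { tab$degenerate[i] <- TRUE; tab$class[i] <- "unchanged"; next }
      tab$p_value[i] <- t.test(d)$p.value
    } else {
      if (sd(c(ls, lc)) == 0 || (sd(ls) == 0 && sd(lc) == 0)) {
        tab$degenerate[i] <- TRUE; tab$class[i] <- "unchanged"; next
      }
      tab$p_value[i] <- t.test(ls, lc, var.equal = TRUE)$p.value
    }
  }
  tested <- !is.na(tab$p_value)
  tab$q_value[tested] <- p.adjust(tab$p_value[tested], method = "BH")
  tab$class[tested] <- classify_volcano(tab$log_ratio[tested], tab$p_value[tested],
                                        fc_up = fc_up, fc_down = fc_down,
                                        alpha = alpha)
  structure(list(table = tab, zero_set = part$zero_set,
                 undetected = part$undetected,
                 n_detected = n + length(part$zero_set),
                 mode = mode, min_pairs = min_pairs,
                 thresholds = list(fc_up = fc_up, fc_down = fc_down, alpha = alpha),
                 call = match.call()),
            class = "cosed_diff")
}

#' @export
print.cosed_diff <- function(x, ...) {
  cl <- table(factor(x$table$class,
                     c("increased", "decreased", "unchanged", "insufficient")))
  cat(sprintf("Differential co-sedimentation fit (%s t-test)\n", x$mode))
  cat(sprintf("  detected: %d genes (%d zero-set, analysed separately)\n",
              x$n_detected, length(x$zero_set)))
  cat(sprintf("  quantifiable in >= %d pairs: %d\n",
              x$min_pairs, sum(x$table$class != "insufficient")))
  cat(sprintf("  increased: %d  decreased: %d  unchanged: %d (fc > %.4g / < %.4g, p < %g)\n",
              cl[["increased"]], cl[["decreased"]], cl[["unchanged"]],
              x$thresholds$fc_up, x$thresholds$fc_down, x$thresholds$alpha))
  invisible(x)
}

#' @method summary cosed_diff
#' @export
summary.cosed_diff <- function(object, n_top = 10, ...) {
  tab <- object$table
  cl <- table(factor(tab$class,
                     c("increased", "decreased", "unchanged", "insufficient")))
  out <- list(
    counts = c(detected = object$n_detected,
               quantifiable = sum(tab$class != "insufficient"),
               increased = unname(cl[["increased"]]),
               decreased = unname(cl[["decreased"]]),
               unchanged = unname(cl[["unchanged"]]),
               insufficient = unname(cl[["insufficient"]]),
               zero_set = length(object$zero_set),
               degenerate = sum(tab$degenerate)),
    top = head(tab[order(-tab$log_ratio), c("gene", "n_pairs", "log_ratio",
                                            "p_value", "q_value", "class")], n_top),
    mode = object$mode, thresholds = object$thresholds
  )
  class(out) <- "summary.cosed_diff"
  out
}

#' @export
print.summary.cosed_diff <- function(x, ...) {
  cat(sprintf("Differential co-sedimentation fit (%s t-test)\n", x$mode))
  print(x$counts)
  cat("Largest log2 ratios:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom stats coef
#' @method coef cosed_diff
#' @export
coef.cosed_diff <- function(object, ...) {
  setNames(object$table$log_ratio, object$table$gene)
}

#' @method as.data.frame cosed_diff
#' @export
as.data.frame.cosed_diff <- function(x, ...) x$table

#' Volcano plot of a differential fit
#'
#' Plots the log2 fold change against -log10 p for every tested gene,
#' colouring the `increased` (red) and `decreased` (blue) classes, with the
#' fold-change and significance thresholds drawn as dashed lines.
#'
#' @param x A `cosed_diff` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @method plot cosed_diff
#' @export
plot.cosed_diff <- function(x, ...) {
  tab <- x$table[!is.na(x$table$p_value), ]
  col <- ifelse(tab$class == "increased", "red3",
                ifelse(tab$class == "decreased", "blue3", "grey50"))
  plot(tab$log_ratio, -log10(tab$p_value), col = col, pch = 16, cex = 0.5,
       xlab = "log2 fold change (inhibitor / control)",
       ylab = "-log10 p-value", ...)
  abline(v = log2(c(x$thresholds$fc_up, x$thresholds$fc_down)), lty = 2)
  abline(h = -log10(x$thresholds$alpha), lty = 2)
  legend("topleft", c("increased", "decreased"), col = c("red3", "blue3"),
         pch = 16, bty = "n")
  invisible(tab)
}

#' Ordered volcano report table
#'
#' @param fit A `cosed_diff` object.
#' @param all Include `insufficient` genes (default FALSE: tested genes
#'   only).
#' @return Data frame sorted by `logratio` descending (ties broken by gene
#'   name) with columns `gene`, `n_pairs`, `logSAM`, `logCON`, `logratio`,
#'   `p`, `q`, `class`; per-class counts in `attr(, "class_counts")`.
#' @export
volcano_table <- function(fit, all = FALSE) {
  stopifnot(inherits(fit, "cosed_diff"))
  tab <- fit$table
  if (!all) tab <- tab[tab$class != "insufficient", , drop = FALSE]
  tab <- tab[order(-tab$log_ratio, tab$gene), , drop = FALSE]
  out <- data.frame(gene = tab$gene, n_pairs = tab$n_pairs,
                    logSAM = tab$log_sam, logCON = tab$log_con,
                    logratio = tab$log_ratio, p = tab$p_value,
                    q = tab$q_value, class = tab$class,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "class_counts") <- table(factor(out$class,
    c("increased", "decreased", "unchanged", "insufficient")))
  out
}
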