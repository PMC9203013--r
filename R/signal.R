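# Densitometry and phenotype statistics: the two-box background-subtraction
# formula used for blot bands and spindle fluorescence, pulldown
# normalisation, rank-sum comparison of intensity groups, and the Fisher
# test on centromere orientation counts.

#' Background-subtracted total signal of a boxed measurement
#'
#' Two boxes are drawn around a band or structure: an inner box S containing
#' mainly the signal, and a larger box L containing the signal plus the
#' surrounding background. With I the total pixel intensity and N the pixel
#' count of each box, the signal over background is
#' \deqn{I_S - N_S (I_L - I_S) / (N_L - N_S)}
#' i.e. the inner total minus the inner area times the mean per-pixel
#' intensity of the surrounding ring. When the background is uniform this
#' removes it exactly. The result may be negative (background brighter than
#' the box); it is returned as-is with a warning.
#'
#' @param i_s,n_s,i_l,n_l Total intensity and pixel count of the inner (S)
#'   and larger (L) boxes; vectorised. Requires `n_l > n_s > 0`,
#'   `i_l >= i_s >= 0`.
#' @return Numeric vector of background-subtracted signals.
#' @export
background_subtract <- function(i_s, n_s, i_l, n_l) {
  if (any(n_s <= 0)) .stopf("inner box must contain pixels (N_S > 0)")
  if (any(n_l <= n_s)) .stopf("larger box must be larger than inner box (N_L > N_S)")
  if (any(i_s < 0) || any(i_l < 0)) .stopf("intensities must be >= 0")
  if (any(i_l < i_s)) .stopf("larger-box intensity must be >= inner-box intensity")
  out <- i_s - n_s * (i_l - i_s) / (n_l - n_s)
  if (any(out < 0))
    .warnf("%d negative background-subtracted signal(s) (reported as-is)",
           sum(out < 0))
  out
}

#' Normalise pulldown band signals to a reference band
#'
#' Divides each band's background-subtracted signal by the reference band's
#' signal, separately within each experiment, so that amounts are
#' comparable across blots.
#'
#' @param data Data frame with columns `label`, `signal` and optionally
#'   `experiment` (a single experiment is assumed when absent).
#' @param reference_label The label of the reference band; it must be
#'   present in every experiment with a signal > 0.
#' @return The input with an added `normalised` column.
#' @export
normalize_pulldown <- function(data, reference_label) {
  .require_columns(data, c("label", "signal"), "pulldown table")
  if (!"experiment" %in% names(data)) data$experiment <- 1L
  data$normalised <- NA_real_
  for (ex in unique(data$experiment)) {
    rows <- data$experiment == ex
    ref <- data$signal[rows & data$label == reference_label]
    if (length(ref) == 0)
      .stopf("reference '%s' missing in experiment '%s'", reference_label, ex)
    if (length(ref) > 1)
      .stopf("reference '%s' appears %d times in experiment '%s'",
             reference_label, length(ref), ex)
    if (ref <= 0)
      .stopf("reference '%s' has non-positive signal in experiment '%s'",
             reference_label, ex)
    data$normalised[rows] <- data$signal[rows] / ref
  }
  data
}

#' Compare two intensity groups by medians and a rank-sum test
#'
#' Reports the group medians, the percent change of group B relative to
#' group A, `100 * (median_a - median_b) / median_a` (positive = reduction
#' in B), and a two-sided Wilcoxon rank-sum p-value. The exact distribution
#' is used for small samples without ties; with ties, mid-ranks and the
#' normal approximation with tie correction are used.
#'
#' @param group_a,group_b Non-empty numeric vectors (e.g. per-oocyte
#'   fluorescence of a wild-type and a mutant).
#' @return List: `median_a`, `median_b`, `percent_change`, `p_value`.
#' @export
compare_intensities <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    .stopf("both groups must be non-empty")
  ma <- median(group_a); mb <- median(group_b)
  p <- suppressWarnings(wilcox.test(group_a, group_b)$p.value)
  list(median_a = ma, median_b = mb,
       percent_change = 100 * (ma - mb) / ma, p_value = p)
}

#' Fisher test on bi- vs mono-orientation counts
#'
#' Compares the frequency of mono-oriented homologous centromeres between
#' two genotypes with a two-sided Fisher exact test on the 2x2 count table.
#'
#' @param counts 2x2 matrix: rows = genotypes, columns =
#'   `c(bioriented, monooriented)` counts of scored oocytes. Each genotype
#'   must have at least one oocyte.
#' @return List: `mono_freq` (per-genotype mono-orientation frequency),
#'   `p_value`.
#' @export
biorientation_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) .stopf("counts must be a 2x2 matrix")
  if (any(counts < 0)) .stopf("counts must be >= 0")
  n <- rowSums(counts)
  if (any(n == 0)) .stopf("each genotype needs at least one scored oocyte")
  list(mono_freq = counts[, 2] / n,
       p_value = fisher.test(counts)$p.value)
}
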