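# Physical-interaction edge counting within a candidate protein set and a
# permutation null over a background proteome, standing in for an external
# database's analytic expected-edge model.

#' Count interaction edges within a protein set
#'
#' @param protein_set Character vector of protein identifiers.
#' @param edges Edge data frame from [read_edge_table()] (columns `from`,
#'   `to`; assumed deduplicated and undirected).
#' @return Number of edges with both endpoints in the set.
#' @export
count_edges <- function(protein_set, edges) {
  sum(edges$from %in% protein_set & edges$to %in% protein_set)
}

#' Edge enrichment of a protein set against a permutation null
#'
#' Counts the physical-interaction edges observed within `protein_set` and
#' compares the count with a null distribution obtained by drawing
#' `n_permutations` uniform subsets of the same size from the background
#' proteome. The empirical p-value uses the add-one convention
#' `(1 + #{null >= observed}) / (n_permutations + 1)`, so it can never be
#' exactly zero.
#'
#' @param protein_set Candidate proteins (must all be in `background`).
#' @param background Character vector of proteins the set was drawn from
#'   (typically all quantifiable proteins, not the whole proteome).
#' @param edges Edge data frame (`from`, `to`).
#' @param n_permutations Number of null draws (>= 100).
#' @param seed Integer seed.
#' @return Object of class `network_enrichment`: `observed_edges`,
#'   `expected_edges` (null mean), `empirical_p`, `n_permutations`, `seed`,
#'   and the full `null_counts` vector.
#' @export
edge_enrichment <- function(protein_set, background, edges,
                            n_permutations = 1000, seed = 1) {
  protein_set <- unique(protein_set)
  background <- unique(background)
  if (n_permutations < 100) .stopf("n_permutations must be >= 100")
  if (length(protein_set) > length(background))
    .stopf("set size (%d) exceeds background size (%d)",
           length(protein_set), length(background))
  outside <- setdiff(protein_set, background)
  if (length(outside))
    .stopf("protein(s) not in background: %s", paste(head(outside, 3), collapse = ", "))
  observed <- count_edges(protein_set, edges)
  k <- length(protein_set)
  # restrict to edges inside the background once; indices beat string
  # matching in the permutation loop
  ei <- match(edges$from, background)
  ej <- match(edges$to, background)
  ok <- !is.na(ei) & !is.na(ej)
  ei <- ei[ok]; ej <- ej[ok]
  set.seed(seed)
  null_counts <- integer(n_permutations)
  nb <- length(background)
  for (b in seq_len(n_permutations)) {
    inset <- logical(nb)
    inset[sample.int(nb, k)] <- TRUE
    null_counts[b] <- sum(inset[ei] & inset[ej])
  }
  structure(list(observed_edges = observed,
                 expected_edges = mean(null_counts),
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (n_permutations + 1),
                 n_permutations = n_permutations, seed = seed,
                 null_counts = null_counts),
            class = "network_enrichment")
}

#' @export
print.network_enrichment <- function(x, ...) {
  cat("Interaction-edge enrichment (permutation null)\n")
  cat(sprintf("  observed: %d edges; expected under null: %.2f\n",
              x$observed_edges, x$expected_edges))
  cat(sprintf("  empirical p = %.4g (%d permutations, seed %d)\n",
              x$empirical_p, x$n_permutations, x$seed))
  invisible(x)
}
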