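#' Paired intensity matrix (control vs sample arms)
#'
#' Container for per-gene intensities across replicate pairs. Each gene has
#' one control and one sample (inhibitor-treated) intensity per pair; an
#' intensity of 0 means "not detected" and is never imputed.
#'
#' @param con,sam Numeric matrices, genes x replicate pairs, with identical
#'   dimensions and row names (gene symbols). All values must be >= 0.
#' @return An object of class `pair_matrix`.
#' @export
pair_matrix <- function(con, sam) {
  con <- as.matrix(con); sam <- as.matrix(sam)
  if (!identical(dim(con), dim(sam)))
    .stopf("'con' and 'sam' must have identical dimensions")
  if (is.null(rownames(con))) .stopf("'con' must have gene row names")
  if (!identical(rownames(con), rownames(sam)))
    .stopf("'con' and 'sam' must have identical gene row names")
  if (anyDuplicated(rownames(con)))
    .stopf("duplicate gene '%s': pair matrices are one row per gene",
           rownames(con)[duplicated(rownames(con))][1])
  if (any(con < 0) || any(sam < 0)) .stopf("intensities must be >= 0")
  if (is.null(colnames(con))) colnames(con) <- as.character(seq_len(ncol(con)))
  colnames(sam) <- colnames(con)
  structure(list(con = con, sam = sam, pairs = colnames(con)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d genes x %d replicate pairs (%s)\n",
              nrow(x$con), length(x$pairs), paste(x$pairs, collapse = ", ")))
  both <- x$con > 0 & x$sam > 0
  cat(sprintf("  detected genes: %d; doubly-detected cells: %d/%d\n",
              sum(rowSums(x$con > 0 | x$sam > 0) > 0), sum(both), length(both)))
  invisible(x)
}

#' @export
dim.pair_matrix <- function(x) dim(x$con)

#' @rdname pair_matrix
#' @param x A `pair_matrix`.
#' @param genes Character vector of gene names to keep.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "pair_matrix"))
  missing <- setdiff(genes, rownames(x$con))
  if (length(missing))
    .stopf("gene(s) not in matrix: %s", paste(head(missing, 3), collapse = ", "))
  pair_matrix(x$con[genes, , drop = FALSE], x$sam[genes, , drop = FALSE])
}

#' Write / read the canonical tidy TSV of a pair matrix
#'
#' One row per gene with columns `gene`, then `con_<pair>` and `sam_<pair>`
#' for every replicate pair. Reading a written file reproduces the matrix
#' exactly.
#'
#' @param x A `pair_matrix`.
#' @param path Output (or input) TSV path.
#' @return `write_pair_matrix`: the path, invisibly. `read_pair_matrix`: a
#'   `pair_matrix`.
#' @export
write_pair_matrix <- function(x, path) {
  stopifnot(inherits(x, "pair_matrix"))
  df <- data.frame(gene = rownames(x$con), stringsAsFactors = FALSE)
  for (j in seq_along(x$pairs)) {
    df[[paste0("con_", x$pairs[j])]] <- x$con[, j]
    df[[paste0("sam_", x$pairs[j])]] <- x$sam[, j]
  }
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) .stopf("missing mandatory column 'gene'")
  con_cols <- grep("^con_", names(df), value = TRUE)
  sam_cols <- grep("^sam_", names(df), value = TRUE)
  if (!length(con_cols) || !identical(sub("^con_", "", con_cols),
                                      sub("^sam_", "", sam_cols)))
    .stopf("con_/sam_ columns must come in matched pairs")
  con <- as.matrix(df[con_cols]); sam <- as.matrix(df[sam_cols])
  rownames(con) <- rownames(sam) <- df$gene
  colnames(con) <- sub("^con_", "", con_cols)
  pair_matrix(con, sam)
}
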