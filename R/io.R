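# Readers for protein-groups tables (two explicit dialects), FASTA,
# 14-3-3 site predictor output, and interaction edge tables. Dialects are
# selected by flag, never sniffed: silently mis-parsing intensity columns is
# the dominant failure mode for this kind of table.

.flag_to_logical <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & trimws(as.character(x)) == "+"
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stopf("%s: missing mandatory column '%s'", what, missing[1])
}

.numeric_or_zero <- function(x, column) {
  x <- as.character(x)
  x[is.na(x) | trimws(x) == "" | x == "NA" | x == "NaN"] <- "0"
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    .stopf("unparseable numeric cell in column '%s' at row %d",
           column, which(is.na(v))[1])
  v
}

#' Read a protein-groups quantification table
#'
#' Two dialects are supported and must be named explicitly:
#' \describe{
#'   \item{`"maxquant"`}{a MaxQuant-style `proteinGroups` TSV with columns
#'     `Protein IDs`, `Gene names`, `Peptides`, `Score`, the `+` flag columns
#'     `Reverse` / `Potential contaminant` / `Only identified by site`, and
#'     paired intensity columns `LFQ intensity CON<r>` / `LFQ intensity
#'     SAM<r>`.}
#'   \item{`"supplementary"`}{a result-table sheet (XLSX or TSV) keyed by
#'     `geneName` and `Accession.No`, carrying per-replicate log2 intensity
#'     columns `logCON<r>` / `logSAM<r>` (converted back to the natural scale
#'     on read; blank cells become 0 = not detected). Replicate labels are
#'     exposed verbatim, without renumbering.}
#' }
#'
#' @param path File path. `.xlsx` files are read with \pkg{readxl}
#'   (supplementary dialect only); anything else is read as TSV.
#' @param dialect `"maxquant"` or `"supplementary"`.
#' @param sheet Sheet index or name for XLSX input.
#' @return A data frame of protein-group records: `protein_ids`,
#'   `majority_ids`, `gene_name`, `peptides_total`, `razor_unique_peptides`,
#'   `unique_peptides`, `score`, logical flags `flag_reverse`,
#'   `flag_contaminant`, `flag_only_by_site`, and numeric intensity columns
#'   `con_<r>` / `sam_<r>` (0 = not detected). The replicate labels are kept
#'   in `attr(, "replicates")`.
#' @export
read_protein_groups <- function(path, dialect = c("maxquant", "supplementary"),
                                sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  is_xlsx <- grepl("\\.xlsx?$", path, ignore.case = TRUE)
  df <- if (is_xlsx) {
    as.data.frame(readxl::read_excel(path, sheet = sheet, .name_repair = "minimal"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
               colClasses = "character")
  }
  if (dialect == "maxquant") .parse_maxquant(df) else .parse_supplementary(df)
}

.parse_maxquant <- function(df) {
  .require_columns(df, c("Protein IDs", "Score"), "proteinGroups")
  con_cols <- grep("^LFQ intensity CON", names(df), value = TRUE)
  sam_cols <- grep("^LFQ intensity SAM", names(df), value = TRUE)
  if (!length(con_cols) || !length(sam_cols))
    .stopf("proteinGroups: missing mandatory column 'LFQ intensity CON*/SAM*'")
  con_lab <- sub("^LFQ intensity CON", "", con_cols)
  sam_lab <- sub("^LFQ intensity SAM", "", sam_cols)
  labels <- intersect(con_lab, sam_lab)
  if (!length(labels))
    .stopf("proteinGroups: CON and SAM intensity columns do not share replicate labels")

  first_or_na <- function(x) {
    if (is.null(x)) return(rep(NA_character_, nrow(df)))
    vapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  }
  num_or_na <- function(col) {
    if (is.null(df[[col]])) rep(NA_real_, nrow(df))
    else suppressWarnings(as.numeric(df[[col]]))
  }
  out <- data.frame(
    protein_ids = as.character(df[["Protein IDs"]]),
    majority_ids = as.character(df[["Majority protein IDs"]] %||% df[["Protein IDs"]]),
    gene_name = first_or_na(df[["Gene names"]]),
    peptides_total = num_or_na("Peptides"),
    razor_unique_peptides = num_or_na("Razor + unique peptides"),
    unique_peptides = num_or_na("Unique peptides"),
    score = num_or_na("Score"),
    flag_reverse = .flag_to_logical(df[["Reverse"]]),
    flag_contaminant = .flag_to_logical(df[["Potential contaminant"]]),
    flag_only_by_site = .flag_to_logical(df[["Only identified by site"]]),
    stringsAsFactors = FALSE
  )
  if (nrow(out) && !all(out$protein_ids != ""))
    .stopf("proteinGroups: empty 'Protein IDs' at row %d", which(out$protein_ids == "")[1])
  for (lab in labels) {
    out[[paste0("con_", lab)]] <- .numeric_or_zero(df[[paste0("LFQ intensity CON", lab)]],
                                                   paste0("LFQ intensity CON", lab))
    out[[paste0("sam_", lab)]] <- .numeric_or_zero(df[[paste0("LFQ intensity SAM", lab)]],
                                                   paste0("LFQ intensity SAM", lab))
  }
  attr(out, "replicates") <- labels
  out
}

.parse_supplementary <- function(df) {
  .require_columns(df, c("geneName", "Accession.No"), "supplementary table")
  con_cols <- grep("^logCON[0-9]+$", names(df), value = TRUE)
  sam_cols <- grep("^logSAM[0-9]+$", names(df), value = TRUE)
  labels <- intersect(sub("^logCON", "", con_cols), sub("^logSAM", "", sam_cols))
  if (!length(labels))
    .stopf("supplementary table: missing mandatory column 'logCON*/logSAM*'")
  out <- data.frame(
    protein_ids = as.character(df[["Accession.No"]]),
    majority_ids = as.character(df[["Accession.No"]]),
    gene_name = as.character(df[["geneName"]]),
    peptides_total = NA_real_,
    razor_unique_peptides = NA_real_,
    unique_peptides = NA_real_,
    score = NA_real_,
    flag_reverse = FALSE,
    flag_contaminant = FALSE,
    flag_only_by_site = FALSE,
    stringsAsFactors = FALSE
  )
  delog <- function(col) {
    x <- as.character(df[[col]])
    blank <- is.na(x) | trimws(x) == "" | x == "NA"
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v) & !blank))
      .stopf("unparseable numeric cell in column '%s' at row %d",
             col, which(is.na(v) & !blank)[1])
    out <- 2^v
    out[blank] <- 0
    out
  }
  for (lab in labels) {
    out[[paste0("con_", lab)]] <- delog(paste0("logCON", lab))
    out[[paste0("sam_", lab)]] <- delog(paste0("logSAM", lab))
  }
  attr(out, "replicates") <- labels
  out
}

#' Remove decoy, contaminant and site-only protein groups
#'
#' Drops records flagged as reverse-database hits (likely false
#' discoveries), likely contaminants, or groups identified only by a
#' modification site. Idempotent.
#'
#' @param records Data frame from [read_protein_groups()].
#' @param quiet Suppress the removal-count message.
#' @return The filtered records; removal counts in `attr(, "removed")`.
#' @export
filter_standard_flags <- function(records, quiet = FALSE) {
  drop <- records$flag_reverse | records$flag_contaminant | records$flag_only_by_site
  removed <- c(reverse = sum(records$flag_reverse),
               contaminant = sum(records$flag_contaminant & !records$flag_reverse),
               only_by_site = sum(records$flag_only_by_site &
                                    !records$flag_reverse & !records$flag_contaminant))
  if (!quiet && any(drop))
    message(sprintf("filter_standard_flags: removed %d of %d records (%s)",
                    sum(drop), nrow(records),
                    paste(names(removed), removed, sep = "=", collapse = ", ")))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicates") <- attr(records, "replicates")
  attr(out, "removed") <- removed
  out
}

#' Read a FASTA file of protein sequences
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase amino-acid sequences.
#'   Duplicate identifiers and empty sequences are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    .stopf("duplicate FASTA identifier: %s", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0))
    .stopf("empty sequence for FASTA identifier: %s", ids[nchar(seqs) == 0][1])
  setNames(seqs, ids)
}

#' Read a protein-interaction edge table
#'
#' Reads a STRING-style export with two endpoint columns and a combined
#' score, keeps edges at or above the confidence cutoff, deduplicates
#' reversed pairs and drops self-loops. When `physical_only = TRUE` and a
#' `network_type` column is present, only rows labelled `physical` are kept
#' (STRING's physical-subnetwork exports usually encode this in the file
#' itself, in which case the column is absent and the flag is a no-op).
#'
#' @param path TSV path with columns `protein1`, `protein2`,
#'   `combined_score` (synonyms `node1`/`node2`/`score` accepted).
#' @param min_score Minimum combined score; edges strictly below it are
#'   dropped. STRING scores in 0-999 are accepted and rescaled to 0-1.
#' @param physical_only See above.
#' @return Data frame with columns `from`, `to`, `score`; one row per
#'   undirected edge, `from < to` lexicographically.
#' @export
read_edge_table <- function(path, min_score = 0.400, physical_only = TRUE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (!length(hit)) .stopf("edge table: missing mandatory column '%s'", cands[1])
    df[[hit[1]]]
  }
  from <- as.character(pick(c("protein1", "node1", "#node1", "from")))
  to <- as.character(pick(c("protein2", "node2", "to")))
  score <- suppressWarnings(as.numeric(pick(c("combined_score", "score"))))
  bad <- is.na(from) | is.na(to) | from == "" | to == "" | is.na(score)
  if (any(bad)) {
    .warnf("edge table: skipped %d malformed row(s)", sum(bad))
    from <- from[!bad]; to <- to[!bad]; score <- score[!bad]
  }
  if (length(score) && max(score) > 1) score <- score / 1000
  if (physical_only && "network_type" %in% names(df)) {
    keep <- df$network_type[!bad] == "physical"
    from <- from[keep]; to <- to[keep]; score <- score[keep]
  }
  keep <- score >= min_score & from != to
  from <- from[keep]; to <- to[keep]; score <- score[keep]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  data.frame(from = a[!dup], to = b[!dup], score = score[!dup],
             stringsAsFactors = FALSE)
}

#' Build a pair matrix from filtered, collapsed records
#'
#' Keys rows by gene symbol (first entry of the gene-name column), falling
#' back to the lead accession for records without one. Requires the records
#' to be one-per-gene already (see [collapse_accessions()]).
#'
#' @param records Data frame of protein-group records.
#' @return A [pair_matrix()].
#' @export
build_pair_matrix <- function(records) {
  labels <- attr(records, "replicates")
  if (is.null(labels)) {
    labels <- sub("^con_", "", grep("^con_", names(records), value = TRUE))
    if (!length(labels)) .stopf("records carry no con_/sam_ intensity columns")
  }
  gene <- gene_key(records)
  if (anyDuplicated(gene))
    .stopf("duplicate gene '%s': collapse accessions first",
           gene[duplicated(gene)][1])
  con <- as.matrix(records[paste0("con_", labels)])
  sam <- as.matrix(records[paste0("sam_", labels)])
  rownames(con) <- rownames(sam) <- gene
  colnames(con) <- colnames(sam) <- labels
  pair_matrix(con, sam)
}

#' @rdname build_pair_matrix
#' @export
gene_key <- function(records) {
  gene <- records$gene_name
  lead <- vapply(strsplit(records$protein_ids, ";", fixed = TRUE),
                 function(p) p[[1]], character(1))
  ifelse(is.na(gene) | gene == "", lead, gene)
}
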