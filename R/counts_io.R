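# Reading, validation and writing of count matrices, sample designs, Ct
# tables and pipeline outputs.  All files are plain TSV: tab separator,
# UTF-8, mandatory header, no quoting, "NA" for missing values.

.CONDITIONS <- c("VEHICLE", "TRT_A", "TRT_B", "COMBO")

#' Treatment condition levels
#'
#' The four-level treatment factor used throughout the package, in reference
#' order: vehicle, single treatment A, single treatment B, and the combined
#' treatment.  The factor is fixed at exactly these four levels; designs with
#' any other label are rejected.
#'
#' @return Character vector of length four.
#' @export
condition_levels <- function() .CONDITIONS

#' Validate a count matrix
#'
#' Checks that `counts` is a numeric matrix of finite, non-negative integer
#' values with unique, non-empty gene (row) and sample (column) identifiers.
#'
#' @param counts Matrix of read counts, genes in rows, samples in columns,
#'   with `rownames` (gene ids) and `colnames` (sample ids).
#' @return The validated matrix, invisibly unchanged apart from integer
#'   storage mode.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_("counts must be a numeric matrix")
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid))
    stop_("counts must have gene ids as rownames and sample ids as colnames")
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g))
    stop_("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s))
    stop_("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(counts))
    stop_(sprintf(
      "non-integer, negative or non-finite count at gene '%s' (row %d), sample '%s' (column %d)",
      gid[ij[1]], ij[1], sid[ij[2]], ij[2]))
  }
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a count matrix from a TSV file
#'
#' The first column holds gene identifiers; the header row holds sample
#' identifiers.  Row and column order are preserved as in the file.
#'
#' @param path Path to a tab-separated counts file.
#' @return Validated integer matrix (genes x samples).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_("counts file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop_("counts file needs a gene-id column plus at least one sample column")
  gid <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop_("counts file contains non-numeric entries in the sample columns")
  rownames(mat) <- gid
  mat <- validate_counts(mat)
  mat
}

#' Write a count matrix to a TSV file
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` returns a
#' matrix identical to `x`.
#'
#' @param counts Validated count matrix.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.as_condition <- function(x) {
  lab <- toupper(trimws(as.character(x)))
  bad <- setdiff(unique(lab), .CONDITIONS)
  if (length(bad))
    stop_("unknown condition label(s): ", paste(bad, collapse = ", "),
          "; allowed labels are ", paste(.CONDITIONS, collapse = ", "))
  factor(lab, levels = .CONDITIONS)
}

#' Read (or validate) a sample design table
#'
#' A design maps each sample to one of the four treatment conditions and a
#' replicate index.  Condition labels are matched case-insensitively onto
#' `VEHICLE`, `TRT_A`, `TRT_B`, `COMBO`.  A condition with fewer than two
#' replicates triggers a warning here; differential-expression operations
#' raise an error when they are actually attempted on such a design.
#'
#' @param path Path to a TSV file with columns `sample_id`, `condition`,
#'   `replicate`.
#' @return A `data.frame` with class `sample_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_("design file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_design(df)
}

#' @rdname read_design
#' @param df Data frame with columns `sample_id`, `condition`, `replicate`.
#' @export
as_design <- function(df) {
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("design is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    condition = .as_condition(df$condition),
                    replicate = as.integer(df$replicate),
                    stringsAsFactors = FALSE)
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup))
    stop_("duplicate sample identifier(s) in design: ", paste(dup, collapse = ", "))
  if (any(!is.finite(out$replicate) | out$replicate < 1))
    stop_("replicate indices must be positive integers")
  tab <- table(out$condition)
  low <- names(tab)[tab > 0 & tab < 2]
  if (length(low))
    warning("condition(s) with fewer than 2 replicates: ",
            paste(low, collapse = ", "), call. = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Write a design table to TSV
#' @param design A `sample_design` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = design$sample_id,
               condition = as.character(design$condition),
               replicate = design$replicate),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Cross-validate counts vs design and return the condition factor aligned to
# the matrix columns.
design_conditions <- function(counts, design) {
  sid <- colnames(counts)
  extra <- setdiff(design$sample_id, sid)
  if (length(extra))
    stop_("design names sample(s) absent from the counts: ",
          paste(extra, collapse = ", "))
  missing <- setdiff(sid, design$sample_id)
  if (length(missing))
    stop_("counts contain sample(s) absent from the design: ",
          paste(missing, collapse = ", "))
  design$condition[match(sid, design$sample_id)]
}

# Error unless every condition needed for DE has >= 2 replicates.
check_de_ready <- function(cond, needed = levels(cond)) {
  tab <- table(cond)
  low <- intersect(needed, names(tab)[tab < 2])
  if (length(low))
    stop_("condition(s) with fewer than 2 replicates: ",
          paste(low, collapse = ", "),
          "; differential expression requires >= 2 per condition")
  invisible(TRUE)
}

#' Read a Ct table for the qPCR module
#'
#' @param path TSV file with columns `sample_id`, `condition`, `gene`, `ct`,
#'   `replicate`.
#' @return Data frame with the condition column folded onto the four-level
#'   treatment factor.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop_("Ct file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "gene", "ct", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  df$condition <- .as_condition(df$condition)
  if (any(!is.finite(df$ct)))
    stop_("Ct table contains non-finite ct values")
  df
}

#' Write pipeline result tables and a JSON summary
#'
#' Writes one TSV per named contrast table (columns `gene_id`, `base_mean`,
#' `log2fc`, `se`, `wald_stat`, `pvalue`, `padj`) plus a machine-readable
#' `summary.json` holding any aggregate results (Venn counts, regression
#' fits, attenuation counts, ...).  Re-running with identical inputs yields
#' byte-identical files.
#'
#' @param tables Named list of contrast result data frames (possibly empty).
#' @param dir Output directory, created if needed.
#' @param summary List of aggregate results serialised to JSON.
#' @return Character vector manifest of every file written.
#' @export
write_results <- function(tables = list(), dir, summary = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_("cannot create output directory: ", dir)
  cols <- c("gene_id", "base_mean", "log2fc", "se", "wald_stat", "pvalue", "padj")
  manifest <- character()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])[, cols]
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, f)
  }
  sf <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  c(manifest, sf)
}
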