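# Comparative-Ct (delta-delta-Ct) quantification for RT-qPCR validation,
# normalized independently against several housekeeping genes.

#' Comparative-Ct fold changes against multiple housekeeping genes
#'
#' Technical replicates are averaged on the Ct scale per (sample, gene)
#' first, then Ct values are averaged per (condition, gene).  For each
#' housekeeper h: `dCt = Ct_target - Ct_h` per condition,
#' `ddCt = dCt_condition - dCt_reference`, `fc_h = 2^-ddCt`.  The reported
#' `mean_fc` is by default the arithmetic mean of the per-housekeeper fold
#' changes (each housekeeper normalizes independently, then the resulting
#' expression values are averaged); set `hk_average = "geometric"` for the
#' geometric-mean alternative.
#'
#' @param ct_table Data frame with columns `sample_id`, `condition`, `gene`,
#'   `ct`, `replicate` (see [read_ct_table()]).
#' @param targets Character vector of target gene ids.
#' @param housekeepers Character vector of housekeeping gene ids.
#' @param reference_condition Condition that defines fold-change 1.
#' @param hk_average `"arithmetic"` (default) or `"geometric"` averaging of
#'   per-housekeeper fold changes.
#' @return Data frame with one row per (target, condition): per-housekeeper
#'   fold-change columns `fc_<housekeeper>`, `mean_fc` and
#'   `log2_fc = log2(mean_fc)`.
#' @export
comparative_ct <- function(ct_table, targets,
                           housekeepers = c("RPLP0", "GAPDH", "B2M"),
                           reference_condition = "VEHICLE",
                           hk_average = c("arithmetic", "geometric")) {
  hk_average <- match.arg(hk_average)
  need <- c("sample_id", "condition", "gene", "ct", "replicate")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop_("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  ct_table$condition <- .as_condition(ct_table$condition)
  reference_condition <- as.character(.as_condition(reference_condition))
  if (!reference_condition %in% as.character(ct_table$condition))
    stop_("reference condition ", reference_condition, " absent from Ct table")
  bad_t <- setdiff(targets, ct_table$gene)
  if (length(bad_t))
    stop_("target gene(s) absent from Ct table: ", paste(bad_t, collapse = ", "))
  bad_h <- setdiff(housekeepers, ct_table$gene)
  if (length(bad_h))
    stop_("housekeeping gene(s) absent from Ct table: ",
          paste(bad_h, collapse = ", "))
  # every sample must carry every housekeeper
  for (s in unique(ct_table$sample_id)) {
    have <- unique(ct_table$gene[ct_table$sample_id == s])
    mh <- setdiff(housekeepers, have)
    if (length(mh))
      stop_("sample '", s, "' lacks Ct values for housekeeping gene(s): ",
            paste(mh, collapse = ", "))
  }
  # replicate averaging per (sample, gene), then condition averaging
  by_sample <- stats::aggregate(ct ~ sample_id + condition + gene,
                                data = ct_table, FUN = mean)
  by_cond <- stats::aggregate(ct ~ condition + gene, data = by_sample,
                              FUN = mean)
  ctval <- function(gene, condition) {
    v <- by_cond$ct[by_cond$gene == gene &
                    as.character(by_cond$condition) == condition]
    if (!length(v)) NA_real_ else v
  }
  conds <- intersect(.CONDITIONS, as.character(unique(ct_table$condition)))
  rows <- list()
  for (tg in targets) {
    for (cd in conds) {
      fc_h <- vapply(housekeepers, function(h) {
        dct <- ctval(tg, cd) - ctval(h, cd)
        dct_ref <- ctval(tg, reference_condition) - ctval(h, reference_condition)
        2^(-(dct - dct_ref))
      }, numeric(1))
      if (any(is.na(fc_h)))
        stop_("missing Ct value for target '", tg, "' in condition ", cd)
      mean_fc <- if (hk_average == "arithmetic") mean(fc_h)
                 else exp(mean(log(fc_h)))
      row <- data.frame(gene = tg, condition = cd, t(fc_h),
                        mean_fc = mean_fc, log2_fc = log2(mean_fc),
                        stringsAsFactors = FALSE)
      names(row)[2 + seq_along(housekeepers)] <- paste0("fc_", housekeepers)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
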