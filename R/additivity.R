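# Combination analysis: Venn partition of the three DE gene sets,
# direction-concordance classes over the common targets, the expected
# additive effect (sum of the two single-treatment log2 fold-changes),
# observed-vs-expected simple linear regression, and the attenuation
# quantification for genes where the combination opposes the B effect.

.as_gene_set <- function(x) {
  if (inherits(x, "de_gene_set")) return(x$genes)
  if (is.character(x)) return(unique(x))
  stop_("expected a de_gene_set or a character vector of gene ids")
}

#' Venn partition of three DE gene sets
#'
#' Partitions `(A, B, AB)` — the genes called differentially expressed under
#' treatment A, treatment B, and the combined treatment — into the seven
#' disjoint regions of the three-set Venn diagram, plus the derived
#' marginals used in reporting: `commonAB = A int B`, `union_singles =
#' A un B`, and `combo_overlap = AB int (A un B)`.  Percentages (share of
#' single-treatment targets unshared with the other single treatment, and
#' share of combination targets overlapping a single treatment) are reported
#' rounded half-up to the nearest integer.
#'
#' @param setA,setB,setAB `de_gene_set` objects or character vectors.
#' @return A `venn_partition` list with `regions` (seven disjoint sets),
#'   `marginals`, `counts` (named integer vector) and `percents`.
#' @export
partition_sets <- function(setA, setB, setAB) {
  A <- .as_gene_set(setA); B <- .as_gene_set(setB); AB <- .as_gene_set(setAB)
  regions <- list(
    A_only      = setdiff(A, union(B, AB)),
    B_only      = setdiff(B, union(A, AB)),
    AB_only     = setdiff(AB, union(A, B)),
    A_B_not_AB  = setdiff(intersect(A, B), AB),
    A_AB_not_B  = setdiff(intersect(A, AB), B),
    B_AB_not_A  = setdiff(intersect(B, AB), A),
    A_B_AB      = intersect(intersect(A, B), AB))
  marginals <- list(
    commonAB      = intersect(A, B),
    union_singles = union(A, B),
    combo_overlap = intersect(AB, union(A, B)))
  counts <- c(vapply(regions, length, integer(1)),
              commonAB      = length(marginals$commonAB),
              union_singles = length(marginals$union_singles),
              combo_overlap = length(marginals$combo_overlap),
              A = length(A), B = length(B), AB = length(AB),
              A_unshared = length(setdiff(A, B)),
              B_unshared = length(setdiff(B, A)))
  percents <- c(
    A_unshared_pct = if (length(A)) round_half_up(100 * counts[["A_unshared"]] / length(A)) else NA_real_,
    B_unshared_pct = if (length(B)) round_half_up(100 * counts[["B_unshared"]] / length(B)) else NA_real_,
    combo_overlap_pct = if (length(AB)) round_half_up(100 * counts[["combo_overlap"]] / length(AB)) else NA_real_)
  structure(list(regions = regions, marginals = marginals,
                 counts = counts, percents = percents),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of DE gene sets\n")
  print(x$counts)
  print(x$percents)
  invisible(x)
}

#' Direction-concordance classes over the common targets
#'
#' Splits the genes regulated by both single treatments into four disjoint
#' classes by the signs of their two single-treatment log2 fold-changes:
#' `both_up`, `both_down`, `A_up_B_down`, `A_down_B_up`.  The concordant
#' percentage (`both_up` plus `both_down`) is rounded half-up; the
#' discordant percentage is defined as its complement to 100, so the pair
#' always sums to 100.
#'
#' @param common Character vector of common target gene ids.
#' @param lfcA,lfcB Named numeric vectors of single-treatment log2
#'   fold-changes covering `common`.
#' @return A `concordance_classes` list with the four gene sets, their
#'   counts, and `concordant_pct` / `discordant_pct`.
#' @export
classify_concordance <- function(common, lfcA, lfcB) {
  common <- .as_gene_set(common)
  a <- lfcA[common]; b <- lfcB[common]
  if (any(is.na(a)) || any(is.na(b)))
    stop_("every common gene needs a log2 fold-change under both treatments")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_("non-finite log2 fold-change among common genes")
  if (any(a == 0) || any(b == 0))
    stop_("log2 fold-change of exactly 0 for a DE gene signals an upstream ",
          "inconsistency")
  classes <- list(both_up     = common[a > 0 & b > 0],
                  both_down   = common[a < 0 & b < 0],
                  A_up_B_down = common[a > 0 & b < 0],
                  A_down_B_up = common[a < 0 & b > 0])
  counts <- vapply(classes, length, integer(1))
  n <- length(common)
  conc <- if (n) round_half_up(100 * (counts[["both_up"]] + counts[["both_down"]]) / n) else NA_real_
  structure(list(classes = classes, counts = counts, n_common = n,
                 concordant_pct = conc,
                 discordant_pct = if (is.na(conc)) NA_real_ else 100 - conc),
            class = "concordance_classes")
}

#' Expected additive effect
#'
#' The additive null model for the combined treatment: the sum of the two
#' single-treatment log2 fold-changes.
#'
#' @param lfcA,lfcB Finite numeric vectors (recycled as usual).
#' @return `lfcA + lfcB`.
#' @export
expected_additive_lfc <- function(lfcA, lfcB) {
  if (any(!is.finite(lfcA)) || any(!is.finite(lfcB)))
    stop_("expected additive effect requires finite log2 fold-changes")
  lfcA + lfcB
}

#' Observed-vs-expected additivity regression
#'
#' Ordinary least squares of the observed combined-treatment log2
#' fold-change on the expected additive effect over a stated gene subset.
#' Reports slope, intercept, Pearson r, r-squared and the two-sided slope
#' p-value.  Under perfect additivity the slope is 1 and the intercept 0.
#'
#' @param observed,expected Named numeric vectors (per gene).
#' @param subset Gene ids to fit on (default: all genes shared by both
#'   vectors with finite values).
#' @param subset_name Label stored in the result.
#' @return An `additivity_fit` list.
#' @export
fit_additivity <- function(observed, expected, subset = NULL,
                           subset_name = "all") {
  if (is.null(subset))
    subset <- intersect(names(observed), names(expected))
  subset <- .as_gene_set(subset)
  y <- observed[subset]; x <- expected[subset]
  if (any(is.na(y)) || any(is.na(x)) || any(!is.finite(y)) || any(!is.finite(x)))
    stop_("subset contains genes without finite observed and expected values")
  n <- length(subset)
  if (n < 3) stop_("additivity fit needs at least 3 genes, got ", n)
  if (stats::sd(x) == 0)
    stop_("expected additive effects have zero variance; slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  structure(list(subset_name = subset_name, n = n,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 pearson_r = r, r_squared = r^2,
                 slope_pvalue = summary(fit)$coefficients[2, 4]),
            class = "additivity_fit")
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat(sprintf(
    "Additivity fit [%s]: n = %d, slope = %.3f, intercept = %.3f, r^2 = %.3f (p = %.3g)\n",
    x$subset_name, x$n, x$slope, x$intercept, x$r_squared, x$slope_pvalue))
  invisible(x)
}

#' Attenuation of the B effect by the combined treatment
#'
#' Among the genes differentially expressed under treatment B alone, finds
#' those where the combined treatment significantly shifts expression back
#' toward the vehicle level: the COMBO-vs-B contrast must be significant
#' (BH-adjusted within the candidate set) with a log2 fold-change of
#' opposite sign to the B-vs-vehicle effect.  Candidates lacking a raw
#' p-value in the COMBO-vs-B contrast (expression-filtered genes) are
#' excluded and counted in `n_excluded`.
#'
#' @param setB `de_gene_set` (or character vector) of B-vs-vehicle DE genes.
#' @param result_B `contrast_result` for B vs vehicle.
#' @param result_AB_vs_B `contrast_result` for COMBO vs B.
#' @param alpha FDR threshold applied within the candidate set.
#' @return An `attenuation_result` list with `candidate_set`, `attenuated`,
#'   counts, `fraction` (`NA` when there are no candidates) and `percent`
#'   (rounded half-up).
#' @export
attenuation <- function(setB, result_B, result_AB_vs_B, alpha = 0.05) {
  genesB <- .as_gene_set(setB)
  iB <- match(genesB, result_B$gene_id)
  iC <- match(genesB, result_AB_vs_B$gene_id)
  if (any(is.na(iB)) || any(is.na(iC)))
    stop_("both contrast results must cover every gene in setB")
  p <- result_AB_vs_B$pvalue[iC]
  keep <- is.finite(p)
  n_excluded <- sum(!keep)
  if (n_excluded)
    message(n_excluded, " candidate gene(s) without a COMBO-vs-B p-value excluded")
  cand <- genesB[keep]
  if (!length(cand)) {
    return(structure(list(candidate_set = character(), attenuated = character(),
                          n_candidates = 0L, n_attenuated = 0L,
                          n_excluded = n_excluded,
                          fraction = NA_real_, percent = NA_real_),
                     class = "attenuation_result"))
  }
  padj_c <- bh_adjust(p[keep])
  lfc_B <- result_B$log2fc[iB][keep]
  lfc_C <- result_AB_vs_B$log2fc[iC][keep]
  att <- cand[padj_c < alpha & sign(lfc_C) == -sign(lfc_B)]
  fraction <- length(att) / length(cand)
  structure(list(candidate_set = cand, attenuated = att,
                 n_candidates = length(cand), n_attenuated = length(att),
                 n_excluded = n_excluded,
                 fraction = fraction,
                 percent = round_half_up(100 * fraction)),
            class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf("Attenuation: %d / %d candidate genes (%s%%)\n",
              x$n_attenuated, x$n_candidates,
              ifelse(is.na(x$percent), "NA", x$percent)))
  invisible(x)
}
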