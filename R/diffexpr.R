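# Negative-binomial differential expression engine: median-of-ratios size
# factors, gene-wise dispersion estimation (method-of-moments start refined
# by Cox-Reid-adjusted profile maximum likelihood), a one-factor NB GLM with
# log link and size-factor offsets fitted by Fisher scoring, Wald contrasts,
# and Benjamini-Hochberg FDR adjustment.
#
# Deliberate simplifications relative to full DESeq2-style machinery: no
# empirical-Bayes shrinkage of dispersions toward a fitted trend, no outlier
# refitting, no independent filtering, no fold-change shrinkage.  The aim is
# a calibrated Wald test, not bit-compatibility with any particular release.

#' Median-of-ratios size factors
#'
#' For each sample the factor is the median, over the reference genes, of
#' `count / geometric-mean-across-samples`.  Reference genes are those with
#' no zero count in any sample.  Even-sized reference sets use the midpoint
#' (arithmetic mean of the two central ratios).
#'
#' @param counts Validated count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- validate_counts(counts)
  ref <- rowSums(counts == 0L) == 0L
  if (!any(ref))
    stop_("size-factor reference set is empty: every gene has at least one ",
          "zero count, so the median-of-ratios estimator is undefined; ",
          "no pseudo-reference fallback is applied silently")
  m <- counts[ref, , drop = FALSE]
  gm <- exp(rowMeans(log(m)))
  apply(m / gm, 2, stats::median)
}

# Cox-Reid adjusted profile log-likelihood of log-dispersion `la` for one
# gene, with fitted means profiled out via the plug-in group means.
.crapl <- function(la, y, mu, grp_idx) {
  a <- exp(la)
  w <- mu / (1 + a * mu)
  sums <- vapply(grp_idx, function(j) sum(w[j]), numeric(1))
  sums <- sums[sums > 0]
  sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE)) -
    0.5 * sum(log(sums))
}

#' Gene-wise NB dispersion estimates
#'
#' Per gene: a method-of-moments start from the within-condition residual
#' variance of normalized counts, refined by maximizing the Cox-Reid
#' adjusted profile negative-binomial likelihood (condition means profiled
#' out) over `[alpha_min, alpha_max]`.  `method_flag` records the path:
#' `MLE` (interior optimum), `FLOOR` (clamped at `alpha_min`, including
#' all-zero and under-dispersed genes), `MOM` (likelihood refinement failed,
#' moment estimate kept).
#'
#' @param counts Validated count matrix.
#' @param sf Size factors from [estimate_size_factors()].
#' @param design Sample design (only the condition grouping is used; any
#'   subset of the four levels with at least 2 replicates somewhere works).
#' @param alpha_min,alpha_max Global dispersion bounds.
#' @return Data frame with `gene_id`, `alpha_hat`, `method_flag`.
#' @export
estimate_dispersion <- function(counts, sf, design,
                                alpha_min = 1e-8, alpha_max = 10) {
  counts <- validate_counts(counts)
  cond <- design_conditions(counts, design)
  cond <- droplevels(cond)
  if (!any(table(cond) >= 2))
    stop_("dispersion estimation needs >= 2 replicates in >= 1 condition")
  q <- sweep(counts, 2, sf, "/")
  grp_idx <- split(seq_along(cond), cond)
  G <- length(grp_idx)
  N <- ncol(counts)
  xim <- mean(1 / sf)
  qbar <- vapply(grp_idx, function(j) rowMeans(q[, j, drop = FALSE]),
                 numeric(nrow(counts)))
  if (is.null(dim(qbar))) qbar <- matrix(qbar, nrow = nrow(counts))
  # pooled within-condition residual variance on the normalized scale
  rss <- numeric(nrow(counts))
  for (g in seq_len(G)) {
    j <- grp_idx[[g]]
    rss <- rss + rowSums((q[, j, drop = FALSE] - qbar[, g])^2)
  }
  v <- rss / max(N - G, 1)
  qb <- rowMeans(q)
  lo <- log(alpha_min)
  hi <- log(alpha_max)
  n_genes <- nrow(counts)
  alpha_hat <- rep(alpha_min, n_genes)
  flag <- rep("FLOOR", n_genes)
  fitted_mu <- qbar[, as.integer(cond), drop = FALSE] *
    rep(sf, each = n_genes)
  for (i in seq_len(n_genes)) {
    y <- counts[i, ]
    if (all(y == 0L)) next                      # FLOOR, excluded downstream
    mom <- (v[i] - qb[i] * xim) / qb[i]^2
    opt <- tryCatch(
      stats::optimize(.crapl, c(lo, hi), maximum = TRUE,
                      y = y, mu = fitted_mu[i, ], grp_idx = grp_idx),
      error = function(e) NULL)
    if (is.null(opt)) {
      alpha_hat[i] <- min(max(mom, alpha_min), alpha_max)
      flag[i] <- "MOM"
    } else {
      a <- exp(opt$maximum)
      # optimize never returns the exact endpoint; treat near-boundary as floor
      if (a <= alpha_min * 3) {
        alpha_hat[i] <- alpha_min
        flag[i] <- "FLOOR"
      } else {
        alpha_hat[i] <- min(a, alpha_max)
        flag[i] <- "MLE"
      }
    }
  }
  data.frame(gene_id = rownames(counts), alpha_hat = alpha_hat,
             method_flag = flag, stringsAsFactors = FALSE)
}

# Fit the one-factor NB GLM (log link, size-factor offsets, gene-wise
# dispersion) in the cell-means parameterization: one coefficient per
# condition, solved by Fisher scoring.  This is the same maximum-likelihood
# fit as the dummy-coded IRLS formulation; contrasts are coefficient
# differences from this single fit.
.fit_group_coefs <- function(counts, sf, alpha, cond,
                             max_iter = 50L, tol = 1e-8) {
  lv <- levels(droplevels(cond))
  n <- nrow(counts)
  beta <- matrix(NA_real_, n, length(lv), dimnames = list(rownames(counts), lv))
  vbeta <- beta
  conv <- matrix(FALSE, n, length(lv), dimnames = dimnames(beta))
  for (g in seq_along(lv)) {
    j <- which(cond == lv[g])
    y <- counts[, j, drop = FALSE]
    s <- sf[j]
    tot <- rowSums(y)
    pos <- tot > 0
    b <- log(pmax(tot / sum(s), 1e-8))
    done <- !pos                               # all-zero groups stay NA
    active <- which(pos)
    for (it in seq_len(max_iter)) {
      if (!length(active)) break
      mu <- exp(b[active]) %*% t(s)
      den <- 1 + alpha[active] * mu
      score <- rowSums((y[active, , drop = FALSE] - mu) / den)
      info <- rowSums(mu / den)
      step <- pmin(pmax(score / info, -5), 5)
      b[active] <- b[active] + step
      fin <- abs(step) < tol
      done[active[fin]] <- TRUE
      active <- active[!fin]
    }
    mu <- exp(b[pos]) %*% t(s)
    den <- 1 + alpha[pos] * mu
    beta[pos, g] <- b[pos]
    vbeta[pos, g] <- 1 / rowSums(mu / den)
    conv[, g] <- done & pos
  }
  list(beta = beta, vbeta = vbeta, converged = conv, levels = lv)
}

#' Fit the four-level NB model once
#'
#' Convenience wrapper returning the fitted per-condition coefficients (on
#' the natural-log scale) so several Wald contrasts can be computed from one
#' fit via [wald_contrast()]'s `fit` argument.
#'
#' @inheritParams estimate_dispersion
#' @param disp Dispersion table from [estimate_dispersion()].
#' @return Opaque fit object consumed by [wald_contrast()].
#' @export
fit_nb_model <- function(counts, sf, disp, design) {
  counts <- validate_counts(counts)
  cond <- design_conditions(counts, design)
  alpha <- disp$alpha_hat[match(rownames(counts), disp$gene_id)]
  if (any(is.na(alpha)))
    stop_("dispersion table does not cover every gene in the counts")
  .fit_group_coefs(counts, sf, alpha, cond)
}

#' NB-GLM Wald contrast between two conditions
#'
#' Fits (or reuses) the one-factor four-level NB GLM with log link and
#' size-factor offsets, and tests the difference between the two condition
#' coefficients.  `log2fc` is that difference converted to base 2, `se` comes
#' from the observed Fisher information, and the p-value is the two-sided
#' tail of a t distribution with the model's residual degrees of freedom
#' (samples minus fitted condition means), which keeps the test calibrated
#' when the gene-wise dispersion is itself estimated from few replicates.
#' Genes where either contrast group has only zero counts (separation) or
#' where scoring fails to converge fall back to a pseudo-mean estimate
#' (normalized group means + 0.5) with a delta-method standard error, flagged
#' `pseudo` in `fit_method`, never an exception.  Genes whose total raw count
#' is below `min_total_count` keep their `log2fc` but get a missing `padj`;
#' BH adjustment is applied within this contrast over the tested genes only.
#'
#' @inheritParams fit_nb_model
#' @param contrast Character pair `c(numerator_condition, denominator_condition)`,
#'   e.g. `c("TRT_A", "VEHICLE")`.
#' @param min_total_count Expression filter: genes with a smaller total raw
#'   count across all samples are excluded from testing (missing `padj`).
#' @param fit Optional precomputed [fit_nb_model()] object.
#' @return A `contrast_result` data frame with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se`, `wald_stat`, `pvalue`, `padj`,
#'   `fit_method`; the contrast name is stored in
#'   `attr(, "contrast_name")`.
#' @export
wald_contrast <- function(counts, sf, disp, design, contrast,
                          min_total_count = 10, fit = NULL) {
  counts <- validate_counts(counts)
  cond <- design_conditions(counts, design)
  if (length(contrast) != 2 || !all(contrast %in% .CONDITIONS))
    stop_("contrast must be two of: ", paste(.CONDITIONS, collapse = ", "))
  A <- contrast[1]; B <- contrast[2]
  if (A == B) stop_("contrast conditions must differ")
  check_de_ready(cond, needed = c(A, B))
  if (is.null(fit)) fit <- fit_nb_model(counts, sf, disp, design)
  alpha <- disp$alpha_hat[match(rownames(counts), disp$gene_id)]
  q <- sweep(counts, 2, sf, "/")
  qA <- rowMeans(q[, cond == A, drop = FALSE])
  qB <- rowMeans(q[, cond == B, drop = FALSE])
  nA <- sum(cond == A); nB <- sum(cond == B)
  lfc_nat <- fit$beta[, A] - fit$beta[, B]
  var_nat <- fit$vbeta[, A] + fit$vbeta[, B]
  use_pseudo <- !(fit$converged[, A] & fit$converged[, B]) |
    !is.finite(lfc_nat) | !is.finite(var_nat)
  ln2 <- log(2)
  log2fc <- ifelse(use_pseudo, log2((qA + 0.5) / (qB + 0.5)), lfc_nat / ln2)
  v_pseudo <- (1 / (nA * (qA + 0.5)) + alpha / nA +
               1 / (nB * (qB + 0.5)) + alpha / nB) / ln2^2
  se <- ifelse(use_pseudo, sqrt(v_pseudo), sqrt(var_nat) / ln2)
  wald <- log2fc / se
  # t reference with the model's residual df: with a handful of replicates
  # the gene-wise dispersion estimate carries real uncertainty, and a plain
  # normal reference is anti-conservative (P(|t_8| > 1.96) ~ 0.086); the
  # t_{N-G} reference restores nominal type-I error.
  df_resid <- max(length(cond) - nlevels(droplevels(cond)), 1L)
  pvalue <- 2 * stats::pt(-abs(wald), df = df_resid)
  tested <- rowSums(counts) >= min_total_count & is.finite(pvalue)
  padj <- rep(NA_real_, nrow(counts))
  padj[tested] <- bh_adjust(pvalue[tested])
  out <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(q),
                    log2fc = log2fc, se = se, wald_stat = wald,
                    pvalue = pvalue, padj = padj,
                    fit_method = ifelse(use_pseudo, "pseudo", "wald"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast_name") <- paste(A, "vs", B, sep = "_")
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min_(j >= i) (m * p_(j) / j)` on the sorted scale, capped at
#' 1 and mapped back to the input order.  Missing values pass through as
#' missing and do not count toward `m`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0L) return(out)
  ord <- ok[order(pvalues[ok])]
  stepup <- m * pvalues[ord] / seq_len(m)
  adj <- rev(cummin(rev(stepup)))
  out[ord] <- pmin(adj, 1)
  out
}

#' Select differentially expressed genes
#'
#' Strict threshold `padj < alpha`; genes with missing `padj` are excluded.
#'
#' @param result A `contrast_result`.
#' @param alpha FDR threshold in (0, 1).
#' @return A `de_gene_set` list with `contrast`, `alpha` and the sorted
#'   character vector `genes`.
#' @export
select_de <- function(result, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  sel <- !is.na(result$padj) & result$padj < alpha
  structure(list(contrast = attr(result, "contrast_name") %||% "contrast",
                 alpha = alpha,
                 genes = sort(result$gene_id[sel])),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat(sprintf("DE gene set '%s': %d genes at padj < %g\n",
              x$contrast, length(x$genes), x$alpha))
  invisible(x)
}
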