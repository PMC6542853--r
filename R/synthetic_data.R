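# Synthetic factorial negative-binomial datasets with known per-gene ground
# truth.  The generator emulates the structure of a 4-condition x 3-replicate
# bulk RNA-seq experiment: log-normal baseline means, uniform |log2| effect
# sizes with random (Rademacher) signs, log-normal gene-wise dispersions, and
# an optional log2 interaction term gamma that measures the deviation of the
# combined treatment from additivity (gamma = 0 means exactly additive).

#' Simulation parameters
#'
#' Defaults emulate the factorial study design the package targets: ~15,000
#' expressed genes, 4 conditions x 3 replicates, regulated fractions that
#' reproduce the observed proportions of A-only / B-only / common targets,
#' |log2 effect| drawn uniformly in \[0.5, 3\] with equiprobable signs, no
#' interaction (point mass at 0), baseline means LogNormal(log 100, 1.2) and
#' dispersions LogNormal(log 0.05, 0.5).
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition (>= 2).
#' @param frac_A_only,frac_B_only,frac_both Fractions of genes regulated by
#'   A alone, B alone, or both; must be non-negative and sum to <= 1.
#' @param effect_min,effect_max Range of |beta| (log2 scale) for regulated
#'   genes; signs are +/-1 with equal probability, independent of magnitude.
#' @param gamma_sd Standard deviation of the Normal(0, gamma_sd) interaction
#'   term applied to regulated genes; 0 (default) gives exact additivity.
#' @param mu_meanlog,mu_sdlog Log-normal parameters of baseline means.
#' @param disp_meanlog,disp_sdlog Log-normal parameters of dispersions.
#' @param libsize_factors Optional vector of `4 * n_reps` per-sample library
#'   size multipliers; if `NULL` they are drawn LogNormal(0, `libsize_sdlog`).
#' @param libsize_sdlog Spread of the drawn library-size factors.
#' @param seed Integer seed driving both the truth and the counts stream.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_genes = 15000L, n_reps = 3L,
                              frac_A_only = 0.155, frac_B_only = 0.066,
                              frac_both = 0.053,
                              effect_min = 0.5, effect_max = 3,
                              gamma_sd = 0,
                              mu_meanlog = log(100), mu_sdlog = 1.2,
                              disp_meanlog = log(0.05), disp_sdlog = 0.5,
                              libsize_factors = NULL, libsize_sdlog = 0.15,
                              seed = 1L) {
  fr <- c(frac_A_only, frac_B_only, frac_both)
  if (any(fr < 0) || sum(fr) > 1)
    stop_("regulated fractions must be >= 0 and sum to <= 1")
  if (n_reps < 2) stop_("n_reps must be >= 2")
  if (effect_min < 0 || effect_max < effect_min)
    stop_("effect size range must satisfy 0 <= effect_min <= effect_max")
  if (gamma_sd < 0 || mu_sdlog < 0 || disp_sdlog < 0 || libsize_sdlog < 0)
    stop_("all distribution scales must be >= 0")
  if (!is.null(libsize_factors)) {
    if (length(libsize_factors) != 4L * n_reps || any(libsize_factors <= 0))
      stop_("libsize_factors must be ", 4L * n_reps, " positive multipliers")
  }
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 frac_A_only = frac_A_only, frac_B_only = frac_B_only,
                 frac_both = frac_both,
                 effect_min = effect_min, effect_max = effect_max,
                 gamma_sd = gamma_sd,
                 mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 disp_meanlog = disp_meanlog, disp_sdlog = disp_sdlog,
                 libsize_factors = libsize_factors,
                 libsize_sdlog = libsize_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

.rademacher <- function(n) sample(c(-1, 1), n, replace = TRUE)

#' Generate per-gene ground truth
#'
#' Draws one row per gene: baseline mean `mu0`, log2 treatment effects
#' `betaA` and `betaB`, log2 interaction `gamma`, and NB dispersion
#' `alpha_disp`.  The regulated fractions are realised exactly (deterministic
#' rounding of `n_genes * fraction`); non-regulated genes have
#' `betaA = betaB = gamma = 0`.  A gene is additive iff `gamma == 0`; its
#' true combined log2 effect is `betaA + betaB + gamma`.
#'
#' @param params A [simulation_params()] object.
#' @return Data frame with columns `gene_id`, `mu0`, `betaA`, `betaB`,
#'   `gamma`, `alpha_disp`.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(truth_seed(params$seed))
  n <- params$n_genes
  nA <- round(n * params$frac_A_only)
  nB <- round(n * params$frac_B_only)
  nAB <- round(n * params$frac_both)
  if (nA + nB + nAB > n) stop_("regulated fractions round to more genes than n_genes")
  gene_id <- sprintf("gene%05d", seq_len(n))
  idx <- sample.int(n, nA + nB + nAB)
  iA <- idx[seq_len(nA)]
  iB <- idx[nA + seq_len(nB)]
  iAB <- idx[nA + nB + seq_len(nAB)]
  draw_beta <- function(k)
    .rademacher(k) * stats::runif(k, params$effect_min, params$effect_max)
  betaA <- betaB <- gamma <- numeric(n)
  betaA[c(iA, iAB)] <- draw_beta(nA + nAB)
  betaB[c(iB, iAB)] <- draw_beta(nB + nAB)
  if (params$gamma_sd > 0) {
    reg <- c(iA, iB, iAB)
    gamma[reg] <- stats::rnorm(length(reg), 0, params$gamma_sd)
  }
  mu0 <- stats::rlnorm(n, params$mu_meanlog, params$mu_sdlog)
  alpha_disp <- stats::rlnorm(n, params$disp_meanlog, params$disp_sdlog)
  data.frame(gene_id = gene_id, mu0 = mu0, betaA = betaA, betaB = betaB,
             gamma = gamma, alpha_disp = alpha_disp,
             stringsAsFactors = FALSE)
}

#' Simulate a factorial count matrix from a truth table
#'
#' For sample j in condition c the count of gene i is drawn from a negative
#' binomial with mean `s_j * mu0_i * 2^(betaA*[A in c] + betaB*[B in c] +
#' gamma*[c == COMBO])` and variance `mean + alpha_disp * mean^2`
#' (`alpha_disp = 0` falls back to Poisson).  The counts stream is seeded
#' independently of the truth stream, so the same `params` regenerate either
#' piece on its own.
#'
#' @param truth Truth table as returned by [generate_truth()] (or built by
#'   hand with the same columns).
#' @param params A [simulation_params()] object.
#' @return List with elements `counts` (validated integer matrix), `design`
#'   (a `sample_design` data frame) and `size_factors_true` (the library-size
#'   multipliers used).
#' @export
simulate_counts <- function(truth, params) {
  stopifnot(inherits(params, "simulation_params"))
  need <- c("gene_id", "mu0", "betaA", "betaB", "gamma", "alpha_disp")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop_("truth table missing column(s): ", paste(miss, collapse = ", "))
  if (any(truth$mu0 <= 0) || any(truth$alpha_disp < 0))
    stop_("truth table requires mu0 > 0 and alpha_disp >= 0")
  set.seed(counts_seed(params$seed))
  n <- nrow(truth)
  nr <- params$n_reps
  cond <- rep(.CONDITIONS, each = nr)
  repl <- rep(seq_len(nr), times = 4L)
  sample_id <- sprintf("%s_r%d", tolower(cond), repl)
  sf <- params$libsize_factors %||% stats::rlnorm(4L * nr, 0, params$libsize_sdlog)
  # per-condition log2 effect: A in {TRT_A, COMBO}, B in {TRT_B, COMBO}
  eff <- cbind(VEHICLE = 0,
               TRT_A = truth$betaA,
               TRT_B = truth$betaB,
               COMBO = truth$betaA + truth$betaB + truth$gamma)
  mu <- (truth$mu0 * 2^eff[, cond, drop = FALSE]) * rep(sf, each = n)
  counts <- matrix(0L, n, 4L * nr, dimnames = list(truth$gene_id, sample_id))
  pos <- truth$alpha_disp > 0
  if (any(pos))
    counts[pos, ] <- stats::rnbinom(sum(pos) * 4L * nr,
                                    mu = mu[pos, , drop = FALSE],
                                    size = rep(1 / truth$alpha_disp[pos], 4L * nr))
  if (any(!pos))
    counts[!pos, ] <- stats::rpois(sum(!pos) * 4L * nr, mu[!pos, , drop = FALSE])
  counts <- validate_counts(counts)
  design <- as_design(data.frame(sample_id = sample_id, condition = cond,
                                 replicate = repl))
  list(counts = counts, design = design, size_factors_true = sf)
}
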