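# End-to-end orchestration: simulate (or load) -> size factors -> dispersion
# -> four Wald contrasts -> DE selection -> Venn / concordance / additivity
# fits / attenuation -> TSV outputs plus a machine-readable JSON report.

#' Analysis configuration
#'
#' @param alpha FDR threshold in (0, 1) for DE selection.
#' @param min_total_count Expression filter: genes with a smaller total raw
#'   count get a missing adjusted p-value.
#' @param seed Integer seed (drives the simulation when one is run).
#' @param output_dir Directory for all written artifacts.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, min_total_count = 10, seed = 1L,
                            output_dir = tempfile("factorialDE_run_")) {
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  if (min_total_count < 0) stop_("min_total_count must be >= 0")
  structure(list(alpha = alpha, min_total_count = as.integer(min_total_count),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

.de_counts <- function(result, alpha) {
  sel <- !is.na(result$padj) & result$padj < alpha
  lfc <- result$log2fc[sel]
  list(total = sum(sel), induced = sum(lfc > 0), repressed = sum(lfc < 0))
}

#' Run the full factorial analysis pipeline
#'
#' Executes simulate (or load) -> normalization -> dispersion -> the four
#' contrasts (A vs vehicle, B vs vehicle, combined vs vehicle, combined vs
#' B, all from one model fit) -> DE selection -> Venn partition ->
#' concordance -> additivity regressions on the three standard subsets
#' (union of single-treatment DE genes, common DE genes, combination-only
#' DE genes) -> attenuation.  Writes per-contrast TSVs, scatter TSVs
#' (gene, expected, observed) and a JSON report; the report is byte-stable
#' for a fixed configuration and seed.
#'
#' @param config An [analysis_config()].
#' @param sim_params A [simulation_params()] object, or `NULL` when reading
#'   real data (its seed is overridden by `config$seed` so one seed governs
#'   the run).
#' @param counts_path,design_path TSV paths for real data (mutually
#'   exclusive with `sim_params`).
#' @param verbose Emit one message per stage.
#' @return List with `report` (also serialised to `summary.json`) and
#'   `manifest` of written files, invisibly.
#' @export
run_pipeline <- function(config = analysis_config(), sim_params = NULL,
                         counts_path = NULL, design_path = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  simulate <- !is.null(sim_params)
  if (simulate == (!is.null(counts_path) || !is.null(design_path)))
    stop_("provide either sim_params or counts_path + design_path, not both")
  say <- function(...) if (verbose) message("[factorialDE] ", ...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (simulate) {
    sim_params$seed <- config$seed
    say("simulate: ", sim_params$n_genes, " genes x ",
        4 * sim_params$n_reps, " samples, seed ", config$seed)
    truth <- generate_truth(sim_params)
    sim <- simulate_counts(truth, sim_params)
    counts <- sim$counts
    design <- sim$design
    utils::write.table(truth, file.path(config$output_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_counts(counts, file.path(config$output_dir, "counts.tsv"))
    write_design(design, file.path(config$output_dir, "design.tsv"))
  } else {
    if (is.null(counts_path) || is.null(design_path))
      stop_("real-data mode needs both counts_path and design_path")
    say("load: ", counts_path)
    counts <- read_counts(counts_path)
    design <- read_design(design_path)
  }
  cond <- design_conditions(counts, design)
  check_de_ready(cond)

  say("size factors: ", ncol(counts), " samples")
  sf <- estimate_size_factors(counts)
  say("dispersion: ", nrow(counts), " genes")
  disp <- estimate_dispersion(counts, sf, design)
  fit <- fit_nb_model(counts, sf, disp, design)

  contrasts <- list(TRT_A_vs_VEHICLE = c("TRT_A", "VEHICLE"),
                    TRT_B_vs_VEHICLE = c("TRT_B", "VEHICLE"),
                    COMBO_vs_VEHICLE = c("COMBO", "VEHICLE"),
                    COMBO_vs_TRT_B   = c("COMBO", "TRT_B"))
  results <- lapply(contrasts, function(ct) {
    say("wald contrast: ", paste(ct, collapse = " vs "))
    wald_contrast(counts, sf, disp, design, ct,
                  min_total_count = config$min_total_count, fit = fit)
  })

  deA <- select_de(results$TRT_A_vs_VEHICLE, config$alpha)
  deB <- select_de(results$TRT_B_vs_VEHICLE, config$alpha)
  deAB <- select_de(results$COMBO_vs_VEHICLE, config$alpha)
  venn <- partition_sets(deA, deB, deAB)

  lfcA <- stats::setNames(results$TRT_A_vs_VEHICLE$log2fc,
                          results$TRT_A_vs_VEHICLE$gene_id)
  lfcB <- stats::setNames(results$TRT_B_vs_VEHICLE$log2fc,
                          results$TRT_B_vs_VEHICLE$gene_id)
  observed <- stats::setNames(results$COMBO_vs_VEHICLE$log2fc,
                              results$COMBO_vs_VEHICLE$gene_id)
  expected <- expected_additive_lfc(lfcA, lfcB)

  conc <- if (length(venn$marginals$commonAB))
    classify_concordance(venn$marginals$commonAB, lfcA, lfcB) else NULL

  subsets <- list(union_singles = venn$marginals$union_singles,
                  commonAB = venn$marginals$commonAB,
                  AB_only = venn$regions$AB_only)
  fits <- list()
  scatter_files <- character()
  for (nm in names(subsets)) {
    gs <- subsets[[nm]]
    fits[[nm]] <- if (length(gs) >= 3 && stats::sd(expected[gs]) > 0)
      fit_additivity(observed, expected, gs, nm) else NULL
    if (length(gs)) {
      f <- file.path(config$output_dir, paste0("scatter_", nm, ".tsv"))
      utils::write.table(
        data.frame(gene_id = gs, expected = expected[gs],
                   observed = observed[gs]),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      scatter_files <- c(scatter_files, f)
    }
  }

  att <- attenuation(deB, results$TRT_B_vs_VEHICLE, results$COMBO_vs_TRT_B,
                     config$alpha)

  report <- list(
    config = list(alpha = config$alpha,
                  min_total_count = config$min_total_count,
                  seed = config$seed,
                  mode = if (simulate) "simulation" else "real_data"),
    de_counts = lapply(results, .de_counts, alpha = config$alpha),
    venn_counts = as.list(venn$counts),
    venn_percents = as.list(venn$percents),
    concordance = if (is.null(conc)) NULL else
      list(counts = as.list(conc$counts), n_common = conc$n_common,
           concordant_pct = conc$concordant_pct,
           discordant_pct = conc$discordant_pct),
    additivity_fits = lapply(fits, function(f) if (is.null(f)) NULL else
      f[c("subset_name", "n", "slope", "intercept", "pearson_r",
          "r_squared", "slope_pvalue")]),
    attenuation = att[c("n_candidates", "n_attenuated", "n_excluded",
                        "fraction", "percent")],
    version = as.character(utils::packageVersion("factorialDE")))

  manifest <- write_results(results, config$output_dir, summary = report)
  manifest <- c(manifest, scatter_files)
  report$files <- basename(manifest)
  # rewrite the summary with the manifest embedded (names only, so reruns
  # into different directories stay byte-identical)
  manifest <- c(write_results(results, config$output_dir, summary = report),
                scatter_files)
  say("done: ", length(manifest), " files in ", config$output_dir)
  invisible(list(report = report, manifest = manifest,
                 results = results, venn = venn, concordance = conc,
                 fits = fits, attenuation = att))
}
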