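# Shared fixtures: all built in code at test time.

# A tiny valid counts matrix with gene/sample ids.
tiny_counts <- function(vals = 1:4, genes = c("gA", "gB"),
                        samples = c("s1", "s2")) {
  m <- matrix(as.integer(vals), nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  m
}

# Balanced 4-condition design for a set of sample ids.
balanced_design <- function(n_reps = 3) {
  cond <- rep(condition_levels(), each = n_reps)
  as_design(data.frame(sample_id = sprintf("%s_r%d", tolower(cond),
                                           rep(seq_len(n_reps), 4)),
                       condition = cond,
                       replicate = rep(seq_len(n_reps), 4)))
}

# Run size factors + dispersion + one shared model fit on a simulation.
quick_de <- function(sim) {
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sf, sim$design)
  fit <- fit_nb_model(sim$counts, sf, disp, sim$design)
  list(sf = sf, disp = disp, fit = fit)
}

wald_with <- function(sim, de, contrast, ...) {
  wald_contrast(sim$counts, de$sf, de$disp, sim$design, contrast,
                fit = de$fit, ...)
}

# Three DE gene-set fixtures realising the study's printed marginal counts:
# |A| = 3129, |B| = 1794, |A int B| = 800, |AB| = 4296 with
# |AB int (A un B)| = 2987 (split 800 common + 1500 from A-only + 687 from
# B-only) and therefore 1309 combination-only genes.
marginal_sets <- function() {
  ids <- sprintf("g%05d", seq_len(9000))
  common <- ids[1:800]
  A_extra <- ids[801:3129]                       # 2329 unshared A genes
  B_extra <- ids[3130:4123]                      # 994 unshared B genes
  list(A = c(common, A_extra),
       B = c(common, B_extra),
       AB = c(common, A_extra[1:1500], B_extra[1:687], ids[4124:5432]))
}

# Ct-table builder: one row per (sample, gene, replicate).
ct_rows <- function(sample_id, condition, gene, ct, replicate = 1L) {
  data.frame(sample_id = sample_id, condition = condition, gene = gene,
             ct = ct, replicate = replicate, stringsAsFactors = FALSE)
}
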