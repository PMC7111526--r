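# Shared small fixtures, built once per test run.

# A compact panel with planted structure: two correlation blocks, a few
# mQTLs/eQTLs, and traits driven by known metabolites.
small_panel <- function(seed = 42) {
  cfg <- sim_config(
    n_lines = 20, n_variants = 60, maf_min = 0.2, n_metabolites = 24,
    module_spec = data.frame(size = c(8, 6), rho = c(0.8, 0.7)),
    h2_target = 0.43, n_reps = 3, n_genes = 10, seed = seed,
    mqtl_spec = data.frame(variant = c(1, 2), metabolite = c(20, 21),
                           effect = c(2.5, 2.5)),
    eqtl_spec = data.frame(variant = c(1, 3), gene = c(1, 2),
                           effect = c(2.5, 2.5)),
    trait_spec = list(list(metabolites = c(20, 21), weights = c(1, 1),
                           h2 = 0.8)))
  simulate_panel(cfg)
}

# balanced replicate table built directly from a cell-mean specification
replicate_table <- function(line_effects, sex_effect = 0, lxs = NULL,
                            n_reps = 3, noise_sd = 0, analyte = "met",
                            seed = 1) {
  set.seed(seed)
  lines <- names(line_effects) %||% paste0("L", seq_along(line_effects))
  rows <- expand.grid(replicate = seq_len(n_reps), sex = c("F", "M"),
                      line = lines, stringsAsFactors = FALSE)
  li <- match(rows$line, lines)
  sgn <- ifelse(rows$sex == "M", 0.5, -0.5)
  ab <- 10 + line_effects[li] + sgn * sex_effect
  if (!is.null(lxs)) ab <- ab + ifelse(rows$sex == "M", lxs[li], -lxs[li])
  ab <- ab + rnorm(nrow(rows), 0, noise_sd)
  data.frame(line = rows$line, sex = rows$sex, replicate = rows$replicate,
             analyte = analyte, abundance = ab, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
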