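#' Pipeline configuration with validated defaults
#'
#' Collects every tunable of the workflow in one list. Unknown keys are
#' rejected outright, so typos fail fast; the full configuration is echoed
#' into the run manifest for provenance.
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Defaults: `seed = 1`; `n_ions = 60`; `cell_lines`/`stimuli`
#'   defining the condition grid; `totals = 1e4` cells per mix sample;
#'   `fractions = mixing_fractions()`; planted G0 fractions `g0_at_8h = 0.2`
#'   and `g0_at_96h = 0.6`; `replicates = 3`; measurement model
#'   (`background = 100`, `noise_cv = 0.1`, `noise_floor_sd = 0`,
#'   `saturation = Inf`); `n_events = 5000` cytometry events per end point;
#'   gating (`dna_k = 2.5`, `rna_quantile = 0.05`); `alpha_fw = 0.05`;
#'   `bootstrap_reps = 100`; association `threshold_grid = NULL` (data-driven
#'   upper bound); growth (`window_hours = 24`, `shift_hours = 8`);
#'   annotation `tolerance = 0.003`; and the `stages` toggle list.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L, n_ions = 60L,
    cell_lines = c("A549", "HCT116"), stimuli = c("starvation"),
    totals = 1e4, fractions = mixing_fractions(),
    g0_at_8h = 0.2, g0_at_96h = 0.6, replicates = 3L,
    background = 100, noise_cv = 0.1, noise_floor_sd = 0, saturation = Inf,
    n_events = 5000L, dna_k = 2.5, rna_quantile = 0.05,
    alpha_fw = 0.05, bootstrap_reps = 100L, threshold_grid = NULL,
    window_hours = 24, shift_hours = 8, tolerance = 0.003,
    stages = list(simulate = TRUE, gate = TRUE, linearity = TRUE,
                  deconvolve = TRUE, effects = TRUE, associate = TRUE,
                  growth = FALSE, annotate = FALSE))
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$stages)) {
    bad <- setdiff(names(user$stages), names(defaults$stages))
    if (length(bad))
      stop("unknown stage(s): ", paste(bad, collapse = ", "))
    defaults$stages[names(user$stages)] <- user$stages
    user$stages <- NULL
  }
  defaults[names(user)] <- user
  structure(defaults, class = "pipeline_config")
}

#' Run the full synthetic-to-association pipeline
#'
#' Executes, in order: synthetic-experiment generation, cytometry gating of
#' the two end-point event clouds (gates derived on the 8-h-like sample and
#' reused on the 96-h-like sample), the biological-origin linearity filter,
#' constrained deconvolution with bootstrap errors, effect sizes, and the
#' quiescence-association test; optionally growth kinetics and annotation.
#' Every stage writes its table into a named subfolder of `out_dir`, and a
#' JSON manifest records the package version, the full configuration and the
#' MD5 digest of every output, which suffices to re-execute the run
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing).
#' @return (invisibly) list with the in-memory stage results and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  results <- list()
  outputs <- character(0)
  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  conditions <- expand.grid(cell_line = config$cell_lines,
                            stimulus = config$stimuli,
                            stringsAsFactors = FALSE)

  if (!st$simulate)
    stop("stage 'simulate' is required by this runner: the pipeline ",
         "operates on a generated experiment (use the module functions ",
         "directly for externally measured tables)")
  model <- measurement_model(background = config$background,
                             noise_cv = config$noise_cv,
                             noise_floor_sd = config$noise_floor_sd,
                             saturation = config$saturation,
                             seed = config$seed)
  truth <- true_population_profile(config$n_ions, conditions,
                                   seed = config$seed)
  exper <- simulate_mix_experiment(truth, totals = config$totals,
                                   fractions = config$fractions,
                                   g0_at_8h = config$g0_at_8h,
                                   g0_at_96h = config$g0_at_96h,
                                   replicates = config$replicates,
                                   model = model)
  d <- stage_dir("simulate")
  outputs <- c(outputs,
               write_ion_table(exper$intensities,
                               file.path(d, "intensities.tsv")),
               write_tsv(exper$design, file.path(d, "design.tsv")))
  truth_path <- file.path(d, "truth.json")
  jsonlite::write_json(list(alpha_P = truth$alpha_P,
                            alpha_Q = truth$alpha_Q,
                            ions = truth$ions,
                            differential = truth$differential),
                       truth_path, digits = NA)
  outputs <- c(outputs, truth_path)
  results$experiment <- exper

  if (st$gate) {
    ev8 <- simulate_cytometry_events(
      config$n_events,
      phase_fractions = c(G0 = config$g0_at_8h,
                          G1 = (1 - config$g0_at_8h) * 0.55,
                          S = (1 - config$g0_at_8h) * 0.3,
                          G2M = (1 - config$g0_at_8h) * 0.15),
      seed = config$seed)
    ev96 <- simulate_cytometry_events(
      config$n_events,
      phase_fractions = c(G0 = config$g0_at_96h,
                          G1 = (1 - config$g0_at_96h) * 0.8,
                          S = (1 - config$g0_at_96h) * 0.12,
                          G2M = (1 - config$g0_at_96h) * 0.08),
      seed = config$seed + 1L)
    gates <- derive_gates(ev8, k = config$dna_k,
                          rna_quantile = config$rna_quantile)
    fr8 <- classify_phases(ev8, gates)
    fr96 <- classify_phases(ev96, gates)
    d <- stage_dir("gate")
    tab <- rbind(data.frame(sample = "8h", phase = c("G0", "G1", "S", "G2M"),
                            fraction = phase_fractions(fr8)),
                 data.frame(sample = "96h",
                            phase = c("G0", "G1", "S", "G2M"),
                            fraction = phase_fractions(fr96)))
    outputs <- c(outputs, write_tsv(tab, file.path(d, "fractions.tsv")))
    results$gating <- list(gates = gates, fractions_8h = fr8,
                           fractions_96h = fr96)
  }

  if (st$linearity) {
    # intensity-vs-cells series per cell line, blanks pinning the intercept
    set.seed(config$seed + 2L)
    lv <- config$totals * c(0.2, 0.4, 0.6, 0.8, 1.0)
    long <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(k) {
      a <- truth$alpha_P[, k]
      do.call(rbind, lapply(c(0, lv), function(n) {
        mu <- a * n + rep_len(config$background, config$n_ions)
        data.frame(ion = truth$ions$ion,
                   cell_line = conditions$cell_line[k], n_cells = n,
                   intensity = mu * stats::rlnorm(config$n_ions, 0,
                                                  sqrt(log(1 +
                                                    config$noise_cv^2))))
      }))
    }))
    filt <- biological_origin_filter(long, alpha_fw = config$alpha_fw)
    d <- stage_dir("linearity")
    outputs <- c(outputs, write_tsv(filt$report,
                                    file.path(d, "ion_filter.tsv")))
    results$filter <- filt
    keep <- filt$report$ion[filt$report$retained]
  } else keep <- truth$ions$ion

  if (st$deconvolve) {
    idx <- match(keep, truth$ions$ion)
    sub <- exper$intensities$intensity[, idx, drop = FALSE]
    fit <- fit_alphas(sub, exper$design,
                      background = rep_len(config$background,
                                           config$n_ions)[idx])
    fit <- bootstrap_errors(fit, n_reps = config$bootstrap_reps,
                            seed = config$seed + 3L)
    d <- stage_dir("deconvolve")
    outputs <- c(outputs, write_tsv(fit$coefficients,
                                    file.path(d, "coefficients.tsv")))
    results$fit <- fit
  }

  if (st$effects && st$deconvolve) {
    eff <- effect_size_table(results$fit)
    d <- stage_dir("effects")
    outputs <- c(outputs, write_tsv(eff, file.path(d, "effects.tsv")))
    results$effects <- eff
  }

  if (st$associate && st$effects && st$deconvolve) {
    assoc <- g0_association(results$effects,
                            thresholds = config$threshold_grid)
    d <- stage_dir("associate")
    outputs <- c(outputs, write_tsv(assoc, file.path(d, "association.tsv")))
    results$association <- assoc
  }

  if (st$growth) {
    curve <- simulate_confluence_curve(0.1, 0.012, lag = 24, t_max = 96)
    rates <- moving_window_rates(curve, config$window_hours,
                                 config$shift_hours)
    lag <- lag_time(curve, rates)
    d <- stage_dir("growth")
    outputs <- c(outputs, write_tsv(rates, file.path(d, "rates.tsv")),
                 write_tsv(data.frame(lag_time = lag$lag_time,
                                      max_rate = lag$max_rate),
                           file.path(d, "lag.tsv")))
    results$growth <- list(rates = rates, lag = lag)
  }

  if (st$annotate) {
    refs <- derivatize_keto_acids(read_reference_masses(
      system.file("extdata", "reference_metabolites.tsv",
                  package = "mixdeconv")))
    ann <- annotate_ions(stats::setNames(truth$ions$mz, truth$ions$ion),
                         refs, tolerance = config$tolerance)
    d <- stage_dir("annotate")
    outputs <- c(outputs, write_tsv(ann, file.path(d, "annotation.tsv")))
    results$annotation <- ann
  }

  manifest <- list(
    package = "mixdeconv",
    version = as.character(utils::packageVersion("mixdeconv")),
    config = unclass(config),
    outputs = lapply(stats::setNames(outputs,
                                     sub(paste0("^", out_dir, "/?"), "",
                                         outputs)),
                     function(f) unname(tools::md5sum(f))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest_path <- manifest_path
  invisible(results)
}

#' Read a YAML pipeline configuration
#'
#' Thin wrapper turning a YAML file into a validated [pipeline_config()];
#' unknown keys are rejected.
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}
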