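#' Measurement model for synthetic FIA-TOFMS intensities
#'
#' Bundles the instrument-side parameters used by every simulator: the
#' ion-specific background intensity added to each measurement, a
#' multiplicative log-normal noise term (parameterized by its coefficient of
#' variation, dominant at high signal), an additive Gaussian noise floor
#' (dominant near the detection limit), and an optional hard saturation clip
#' above which further concentration increases yield no intensity increase.
#'
#' @param background non-negative numeric vector, per-ion background
#'   intensity (recycled across ions as needed).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise (>= 0; 0 disables).
#' @param noise_floor_sd standard deviation of additive Gaussian noise
#'   (intensity units, >= 0; 0 disables).
#' @param saturation per-ion saturation intensity; `Inf` for unbounded.
#'   When bounded it must be at least as large as every background value.
#' @param seed integer seed used by simulators drawing from this model;
#'   `NULL` leaves the RNG state untouched.
#' @return object of class `measurement_model`.
#' @export
measurement_model <- function(background = 0, noise_cv = 0,
                              noise_floor_sd = 0, saturation = Inf,
                              seed = NULL) {
  stopifnot(all(background >= 0), length(noise_cv) == 1L, noise_cv >= 0,
            length(noise_floor_sd) == 1L, noise_floor_sd >= 0,
            all(saturation > 0))
  if (any(is.finite(saturation)) &&
      any(rep_len(saturation, max(length(saturation), length(background))) <
          rep_len(background, max(length(saturation), length(background)))))
    stop("saturation must be >= every background value")
  structure(list(background = background, noise_cv = noise_cv,
                 noise_floor_sd = noise_floor_sd, saturation = saturation,
                 seed = seed),
            class = "measurement_model")
}

# Apply the model's noise and clipping to a matrix of expected intensities.
# Multiplicative noise is mean-preserving (log-normal with unit mean), so the
# average of many noisy replicates converges to the noise-free expectation.
apply_ms_noise <- function(mu, model) {
  out <- mu
  if (model$noise_cv > 0) {
    sdlog <- sqrt(log(1 + model$noise_cv^2))
    out <- out * matrix(stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2,
                                      sdlog = sdlog),
                        nrow = nrow(mu))
  }
  if (model$noise_floor_sd > 0)
    out <- out + matrix(stats::rnorm(length(mu), sd = model$noise_floor_sd),
                        nrow = nrow(mu))
  sat <- matrix(rep(rep_len(model$saturation, ncol(mu)), each = nrow(mu)),
                nrow = nrow(mu))
  pmin(pmax(out, 0), sat)
}

#' Ground-truth per-cell abundance profiles
#'
#' Creates the true per-cell ion abundances of the quiescent (Q) and
#' proliferating (P) subpopulations for each experimental condition
#' (cell line x stimulus). Abundances are drawn log-normally around a common
#' per-ion baseline, with a configurable fraction of ions carrying a planted
#' Q-vs-P fold-change, so downstream recovery can be scored against a known
#' truth.
#'
#' @param n_ions number of ions.
#' @param conditions data.frame with columns `cell_line` and `stimulus`
#'   (one row per condition); default a single condition.
#' @param mean_log10_alpha,sd_log10_alpha location/spread (log10) of the
#'   per-ion baseline per-cell abundance.
#' @param frac_differential fraction of ions given a planted Q/P difference.
#' @param effect_log2 magnitude (log2) of the planted difference; the sign is
#'   randomized per ion and shared across conditions.
#' @param seed integer seed.
#' @return object of class `population_truth`: list with matrices `alpha_P`,
#'   `alpha_Q` (ions x conditions), `ions` and `conditions` data.frames, and
#'   the logical vector `differential`.
#' @export
true_population_profile <- function(n_ions, conditions = NULL,
                                    mean_log10_alpha = 0,
                                    sd_log10_alpha = 0.5,
                                    frac_differential = 0.3,
                                    effect_log2 = 1, seed = 1L) {
  if (is.null(conditions))
    conditions <- data.frame(cell_line = "CL1", stimulus = "starvation")
  stopifnot(n_ions >= 1, all(c("cell_line", "stimulus") %in%
                               names(conditions)))
  set.seed(seed)
  n_cond <- nrow(conditions)
  base <- 10^stats::rnorm(n_ions, mean_log10_alpha, sd_log10_alpha)
  alpha_P <- matrix(rep(base, n_cond), ncol = n_cond) *
    10^matrix(stats::rnorm(n_ions * n_cond, 0, 0.05), ncol = n_cond)
  differential <- seq_len(n_ions) <= round(frac_differential * n_ions)
  sign <- sample(c(-1, 1), n_ions, replace = TRUE)
  shift <- ifelse(differential, 2^(sign * effect_log2), 1)
  alpha_Q <- alpha_P * shift
  ion <- sprintf("ion%04d", seq_len(n_ions))
  dimnames(alpha_P) <- dimnames(alpha_Q) <-
    list(ion, paste(conditions$cell_line, conditions$stimulus, sep = "."))
  structure(list(alpha_P = alpha_P, alpha_Q = alpha_Q,
                 ions = data.frame(ion = ion,
                                   mz = round(stats::runif(n_ions, 80, 900),
                                              4)),
                 conditions = conditions, differential = differential),
            class = "population_truth")
}

#' Container for a samples-by-ions intensity table
#'
#' @param intensity numeric matrix, samples in rows, ions in columns.
#' @param samples data.frame of per-sample metadata (one row per matrix row).
#' @param ions data.frame of per-ion metadata (one row per matrix column),
#'   must contain an `ion` column.
#' @return object of class `ion_table`.
#' @export
ion_table <- function(intensity, samples, ions) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(intensity) == nrow(samples),
            ncol(intensity) == nrow(ions), "ion" %in% names(ions))
  colnames(intensity) <- ions$ion
  structure(list(intensity = intensity, samples = samples, ions = ions),
            class = "ion_table")
}

#' @export
print.ion_table <- function(x, ...) {
  cat("ion_table:", nrow(x$intensity), "samples x", ncol(x$intensity),
      "ions\n")
  invisible(x)
}

#' Simulate a mixed-extract deconvolution experiment
#'
#' Generates bulk intensities for the full mixing design: extracts taken at
#' the early (8 h, proliferation-enriched) and late (96 h, G0-enriched) end
#' points are mixed at defined ratios, so each mix sample contains known
#' numbers of quiescent (`N_Q`) and non-quiescent (`N_P`) cells. Each ion's
#' expected intensity follows the linear mixture model
#' `I = alpha_P * N_P * V_P + alpha_Q * N_Q * V_Q + beta`, then noise and
#' saturation from `model` are applied.
#'
#' @param truth a [true_population_profile()] object.
#' @param totals total cells per mix sample (constant across mixes within a
#'   condition; scalar or one value per condition).
#' @param fractions mixing fractions of the 8-h extract, in `[0, 1]`;
#'   default the eight-point design `1.00, 0.85, ..., 0.10, 0.00`.
#' @param g0_at_8h,g0_at_96h G0 fraction measured in the 8-h and 96-h
#'   end-point cultures (scalar or per condition), in `[0, 1]`.
#' @param replicates independent replicate mixes per condition.
#' @param model a [measurement_model()].
#' @param volumes per-population relative cell volumes `c(P = , Q = )`.
#' @return object of class `synthetic_experiment`: list with `truth`,
#'   `design` (see [build_mix_design()]), `intensities` (an [ion_table()])
#'   and `model`.
#' @export
simulate_mix_experiment <- function(truth, totals = 1e4,
                                    fractions = mixing_fractions(),
                                    g0_at_8h = 0.2, g0_at_96h = 0.6,
                                    replicates = 3,
                                    model = measurement_model(),
                                    volumes = c(P = 1, Q = 1)) {
  stopifnot(inherits(truth, "population_truth"),
            all(fractions >= 0 & fractions <= 1),
            all(g0_at_8h >= 0 & g0_at_8h <= 1),
            all(g0_at_96h >= 0 & g0_at_96h <= 1), all(totals > 0))
  if (any(truth$alpha_P < 0) || any(truth$alpha_Q < 0))
    stop("true abundances must be non-negative")
  design <- build_mix_design(totals = totals, fractions = fractions,
                             g0_fraction_8h = g0_at_8h,
                             g0_fraction_96h = g0_at_96h,
                             conditions = truth$conditions,
                             replicates = replicates, volumes = volumes)
  n_ions <- nrow(truth$ions)
  cond_key <- paste(design$cell_line, design$stimulus, sep = ".")
  cond_idx <- match(cond_key, colnames(truth$alpha_P))
  mu <- t(truth$alpha_P)[cond_idx, , drop = FALSE] *
    (design$n_p * design$v_p) +
    t(truth$alpha_Q)[cond_idx, , drop = FALSE] * (design$n_q * design$v_q)
  mu <- mu + matrix(rep(rep_len(model$background, n_ions),
                        each = nrow(design)), nrow = nrow(design))
  if (!is.null(model$seed)) set.seed(model$seed)
  intensity <- apply_ms_noise(mu, model)
  rownames(intensity) <- design$sample_id
  structure(list(truth = truth, design = design,
                 intensities = ion_table(intensity, design, truth$ions),
                 model = model),
            class = "synthetic_experiment")
}

#' The eight-point extract mixing design
#'
#' Fractions of the early (8-h) extract used when preparing mixed samples:
#' 100, 85, 70, 55, 40, 25, 10 and 0 percent.
#' @return numeric vector of length 8.
#' @export
mixing_fractions <- function() c(1.00, 0.85, 0.70, 0.55, 0.40, 0.25, 0.10, 0)

#' Log-spaced spike amounts spanning three decades
#'
#' Default grid emulating a spike-in series from 3 pmol to 3 nmol.
#' @param n number of levels.
#' @param from,to range in pmol.
#' @return numeric vector of spike amounts (pmol), strictly increasing.
#' @export
default_spike_amounts <- function(n = 7, from = 3, to = 3000)
  10^seq(log10(from), log10(to), length.out = n)

#' Simulate a spike-in linearity series
#'
#' Emulates supplementing a cell-extract matrix with increasing amounts of
#' pure standards: each ion responds linearly
#' (`intensity = base + slope * spike`) until the saturation limit of the
#' measurement model clips the signal.
#'
#' @param base_extract_levels per-ion intensity of the unspiked extract
#'   (becomes the intercept).
#' @param spike_amounts strictly increasing, non-negative spike amounts; a
#'   zero first level reproduces the unspiked extract.
#' @param response_slope per-ion intensity increase per unit spike.
#' @param model a [measurement_model()] (its `background` is ignored here:
#'   the base extract level already plays the intercept role).
#' @param replicates replicate injections per spike level.
#' @return an [ion_table()]; `samples` has columns `spike` and `replicate`.
#' @export
simulate_spikein_series <- function(base_extract_levels,
                                    spike_amounts = default_spike_amounts(),
                                    response_slope = 1,
                                    model = measurement_model(),
                                    replicates = 3) {
  if (any(diff(spike_amounts) <= 0) || any(spike_amounts < 0))
    stop("spike_amounts must be non-negative and strictly increasing")
  n_ions <- max(length(base_extract_levels), length(response_slope))
  base <- rep_len(base_extract_levels, n_ions)
  slope <- rep_len(response_slope, n_ions)
  samples <- data.frame(spike = rep(spike_amounts, each = replicates),
                        replicate = rep(seq_len(replicates),
                                        length(spike_amounts)))
  samples$sample_id <- sprintf("spike%02d_r%d",
                               rep(seq_along(spike_amounts),
                                   each = replicates), samples$replicate)
  mu <- outer(samples$spike, slope) +
    matrix(rep(base, each = nrow(samples)), nrow = nrow(samples))
  if (!is.null(model$seed)) set.seed(model$seed)
  intensity <- apply_ms_noise(mu, model)
  ions <- data.frame(ion = sprintf("ion%04d", seq_len(n_ions)),
                     mz = NA_real_)
  ion_table(intensity, samples, ions)
}

#' Simulate DNA/RNA co-staining cytometry events
#'
#' Draws single-cell events emulating Hoechst (DNA) and Pyronin-Y (RNA)
#' staining of a culture with known cell-cycle composition. G0 and G1 events
#' sit at the 2n DNA peak, G2/M at the 4n peak (twice the G1 location), and
#' S-phase events are spread uniformly across the interior of the 2n-4n gap
#' (a margin keeps the S cloud off the peak windows so the clouds are
#' separable). Both channels carry log-normal spread; G0 events have a
#' distinctly lower RNA location than the proliferating phases. Ground-truth
#' labels are always stored.
#'
#' @param n_events number of events (>= 1).
#' @param phase_fractions named fractions over `G0, G1, S, G2M`, summing to 1
#'   (within 1e-9).
#' @param dna_peak_g1 DNA-channel location of the 2n peak.
#' @param rna_location named per-phase RNA-channel locations; the G0 value
#'   must be the smallest.
#' @param rna_scale,dna_scale log-normal `sdlog` of the two channels (> 0).
#' @param s_margin fraction of the 2n-4n gap kept free of S events on each
#'   side.
#' @param seed integer seed.
#' @return data.frame of class `event_table` with columns `dna`, `rna`,
#'   `label`.
#' @export
simulate_cytometry_events <- function(n_events,
                                      phase_fractions = c(G0 = 0.4, G1 = 0.3,
                                                          S = 0.2,
                                                          G2M = 0.1),
                                      dna_peak_g1 = 100,
                                      rna_location = c(G0 = 25, G1 = 200,
                                                       S = 200, G2M = 210),
                                      rna_scale = 0.15, dna_scale = 0.04,
                                      s_margin = 0.2, seed = 1L) {
  phases <- c("G0", "G1", "S", "G2M")
  stopifnot(n_events >= 1, all(phases %in% names(phase_fractions)),
            abs(sum(phase_fractions) - 1) <= 1e-9,
            all(phase_fractions >= 0))
  if (rna_scale <= 0 || dna_scale <= 0)
    stop("scale parameters must be > 0")
  if (rna_location[["G0"]] >= min(rna_location[c("G1", "S", "G2M")]))
    stop("G0 RNA location must lie strictly below the other phases")
  set.seed(seed)
  label <- sample(phases, n_events, replace = TRUE,
                  prob = phase_fractions[phases])
  g1 <- dna_peak_g1
  g2m <- 2 * dna_peak_g1
  dna_base <- numeric(n_events)
  dna_base[label %in% c("G0", "G1")] <- g1
  dna_base[label == "G2M"] <- g2m
  ns <- sum(label == "S")
  gap <- g2m - g1
  dna_base[label == "S"] <- stats::runif(ns, g1 + s_margin * gap,
                                         g2m - s_margin * gap)
  dna <- dna_base * stats::rlnorm(n_events, 0, dna_scale)
  rna <- stats::rlnorm(n_events,
                       meanlog = log(rna_location[label]),
                       sdlog = rna_scale)
  out <- data.frame(dna = dna, rna = rna, label = label)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Simulate a confluence time series with a growth lag
#'
#' Confluence stays at its initial value during the lag, then grows
#' exponentially (`c0 * 10^(rate * (t - lag))`) until capped at the plateau;
#' optional additive Gaussian noise is applied afterwards and the series is
#' clamped to `[0, 1]`.
#'
#' @param c0 initial confluence, `0 < c0 < plateau`.
#' @param rate exponential growth rate (log10 confluence per hour).
#' @param lag lag duration in hours.
#' @param t_max,dt time span and sampling interval in hours (default 1.5-h
#'   imaging interval).
#' @param noise_sd additive noise SD (confluence units).
#' @param plateau maximal confluence, `<= 1`.
#' @param replicate replicate identifier stored with the curve.
#' @return data.frame of class `confluence_curve` with columns `time_h`,
#'   `confluence`, `replicate`.
#' @export
simulate_confluence_curve <- function(c0, rate, lag = 0, t_max = 96,
                                      dt = 1.5, noise_sd = 0, plateau = 1,
                                      replicate = 1L) {
  stopifnot(c0 > 0, c0 < plateau, plateau <= 1, dt > 0, lag >= 0,
            noise_sd >= 0)
  time_h <- seq(0, t_max, by = dt)
  conf <- ifelse(time_h < lag, c0,
                 pmin(plateau, c0 * 10^(rate * (time_h - lag))))
  if (noise_sd > 0)
    conf <- pmin(pmax(conf + stats::rnorm(length(conf), sd = noise_sd), 0), 1)
  out <- data.frame(time_h = time_h, confluence = conf,
                    replicate = replicate)
  class(out) <- c("confluence_curve", "data.frame")
  out
}
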