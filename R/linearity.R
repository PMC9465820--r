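#' Detect the saturation limit of a spike-in response
#'
#' Scans a concentration-response series for the intensity above which
#' further spiking no longer increases the measured signal. Replicate
#' intensities are averaged per spike level, successive-difference slopes are
#' normalized by the initial-region slope (OLS on the first three levels),
#' and the limit is the lowest mean intensity from which the relative slope
#' stays below `rel_slope_cutoff` for all subsequent intervals. A series
#' whose relative slope never collapses is unbounded (`Inf`); a series with
#' non-positive initial slope is non-responsive.
#'
#' @param spike spike amounts (any units), with `>= 5` distinct increasing
#'   levels.
#' @param intensity measured intensities (same length; replicates allowed as
#'   repeated `spike` values).
#' @param rel_slope_cutoff relative-slope cutoff (default 0.1).
#' @return list with `limit` (intensity; `Inf` if unbounded, `NA` if
#'   non-responsive), `non_responsive`, `saturated` (logical per input
#'   point: at/above the limit), and `initial_slope`.
#' @export
detect_saturation_limit <- function(spike, intensity,
                                    rel_slope_cutoff = 0.1) {
  stopifnot(length(spike) == length(intensity))
  lv <- sort(unique(spike))
  if (length(lv) < 5) stop("need >= 5 distinct spike levels")
  ybar <- vapply(lv, function(s) mean(intensity[spike == s]), numeric(1))
  init <- stats::coef(stats::lm(ybar[1:3] ~ lv[1:3]))[2]
  essentially_flat <- diff(range(ybar)) <= 1e-9 * max(abs(ybar), 1)
  if (!is.finite(init) || init <= 0 || essentially_flat)
    return(list(limit = NA_real_, non_responsive = TRUE,
                saturated = rep(FALSE, length(spike)),
                initial_slope = unname(init)))
  rel <- diff(ybar) / diff(lv) / init
  flat_from <- NA_integer_
  for (j in seq_along(rel)) {
    if (all(rel[j:length(rel)] < rel_slope_cutoff)) { flat_from <- j; break }
  }
  if (is.na(flat_from)) {
    return(list(limit = Inf, non_responsive = FALSE,
                saturated = rep(FALSE, length(spike)),
                initial_slope = unname(init)))
  }
  limit <- ybar[flat_from]
  list(limit = limit, non_responsive = FALSE,
       saturated = intensity >= limit, initial_slope = unname(init))
}

#' Fit the base linear spike-response model
#'
#' Ordinary least squares of intensity on spike amount, after removing
#' saturated points; the slope captures the response per unit spiked amount
#' and the intercept the basal abundance of the compound in the extract
#' matrix.
#'
#' @param spike,intensity the series (replicates allowed).
#' @param saturation intensity saturation limit; points at/above it are
#'   dropped (default `Inf`: auto-detect with [detect_saturation_limit()]
#'   when `>= 5` levels are present, otherwise keep all).
#' @return list of class `linear_fit`: `slope`, `intercept`, `p_value`
#'   (two-sided, slope), `r_squared`, `saturation_limit`, `n_points_used`.
#'   Errors if fewer than 3 unsaturated points remain or the design is
#'   rank-deficient (a single distinct spike level).
#' @export
fit_base_model <- function(spike, intensity, saturation = NULL) {
  stopifnot(length(spike) == length(intensity))
  if (is.null(saturation)) {
    saturation <- if (length(unique(spike)) >= 5)
      detect_saturation_limit(spike, intensity)$limit else Inf
    if (is.na(saturation)) saturation <- Inf
  }
  keep <- intensity < saturation
  x <- spike[keep]
  y <- intensity[keep]
  if (length(x) < 3) stop("fewer than 3 unsaturated points: fit refused")
  if (length(unique(x)) < 2)
    stop("rank-deficient design (single spike level): fit refused")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = sm$coefficients[2, 4],
                 r_squared = sm$r.squared,
                 saturation_limit = saturation,
                 n_points_used = length(x)),
            class = "linear_fit")
}

#' Cross-matrix goodness of fit with a fixed slope
#'
#' Tests whether the base model's slope transfers to another sample matrix:
#' the intercept is refit by least squares (its optimum is the mean of
#' `intensity - slope * spike`) while the slope stays at the base value,
#' and the returned value is `1 - SS_resid / SS_total` on the other matrix.
#' It can be negative when the fixed slope fits worse than a constant, and
#' is invariant to adding any constant to the other matrix's intensities.
#'
#' @param base a `linear_fit` from [fit_base_model()].
#' @param spike,intensity the other matrix's series.
#' @return list with `r_squared` (`NA` if the other matrix has zero total
#'   variance) and `intercept` (the refit value).
#' @export
cross_matrix_r2 <- function(base, spike, intensity) {
  stopifnot(inherits(base, "linear_fit"), is.finite(base$slope))
  intercept <- mean(intensity - base$slope * spike)
  pred <- intercept + base$slope * spike
  ss_tot <- sum((intensity - mean(intensity))^2)
  if (ss_tot == 0)
    return(list(r_squared = NA_real_, intercept = intercept))
  list(r_squared = 1 - sum((intensity - pred)^2) / ss_tot,
       intercept = intercept)
}

#' Filter ions to those of likely biological origin
#'
#' During steady-state growth an intracellular metabolite's ion intensity
#' scales linearly with the number of cells extracted. Per ion, a stacked
#' regression with one cell-line-specific slope per cell line and a single
#' shared intercept (pinned by blank rows with zero cells) is fit; the ion
#' is retained when its smallest slope p-value across cell lines falls below
#' the Bonferroni threshold `alpha_fw / (n_ions * n_cell_lines)`.
#'
#' @param data long data.frame with columns `ion`, `cell_line`, `n_cells`
#'   and `intensity`. Blank samples are rows with `n_cells == 0` (their
#'   `cell_line` value is irrelevant); they are required, as they pin the
#'   shared intercept. Each cell line needs `>= 3` biomass levels.
#' @param alpha_fw family-wise alpha (default 0.05).
#' @param n_ions number of ions in the family (default: ions present in
#'   `data`; pass the full annotation count when filtering a subset).
#' @return list of class `ion_filter_report`: data.frame `report` (`ion`,
#'   `best_p_value`, `retained`), `threshold`, `n_ions`, `n_cell_lines`.
#' @export
biological_origin_filter <- function(data, alpha_fw = 0.05, n_ions = NULL) {
  stopifnot(all(c("ion", "cell_line", "n_cells", "intensity") %in%
                  names(data)))
  if (!any(data$n_cells == 0))
    stop("no blank samples (n_cells == 0): shared intercept undefined")
  lines <- sort(unique(data$cell_line[data$n_cells > 0]))
  ions <- unique(data$ion)
  if (is.null(n_ions)) n_ions <- length(ions)
  threshold <- bonferroni_threshold(alpha_fw, n_ions, length(lines))
  for (cl in lines) {
    lv <- unique(data$n_cells[data$cell_line == cl & data$n_cells > 0])
    if (length(lv) < 3)
      stop("cell line ", cl, " has fewer than 3 biomass levels")
  }
  best_p <- vapply(ions, function(i) {
    d <- data[data$ion == i, ]
    cl <- factor(ifelse(d$n_cells == 0, lines[1], as.character(d$cell_line)),
                 levels = lines)
    fit <- stats::lm(intensity ~ n_cells:cl, data = data.frame(
      intensity = d$intensity, n_cells = d$n_cells, cl = cl))
    sm <- summary(fit)$coefficients
    slopes <- grep("^n_cells:", rownames(sm))
    if (length(slopes) == 0) return(NA_real_)
    min(sm[slopes, 4], na.rm = TRUE)
  }, numeric(1))
  structure(list(report = data.frame(ion = ions, best_p_value = best_p,
                                     retained = !is.na(best_p) &
                                       best_p < threshold),
                 threshold = threshold, n_ions = n_ions,
                 n_cell_lines = length(lines)),
            class = "ion_filter_report")
}

#' Bonferroni threshold for the biological-origin filter
#'
#' Family-wise alpha divided by the number of ions times the number of cell
#' lines; with 2,099 annotated ions across 6 cell lines and alpha 0.05 this
#' gives 3.97e-06.
#'
#' @param alpha_fw family-wise alpha.
#' @param n_ions,n_cell_lines family size factors.
#' @return the per-test p-value threshold.
#' @export
bonferroni_threshold <- function(alpha_fw = 0.05, n_ions = 2099,
                                 n_cell_lines = 6) {
  stopifnot(alpha_fw > 0, n_ions >= 1, n_cell_lines >= 1)
  alpha_fw / (n_ions * n_cell_lines)
}
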