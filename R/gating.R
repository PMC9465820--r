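#' Freedman-Diaconis bin width
#' @noRd
fd_binwidth <- function(x) {
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) h <- diff(range(x)) / max(1, ceiling(sqrt(length(x))))
  h
}

#' Pick the 2n (G1) and 4n (G2/M) DNA-content peaks
#'
#' Locates the two most prominent modes of a kernel-smoothed DNA-intensity
#' histogram whose ratio falls inside the expected 4n/2n band. The kernel
#' bandwidth equals the Freedman-Diaconis bin width, so the peak locations
#' are scale-equivariant. If only one acceptable peak is found, the 4n peak
#' is set to twice the 2n peak and flagged.
#'
#' @param events data.frame with a `dna` column (an
#'   [simulate_cytometry_events()] table, or anything with finite,
#'   non-negative `dna` values).
#' @param ratio_band acceptable `g2m / g1` interval (default `c(1.7, 2.3)`).
#' @param min_events minimum number of events required.
#' @return list with `g1_peak`, `g2m_peak`, `fallback` (TRUE when the 4n
#'   peak was imputed as `2 * g1`) and `bandwidth`.
#' @export
pick_dna_peaks <- function(events, ratio_band = c(1.7, 2.3),
                           min_events = 1000) {
  dna <- events$dna
  stopifnot(all(is.finite(dna)), all(dna >= 0))
  if (length(dna) < min_events)
    stop("need at least ", min_events, " events to gate the DNA channel")
  bw <- fd_binwidth(dna)
  d <- stats::density(dna, bw = bw, n = 1024)
  y <- d$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  peaks <- data.frame(x = d$x[is_max], h = y[is_max])
  if (nrow(peaks) == 0)
    stop("no detectable peak in the DNA channel")
  peaks <- peaks[order(-peaks$h), ]
  anchor <- peaks$x[1]
  partner <- NA_real_
  if (nrow(peaks) > 1) {
    ratio <- peaks$x[-1] / anchor
    ok <- (ratio >= ratio_band[1] & ratio <= ratio_band[2]) |
      (1 / ratio >= ratio_band[1] & 1 / ratio <= ratio_band[2])
    if (any(ok)) partner <- peaks$x[-1][which(ok)[1]]
  }
  if (is.na(partner)) {
    g1 <- anchor
    g2m <- 2 * anchor
    fallback <- TRUE
    warning("only one DNA peak found; assuming 4n = 2 x 2n")
  } else {
    g1 <- min(anchor, partner)
    g2m <- max(anchor, partner)
    fallback <- FALSE
  }
  list(g1_peak = g1, g2m_peak = g2m, fallback = fallback, bandwidth = bw)
}

#' Derive cell-cycle gates from a reference event table
#'
#' Builds the DNA windows around the 2n and 4n peaks (half-width `k` robust
#' SDs of the respective mode) and the RNA threshold separating G0 from G1:
#' the `rna_quantile` percentile of RNA intensity among events inside the
#' S/G2M DNA region, i.e. the lower envelope of the proliferating-cell RNA
#' distribution.
#'
#' @param events reference event table (typically the 8-h sample, which
#'   contains all proliferating phases).
#' @param k DNA-window half-width in robust-SD units (default 2.5).
#' @param rna_quantile percentile defining the RNA threshold (default 0.05).
#' @param ratio_band,min_events passed to [pick_dna_peaks()].
#' @return list of class `cycle_gates`: `g1_peak`, `g2m_peak`, `g1_halfwidth`,
#'   `g2m_halfwidth`, `rna_threshold`, `fallback`.
#' @export
derive_gates <- function(events, k = 2.5, rna_quantile = 0.05,
                         ratio_band = c(1.7, 2.3), min_events = 1000) {
  pk <- pick_dna_peaks(events, ratio_band = ratio_band,
                       min_events = min_events)
  dna <- events$dna
  robust_sd <- function(center) {
    v <- dna[dna >= 0.9 * center & dna <= 1.1 * center]
    s <- stats::mad(v, center = center)
    if (!is.finite(s) || s == 0) s <- 0.05 * center
    s
  }
  s1 <- robust_sd(pk$g1_peak)
  s2 <- robust_sd(pk$g2m_peak)
  g1_hw <- k * s1
  g2m_hw <- k * s2
  in_s_g2m <- dna > pk$g1_peak + g1_hw & dna <= pk$g2m_peak + g2m_hw
  # a handful of stray 2n-tail events must not stand in for the
  # proliferating RNA distribution
  if (sum(in_s_g2m) < max(20, 0.01 * length(dna)))
    stop("no (or too few) events in the S/G2M DNA region of the reference ",
         "sample: RNA threshold underivable")
  thr <- stats::quantile(events$rna[in_s_g2m], rna_quantile, names = FALSE)
  structure(list(g1_peak = pk$g1_peak, g2m_peak = pk$g2m_peak,
                 g1_halfwidth = g1_hw, g2m_halfwidth = g2m_hw,
                 rna_threshold = thr, fallback = pk$fallback),
            class = "cycle_gates")
}

#' Classify events into G0, G1, S and G2/M and compute phase fractions
#'
#' Events inside the 2n DNA window with RNA below the threshold are G0
#' (2n DNA, low RNA content); inside the 2n window with RNA at/above the
#' threshold, G1; strictly between the 2n and 4n windows, S; inside the 4n
#' window, G2/M. Events outside all windows are counted as unclassified and
#' excluded from the fractions. Gates are derived from the data itself
#' (`gates = "derive"`) or reused from a reference sample, following the
#' reference-gating scheme where gates defined on the early (8-h) sample of
#' a cell line are applied to its late (96-h) sample.
#'
#' @param events event table with `dna` and `rna` columns.
#' @param gates `"derive"` or a `cycle_gates` object from [derive_gates()].
#' @param ... passed to [derive_gates()] when deriving.
#' @return list of class `cell_cycle_fractions`: `fractions` (named vector
#'   over G0/G1/S/G2M summing to 1), `counts`, `n_unclassified`, `gates`,
#'   and the per-event `phase` factor (`NA` = unclassified).
#' @export
classify_phases <- function(events, gates = "derive", ...) {
  if (identical(gates, "derive")) gates <- derive_gates(events, ...)
  stopifnot(inherits(gates, "cycle_gates"))
  dna <- events$dna
  rna <- events$rna
  lo1 <- gates$g1_peak - gates$g1_halfwidth
  hi1 <- gates$g1_peak + gates$g1_halfwidth
  lo2 <- gates$g2m_peak - gates$g2m_halfwidth
  hi2 <- gates$g2m_peak + gates$g2m_halfwidth
  phase <- rep(NA_character_, length(dna))
  in1 <- dna >= lo1 & dna <= hi1
  phase[in1 & rna < gates$rna_threshold] <- "G0"
  phase[in1 & rna >= gates$rna_threshold] <- "G1"
  phase[dna > hi1 & dna < lo2] <- "S"
  phase[dna >= lo2 & dna <= hi2] <- "G2M"
  phase <- factor(phase, levels = c("G0", "G1", "S", "G2M"))
  counts <- table(phase)
  n_cl <- sum(counts)
  if (n_cl == 0) stop("no events fall inside the gates")
  structure(list(fractions = as.numeric(counts) / n_cl,
                 counts = as.integer(counts),
                 n_unclassified = sum(is.na(phase)),
                 gates = gates, phase = phase),
            class = "cell_cycle_fractions")
}

#' @export
print.cell_cycle_fractions <- function(x, ...) {
  f <- x$fractions
  names(f) <- c("G0", "G1", "S", "G2M")
  print(round(f, 3))
  cat(x$n_unclassified, "events unclassified\n")
  invisible(x)
}

#' Named phase fractions from a classification
#' @param x a `cell_cycle_fractions` object.
#' @return named numeric vector over `G0, G1, S, G2M`.
#' @export
phase_fractions <- function(x) {
  stopifnot(inherits(x, "cell_cycle_fractions"))
  stats::setNames(x$fractions, c("G0", "G1", "S", "G2M"))
}
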