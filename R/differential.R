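#' Standardized effect size between quiescent and proliferating coefficients
#'
#' `d = (alpha_Q - alpha_P) / sqrt((sd_P^2 + sd_Q^2) / 2)`: the difference in
#' per-cell abundance between the G0 and non-G0 subpopulations of one
#' condition, standardized to the pooled bootstrap SD. Negative values mean
#' lower abundance in quiescent cells. Entries with zero pooled SD are
#' undefined (`NA`) and excluded downstream.
#'
#' @param alpha_Q,alpha_P coefficient estimates (vectorized).
#' @param sd_Q,sd_P their bootstrap SDs (>= 0).
#' @return numeric vector of effect sizes.
#' @export
effect_size <- function(alpha_Q, alpha_P, sd_Q, sd_P) {
  stopifnot(all(sd_Q >= 0, na.rm = TRUE), all(sd_P >= 0, na.rm = TRUE))
  pooled <- sqrt((sd_P^2 + sd_Q^2) / 2)
  out <- (alpha_Q - alpha_P) / pooled
  out[pooled == 0] <- NA_real_
  out
}

#' Effect-size table from a fitted population profile
#'
#' Pairs each condition's P and Q coefficients and applies [effect_size()].
#'
#' @param profile a bootstrapped `population_profile` (see
#'   [bootstrap_errors()]).
#' @return data.frame with columns `ion`, `cell_line`, `stimulus`, `d`,
#'   `pooled_sd`.
#' @export
effect_size_table <- function(profile) {
  co <- profile$coefficients
  if (all(is.na(co$sd)))
    stop("profile has no bootstrap SDs; run bootstrap_errors() first")
  p <- co[co$population == "P", ]
  q <- co[co$population == "Q", ]
  q <- q[match(paste(p$ion, p$cell_line, p$stimulus, sep = "\r"),
               paste(q$ion, q$cell_line, q$stimulus, sep = "\r")), ]
  data.frame(ion = p$ion, cell_line = p$cell_line, stimulus = p$stimulus,
             d = effect_size(q$alpha, p$alpha, q$sd, p$sd),
             pooled_sd = sqrt((p$sd^2 + q$sd^2) / 2))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(total `n_total`, successes `n_success`,
#' draws `n_draw`).
#' @noRd
hyper_upper_tail <- function(k, n_success, n_total, n_draw) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, n_success, n_total - n_success, n_draw,
                lower.tail = FALSE)
}

#' Consistent quiescence association by iterative effect-size thresholding
#'
#' For each ion and each threshold `t` in the grid, the numbers of
#' conditions with `d > t` and with `d < -t` are counted and the sign with
#' the larger count is prioritized. The significance of that consistent
#' pattern is the upper-tail hypergeometric probability of drawing at least
#' as many threshold-passing entries when sampling the ion's number of
#' conditions at random from all same-sign effect sizes pooled over the
#' whole table. Per ion, the threshold giving the smallest p-value is
#' reported (ties resolved toward the smallest threshold), the association
#' is the signed fraction of conditions passing it, and Benjamini-Hochberg
#' correction is applied across ions at the end.
#'
#' @param effects an effect-size table from [effect_size_table()], or a
#'   numeric matrix (ions x conditions) of effect sizes.
#' @param thresholds threshold grid; default `3` to
#'   `max(3, ceiling(mean(|d|)))` in steps of 1 (the fixed grid `3:13` can
#'   be supplied directly).
#' @param draws `"conditions"` (default): the hypergeometric draw count is
#'   the ion's total number of conditions (18 in the full design), truncated
#'   to the pooled population size; `"same_sign"`: the ion's count of
#'   same-sign entries.
#' @return data.frame of class `g0_association`: `ion`, `direction`
#'   (`+1`/`-1`), `n_pass`, `n_conditions`, `g0_association` (signed
#'   fraction), `threshold`, `p_value`, `p_adjusted`, `tie_flag`.
#' @export
g0_association <- function(effects, thresholds = NULL,
                           draws = c("conditions", "same_sign")) {
  draws <- match.arg(draws)
  if (is.data.frame(effects)) {
    m <- tapply(effects$d,
                list(effects$ion,
                     paste(effects$cell_line, effects$stimulus, sep = ".")),
                function(v) v[1])
  } else m <- as.matrix(effects)
  if (is.null(thresholds)) {
    upper <- max(3, ceiling(mean(abs(m), na.rm = TRUE)))
    thresholds <- seq(3, upper)
  }
  pos_pool <- m[!is.na(m) & m > 0]
  neg_pool <- m[!is.na(m) & m < 0]
  n_cond <- ncol(m)
  ions <- rownames(m)
  if (is.null(ions)) ions <- sprintf("ion%04d", seq_len(nrow(m)))
  res <- data.frame(ion = ions, direction = NA_real_, n_pass = NA_integer_,
                    n_conditions = n_cond, g0_association = NA_real_,
                    threshold = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, tie_flag = FALSE)
  for (i in seq_len(nrow(m))) {
    di <- m[i, ]
    best <- list(p = Inf, t = NA, k = 0L, dir = 1, tie = FALSE)
    for (t in thresholds) {
      k_pos <- sum(di > t, na.rm = TRUE)
      k_neg <- sum(di < -t, na.rm = TRUE)
      tie <- FALSE
      if (k_pos > k_neg) dir <- 1
      else if (k_neg > k_pos) dir <- -1
      else {  # equal counts: take the sign with the larger summed |d|
        s_pos <- sum(di[!is.na(di) & di > t])
        s_neg <- sum(abs(di[!is.na(di) & di < -t]))
        dir <- if (s_pos >= s_neg) 1 else -1
        tie <- k_pos > 0
      }
      k <- if (dir > 0) k_pos else k_neg
      pool <- if (dir > 0) pos_pool else neg_pool
      n_total <- length(pool)
      if (n_total == 0) next
      n_success <- if (dir > 0) sum(pool > t) else sum(pool < -t)
      n_draw <- if (draws == "conditions")
        min(sum(!is.na(di)), n_total) else
        min(sum(!is.na(di) & sign(di) == dir), n_total)
      p <- hyper_upper_tail(k, n_success, n_total, n_draw)
      if (p < best$p - 1e-15 ||
          (abs(p - best$p) <= 1e-15 && !is.na(best$t) && t < best$t)) {
        best <- list(p = p, t = t, k = k, dir = dir, tie = tie)
      }
    }
    if (is.finite(best$p)) {
      res$direction[i] <- best$dir
      res$n_pass[i] <- best$k
      res$g0_association[i] <- best$dir * best$k / n_cond
      res$threshold[i] <- best$t
      res$p_value[i] <- best$p
      res$tie_flag[i] <- best$tie
    } else {
      res$n_pass[i] <- 0L
      res$g0_association[i] <- 0
      res$p_value[i] <- 1
      res$direction[i] <- 1
      res$threshold[i] <- thresholds[1]
    }
  }
  res$p_adjusted <- bh_adjust(res$p_value)
  class(res) <- c("g0_association", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]; `NA`
#' inputs are propagated and excluded from the number of tests.
#'
#' @param p p-values in `(0, 1]` (`NA` allowed).
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  stopifnot(all(p[ok] > 0 & p[ok] <= 1))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-ion one-way ANOVA across stimuli
#'
#' Fixed-effects F-test of whether an ion's values differ across stimulus
#' groups (e.g. effect sizes across the three quiescence stimuli, grouped
#' over cell lines), with Benjamini-Hochberg correction across ions.
#'
#' @param data long data.frame with columns `ion`, `stimulus`, `value`.
#' @return data.frame: `ion`, `p_value`, `p_adjusted`.
#' @export
stimulus_anova <- function(data) {
  stopifnot(all(c("ion", "stimulus", "value") %in% names(data)))
  ions <- unique(data$ion)
  p <- vapply(ions, function(i) {
    d <- data[data$ion == i & !is.na(data$value), ]
    tab <- table(d$stimulus)
    tab <- tab[tab > 0]
    if (length(tab) < 2 || any(tab < 2))
      stop("ion ", i, ": need >= 2 groups with >= 2 observations each")
    if (stats::var(d$value) == 0) return(NA_real_)
    av <- stats::aov(value ~ factor(stimulus), data = d)
    summary(av)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  data.frame(ion = ions, p_value = p, p_adjusted = bh_adjust(p))
}

#' Confluence-normalized dynamic fold-changes
#'
#' For each ion, a linear model of abundance versus cell confluence is fit
#' on steady-state (unperturbed, full-medium) samples; every time-course
#' sample's measured abundance is then compared with the steady-state
#' expectation at its matching confluence as `log2(measured / expected)`.
#' Significance per ion is an unpaired t-test of the treated samples'
#' log2 fold-changes against those of all unperturbed samples, with
#' Benjamini-Hochberg correction across ions.
#'
#' @param measured numeric matrix samples x ions (time-course samples).
#' @param confluence per-sample confluence for `measured`.
#' @param treated logical per sample: TRUE = perturbed, FALSE = unperturbed
#'   reference samples.
#' @param steady_abundance matrix samples x ions of steady-state samples.
#' @param steady_confluence their confluences.
#' @return list of class `dynamic_fold_change`: `log2fc` (samples x ions;
#'   `NA` where the expected abundance is non-positive), `extrapolated`
#'   (per sample), `tests` (data.frame `ion`, `p_value`, `p_adjusted`),
#'   `flagged` (count of undefined entries).
#' @export
dynamic_fold_change <- function(measured, confluence, treated,
                                steady_abundance, steady_confluence) {
  measured <- as.matrix(measured)
  steady_abundance <- as.matrix(steady_abundance)
  stopifnot(nrow(measured) == length(confluence),
            length(treated) == nrow(measured),
            nrow(steady_abundance) == length(steady_confluence),
            ncol(measured) == ncol(steady_abundance))
  rng <- range(steady_confluence)
  extrapolated <- confluence < rng[1] | confluence > rng[2]
  n_ions <- ncol(measured)
  log2fc <- matrix(NA_real_, nrow(measured), n_ions,
                   dimnames = dimnames(measured))
  for (j in seq_len(n_ions)) {
    fit <- stats::lm(steady_abundance[, j] ~ steady_confluence)
    expected <- stats::coef(fit)[1] + stats::coef(fit)[2] * confluence
    ok <- expected > 0
    log2fc[ok, j] <- log2(measured[ok, j] / expected[ok])
  }
  p <- vapply(seq_len(n_ions), function(j) {
    a <- log2fc[treated, j]
    b <- log2fc[!treated, j]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    # exactly constant groups (noise-free fixtures) leave the t-test
    # undefined
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  ions <- colnames(measured)
  if (is.null(ions)) ions <- sprintf("ion%04d", seq_len(n_ions))
  structure(list(log2fc = log2fc, extrapolated = extrapolated,
                 tests = data.frame(ion = ions, p_value = p,
                                    p_adjusted = bh_adjust(p)),
                 flagged = sum(is.na(log2fc))),
            class = "dynamic_fold_change")
}
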