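#' Build the mixing design from totals, fractions and G0 fractions
#'
#' For a mix sample containing a fraction `f` of the 8-h extract (and
#' `1 - f` of the 96-h extract), the number of quiescent cells is
#' `N_Q = totals * (f * g0_8h + (1 - f) * g0_96h)` and
#' `N_P = totals - N_Q`. The total number of cells is constant across mixes
#' within a condition; varying `f` varies only the subpopulation split, which
#' is what makes the regression identifiable.
#'
#' @param totals total cells per mix sample (scalar or per condition).
#' @param fractions mixing fractions of the 8-h extract, in `[0, 1]`.
#' @param g0_fraction_8h,g0_fraction_96h gated G0 fractions of the two
#'   end-point cultures (scalar or per condition). They must differ within a
#'   condition, otherwise all mixes have the same composition and the design
#'   is rank-deficient.
#' @param conditions data.frame with columns `cell_line`, `stimulus`.
#' @param replicates replicate mixes per condition.
#' @param volumes relative cell volumes `c(P = , Q = )`.
#' @return data.frame of class `mix_design` with one row per sample:
#'   `sample_id`, `cell_line`, `stimulus`, `mix`, `replicate`, `fraction`,
#'   `n_p`, `n_q`, `v_p`, `v_q`, `total`.
#' @export
build_mix_design <- function(totals, fractions = mixing_fractions(),
                             g0_fraction_8h, g0_fraction_96h,
                             conditions = NULL, replicates = 3,
                             volumes = c(P = 1, Q = 1)) {
  if (is.null(conditions))
    conditions <- data.frame(cell_line = "CL1", stimulus = "starvation")
  stopifnot(all(fractions >= 0 & fractions <= 1),
            all(g0_fraction_8h >= 0 & g0_fraction_8h <= 1),
            all(g0_fraction_96h >= 0 & g0_fraction_96h <= 1),
            all(totals > 0), replicates >= 1)
  n_cond <- nrow(conditions)
  totals <- rep_len(totals, n_cond)
  g0_8 <- rep_len(g0_fraction_8h, n_cond)
  g0_96 <- rep_len(g0_fraction_96h, n_cond)
  if (any(abs(g0_8 - g0_96) < 1e-12))
    stop("g0_fraction_8h equals g0_fraction_96h in at least one condition: ",
         "all mixes would share one composition (rank-deficient design)")
  rows <- lapply(seq_len(n_cond), function(k) {
    f <- rep(fractions, each = replicates)
    n_q <- totals[k] * (f * g0_8[k] + (1 - f) * g0_96[k])
    data.frame(cell_line = conditions$cell_line[k],
               stimulus = conditions$stimulus[k],
               mix = rep(seq_along(fractions), each = replicates),
               replicate = rep(seq_len(replicates), length(fractions)),
               fraction = f,
               n_p = totals[k] - n_q, n_q = n_q,
               v_p = unname(volumes["P"]), v_q = unname(volumes["Q"]),
               total = totals[k])
  })
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf("%s.%s.m%d.r%d", design$cell_line,
                              design$stimulus, design$mix, design$replicate)
  design <- design[, c("sample_id", setdiff(names(design), "sample_id"))]
  class(design) <- c("mix_design", "data.frame")
  design
}

#' Expand a mixing design into the block design matrix
#'
#' For K conditions the matrix has 2K columns, ordered
#' `(cond1.P, cond1.Q, cond2.P, cond2.Q, ...)`; the row of sample
#' `(cl, st, m, n)` carries `N_P * V_P` and `N_Q * V_Q` in its condition's
#' two columns and zeros elsewhere. The block-diagonal structure makes the
#' joint fit over all conditions separable condition by condition.
#'
#' @param design a [build_mix_design()] data.frame.
#' @return numeric matrix (`nrow(design)` x `2 * n_conditions`) with an
#'   attribute `condition` giving each column's condition key and
#'   `population` giving `"P"`/`"Q"`.
#' @export
build_design_matrix <- function(design) {
  key <- paste(design$cell_line, design$stimulus, sep = ".")
  conds <- unique(key)
  X <- matrix(0, nrow(design), 2L * length(conds))
  colnames(X) <- paste(rep(conds, each = 2), c("P", "Q"), sep = ".")
  for (k in seq_along(conds)) {
    rows <- key == conds[k]
    X[rows, 2L * k - 1L] <- design$n_p[rows] * design$v_p[rows]
    X[rows, 2L * k] <- design$n_q[rows] * design$v_q[rows]
  }
  attr(X, "condition") <- rep(conds, each = 2)
  attr(X, "population") <- rep(c("P", "Q"), length(conds))
  X
}

#' Estimate per-ion MS background from blank samples
#'
#' The background term of the mixture model is taken as the mean intensity
#' across cell-free (blank) samples for each ion.
#'
#' @param blanks an [ion_table()] of blank injections, or a numeric matrix
#'   (samples x ions).
#' @return named numeric vector of per-ion background intensities.
#' @export
estimate_background <- function(blanks) {
  m <- if (inherits(blanks, "ion_table")) blanks$intensity else
    as.matrix(blanks)
  colMeans(m)
}

#' Fit per-subpopulation abundance coefficients
#'
#' Per ion, solves the non-negatively constrained least-squares problem
#' `min || (I_mix - beta) - X alpha ||^2, alpha >= 0` over all conditions at
#' once, where `X` is the block design matrix of [build_design_matrix()].
#' Negative background-subtracted intensities are kept as-is (not floored):
#' the constraint acts on the coefficients, not the data. Residuals and
#' fitted values are retained for the residual bootstrap.
#'
#' @param intensities an [ion_table()] whose rows match `design`, or a
#'   numeric matrix (samples x ions).
#' @param design a [build_mix_design()] data.frame.
#' @param background per-ion background (scalar recycled, or vector); use 0
#'   when intensities are already background-free.
#' @param tol KKT tolerance passed to [nnls_fit()].
#' @return object of class `population_profile`: list with `coefficients`
#'   (long data.frame: `ion`, `cell_line`, `stimulus`, `population`,
#'   `alpha`, `sd`, `n_bootstrap`, `identifiable`), plus `fitted`,
#'   `residuals` (samples x ions matrices), `design`, `background`.
#' @export
fit_alphas <- function(intensities, design, background = 0, tol = 1e-10) {
  I <- if (inherits(intensities, "ion_table")) intensities$intensity else
    as.matrix(intensities)
  stopifnot(nrow(I) == nrow(design))
  n_ions <- ncol(I)
  beta <- rep_len(background, n_ions)
  X <- build_design_matrix(design)
  key <- attr(X, "condition")[c(TRUE, FALSE)]
  Y <- sweep(I, 2, beta, "-")
  row_key <- paste(design$cell_line, design$stimulus, sep = ".")
  coefs <- matrix(NA_real_, ncol(X), n_ions)
  fitted <- residuals <- matrix(NA_real_, nrow(I), n_ions,
                                dimnames = dimnames(I))
  identifiable <- matrix(TRUE, length(key), n_ions)
  # block separability: solve each condition's two-column problem
  for (k in seq_along(key)) {
    rows <- which(row_key == key[k])
    Xk <- X[rows, c(2L * k - 1L, 2L * k), drop = FALSE]
    ok <- qr(Xk)$rank == 2L
    if (!ok) identifiable[k, ] <- FALSE
    for (j in seq_len(n_ions)) {
      if (!ok) next
      fit <- nnls_fit(Xk, Y[rows, j], tol = tol)
      coefs[c(2L * k - 1L, 2L * k), j] <- fit$coefficients
      fitted[rows, j] <- fit$fitted
      residuals[rows, j] <- fit$residuals
    }
  }
  ion_names <- colnames(I)
  if (is.null(ion_names)) ion_names <- sprintf("ion%04d", seq_len(n_ions))
  cond_df <- unique(design[, c("cell_line", "stimulus")])
  co <- data.frame(
    ion = rep(ion_names, each = ncol(X)),
    cell_line = rep(cond_df$cell_line[rep(seq_along(key), each = 2)],
                    n_ions),
    stimulus = rep(cond_df$stimulus[rep(seq_along(key), each = 2)], n_ions),
    population = rep(attr(X, "population"), n_ions),
    alpha = as.vector(coefs),
    sd = NA_real_, n_bootstrap = 0L,
    identifiable = as.vector(identifiable[rep(seq_along(key), each = 2), ,
                                          drop = FALSE]))
  structure(list(coefficients = co, fitted = fitted, residuals = residuals,
                 design = design, background = beta, tol = tol),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat("population_profile:", length(unique(x$coefficients$ion)), "ions,",
      nrow(unique(x$design[, c("cell_line", "stimulus")])), "conditions\n")
  invisible(x)
}

#' Residual-bootstrap errors for the fitted coefficients
#'
#' Per repetition, residuals are resampled with replacement within each
#' condition block (the design is fixed by construction) and added to the
#' fitted values; the constrained model is refit and, after `n_reps`
#' repetitions, each coefficient's error is the standard deviation of its
#' bootstrap draws.
#'
#' @param fit a [fit_alphas()] result.
#' @param n_reps bootstrap repetitions (default 100, >= 2).
#' @param seed integer seed making the resampling reproducible.
#' @return the `population_profile` with `sd` and `n_bootstrap` filled in.
#' @export
bootstrap_errors <- function(fit, n_reps = 100, seed = 1L) {
  stopifnot(inherits(fit, "population_profile"), n_reps >= 2)
  set.seed(seed)
  design <- fit$design
  X <- build_design_matrix(design)
  key <- attr(X, "condition")[c(TRUE, FALSE)]
  row_key <- paste(design$cell_line, design$stimulus, sep = ".")
  n_ions <- ncol(fit$fitted)
  draws <- array(NA_real_, c(ncol(X), n_ions, n_reps))
  for (k in seq_along(key)) {
    rows <- which(row_key == key[k])
    Xk <- X[rows, c(2L * k - 1L, 2L * k), drop = FALSE]
    if (qr(Xk)$rank < 2L) next
    fit_k <- fit$fitted[rows, , drop = FALSE]
    res_k <- fit$residuals[rows, , drop = FALSE]
    for (b in seq_len(n_reps)) {
      idx <- sample.int(length(rows), replace = TRUE)
      Yb <- fit_k + res_k[idx, , drop = FALSE]
      for (j in seq_len(n_ions)) {
        draws[c(2L * k - 1L, 2L * k), j, b] <-
          nnls_fit(Xk, Yb[, j], tol = fit$tol)$coefficients
      }
    }
  }
  sds <- apply(draws, c(1, 2), stats::sd)
  fit$coefficients$sd <- as.vector(sds)
  fit$coefficients$n_bootstrap <- n_reps
  fit
}

#' Purified end-point intensity profiles
#'
#' Reconstructs the intensity attributable to one subpopulation in an
#' end-point sample by subtracting the modeled contribution of the other:
#' for the 96-h (G0-enriched) sample
#' `I_G0 = I_mix - alpha_P * N_P * V_P`, and symmetrically for the 8-h
#' sample. The purified intensity is then normalized per cell of the focal
#' population. Negative purified values are floored at zero and flagged.
#'
#' @param intensities an [ion_table()] or matrix of end-point samples.
#' @param design design rows matching those samples (must carry `n_p`,
#'   `n_q`, `v_p`, `v_q`, `cell_line`, `stimulus`).
#' @param profile a fitted `population_profile`.
#' @param focal `"Q"` (96-h sample: remove the P contribution, normalize by
#'   `N_Q`) or `"P"`; scalar or one value per sample row.
#' @return list with matrices `purified` and `per_cell` (samples x ions), a
#'   logical matrix `floored`, and `focal`.
#' @export
purify_intensities <- function(intensities, design, profile, focal = "Q") {
  I <- if (inherits(intensities, "ion_table")) intensities$intensity else
    as.matrix(intensities)
  stopifnot(nrow(I) == nrow(design), inherits(profile, "population_profile"))
  focal <- rep_len(focal, nrow(design))
  stopifnot(all(focal %in% c("P", "Q")))
  co <- profile$coefficients
  key <- paste(design$cell_line, design$stimulus, sep = ".")
  co_key <- paste(co$cell_line, co$stimulus, sep = ".")
  ion_names <- colnames(I)
  purified <- per_cell <- matrix(NA_real_, nrow(I), ncol(I),
                                 dimnames = dimnames(I))
  floored <- matrix(FALSE, nrow(I), ncol(I))
  for (s in seq_len(nrow(I))) {
    other <- if (focal[s] == "Q") "P" else "Q"
    a_other <- co$alpha[co_key == key[s] & co$population == other]
    names(a_other) <- co$ion[co_key == key[s] & co$population == other]
    a_other <- a_other[ion_names]
    n_other <- if (other == "P") design$n_p[s] * design$v_p[s] else
      design$n_q[s] * design$v_q[s]
    n_focal <- if (focal[s] == "Q") design$n_q[s] else design$n_p[s]
    if (n_focal <= 0)
      stop("focal population has zero cells in sample ", s,
           ": per-cell normalization undefined")
    v <- I[s, ] - a_other * n_other
    floored[s, ] <- v < 0
    v <- pmax(v, 0)
    purified[s, ] <- v
    per_cell[s, ] <- v / n_focal
  }
  list(purified = purified, per_cell = per_cell, floored = floored,
       focal = focal)
}

#' Compare deconvolved profiles against a reference abundance table
#'
#' Selects "characteristic" ions whose variation across cell lines exceeds
#' three times the typical (median) per-cell-line error, computes per-ion
#' Spearman correlations between the deconvolved and reference profiles
#' across cell lines, and builds a permutation null by scrambling cell-line
#' labels.
#'
#' @param profiles numeric matrix, ions x cell lines (deconvolved estimates;
#'   rownames = ion ids).
#' @param reference numeric matrix, ions x cell lines, same orientation;
#'   rows matched by name to `profiles`.
#' @param errors optional ions x cell lines matrix of estimate errors used
#'   by the characteristic-ion rule; `NULL` keeps all shared ions.
#' @param sd_factor characteristic-ion rule: cross-cell-line SD must exceed
#'   `sd_factor` times the median error (default 3).
#' @param n_perm label-scrambling repetitions for the null.
#' @param seed integer seed.
#' @return list with `correlations` (data.frame: `ion`, `rho`,
#'   `characteristic`), `null_rho` (matrix, characteristic ions x
#'   permutations) and `n_shared_lines`.
#' @export
compare_to_reference <- function(profiles, reference, errors = NULL,
                                 sd_factor = 3, n_perm = 1000, seed = 1L) {
  shared_lines <- intersect(colnames(profiles), colnames(reference))
  shared_ions <- intersect(rownames(profiles), rownames(reference))
  if (length(shared_lines) < 3)
    stop("need >= 3 shared cell lines for a Spearman comparison")
  P <- profiles[shared_ions, shared_lines, drop = FALSE]
  R <- reference[shared_ions, shared_lines, drop = FALSE]
  characteristic <- rep(TRUE, length(shared_ions))
  if (!is.null(errors)) {
    E <- errors[shared_ions, shared_lines, drop = FALSE]
    characteristic <- apply(P, 1, stats::sd) >
      sd_factor * apply(E, 1, stats::median)
  }
  rho <- vapply(seq_along(shared_ions), function(i)
    suppressWarnings(stats::cor(P[i, ], R[i, ], method = "spearman")),
    numeric(1))
  set.seed(seed)
  idx_char <- which(characteristic)
  null_rho <- matrix(NA_real_, length(idx_char), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(length(shared_lines))
    null_rho[, b] <- vapply(idx_char, function(i)
      suppressWarnings(stats::cor(P[i, perm], R[i, ], method = "spearman")),
      numeric(1))
  }
  list(correlations = data.frame(ion = shared_ions, rho = rho,
                                 characteristic = characteristic),
       null_rho = null_rho, n_shared_lines = length(shared_lines))
}
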