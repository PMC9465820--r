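# Shared fixture builders and independent oracles for the suite.

# Noise-free mixing experiment with known truth.
noisefree_experiment <- function(n_ions = 20, background = 50, seed = 2,
                                 conditions = NULL, ...) {
  tr <- true_population_profile(n_ions, conditions = conditions, seed = seed)
  ex <- simulate_mix_experiment(
    tr, model = measurement_model(background = background), ...)
  list(truth = tr, exper = ex, background = background)
}

# Independent exhaustive-enumeration oracle for the upper-tail
# hypergeometric probability (direct sum over lchoose terms, no phyper).
enum_hyper_tail <- function(k, n_success, n_total, n_draw) {
  if (k <= 0) return(1)
  kk <- k:min(n_success, n_draw)
  if (length(kk) == 0 || max(kk) < k) return(0)
  sum(exp(lchoose(n_success, kk) + lchoose(n_total - n_success, n_draw - kk) -
            lchoose(n_total, n_draw)))
}

# Closed-form unconstrained normal-equations solution for a block.
normal_equations <- function(X, y)
  unname(drop(solve(crossprod(X), crossprod(X, y))))

# Brute-force exact NNLS for a 2-column block: best feasible candidate among
# the unconstrained optimum and every boundary restriction.
brute_nnls2 <- function(X, y) {
  cands <- list(c(0, 0))
  b12 <- tryCatch(normal_equations(X, y), error = function(e) NULL)
  if (!is.null(b12) && all(b12 >= 0)) cands <- c(cands, list(b12))
  b1 <- sum(X[, 1] * y) / sum(X[, 1]^2)
  if (b1 >= 0) cands <- c(cands, list(c(b1, 0)))
  b2 <- sum(X[, 2] * y) / sum(X[, 2]^2)
  if (b2 >= 0) cands <- c(cands, list(c(0, b2)))
  rss <- vapply(cands, function(b) sum((y - X %*% b)^2), numeric(1))
  cands[[which.min(rss)]]
}
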