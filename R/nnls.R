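#' Non-negative least squares by active-set iteration
#'
#' Solves \eqn{\min_{b \ge 0} \|y - X b\|^2} with the Lawson--Hanson
#' active-set strategy on the normal equations. The mixture blocks solved
#' during deconvolution are small (typically two columns per condition), so a
#' dense normal-equations formulation is both exact and fast; on blocks whose
#' unconstrained optimum is already non-negative the result coincides with the
#' ordinary least-squares solution.
#'
#' @param X numeric design matrix (n x p), n >= 1.
#' @param y numeric response vector of length n.
#' @param tol convergence tolerance on the KKT (dual feasibility) residual,
#'   relative to the magnitude of `X'y`.
#' @return list with `coefficients` (length p, all >= 0), `fitted`,
#'   `residuals`, and `rss`.
#' @examples
#' X <- cbind(c(1, 2, 3), c(3, 2, 1))
#' nnls_fit(X, X %*% c(2, 0.5))$coefficients
#' @export
nnls_fit <- function(X, y, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  scale <- max(abs(Xty), sum(abs(XtX)), 1)
  beta <- numeric(p)
  passive <- rep(FALSE, p)
  w <- Xty                              # gradient of -0.5*RSS at beta = 0
  outer_iter <- 0L
  max_outer <- 3L * p + 30L
  while (outer_iter < max_outer) {
    outer_iter <- outer_iter + 1L
    cand <- which(!passive & w > tol * scale)
    if (length(cand) == 0L) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      s <- numeric(p)
      s[idx] <- tryCatch(
        solve(XtX[idx, idx, drop = FALSE], Xty[idx]),
        error = function(e) qr.solve(XtX[idx, idx, drop = FALSE], Xty[idx],
                                     tol = 1e-12)
      )
      if (all(s[idx] > 0)) { beta <- s; break }
      neg <- passive & s <= 0
      step <- min(beta[neg] / (beta[neg] - s[neg]))
      beta <- beta + step * (s - beta)
      passive <- passive & beta > tol * scale
      beta[!passive] <- 0
      if (!any(passive)) break
    }
    w <- Xty - drop(XtX %*% beta)
  }
  fitted <- drop(X %*% beta)
  res <- y - fitted
  list(coefficients = beta, fitted = fitted, residuals = res,
       rss = sum(res^2))
}
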