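#' Multitask regression cost with L2,1 and Frobenius penalties
#'
#' Evaluates the joint least-squares cost
#' \deqn{\sum_t \|W_t^T X - Y_t\|_F^2 + \rho_1 \|W\|_{2,1} + \rho_{L2} \|W\|_F^2}
#' where the L2,1 norm is the sum over coefficient rows (genes) of the row-wise
#' Euclidean norm across tasks. The L2,1 penalty zeroes whole gene rows
#' jointly across tasks, giving grouped sparsity.
#'
#' @param W Coefficient matrix (genes x tasks).
#' @param X Design matrix (genes x samples), shared across tasks.
#' @param Y Response matrix (tasks x samples).
#' @param rho1 Non-negative L2,1 penalty weight.
#' @param rhoL2 Non-negative squared-Frobenius penalty weight.
#' @return The scalar cost.
#' @export
mtl_cost <- function(W, X, Y, rho1, rhoL2) {
  W <- as.matrix(W); X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(W) != nrow(X) || ncol(W) != nrow(Y) || ncol(X) != ncol(Y))
    stop("shape mismatch: need W (n x m), X (n x s), Y (m x s)")
  if (rho1 < 0 || rhoL2 < 0) stop("penalty weights must be non-negative")
  resid <- crossprod(W, X) - Y          # m x s
  sum(resid^2) + rho1 * sum(sqrt(rowSums(W^2))) + rhoL2 * sum(W^2)
}

#' Row-wise group soft-threshold (proximal operator of the L2,1 norm)
#'
#' Returns the minimizer of \eqn{\frac12\|Z - W\|_F^2 + \theta \|Z\|_{2,1}}:
#' each row of `W` is shrunk by `theta` in Euclidean norm and zeroed exactly
#' when its norm is at most `theta`.
#'
#' @param W Numeric matrix (rows are the groups).
#' @param theta Non-negative threshold.
#' @return Matrix of the same shape.
#' @export
prox_l21 <- function(W, theta) {
  if (theta < 0) stop("theta must be non-negative")
  if (theta == 0) return(W)
  W <- as.matrix(W)
  nrm <- sqrt(rowSums(W^2))
  scale <- ifelse(nrm > theta, 1 - theta / nrm, 0)
  W * scale
}

#' Fit the L2,1-regularized multitask model by accelerated proximal gradient
#'
#' Minimizes [mtl_cost()] over the coefficient matrix W with FISTA:
#' accelerated gradient steps on the smooth part (least squares + Frobenius
#' ridge), the row-wise group soft-threshold [prox_l21()] for the L2,1 part,
#' backtracking line search for the step size, and restart of the momentum
#' whenever the cost would increase (which makes the recorded cost trace
#' non-increasing). W starts at zero; the fit is deterministic.
#'
#' @param X Design matrix (genes x samples); rows should be on a comparable
#'   scale (the training pipeline passes the min-max normalized matrix).
#' @param Y Response matrix (tasks x samples). With
#'   `standardize_y = TRUE` (default) each task row is z-scored before
#'   fitting so the penalties act on comparable scales.
#' @param rho1 Non-negative L2,1 penalty.
#' @param rhoL2 Non-negative squared-Frobenius penalty.
#' @param max_iter Iteration cap (default 10000).
#' @param tol Stop when the relative cost change falls below this (1e-6).
#' @param standardize_y Z-score each task row of Y before fitting.
#' @return Object of class `"tme_mtl"`: list with `W` (genes x tasks, row
#'   names from X), `objective_trace`, `converged`, `n_iter`, `rho1`, `rhoL2`.
#' @export
fit_mtl <- function(X, Y, rho1, rhoL2, max_iter = 10000L, tol = 1e-6,
                    standardize_y = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share the sample dimension")
  if (rho1 < 0 || rhoL2 < 0) stop("penalty weights must be non-negative")
  if (standardize_y) {
    mu <- rowMeans(Y)
    sdp <- sqrt(rowMeans((Y - mu)^2))
    if (any(sdp == 0)) stop("constant task row in Y cannot be standardized")
    Y <- (Y - mu) / sdp
  }
  n <- nrow(X); m <- nrow(Y)
  XYt <- tcrossprod(X, Y)              # n x m, fixed
  grad <- function(W) 2 * (X %*% crossprod(X, W) - XYt) + 2 * rhoL2 * W
  fsmooth <- function(W) {
    r <- crossprod(W, X) - Y
    sum(r^2) + rhoL2 * sum(W^2)
  }
  cost <- function(W) fsmooth(W) + rho1 * sum(sqrt(rowSums(W^2)))

  W <- matrix(0, n, m)
  Z <- W
  tk <- 1
  L <- max(sum(X^2) / ncol(X), 1)       # initial Lipschitz guess; refined by backtracking
  trace <- numeric(max_iter + 1L)
  c_prev <- cost(W)
  trace[1L] <- c_prev
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    gZ <- grad(Z)
    fZ <- fsmooth(Z)
    bt <- 0L
    repeat {
      Wn <- prox_l21(Z - gZ / L, rho1 / L)
      D <- Wn - Z
      if (fsmooth(Wn) <= fZ + sum(gZ * D) + (L / 2) * sum(D^2) + 1e-12) break
      L <- 2 * L
      bt <- bt + 1L
      if (bt > 60L) stop("backtracking line search failed to find a valid step")
    }
    c_new <- cost(Wn)
    if (c_new > c_prev) {
      # monotone safeguard: restart momentum from the best iterate
      Z <- W
      tk <- 1
      gZ <- grad(Z)
      fZ <- fsmooth(Z)
      repeat {
        Wn <- prox_l21(Z - gZ / L, rho1 / L)
        D <- Wn - Z
        if (fsmooth(Wn) <= fZ + sum(gZ * D) + (L / 2) * sum(D^2) + 1e-12) break
        L <- 2 * L
      }
      c_new <- cost(Wn)
      if (c_new > c_prev + 1e-12 * max(1, c_prev))
        stop("objective failed to decrease despite restart: numerical problem")
      c_new <- min(c_new, c_prev)
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Wn + ((tk - 1) / tn) * (Wn - W)
    W <- Wn
    tk <- tn
    trace[it + 1L] <- c_new
    if (abs(c_prev - c_new) < tol * max(abs(c_prev), 1e-12)) {
      converged <- TRUE
      c_prev <- c_new
      break
    }
    c_prev <- c_new
  }
  trace <- trace[seq_len(n_iter + 1L)]
  rownames(W) <- rownames(X)
  colnames(W) <- rownames(Y)
  structure(list(W = W, objective_trace = trace, converged = converged,
                 n_iter = n_iter, rho1 = rho1, rhoL2 = rhoL2),
            class = "tme_mtl")
}

#' @export
print.tme_mtl <- function(x, ...) {
  nz <- sum(sqrt(rowSums(x$W^2)) > 1e-8)
  cat("L2,1 multitask fit: ", nrow(x$W), " genes x ", ncol(x$W), " tasks; ",
      nz, " nonzero rows; rho1=", x$rho1, ", rhoL2=", x$rhoL2, "; ",
      x$n_iter, " iterations",
      if (x$converged) " (converged)\n" else " (max_iter reached)\n", sep = "")
  invisible(x)
}

#' Genes selected by the multitask fit
#'
#' Genes whose coefficient row has Euclidean norm above `zero_tol`. Rows
#' zeroed by the group soft-threshold are exactly zero, so the tolerance only
#' guards accumulated floating-point noise.
#'
#' @param fit A `"tme_mtl"` object.
#' @param zero_tol Row-norm threshold (default 1e-8).
#' @return Character vector of gene identifiers.
#' @export
selected_genes <- function(fit, zero_tol = 1e-8) {
  stopifnot(inherits(fit, "tme_mtl"))
  nrm <- sqrt(rowSums(fit$W^2))
  rownames(fit$W)[nrm > zero_tol]
}

#' Smallest L2,1 penalty that zeroes all coefficients
#'
#' For penalty weights at or above this value the all-zero matrix minimizes
#' the multitask cost. Useful as the upper anchor of a penalty grid.
#'
#' @param X Design matrix (genes x samples).
#' @param Y Response matrix (tasks x samples); standardized the same way as
#'   in [fit_mtl()] when `standardize_y = TRUE`.
#' @param standardize_y Match the standardization used at fit time.
#' @return Scalar: `2 * max` row norm of `X %*% t(Y)`.
#' @export
rho1_max <- function(X, Y, standardize_y = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (standardize_y) {
    mu <- rowMeans(Y)
    sdp <- sqrt(rowMeans((Y - mu)^2))
    Y <- (Y - mu) / sdp
  }
  2 * sqrt(max(rowSums(tcrossprod(X, Y)^2)))
}

#' Log-spaced L2,1 penalty grid
#'
#' @param X,Y,standardize_y As in [rho1_max()].
#' @param n_values Grid length (default 10).
#' @param min_frac Smallest grid value as a fraction of [rho1_max()] (0.01).
#' @return Decreasing numeric vector of candidate `rho1` values.
#' @export
rho1_grid <- function(X, Y, n_values = 10L, min_frac = 0.01,
                      standardize_y = TRUE) {
  top <- rho1_max(X, Y, standardize_y = standardize_y)
  exp(seq(log(top), log(top * min_frac), length.out = n_values))
}
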