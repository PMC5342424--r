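#' Multi-task longitudinal sparse regression
#'
#' Fits the association between a longitudinal imaging-feature tensor
#' `X` (n samples x d features x T time points) and an expression matrix
#' `Y` (n x c) by minimizing
#'
#'   `sum_t ||X_t W_t - Y||_F^2
#'     + theta1 * sum_k sqrt(sum_t ||W_t^k - Wbar^k||^2)
#'     + theta2 * ||W(1)||_*`
#'
#' where `W_t^k` is the k-th row of the coefficient matrix at time t,
#' `Wbar = (1/T) sum_t W_t`, and `||W(1)||_*` is the trace (nuclear) norm of
#' the tensor unfolded along the feature dimension.  The group term couples
#' the tasks across time: it is a row-wise group penalty on the temporal
#' deviations, inducing feature-level sparsity shared by all time points,
#' while the trace norm favors low-rank (redundancy-reduced) coefficients.
#'
#' The solver is an iteratively reweighted closed-form update: each sweep
#' recomputes the diagonal reweighting `D` (from the row-group deviations),
#' the temporal mean `Wbar` and the trace-norm reweighting
#' `Dbb = (1/2)(W(1)W(1)' + eps I)^(-1/2)`, then solves for every time point
#'
#'   `W_t = (X_t'X_t + theta1 D + theta2 Dbb)^(-1) (X_t'Y + theta1 D Wbar)`
#'
#' via a symmetric positive-definite factorization.  Both reweighting square
#' roots are smoothed by `epsilon`, which makes each sweep the exact
#' minimizer of a majorizing surrogate of the epsilon-smoothed objective;
#' the recorded objective trace is therefore non-increasing.
#'
#' @param X numeric array `n x d x T` (finite).
#' @param Y numeric matrix `n x c`, kept on its native expression scale by
#'   default so that overall weights reflect both association strength and
#'   expression-scale differences; set `standardize_y = TRUE` to z-score the
#'   gene columns before fitting.
#' @param theta1 temporal-smoothness / group-sparsity weight (>= 0).
#' @param theta2 trace-norm weight (>= 0).
#' @param max_iter maximum number of sweeps.
#' @param tol relative objective-change stopping tolerance; set to 0 to run
#'   exactly `max_iter` sweeps (fixed-count mode, used by the hyperparameter
#'   grid).
#' @param epsilon reweighting smoothing constant (> 0).
#' @param ridge_init ridge used for the deterministic per-time-point
#'   initialization `W_t = (X_t'X_t + ridge_init I)^(-1) X_t'Y`.
#' @param standardize_y z-score the gene columns of `Y` before fitting.
#' @param checkpoints integer iteration counts at which to snapshot `W`
#'   (requires `tol = 0`); used by [run_grid()] to share one fit across
#'   several fixed iteration counts.
#' @return An object of class `longreg_fit`: list with `W` (d x c x T
#'   array), `objective` (trace of the epsilon-smoothed objective, one value
#'   per sweep plus the final state), `iterations`, `converged`,
#'   `singular_values` of the final unfolding, `snapshots` (named list of W
#'   arrays) and the fit settings.
#' @seealso [objective()], [update_reweighting()], [overall_weights()]
#' @export
fit_longreg <- function(X, Y, theta1 = 1, theta2 = 1, max_iter = 1000L,
                        tol = 1e-6, epsilon = 1e-8, ridge_init = 1e-3,
                        standardize_y = FALSE, checkpoints = integer(0)) {
  dm <- check_xy(X, Y)
  stopifnot(theta1 >= 0, theta2 >= 0, epsilon > 0, ridge_init >= 0,
            max_iter >= 1, tol >= 0)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (length(checkpoints)) {
    if (tol > 0)
      stop("checkpoints require fixed-count mode (tol = 0)")
    if (max(checkpoints) > max_iter)
      stop("checkpoints must not exceed max_iter")
  }
  Ys <- Y
  if (standardize_y) {
    sds <- apply(Y, 2, sd)
    if (any(sds == 0))
      stop("zero-variance gene column(s): ",
           paste(colnames(Y)[sds == 0], collapse = ", "))
    Ys <- scale(Y)
  }
  res <- fit_longreg_cpp(X, Ys, theta1, theta2, as.integer(max_iter), tol,
                         epsilon, ridge_init, as.integer(checkpoints))
  dn <- list(dimnames(X)[[2]], colnames(Y), dimnames(X)[[3]])
  W <- res$W
  dimnames(W) <- dn
  snaps <- res$snapshots
  if (length(snaps)) {
    snaps <- lapply(snaps, function(w) { dimnames(w) <- dn; w })
    names(snaps) <- paste0("iter", res$snapshot_iters)
  }
  structure(list(W = W, objective = as.numeric(res$objective),
                 iterations = res$iterations, converged = res$converged,
                 singular_values = as.numeric(res$singular_values),
                 snapshots = snaps,
                 theta1 = theta1, theta2 = theta2, epsilon = epsilon,
                 ridge_init = ridge_init, tol = tol,
                 standardize_y = standardize_y, dims = dm),
            class = "longreg_fit")
}

check_xy <- function(X, Y) {
  if (length(dim(X)) != 3L)
    stop("X must be a 3D array (samples x features x time points)")
  if (length(dim(Y)) != 2L)
    stop("Y must be a matrix (samples x genes)")
  if (dim(X)[1] != nrow(Y))
    stop(sprintf("sample axis mismatch: X has %d samples, Y has %d",
                 dim(X)[1], nrow(Y)))
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (any(!is.finite(Y))) stop("Y contains non-finite values")
  c(n = dim(X)[1], d = dim(X)[2], T = dim(X)[3], c = ncol(Y))
}

#' @export
print.longreg_fit <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "Longitudinal sparse regression fit: d = %d features, c = %d genes, T = %d\n",
    d["d"], d["c"], d["T"]))
  cat(sprintf("  theta1 = %g, theta2 = %g, %d sweep(s)%s\n", x$theta1,
              x$theta2, x$iterations,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  objective %.6g -> %.6g\n", x$objective[1],
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Unfold a coefficient tensor along the feature dimension
#'
#' Returns `W(1) = [W_1 W_2 ... W_T]`, the `d x (c T)` matrix obtained by
#' concatenating the time slices along columns.  This is a pure re-view of
#' the same values.
#'
#' @param W numeric array `d x c x T`.
#' @return A `d x (c*T)` matrix.
#' @export
unfold_coefficients <- function(W) {
  stopifnot(length(dim(W)) == 3L)
  d <- dim(W)
  out <- matrix(W, d[1], d[2] * d[3])
  if (!is.null(dimnames(W)))
    dimnames(out) <- list(dimnames(W)[[1]],
                          as.vector(outer(dimnames(W)[[2]], dimnames(W)[[3]],
                                          paste, sep = ".")))
  out
}

#' Regression objective value
#'
#' Evaluates the penalized objective
#' `sum_t ||X_t W_t - Y||_F^2 + theta1 * sum_k sqrt(sum_t ||W_t^k - Wbar^k||^2 + epsilon)
#'  + theta2 * ||W(1)||_*` (with the trace norm smoothed to
#' `sum_i sqrt(sigma_i^2 + epsilon)` when `epsilon > 0`).  With the default
#' `epsilon = 0` this is the exact objective; [fit_longreg()] traces the
#' epsilon-smoothed version.
#'
#' @param X `n x d x T` array.
#' @param Y `n x c` matrix (pass the standardized matrix to reproduce a
#'   fit's trace).
#' @param W `d x c x T` coefficient array.
#' @param theta1,theta2 penalty weights.
#' @param epsilon smoothing constant (default 0, the unsmoothed objective).
#' @return The scalar objective value.
#' @export
objective <- function(X, Y, W, theta1, theta2, epsilon = 0) {
  dm <- check_xy(X, Y)
  if (!all(dim(W) == c(dm["d"], dm["c"], dm["T"])))
    stop(sprintf("W must be %d x %d x %d; got %s", dm["d"], dm["c"],
                 dm["T"], paste(dim(W), collapse = " x ")))
  T_ <- dm["T"]
  rss <- 0
  for (t in seq_len(T_))
    rss <- rss + sum((X[, , t] %*% W[, , t] - Y)^2)
  Wbar <- apply(W, c(1, 2), mean)
  g <- rowSums(vapply(seq_len(T_),
                      function(t) rowSums((W[, , t] - Wbar)^2),
                      numeric(dm["d"])))
  grp <- sum(sqrt(g + epsilon))
  sv <- svd(unfold_coefficients(W), nu = 0, nv = 0)$d
  nuc <- sum(sqrt(sv^2 + epsilon))
  rss + theta1 * grp + theta2 * nuc
}

#' Reweighting matrices of the iterative solver
#'
#' Computes, for a given coefficient tensor, the quantities recomputed at
#' the start of each solver sweep: the diagonal row-group reweighting
#' `D_kk = 1 / (2 sqrt(sum_t ||W_t^k||^2 - (1/T)||sum_t W_t^k||^2 + epsilon))`,
#' the temporal mean `Wbar = (1/T) sum_t W_t`, and the trace-norm
#' reweighting `Dbb = (1/2)(W(1) W(1)' + epsilon I)^(-1/2)` obtained from
#' the symmetric eigendecomposition with eigenvalues clipped at zero before
#' the epsilon shift.
#'
#' @param W `d x c x T` coefficient array (finite).
#' @param epsilon smoothing constant (> 0).
#' @return A list with `D` (length-d vector of diagonal entries), `Wbar`
#'   (d x c), `Dbb` (d x d symmetric positive definite), `g` (row-group
#'   squared deviations) and `singular_values` of `W(1)`.
#' @export
update_reweighting <- function(W, epsilon = 1e-8) {
  stopifnot(length(dim(W)) == 3L, epsilon > 0)
  if (any(!is.finite(W))) stop("W contains non-finite values")
  d <- dim(W)[1]; T_ <- dim(W)[3]
  Wbar <- apply(W, c(1, 2), mean)
  g <- rowSums(vapply(seq_len(T_),
                      function(t) rowSums((W[, , t] - Wbar)^2),
                      numeric(d)))
  D <- 1 / (2 * sqrt(g + epsilon))
  W1 <- unfold_coefficients(W)
  eg <- eigen(tcrossprod(W1), symmetric = TRUE)
  lam <- pmax(eg$values, 0) + epsilon
  Dbb <- eg$vectors %*% (0.5 / sqrt(lam) * t(eg$vectors))
  list(D = D, Wbar = Wbar, Dbb = Dbb, g = g,
       singular_values = sqrt(pmax(eg$values, 0)))
}

#' Per-gene overall association weights
#'
#' Aggregates a coefficient tensor into the overall weight of each gene at
#' each time point, `W'(t, j) = sum_i |W_t(i, j)|` (the total magnitude of
#' the coefficients linking all imaging features to gene j at time t), and
#' the per-gene time average used to rank genes.  Absolute values are used
#' so that oppositely signed coefficients cannot cancel.
#'
#' @param W a `longreg_fit` or a `d x c x T` coefficient array.
#' @return An object of class `weight_map`: list with `W_prime` (T x c
#'   matrix), `avg_weight` (named length-c vector) and `order` (gene indices
#'   in decreasing average weight, ties broken by gene index).
#' @export
overall_weights <- function(W) {
  if (inherits(W, "longreg_fit")) W <- W$W
  stopifnot(length(dim(W)) == 3L)
  if (any(!is.finite(W))) stop("W contains non-finite values")
  T_ <- dim(W)[3]; c_ <- dim(W)[2]
  Wp <- t(vapply(seq_len(T_), function(t) colSums(abs(W[, , t])),
                 numeric(c_)))
  rownames(Wp) <- dimnames(W)[[3]]
  colnames(Wp) <- dimnames(W)[[2]]
  avg <- colMeans(Wp)
  ord <- order(-avg, seq_len(c_))
  structure(list(W_prime = Wp, avg_weight = avg, order = ord),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  k <- min(10L, length(x$avg_weight))
  top <- x$order[seq_len(k)]
  nm <- names(x$avg_weight)
  if (is.null(nm)) nm <- as.character(seq_along(x$avg_weight))
  cat(sprintf("Overall gene weights (%d time points x %d genes)\n",
              nrow(x$W_prime), ncol(x$W_prime)))
  cat("  top genes:",
      paste(sprintf("%s (%.3g)", nm[top], x$avg_weight[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Top-ranked genes by average overall weight
#'
#' @param weight_map an [overall_weights()] result.
#' @param k number of genes to return (default 50).
#' @return Character vector of gene names (or indices as character when
#'   unnamed), ranked by decreasing average overall weight.
#' @export
top_genes <- function(weight_map, k = 50L) {
  stopifnot(inherits(weight_map, "weight_map"))
  c_ <- length(weight_map$avg_weight)
  if (k > c_)
    stop(sprintf("k = %d exceeds the number of genes (%d)", k, c_))
  idx <- weight_map$order[seq_len(k)]
  nm <- names(weight_map$avg_weight)
  if (is.null(nm)) as.character(idx) else nm[idx]
}
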