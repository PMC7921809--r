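## Fast combinatorial non-negative least squares (active-set) for many
## right-hand sides sharing one Gram matrix: minimise ||A X - B||_F subject
## to X >= 0 on constrained rows, working from AtA = A'A and AtB = A'B.
## Columns sharing a passive set are solved together in one linear solve.

.solve_ridge <- function(A, B, env = NULL) {
  out <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    if (!is.null(env)) env$ridged <- TRUE
    lam <- 1e-10 * max(sum(diag(A)), .Machine$double.xmin)
    out <- tryCatch(solve(A + diag(lam, nrow(A)), B), error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out))) {
      ## e.g. an all-zero Gram matrix: eigen-truncated pseudoinverse gives
      ## the minimum-norm least-squares solution
      ee <- eigen(A, symmetric = TRUE)
      keep <- ee$values > max(ee$values, 0) * 1e-12
      out <- if (!any(keep)) matrix(0, nrow(A), ncol(B))
             else ee$vectors[, keep, drop = FALSE] %*%
               ((crossprod(ee$vectors[, keep, drop = FALSE], B)) /
                  ee$values[keep])
    }
  }
  out
}

## combinatorial subspace least squares: one solve per distinct passive set
.cssls <- function(AtA, AtB, Pass = NULL, env = NULL) {
  K <- nrow(AtA)
  if (is.null(Pass)) return(.solve_ridge(AtA, AtB, env))
  X <- matrix(0, K, ncol(AtB))
  codes <- colSums(Pass * 2^(seq_len(K) - 1))
  for (cd in unique(codes)) {
    cols <- which(codes == cd)
    p <- Pass[, cols[1]]
    if (!any(p)) next
    X[p, cols] <- .solve_ridge(AtA[p, p, drop = FALSE],
                               AtB[p, cols, drop = FALSE], env)
  }
  X
}

.clip_neg <- function(X, rows, cols) {
  sub <- X[rows, cols, drop = FALSE]
  sub[sub < 0] <- 0
  X[rows, cols] <- sub
  X
}

#' Multi-RHS non-negative least squares from Gram matrices
#'
#' Solves `min ||A X - B||` columnwise with `X >= 0` on all rows except
#' `unconstrained` (used for the signed baseline coefficient), given
#' `AtA = t(A) %*% A` and `AtB = t(A) %*% B`.
#'
#' @param AtA K x K Gram matrix.
#' @param AtB K x n right-hand sides.
#' @param unconstrained row indices exempt from the non-negativity bound.
#' @return list: `X` (K x n solution), `ridged` (TRUE if a rank-deficiency
#'   ridge fallback was used).
#' @keywords internal
fcnnls <- function(AtA, AtB, unconstrained = integer(0)) {
  K <- nrow(AtA); n <- ncol(AtB)
  env <- new.env(); env$ridged <- FALSE
  cons <- setdiff(seq_len(K), unconstrained)
  if (!length(cons))
    return(list(X = .cssls(AtA, AtB, NULL, env), ridged = env$ridged))
  tol <- 1e-12 * max(abs(AtB), 1)
  X <- .cssls(AtA, AtB, NULL, env)
  Pass <- X > 0
  if (length(unconstrained)) Pass[unconstrained, ] <- TRUE
  Fset <- which(colSums(X[cons, , drop = FALSE] < -tol) > 0L)
  X <- .clip_neg(X, cons, seq_len(n))
  guard <- 0L
  while (length(Fset)) {
    guard <- guard + 1L
    if (guard > 50L * K) {
      warning("NNLS active-set iteration limit reached; ",
              "returning clipped feasible solution")
      X <- .clip_neg(X, cons, Fset)
      break
    }
    X[, Fset] <- .cssls(AtA, AtB[, Fset, drop = FALSE],
                        Pass[, Fset, drop = FALSE], env)
    Hset <- Fset[colSums(X[cons, Fset, drop = FALSE] < -tol) > 0L]
    inner <- 0L
    while (length(Hset)) {
      inner <- inner + 1L
      if (inner > 10L * K) break
      Ph <- Pass[, Hset, drop = FALSE]
      neg <- X[, Hset, drop = FALSE] < -tol
      if (length(unconstrained)) neg[unconstrained, ] <- FALSE
      Ph[neg] <- FALSE
      Pass[, Hset] <- Ph
      X[, Hset] <- .cssls(AtA, AtB[, Hset, drop = FALSE],
                          Pass[, Hset, drop = FALSE], env)
      Hset <- Hset[colSums(X[cons, Hset, drop = FALSE] < -tol) > 0L]
    }
    X <- .clip_neg(X, cons, Fset)
    ## optimality: a positive gradient on an active constrained variable
    ## means that variable must enter the passive set
    W <- AtB[, Fset, drop = FALSE] - AtA %*% X[, Fset, drop = FALSE]
    Wc <- W[cons, , drop = FALSE]
    Wc[Pass[cons, Fset, drop = FALSE]] <- -Inf
    jmax <- max.col(t(Wc), ties.method = "first")
    wmax <- Wc[cbind(jmax, seq_along(Fset))]
    keep <- wmax > tol
    if (any(keep)) {
      Pass[cbind(cons[jmax[keep]], Fset[keep])] <- TRUE
    }
    Fset <- Fset[keep]
  }
  list(X = X, ridged = env$ridged)
}
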