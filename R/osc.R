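# Orthogonal signal correction.
#
# Each component finds the direction of maximal X-variance whose score is
# exactly orthogonal to the response: w maximizes ||X w|| subject to
# w'X'y = 0 and ||w|| = 1, so t = X w satisfies t'y = 0 to machine precision
# (the constrained-eigenvector formulation of OSC). X is then deflated by
# t p' with p = X't / t't. Because the constraint is built into w, applying
# the stored w/p to the training matrix reproduces the corrected matrix
# exactly, and no iterative convergence is involved.

#' Fit orthogonal signal correction components
#'
#' @param x Centered spectra matrix (samples x variables).
#' @param y Class-code response (at least two distinct values); centered
#'   internally.
#' @param n_osc Number of components to remove (0 returns `x` unchanged).
#' @return An `osc` object: matrices `w` (weights, unit columns), `p`
#'   (loadings), `t` (training scores), vector `removed` (fraction of total
#'   X sum of squares removed per component), and `x_corrected`.
#' @export
osc_fit <- function(x, y, n_osc = 1) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  if (length(unique(y)) < 2) {
    stop("response must have at least two distinct values", call. = FALSE)
  }
  yc <- unname(y - mean(y))
  totss <- sum(x^2)
  p_dim <- ncol(x)
  w_mat <- p_mat <- matrix(0, p_dim, n_osc)
  t_mat <- matrix(0, nrow(x), n_osc)
  removed <- numeric(n_osc)
  for (k in seq_len(n_osc)) {
    v <- drop(crossprod(x, yc))
    vn <- sqrt(sum(v^2))
    if (vn < .Machine$double.eps * p_dim) {
      stop("X carries no response-related signal to orthogonalize against",
           call. = FALSE)
    }
    v <- v / vn
    # top right singular vector of X restricted to the subspace orthogonal
    # to v: deflate v out of X's rows and take the leading loading
    xp <- x - (x %*% v) %*% t(v)
    sv <- svd(xp, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12 * sqrt(totss)) {
      # all X variance is response-related: nothing orthogonal to remove
      w_mat <- w_mat[, seq_len(k - 1), drop = FALSE]
      p_mat <- p_mat[, seq_len(k - 1), drop = FALSE]
      t_mat <- t_mat[, seq_len(k - 1), drop = FALSE]
      removed <- removed[seq_len(k - 1)]
      return(structure(list(w = w_mat, p = p_mat, t = t_mat,
                            removed = removed, x_corrected = x,
                            n_osc = ncol(w_mat)),
                       class = "osc"))
    }
    w <- drop(sv$v[, 1])
    w <- w - v * sum(v * w)          # enforce the constraint exactly
    w <- w / sqrt(sum(w^2))
    tt <- drop(x %*% w)
    p <- drop(crossprod(x, tt)) / sum(tt^2)
    x <- x - tcrossprod(tt, p)
    w_mat[, k] <- w
    p_mat[, k] <- p
    t_mat[, k] <- tt
    removed[k] <- sum(tt^2 * sum(p^2)) / totss
  }
  structure(list(w = w_mat, p = p_mat, t = t_mat, removed = removed,
                 x_corrected = x, n_osc = n_osc),
            class = "osc")
}

#' Apply a fitted OSC filter to new samples
#'
#' Uses only the stored weights and loadings (no access to labels):
#' `t_new = X w / (w'w)` per component, then deflation by `t_new p'`.
#'
#' @param object An [osc_fit()] result.
#' @param x_new Matrix centered with the training means.
#' @return Corrected matrix.
#' @export
osc_apply <- function(object, x_new) {
  x_new <- as.matrix(x_new)
  dimnames(x_new) <- NULL
  if (ncol(x_new) != nrow(object$w)) {
    stop("grid mismatch between new data and OSC model", call. = FALSE)
  }
  for (k in seq_len(object$n_osc)) {
    w <- object$w[, k]
    tt <- drop(x_new %*% w) / sum(w^2)
    x_new <- x_new - tcrossprod(tt, object$p[, k])
  }
  x_new
}
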