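#' Optimal weighted rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the weighted RMSD
#' between two coordinate sets, i.e. the transform taking `Y` onto `X`.
#' Reflections are excluded (determinant +1), as required when comparing
#' molecular conformations.
#'
#' @param X,Y `n x 3` coordinate matrices (`n >= 3`, not collinear).
#' @param weights optional non-negative per-point weights (e.g. masses);
#'   default uniform. Must not be all zero.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (the minimised weighted RMSD) and `Y_fit` (`Y` after the
#'   transform). The weighted RMSD is
#'   `sqrt(sum(w_i * |X_i - Y_fit_i|^2) / sum(w))`.
#' @export
kabsch_superpose <- function(X, Y, weights = NULL) {
  X <- .as_coords(X); Y <- .as_coords(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal size", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 points", call. = FALSE)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  w <- weights / sum(weights)
  cx <- colSums(X * w)
  cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  # degenerate (collinear) configurations have a rank-deficient covariance
  # in *both* structures; the rotation about the common axis is undefined
  sx <- svd(Xc * sqrt(w), nu = 0, nv = 0)$d
  sy <- svd(Yc * sqrt(w), nu = 0, nv = 0)$d
  if (min(sx[2], sy[2]) < 1e-10 * max(1, sx[1], sy[1])) {
    stop("degenerate (collinear) point set: superposition is not unique",
         call. = FALSE)
  }
  H <- crossprod(Yc * w, Xc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Y_fit <- Yc %*% t(R)
  msd <- sum(w * rowSums((Xc - Y_fit)^2))
  Y_fit <- sweep(Y_fit, 2, cx, FUN = "+")
  list(rotation = R,
       translation = as.numeric(cx - R %*% cy),
       rmsd = sqrt(max(msd, 0)),
       Y_fit = Y_fit)
}

#' Weighted RMSD without fitting
#'
#' @inheritParams kabsch_superpose
#' @return the plain weighted root-mean-square deviation.
#' @export
rmsd_nofit <- function(X, Y, weights = NULL) {
  X <- .as_coords(X); Y <- .as_coords(Y)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((X - Y)^2)))
}
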