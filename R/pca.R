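#' Principal component analysis of domain motion
#'
#' Eigendecomposition of the Cartesian coordinate covariance matrix over
#' an analysis selection (e.g. the mobile domain), computed across the
#' frames of a trajectory that has normally been aligned first with
#' [fit_superpose_series()] on the *complementary* selection — the
#' fit-excluded protocol that expresses domain motion relative to the
#' scaffold.
#'
#' @param trajectory an `md_trajectory` (>= 2 frames; a single frame
#'   yields all-zero eigenvalues with a warning).
#' @param selection group name or index vector to analyse (`NULL` = all).
#' @return object of class `pca_result`: `mean_coords` (the selection
#'   mean, `k x 3`), `modes` (`3k x m` orthonormal columns),
#'   `eigenvalues` (variances, descending), `fractions`
#'   (eigenvalue/total), `selection`, `n_frames`. The trailing
#'   zero-variance dimensions are retained so fractions sum to 1 and a
#'   full-rank reconstruction is exact.
#' @export
pca_modes <- function(trajectory, selection = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  sel <- if (is.null(trajectory$system)) {
    if (is.null(selection)) seq_len(dim(trajectory$coords)[1]) else
      as.integer(selection)
  } else {
    group_indices(trajectory$system, selection)
  }
  nf <- n_frames(trajectory)
  k <- length(sel)
  M <- t(matrix(trajectory$coords[sel, , ], 3 * k, nf)) # frames x 3k
  mean_flat <- colMeans(M)
  if (nf < 2) {
    warning("single frame: covariance is zero", call. = FALSE)
    modes <- diag(3 * k)
    return(structure(list(
      mean_coords = matrix(mean_flat, k, 3), modes = modes,
      eigenvalues = rep(0, 3 * k), fractions = rep(NA_real_, 3 * k),
      selection = sel, n_frames = nf), class = "pca_result"))
  }
  Mc <- sweep(M, 2, mean_flat)
  sv <- svd(Mc, nu = 0)
  eig <- sv$d^2 / (nf - 1)
  m <- 3 * k
  if (length(eig) < m) { # complete the orthonormal basis; zero variance
    eig <- c(eig, rep(0, m - length(eig)))
    Q <- qr.Q(qr(cbind(sv$v, diag(m))))[, seq_len(m), drop = FALSE]
    modes <- Q
  } else {
    modes <- sv$v
  }
  total <- sum(eig)
  structure(list(mean_coords = matrix(mean_flat, k, 3), modes = modes,
                 eigenvalues = eig,
                 fractions = if (total > 0) eig / total else eig,
                 selection = sel, n_frames = nf),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  top <- utils::head(x$fractions, 3)
  cat("<pca_result> ", length(x$selection), " particles, ", x$n_frames,
      " frames\n  top mode fractions: ",
      paste(sprintf("%.1f%%", 100 * top), collapse = " + "), "\n",
      sep = "")
  invisible(x)
}

#' Project a trajectory onto principal modes
#'
#' Projects each frame's (centred) selection coordinates onto the leading
#' modes. The projection of the mean structure is the origin; for the
#' trajectory the modes were computed from, the per-mode projection
#' variance equals the eigenvalue, and a full-rank projection
#' reconstructs the centred coordinates exactly.
#'
#' @param trajectory an `md_trajectory` with the same selection
#'   dimensions as `pca`.
#' @param pca a [pca_modes()] result.
#' @param n_modes number of leading modes (default 3, capped at the
#'   available count; requesting more is an error).
#' @return tibble with `frame`, `time` and one `pc<i>` column per mode.
#' @export
project_trajectory <- function(trajectory, pca, n_modes = 3) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            inherits(pca, "pca_result"))
  if (n_modes > ncol(pca$modes)) {
    stop("n_modes exceeds available modes (", ncol(pca$modes), ")",
         call. = FALSE)
  }
  sel <- pca$selection
  nf <- n_frames(trajectory)
  M <- t(matrix(trajectory$coords[sel, , ], 3 * length(sel), nf))
  Mc <- sweep(M, 2, as.vector(pca$mean_coords))
  scores <- Mc %*% pca$modes[, seq_len(n_modes), drop = FALSE]
  colnames(scores) <- paste0("pc", seq_len(n_modes))
  dplyr::bind_cols(tibble::tibble(frame = seq_len(nf),
                                  time = trajectory$times),
                   tibble::as_tibble(scores))
}

#' Tidy a PCA result
#'
#' @param x a `pca_result`.
#' @param ... unused.
#' @return tibble with `mode`, `eigenvalue`, `fraction`,
#'   `cumulative_fraction`.
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 fraction = x$fractions,
                 cumulative_fraction = cumsum(x$fractions))
}

#' One-row PCA summary
#'
#' @param x a `pca_result`.
#' @param ... unused.
#' @return tibble with the total variance and the variance fractions of
#'   the first three modes.
#' @export
glance.pca_result <- function(x, ...) {
  fr <- c(x$fractions, rep(NA_real_, 3))
  tibble::tibble(n_frames = x$n_frames,
                 n_particles = length(x$selection),
                 total_variance = sum(x$eigenvalues),
                 fraction_pc1 = fr[1], fraction_pc2 = fr[2],
                 fraction_pc3 = fr[3],
                 fraction_top3 = sum(fr[1:3], na.rm = TRUE))
}

#' Tidy a step-by-step campaign
#'
#' @param x a `stepwise_campaign`.
#' @param ... unused.
#' @return the per-cycle minimum-metric tibble.
#' @export
tidy.stepwise_campaign <- function(x, ...) {
  x$series
}

#' One-row campaign summary
#'
#' @param x a `stepwise_campaign`.
#' @param ... unused.
#' @return tibble with cycle count, initial and final minimum metric,
#'   convergence flag and failure count.
#' @export
glance.stepwise_campaign <- function(x, ...) {
  tibble::tibble(
    n_cycles = nrow(x$series),
    initial_metric = x$initial_metric,
    final_min_metric = if (nrow(x$series)) {
      utils::tail(x$series$min_metric, 1)
    } else {
      x$initial_metric
    },
    converged = x$converged,
    n_failures = length(x$failures))
}
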