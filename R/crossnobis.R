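#' Multi-run beta patterns plus residual time courses
#'
#' Container for the inputs of crossnobis RDM estimation: per-run GLM beta
#' estimates (one multi-voxel pattern per category per run) and per-run GLM
#' residual time courses used to estimate the voxel noise covariance.
#'
#' @param betas numeric array, runs x categories x voxels.
#' @param residuals numeric array, runs x timepoints x voxels, or `NULL`
#'   when no noise estimation is needed.
#' @param labels category labels (length = dim(betas)\[2\]).
#' @param run_ids run identifiers (length = dim(betas)\[1\]).
#' @export
pattern_dataset <- function(betas, residuals = NULL, labels = NULL, run_ids = NULL) {
  if (length(dim(betas)) != 3) stop("betas must be a runs x categories x voxels array")
  nr <- dim(betas)[1]; nc <- dim(betas)[2]; nv <- dim(betas)[3]
  if (nr < 2) stop("need at least 2 runs")
  if (anyNA(betas)) stop("betas contain missing values")
  if (!is.null(residuals)) {
    if (length(dim(residuals)) != 3) {
      stop("residuals must be a runs x timepoints x voxels array")
    }
    if (dim(residuals)[1] != nr) stop("residual run count does not match betas")
    if (dim(residuals)[3] != nv) stop("residual voxel count does not match betas")
    if (anyNA(residuals)) stop("residuals contain missing values")
  }
  if (is.null(labels)) labels <- paste0("cat", seq_len(nc))
  if (length(labels) != nc) stop("label count does not match category dimension")
  if (is.null(run_ids)) run_ids <- paste0("run", seq_len(nr))
  if (length(run_ids) != nr) stop("run_ids length does not match run dimension")
  structure(list(betas = betas, residuals = residuals,
                 labels = as.character(labels), run_ids = as.character(run_ids)),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  d <- dim(x$betas)
  cat("Pattern dataset:", d[1], "runs x", d[2], "categories x", d[3], "voxels",
      if (is.null(x$residuals)) "(no residuals)\n"
      else paste0("(residuals: ", dim(x$residuals)[2], " timepoints/run)\n"))
  invisible(x)
}

#' Noise model: shrinkage-regularized voxel covariance and whitener
#'
#' Wraps a voxel covariance estimate with its shrinkage intensity and the
#' symmetric inverse-square-root whitening transform W satisfying
#' \eqn{W' \Sigma W = I}.
#'
#' @param sigma symmetric positive-definite voxel x voxel covariance.
#' @param lambda shrinkage intensity used to produce `sigma` (metadata).
#' @export
noise_model <- function(sigma, lambda = NA_real_) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma)) stop("sigma must be square")
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) <= 0) {
    stop("sigma is not positive definite (min eigenvalue ", format(min(e$values)), ")")
  }
  w <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  structure(list(sigma = sigma, lambda = lambda, whitener = w),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Noise model:", nrow(x$sigma), "voxels, shrinkage lambda =",
      format(x$lambda, digits = 3), "\n")
  invisible(x)
}

#' Identity noise model (no whitening)
#' @param n_voxels voxel count.
#' @export
noise_model_identity <- function(n_voxels) noise_model(diag(n_voxels), lambda = 0)

#' Estimate the voxel noise covariance from GLM residuals
#'
#' Per-run residual time courses are column-centered within run and pooled
#' into one sample covariance (equivalent, for equal-length runs, to
#' averaging per-run covariances), which is then shrunk toward its diagonal:
#' \eqn{\hat\Sigma = (1-\lambda) S + \lambda \mathrm{diag}(S)}. With
#' `shrinkage = "auto"` the intensity is the analytic diagonal-target
#' (Schafer-Strimmer/Ledoit-Wolf style) estimator; a fixed numeric
#' \eqn{\lambda \in [0, 1]} can be supplied instead.
#'
#' @param residuals runs x timepoints x voxels array, a list of
#'   timepoints x voxels matrices (one per run), or a single matrix.
#' @param shrinkage `"auto"` or a number in \[0, 1\].
#' @return a [noise_model()].
#' @export
estimate_noise <- function(residuals, shrinkage = "auto") {
  if (is.array(residuals) && length(dim(residuals)) == 3) {
    residuals <- lapply(seq_len(dim(residuals)[1]),
                        function(r) residuals[r, , , drop = TRUE])
  } else if (is.matrix(residuals)) {
    residuals <- list(residuals)
  }
  if (!is.list(residuals) || length(residuals) < 1) {
    stop("residuals must be a matrix, list of matrices, or 3-D array")
  }
  for (r in residuals) {
    if (!is.matrix(r) || nrow(r) < 2) stop("each run needs >= 2 timepoints")
    if (anyNA(r) || any(!is.finite(r))) stop("non-finite residual values")
  }
  p <- ncol(residuals[[1]])
  centered <- lapply(residuals, function(r) scale(r, center = TRUE, scale = FALSE))
  x <- do.call(rbind, centered)
  n <- nrow(x)
  dof <- n - length(residuals)           # one mean removed per run
  s <- crossprod(x) / dof
  v <- diag(s)
  if (any(v <= 0)) {
    stop("zero-variance voxel(s): ", paste(which(v <= 0), collapse = ", "))
  }
  if (identical(shrinkage, "auto")) {
    # analytic diagonal-target shrinkage: lambda* =
    # sum_{i != j} Var-hat(s_ij) / sum_{i != j} s_ij^2
    w_bar <- crossprod(x) / n
    w_var <- crossprod(x^2) / n - w_bar^2
    var_s <- n / ((n - 1)^3) * n * w_var
    off <- upper.tri(s)
    denom <- sum((s[off])^2)
    lambda <- if (denom > 0) sum(var_s[off]) / denom else 1
    lambda <- min(1, max(0, lambda))
  } else {
    lambda <- as.numeric(shrinkage)
    if (is.na(lambda) || lambda < 0 || lambda > 1) {
      stop("fixed shrinkage must lie in [0, 1]")
    }
  }
  sigma <- (1 - lambda) * s + lambda * diag(v, nrow = p)
  noise_model(sigma, lambda = lambda)
}

#' Whiten beta patterns with a noise model
#'
#' Right-multiplies each pattern by the whitening transform (symmetric
#' inverse square root of the noise covariance). An identity noise model
#' leaves the patterns unchanged.
#'
#' @param betas categories x voxels matrix, or runs x categories x voxels
#'   array.
#' @param noise a [noise_model()].
#' @export
whiten <- function(betas, noise) {
  stopifnot(inherits(noise, "noise_model"))
  w <- noise$whitener
  if (is.matrix(betas)) {
    if (ncol(betas) != nrow(w)) stop("voxel dimension mismatch")
    return(betas %*% w)
  }
  if (length(dim(betas)) == 3) {
    if (dim(betas)[3] != nrow(w)) stop("voxel dimension mismatch")
    out <- betas
    for (r in seq_len(dim(betas)[1])) {
      out[r, , ] <- betas[r, , , drop = TRUE] %*% w
    }
    return(out)
  }
  stop("betas must be a matrix or 3-D array")
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' Leave-one-run-out cross-validated squared Mahalanobis distances between
#' category patterns. Patterns are first whitened by the noise model; for
#' each left-out run m the fold distance is
#' \deqn{d_m(i,j) = (\bar u_i - \bar u_j) \cdot (u_i^{(m)} - u_j^{(m)}) / P}
#' with \eqn{\bar u} the mean whitened pattern over the remaining runs and
#' P the voxel count (set `normalize_by_voxels = FALSE` to skip the 1/P).
#' The returned entry is the mean over folds. Because the two factors come
#' from independent data, the estimator is unbiased: true-equal patterns
#' give distances distributed around zero, so entries may be negative.
#'
#' @param data a [pattern_dataset()].
#' @param noise a [noise_model()]; defaults to estimating one from the
#'   dataset's residuals (auto shrinkage), or the identity if the dataset
#'   has no residuals.
#' @param normalize_by_voxels divide by voxel count so values are comparable
#'   across ROI/searchlight sizes (default `TRUE`).
#' @return an [rdm()] over the dataset's category labels.
#' @export
crossnobis_rdm <- function(data, noise = NULL, normalize_by_voxels = TRUE) {
  stopifnot(inherits(data, "pattern_dataset"))
  nr <- dim(data$betas)[1]
  nv <- dim(data$betas)[3]
  if (nr < 2) stop("need at least 2 runs")
  if (is.null(noise)) {
    noise <- if (is.null(data$residuals)) noise_model_identity(nv)
             else estimate_noise(data$residuals)
  }
  u <- whiten(data$betas, noise)
  denom <- if (normalize_by_voxels) nv else 1
  acc <- matrix(0, dim(u)[2], dim(u)[2])
  for (m in seq_len(nr)) {
    train <- apply(u[-m, , , drop = FALSE], c(2, 3), mean)
    test <- u[m, , , drop = TRUE]
    if (is.null(dim(test))) test <- matrix(test, nrow = dim(u)[2])
    cp <- train %*% t(test)                      # cp[i,j] = train_i . test_j
    d <- outer(diag(cp), diag(cp), `+`) - cp - t(cp)
    acc <- acc + d / denom
  }
  out <- acc / nr
  diag(out) <- 0
  rdm(out, labels = data$labels, tol = 1e-8)
}
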