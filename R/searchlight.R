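#' Volumetric multi-run pattern dataset for searchlight analysis
#'
#' Stores per-run beta patterns (and optionally residual time courses) for
#' every in-mask voxel of a 3-D volume, together with the voxel mask that
#' maps the flat voxel dimension back into the volume.
#'
#' @param betas runs x categories x in-mask-voxels array. Voxel order is
#'   the order of `which(mask)` (column-major).
#' @param mask logical 3-D array marking the analyzed voxels.
#' @param residuals optional runs x timepoints x in-mask-voxels array.
#' @param labels category labels.
#' @param run_ids run identifiers.
#' @export
volume_dataset <- function(betas, mask, residuals = NULL, labels = NULL,
                           run_ids = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3 || !is.logical(mask)) {
    stop("mask must be a logical 3-D array")
  }
  if (!any(mask)) stop("mask is empty")
  nmask <- sum(mask)
  if (length(dim(betas)) != 3 || dim(betas)[3] != nmask) {
    stop("betas must be runs x categories x ", nmask, " (in-mask voxels)")
  }
  pd <- pattern_dataset(betas, residuals, labels, run_ids)
  structure(c(pd, list(mask = mask, dims = dim(mask))),
            class = c("volume_dataset", "pattern_dataset"))
}

#' @export
print.volume_dataset <- function(x, ...) {
  d <- dim(x$betas)
  cat("Volume dataset:", paste(x$dims, collapse = " x "), "volume,",
      sum(x$mask), "in-mask voxels,", d[1], "runs x", d[2], "categories\n")
  invisible(x)
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets with Euclidean norm at most `radius`, center
#' included, in lexicographic (dx, dy, dz) order. Radius 3 yields the
#' 123-voxel spherical neighborhood used for whole-brain mapping.
#'
#' @param radius sphere radius in voxels (boundary inclusive).
#' @return integer matrix with columns dx, dy, dz.
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)  # dx slowest => lexicographic
  g <- g[, c("dx", "dy", "dz")]
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-12
  m <- as.matrix(g[keep, , drop = FALSE])
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Searchlight map of model partial correlations
#'
#' Moves a spherical neighborhood over every in-mask voxel, computes the
#' crossnobis RDM from the sphere's voxels (noise-normalized per sphere
#' when residuals are available), and assigns to the center voxel the
#' partial correlation of each model RDM with the sphere RDM, controlling
#' for the remaining models.
#'
#' @param vol a [volume_dataset()].
#' @param models named list of model RDM vectors (from [rdm_vectorize()]),
#'   all matching the dataset's category pairs.
#' @param radius sphere radius in voxels (default 3, the 123-voxel sphere).
#' @param min_voxels centers whose sphere holds fewer in-mask voxels are
#'   skipped (left `NA`).
#' @param noise `"per_sphere"` re-estimates the noise covariance from the
#'   sphere's residuals (when present); `"identity"` skips whitening.
#' @param shrinkage shrinkage passed to [estimate_noise()].
#' @return list with one 3-D partial-correlation array per model (`NA`
#'   outside the mask and at skipped centers) and `n_skipped`.
#' @export
run_searchlight <- function(vol, models, radius = 3, min_voxels = 2,
                            noise = c("per_sphere", "identity"),
                            shrinkage = "auto") {
  stopifnot(inherits(vol, "volume_dataset"))
  noise <- match.arg(noise)
  ncat <- dim(vol$betas)[2]
  npair <- ncat * (ncat - 1) / 2
  if (!is.list(models) || length(models) < 2) {
    stop("models must be a list of at least 2 RDM vectors")
  }
  models <- lapply(models, vectorize_arg)
  if (any(vapply(models, length, 1L) != npair)) {
    stop("model vector length must be ", npair, " (category pairs)")
  }
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))

  dims <- vol$dims
  vox_index <- array(0L, dims)
  vox_index[vol$mask] <- seq_len(sum(vol$mask))
  centers <- which(vol$mask, arr.ind = TRUE)
  offs <- sphere_offsets(radius)
  out <- lapply(models, function(m) array(NA_real_, dims))
  n_skipped <- 0L
  use_noise <- noise == "per_sphere" && !is.null(vol$residuals)

  for (ci in seq_len(nrow(centers))) {
    pos <- sweep(offs, 2, centers[ci, ], `+`)
    ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
          pos[, 2] >= 1 & pos[, 2] <= dims[2] &
          pos[, 3] >= 1 & pos[, 3] <= dims[3]
    ids <- vox_index[pos[ok, , drop = FALSE]]
    ids <- ids[ids > 0]
    if (length(ids) < min_voxels) {
      n_skipped <- n_skipped + 1L
      next
    }
    nm <- if (use_noise) {
      estimate_noise(vol$residuals[, , ids, drop = FALSE], shrinkage = shrinkage)
    } else {
      noise_model_identity(length(ids))
    }
    pd <- pattern_dataset(vol$betas[, , ids, drop = FALSE],
                          labels = vol$labels, run_ids = vol$run_ids)
    vals <- tryCatch({
      v <- rdm_vectorize(crossnobis_rdm(pd, noise = nm))
      vapply(seq_along(models), function(k) {
        partial_correlation(v, models[[k]], models[-k])
      }, 1)
    }, error = function(e) rep(NA_real_, length(models)))
    for (k in seq_along(models)) {
      out[[k]][centers[ci, 1], centers[ci, 2], centers[ci, 3]] <- vals[k]
    }
  }
  c(out, list(n_skipped = n_skipped))
}

#' Threshold-free cluster enhancement of a statistic volume
#'
#' Integrates cluster extent and height over all thresholds:
#' \deqn{TFCE(v) = \sum_{h = dh, 2dh, \ldots} e_v(h)^E h^H \, dh}
#' where \eqn{e_v(h)} is the size of the connected supra-threshold cluster
#' containing v at height h. Negative values are enhanced symmetrically
#' (transform of the negated map, negated). Non-finite voxels are treated
#' as outside the mask.
#'
#' @param stat 3-D numeric array (`NA` outside the mask).
#' @param E,H extent and height exponents (defaults 0.5 and 2, the
#'   conventional values).
#' @param dh integration step.
#' @param connectivity cluster connectivity: 6, 18 or 26.
#' @return 3-D array of TFCE values.
#' @export
tfce_transform <- function(stat, E = 0.5, H = 2, dh = 0.1, connectivity = 18) {
  if (!is.array(stat) || length(dim(stat)) != 3) stop("stat must be a 3-D array")
  if (dh <= 0) stop("dh must be positive")
  out <- tfce_cpp(as.numeric(stat), as.integer(dim(stat)),
                  E, H, dh, as.integer(connectivity))
  array(out, dim(stat))
}

group_t_to_z <- function(x) {
  # x: participants x voxels; returns z-converted one-sample t per voxel
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  stats::qnorm(stats::pt(t, df = n - 1, lower.tail = FALSE, log.p = TRUE),
               lower.tail = FALSE, log.p = TRUE)
}

#' Sign-flip permutation group inference with TFCE correction
#'
#' One-sample group test of per-participant statistic volumes against zero.
#' The observed map is the TFCE transform of the voxelwise one-sample t map
#' (converted to z). The null distribution is the maximum TFCE value over
#' the mask under random sign flips of whole participant maps; the
#' corrected p-value per voxel is `(1 + #{max_perm >= observed}) /
#' (1 + n_perm)`. Sign vectors are drawn in antithetic pairs (each base
#' draw and its negation), which balances the null and makes it exactly
#' symmetric under negating all input maps; use an even `n_perm`. A one-sided display threshold at `z_threshold` (default
#' 1.64, one-sided p < 0.05) is combined with the corrected p to give the
#' `significant` overlay.
#'
#' @param maps list of per-participant 3-D arrays (aligned; `NA` outside
#'   the shared mask), or a 4-D array with participants in the 4th
#'   dimension.
#' @param n_perm number of sign-flip permutations (the study used 10,000).
#' @param rng_seed integer seed.
#' @param alpha familywise error level for the `significant` overlay.
#' @param z_threshold one-sided display threshold on the z map.
#' @inheritParams tfce_transform
#' @return list with `z`, `tfce`, `p_corrected`, `significant` (3-D
#'   arrays) and `max_null` (the permutation maxima).
#' @export
group_sign_permutation <- function(maps, n_perm = 10000, rng_seed = NULL,
                                   E = 0.5, H = 2, dh = 0.1, connectivity = 18,
                                   alpha = 0.05, z_threshold = 1.64) {
  if (is.array(maps) && length(dim(maps)) == 4) {
    maps <- lapply(seq_len(dim(maps)[4]), function(i) maps[, , , i])
  }
  n <- length(maps)
  if (n < 5) stop("need at least 5 participants")
  dims <- dim(maps[[1]])
  if (any(!vapply(maps, function(m) identical(dim(m), dims), TRUE))) {
    stop("participant volumes are not aligned (differing dims)")
  }
  if (n_perm < ceiling(1 / alpha) - 1) {
    warning("n_perm too small to ever reach p < ", alpha)
  }
  flat <- do.call(rbind, lapply(maps, as.numeric))
  mask <- colSums(is.finite(flat)) == n
  if (!any(mask)) stop("no voxel is finite in all participants")
  x <- flat[, mask, drop = FALSE]

  z_of <- function(xx) {
    v <- rep(NA_real_, prod(dims))
    v[mask] <- group_t_to_z(xx)
    array(v, dims)
  }
  tf_of <- function(zz) tfce_transform(zz, E = E, H = H, dh = dh,
                                       connectivity = connectivity)
  z_obs <- z_of(x)
  tfce_obs <- tf_of(z_obs)
  with_seed(rng_seed, {
    # antithetic draws: each base sign vector contributes itself and its
    # negation, so the realized null set is closed under negating the data
    max_null <- unlist(lapply(seq_len(ceiling(n_perm / 2)), function(b) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      c(max(tf_of(z_of(signs * x))[mask]),
        max(tf_of(z_of(-signs * x))[mask]))
    }))[seq_len(n_perm)]
    obs_vals <- tfce_obs[mask]
    p <- vapply(obs_vals, function(v) (1 + sum(max_null >= v)) / (1 + n_perm), 1)
    p_vol <- array(NA_real_, dims); p_vol[mask] <- p
    sig <- array(NA, dims)
    sig[mask] <- (z_obs[mask] > z_threshold) & (p < alpha)
    list(z = z_obs, tfce = tfce_obs, p_corrected = p_vol,
         significant = sig, max_null = max_null)
  })
}
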