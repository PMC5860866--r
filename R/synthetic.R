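#' Generate model RDM triplets with controlled inter-correlation
#'
#' Builds `n_models` feature matrices as weighted mixtures of one shared
#' latent feature block and independent model-specific blocks, then
#' converts each to an RDM via [rdm_from_features()]. With a fraction
#' \eqn{\alpha} of each item's feature variance coming from the shared
#' block, the expected between-model RDM correlation is \eqn{\alpha^2}
#' (the shared-by-shared term of the feature inner products; the
#' shared-by-own cross terms act as model-specific noise), so the
#' generator uses \eqn{\alpha = \sqrt{target}}. Achieved correlations
#' scatter around the target with finite-sample error (standard deviation
#' about 0.05 at 30 items, i.e. 435 pairs).
#'
#' @param n_items number of items (>= 4).
#' @param n_models number of models (the study design uses 3).
#' @param target_pairwise_r desired pairwise RDM correlation, in \[0, 1).
#'   Negative targets are not constructible from a shared component for
#'   three mutually negative models and raise an error.
#' @param n_features features per model.
#' @param rng_seed integer seed.
#' @return named list of `rdm` objects sharing the same labels.
#' @export
gen_model_rdms <- function(n_items = 30, n_models = 3, target_pairwise_r = 0.25,
                           n_features = 50, rng_seed = NULL) {
  if (n_items < 4) stop("n_items must be >= 4")
  if (abs(target_pairwise_r) >= 1) stop("|target_pairwise_r| must be < 1")
  if (target_pairwise_r < 0) {
    stop("infeasible correlation structure: a shared-component design cannot ",
         "make all model pairs negatively correlated")
  }
  alpha <- sqrt(target_pairwise_r)           # shared share of feature variance
  labels <- sprintf("cat%02d", seq_len(n_items))
  with_seed(rng_seed, {
    shared <- matrix(stats::rnorm(n_items * n_features), n_items)
    out <- lapply(seq_len(n_models), function(m) {
      own <- matrix(stats::rnorm(n_items * n_features), n_items)
      f <- sqrt(alpha) * shared + sqrt(1 - alpha) * own
      rownames(f) <- labels
      rdm_from_features(f)
    })
    names(out) <- paste0("model", seq_len(n_models))
    out
  })
}

embed_target_patterns <- function(target, n_voxels, tol = 1e-8) {
  # distance-to-Gram embedding: patterns whose pairwise squared Euclidean
  # distances equal target * n_voxels
  d <- unclass(as_rdm_matrix(target)) * n_voxels
  n <- nrow(d)
  cmat <- diag(n) - 1 / n
  g <- -0.5 * cmat %*% d %*% cmat
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  neg <- -min(e$values, 0)
  if (neg > tol * max(abs(e$values), 1)) {
    stop("target RDM is not embeddable as squared Euclidean distances ",
         "(negative Gram eigenvalue ", format(-neg), "); consider adding a ",
         "constant to the off-diagonal entries (diagonal inflation)")
  }
  ev <- pmax(e$values, 0)
  r <- sum(ev > tol * max(ev, 1))
  if (r > n_voxels) {
    stop("target RDM needs ", r, " dimensions but only ", n_voxels,
         " voxels are available")
  }
  x0 <- e$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(r)]), nrow = r)
  # spread over voxels through a random orthonormal basis
  q <- qr.Q(qr(matrix(stats::rnorm(n_voxels * r), n_voxels)))[, seq_len(r), drop = FALSE]
  x0 %*% t(q)
}

random_spd_cov <- function(p) {
  a <- matrix(stats::rnorm(p * (p + 5)), p + 5, p)
  s <- crossprod(a) / (p + 5)
  s / mean(diag(s))                          # unit average voxel variance
}

#' Generate a multi-run pattern dataset realizing a target RDM
#'
#' Category base patterns are constructed by the classical
#' distance-to-Gram embedding (double-centered second moment, eigenvalues
#' clipped at zero) so their pairwise squared Euclidean distances divided
#' by the voxel count equal the target RDM exactly; per-run betas add
#' Gaussian noise with the requested voxel covariance, and residual time
#' courses share that covariance. With `noise_sd = 0` the crossnobis RDM
#' of the output reproduces the target up to numerical error (no residuals
#' are generated in that case, since a noiseless covariance is degenerate).
#'
#' @param target an `rdm`; must be embeddable (e.g. any 1 - Pearson RDM).
#' @param n_voxels voxels per pattern (>= embedding rank).
#' @param n_runs number of runs (the study's event-related design used 8).
#' @param signal_scale multiplier on the base patterns (squared distances
#'   scale by its square).
#' @param noise_sd per-voxel noise standard deviation.
#' @param noise_cov `"identity"`, `"random_spd"`, or an explicit voxel
#'   covariance matrix.
#' @param n_timepoints residual timepoints per run.
#' @param rng_seed integer seed.
#' @return a [pattern_dataset()] with a `ground_truth` attribute recording
#'   the target, noise level, noise covariance and seed.
#' @export
gen_pattern_dataset <- function(target, n_voxels, n_runs = 8, signal_scale = 1,
                                noise_sd = 1, noise_cov = "identity",
                                n_timepoints = 100, rng_seed = NULL) {
  target <- as_rdm_matrix(target)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(rng_seed, {
    base <- embed_target_patterns(target, n_voxels) * signal_scale
    ncat <- nrow(base)
    sigma <- if (is.matrix(noise_cov)) {
      noise_cov
    } else if (identical(noise_cov, "identity")) {
      diag(n_voxels)
    } else if (identical(noise_cov, "random_spd")) {
      random_spd_cov(n_voxels)
    } else stop("noise_cov must be 'identity', 'random_spd' or a matrix")
    lt <- chol(sigma)
    betas <- array(0, c(n_runs, ncat, n_voxels))
    for (r in seq_len(n_runs)) {
      noise <- if (noise_sd > 0) {
        noise_sd * matrix(stats::rnorm(ncat * n_voxels), ncat) %*% lt
      } else 0
      betas[r, , ] <- base + noise
    }
    residuals <- NULL
    if (noise_sd > 0 && n_timepoints > 0) {
      residuals <- array(0, c(n_runs, n_timepoints, n_voxels))
      for (r in seq_len(n_runs)) {
        residuals[r, , ] <- noise_sd *
          matrix(stats::rnorm(n_timepoints * n_voxels), n_timepoints) %*% lt
      }
    }
    out <- pattern_dataset(betas, residuals, labels = rdm_labels(target))
    attr(out, "ground_truth") <- list(target = target, noise_sd = noise_sd,
                                      sigma = noise_sd^2 * sigma,
                                      signal_scale = signal_scale,
                                      seed = rng_seed)
    out
  })
}

#' Generate a circular-arena arrangement realizing a target RDM
#'
#' Category anchor positions come from classical 2-D multidimensional
#' scaling of the target (treated as squared distances), rescaled to fit
#' inside the arena; each category's exemplars scatter around its anchor
#' with Gaussian jitter and are radially clamped to the arena boundary.
#' With zero jitter and a 2-D-embeddable target, [arrangement_to_rdm()] of
#' the output is exactly proportional to the target.
#'
#' @param target an `rdm` over the categories (>= 2 categories).
#' @param exemplars_per_category exemplars scattered per category (the
#'   study showed 4 exemplars per category per set).
#' @param jitter_sd exemplar scatter, in pixels.
#' @param arena_radius arena radius in pixels.
#' @param rng_seed integer seed.
#' @return an [arrangement()] with a `ground_truth` attribute.
#' @export
gen_arrangement <- function(target, exemplars_per_category = 4, jitter_sd = 0,
                            arena_radius = 700, rng_seed = NULL) {
  target <- as_rdm_matrix(target)
  n <- nrow(target)
  if (n < 2) stop("need at least 2 categories")
  if (arena_radius <= 0) stop("arena_radius must be positive")
  d <- sqrt(pmax(unclass(target), 0))
  k <- min(2, n - 1)
  anchors <- stats::cmdscale(stats::as.dist(d), k = k)
  if (ncol(anchors) < 2) anchors <- cbind(anchors, 0)
  rmax <- max(sqrt(rowSums(anchors^2)))
  if (rmax > 0) anchors <- anchors * (0.8 * arena_radius / rmax)
  with_seed(rng_seed, {
    ex <- do.call(rbind, lapply(seq_len(n), function(i) {
      xy <- matrix(rep(anchors[i, ], exemplars_per_category),
                   ncol = 2, byrow = TRUE) +
        matrix(stats::rnorm(2 * exemplars_per_category, sd = jitter_sd), ncol = 2)
      data.frame(exemplar_id = paste0(rdm_labels(target)[i], "_e",
                                      seq_len(exemplars_per_category)),
                 category = rdm_labels(target)[i],
                 x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
    }))
    # clamp any jittered exemplar back onto the arena boundary
    r <- sqrt(ex$x^2 + ex$y^2)
    over <- r > arena_radius
    if (any(over)) {
      scale <- arena_radius / r[over]
      ex$x[over] <- ex$x[over] * scale
      ex$y[over] <- ex$y[over] * scale
    }
    out <- arrangement(ex, arena_radius = arena_radius)
    attr(out, "ground_truth") <- list(target = target, jitter_sd = jitter_sd,
                                      seed = rng_seed)
    out
  })
}

#' Generate a volumetric dataset with a planted representational region
#'
#' Voxels inside the planted region carry category patterns realizing
#' `region_target` (plus noise); all other voxels are pure noise. Returns
#' the dataset together with the ground-truth region mask for recovery
#' scoring of searchlight analyses.
#'
#' @param dims length-3 integer volume dimensions.
#' @param region logical 3-D array or integer matrix of voxel coordinates
#'   (rows = voxels, columns = x, y, z) marking the planted region.
#' @param region_target an `rdm` the region's patterns realize.
#' @param n_runs runs.
#' @param signal_scale multiplier on the planted patterns; 0 plants no
#'   signal and the returned truth mask is empty.
#' @param noise_sd noise standard deviation everywhere.
#' @param n_timepoints residual timepoints per run (0 for none).
#' @param rng_seed integer seed.
#' @return list with `data` (a [volume_dataset()]), `truth` (logical 3-D
#'   array) and `ground_truth`.
#' @export
gen_searchlight_volume <- function(dims, region, region_target, n_runs = 4,
                                   signal_scale = 1, noise_sd = 1,
                                   n_timepoints = 0, rng_seed = NULL) {
  if (length(dims) != 3) stop("dims must have length 3")
  region_target <- as_rdm_matrix(region_target)
  if (is.matrix(region) && !is.logical(region)) {
    rm_ <- array(FALSE, dims)
    rm_[region] <- TRUE
    region <- rm_
  }
  if (!is.array(region) || length(dim(region)) != 3 || !all(dim(region) == dims)) {
    stop("region must be a logical array of dim `dims` or a coordinate matrix")
  }
  if (!any(region)) stop("planted region is empty")
  mask <- array(TRUE, dims)
  nvox <- prod(dims)
  ncat <- nrow(region_target)
  region_ids <- which(region)                # mask is all-TRUE: flat indices
  with_seed(rng_seed, {
    betas <- array(stats::rnorm(n_runs * ncat * nvox, sd = noise_sd),
                   c(n_runs, ncat, nvox))
    if (signal_scale > 0) {
      base <- embed_target_patterns(region_target, length(region_ids)) * signal_scale
      for (r in seq_len(n_runs)) {
        betas[r, , region_ids] <- betas[r, , region_ids] + base
      }
    }
    residuals <- NULL
    if (n_timepoints > 0) {
      residuals <- array(stats::rnorm(n_runs * n_timepoints * nvox, sd = noise_sd),
                         c(n_runs, n_timepoints, nvox))
    }
    truth <- if (signal_scale > 0) region else array(FALSE, dims)
    list(data = volume_dataset(betas, mask, residuals,
                               labels = rdm_labels(region_target)),
         truth = truth,
         ground_truth = list(target = region_target, noise_sd = noise_sd,
                             signal_scale = signal_scale, seed = rng_seed))
  })
}
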