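# Shared fixtures: all data is generated in code, never stored.

# random RDM with valid invariants (not necessarily Euclidean-embeddable)
random_rdm <- function(n, seed, labels = sprintf("c%02d", seq_len(n))) {
  set.seed(seed)
  rdm_unvectorize(runif(n * (n - 1) / 2), labels = labels)
}

# RDM guaranteed embeddable as squared Euclidean distances (1 - Pearson of
# standardized feature rows is proportional to a squared distance)
embeddable_rdm <- function(n, seed, n_features = 40) {
  set.seed(seed)
  f <- matrix(rnorm(n * n_features), n)
  rownames(f) <- sprintf("c%02d", seq_len(n))
  rdm_from_features(f)
}

# RDM that is exactly a squared-distance matrix of 2-D points
planar_rdm <- function(n, seed) {
  set.seed(seed)
  pts <- cbind(rnorm(n), rnorm(n))
  rdm(as.matrix(dist(pts))^2, labels = sprintf("c%02d", seq_len(n)))
}

# small category pool with three class-balanced superordinate groups
make_pool <- function(n_per_class = 4, target_r = 0, seed = 1, n_features = 30) {
  n <- 3 * n_per_class
  models <- gen_model_rdms(n_items = n, n_models = 3,
                           target_pairwise_r = target_r,
                           n_features = n_features, rng_seed = seed)
  category_pool(rdm_labels(models[[1]]),
                rep(c("indoor", "outdoor man-made", "outdoor natural"),
                    each = n_per_class),
                models)
}

# definitional Pearson correlation (sum formula), independent of cor()
pearson_by_sums <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# naive sort-based ranking with average ties, independent of rank()
naive_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}
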