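vectorize_arg <- function(x) {
  if (is_rdm(x) || (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 1)) {
    x <- rdm_vectorize(x)
  }
  as.numeric(x)
}

#' Partial correlation between two vectorized RDMs
#'
#' Pearson correlation between the residuals of `y` and of `x` after
#' least-squares regression of each on the covariate vectors (with
#' intercept). With no covariates this reduces to the zero-order Pearson
#' correlation.
#'
#' @param y,x RDM vectors (or RDMs, vectorized on the fly).
#' @param covariates list of RDM vectors to partial out (possibly empty).
#' @export
partial_correlation <- function(y, x, covariates = list()) {
  y <- vectorize_arg(y); x <- vectorize_arg(x)
  if (!is.list(covariates)) covariates <- list(covariates)
  covariates <- lapply(covariates, vectorize_arg)
  n <- length(y)
  if (length(x) != n || any(vapply(covariates, length, 1L) != n)) {
    stop("all vectors must have equal length")
  }
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    stop("cannot correlate a constant (zero-variance) vector")
  }
  if (length(covariates) == 0) return(correlate_rdms(y, x, "pearson"))
  z <- cbind(1, do.call(cbind, covariates))
  q <- qr(z)
  if (q$rank < ncol(z)) stop("collinear covariates (rank-deficient design)")
  ry <- qr.resid(q, y)
  rx <- qr.resid(q, x)
  # a vector fully explained by the covariates has no residual structure
  # left to correlate; its partial correlation is 0 by convention
  if (stats::var(ry) / stats::var(y) < 1e-20 ||
      stats::var(rx) / stats::var(x) < 1e-20) {
    return(0)
  }
  stats::cor(ry, rx)
}

#' Commonality-analysis variance partitioning over three predictors
#'
#' Fits the seven possible multiple regressions (with intercept) of `y` on
#' the predictor subsets of \{A, B, C\} and decomposes the full-model
#' \eqn{r^2} into three unique, three pairwise-shared, and one triple-shared
#' commonality component:
#' \deqn{u_A = r^2_{ABC} - r^2_{BC}}
#' \deqn{s_{AB} = r^2_{AC} + r^2_{BC} - r^2_{ABC} - r^2_{C}}
#' \deqn{s_{ABC} = r^2_A + r^2_B + r^2_C - r^2_{AB} - r^2_{AC} - r^2_{BC} + r^2_{ABC}}
#' (and cyclic permutations). Raw components may be negative (suppression);
#' the percentage view divides by the full-model \eqn{r^2} and clips
#' negative components at zero (Euler-diagram convention), with the clipping
#' recorded in `clipped`.
#'
#' @param y dependent RDM vector (e.g. behavioral or ROI RDM).
#' @param a,b,c predictor RDM vectors (the three model RDMs).
#' @param names optional length-3 character vector naming the predictors.
#' @return object of class `variance_partition`: list with `r2` (all 7
#'   subset regressions), `components` (raw, sums to `r2_full`), `percent`
#'   (clipped percentages of explained variance), `r2_full`, `clipped`, `n`.
#' @export
variance_partition <- function(y, a, b, c, names = c("A", "B", "C")) {
  y <- vectorize_arg(y)
  preds <- list(vectorize_arg(a), vectorize_arg(b), vectorize_arg(c))
  n <- length(y)
  if (any(vapply(preds, length, 1L) != n)) stop("all vectors must have equal length")
  if (length(names) != 3) stop("names must have length 3")
  x <- do.call(cbind, preds)
  if (any(apply(x, 2, stats::var) == 0)) {
    stop("constant predictor (zero variance)")
  }
  # perfectly redundant predictors are legitimate here (their shared
  # component carries the variance); lm.fit's pivoted QR handles them

  r2_of <- function(cols) {
    fit <- stats::lm.fit(cbind(1, x[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  r2 <- c(A = r2_of(1), B = r2_of(2), C = r2_of(3),
          AB = r2_of(c(1, 2)), AC = r2_of(c(1, 3)), BC = r2_of(c(2, 3)),
          ABC = r2_of(1:3))

  comp <- c(
    u_A = r2[["ABC"]] - r2[["BC"]],
    u_B = r2[["ABC"]] - r2[["AC"]],
    u_C = r2[["ABC"]] - r2[["AB"]],
    s_AB = r2[["AC"]] + r2[["BC"]] - r2[["ABC"]] - r2[["C"]],
    s_AC = r2[["AB"]] + r2[["BC"]] - r2[["ABC"]] - r2[["B"]],
    s_BC = r2[["AB"]] + r2[["AC"]] - r2[["ABC"]] - r2[["A"]],
    s_ABC = r2[["A"]] + r2[["B"]] + r2[["C"]] -
      r2[["AB"]] - r2[["AC"]] - r2[["BC"]] + r2[["ABC"]]
  )
  clipped <- comp < 0
  pct <- pmax(comp, 0)
  pct <- if (r2[["ABC"]] > 0) 100 * pct / r2[["ABC"]] else pct * NA_real_
  structure(list(r2 = r2, r2_full = r2[["ABC"]], components = comp,
                 percent = pct, clipped = clipped, n = n,
                 predictor_names = names),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  nm <- x$predictor_names
  cat("Variance partitioning over predictors", paste(nm, collapse = ", "),
      sprintf("(n = %d pairs)\n", x$n))
  cat(sprintf("full model r2 = %.4f (%.1f%% of total variance)\n",
              x$r2_full, 100 * x$r2_full))
  lab <- c(paste0("unique ", nm), paste0("shared ", c(paste(nm[1], nm[2]),
           paste(nm[1], nm[3]), paste(nm[2], nm[3]))), "shared all three")
  for (i in seq_along(x$components)) {
    cat(sprintf("  %-22s %+.4f  (%s%.1f%% of explained)\n", lab[i],
                x$components[i], if (x$clipped[i]) "clipped to " else "",
                x$percent[i]))
  }
  invisible(x)
}

#' Wilcoxon signed-rank test for per-participant coefficients
#'
#' Tests whether paired differences (or a single sample against zero) are
#' symmetrically distributed around zero. Zero differences are dropped
#' (Wilcoxon's prescription). W is the sum of ranks of positive
#' differences. The p-value is exact (from the signed-rank distribution)
#' when n <= 25 with no tied absolute differences, and otherwise uses the
#' normal approximation with tie-corrected variance; the z ratio
#' \eqn{z = (W - n(n+1)/4)/\sigma_W} is reported alongside in both cases.
#'
#' @param values numeric vector of per-participant coefficients.
#' @param paired_with optional second sample of equal length; the test is
#'   then run on `values - paired_with`.
#' @param sided `"one"` (greater than zero) or `"two"`.
#' @return list of class `signed_rank_test` with `W`, `z`, `p`, `n` (after
#'   dropping zeros), `sided`, `exact`.
#' @export
signed_rank_test <- function(values, paired_with = NULL, sided = c("one", "two")) {
  sided <- match.arg(sided)
  d <- if (is.null(paired_with)) as.numeric(values)
       else as.numeric(values) - as.numeric(paired_with)
  if (!is.null(paired_with) && length(values) != length(paired_with)) {
    stop("paired samples must have equal length")
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n < 5) warning("fewer than 5 nonzero differences; test has little power")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu) / sqrt(sigma2)
  exact <- !ties && n <= 25
  if (exact) {
    p_ge <- stats::psignrank(w - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(w, n)
    p <- if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
  } else {
    p <- if (sided == "one") stats::pnorm(z, lower.tail = FALSE)
         else 2 * stats::pnorm(-abs(z))
  }
  structure(list(W = w, z = z, p = p, n = n, sided = sided, exact = exact),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W(%d) = %g, z = %.2f, %s-sided p = %.4g%s\n",
              x$n, x$W, x$z, x$sided, x$p,
              if (x$exact) " (exact)" else " (normal approx.)"))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment within test families
#'
#' Applies the BH step-up adjustment separately within each family (e.g.
#' per ROI, covering both the individual-model and pairwise-comparison
#' tests of that ROI).
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @param family optional vector of family labels (same length); `NULL`
#'   treats all p-values as one family.
#' @return adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p_values, family = NULL) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) stop("empty p-value family")
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (is.null(family)) return(stats::p.adjust(p_values, method = "BH"))
  if (length(family) != length(p_values)) {
    stop("family labels must match p-values in length")
  }
  out <- p_values
  for (f in unique(family)) {
    idx <- family == f
    out[idx] <- stats::p.adjust(p_values[idx], method = "BH")
  }
  out
}

#' Noise ceiling for model-RDM correlations
#'
#' Upper bound: mean correlation between each participant's RDM and the
#' group-average RDM (which includes that participant). Lower bound: mean
#' correlation with the average of the remaining participants
#' (leave-one-out).
#'
#' @param rdms list of per-participant `rdm` objects with shared labels.
#' @param method correlation method (the standard choice is Pearson).
#' @return list with `upper` and `lower`.
#' @export
noise_ceiling <- function(rdms, method = "pearson") {
  if (length(rdms) < 3) stop("need at least 3 participants")
  vecs <- lapply(rdms, function(x) rdm_vectorize(as_rdm_matrix(x)))
  len <- vapply(vecs, length, 1L)
  if (length(unique(len)) != 1) stop("participants must share the same labels")
  if (any(vapply(vecs, stats::var, 1) == 0)) {
    stop("constant RDM for participant(s): ",
         paste(which(vapply(vecs, stats::var, 1) == 0), collapse = ", "))
  }
  v <- do.call(cbind, vecs)
  grand <- rowMeans(v)
  n <- ncol(v)
  upper <- mean(vapply(seq_len(n), function(i) stats::cor(v[, i], grand, method = method), 1))
  lower <- mean(vapply(seq_len(n), function(i) {
    stats::cor(v[, i], rowMeans(v[, -i, drop = FALSE]), method = method)
  }, 1))
  list(upper = upper, lower = lower)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

permute_rdm_labels <- function(m, perm) m[perm, perm, drop = FALSE]

#' Split-group reproducibility test of representational structure
#'
#' Compares the group-average RDMs of two independent participant groups
#' (e.g. the two exemplar-set halves of a study). The observed statistic is
#' the Pearson correlation between the two average RDM vectors. The null
#' distribution is built by jointly permuting the category labels (rows and
#' columns) of one group-average RDM; p uses the add-one convention
#' \eqn{(1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}. A percentile
#' bootstrap over participants within each group gives the confidence
#' interval.
#'
#' @param rdms_group1,rdms_group2 lists of per-participant `rdm`s with a
#'   shared label set.
#' @param n_perm number of label permutations (the study used 10,000);
#'   ignored when `exhaustive = TRUE`.
#' @param n_boot bootstrap resamples for the CI.
#' @param conf confidence level (default 0.95).
#' @param rng_seed integer seed.
#' @param exhaustive enumerate all n! label permutations instead of random
#'   draws (only for small item counts).
#' @return list of class `reproducibility_test` with `r`, `ci`, `p`,
#'   `n_perm`, `perm_distribution`.
#' @export
reproducibility_test <- function(rdms_group1, rdms_group2, n_perm = 10000,
                                 n_boot = 10000, conf = 0.95, rng_seed = NULL,
                                 exhaustive = FALSE) {
  if (length(rdms_group1) < 1 || length(rdms_group2) < 1) {
    stop("each group needs at least one participant")
  }
  if (!exhaustive && n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  g1 <- lapply(rdms_group1, as_rdm_matrix)
  g2 <- lapply(rdms_group2, as_rdm_matrix)
  avg1 <- average_rdms(g1)
  avg2 <- average_rdms(g2)
  if (!identical(rdm_labels(avg1), rdm_labels(avg2))) {
    stop("the two groups must share category labels")
  }
  nitems <- nrow(avg1)
  v1 <- rdm_vectorize(avg1)
  r_obs <- stats::cor(v1, rdm_vectorize(avg2))
  with_seed(rng_seed, {
    m2 <- unclass(avg2)
    if (exhaustive) {
      perms <- all_permutations(nitems)
      perms <- perms[!vapply(perms, function(p) all(p == seq_len(nitems)), TRUE)]
    } else {
      # the identity relabeling is the observed arrangement itself (already
      # counted by the add-one convention), so it is excluded from the null
      draw_perm <- function() {
        repeat {
          p <- sample.int(nitems)
          if (!all(p == seq_len(nitems))) return(p)
        }
      }
      perms <- replicate(n_perm, draw_perm(), simplify = FALSE)
    }
    r_perm <- vapply(perms, function(p) {
      stats::cor(v1, rdm_vectorize(rdm(permute_rdm_labels(m2, p),
                                       labels = rdm_labels(avg2))))
    }, 1)
    p <- (1 + sum(r_perm >= r_obs)) / (1 + length(r_perm))
    ci <- NULL
    if (length(g1) > 1 && length(g2) > 1 && n_boot >= 1) {
      r_boot <- vapply(seq_len(n_boot), function(b) {
        s1 <- g1[sample.int(length(g1), replace = TRUE)]
        s2 <- g2[sample.int(length(g2), replace = TRUE)]
        stats::cor(rdm_vectorize(average_rdms(s1)), rdm_vectorize(average_rdms(s2)))
      }, 1)
      alpha <- (1 - conf) / 2
      ci <- unname(stats::quantile(r_boot, c(alpha, 1 - alpha)))
    } else {
      message("a group has a single participant; bootstrap CI omitted")
    }
    structure(list(r = r_obs, ci = ci, p = p, n_perm = length(r_perm),
                   conf = conf, perm_distribution = r_perm),
              class = "reproducibility_test")
  })
}

#' @export
print.reproducibility_test <- function(x, ...) {
  cat(sprintf("Reproducibility: r = %.3f", x$r))
  if (!is.null(x$ci)) {
    cat(sprintf(" [%.0f%% CI %.2f-%.2f]", 100 * x$conf, x$ci[1], x$ci[2]))
  }
  cat(sprintf(", permutation p = %.4g (n_perm = %d)\n", x$p, x$n_perm))
  invisible(x)
}
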