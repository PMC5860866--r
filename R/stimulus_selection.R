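#' Category pool for stimulus-set selection
#'
#' Bundles a pool of scene categories, their superordinate classes (indoor /
#' outdoor man-made / outdoor natural), and the three full-pool model RDMs
#' over the same labels.
#'
#' @param labels character vector of category labels.
#' @param classes character/factor of the same length: the superordinate
#'   class of each category.
#' @param model_rdms named list of three `rdm` objects sharing exactly the
#'   pool's labels and order.
#' @export
category_pool <- function(labels, classes, model_rdms) {
  labels <- as.character(labels)
  classes <- as.character(classes)
  if (length(labels) != length(classes)) {
    stop("labels and classes must have equal length")
  }
  if (anyDuplicated(labels)) stop("duplicate category labels in pool")
  if (anyNA(classes)) stop("every category needs exactly one class")
  if (!is.list(model_rdms) || length(model_rdms) != 3) {
    stop("model_rdms must be a list of three RDMs")
  }
  if (is.null(names(model_rdms))) {
    names(model_rdms) <- paste0("model", 1:3)
  }
  model_rdms <- lapply(model_rdms, as_rdm_matrix)
  for (nm in names(model_rdms)) {
    if (!identical(rdm_labels(model_rdms[[nm]]), labels)) {
      stop("model RDM '", nm, "' labels do not match the pool labels/order")
    }
  }
  structure(list(labels = labels, classes = classes, models = model_rdms),
            class = "category_pool")
}

#' @export
print.category_pool <- function(x, ...) {
  cat("Category pool:", length(x$labels), "categories,",
      length(unique(x$classes)), "classes,",
      length(x$models), "model RDMs\n")
  print(table(x$classes))
  invisible(x)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Draw a class-balanced candidate category set
#'
#' Samples `set_size` categories uniformly without replacement with exactly
#' `set_size / k` categories per superordinate class (k = number of
#' classes).
#'
#' @param pool a [category_pool()].
#' @param set_size number of categories; must be divisible by the number of
#'   classes.
#' @param rng_seed optional integer; when given, the draw is made under this
#'   seed without disturbing the caller's RNG stream.
#' @return character vector of sampled labels.
#' @export
sample_candidate <- function(pool, set_size, rng_seed = NULL) {
  stopifnot(inherits(pool, "category_pool"))
  classes <- unique(pool$classes)
  k <- length(classes)
  if (set_size %% k != 0) {
    stop("set_size (", set_size, ") must be divisible by the number of classes (", k, ")")
  }
  quota <- set_size / k
  counts <- table(factor(pool$classes, levels = classes))
  deficit <- quota - counts
  if (any(deficit > 0)) {
    bad <- names(counts)[deficit > 0]
    stop("infeasible quota; class deficit: ",
         paste(sprintf("%s needs %d more", bad, deficit[deficit > 0]), collapse = "; "))
  }
  with_seed(rng_seed, {
    picked <- unlist(lapply(classes, function(cl) {
      members <- pool$labels[pool$classes == cl]
      members[sample.int(length(members), quota)]
    }), use.names = FALSE)
    picked
  })
}

#' Score a candidate set by its inter-model RDM correlations
#'
#' Subsets each of the pool's three model RDMs to the candidate labels,
#' vectorizes, and computes the three pairwise Spearman correlations. The
#' summary value is the maximum of the three — the worst remaining
#' inter-model correlation, which the selection procedure minimizes.
#'
#' @param pool a [category_pool()].
#' @param labels candidate category labels (drawn from the pool).
#' @param method correlation method; selection uses Spearman.
#' @return list with `labels`, `correlations` (named length-3 vector) and
#'   `summary` (their maximum).
#' @export
score_candidate <- function(pool, labels, method = "spearman") {
  stopifnot(inherits(pool, "category_pool"))
  vecs <- lapply(pool$models, function(m) rdm_vectorize(rdm_subset(m, labels)))
  nm <- names(pool$models)
  pairs <- utils::combn(3, 2)
  cors <- apply(pairs, 2, function(ij) {
    correlate_rdms(vecs[[ij[1]]], vecs[[ij[2]]], method = method)
  })
  names(cors) <- apply(pairs, 2, function(ij) paste(nm[ij[1]], nm[ij[2]], sep = "~"))
  list(labels = labels, correlations = cors, summary = max(cors))
}

#' Select a minimally inter-correlated category set (odds-algorithm variant)
#'
#' Secretary-style stopping rule for stimulus-set decorrelation: draw
#' `n_learning` class-balanced candidate sets, record the minimum candidate
#' summary (the per-candidate maximum pairwise inter-model Spearman
#' correlation) observed in that learning phase, then keep drawing and stop
#' at the first candidate whose summary is strictly lower than the learning
#' record. If `max_iterations` draws pass without such a candidate, the best
#' candidate seen overall is returned with `exhausted = TRUE`.
#'
#' @param pool a [category_pool()].
#' @param set_size categories per candidate (divisible by class count).
#' @param n_learning number of learning-phase draws (the study used 10,000).
#' @param max_iterations total draw budget; defaults to `10 * n_learning`.
#' @param rng_seed integer seed making the whole search reproducible.
#' @return list with `labels`, `score` (a [score_candidate()] result),
#'   `iterations` (draws used), `exhausted` flag, `learning_record` (the
#'   learning-phase minimum summary) and `trace` (every candidate summary in
#'   draw order, for auditing the stopping rule).
#' @export
select_set <- function(pool, set_size, n_learning,
                       max_iterations = 10 * n_learning, rng_seed = NULL) {
  stopifnot(inherits(pool, "category_pool"))
  if (n_learning < 1) stop("n_learning must be >= 1")
  if (max_iterations <= n_learning) stop("max_iterations must exceed n_learning")
  with_seed(rng_seed, {
    trace <- numeric(0)
    best <- NULL
    record <- Inf
    for (i in seq_len(max_iterations)) {
      labs <- sample_candidate(pool, set_size)
      sc <- score_candidate(pool, labs)
      trace[i] <- sc$summary
      if (is.null(best) || sc$summary < best$summary) best <- sc
      if (i <= n_learning) {
        record <- min(record, sc$summary)
      } else if (sc$summary < record) {
        return(list(labels = sc$labels, score = sc, iterations = i,
                    exhausted = FALSE, learning_record = record, trace = trace))
      }
    }
    list(labels = best$labels, score = best, iterations = max_iterations,
         exhausted = TRUE, learning_record = record, trace = trace)
  })
}
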