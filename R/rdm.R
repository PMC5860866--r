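#' Construct a representational dissimilarity matrix (RDM)
#'
#' An RDM is a square symmetric matrix of pairwise dissimilarities between
#' items (here: scene categories), with a zero diagonal. Crossnobis RDMs may
#' contain negative entries, so no positivity constraint is imposed.
#'
#' Inputs that are symmetric only up to `tol` are symmetrized by averaging
#' with their transpose; diagonal entries within `tol` of zero are forced to
#' exactly zero.
#'
#' @param values square numeric matrix of dissimilarities.
#' @param labels character vector of item identifiers, one per row. Defaults
#'   to the matrix rownames, or `item1..itemN` when absent.
#' @param tol absolute tolerance for the symmetry and zero-diagonal checks.
#' @return an object of class `rdm` (a labelled matrix).
#' @export
rdm <- function(values, labels = NULL, tol = 1e-10) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("RDM must be square; got ", nrow(values), " x ", ncol(values))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("RDM contains missing or non-finite values")
  }
  n <- nrow(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("item", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("label count (", length(labels), ") does not match matrix order (", n, ")")
  }
  if (anyDuplicated(labels)) stop("duplicate item labels are not allowed")
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop("matrix is asymmetric beyond tolerance (max |x - t(x)| = ",
         format(asym), ")")
  }
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > tol) {
    stop("RDM diagonal must be zero (max |diag| = ", format(max(abs(diag(values)))), ")")
  }
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  class(values) <- c("rdm", "matrix", "array")
  values
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM over", nrow(x), "items\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Test whether an object is an RDM
#' @param x object to test.
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' Item labels of an RDM
#' @param x an `rdm`.
#' @export
rdm_labels <- function(x) rownames(x)

as_rdm_matrix <- function(x) {
  if (is_rdm(x)) return(x)
  rdm(x)
}

#' Build an RDM from a feature matrix
#'
#' Computes the pairwise dissimilarity between items as 1 minus the Pearson
#' correlation of their feature vectors — the standard metric for comparing
#' DNN layer activations or label-count vectors across stimuli.
#'
#' @param features numeric matrix, items in rows, features in columns;
#'   rownames are taken as item labels.
#' @param metric dissimilarity metric; only `"one_minus_pearson"` is
#'   supported.
#' @return an [rdm()] with entry (i, j) = 1 - cor(features\[i, \], features\[j, \]).
#' @export
rdm_from_features <- function(features, metric = "one_minus_pearson") {
  metric <- match.arg(metric, "one_minus_pearson")
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 items")
  if (ncol(features) < 1) stop("need at least 1 feature")
  if (anyNA(features)) stop("feature matrix contains missing values")
  labels <- rownames(features)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(features)))
  v <- apply(features, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance feature vector for item(s): ",
         paste(labels[v == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(features))
  diag(d) <- 0
  # numerical asymmetry from cor() is below 1e-14; constructor symmetrizes
  rdm(d, labels = labels)
}

#' Subset an RDM to a set of items
#'
#' Returns the principal submatrix of `x` for the items in `keep`, in the
#' order given.
#'
#' @param x an `rdm`.
#' @param keep character vector of labels to retain (no duplicates).
#' @export
rdm_subset <- function(x, keep) {
  x <- as_rdm_matrix(x)
  keep <- as.character(keep)
  unknown <- setdiff(keep, rdm_labels(x))
  if (length(unknown) > 0) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keep)) {
    stop("duplicate label(s) in keep: ",
         paste(unique(keep[duplicated(keep)]), collapse = ", "))
  }
  rdm(unclass(x)[keep, keep, drop = FALSE], labels = keep)
}

#' Vectorize an RDM to its lower-triangle entries
#'
#' Extracts the n(n-1)/2 off-diagonal dissimilarities in the package-wide
#' canonical order: the lower triangle traversed row-major, i.e. pairs
#' (2,1), (3,1), (3,2), (4,1), ... Element names are `"<itemA>:<itemB>"`
#' with A the earlier label.
#'
#' @param x an `rdm` (or a matrix passing the RDM invariants).
#' @return named numeric vector of length n(n-1)/2.
#' @seealso [rdm_unvectorize()] for the inverse packing.
#' @export
rdm_vectorize <- function(x) {
  x <- as_rdm_matrix(x)
  labels <- rdm_labels(x)
  ut <- upper.tri(x)
  v <- unclass(x)[ut]   # column-major upper triangle == row-major lower triangle
  idx <- which(ut, arr.ind = TRUE)
  names(v) <- paste(labels[idx[, "row"]], labels[idx[, "col"]], sep = ":")
  v
}

#' Rebuild an RDM from its vectorized lower triangle
#'
#' @param v numeric vector of length n(n-1)/2 in the canonical pair order of
#'   [rdm_vectorize()].
#' @param labels item labels; length n must satisfy n(n-1)/2 = length(v).
#' @export
rdm_unvectorize <- function(v, labels = NULL) {
  m <- length(v)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("vector length ", m, " is not of the form n(n-1)/2")
  }
  n <- round(n)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  x <- matrix(0, n, n)
  x[upper.tri(x)] <- as.numeric(v)
  x <- x + t(x)
  rdm(x, labels = labels)
}

#' Correlate two vectorized RDMs
#'
#' @param a,b RDMs or vectors from [rdm_vectorize()]; both must use the same
#'   pair ordering.
#' @param method `"pearson"` or `"spearman"` (average ranks for ties).
#' @return correlation coefficient in \[-1, 1\].
#' @export
correlate_rdms <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is_rdm(a) || (is.matrix(a) && nrow(a) == ncol(a) && nrow(a) > 1)) {
    a <- rdm_vectorize(a)
  }
  if (is_rdm(b) || (is.matrix(b) && nrow(b) == ncol(b) && nrow(b) > 1)) {
    b <- rdm_vectorize(b)
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("cannot correlate a constant (zero-variance) dissimilarity vector")
  }
  stats::cor(a, b, method = method)
}

#' Rank-transform an RDM for display
#'
#' Replaces the off-diagonal entries by their average ranks (ties averaged),
#' mirroring the rank-ordered RDM images used in figures. For visualization
#' only; never feed the result into inference.
#'
#' @param x an `rdm`.
#' @export
rdm_rank_transform <- function(x) {
  x <- as_rdm_matrix(x)
  v <- rdm_vectorize(x)
  rdm_unvectorize(rank(v), labels = rdm_labels(x))
}

#' Entrywise average of RDMs
#'
#' Group-average RDM across participants. All RDMs must share the same label
#' set in the same order.
#'
#' @param rdms list of `rdm` objects.
#' @param normalize if `TRUE`, each RDM is scaled to unit sum of off-diagonal
#'   entries before averaging (off by default; raw averaging is the standard
#'   treatment).
#' @export
average_rdms <- function(rdms, normalize = FALSE) {
  if (!is.list(rdms) || length(rdms) < 1) stop("need a nonempty list of RDMs")
  rdms <- lapply(rdms, as_rdm_matrix)
  ref <- rdm_labels(rdms[[1]])
  for (i in seq_along(rdms)) {
    if (!identical(rdm_labels(rdms[[i]]), ref)) {
      stop("RDM ", i, " has mismatching labels")
    }
  }
  mats <- lapply(rdms, function(x) {
    m <- unclass(x)
    if (normalize) m <- m / sum(m[upper.tri(m)])
    m
  })
  rdm(Reduce(`+`, mats) / length(mats), labels = ref)
}

#' Read an RDM from a delimited file
#'
#' Expects a square table with a header row and a first column both holding
#' the item labels. The separator is inferred from the extension (`.csv` vs
#' `.tsv`/`.txt`) unless given.
#'
#' @param path file path.
#' @param sep field separator; `NULL` to infer from the extension.
#' @export
read_rdm <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels differ in ", path)
  }
  rdm(m, labels = rownames(m))
}

#' Write an RDM to a delimited file
#' @param x an `rdm`.
#' @param path file path; extension selects the separator as in [read_rdm()].
#' @param sep field separator; `NULL` to infer.
#' @export
write_rdm <- function(x, path, sep = NULL) {
  x <- as_rdm_matrix(x)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(unclass(x), path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a feature matrix (items x features) from a delimited file
#'
#' First column holds item labels; remaining columns are numeric features.
#'
#' @inheritParams read_rdm
#' @export
read_feature_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("feature matrix in ", path, " contains missing values")
  m
}
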