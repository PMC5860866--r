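#' Multi-arrangement data: thumbnail positions inside a circular arena
#'
#' Represents one participant's final arrangement of exemplar thumbnails in
#' the similarity-sorting task. Coordinates are screen pixels relative to
#' the arena center.
#'
#' @param exemplars data frame with columns `exemplar_id`, `category`, `x`,
#'   `y` (pixels, arena-centered).
#' @param arena_radius arena radius in pixels.
#' @param tol slack (pixels) allowed on the in-arena check.
#' @export
arrangement <- function(exemplars, arena_radius, tol = 1e-8) {
  req <- c("exemplar_id", "category", "x", "y")
  if (!is.data.frame(exemplars) || !all(req %in% names(exemplars))) {
    stop("exemplars must be a data frame with columns ", paste(req, collapse = ", "))
  }
  exemplars <- exemplars[, req]
  exemplars$exemplar_id <- as.character(exemplars$exemplar_id)
  exemplars$category <- as.character(exemplars$category)
  if (anyDuplicated(exemplars$exemplar_id)) {
    stop("duplicate exemplar ids: ",
         paste(unique(exemplars$exemplar_id[duplicated(exemplars$exemplar_id)]),
               collapse = ", "))
  }
  if (!is.numeric(arena_radius) || arena_radius <= 0) {
    stop("arena_radius must be positive")
  }
  r <- sqrt(exemplars$x^2 + exemplars$y^2)
  if (any(r > arena_radius + tol)) {
    stop(sum(r > arena_radius + tol), " exemplar(s) lie outside the arena")
  }
  structure(list(exemplars = exemplars, arena_radius = arena_radius),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat("Arrangement:", nrow(x$exemplars), "exemplars,",
      length(unique(x$exemplars$category)), "categories, arena radius",
      x$arena_radius, "px\n")
  invisible(x)
}

#' Category-level behavioral RDM from an arrangement
#'
#' Entry (A, B) is the mean over all exemplar pairs (a in A, b in B) of the
#' squared Euclidean on-screen distance between the arranged thumbnails, in
#' pixels squared. Within-category distances are discarded (diagonal fixed
#' at 0). Category order follows first appearance in the exemplar table.
#'
#' @param arr an [arrangement()].
#' @export
arrangement_to_rdm <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  ex <- arr$exemplars
  cats <- unique(ex$category)
  if (length(cats) < 2) stop("need at least 2 categories")
  counts <- table(factor(ex$category, levels = cats))
  if (any(counts == 0)) {
    stop("category with zero exemplars: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  d2 <- as.matrix(stats::dist(cbind(ex$x, ex$y)))^2
  g <- outer(ex$category, cats, `==`) * 1        # exemplars x categories
  sums <- t(g) %*% d2 %*% g
  npairs <- outer(as.numeric(counts), as.numeric(counts))
  out <- sums / npairs
  out <- (out + t(out)) / 2   # exact symmetry at pixel^2 scale
  diag(out) <- 0
  rdm(out, labels = cats)
}

#' Read an arrangement from CSV
#'
#' Expects columns `exemplar_id`, `category`, `x_px`, `y_px`.
#'
#' @param path CSV file path.
#' @param arena_radius arena radius in pixels (a sidecar value, not stored
#'   in the CSV).
#' @export
read_arrangement <- function(path, arena_radius) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("exemplar_id", "category", "x_px", "y_px")
  if (!all(req %in% names(tab))) {
    stop("arrangement CSV must have columns ", paste(req, collapse = ", "))
  }
  arrangement(data.frame(exemplar_id = tab$exemplar_id,
                         category = tab$category,
                         x = tab$x_px, y = tab$y_px,
                         stringsAsFactors = FALSE),
              arena_radius = arena_radius)
}
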