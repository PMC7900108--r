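#' Construct a connectome
#'
#' A connectome is a weighted, undirected brain network: an `N x N`
#' symmetric, nonnegative weight matrix (streamline counts between region
#' pairs) together with an ordered vector of region labels.  The default
#' parcellation has 90 regions (78 cortical + 12 subcortical).
#'
#' Validation is strict: the matrix must be square and numeric, weights
#' must be nonnegative and finite, and the diagonal must be zero.
#' Asymmetry beyond a relative tolerance of `tol` is an error; asymmetry
#' *within* tolerance (e.g. from rounding on disk) is repaired by
#' mirroring the strict upper triangle onto the lower, with a message.
#'
#' @param weights Square numeric matrix of nonnegative edge weights.
#' @param node_labels Character vector of region names, one per node.
#'   Defaults to the matrix dimnames, or `"node_1" ... "node_N"`.
#' @param subject_id Identifier carried through metric tables.
#' @param tol Relative tolerance for symmetry checking.
#' @return An object of class `connectome`: a list with elements
#'   `weights`, `node_labels` and `subject_id`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 10
#' w[2, 3] <- w[3, 2] <- 5
#' conn <- connectome(w, node_labels = c("A", "B", "C"), subject_id = "s01")
#' nodal_strength(conn)
#' @export
connectome <- function(weights, node_labels = NULL, subject_id = "subject",
                       tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort("`weights` must be a numeric matrix.", class = "strucnet_invalid")
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    abort(
      sprintf("`weights` must be square; got %d x %d.", n, ncol(weights)),
      class = "strucnet_invalid"
    )
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    abort("`weights` contains missing or non-finite entries.",
          class = "strucnet_invalid")
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    abort(
      sprintf("negative weight at [%d, %d]; weights must be >= 0.",
              bad[1], bad[2]),
      class = "strucnet_invalid"
    )
  }
  scale <- max(abs(weights), 1)
  asym <- abs(weights - t(weights))
  if (any(asym > tol * scale)) {
    bad <- which(asym > tol * scale, arr.ind = TRUE)[1, ]
    abort(
      sprintf(
        "`weights` is asymmetric at [%d, %d] (|w_ij - w_ji| = %.3g).",
        bad[1], bad[2], asym[bad[1], bad[2]]
      ),
      class = "strucnet_invalid"
    )
  }
  if (any(asym > 0)) {
    inform("Mirroring upper triangle onto lower (asymmetry within tolerance).")
    weights[lower.tri(weights)] <- t(weights)[lower.tri(weights)]
  }
  if (any(diag(weights) != 0)) {
    abort("diagonal of `weights` must be zero (no self-connections).",
          class = "strucnet_invalid")
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(weights) %||% paste0("node_", seq_len(n))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != n) {
    abort(
      sprintf("%d node labels supplied for %d nodes.", length(node_labels), n),
      class = "strucnet_invalid"
    )
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(weights = weights, node_labels = node_labels,
         subject_id = as.character(subject_id)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights
  n_edges <- sum(w[upper.tri(w)] > 0)
  cat(sprintf(
    "<connectome> subject '%s': %d nodes, %d edges (density %.3f)\n",
    x$subject_id, nrow(w), n_edges, n_edges / choose(nrow(w), 2)
  ))
  invisible(x)
}

n_nodes <- function(conn) length(conn$node_labels)

as_connectome <- function(x, ...) {
  if (inherits(x, "connectome")) x else connectome(x, ...)
}

#' Region labels of the 90-node automated anatomical labelling parcellation
#'
#' The conventional ordering of the 90 cerebral regions (left/right
#' interleaved, cerebellum excluded) used as the default node order for
#' connectivity matrices.
#'
#' @return Character vector of length 90.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "strucnet",
                      mustWork = TRUE)
  readLines(path)
}
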