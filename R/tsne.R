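#' Exact t-SNE embedding to two dimensions
#'
#' t-distributed stochastic neighbour embedding with the exact O(n^2)
#' gradient: per-point Gaussian bandwidths are calibrated to the requested
#' perplexity by bisection, the joint similarities are symmetrised, and the
#' Student-t low-dimensional similarities are optimised by gradient descent
#' with early exaggeration, momentum and adaptive gains. Deterministic
#' given `seed`.
#'
#' @param X Numeric matrix (rows = observations).
#' @param perplexity Target perplexity; automatically clamped to
#'   `min(perplexity, (n - 1) / 3)` with a warning when the row count is
#'   small.
#' @param seed Integer seed for the random initialisation.
#' @param n_iter Gradient iterations.
#' @param eta Learning rate.
#' @param exaggeration,exaggeration_iter Early-exaggeration factor and the
#'   number of initial iterations it is applied for.
#' @return An `n x 2` matrix of embedded coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, seed = 0L, n_iter = 500,
                       eta = 200, exaggeration = 12,
                       exaggeration_iter = 100) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 4) stop("t-SNE needs at least 4 rows, got ", n, call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("t-SNE input must be finite", call. = FALSE)
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warning(sprintf(
      "perplexity %.1f too large for %d rows; clamped to %.2f (use a value below (n-1)/3)",
      perplexity, n, max_perp), call. = FALSE)
    perplexity <- max_perp
  }
  if (perplexity >= n)
    stop("perplexity must be below the number of rows", call. = FALSE)
  .tsne_cpp(X, perplexity, as.integer(n_iter), eta, exaggeration,
            as.integer(exaggeration_iter), as.integer(seed))
}
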