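#' Principal component analysis of per-piece TP vectors
#'
#' Decompose the correlation structure of the pieces, computed across the
#' shared pattern vocabulary: pieces are the entities receiving component
#' loadings, so each piece gets a coordinate on each component and pieces
#' whose TP profiles covary load together. Components with eigenvalue above 1
#' (each piece contributing unit variance after standardisation) are retained;
#' the first two are the ones inspected for musician structure. A first
#' component on which every piece loads highly and with the same sign is a
#' style shared by the whole corpus; musician individuality appears as
#' separation of the musicians' pieces in the component-1/2 plane.
#'
#' @param tp_matrix A wide piece-by-pattern tibble from [align_tp_matrix()]:
#'   at least 3 pieces and 2 pattern columns with nonzero variance.
#' @return An object of class `tp_pca` with elements `eigenvalues`,
#'   `var_pct`, `cum_pct`, `retained` (eigenvalue > 1), `loadings` (pieces x
#'   components, each column scaled by the square root of its eigenvalue) and
#'   the piece identifiers. `tidy()` gives per-piece loadings, `glance()` the
#'   variance summary, `autoplot()` the component-1/2 scatter.
#' @export
tp_pca <- function(tp_matrix) {
  stopifnot(is.data.frame(tp_matrix))
  ids <- id_cols(tp_matrix)
  if (!"piece_id" %in% ids) abort("`tp_matrix` needs a piece_id column.")
  X <- as.matrix(tp_matrix[, setdiff(names(tp_matrix), ids), drop = FALSE])
  if (nrow(X) < 3L) abort("PCA needs at least 3 pieces.")
  if (ncol(X) < 2L) abort("PCA needs at least 2 pattern columns.")
  piece_sd <- apply(X, 1L, sd)
  if (any(piece_sd == 0)) {
    abort(paste0("Constant TP profile (no variance across patterns) for piece(s): ",
                 paste(tp_matrix$piece_id[piece_sd == 0], collapse = ", ")))
  }
  R <- cor(t(X))
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  loadings <- eig$vectors %*% diag(sqrt(ev))
  # orient components deterministically: majority of loadings non-negative
  flip <- colSums(loadings) < 0
  loadings[, flip] <- -loadings[, flip]
  colnames(loadings) <- paste0("PC", seq_along(ev))
  structure(
    list(
      eigenvalues = ev,
      var_pct = 100 * ev / sum(ev),
      cum_pct = cumsum(100 * ev / sum(ev)),
      retained = ev > 1,
      loadings = loadings,
      pieces = tp_matrix[, ids, drop = FALSE],
      n_pieces = nrow(X),
      n_patterns = ncol(X)
    ),
    class = "tp_pca"
  )
}

#' @export
print.tp_pca <- function(x, ...) {
  cat(sprintf("<tp_pca> %d pieces x %d patterns; %d component(s) with eigenvalue > 1\n",
              x$n_pieces, x$n_patterns, sum(x$retained)))
  cat(sprintf("  first two components: %.1f%% + %.1f%% = %.1f%% of variance\n",
              x$var_pct[1], x$var_pct[2], x$cum_pct[2]))
  invisible(x)
}

#' @rdname tp_pca
#' @param x,object A `tp_pca` object.
#' @param n_components Number of components of loadings to return.
#' @param ... Unused.
#' @export
tidy.tp_pca <- function(x, n_components = 2L, ...) {
  ld <- as_tibble(x$loadings[, seq_len(n_components), drop = FALSE])
  dplyr::bind_cols(x$pieces, ld)
}

#' @rdname tp_pca
#' @export
glance.tp_pca <- function(x, ...) {
  tibble(
    n_pieces = x$n_pieces, n_patterns = x$n_patterns,
    n_retained = sum(x$retained),
    eigenvalue_1 = x$eigenvalues[1], eigenvalue_2 = x$eigenvalues[2],
    var_pct_1 = x$var_pct[1], var_pct_2 = x$var_pct[2],
    cum_pct_2 = x$cum_pct[2]
  )
}

#' @rdname tp_pca
#' @export
autoplot.tp_pca <- function(object, ...) {
  d <- tidy(object)
  aes <- if ("musician_id" %in% names(d)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$musician_id)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("Component 1 (%.1f%%)", object$var_pct[1]),
      y = sprintf("Component 2 (%.1f%%)", object$var_pct[2]),
      colour = "Musician"
    ) +
    ggplot2::theme_minimal()
}
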