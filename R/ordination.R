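# 2-D principal component ordination of read/sequence embeddings.

#' Project embeddings onto the top two principal components
#'
#' Covariance PCA (centered, not scaled to unit variance — the embedding
#' dimensions share a scale) of an n x N_h embedding matrix, keeping the two
#' components that explain the most variance. Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so the
#' projection is fully deterministic.
#'
#' @param embeddings An n x N_h numeric matrix, n >= 3 and N_h >= 2.
#' @return A list of class \code{ampatt_projection}: \code{coords} (n x 2,
#'   centered), \code{variance_explained} (fractions of total variance,
#'   non-increasing), \code{component_loadings} (2 x N_h), and
#'   \code{degenerate} (TRUE when fewer than 2 non-null directions exist, in
#'   which case the second column is zero).
#' @export
pca_project <- function(embeddings) {
  x <- as.matrix(embeddings)
  if (nrow(x) < 3L) stop("need at least 3 points")
  if (ncol(x) < 2L) stop("need at least 2 dimensions")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  degenerate <- k < 2L || ev[2] <= .Machine$double.eps * max(ev[1], 1)
  if (k < 2L) {
    rot <- cbind(rot, 0); coords <- cbind(coords, 0); ev <- c(ev, 0)
  }
  ve <- ev[1:2] / sum(ev)
  if (degenerate)
    warning("fewer than 2 non-degenerate components; PC2 carries no variance")
  structure(list(coords = coords[, 1:2, drop = FALSE],
                 variance_explained = ve,
                 component_loadings = t(rot[, 1:2, drop = FALSE]),
                 degenerate = degenerate),
            class = "ampatt_projection")
}

#' Write projection coordinates with labels as TSV
#'
#' @param projection An \code{ampatt_projection}.
#' @param labels Optional per-point labels (class, genus, ...).
#' @param path Output TSV path.
#' @export
write_projection <- function(projection, path, labels = NULL) {
  df <- data.frame(PC1 = projection$coords[, 1], PC2 = projection$coords[, 2])
  if (!is.null(labels)) df$label <- as.character(labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
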