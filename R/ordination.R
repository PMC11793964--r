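# Shape PCA, group mean shapes and projections into the morphospace.

#' Principal component analysis of superimposed shape coordinates
#'
#' Covariance PCA of the mean-centered, flattened (x1, y1, z1, ...)
#' Procrustes coordinates, computed by singular value decomposition.
#' Components are ordered by decreasing variance; each axis is oriented so
#' its largest-magnitude loading is positive, making scores reproducible
#' across runs and platforms.
#'
#' @param aligned an `aligned_shapes` object (n >= 3) or n x 3k matrix.
#' @return An object of class `shape_pca`: `scores` (n x m), `axes` (3k x m,
#'   orthonormal columns), `var_prop` (length m, sums to 1 over the non-null
#'   components), `sdev`, `total_variance` (sum of eigenvalues), and `center`
#'   (the mean flattened shape).
#' @export
shape_pca <- function(aligned) {
  Y <- if (inherits(aligned, "aligned_shapes")) flatten_shapes(aligned) else as.matrix(aligned)
  n <- nrow(Y)
  if (n < 3L) stop("shape PCA needs n >= 3 specimens")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  sv <- svd(Yc)
  eig <- sv$d^2 / (n - 1)
  m <- sum(sv$d > max(sv$d) * 1e-10)      # drop numerically null components
  axes <- sv$v[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- Yc %*% axes
  total <- sum(eig)
  structure(list(scores = scores, axes = axes,
                 var_prop = eig[seq_len(m)] / total,
                 sdev = sqrt(eig[seq_len(m)]),
                 total_variance = total, center = ctr,
                 n = n, q = ncol(Y)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca>", x$n, "specimens,", length(x$var_prop), "components\n")
  shown <- utils::head(x$var_prop, 5L)
  cat("  variance proportions:",
      paste(sprintf("PC%d %.1f%%", seq_along(shown), 100 * shown),
            collapse = ", "), "\n")
  invisible(x)
}

#' Mean shape per group
#'
#' Coordinate-wise mean of the aligned coordinates within each level of a
#' grouping factor (e.g. lineage x period cells).
#'
#' @param aligned an `aligned_shapes` object.
#' @param labels factor (or vector) of group labels, one per specimen; every
#'   level must be represented.
#' @return Named list of k x 3 mean shapes, one per level.
#' @export
group_mean_shapes <- function(aligned, labels) {
  labels <- if (is.factor(labels)) labels else factor(labels)
  n <- dim(aligned$coords)[3L]
  if (length(labels) != n) stop("labels must have one value per specimen")
  empty <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(empty)) stop("empty group level: ", empty[1L])
  out <- lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    apply(aligned$coords[, , idx, drop = FALSE], c(1L, 2L), mean)
  })
  names(out) <- levels(labels)
  out
}

#' Project shapes into an existing PCA space
#'
#' Centers the flattened coordinates with the PCA's stored mean and
#' multiplies by its axes. Projecting the training specimens reproduces their
#' stored scores; projecting the consensus (the mean shape) gives all-zero
#' scores.
#'
#' @param shapes an `aligned_shapes` object, a k x 3 matrix (one shape), a
#'   list of k x 3 matrices, or an n x 3k flattened matrix.
#' @param pca a `shape_pca`.
#' @return n x m score matrix.
#' @export
project <- function(shapes, pca) {
  stopifnot(inherits(pca, "shape_pca"))
  Y <- if (inherits(shapes, "aligned_shapes")) {
    flatten_shapes(shapes)
  } else if (is.list(shapes)) {
    do.call(rbind, lapply(shapes, function(s) as.vector(t(s))))
  } else if (is.matrix(shapes) && ncol(shapes) == 3L) {
    matrix(as.vector(t(shapes)), 1L)
  } else {
    as.matrix(shapes)
  }
  if (ncol(Y) != pca$q)
    stop("shape dimension ", ncol(Y), " does not match PCA space (", pca$q, ")")
  sweep(Y, 2L, pca$center) %*% pca$axes
}
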