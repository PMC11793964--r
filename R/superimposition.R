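# Centroid size, generalized Procrustes analysis and object symmetry.
#
# All superimpositions use the full Procrustes fit: every configuration is
# centered and scaled to unit centroid size and only rotated thereafter; the
# consensus is re-scaled to unit centroid size at each iteration. Reflections
# are never permitted (det(R) = +1 enforced).

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid — the standard geometric-morphometric size measure. Homogeneous
#' of degree 1: `centroid_size(s * X) == s * centroid_size(X)`.
#'
#' @param config a `landmark_config` or a k x 3 coordinate matrix.
#' @return Non-negative scalar (0 iff all landmarks coincide).
#' @export
centroid_size <- function(config) {
  X <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  if (any(!is.finite(X))) stop("non-finite coordinates")
  Xc <- sweep(X, 2L, colMeans(X))
  sqrt(sum(Xc * Xc))
}

center_config <- function(X) sweep(X, 2L, colMeans(X))

center_scale <- function(X, id = "?") {
  Xc <- center_config(X)
  cs <- sqrt(sum(Xc * Xc))
  if (cs < .Machine$double.eps * nrow(X))
    stop("degenerate configuration (zero centroid size) for specimen '", id, "'")
  Xc / cs
}

#' Optimal proper rotation between two centered configurations
#'
#' Solves the orthogonal Procrustes problem: the 3 x 3 rotation `R`
#' minimizing `sum((B %*% R - A)^2)`. Reflections are disallowed: if the
#' unconstrained optimum has determinant -1, the smallest singular direction
#' is sign-flipped, yielding the best proper rotation.
#'
#' @param A,B centered k x 3 coordinate matrices (same k >= 3).
#' @return 3 x 3 rotation matrix with determinant +1, to be applied as
#'   `B %*% R`.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("configurations differ in dimension")
  H <- crossprod(B, A)                       # 3 x 3
  sv <- svd(H)
  if (sv$d[2L] < max(sv$d) * 1e-12)
    stop("rank-deficient (collinear) configuration: rotation not unique")
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) stop("degenerate configuration: rotation undetermined")
  D <- diag(c(1, 1, s))
  sv$u %*% D %*% t(sv$v)
}

# Deterministic canonical orientation: rotate so the consensus lies in its
# principal-axes frame. Makes GPA output invariant to the orientation of the
# input data. Sign convention: axes 1 and 2 oriented so their
# largest-magnitude loading is positive; axis 3 = cross product (proper
# rotation guaranteed).
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Axis signs are fixed by the sign of the cube-sum of the landmark
# coordinates along each axis — a smooth functional that is robust to tiny
# perturbations. For a bilaterally symmetric consensus the cube-sum along
# the symmetry axis vanishes identically, so only the two axes where it is
# largest in magnitude are sign-fixed directly; the remaining axis follows
# from right-handedness (det +1, reflections excluded).
canonical_orientation <- function(consensus) {
  V <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  w <- consensus %*% V          # landmark coordinates along candidate axes
  s <- colSums(w^3)
  fix <- order(abs(s), decreasing = TRUE)[1:2]
  for (j in fix) if (s[j] < 0) V[, j] <- -V[, j]
  rem <- setdiff(1:3, fix)
  pred <- c(2L, 3L, 1L)[rem]    # cyclic predecessor/successor: rem = pred x succ
  succ <- c(3L, 1L, 2L)[rem]
  V[, rem] <- cross3(V[, pred], V[, succ])
  V
}

aligned_shapes <- function(coords, consensus, centroid_sizes, symmetric,
                           iterations, final_change, landmark_names, ids,
                           lineage = NULL, period = NULL, symmetry = NULL) {
  dimnames(coords) <- list(landmark_names, c("x", "y", "z"), ids)
  structure(list(coords = coords, consensus = consensus,
                 centroid_sizes = centroid_sizes,
                 log_cs = log(centroid_sizes),
                 symmetric = symmetric, iterations = iterations,
                 final_change = final_change,
                 landmark_names = landmark_names, specimen_id = ids,
                 lineage = lineage, period = period, symmetry = symmetry),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("<aligned_shapes>", dim(x$coords)[3L], "specimens, k =",
      dim(x$coords)[1L], if (isTRUE(x$symmetric)) "(symmetric component)",
      "\n  GPA:", x$iterations, "iterations, final consensus change",
      format(x$final_change, digits = 3), "\n")
  invisible(x)
}

gpa_core <- function(arr, ids, tol, max_iter) {
  n <- dim(arr)[3L]; k <- dim(arr)[1L]
  X <- array(NA_real_, dim(arr))
  for (i in seq_len(n)) X[, , i] <- center_scale(arr[, , i], ids[i])
  ref <- X[, , 1L]
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% optimal_rotation(ref, X[, , i])
  consensus <- apply(X, c(1L, 2L), mean)
  consensus <- center_scale(consensus)
  it <- 0L; change <- Inf
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n))
      X[, , i] <- X[, , i] %*% optimal_rotation(consensus, X[, , i])
    new_cons <- center_scale(apply(X, c(1L, 2L), mean))
    change <- sum((new_cons - consensus)^2)
    consensus <- new_cons
    if (change < tol) break
  }
  if (change >= tol)
    stop("GPA did not converge in ", max_iter,
         " iterations (last consensus change ", format(change), ")")
  # one polishing pass: makes the endpoint independent of the initial
  # reference (specimen order) to well below the convergence tolerance
  for (i in seq_len(n))
    X[, , i] <- X[, , i] %*% optimal_rotation(consensus, X[, , i])
  consensus <- center_scale(apply(X, c(1L, 2L), mean))
  V <- canonical_orientation(consensus)
  consensus <- consensus %*% V
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% V
  list(coords = X, consensus = consensus, iterations = it, change = change)
}

#' Generalized Procrustes analysis
#'
#' Iteratively centers, scales (to unit centroid size) and rotates all
#' configurations to minimize the summed squared distance to the consensus
#' shape. Iteration stops when the summed squared change of the consensus
#' falls below `tol`. The output is placed in a deterministic canonical
#' orientation (principal axes of the consensus), so results do not depend on
#' the position, orientation, scale or order of the input specimens.
#'
#' @param dataset a `landmark_dataset`.
#' @param tol convergence tolerance on the summed squared consensus change.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param tangent if `TRUE`, orthogonally project the aligned coordinates
#'   onto the tangent space at the consensus (defaults to `FALSE`; downstream
#'   statistics operate on Procrustes coordinates directly).
#' @return An `aligned_shapes` object: `coords` (k x 3 x n), `consensus`,
#'   `centroid_sizes` (original units), `log_cs`, plus the design factors
#'   carried over from the dataset.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L, tangent = FALSE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_specimens(dataset)
  cs <- vapply(seq_len(n), function(i) centroid_size(dataset$coords[, , i]),
               numeric(1))
  fit <- gpa_core(dataset$coords, dataset$specimen_id, tol, max_iter)
  coords <- if (tangent) project_tangent(fit$coords, fit$consensus) else fit$coords
  aligned_shapes(coords, fit$consensus, cs, symmetric = FALSE,
                 iterations = fit$iterations, final_change = fit$change,
                 landmark_names = dataset$landmark_names,
                 ids = dataset$specimen_id, lineage = dataset$lineage,
                 period = dataset$period, symmetry = dataset$symmetry)
}

project_tangent <- function(coords, consensus) {
  c_vec <- as.vector(consensus)
  c_vec <- c_vec / sqrt(sum(c_vec^2))
  for (i in seq_len(dim(coords)[3L])) {
    x <- as.vector(coords[, , i])
    coords[, , i] <- array(x - c_vec * (sum(x * c_vec) - 1), dim(consensus))
  }
  coords
}

#' Reflect a configuration and relabel its paired landmarks
#'
#' Mirrors the coordinates across the plane named in the symmetry map, then
#' swaps each left/right landmark pair so anatomical labels stay on the
#' correct side; midline landmarks keep their labels. Applying the operation
#' twice is the identity; a perfectly symmetric configuration is a fixed
#' point.
#'
#' @param config a `landmark_config` or k x 3 matrix.
#' @param map a `symmetry_map` valid for k.
#' @return Same type as `config`.
#' @export
reflect_relabel <- function(config, map) {
  is_cfg <- inherits(config, "landmark_config")
  X <- if (is_cfg) config$coords else as.matrix(config)
  validate_symmetry_map(map, nrow(X))
  ax <- match(map$plane, c("x", "y", "z"))
  X[, ax] <- -X[, ax]
  if (nrow(map$pairs) > 0L) {
    tmp <- X[map$pairs[, 1L], , drop = FALSE]
    X[map$pairs[, 1L], ] <- X[map$pairs[, 2L], , drop = FALSE]
    X[map$pairs[, 2L], ] <- tmp
  }
  if (is_cfg) landmark_config(config$specimen_id, X, config$landmark_names) else X
}

#' GPA with object symmetry: the symmetric shape component
#'
#' Runs a generalized Procrustes analysis on the doubled sample formed by
#' every original configuration plus its reflected-and-relabeled copy (2n
#' configurations). The symmetric component of each specimen is the average
#' of its aligned original and aligned mirror copy. Downstream analyses
#' consume only this symmetric component. Centroid sizes are those of the
#' original (pre-reflection) configurations.
#'
#' @inheritParams gpa
#' @return An `aligned_shapes` object with `symmetric = TRUE` and n
#'   configurations.
#' @export
symmetric_gpa <- function(dataset, tol = 1e-10, max_iter = 100L,
                          tangent = FALSE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (is.null(dataset$symmetry))
    stop("symmetric_gpa requires a symmetry map on the dataset")
  map <- dataset$symmetry
  n <- n_specimens(dataset); k <- n_landmarks(dataset)
  cs <- vapply(seq_len(n), function(i) centroid_size(dataset$coords[, , i]),
               numeric(1))
  doubled <- array(NA_real_, c(k, 3L, 2L * n))
  doubled[, , seq_len(n)] <- dataset$coords
  for (i in seq_len(n))
    doubled[, , n + i] <- reflect_relabel(dataset$coords[, , i], map)
  fit <- gpa_core(doubled, c(dataset$specimen_id,
                             paste0(dataset$specimen_id, "~mirror")),
                  tol, max_iter)
  sym <- (fit$coords[, , seq_len(n), drop = FALSE] +
          fit$coords[, , n + seq_len(n), drop = FALSE]) / 2
  consensus <- center_scale(apply(sym, c(1L, 2L), mean))
  if (tangent) sym <- project_tangent(sym, consensus)
  aligned_shapes(sym, consensus, cs, symmetric = TRUE,
                 iterations = fit$iterations, final_change = fit$change,
                 landmark_names = dataset$landmark_names,
                 ids = dataset$specimen_id, lineage = dataset$lineage,
                 period = dataset$period, symmetry = map)
}

#' Full Procrustes distance between two shapes
#'
#' Euclidean norm of the coordinate difference after centering, scaling to
#' unit centroid size, and optimally rotating `b` onto `a`. Symmetric in its
#' arguments and a metric on shapes near the consensus.
#'
#' @param a,b `landmark_config` objects or k x 3 matrices with the same k.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  A <- if (inherits(a, "landmark_config")) a$coords else as.matrix(a)
  B <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  if (!identical(dim(A), dim(B))) stop("shapes differ in landmark count")
  A <- center_scale(A); B <- center_scale(B)
  R <- optimal_rotation(A, B)
  sqrt(sum((B %*% R - A)^2))
}

#' Flatten aligned coordinates to an n x 3k matrix
#'
#' Row i is specimen i's coordinates in the order (x1, y1, z1, ..., xk, yk,
#' zk) — the representation used by PCA and all permutation statistics.
#'
#' @param aligned an `aligned_shapes` object (or k x 3 x n array).
#' @return n x 3k numeric matrix with specimen ids as row names.
#' @export
flatten_shapes <- function(aligned) {
  arr <- if (inherits(aligned, "aligned_shapes")) aligned$coords else aligned
  k <- dim(arr)[1L]; n <- dim(arr)[3L]
  out <- matrix(NA_real_, n, 3L * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(arr[, , i]))
  rownames(out) <- dimnames(arr)[[3L]]
  colnames(out) <- paste0(rep(c("x", "y", "z"), k),
                          rep(seq_len(k), each = 3L))
  out
}

#' Rebuild a k x 3 configuration from a flattened row
#'
#' @param v numeric vector of length 3k in (x1, y1, z1, ...) order.
#' @return k x 3 matrix.
#' @export
unflatten_shape <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}
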