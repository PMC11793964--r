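test_that("centroid size: closed form, homogeneity, brute-force oracle", {
  sq <- matrix(c(1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1, 0), 4, 3, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(8))

  X <- rand_config(82, seed = 1)
  expect_equal(centroid_size(3.7 * X), 3.7 * centroid_size(X))

  # brute force: double loop over landmarks against the centroid
  ctr <- colMeans(X)
  acc <- 0
  for (j in seq_len(nrow(X))) acc <- acc + sum((X[j, ] - ctr)^2)
  expect_equal(centroid_size(X), sqrt(acc))
})

test_that("optimal rotation recovers known rotations and refuses reflections", {
  A <- rand_config(10, seed = 2)
  A <- sweep(A, 2, colMeans(A))
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE) # 90 deg z
  R_hat <- optimal_rotation(A, A %*% Rz)
  expect_lt(sum((A %*% Rz %*% R_hat - A)^2), 1e-20)

  # mirrored target: best proper rotation keeps det +1, nonzero residual
  M <- A; M[, 1] <- -M[, 1]
  R_m <- optimal_rotation(A, M)
  expect_equal(det(R_m), 1, tolerance = 1e-12)
  expect_gt(sum((M %*% R_m - A)^2), 1e-4)

  # random rotations recovered to 1e-8
  set.seed(3)
  for (i in 1:5) {
    R <- rand_rotation3()
    R_hat <- optimal_rotation(A, A %*% R)
    expect_lt(max(abs(R %*% R_hat - diag(3))), 1e-8)
  }

  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  line <- sweep(line, 2, colMeans(line))
  expect_error(optimal_rotation(line, line), "collinear")
})

test_that("GPA aligns identical shapes exactly and satisfies its invariants", {
  base <- rand_config(12, seed = 4)
  set.seed(5)
  configs <- lapply(1:8, function(i) {
    X <- sweep(base %*% rand_rotation3() * runif(1, 0.5, 3), 2,
               rnorm(3, 0, 10), "+")
    landmark_config(paste0("s", i), X)
  })
  ds <- landmark_dataset(configs)
  al <- gpa(ds)

  # total Procrustes SS vanishes for identical shapes
  ss <- sum(sweep(al$coords, c(1, 2), al$consensus)^2)
  expect_lt(ss, 1e-12)
  expect_lt(max(abs(al$coords[, , 1] - al$coords[, , 8])), 1e-8)

  # unit CS, centered, consensus = mean of aligned coordinates
  for (i in 1:8) {
    expect_lt(max(abs(colMeans(al$coords[, , i]))), 1e-9)
    expect_lt(abs(sqrt(sum(al$coords[, , i]^2)) - 1), 1e-9)
  }
  expect_lt(max(abs(apply(al$coords, c(1, 2), mean) - al$consensus)), 1e-6)

  # centroid sizes are those of the input configurations
  expect_equal(al$centroid_sizes,
               vapply(seq_len(8), function(i) centroid_size(ds$coords[, , i]),
                      numeric(1)))
})

test_that("GPA output is invariant to similarity transforms and order", {
  ds <- simulate_dataset(small_params(seed = 6))$dataset
  al <- gpa(ds)
  al_t <- gpa(transform_dataset(ds, seed = 7))
  expect_lt(max(abs(al$coords - al_t$coords)), 1e-8)

  set.seed(8)
  ord <- sample(n_specimens(ds))
  al_o <- gpa(subset_dataset(ds, ord))
  back <- match(ds$specimen_id, ds$specimen_id[ord])
  expect_lt(max(abs(al$coords - al_o$coords[, , back])), 1e-8)
})

test_that("two-specimen GPA reproduces the direct pairwise solution", {
  A <- rand_config(10, seed = 9)
  B <- rand_config(10, seed = 10)
  ds <- landmark_dataset(list(landmark_config("a", A), landmark_config("b", B)))
  al <- gpa(ds)
  d_gpa <- sqrt(sum((al$coords[, , 1] - al$coords[, , 2])^2))
  expect_equal(d_gpa, procrustes_distance(A, B), tolerance = 1e-8)
})

test_that("reflect_relabel is an involution with symmetric fixed points", {
  tmpl <- make_template(6, 3, seed = 11)
  expect_lt(max(abs(reflect_relabel(tmpl$template$coords, tmpl$map) -
                    tmpl$template$coords)), 1e-12)

  X <- rand_config(15, seed = 12)
  twice <- reflect_relabel(reflect_relabel(X, tmpl$map), tmpl$map)
  expect_equal(twice, X, ignore_attr = TRUE)
})

test_that("symmetric GPA equals plain GPA on symmetric data and reduces variance", {
  ds_sym <- symmetric_noise_dataset(n = 12, seed = 13)
  al_plain <- gpa(ds_sym)
  al_sym <- symmetric_gpa(ds_sym)
  expect_lt(max(abs(al_plain$coords - al_sym$coords)), 1e-8)
  expect_true(al_sym$symmetric)

  # asymmetric data: symmetric-component variance <= raw aligned variance
  ds <- simulate_dataset(small_params(seed = 14))$dataset
  v_raw <- sum(sweep(gpa(ds)$coords, c(1, 2), gpa(ds)$consensus)^2)
  al2 <- symmetric_gpa(ds)
  v_sym <- sum(sweep(al2$coords, c(1, 2), al2$consensus)^2)
  expect_lte(v_sym, v_raw)

  # invariant to which side is labelled "left" globally
  ds_swap <- ds
  ds_swap$symmetry <- symmetry_map(ds$symmetry$pairs[, c(2, 1)],
                                   ds$symmetry$midline, ds$symmetry$plane)
  al_swap <- symmetric_gpa(ds_swap)
  expect_lt(max(abs(al2$coords - al_swap$coords)), 1e-8)

  ds_nosym <- ds; ds_nosym$symmetry <- NULL
  expect_error(symmetric_gpa(ds_nosym), "symmetry map")
})

test_that("procrustes_distance is a symmetric metric near the consensus", {
  a <- rand_config(9, seed = 15)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)

  set.seed(16)
  for (i in 1:5) {
    x <- rand_config(9); y <- rand_config(9); z <- rand_config(9)
    expect_lt(abs(procrustes_distance(x, y) - procrustes_distance(y, x)), 1e-10)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-9)
  }
  expect_error(procrustes_distance(rand_config(9), rand_config(8)),
               "landmark count")
})

test_that("tangent projection is a small, optional correction", {
  ds <- simulate_dataset(small_params(seed = 17))$dataset
  al <- gpa(ds)
  al_t <- gpa(ds, tangent = TRUE)
  # projected coordinates orthogonal to the consensus direction
  cvec <- as.vector(al_t$consensus) / sqrt(sum(al_t$consensus^2))
  dots <- apply(al_t$coords, 3, function(X) sum(as.vector(X) * cvec) - 1)
  expect_lt(max(abs(dots)), 1e-9)
  # near-identity in the small-variation regime
  expect_lt(max(abs(al$coords - al_t$coords)), 1e-3)
})
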