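# Shared fixture builders. All randomness is seeded explicitly; analysis
# seeds are kept in ranges disjoint from data seeds (set.seed() inside
# package functions resets the global RNG stream).

rand_config <- function(k = 10, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(k * 3), k, 3) * scale
}

rand_rotation3 <- function() {
  d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(d) %*% diag(sign(diag(qr.R(d))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a random similarity transform (rotation, scale, translation) to
# every specimen of a dataset.
transform_dataset <- function(ds, seed) {
  set.seed(seed)
  for (i in seq_len(dim(ds$coords)[3])) {
    R <- rand_rotation3()
    s <- stats::runif(1, 0.2, 5)
    tr <- stats::rnorm(3, 0, 50)
    ds$coords[, , i] <- sweep(ds$coords[, , i] %*% R * s, 2, tr, "+")
  }
  ds
}

# Small, fast simulation world for unit tests (24 landmarks, 51 specimens).
small_params <- function(...) {
  defaults <- list(k_pairs = 8L, k_midline = 4L,
                   n_per_cell = matrix(c(10L, 9L, 11L, 8L, 7L, 6L), 3L, 2L))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

# Dataset of n perfectly bilaterally symmetric configurations (template +
# symmetrized noise), useful for symmetric_gpa vs gpa comparisons.
symmetric_noise_dataset <- function(n = 12, k_pairs = 6, k_midline = 3,
                                    sd = 0.01, seed = 1) {
  tmpl <- make_template(k_pairs, k_midline, seed = seed)
  k <- 2 * k_pairs + k_midline
  configs <- lapply(seq_len(n), function(i) {
    e <- matrix(stats::rnorm(k * 3, sd = sd), k, 3)
    e_sym <- (e + reflect_relabel(e, tmpl$map)) / 2
    landmark_config(paste0("s", i), tmpl$template$coords + e_sym,
                    tmpl$template$landmark_names)
  })
  landmark_dataset(configs, symmetry = tmpl$map)
}
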