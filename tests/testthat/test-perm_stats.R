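test_that("rrpp_anova reproduces the classical F for balanced one-way designs", {
  set.seed(31)
  for (rep in 1:3) {
    y <- rnorm(24)
    g <- factor(rep(letters[1:3], each = 8))
    tab <- rrpp_anova(y, data.frame(g = g), ~ g, n_perm = 99, seed = 1000 + rep)
    F_lm <- anova(stats::lm(y ~ g))$"F value"[1]
    expect_lt(abs(tab$F[1] - F_lm), 1e-10)
    expect_equal(tab$df, c(2L, 21L))
    expect_equal(tab$SS[1] / (tab$SS[1] + tab$SS[2]), tab$R2[1],
                 tolerance = 1e-12)
  }
})

test_that("Type II SS equals Type I SS on balanced orthogonal designs", {
  set.seed(32)
  dat <- data.frame(a = factor(rep(c("x", "y"), each = 12)),
                    b = factor(rep(rep(c("u", "v", "w"), each = 4), 2)))
  Y <- matrix(rnorm(24 * 3), 24)
  tab <- rrpp_anova(Y, dat, ~ a * b, n_perm = 99, seed = 2000)

  # sequential (Type I) SS via nested least-squares fits, summed over columns
  rss <- function(form) sum(stats::resid(stats::lm(form, data = dat))^2)
  ss_a  <- rss(Y ~ 1) - rss(Y ~ a)
  ss_b  <- rss(Y ~ a) - rss(Y ~ a + b)
  ss_ab <- rss(Y ~ a + b) - rss(Y ~ a * b)
  expect_equal(tab$SS[tab$term == "a"], ss_a, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "b"], ss_b, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "a:b"], ss_ab, tolerance = 1e-9)
})

test_that("permutation p matches exhaustive enumeration on a tiny design", {
  set.seed(33)
  for (rep in 1:3) {
    y <- rnorm(8)
    g <- factor(rep(c("A", "B"), each = 4))

    # oracle: enumerate all 70 assignments of the 8 values to group A
    f_of <- function(yy) {
      m <- tapply(yy, g, mean)
      ssb <- 4 * sum((m - mean(yy))^2)
      (ssb / 1) / (sum((yy - m[g])^2) / 6)
    }
    combos <- utils::combn(8, 4)
    Fs <- apply(combos, 2, function(s) {
      yy <- numeric(8); yy[1:4] <- y[s]; yy[5:8] <- y[-s]; f_of(yy)
    })
    p_oracle <- mean(Fs >= f_of(y))

    # implementation: one representative permutation per non-identity
    # assignment class (class sizes are all equal, so proportions agree)
    id_col <- which(apply(combos, 2, function(s) all(s == 1:4)))
    pm <- sapply(seq_len(ncol(combos))[-id_col], function(ci) {
      s <- combos[, ci]; c(s, setdiff(1:8, s))
    })
    tab <- rrpp_anova(y, data.frame(g = g), ~ g, perm_matrix = pm)
    expect_identical(tab$p[1], p_oracle)
  }
})

test_that("rrpp_anova is deterministic under a fixed seed and validates input", {
  ds <- simulate_dataset(small_params(seed = 34))$dataset
  al <- gpa(ds)
  dat <- data.frame(lineage = al$lineage, period = al$period)
  t1 <- rrpp_anova(al, dat, ~ period * lineage, n_perm = 99, seed = 7)
  t2 <- rrpp_anova(al, dat, ~ period * lineage, n_perm = 99, seed = 7)
  expect_identical(t1$p, t2$p)
  expect_identical(t1$Z, t2$Z)

  expect_error(rrpp_anova(rep(1, n_specimens(ds)), dat, ~ period * lineage,
                          n_perm = 99, seed = 1), "constant response")

  # empty lineage x period cell is named
  dat2 <- dat
  dat2$period[dat2$lineage == "DL"] <- "historic"
  dat2$period <- droplevels(factor(dat2$period))
  expect_error(rrpp_anova(al, dat2, ~ period * lineage, n_perm = 99, seed = 1),
               "empty cell")
  expect_error(rrpp_anova(al$log_cs, dat, ~ period * lineage, n_perm = 50,
                          seed = 1), ">= 99")
})

test_that("rrpp_anova p-values are uniform under a true null", {
  # two-way design, no effects anywhere; KS on the main-effect p-values
  n_runs <- 500
  p_per <- p_lin <- numeric(n_runs)
  dat <- data.frame(lineage = factor(rep(c("a", "b", "c"), each = 14)),
                    period = factor(rep(rep(c("h", "m"), each = 7), 3)))
  for (r in seq_len(n_runs)) {
    set.seed(4000000 + r)
    y <- rnorm(42)
    tab <- rrpp_anova(y, dat, ~ period * lineage, n_perm = 99,
                      seed = 7000000 + r)
    p_per[r] <- tab$p[tab$term == "period"]
    p_lin[r] <- tab$p[tab$term == "lineage"]
  }
  expect_gt(suppressWarnings(stats::ks.test(p_per, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(p_lin, "punif"))$p.value, 0.01)
})

test_that("procrustes_variance matches its analytic oracle", {
  Y0 <- matrix(1, 10, 6)
  expect_equal(unname(procrustes_variance(Y0 + 0, rep("g", 10))), 0)

  # isotropic Gaussian noise: E[PV] = q sigma^2 (n-1)/n
  q <- 5; n_g <- 12; sigma <- 1.5
  pv <- numeric(200)
  for (r in 1:200) {
    set.seed(5000000 + r)
    pv[r] <- procrustes_variance(matrix(rnorm(n_g * q, sd = sigma), n_g),
                                 rep("g", n_g))
  }
  expected <- q * sigma^2 * (n_g - 1) / n_g
  se <- stats::sd(pv) / sqrt(200)
  expect_lt(abs(mean(pv) - expected), 3 * se)

  # equal generating noise -> equal variances within sampling error
  set.seed(51)
  Y <- matrix(rnorm(60 * q), 60)
  pv2 <- procrustes_variance(Y, rep(c("a", "b"), each = 30))
  expect_lt(abs(pv2["a"] - pv2["b"]), 4 * sqrt(2 * q / 30))

  expect_error(procrustes_variance(Y, c("a", rep("b", 59))), "fewer than 2")
})

test_that("pairwise mean comparisons: statistic, pair structure, consistency", {
  # duplicated group: distance exactly 0
  set.seed(52)
  block <- matrix(rnorm(10 * 4), 10)
  Y <- rbind(block, block)
  lin <- rep("DE", 20)
  per <- rep(c("historic", "modern"), each = 10)
  pw <- pairwise_means(Y, lin, per, n_perm = 99, seed = 1)
  expect_equal(pw$distance, 0)
  expect_equal(pw$p, 1)

  # shifting one group by delta in one coordinate: distance ~ delta
  delta <- 0.5
  set.seed(53)
  Y2 <- matrix(rnorm(400 * 4, sd = 0.05), 400)
  Y2[201:400, 2] <- Y2[201:400, 2] + delta
  pw2 <- pairwise_means(Y2, rep("DE", 400),
                        rep(c("historic", "modern"), each = 200),
                        n_perm = 99, seed = 2)
  expect_equal(pw2$distance, delta, tolerance = 0.05)
  expect_equal(pw2$p, 0.01)

  # pair structure: 3 within-lineage pairs by default, 15 for all cells
  ds <- simulate_dataset(small_params(seed = 54))$dataset
  al <- gpa(ds)
  pw3 <- pairwise_means(al, al$lineage, al$period, n_perm = 99, seed = 3)
  expect_equal(nrow(pw3), 3L)
  expect_true(all(grepl("historic", pw3$group_a) & grepl("modern", pw3$group_b)))
  pw4 <- pairwise_means(al, al$lineage, al$period, n_perm = 99, seed = 3,
                        pairs = "all")
  expect_equal(nrow(pw4), 15L)
  expect_equal(length(attr(pw3, "group_variances")), 6L)
})

test_that("pairwise variance comparisons: null behaviour and power", {
  # identical groups: statistic 0, p at the maximum
  block <- matrix(rnorm(12 * 5, sd = 2), 12)
  Y <- rbind(block, block)
  pw <- pairwise_variances(Y, rep("DE", 24),
                          rep(c("historic", "modern"), each = 12),
                          n_perm = 99, seed = 4)
  expect_equal(pw$distance, 0, tolerance = 1e-12)
  expect_equal(pw$p, 1)

  # sd ratio 2 at the generator's default historic/modern cell sizes
  rej <- 0
  for (r in 1:60) {
    set.seed(5500000 + r)
    Y2 <- rbind(matrix(rnorm(28 * 20, sd = 2), 28),
                matrix(rnorm(20 * 20, sd = 1), 20))
    pv <- pairwise_variances(Y2, rep("DE", 48),
                             rep(c("historic", "modern"), c(28, 20)),
                             n_perm = 99, seed = 6500000 + r)
    rej <- rej + (pv$p[1] <= 0.05)
  }
  expect_gte(rej / 60, 0.8)
})

test_that("pairwise variance test holds its type I error under the null", {
  n_runs <- 500
  rej <- 0
  for (r in seq_len(n_runs)) {
    set.seed(3000000 + r)
    Y <- matrix(rnorm(48 * 10), 48)
    p <- pairwise_variances(Y, rep("DE", 48),
                            rep(c("historic", "modern"), c(28, 20)),
                            n_perm = 99, seed = 6000000 + r)$p[1]
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / n_runs, 0.03)
  expect_lte(rej / n_runs, 0.07)
})

test_that("pairwise results are deterministic and symmetric in (a, b)", {
  ds <- simulate_dataset(small_params(seed = 55))$dataset
  al <- gpa(ds)
  a1 <- pairwise_means(al, al$lineage, al$period, n_perm = 99, seed = 9)
  a2 <- pairwise_means(al, al$lineage, al$period, n_perm = 99, seed = 9)
  expect_identical(a1$p, a2$p)
  expect_identical(a1$Z, a2$Z)

  # swapping the period level order swaps pair roles but not distances
  per_swapped <- factor(al$period, levels = c("modern", "historic"))
  a3 <- pairwise_means(al, al$lineage, per_swapped, n_perm = 99, seed = 9)
  expect_equal(sort(a3$distance), sort(a1$distance), tolerance = 1e-12)
})
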