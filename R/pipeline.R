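# Full analysis pipeline: load/simulate -> symmetric GPA -> size ANOVA ->
# shape PCA/ANOVA (full dataset A, domestic-only dataset B) -> MCI test.

#' Pipeline run configuration
#'
#' @param seed integer seed (mandatory); every stochastic stage derives its
#'   seed from it, so a rerun with the same configuration is reproducible.
#' @param out_dir output directory (created if missing).
#' @param simulate optional [simulation_params()]; when given, the dataset
#'   is simulated instead of read from files.
#' @param coords,metadata,pairs input file paths (coordinates CSV, metadata
#'   CSV, symmetry-pairs CSV) used when `simulate` is `NULL`.
#' @param coords_schema `"long"` or `"wide"` for the coordinates CSV.
#' @param symmetric run GPA with object symmetry (requires a symmetry map).
#' @param tangent project aligned coordinates to tangent space.
#' @param n_perm permutations for ANOVA/pairwise tests (>= 99).
#' @param n_rand randomizations for the MCI test (>= 99).
#' @param lineages_used the two lineages entering the MCI.
#' @param refit_subset re-run GPA on the domestic-only subset (default) or
#'   reuse dataset A's superimposition.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, out_dir, simulate = NULL, coords = NULL,
                       metadata = NULL, pairs = NULL,
                       coords_schema = "long", symmetric = TRUE,
                       tangent = FALSE, n_perm = 999L, n_rand = 999L,
                       lineages_used = c("DE", "DL"), refit_subset = TRUE) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is mandatory")
  if (n_perm < 99L || n_rand < 99L) stop("n_perm and n_rand must be >= 99")
  if (is.null(simulate) && (is.null(coords) || is.null(metadata)))
    stop("either 'simulate' params or coords+metadata paths are required")
  if (is.null(simulate) && symmetric && is.null(pairs))
    stop("symmetric GPA requires a 'pairs' symmetry table")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, coords = coords, metadata = metadata,
                 pairs = pairs, coords_schema = coords_schema,
                 symmetric = isTRUE(symmetric), tangent = isTRUE(tangent),
                 n_perm = as.integer(n_perm), n_rand = as.integer(n_rand),
                 lineages_used = lineages_used,
                 refit_subset = isTRUE(refit_subset)),
            class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

anova_to_df <- function(tab) as.data.frame(unclass(tab))

pairwise_to_df <- function(pw) {
  df <- as.data.frame(unclass(pw))
  gv <- attr(pw, "group_variances")
  attr(df, "group_variances") <- NULL
  list(table = df,
       group_variances = data.frame(group = names(gv), variance = unname(gv)))
}

write_pairwise <- function(pw, stem, out_dir) {
  parts <- pairwise_to_df(pw)
  utils::write.csv(parts$table, file.path(out_dir, paste0(stem, ".csv")),
                   row.names = FALSE)
  utils::write.csv(parts$group_variances,
                   file.path(out_dir, paste0(stem, "_group_variances.csv")),
                   row.names = FALSE)
}

write_pca_dir <- function(pca, aligned, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  sc <- pca$scores[, seq_len(min(10L, ncol(pca$scores))), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  utils::write.csv(data.frame(specimen_id = aligned$specimen_id,
                              lineage = aligned$lineage,
                              period = aligned$period, sc),
                   file.path(dir_path, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(pca$var_prop),
                              var_prop = pca$var_prop),
                   file.path(dir_path, "var_prop.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(pca$axes),
                   file.path(dir_path, "axes.csv"), row.names = FALSE)
  cells <- cell_factor(aligned$lineage, aligned$period)
  gm <- group_mean_shapes(aligned, cells)
  gm_long <- do.call(rbind, lapply(names(gm), function(g) {
    data.frame(group = g, landmark = rownames(gm[[g]]),
               x = gm[[g]][, 1L], y = gm[[g]][, 2L], z = gm[[g]][, 3L])
  }))
  utils::write.csv(gm_long, file.path(dir_path, "group_means.csv"),
                   row.names = FALSE)
  invisible(dir_path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate the dataset; (symmetric) GPA; log
#' centroid size two-way permutation ANOVA with within-lineage pairwise mean
#' and variance tests; shape PCA of the full dataset (A); shape two-way
#' ANOVA and pairwise tests on dataset A; the same PCA/ANOVA on the
#' domestic-only dataset B (re-superimposed by default); and the MCI
#' randomization test on the domestic lineages. Per-stage CSV/JSON files are
#' written under `config$out_dir` along with a single `report.json`. A stage
#' failure aborts the run with the stage named; a `FAILED` marker file
#' records the stage and message, and earlier outputs are retained.
#'
#' @param config a [run_config()].
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("morphoconverge")),
                 r_version = R.version.string,
                 n_perm = config$n_perm, n_rand = config$n_rand,
                 symmetric = config$symmetric, tangent = config$tangent,
                 dataset_b_refit = config$refit_subset,
                 stages = list())
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      writeLines(paste0("FAILED at stage '", name, "': ",
                        conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[morphoconverge] stage=%s elapsed=%.3fs seed=%d",
                    name, elapsed, config$seed))
    report$stages[[name]] <<- list(elapsed_s = elapsed)
    res
  }

  dataset <- stage("load", function() {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      sim$dataset
    } else {
      frag <- read_landmarks_csv(config$coords, config$coords_schema)
      sym <- if (!is.null(config$pairs))
        read_symmetry_csv(config$pairs, dim(frag$coords)[1L])
      assemble_dataset(frag, config$metadata, sym)
    }
  })

  aligned <- stage("gpa", function() {
    fit <- if (config$symmetric) symmetric_gpa(dataset, tangent = config$tangent)
           else gpa(dataset, tangent = config$tangent)
    write_landmarks_csv(list(coords = fit$coords,
                             specimen_id = fit$specimen_id,
                             landmark_names = fit$landmark_names),
                        file.path(out, "aligned_coords.csv"), "long")
    write_json_file(list(n = dim(fit$coords)[3L], k = dim(fit$coords)[1L],
                         iterations = fit$iterations,
                         final_change = fit$final_change,
                         symmetric = fit$symmetric),
                    file.path(out, "gpa_report.json"))
    fit
  })

  size_tables <- stage("size_anova", function() {
    dat <- data.frame(lineage = aligned$lineage, period = aligned$period)
    tab <- rrpp_anova(aligned$log_cs, dat, ~ period * lineage,
                      n_perm = config$n_perm, seed = config$seed)
    pw_m <- pairwise_means(aligned$log_cs, aligned$lineage, aligned$period,
                           n_perm = config$n_perm, seed = config$seed + 1L)
    pw_v <- pairwise_variances(aligned$log_cs, aligned$lineage,
                               aligned$period, n_perm = config$n_perm,
                               seed = config$seed + 2L)
    utils::write.csv(anova_to_df(tab), file.path(out, "anova_size.csv"),
                     row.names = FALSE)
    write_pairwise(pw_m, "pairwise_size_means", out)
    write_pairwise(pw_v, "pairwise_size_variances", out)
    list(anova = tab, means = pw_m, variances = pw_v)
  })

  pca_full <- stage("pca_full", function() {
    pca <- shape_pca(aligned)
    write_pca_dir(pca, aligned, file.path(out, "pca_full"))
    pca
  })

  shape_a <- stage("shape_anova_A", function() {
    dat <- data.frame(lineage = aligned$lineage, period = aligned$period)
    tab <- rrpp_anova(aligned, dat, ~ period * lineage,
                      n_perm = config$n_perm, seed = config$seed + 3L)
    pw_m <- pairwise_means(aligned, aligned$lineage, aligned$period,
                           n_perm = config$n_perm, seed = config$seed + 4L)
    pw_v <- pairwise_variances(aligned, aligned$lineage, aligned$period,
                               n_perm = config$n_perm,
                               seed = config$seed + 5L)
    utils::write.csv(anova_to_df(tab), file.path(out, "anova_shape_A.csv"),
                     row.names = FALSE)
    write_pairwise(pw_m, "pairwise_shape_A_means", out)
    write_pairwise(pw_v, "pairwise_shape_A_variances", out)
    list(anova = tab, means = pw_m, variances = pw_v)
  })

  domestic <- stage("dataset_B", function() {
    keep <- dataset$lineage %in% config$lineages_used
    if (config$refit_subset) {
      sub <- subset_dataset(dataset, keep)
      if (config$symmetric) symmetric_gpa(sub, tangent = config$tangent)
      else gpa(sub, tangent = config$tangent)
    } else {
      structure(list(coords = aligned$coords[, , keep, drop = FALSE],
                     consensus = aligned$consensus,
                     centroid_sizes = aligned$centroid_sizes[keep],
                     log_cs = aligned$log_cs[keep],
                     symmetric = aligned$symmetric,
                     iterations = aligned$iterations,
                     final_change = aligned$final_change,
                     landmark_names = aligned$landmark_names,
                     specimen_id = aligned$specimen_id[keep],
                     lineage = droplevels(aligned$lineage[keep]),
                     period = droplevels(aligned$period[keep]),
                     symmetry = aligned$symmetry),
                class = "aligned_shapes")
    }
  })

  pca_b <- stage("pca_domestic", function() {
    pca <- shape_pca(domestic)
    write_pca_dir(pca, domestic, file.path(out, "pca_domestic"))
    pca
  })

  shape_b <- stage("shape_anova_B", function() {
    dat <- data.frame(lineage = domestic$lineage, period = domestic$period)
    tab <- rrpp_anova(domestic, dat, ~ period * lineage,
                      n_perm = config$n_perm, seed = config$seed + 6L)
    pw_m <- pairwise_means(domestic, domestic$lineage, domestic$period,
                           n_perm = config$n_perm, seed = config$seed + 7L)
    pw_v <- pairwise_variances(domestic, domestic$lineage, domestic$period,
                               n_perm = config$n_perm,
                               seed = config$seed + 8L)
    utils::write.csv(anova_to_df(tab), file.path(out, "anova_shape_B.csv"),
                     row.names = FALSE)
    write_pairwise(pw_m, "pairwise_shape_B_means", out)
    write_pairwise(pw_v, "pairwise_shape_B_variances", out)
    list(anova = tab, means = pw_m, variances = pw_v)
  })

  mci_res <- stage("mci", function() {
    res <- mci_test(domestic, lineages_used = config$lineages_used,
                    n_rand = config$n_rand, seed = config$seed + 9L)
    write_json_file(list(mci = res$mci, p = res$p,
                         null_mean = res$null_mean, n_rand = res$n_rand,
                         stratified = res$stratified,
                         null_values = res$null_values),
                    file.path(out, "mci.json"))
    res
  })

  report$results <- list(
    n = dim(aligned$coords)[3L], k = dim(aligned$coords)[1L],
    size_anova = anova_to_df(size_tables$anova),
    size_pairwise_means = pairwise_to_df(size_tables$means),
    size_pairwise_variances = pairwise_to_df(size_tables$variances),
    pca_full_var_prop = utils::head(pca_full$var_prop, 10L),
    shape_anova_A = anova_to_df(shape_a$anova),
    shape_pairwise_A_means = pairwise_to_df(shape_a$means),
    shape_pairwise_A_variances = pairwise_to_df(shape_a$variances),
    pca_domestic_var_prop = utils::head(pca_b$var_prop, 10L),
    shape_anova_B = anova_to_df(shape_b$anova),
    shape_pairwise_B_means = pairwise_to_df(shape_b$means),
    shape_pairwise_B_variances = pairwise_to_df(shape_b$variances),
    mci = list(mci = mci_res$mci, p = mci_res$p,
               null_mean = mci_res$null_mean, n_rand = mci_res$n_rand))
  write_json_file(report, file.path(out, "report.json"))
  invisible(report)
}
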