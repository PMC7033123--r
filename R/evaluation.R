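#' Seeded k-fold assignment
#'
#' Shuffles sample indices with a fixed seed and chunks them into k
#' contiguous folds whose sizes differ by at most one.
#'
#' @param n Number of samples.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer RNG seed.
#' @return An integer vector of length `n` assigning each sample to a
#'   fold in `1:k`.
#' @examples
#' table(kfold_indices(17, 3, seed = 1))  # folds of 6, 6, 5
#' @export
kfold_indices <- function(n, k, seed = 1) {
  if (k < 2 || k > n) abort("k must satisfy 2 <= k <= n")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Used on pooled
#' out-of-fold predictions, where it can be negative (worse than the
#' global-mean predictor) but never exceeds 1.
#'
#' @param y Observed values (non-constant, length >= 2).
#' @param y_hat Predictions of the same length.
#' @return A single numeric value <= 1.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 1))  # 0.5
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("y and y_hat must have equal length")
  if (length(y) < 2) abort("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("R-squared undefined for constant y")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' The default model grid
#'
#' One CART row, epsilon-SVR and LSSVM across the four kernels and
#' gamma in {0.01, 0.05, 0.10}, and one Naive Bayes row: 26
#' configurations in total. C = 10 and epsilon = 0.1 (on the z-scored
#' response) throughout; only gamma is swept.
#'
#' @param C,epsilon Kernel-machine regularization and tube width.
#' @param gammas Kernel parameter sweep.
#' @param min_leaf,max_depth CART bounds.
#' @return A tibble with one row per model configuration.
#' @export
default_model_grid <- function(C = 10, epsilon = 0.1,
                               gammas = c(0.01, 0.05, 0.10),
                               min_leaf = 2, max_depth = NULL) {
  kernels <- c("linear", "polynomial", "gaussian", "sigmoid")
  sweep <- tidyr::expand_grid(kernel = kernels, gamma = gammas)
  dplyr::bind_rows(
    tibble::tibble(family = "cart", kernel = NA_character_, gamma = NA_real_,
                   C = NA_real_, epsilon = NA_real_, min_leaf = min_leaf,
                   max_depth = list(max_depth)),
    tibble::tibble(family = "svr", kernel = sweep$kernel, gamma = sweep$gamma,
                   C = C, epsilon = epsilon, min_leaf = NA_real_,
                   max_depth = list(NULL)),
    tibble::tibble(family = "lssvm", kernel = sweep$kernel,
                   gamma = sweep$gamma, C = C, epsilon = NA_real_,
                   min_leaf = NA_real_, max_depth = list(NULL)),
    tibble::tibble(family = "nb", kernel = NA_character_, gamma = NA_real_,
                   C = NA_real_, epsilon = NA_real_, min_leaf = NA_real_,
                   max_depth = list(NULL))
  )
}

fit_config <- function(config, train) {
  kern <- if (!is.na(config$kernel)) kernel_spec(config$kernel, config$gamma)
  switch(config$family,
    cart = fit_cart(train, min_leaf = config$min_leaf,
                    max_depth = config$max_depth[[1]]),
    svr = fit_svr(train, kernel = kern, C = config$C,
                  epsilon = config$epsilon),
    lssvm = fit_lssvm(train, kernel = kern, C = config$C),
    nb = fit_nb(train),
    abort(paste0("unknown model family: ", config$family))
  )
}

config_label <- function(config) {
  if (config$family %in% c("svr", "lssvm")) {
    sprintf("%s / %s, gamma=%g", config$family, config$kernel, config$gamma)
  } else {
    config$family
  }
}

#' Cross-validate a grid of model configurations
#'
#' For every configuration and every fold seed, runs k-fold
#' cross-validation, pools the out-of-fold predictions, and scores them
#' with [r_squared()]. The reported `r2_mean` averages the pooled R^2
#' over the fold seeds, quantifying fold-assignment variability.
#'
#' @param data A `stress_dataset` (or data frame with `y` and feature
#'   columns).
#' @param grid A configuration tibble like [default_model_grid()].
#' @param k Number of folds.
#' @param seeds Integer vector of fold seeds (one CV repetition each).
#' @param features,response Passed through to the fitters.
#' @return A `cv_grid` tibble: one row per configuration with `label`,
#'   the configuration columns, `r2_mean`, `r2_sd` and the per-seed
#'   values in the list column `r2_seeds`.
#' @export
run_model_grid <- function(data, grid = default_model_grid(), k = 3,
                           seeds = 1:20, features = NULL, response = "y") {
  features <- features %||% attr(data, "features")
  df <- as.data.frame(data)
  y <- df[[response]]
  n <- nrow(df)
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    config <- grid[g, ]
    r2s <- vapply(seeds, function(s) {
      fold <- kfold_indices(n, k, seed = s)
      oof <- numeric(n)
      for (f in seq_len(k)) {
        train <- df[fold != f, , drop = FALSE]
        test <- df[fold == f, , drop = FALSE]
        attr(train, "features") <- features
        m <- fit_config(config, train)
        oof[fold == f] <- predict(m, test)
      }
      r_squared(y, oof)
    }, numeric(1))
    dplyr::bind_cols(
      tibble::tibble(label = config_label(config)), config,
      tibble::tibble(r2_mean = mean(r2s), r2_sd = sd(r2s),
                     r2_seeds = list(r2s)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- k
  attr(out, "seeds") <- seeds
  class(out) <- c("cv_grid", class(out))
  out
}

#' @rdname mirstress-tidiers
#' @exportS3Method generics::tidy
tidy.cv_grid <- function(x, ...) {
  seeds <- attr(x, "seeds")
  tb <- tibble::as_tibble(unclass(x))
  purrr::pmap_dfr(
    list(tb$label, tb$family, tb$kernel, tb$gamma, tb$r2_seeds),
    function(label, family, kernel, gamma, r2s) {
      tibble::tibble(label = label, family = family, kernel = kernel,
                     gamma = gamma, seed = seeds, r2 = r2s)
    })
}

#' Reproduce the full analysis
#'
#' End-to-end driver: loads the packaged concentration table, computes
#' the Banzhaf rank matrix across the four stresses, cross-validates the
#' default model grid on the 17-pattern, 3-miRNA dataset
#' (miRNA-169, miRNA-393, miRNA-396; ordinal severity targets), and
#' writes CSV/JSON outputs plus a provenance manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; replicate sampling uses it directly and the
#'   CV fold seeds are derived from it.
#' @param n_cv_seeds Number of fold seeds for the model grid.
#' @param config A [payoff_config()] for the ranking stage.
#' @param table An `expression_table`; defaults to the packaged one.
#' @return Invisibly, a list with elements `ranks`, `cv`,
#'   `fold_change_mirna167` and the output paths.
#' @export
reproduce <- function(out_dir, seed = 1, n_cv_seeds = 20,
                      config = payoff_config("mi"), table = NULL) {
  table <- table %||% load_expression_table()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ranks <- rank_all_stresses(table, config = config, seed = seed)
  readr::write_csv(tibble::as_tibble(unclass(ranks)),
                   file.path(out_dir, "banzhaf_ranks.csv"), progress = FALSE)
  jsonlite::write_json(
    list(indices = tidy(ranks), top5 = attr(ranks, "top5"),
         consensus_top3 = attr(ranks, "consensus_top3"),
         config = unclass(config), seed = seed),
    file.path(out_dir, "banzhaf_scores.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dat <- build_stress_dataset(table, scope = "all",
                              features = c("miRNA-169", "miRNA-393",
                                           "miRNA-396"),
                              provenance = "means", encoding = "ordinal")
  cv <- run_model_grid(dat, default_model_grid(), k = 3,
                       seeds = seed * 1000 + seq_len(n_cv_seeds))
  cv_out <- dplyr::select(tibble::as_tibble(unclass(cv)), "label", "family",
                          "kernel", "gamma", "C", "epsilon", "r2_mean",
                          "r2_sd")
  readr::write_csv(cv_out, file.path(out_dir, "cv_grid.csv"),
                   progress = FALSE)

  fc <- with(as.data.frame(table),
             mean_fM[treatment_label == "S4" & mirna == "miRNA-167"] /
               mean_fM[treatment_label == "Control" & mirna == "miRNA-167"])
  jsonlite::write_json(
    list(fold_change_mirna167_S4_vs_control = fc,
         fold_change_rounded = round(fc)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(r_version = R.version.string,
         package_version = as.character(utils::packageVersion("mirstress")),
         seed = seed, n_cv_seeds = n_cv_seeds, k = 3,
         payoff = unclass(config)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(ranks = ranks, cv = cv, fold_change_mirna167 = fc,
                 out_dir = out_dir))
}
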