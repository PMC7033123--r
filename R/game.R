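#' Configure the coalition payoff (characteristic function)
#'
#' A coalition of features "wins" (v(S) = 1) when it retains at least a
#' fraction `theta` of the discriminative power of the full feature set,
#' measured either by leave-one-out 1-nearest-neighbour accuracy
#' (`"loo1nn"`) or by plug-in mutual information between the
#' equal-frequency-discretized features and the class (`"mi"`). The empty
#' coalition always loses.
#'
#' @param kind `"loo1nn"` or `"mi"`.
#' @param theta Win threshold in (0, 1]: v(S) = 1 iff
#'   score(S) >= theta * score(full set).
#' @param standardize Z-score features inside the payoff (recommended:
#'   concentrations span ~100x across miRNAs and 1-NN is scale
#'   sensitive).
#' @param bins Equal-frequency bins for the `"mi"` payoff.
#' @return A `payoff_config` list.
#' @export
payoff_config <- function(kind = c("loo1nn", "mi"), theta = 0.9,
                          standardize = TRUE, bins = 3) {
  kind <- match.arg(kind)
  if (!(theta > 0 && theta <= 1)) abort("theta must be in (0, 1]")
  if (bins < 2) abort("bins must be >= 2")
  structure(list(kind = kind, theta = theta, standardize = standardize,
                 bins = as.integer(bins)),
            class = "payoff_config")
}

# ---- coalition scores ------------------------------------------------------

# z-score columns; zero-variance columns become all-zero (uninformative)
standardize_columns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

# deterministic LOO-1NN accuracy from a flattened n*n distance column
loo1nn_from_dist <- function(dvec, n, cls) {
  dm <- matrix(dvec, n, n)
  diag(dm) <- Inf
  nn <- max.col(-dm, ties.method = "first")
  mean(cls[nn] == cls)
}

# per-feature squared-difference blocks, flattened to (n*n) x p, so any
# coalition's distance matrix is one matrix product away
feature_dist_blocks <- function(Z) {
  n <- nrow(Z)
  vapply(seq_len(ncol(Z)),
         function(j) as.vector(outer(Z[, j], Z[, j], "-")^2),
         numeric(n * n))
}

# equal-frequency discretization into `bins` levels
discretize_ef <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mi_score <- function(D, cls, cols) {
  if (length(cols) == 0) return(0)
  cell <- do.call(paste, c(as.data.frame(D[, cols, drop = FALSE]),
                           sep = "\r"))
  h_c <- entropy_counts(table(cls))
  h_s <- entropy_counts(table(cell))
  h_sc <- entropy_counts(table(paste(cell, cls, sep = "\v")))
  h_c + h_s - h_sc
}

# raw (unthresholded) score of every coalition, indexed by bitmask + 1
coalition_scores <- function(X, cls, config) {
  p <- ncol(X)
  n <- nrow(X)
  n_coal <- 2^p
  masks <- 0:(n_coal - 1)
  member <- vapply(seq_len(p),
                   function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L,
                   logical(n_coal))
  scores <- numeric(n_coal)
  if (config$kind == "loo1nn") {
    Z <- if (config$standardize) standardize_columns(X) else X
    blocks <- feature_dist_blocks(Z)
    dist_all <- blocks %*% t(member * 1)
    for (m in masks[-1]) {
      scores[m + 1] <- loo1nn_from_dist(dist_all[, m + 1], n, cls)
    }
  } else {
    D <- vapply(seq_len(p), function(j) discretize_ef(X[, j], config$bins),
                integer(n))
    for (m in masks[-1]) {
      scores[m + 1] <- mi_score(D, cls, which(member[m + 1, ]))
    }
  }
  scores
}

#' Coalition payoff v(S)
#'
#' Binary characteristic function over feature coalitions: 1 if the
#' coalition wins under `config`, 0 if it loses. The empty coalition
#' loses by definition.
#'
#' @param data A `stress_dataset` (needs `class_label` and feature
#'   columns).
#' @param coalition Character vector of feature names, or integer indices
#'   into the dataset's feature order.
#' @param config A [payoff_config()].
#' @return 0 or 1.
#' @export
coalition_payoff <- function(data, coalition, config = payoff_config()) {
  feats <- attr(data, "features")
  cls <- validate_game_data(data)
  if (is.character(coalition)) {
    bad <- setdiff(coalition, feats)
    if (length(bad) > 0) abort(paste0("unknown feature(s): ",
                                      paste(bad, collapse = ", ")))
    coalition <- match(coalition, feats)
  }
  if (length(coalition) == 0) return(0L)
  X <- feature_matrix(data)
  score_S <- coalition_score_single(X, cls, as.integer(coalition), config)
  score_N <- coalition_score_single(X, cls, seq_len(ncol(X)), config)
  as.integer(score_S >= config$theta * score_N)
}

coalition_score_single <- function(X, cls, cols, config) {
  if (config$kind == "loo1nn") {
    Z <- if (config$standardize) standardize_columns(X) else X
    Zs <- Z[, cols, drop = FALSE]
    dvec <- rowSums(feature_dist_blocks(Zs))
    loo1nn_from_dist(dvec, nrow(X), cls)
  } else {
    D <- vapply(seq_len(ncol(X)),
                function(j) discretize_ef(X[, j], config$bins),
                integer(nrow(X)))
    mi_score(D, cls, cols)
  }
}

validate_game_data <- function(data) {
  if (is.null(attr(data, "features"))) {
    abort("data must be a stress_dataset with a `features` attribute")
  }
  if (nrow(data) == 0) abort("empty dataset")
  cls <- data$class_label
  if (length(unique(cls)) < 2) abort("dataset must contain >= 2 classes")
  cls
}

# ---- Banzhaf engine (abstract games) ---------------------------------------

#' Exhaustive normalized Banzhaf index of an arbitrary simple game
#'
#' Enumerates all 2^n coalitions once, counts each player's swings
#' (coalitions S not containing i with v(S) = 0 and v(S + i) = 1) and
#' normalizes by the total swing count.
#'
#' @param n_players Number of players (<= 20).
#' @param payoff_fn Function taking an integer vector of player indices
#'   (possibly empty) and returning 0 or 1. The empty coalition is forced
#'   to 0 regardless.
#' @param player_names Optional player labels.
#' @return A `banzhaf_result` tibble with columns `player`, `swings`,
#'   `index`, `rank`, and attributes `total_swings` and `n_players`.
#'   Ranks are decreasing in `index`, ties broken by player order.
#' @examples
#' # dictator: player 1 wins alone
#' banzhaf_game(3, function(S) as.integer(1 %in% S))
#' @export
banzhaf_game <- function(n_players, payoff_fn, player_names = NULL) {
  if (n_players > 20) abort("exhaustive enumeration limited to 20 players")
  masks <- 0:(2^n_players - 1)
  v <- vapply(masks, function(m) {
    if (m == 0) return(0L)
    as.integer(payoff_fn(which(bitwAnd(m, bitwShiftL(1L, 0:(n_players - 1))) > 0)))
  }, integer(1))
  banzhaf_from_values(v, n_players, player_names)
}

banzhaf_from_values <- function(v, p, player_names = NULL) {
  masks <- 0:(2^p - 1)
  swings <- vapply(seq_len(p), function(i) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    sum(v[without + bit + 1] == 1L & v[without + 1] == 0L)
  }, numeric(1))
  total <- sum(swings)
  if (total == 0) {
    abort(paste("degenerate game: no player is ever a swing (total swings",
                "= 0). With a data payoff, lower `theta` so that some",
                "coalitions lose and others win."))
  }
  new_banzhaf_result(swings, total, player_names %||% paste0("p", seq_len(p)))
}

new_banzhaf_result <- function(swings, total, players, estimated = FALSE) {
  b <- swings / total
  ord <- order(-b, seq_along(b))
  rk <- integer(length(b))
  rk[ord] <- seq_along(b)
  out <- tibble::tibble(player = players, swings = swings, index = b,
                        rank = rk)
  attr(out, "total_swings") <- total
  attr(out, "estimated") <- estimated
  class(out) <- c("banzhaf_result", class(out))
  out
}

#' Monte-Carlo Banzhaf index of an arbitrary simple game
#'
#' Estimates each player's raw swing probability by sampling coalitions
#' uniformly at random (each draw probes every player), then normalizes
#' across players. Converges to [banzhaf_game()] as draws grow; payoffs
#' are memoized so no coalition is evaluated twice.
#'
#' @inheritParams banzhaf_game
#' @param n_draws Number of sampled coalitions (>= 1).
#' @param seed Integer RNG seed.
#' @return A `banzhaf_result` tibble (swings are draw counts here, not
#'   exhaustive counts).
#' @export
banzhaf_game_mc <- function(n_players, payoff_fn, n_draws, seed = 1,
                            player_names = NULL) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  draws <- withr::with_seed(as.integer(seed), {
    if (n_players <= 25) {
      sample.int(2^n_players, n_draws, replace = TRUE) - 1
    } else {
      abort("monte-carlo sampler limited to 25 players")
    }
  })
  memo <- new.env(hash = TRUE, parent = emptyenv())
  v_of <- function(m) {
    key <- as.character(m)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (m == 0) 0L else {
      as.integer(payoff_fn(
        which(bitwAnd(m, bitwShiftL(1L, 0:(n_players - 1))) > 0)))
    }
    memo[[key]] <- val
    val
  }
  swings <- numeric(n_players)
  for (i in seq_len(n_players)) {
    bit <- bitwShiftL(1L, i - 1L)
    s_without <- bitwAnd(draws, bitwNot(bit))
    s_with <- bitwOr(s_without, bit)
    um <- unique(c(s_without, s_with))
    vals <- vapply(um, v_of, integer(1))
    lut <- setNames(vals, as.character(um))
    swings[i] <- sum(lut[as.character(s_with)] == 1L &
                       lut[as.character(s_without)] == 0L)
  }
  if (sum(swings) == 0) {
    abort("degenerate game: no sampled coalition produced a swing")
  }
  new_banzhaf_result(swings, sum(swings),
                     player_names %||% paste0("p", seq_len(n_players)),
                     estimated = TRUE)
}

# ---- data-facing wrappers --------------------------------------------------

#' Banzhaf power indices of the features of a stress dataset
#'
#' Treats the dataset's features (miRNAs) as players of a simple game
#' whose characteristic function is the thresholded discrimination score
#' of [payoff_config()], enumerates all coalitions exhaustively, and
#' returns normalized Banzhaf indices and ranks.
#'
#' @param data A `stress_dataset` with >= 2 classes.
#' @param config A [payoff_config()].
#' @return A `banzhaf_result` tibble, one row per feature.
#' @examples
#' d <- planted_signal_dataset(5, 3, 4, informative = 2,
#'                             class_separation = 10, seed = 7)
#' banzhaf_indices(d)
#' @export
banzhaf_indices <- function(data, config = payoff_config()) {
  cls <- validate_game_data(data)
  feats <- attr(data, "features")
  if (length(feats) > 20) abort("exhaustive enumeration limited to 20 features")
  X <- feature_matrix(data)
  scores <- coalition_scores(X, cls, config)
  full <- scores[length(scores)]
  v <- as.integer(scores >= config$theta * full)
  v[1] <- 0L
  res <- banzhaf_from_values(v, ncol(X), feats)
  attr(res, "config") <- config
  res
}

#' Monte-Carlo Banzhaf indices of a stress dataset
#'
#' Sampling-based counterpart of [banzhaf_indices()] for feature sets too
#' large to enumerate.
#'
#' @inheritParams banzhaf_indices
#' @param n_draws Number of coalitions to sample.
#' @param seed Integer RNG seed.
#' @return A `banzhaf_result` tibble.
#' @export
banzhaf_monte_carlo <- function(data, config = payoff_config(), n_draws,
                                seed = 1) {
  cls <- validate_game_data(data)
  feats <- attr(data, "features")
  X <- feature_matrix(data)
  full <- coalition_score_single(X, cls, seq_len(ncol(X)), config)
  pay <- function(S) {
    as.integer(coalition_score_single(X, cls, S, config) >=
                 config$theta * full)
  }
  res <- banzhaf_game_mc(length(feats), pay, n_draws, seed,
                         player_names = feats)
  attr(res, "config") <- config
  res
}

#' Rank every miRNA's contribution to each stress
#'
#' For each of the four stresses, builds the per-stress dataset (the four
#' severity levels plus the shared control), runs the exhaustive Banzhaf
#' ranking, and assembles the 11 miRNA x 4 stress rank matrix, the top-5
#' miRNAs per stress, and the consensus top-3 across stresses (smallest
#' mean rank, ties broken by table column order).
#'
#' The default pairs the information-theoretic (`"mi"`) payoff with the
#' mean-level database: each per-stress game then has 5 samples in 5
#' severity classes, where a leave-one-out accuracy payoff would be
#' degenerate (every class a singleton) but discretized mutual
#' information is well defined, and the whole rank table is
#' deterministic. The LOO-1NN payoff on synthetic replicates
#' (`payoff_config("loo1nn")`, `provenance = "replicates"`) is the
#' supported alternative.
#'
#' @param table An `expression_table`.
#' @param config A [payoff_config()].
#' @param provenance `"means"` (default: 5 samples per game) or
#'   `"replicates"` (`n_replicates` synthetic replicates per treatment,
#'   25 samples per game by default).
#' @param n_replicates,seed Replicate draws per treatment and RNG seed
#'   when `provenance = "replicates"`.
#' @return A `banzhaf_ranks` object: a tibble with column `mirna` and one
#'   integer rank column per stress (rank 1 = most important), with
#'   attributes `indices` (long tibble of per-stress swings/indices),
#'   `top5` (list per stress) and `consensus_top3`.
#' @export
rank_all_stresses <- function(table, config = payoff_config("mi"),
                              provenance = c("means", "replicates"),
                              n_replicates = 5, seed = 1) {
  provenance <- match.arg(provenance)
  per_stress <- purrr::map(stress_names, function(st) {
    d <- build_stress_dataset(table, scope = st, provenance = provenance,
                              n_replicates = n_replicates, seed = seed)
    res <- banzhaf_indices(d, config)
    dplyr::mutate(tibble::as_tibble(res), stress = st, .before = 1)
  })
  long <- dplyr::bind_rows(per_stress)
  ranks <- tidyr::pivot_wider(long[c("stress", "player", "rank")],
                              names_from = "stress", values_from = "rank")
  names(ranks)[1] <- "mirna"
  ranks <- ranks[match(mirna_names, ranks$mirna), ]
  top5 <- purrr::map(setNames(stress_names, stress_names), function(st) {
    sub <- long[long$stress == st, ]
    sub$player[order(sub$rank)][1:5]
  })
  mean_rank <- rowMeans(as.matrix(ranks[stress_names]))
  consensus <- ranks$mirna[order(mean_rank, seq_along(mean_rank))][1:3]
  attr(ranks, "indices") <- long
  attr(ranks, "top5") <- top5
  attr(ranks, "consensus_top3") <- consensus
  attr(ranks, "config") <- config
  attr(ranks, "provenance") <- provenance
  attr(ranks, "seed") <- seed
  class(ranks) <- c("banzhaf_ranks", class(ranks))
  ranks
}

#' @export
print.banzhaf_ranks <- function(x, ...) {
  cat("miRNA importance ranks per stress (1 = most important)\n")
  print(tibble::as_tibble(unclass(x)), n = nrow(x))
  cat("\nConsensus top-3 across stresses:",
      paste(attr(x, "consensus_top3"), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy mirstress result objects
#'
#' Broom-style accessors: a `banzhaf_result` tidies to its
#' player/swings/index/rank tibble, a `banzhaf_ranks` object to the long
#' per-stress score table, a `cv_grid` to one row per (configuration,
#' fold seed), and a fitted model to its coefficients or parameters.
#'
#' @param x A `banzhaf_result`, `banzhaf_ranks`, `cv_grid` or
#'   `mirstress_model` object.
#' @param ... Unused.
#' @return A tibble.
#' @name mirstress-tidiers
NULL

#' @rdname mirstress-tidiers
#' @exportS3Method generics::tidy
tidy.banzhaf_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname mirstress-tidiers
#' @exportS3Method generics::tidy
tidy.banzhaf_ranks <- function(x, ...) {
  attr(x, "indices")
}
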