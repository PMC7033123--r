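test_that("dictator, majority and constant games match hand enumeration", {
  dict <- banzhaf_game(3, function(S) as.integer(1 %in% S))
  expect_equal(dict$swings, c(4, 0, 0))
  expect_equal(dict$index, c(1, 0, 0))
  expect_equal(dict$rank, 1:3)

  # majority of 3: each player swings in exactly two coalitions
  maj <- banzhaf_game(3, function(S) as.integer(length(S) >= 2))
  expect_equal(maj$index, rep(1 / 3, 3))
  expect_equal(attr(maj, "total_swings"), 6)

  expect_error(banzhaf_game(3, function(S) 0L), "degenerate")
})

test_that("Banzhaf axioms hold on enumerated 3-5 player games", {
  # weighted voting [q; w]: v(S) = 1 iff sum(w[S]) >= q
  wvg <- function(w, q) function(S) as.integer(sum(w[S]) >= q)

  # dummy player: weight 0 never swings
  r <- banzhaf_game(4, wvg(c(3, 2, 2, 0), 4))
  expect_equal(r$index[4], 0)

  # symmetry: equal weights get equal indices
  r5 <- banzhaf_game(5, wvg(c(4, 2, 2, 2, 1), 6))
  expect_equal(r5$index[2], r5$index[3])
  expect_equal(r5$index[3], r5$index[4])

  # normalization across a family of random seeded games
  for (seed in 1:10) {
    w <- withr::with_seed(seed, sample(0:5, 4, replace = TRUE))
    q <- max(1, floor(sum(w) / 2) + 1)
    res <- tryCatch(banzhaf_game(4, wvg(w, q)), error = function(e) NULL)
    if (!is.null(res)) {
      expect_equal(sum(res$index), 1)
      expect_true(all(res$index >= 0))
    }
  }
})

test_that("Monte-Carlo indices agree with exhaustive enumeration", {
  maj <- function(S) as.integer(length(S) >= 2)
  mc <- banzhaf_game_mc(3, maj, n_draws = 1e5, seed = 8)
  expect_true(all(abs(mc$index - 1 / 3) < 0.02))

  # a lopsided 6-player weighted game
  w <- c(5, 4, 3, 2, 1, 1)
  g <- function(S) as.integer(sum(w[S]) >= 9)
  exact <- banzhaf_game(6, g)
  est <- banzhaf_game_mc(6, g, n_draws = 4e4, seed = 8)
  expect_true(all(abs(est$index - exact$index) < 0.03))

  # seeded determinism
  est2 <- banzhaf_game_mc(6, g, n_draws = 4e4, seed = 8)
  expect_identical(est$index, est2$index)
})

test_that("coalition payoff follows the relative-accuracy win rule", {
  d <- planted_signal_dataset(5, 5, 6, informative = 2,
                              class_separation = 10, seed = 4)
  cfg <- payoff_config("loo1nn", theta = 0.9)
  expect_equal(coalition_payoff(d, character(0), cfg), 0L)
  expect_equal(coalition_payoff(d, "f2", cfg), 1L)
  # a pure-noise singleton cannot match the full set at theta = 0.9
  expect_equal(coalition_payoff(d, "f1", cfg), 0L)
  # vacuous threshold: any non-empty coalition wins
  cfg_lo <- payoff_config("loo1nn", theta = 1e-9)
  expect_equal(coalition_payoff(d, "f1", cfg_lo), 1L)
})

test_that("planted informative features earn rank 1 in their own game", {
  for (j in c(2, 5, 6)) {
    d <- planted_signal_dataset(5, 4, 6, informative = j,
                                class_separation = 10, seed = 30 + j)
    res <- banzhaf_indices(d, payoff_config("loo1nn"))
    expect_equal(res$player[res$rank == 1], paste0("f", j))
    expect_equal(sum(res$index), 1)
  }
})

test_that("label shuffling destroys planted-feature recoverability", {
  top_after_shuffle <- vapply(1:8, function(s) {
    d <- planted_signal_dataset(5, 4, 6, informative = 2,
                                class_separation = 10, seed = 77)
    d$class_label <- withr::with_seed(s, sample(d$class_label))
    res <- tryCatch(banzhaf_indices(d, payoff_config("loo1nn")),
                    error = function(e) NULL)
    if (is.null(res)) NA_character_ else res$player[res$rank == 1]
  }, character(1))
  expect_lt(mean(top_after_shuffle == "f2", na.rm = TRUE), 0.5)
})

test_that("identical feature columns share the index; rank ties follow column order", {
  d <- planted_signal_dataset(5, 4, 5, informative = 2,
                              class_separation = 8, seed = 12)
  df <- as.data.frame(d)
  df$f3 <- df$f2  # duplicate the informative column
  dup <- mirstress:::new_stress_dataset(
    tibble::as_tibble(df), features = paste0("f", 1:5),
    encoding = "ordinal", provenance = "synthetic", scope = "synthetic")
  res <- banzhaf_indices(dup, payoff_config("loo1nn"))
  b <- setNames(res$index, res$player)
  r <- setNames(res$rank, res$player)
  expect_equal(unname(b["f2"]), unname(b["f3"]))
  expect_lt(r["f2"], r["f3"])
})

test_that("monte-carlo and exhaustive data games agree", {
  d <- planted_signal_dataset(5, 4, 6, informative = c(2, 4),
                              class_separation = 6, seed = 19)
  cfg <- payoff_config("loo1nn")
  exact <- banzhaf_indices(d, cfg)
  est <- banzhaf_monte_carlo(d, cfg, n_draws = 3e4, seed = 5)
  expect_true(all(abs(est$index - exact$index) < 0.03))
})

test_that("the MI payoff scores informative features above noise", {
  d <- planted_signal_dataset(10, 3, 4, informative = 3,
                              class_separation = 6, seed = 23)
  res <- banzhaf_indices(d, payoff_config("mi", bins = 3))
  expect_equal(res$player[res$rank == 1], "f3")
})

test_that("degenerate data games raise rather than fabricate ranks", {
  d <- planted_signal_dataset(20, 2, 3, informative = integer(0),
                              class_separation = 0, seed = 2)
  # theta so low every non-empty coalition wins: only 3 singleton swings
  # exist, which is fine; instead force all-lose by impossible threshold
  # via a dataset with a single class -> validation error
  d1 <- d
  d1$class_label <- 0L
  expect_error(banzhaf_indices(d1, payoff_config("loo1nn")), "2 classes")
})
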