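# ---- LSSVM ----------------------------------------------------------------

test_that("LSSVM agrees with the kernel-ridge closed form", {
  df <- toy_regression_df(10, seed = 5)
  for (kind in c("linear", "gaussian", "sigmoid")) {
    spec <- kernel_spec(kind, 0.3)
    m <- fit_lssvm(df, spec, C = 7, scale = FALSE,
                   features = c("x1", "x2"))
    K <- kernel_matrix(spec, as.matrix(df[c("x1", "x2")]))
    oracle <- krr_oracle(K, df$y, C = 7)
    expect_lt(max(abs(m$fit$alpha - oracle$alpha)), 1e-6)
    expect_lt(abs(m$fit$b - oracle$b), 1e-6)
  }
})

test_that("LSSVM limits: single point, exact linear data, interpolation", {
  df <- toy_regression_df(12, seed = 42)
  one <- df[1, ]
  m1 <- fit_lssvm(one, kernel_spec("gaussian", 0.05), C = 10,
                  features = c("x1", "x2"))
  expect_equal(unname(predict(m1, df)), rep(one$y, nrow(df)))

  lin <- data.frame(x1 = seq(-2, 2, length.out = 9))
  lin$y <- 2 * lin$x1
  ml <- fit_lssvm(lin, kernel_spec("linear", 1), C = 1e6, features = "x1")
  expect_lt(max(abs(predict(ml, lin) - lin$y)), 1e-4)

  mg <- fit_lssvm(df, kernel_spec("gaussian", 0.5), C = 1e8,
                  features = c("x1", "x2"))
  expect_lt(max(abs(predict(mg, df) - df$y)), 1e-3)
})

# ---- epsilon-SVR ------------------------------------------------------------

test_that("SVR dual matches the exhaustive QP oracle on 4-point toys", {
  toys <- list(
    list(x = c(-1.2, -0.3, 0.4, 1.5), y = c(-2.1, -0.2, 0.9, 2.8)),
    list(x = c(0.1, 0.8, 1.7, 2.2), y = c(1.0, 0.2, -0.5, 2.0))
  )
  for (toy in toys) {
    df <- data.frame(x1 = toy$x, y = toy$y)
    spec <- kernel_spec("linear", 1)
    m <- fit_svr(df, spec, C = 2, epsilon = 0.15, scale = FALSE,
                 features = "x1", tol = 1e-12)
    K <- kernel_matrix(spec, as.matrix(df["x1"]))
    oracle <- svr_enum_oracle(K, df$y, C = 2, eps = 0.15)
    grid_x <- data.frame(x1 = seq(-2, 3, length.out = 11))
    Kg <- kernel_matrix(spec, as.matrix(grid_x), as.matrix(df["x1"]))
    pred_oracle <- drop(Kg %*% oracle$theta) + oracle$b
    expect_lt(max(abs(predict(m, grid_x) - pred_oracle)), 1e-6)
  }
})

test_that("SVR agrees with an independent SMO implementation (libsvm)", {
  skip_if_not_installed("e1071")
  df <- toy_regression_df(14, seed = 7)
  m <- fit_svr(df, kernel_spec("gaussian", 0.4), C = 5, epsilon = 0.1,
               scale = FALSE, features = c("x1", "x2"), tol = 1e-10)
  e <- e1071::svm(y ~ x1 + x2, df, type = "eps-regression",
                  kernel = "radial", gamma = 0.4, cost = 5, epsilon = 0.1,
                  scale = FALSE, tolerance = 1e-8)
  expect_lt(max(abs(predict(m, df) - predict(e, df))), 1e-4)
})

test_that("SVR invariances: constant target, sample order, duplication", {
  df <- toy_regression_df(10, seed = 3)
  dc <- df
  dc$y <- 3
  mc <- fit_svr(dc, kernel_spec("linear", 0.5), C = 10, epsilon = 0.1,
                features = c("x1", "x2"))
  expect_true(all(abs(predict(mc, dc) - 3) <= 0.1 + 1e-8))

  m <- fit_svr(df, kernel_spec("gaussian", 0.4), C = 5, epsilon = 0.1,
               features = c("x1", "x2"), tol = 1e-10)
  perm <- withr::with_seed(2, sample(nrow(df)))
  mp <- fit_svr(df[perm, ], kernel_spec("gaussian", 0.4), C = 5,
                epsilon = 0.1, features = c("x1", "x2"), tol = 1e-10)
  expect_lt(max(abs(predict(m, df) - predict(mp, df))), 1e-6)

  # with an interpolant inside the tube the optimum has zero loss, so
  # duplicating every sample leaves the solution unchanged
  lin <- data.frame(x1 = seq(-2, 2, length.out = 8))
  lin$y <- 2 * lin$x1
  m1 <- fit_svr(lin, kernel_spec("linear", 1), C = 10, epsilon = 0.2,
                scale = FALSE, features = "x1", tol = 1e-12)
  m2 <- fit_svr(rbind(lin, lin), kernel_spec("linear", 1), C = 10,
                epsilon = 0.2, scale = FALSE, features = "x1", tol = 1e-12)
  expect_lt(max(abs(predict(m1, lin) - predict(m2, lin))), 1e-6)
})

# ---- CART -------------------------------------------------------------------

test_that("CART splits match exhaustive search on step data", {
  ds <- data.frame(x1 = c(1, 2, 3, 4, 6, 7, 8, 9),
                   y = c(0, 0, 0, 0, 9, 9, 9, 9))
  m <- fit_cart(ds, min_leaf = 1, response = "y", features = "x1")
  expect_equal(unname(predict(m, ds)), ds$y)
  # two leaves: root plus two children
  expect_equal(nrow(m$fit$tree$frame), 3)

  const <- data.frame(x1 = 1:6, y = 2)
  mc <- fit_cart(const, min_leaf = 1, response = "y", features = "x1")
  expect_equal(nrow(mc$fit$tree$frame), 1)
  expect_equal(unname(predict(mc, const)), rep(2, 6))

  single <- data.frame(x1 = 1, y = 5)
  ms <- fit_cart(single, min_leaf = 1, response = "y", features = "x1")
  expect_equal(unname(predict(ms, single)), 5)
})

test_that("CART training error is non-increasing in depth", {
  df <- toy_regression_df(40, seed = 11)
  sse <- vapply(1:5, function(d) {
    m <- fit_cart(df, min_leaf = 1, max_depth = d, response = "y",
                  features = c("x1", "x2"))
    sum((predict(m, df) - df$y)^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-10))
})

# ---- Naive Bayes ------------------------------------------------------------

test_that("NB posterior picks the dominant class and maps to levels", {
  dn <- withr::with_seed(1, data.frame(
    f1 = c(rnorm(10, -10), rnorm(10, 10)),
    class_label = rep(0:1, each = 10)))
  dn$y <- dn$class_label * 3  # levels 0 and 3
  m <- fit_nb(dn, features = "f1")
  expect_equal(predict(m, data.frame(f1 = 10)), 3)
  expect_equal(predict(m, data.frame(f1 = -10)), 0)
  expect_equal(predict(m, data.frame(f1 = 10), type = "class"), "1")

  # single class: degenerate posterior
  d1 <- dn[dn$class_label == 0, ]
  m1 <- fit_nb(d1, features = "f1")
  expect_equal(predict(m1, data.frame(f1 = c(-10, 10))), c(0, 0))

  # exact posterior tie goes to the lowest class index
  dt <- data.frame(f1 = c(-1, 1, -1, 1), class_label = c(0, 0, 1, 1),
                   y = c(0, 0, 1, 1))
  mt <- fit_nb(dt, features = "f1", scale = FALSE)
  expect_equal(predict(mt, data.frame(f1 = 0), type = "class"), "0")
})

test_that("NB matches an independent implementation on separable data", {
  skip_if_not_installed("e1071")
  dn <- withr::with_seed(2, data.frame(
    f1 = c(rnorm(15, -3), rnorm(15, 3)),
    f2 = c(rnorm(15, 1), rnorm(15, -1)),
    class_label = rep(0:1, each = 15)))
  dn$y <- dn$class_label
  m <- fit_nb(dn, features = c("f1", "f2"), scale = FALSE)
  e <- e1071::naiveBayes(factor(class_label) ~ f1 + f2, dn)
  grid <- expand.grid(f1 = seq(-4, 4, 1), f2 = seq(-2, 2, 1))
  expect_equal(predict(m, grid, type = "class"),
               as.character(predict(e, grid)))
})

test_that("zero-variance class features are floored with a warning", {
  d <- data.frame(f1 = c(1, 1, 2, 3), class_label = c(0, 0, 1, 1),
                  y = c(0, 0, 1, 1))
  expect_warning(fit_nb(d, features = "f1", scale = FALSE), "floored")
})

# ---- shared contract --------------------------------------------------------

test_that("affine feature transforms are absorbed by standardization", {
  df <- toy_regression_df(15, seed = 9)
  shifted <- df
  shifted$x1 <- df$x1 * 100 + 7
  shifted$x2 <- df$x2 * 0.01 - 3
  newd <- toy_regression_df(5, seed = 10)
  news <- newd
  news$x1 <- newd$x1 * 100 + 7
  news$x2 <- newd$x2 * 0.01 - 3

  fits <- list(
    function(d) fit_lssvm(d, kernel_spec("gaussian", 0.3), C = 5,
                          features = c("x1", "x2")),
    function(d) fit_svr(d, kernel_spec("gaussian", 0.3), C = 5,
                        epsilon = 0.1, features = c("x1", "x2"),
                        tol = 1e-10),
    function(d) fit_cart(d, min_leaf = 2, features = c("x1", "x2"))
  )
  for (f in fits) {
    p0 <- predict(f(df), newd)
    p1 <- predict(f(shifted), news)
    expect_lt(max(abs(p0 - p1)), 1e-6)
  }
})

test_that("tidy and glance expose coefficients and settings", {
  df <- toy_regression_df(8, seed = 1)
  m <- fit_svr(df, kernel_spec("gaussian", 0.05), C = 10, epsilon = 0.1,
               features = c("x1", "x2"))
  td <- tidy(m)
  expect_equal(nrow(td), 9)  # 8 coefficients + bias
  g <- glance(m)
  expect_equal(g$family, "svr")
  expect_equal(g$gamma, 0.05)
})
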