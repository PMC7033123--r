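# Regression learners behind one fit/predict contract. All exported
# fitters take a data frame first (a stress_dataset or any data frame
# with a numeric response column and numeric feature columns) and return
# a "mirstress_model"; predict() accepts a data frame with the same
# feature columns. Features (and, for the kernel machines, the target)
# are z-scored with training statistics; predictions are returned on the
# original scale.

resolve_xy <- function(data, response, features) {
  features <- features %||% attr(data, "features")
  if (is.null(features)) {
    num <- vapply(data, is.numeric, logical(1))
    features <- setdiff(names(data)[num],
                        c(response, "class_label", "y", "replicate_id",
                          "level_index", "level_value"))
  }
  if (length(features) == 0) abort("no feature columns found")
  if (!response %in% names(data)) {
    abort(paste0("response column `", response, "` not found"))
  }
  X <- feature_matrix(data, features)
  y <- as.numeric(data[[response]])
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("non-finite values in features or response")
  }
  list(X = X, y = y, features = features)
}

col_scaling <- function(X, scale) {
  if (!scale) {
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = colMeans(X), scale = s)
}

apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")
}

y_scaling <- function(y, scale) {
  if (!scale) return(list(center = 0, scale = 1))
  s <- if (length(y) > 1) sd(y) else 0
  if (!is.finite(s) || s == 0) s <- 1
  list(center = mean(y), scale = s)
}

new_mirstress_model <- function(family, fit, features, x_scaling, y_scaling,
                                hyper, subclass) {
  structure(list(family = family, fit = fit, features = features,
                 x_scaling = x_scaling, y_scaling = y_scaling,
                 hyper = hyper),
            class = c(subclass, "mirstress_model"))
}

#' @export
print.mirstress_model <- function(x, ...) {
  hp <- paste(names(x$hyper), vapply(x$hyper, function(h) {
    if (inherits(h, "kernel_spec")) paste0(h$kind, "(gamma=", h$gamma, ")")
    else paste(format(h), collapse = ",")
  }, character(1)), sep = "=", collapse = ", ")
  cat(sprintf("<mirstress %s model: %d features; %s>\n",
              x$family, length(x$features), hp))
  invisible(x)
}

new_data_matrix <- function(object, new_data) {
  X <- if (is.matrix(new_data)) new_data
       else as.matrix(as.data.frame(new_data)[, object$features,
                                              drop = FALSE])
  apply_scaling(X, object$x_scaling)
}

# ---- least-squares SVM -----------------------------------------------------

#' Fit a least-squares support vector machine regressor
#'
#' Solves the LSSVM saddle-point system
#' `[[0, 1'], [1, K + I/C]] [b; alpha] = [0; y]` by a dense linear solve
#' (equivalent to kernel ridge regression with ridge 1/C plus an
#' unpenalized intercept). Predictions are the kernel expansion
#' `sum_i alpha_i k(x_i, x) + b`.
#'
#' @param data Data frame with a numeric response and feature columns.
#' @param kernel A [kernel_spec()].
#' @param C Regularization weight (> 0); larger values interpolate the
#'   training data more closely.
#' @param response Name of the response column.
#' @param features Feature column names; defaults to the dataset's
#'   feature attribute, else all numeric non-metadata columns.
#' @param scale Z-score features and response with training statistics.
#' @return A `mirstress_model` of family `"lssvm"`.
#' @export
fit_lssvm <- function(data, kernel = kernel_spec("gaussian", 0.05), C = 10,
                      response = "y", features = NULL, scale = TRUE) {
  if (C <= 0) abort("C must be > 0")
  xy <- resolve_xy(data, response, features)
  xs <- col_scaling(xy$X, scale); ys <- y_scaling(xy$y, scale)
  Z <- apply_scaling(xy$X, xs)
  yz <- (xy$y - ys$center) / ys$scale
  n <- nrow(Z)
  K <- kernel_matrix(kernel, Z)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-14) {
    abort(sprintf(
      "singular LSSVM system (reciprocal condition number %.3e)", rc))
  }
  sol <- solve(A, c(0, yz))
  fit <- list(alpha = sol[-1], b = sol[1], Z = Z, kernel = kernel)
  new_mirstress_model("lssvm", fit, xy$features, xs, ys,
                      list(kernel = kernel, C = C), "lssvm_model")
}

#' @export
predict.lssvm_model <- function(object, new_data, ...) {
  Zn <- new_data_matrix(object, new_data)
  Kn <- kernel_matrix(object$fit$kernel, Zn, object$fit$Z)
  f <- drop(Kn %*% object$fit$alpha) + object$fit$b
  f * object$y_scaling$scale + object$y_scaling$center
}

# ---- epsilon-SVR (SMO on the convex dual) ---------------------------------

# Sequential minimal optimization for the epsilon-insensitive dual:
# minimize 1/2 b' Qb b + p' b over b = (alpha, alpha*) in [0, C]^{2n}
# with z' b = 0, z = (+1...,-1...), Qb = (z z') . K~. Standard maximal-
# violating-pair selection; returns theta = alpha - alpha* and the bias.
smo_svr <- function(K, y, C, eps, tol = 1e-8, max_iter = 200000L) {
  n <- length(y)
  z <- c(rep(1, n), rep(-1, n))
  idx <- c(seq_len(n), seq_len(n))
  p <- c(eps - y, eps + y)
  beta <- numeric(2 * n)
  G <- p  # gradient of the dual objective at beta = 0
  Qcol <- function(s) z[s] * z * K[idx, idx[s]]
  tau <- 1e-12
  it <- 0L
  gap <- 0
  repeat {
    it <- it + 1L
    nzG <- -z * G
    up <- (z > 0 & beta < C - 1e-15) | (z < 0 & beta > 1e-15)
    low <- (z > 0 & beta > 1e-15) | (z < 0 & beta < C - 1e-15)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(nzG[up])]
    j <- which(low)[which.min(nzG[low])]
    gap <- nzG[i] - nzG[j]
    if (gap < tol) break
    if (it > max_iter) {
      warn(sprintf(
        "SVR solver stopped after %d iterations (KKT gap %.3e > tol %.1e)",
        max_iter, gap, tol))
      break
    }
    Qi <- Qcol(i); Qj <- Qcol(j)
    old_i <- beta[i]; old_j <- beta[j]
    if (z[i] != z[j]) {
      quad <- max(Qi[i] + Qj[j] + 2 * Qi[j], tau)
      delta <- (-G[i] - G[j]) / quad
      diff <- beta[i] - beta[j]
      beta[i] <- beta[i] + delta; beta[j] <- beta[j] + delta
      if (diff > 0) {
        if (beta[j] < 0) { beta[j] <- 0; beta[i] <- diff }
      } else {
        if (beta[i] < 0) { beta[i] <- 0; beta[j] <- -diff }
      }
      if (diff > 0) {
        if (beta[i] > C) { beta[i] <- C; beta[j] <- C - diff }
      } else {
        if (beta[j] > C) { beta[j] <- C; beta[i] <- C + diff }
      }
    } else {
      quad <- max(Qi[i] + Qj[j] - 2 * Qi[j], tau)
      delta <- (G[i] - G[j]) / quad
      s <- beta[i] + beta[j]
      beta[i] <- beta[i] - delta; beta[j] <- beta[j] + delta
      if (s > C) {
        if (beta[i] > C) { beta[i] <- C; beta[j] <- s - C }
      } else {
        if (beta[j] < 0) { beta[j] <- 0; beta[i] <- s }
      }
      if (s > C) {
        if (beta[j] > C) { beta[j] <- C; beta[i] <- s - C }
      } else {
        if (beta[i] < 0) { beta[i] <- 0; beta[j] <- s }
      }
    }
    G <- G + Qi * (beta[i] - old_i) + Qj * (beta[j] - old_j)
  }
  # bias from the KKT conditions (free variables; bound midpoint fallback)
  yG <- z * G
  free <- beta > 1e-15 & beta < C - 1e-15
  b <- if (any(free)) {
    -mean(yG[free])
  } else {
    ub <- suppressWarnings(min(yG[(z < 0 & beta >= C - 1e-15) |
                                    (z > 0 & beta <= 1e-15)]))
    lb <- suppressWarnings(max(yG[(z > 0 & beta >= C - 1e-15) |
                                    (z < 0 & beta <= 1e-15)]))
    -(ub + lb) / 2
  }
  theta <- beta[seq_len(n)] - beta[n + seq_len(n)]
  list(theta = theta, b = b, iterations = it, kkt_gap = max(0, gap))
}

#' Fit an epsilon-insensitive support vector regressor
#'
#' Solves the convex dual of epsilon-SVR (box constraints `[0, C]`,
#' equality constraint `sum(alpha - alpha*) = 0`) by sequential minimal
#' optimization with maximal-violating-pair selection. Predictions are
#' the kernel expansion plus bias.
#'
#' @inheritParams fit_lssvm
#' @param epsilon Half-width of the insensitive tube (>= 0), on the
#'   z-scored response scale when `scale = TRUE`.
#' @param tol KKT stopping tolerance of the dual solver.
#' @return A `mirstress_model` of family `"svr"` with solver diagnostics
#'   (`iterations`, `kkt_gap`) in `$fit`.
#' @export
fit_svr <- function(data, kernel = kernel_spec("gaussian", 0.05), C = 10,
                    epsilon = 0.1, response = "y", features = NULL,
                    scale = TRUE, tol = 1e-8) {
  if (C <= 0) abort("C must be > 0")
  if (epsilon < 0) abort("epsilon must be >= 0")
  xy <- resolve_xy(data, response, features)
  xs <- col_scaling(xy$X, scale); ys <- y_scaling(xy$y, scale)
  Z <- apply_scaling(xy$X, xs)
  yz <- (xy$y - ys$center) / ys$scale
  K <- kernel_matrix(kernel, Z)
  sol <- smo_svr(K, yz, C, epsilon, tol = tol)
  fit <- list(theta = sol$theta, b = sol$b, Z = Z, kernel = kernel,
              iterations = sol$iterations, kkt_gap = sol$kkt_gap)
  new_mirstress_model("svr", fit, xy$features, xs, ys,
                      list(kernel = kernel, C = C, epsilon = epsilon),
                      "svr_model")
}

#' @export
predict.svr_model <- function(object, new_data, ...) {
  Zn <- new_data_matrix(object, new_data)
  Kn <- kernel_matrix(object$fit$kernel, Zn, object$fit$Z)
  f <- drop(Kn %*% object$fit$theta) + object$fit$b
  f * object$y_scaling$scale + object$y_scaling$center
}

# ---- CART regression tree --------------------------------------------------

#' Fit a CART regression tree
#'
#' Greedy binary splitting by variance reduction with mean-of-leaf
#' predictions, delegated to \pkg{rpart} with pruning disabled
#' (`cp = 0`), so the tree is bounded only by `min_leaf` and
#' `max_depth`.
#'
#' @inheritParams fit_lssvm
#' @param min_leaf Minimum samples per leaf.
#' @param max_depth Maximum tree depth, or `NULL` for unbounded (rpart's
#'   limit of 30).
#' @return A `mirstress_model` of family `"cart"`.
#' @export
fit_cart <- function(data, min_leaf = 1, max_depth = NULL, response = "y",
                     features = NULL) {
  if (min_leaf < 1) abort("min_leaf must be >= 1")
  xy <- resolve_xy(data, response, features)
  df <- as.data.frame(xy$X)
  names(df) <- paste0("x", seq_along(xy$features))
  df$.y <- xy$y
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "anova",
    control = rpart::rpart.control(
      minsplit = max(2, 2 * min_leaf), minbucket = min_leaf,
      maxdepth = if (is.null(max_depth)) 30 else min(max_depth, 30),
      cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0))
  new_mirstress_model("cart", list(tree = fit), xy$features,
                      col_scaling(xy$X, FALSE), y_scaling(xy$y, FALSE),
                      list(min_leaf = min_leaf, max_depth = max_depth),
                      "cart_model")
}

#' @export
predict.cart_model <- function(object, new_data, ...) {
  Xn <- new_data_matrix(object, new_data)
  df <- as.data.frame(Xn)
  names(df) <- paste0("x", seq_along(object$features))
  unname(predict(object$fit$tree, newdata = df))
}

# ---- Gaussian Naive Bayes level predictor ----------------------------------

#' Fit a Gaussian Naive Bayes stress-level predictor
#'
#' Class-conditional Gaussian densities per feature (independence
#' assumption) with uniform-smoothed class priors
#' `(n_c + 1) / (n + K)`. Prediction picks the maximum-posterior class
#' (exact ties resolved toward the lowest class index) and maps it to a
#' numeric level via `class_to_level`, so R-squared is computable
#' alongside the regression models.
#'
#' @inheritParams fit_lssvm
#' @param class_column Name of the discrete class column.
#' @param class_to_level Named numeric vector mapping class (as
#'   character) to numeric level; defaults to the mean of `response`
#'   within each training class (the identity when the response is the
#'   class label).
#' @param var_floor Smallest admissible class-conditional variance;
#'   zero-variance features are floored here (with a warning).
#' @return A `mirstress_model` of family `"nb"`.
#' @export
fit_nb <- function(data, class_column = "class_label", response = "y",
                   features = NULL, class_to_level = NULL,
                   var_floor = 1e-6, scale = TRUE) {
  xy <- resolve_xy(data, response, features)
  cls <- as.character(data[[class_column]])
  xs <- col_scaling(xy$X, scale)
  Z <- apply_scaling(xy$X, xs)
  classes <- sort(unique(cls))
  n <- nrow(Z); K <- length(classes)
  floored <- FALSE
  params <- lapply(classes, function(cl) {
    rows <- Z[cls == cl, , drop = FALSE]
    v <- apply(rows, 2, function(col) if (length(col) > 1) var(col) else 0)
    # a singleton class has no variance to estimate; flooring it is
    # routine, but zero variance across >= 2 samples is worth reporting
    if (nrow(rows) > 1 && any(v < var_floor)) floored <<- TRUE
    list(mu = colMeans(rows), var = pmax(v, var_floor),
         log_prior = log((nrow(rows) + 1) / (n + K)))
  })
  names(params) <- classes
  if (floored) {
    warn(sprintf("zero-variance feature(s) within a class: variance floored at %g",
                 var_floor))
  }
  if (is.null(class_to_level)) {
    class_to_level <- vapply(classes,
                             function(cl) mean(xy$y[cls == cl]), numeric(1))
  }
  new_mirstress_model("nb", list(params = params, classes = classes,
                                 levels = class_to_level),
                      xy$features, xs, y_scaling(xy$y, FALSE),
                      list(var_floor = var_floor), "nb_model")
}

#' Predict with a Naive Bayes model
#'
#' @param object An `nb_model`.
#' @param new_data Data frame or matrix of features.
#' @param type `"level"` for the mapped numeric level (default),
#'   `"class"` for the class label.
#' @param ... Unused.
#' @return Numeric levels or character class labels.
#' @export
predict.nb_model <- function(object, new_data, type = c("level", "class"),
                             ...) {
  type <- match.arg(type)
  Zn <- new_data_matrix(object, new_data)
  lp <- matrix(0, nrow(Zn), length(object$fit$params))
  for (ci in seq_along(object$fit$params)) {
    pr <- object$fit$params[[ci]]
    acc <- rep(pr$log_prior, nrow(Zn))
    for (j in seq_len(ncol(Zn))) {
      acc <- acc + dnorm(Zn[, j], pr$mu[j], sqrt(pr$var[j]), log = TRUE)
    }
    lp[, ci] <- acc
  }
  pick <- apply(lp, 1, function(r) which(r >= max(r) - 1e-12)[1])
  cls <- object$fit$classes[pick]
  if (type == "class") cls else unname(object$fit$levels[cls])
}

# ---- broom-style methods ---------------------------------------------------

#' @rdname mirstress-tidiers
#' @exportS3Method generics::tidy
tidy.mirstress_model <- function(x, ...) {
  switch(x$family,
    svr = tibble::tibble(term = c(paste0("theta_", seq_along(x$fit$theta)),
                                  "bias"),
                         estimate = c(x$fit$theta, x$fit$b)),
    lssvm = tibble::tibble(term = c(paste0("alpha_", seq_along(x$fit$alpha)),
                                    "bias"),
                           estimate = c(x$fit$alpha, x$fit$b)),
    cart = {
      fr <- x$fit$tree$frame
      tibble::tibble(node = as.integer(rownames(fr)), variable = fr$var,
                     n = fr$n, value = fr$yval)
    },
    nb = dplyr::bind_rows(lapply(names(x$fit$params), function(cl) {
      pr <- x$fit$params[[cl]]
      tibble::tibble(class = cl, feature = x$features, mean = unname(pr$mu),
                     variance = unname(pr$var))
    }))
  )
}

#' One-row model summary
#'
#' @param x A `mirstress_model`.
#' @param ... Unused.
#' @return A one-row tibble with family, kernel settings and model size.
#' @exportS3Method generics::glance
glance.mirstress_model <- function(x, ...) {
  k <- x$hyper$kernel
  tibble::tibble(
    family = x$family,
    kernel = if (is.null(k)) NA_character_ else k$kind,
    gamma = if (is.null(k)) NA_real_ else k$gamma,
    C = x$hyper$C %||% NA_real_,
    epsilon = x$hyper$epsilon %||% NA_real_,
    n_features = length(x$features)
  )
}
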