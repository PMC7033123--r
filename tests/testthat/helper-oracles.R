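# Independent oracles used by the tests. They deliberately take different
# computational routes than the package implementations.

# Exact epsilon-SVR dual by exhaustive KKT-pattern enumeration (tiny n):
#   minimize 1/2 t'Kt - y't + eps*||t||_1  s.t.  sum(t) = 0, -C <= t <= C
# Every variable is assigned one of five states (at -C, negative-free, zero,
# positive-free, at C); for each pattern the equality-constrained stationary
# point is solved in closed form and checked for feasibility; the global
# optimum is the feasible candidate with the smallest objective.
svr_enum_oracle <- function(K, y, C, eps) {
  n <- length(y)
  states <- c("lo", "neg", "zero", "pos", "hi")
  grid <- expand.grid(rep(list(states), n), stringsAsFactors = FALSE)
  obj <- function(t) 0.5 * drop(t %*% K %*% t) - sum(y * t) + eps * sum(abs(t))
  best_t <- NULL
  best_obj <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- unlist(grid[r, ], use.names = FALSE)
    t <- numeric(n)
    t[st == "lo"] <- -C
    t[st == "hi"] <- C
    free <- which(st %in% c("neg", "pos"))
    sgn <- ifelse(st == "pos", 1, ifelse(st == "neg", -1, 0))
    if (length(free) == 0) {
      if (abs(sum(t)) > 1e-9) next
    } else {
      fixed <- setdiff(seq_len(n), free)
      lin <- y[free] - eps * sgn[free]
      if (length(fixed) > 0) {
        lin <- lin - drop(K[free, fixed, drop = FALSE] %*% t[fixed])
      }
      A <- rbind(cbind(K[free, free, drop = FALSE], 1),
                 c(rep(1, length(free)), 0))
      sol <- tryCatch(solve(A, c(lin, -sum(t))), error = function(e) NULL)
      if (is.null(sol)) next
      tf <- sol[seq_along(free)]
      tol <- 1e-9
      ok <- all(ifelse(sgn[free] > 0, tf >= -tol & tf <= C + tol,
                       tf <= tol & tf >= -C - tol))
      if (!ok) next
      t[free] <- tf
    }
    o <- obj(t)
    if (o < best_obj - 1e-12) {
      best_obj <- o
      best_t <- t
    }
  }
  # bias from the primal KKT interval: every sample constrains b from
  # below and/or above depending on its dual state; midpoint of the
  # admissible interval (degenerate when free support vectors exist)
  f0 <- drop(K %*% best_t)
  tol <- 1e-7
  lo <- -Inf
  hi <- Inf
  for (i in seq_len(n)) {
    ti <- best_t[i]
    if (ti <= -C + tol) {
      lo <- max(lo, y[i] - f0[i] + eps)
    } else if (ti < -tol) {
      lo <- max(lo, y[i] - f0[i] + eps)
      hi <- min(hi, y[i] - f0[i] + eps)
    } else if (ti < tol) {
      lo <- max(lo, y[i] - f0[i] - eps)
      hi <- min(hi, y[i] - f0[i] + eps)
    } else if (ti < C - tol) {
      lo <- max(lo, y[i] - f0[i] - eps)
      hi <- min(hi, y[i] - f0[i] - eps)
    } else {
      hi <- min(hi, y[i] - f0[i] - eps)
    }
  }
  list(theta = best_t, b = (lo + hi) / 2, objective = best_obj)
}

# Kernel ridge regression with unpenalized intercept, closed form via two
# solves against (K + I/C) rather than one bordered system.
krr_oracle <- function(K, y, C) {
  A <- K + diag(length(y)) / C
  Ai_y <- solve(A, y)
  Ai_1 <- solve(A, rep(1, length(y)))
  b <- sum(Ai_y) / sum(Ai_1)
  alpha <- solve(A, y - b)
  list(alpha = alpha, b = b)
}

# Brute-force LOO-1NN accuracy (double loop; ties to the first minimum)
loo1nn_oracle <- function(X, cls) {
  n <- nrow(X)
  hits <- 0
  for (i in seq_len(n)) {
    d <- apply(X, 1, function(r) sum((r - X[i, ])^2))
    d[i] <- Inf
    hits <- hits + (cls[which.min(d)] == cls[i])
  }
  hits / n
}

toy_regression_df <- function(n = 12, seed = 42, noise = 0.3) {
  withr::with_seed(seed, {
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    df$y <- 1.5 * df$x1 - 0.7 * df$x2 + rnorm(n, 0, noise)
    df
  })
}
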