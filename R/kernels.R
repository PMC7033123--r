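#' Kernel specification
#'
#' The four kernel families used by the regression suite, each governed
#' by a single parameter `gamma`:
#' linear `f = gamma * <x, x0>`, polynomial `f = (gamma * <x, x0>)^3`,
#' Gaussian `f = exp(-gamma * ||x - x0||^2)` and sigmoid
#' `f = tanh(gamma * <x, x0>)`.
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"gaussian"`,
#'   `"sigmoid"`.
#' @param gamma Kernel parameter, > 0. The grid reproduced by
#'   [default_model_grid()] uses 0.01, 0.05 and 0.10.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("gaussian", "linear", "polynomial",
                                 "sigmoid"), gamma = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(gamma) || gamma <= 0) abort("gamma must be > 0")
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s, gamma = %g>\n", x$kind, x$gamma))
  invisible(x)
}

#' Evaluate a kernel between two feature vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,x0 Numeric vectors of equal length.
#' @return A single numeric kernel value.
#' @examples
#' kernel_eval(kernel_spec("gaussian", 0.05), c(1, 2), c(1, 2))  # 1
#' @export
kernel_eval <- function(spec, x, x0) {
  if (length(x) != length(x0)) abort("x and x0 must have equal length")
  drop(kernel_matrix(spec, matrix(x, nrow = 1), matrix(x0, nrow = 1)))
}

#' Kernel Gram matrix between two sample sets
#'
#' @param spec A [kernel_spec()].
#' @param X,X0 Numeric matrices with matching column counts; `X0`
#'   defaults to `X`.
#' @return The `nrow(X)` x `nrow(X0)` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, X0 = X) {
  X <- as.matrix(X); X0 <- as.matrix(X0)
  if (ncol(X) != ncol(X0)) abort("dimension mismatch between X and X0")
  ip <- X %*% t(X0)
  switch(spec$kind,
    linear = spec$gamma * ip,
    polynomial = (spec$gamma * ip)^3,
    sigmoid = tanh(spec$gamma * ip),
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(X0^2), "+") - 2 * ip
      exp(-spec$gamma * pmax(d2, 0))
    }
  )
}
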