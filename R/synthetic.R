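#' Draw synthetic biosensor replicates from printed summary statistics
#'
#' Each (treatment, miRNA) cell of the concentration table reports a mean
#' and SD over n = 5 biosensor measurements. This emulates replicate-level
#' data by drawing from a normal distribution truncated below at
#' `truncation_floor` (concentrations cannot be negative), via rejection
#' sampling so the truncation is exact. The seed stream is split per cell
#' in fixed table order, so any cell's replicates are reproducible
#' independently of which other cells are sampled.
#'
#' @param table An `expression_table`.
#' @param n_replicates Draws per cell (>= 1).
#' @param seed Integer seed for the whole replicate table.
#' @param truncation_floor Lower truncation bound in fM (default 0).
#' @return A tibble like the input table but with one row per replicate:
#'   columns of the table plus `replicate_id` and `value_fM`.
#' @examples
#' reps <- sample_replicates(load_expression_table(), n_replicates = 5,
#'                           seed = 1)
#' @export
sample_replicates <- function(table, n_replicates = 5, seed = 1,
                              truncation_floor = 0) {
  stopifnot(inherits(table, "expression_table"))
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  tab <- tibble::as_tibble(unclass(table))
  draws <- lapply(seq_len(nrow(tab)), function(k) {
    rtruncnorm_cell(n_replicates, tab$mean_fM[k], tab$sd_fM[k],
                    floor = truncation_floor,
                    seed = cell_seed(seed, k))
  })
  out <- tab[rep(seq_len(nrow(tab)), each = n_replicates), ]
  out$replicate_id <- rep(seq_len(n_replicates), times = nrow(tab))
  out$value_fM <- unlist(draws)
  class(out) <- setdiff(class(out), "expression_table")
  out
}

# deterministic per-cell substream; kept below 2^31
cell_seed <- function(seed, k) {
  (as.numeric(seed) %% 1e6) * 1009 + 7919 * k %% 1e6
}

# exact truncated-normal draws by rejection; sd = 0 degenerates to the mean
rtruncnorm_cell <- function(n, mean, sd, floor, seed) {
  if (sd == 0) return(rep(mean, n))
  withr::with_seed(as.integer(seed), {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, mean, sd)
      out <- c(out, x[x >= floor])
    }
    out[seq_len(n)]
  })
}

#' Generate a planted-signal dataset with known informative features
#'
#' Builds a labelled dataset in which only the features in
#' `informative` carry class information: their class-conditional means
#' are spaced `class_separation` noise-SDs apart, while all other
#' features are class-independent standard normal noise. Used to verify
#' that the coalition-game ranker recovers a known ground truth.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes (>= 2); class labels are 0-based
#'   like stress severity levels.
#' @param n_features Total feature count.
#' @param informative Integer indices (1-based) of informative features.
#' @param class_separation Distance between adjacent class means in units
#'   of the noise SD; 0 plants no signal at all.
#' @param seed Integer seed.
#' @return A `stress_dataset` tibble with features `f1 ... f<n>`,
#'   `class_label` in `0:(n_classes-1)` and `y` equal to the class label.
#' @examples
#' planted_signal_dataset(5, n_classes = 5, n_features = 11,
#'                        informative = 2, class_separation = 10, seed = 1)
#' @export
planted_signal_dataset <- function(n_per_class, n_classes, n_features,
                                   informative, class_separation, seed = 1) {
  if (n_classes < 2) abort("n_classes must be >= 2")
  informative <- as.integer(informative)
  if (length(informative) > 0 &&
      (min(informative) < 1 || max(informative) > n_features)) {
    abort("informative feature index out of range")
  }
  n <- n_per_class * n_classes
  cls <- rep(0:(n_classes - 1), each = n_per_class)
  X <- withr::with_seed(as.integer(seed), {
    m <- matrix(rnorm(n * n_features), nrow = n)
    for (j in informative) {
      m[, j] <- m[, j] + class_separation * (cls - (n_classes - 1) / 2)
    }
    m
  })
  colnames(X) <- paste0("f", seq_len(n_features))
  out <- tibble::tibble(
    treatment_label = paste0("class", cls, "_", rep(seq_len(n_per_class),
                                                    times = n_classes)),
    stress_type = "synthetic",
    class_label = as.integer(cls),
    y = as.numeric(cls)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  new_stress_dataset(out, features = colnames(X), encoding = "ordinal",
                     provenance = "synthetic", scope = "synthetic")
}
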