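#' @keywords internal
mirna_names <- c("miRNA-156", "miRNA-159", "miRNA-167", "miRNA-168",
                 "miRNA-169", "miRNA-170", "miRNA-171", "miRNA-319",
                 "miRNA-393", "miRNA-396", "miRNA-398")

#' @keywords internal
stress_names <- c("drought", "salinity", "cold", "heat")

# Baseline (no-stress) value of each stress axis: fully irrigated soil,
# unsalted water, growth-room temperature.
stress_baselines <- c(drought = 100, salinity = 0, cold = 22, heat = 22)

treatment_labels <- c("Control",
                      paste0("W", 1:4), paste0("S", 1:4),
                      paste0("C", 1:4), paste0("H", 1:4))

#' Load the miRNA concentration table
#'
#' Reads a treatment-by-miRNA concentration table (means and standard
#' deviations in femtomolar, fM) and validates it as a complete grid of
#' 17 treatments (a shared control plus four severity levels of drought,
#' salinity, cold and heat) by 11 stress-responsive miRNAs. With no
#' argument, the table packaged with mirstress is loaded.
#'
#' @param source Path to a CSV with columns `treatment_label`,
#'   `stress_type`, `level_index`, `level_value`, `unit`, `mirna`,
#'   `mean_fM`, `sd_fM`, `n` (one row per treatment-miRNA cell), or
#'   `NULL` for the packaged table.
#' @return A tibble of class `expression_table`, one row per
#'   (treatment, miRNA) cell, 187 rows in fixed treatment and miRNA order.
#' @examples
#' tab <- load_expression_table()
#' dplyr::filter(tab, treatment_label == "S4", mirna == "miRNA-167")
#' @export
load_expression_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "table1.csv", package = "mirstress",
                          mustWork = TRUE)
  }
  raw <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  validate_expression_table(raw)
}

#' @keywords internal
validate_expression_table <- function(raw) {
  needed <- c("treatment_label", "stress_type", "level_index", "level_value",
              "unit", "mirna", "mean_fM", "sd_fM", "n")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("expression table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble::as_tibble(raw[needed])

  bad_label <- setdiff(unique(tab$treatment_label), treatment_labels)
  if (length(bad_label) > 0) {
    abort(paste0("malformed treatment label(s): ",
                 paste(bad_label, collapse = ", ")))
  }
  bad_mirna <- setdiff(unique(tab$mirna), mirna_names)
  if (length(bad_mirna) > 0) {
    abort(paste0("unknown miRNA name(s): ", paste(bad_mirna, collapse = ", ")))
  }

  key <- paste(tab$treatment_label, tab$mirna, sep = " / ")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(paste0("duplicate (treatment, miRNA) cell(s): ",
                 paste(unique(dup), collapse = "; ")))
  }
  full <- as.vector(outer(treatment_labels, mirna_names, paste, sep = " / "))
  miss <- setdiff(full, key)
  if (length(miss) > 0) {
    abort(paste0("missing (treatment, miRNA) cell(s): ",
                 paste(miss, collapse = "; ")))
  }

  neg <- tab$mean_fM < 0 | tab$sd_fM < 0
  if (any(neg)) {
    abort(paste0("negative mean or SD at: ",
                 paste(key[neg], collapse = "; ")))
  }
  if (any(tab$n < 1)) abort("replicate count n must be >= 1")

  ctrl <- tab$stress_type == "control"
  if (any(tab$level_index[ctrl] != 0) || any(tab$level_index[!ctrl] == 0)) {
    abort("level_index must be 0 exactly for control treatments")
  }

  # fixed ordering: treatments in table order, miRNAs left-to-right
  tab$treatment_label <- factor(tab$treatment_label, levels = treatment_labels)
  tab$mirna <- factor(tab$mirna, levels = mirna_names)
  tab <- dplyr::arrange(tab, .data$treatment_label, .data$mirna)
  tab$treatment_label <- as.character(tab$treatment_label)
  tab$mirna <- as.character(tab$mirna)
  class(tab) <- c("expression_table", class(tab))
  tab
}

#' Write an expression table to CSV
#'
#' Round-trips through [load_expression_table()]: the reloaded table is
#' identical field-for-field.
#'
#' @param table An `expression_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  readr::write_csv(tibble::as_tibble(unclass(table)), path, progress = FALSE)
  invisible(path)
}

#' Encode a treatment as a numeric regression target
#'
#' Ordinal encoding returns the severity index 0 (control) to 4 (most
#' severe). Native encoding returns the level in the stress axis' own
#' unit: percent of field capacity for drought, mM NaCl for salinity,
#' degrees Celsius for cold and heat; the control maps to the baseline
#' of the scoping stress (100 %FC, 0 mM, 22 degC).
#'
#' @param treatment A one-row data frame (or list) with `stress_type`,
#'   `level_index`, `level_value`.
#' @param encoding `"ordinal"` or `"native"`.
#' @param scope Stress type supplying the control's native baseline;
#'   required only when encoding a control treatment natively.
#' @return A single numeric target.
#' @examples
#' tab <- load_expression_table()
#' s4 <- dplyr::filter(tab, treatment_label == "S4")[1, ]
#' encode_target(s4, "native")  # 80 (mM NaCl)
#' @export
encode_target <- function(treatment, encoding = c("ordinal", "native"),
                          scope = NULL) {
  encoding <- match.arg(encoding)
  stress <- as.character(treatment$stress_type[1])
  if (encoding == "ordinal") {
    return(as.numeric(treatment$level_index[1]))
  }
  if (stress == "control") {
    if (is.null(scope)) {
      # no stress axis to borrow a unit from: the unstressed origin
      return(0)
    }
    return(unname(stress_baselines[scope]))
  }
  as.numeric(treatment$level_value[1])
}

#' Assemble an analysis-ready stress dataset
#'
#' Reshapes the long concentration table into a wide samples-by-features
#' dataset for one stress (its four severity levels plus the shared
#' control) or for all 17 treatments. Rows are either the per-treatment
#' means or synthetic replicate draws (see [sample_replicates()]).
#'
#' @param table An `expression_table`.
#' @param scope One of `"all"`, `"drought"`, `"salinity"`, `"cold"`,
#'   `"heat"`.
#' @param features Character vector of miRNA names (in the desired column
#'   order) or `"all"` for the 11 packaged miRNAs in table order.
#' @param provenance `"means"` (one row per treatment) or `"replicates"`
#'   (`n_replicates` truncated-normal draws per treatment).
#' @param encoding Target encoding, see [encode_target()].
#' @param n_replicates,seed Replicate count and RNG seed used when
#'   `provenance = "replicates"`.
#' @return A tibble of class `stress_dataset` with metadata columns
#'   `treatment_label`, `stress_type`, `class_label` (severity 0-4),
#'   `y` (numeric target) and one numeric column per feature, plus
#'   attributes `features`, `encoding`, `provenance`, `scope`.
#' @examples
#' tab <- load_expression_table()
#' build_stress_dataset(tab, scope = "drought")
#' build_stress_dataset(tab, features = c("miRNA-169", "miRNA-393",
#'                                        "miRNA-396"), encoding = "native")
#' @export
build_stress_dataset <- function(table, scope = "all", features = "all",
                                 provenance = c("means", "replicates"),
                                 encoding = c("ordinal", "native"),
                                 n_replicates = 5, seed = 1) {
  stopifnot(inherits(table, "expression_table"))
  provenance <- match.arg(provenance)
  encoding <- match.arg(encoding)
  if (!(identical(scope, "all") || scope %in% stress_names)) {
    abort(paste0("unknown stress: ", scope))
  }
  if (identical(features, "all")) {
    features <- mirna_names
  }
  bad <- setdiff(features, mirna_names)
  if (length(bad) > 0) {
    abort(paste0("unknown feature(s): ", paste(bad, collapse = ", ")))
  }
  if (provenance == "replicates" && n_replicates < 1) {
    abort("n_replicates must be >= 1")
  }

  keep_types <- if (identical(scope, "all")) {
    c("control", stress_names)
  } else {
    c("control", scope)
  }

  long <- if (provenance == "means") {
    out <- dplyr::filter(tibble::as_tibble(unclass(table)),
                         .data$stress_type %in% keep_types,
                         .data$mirna %in% features)
    out$replicate_id <- 1L
    out$value_fM <- out$mean_fM
    out
  } else {
    reps <- sample_replicates(table, n_replicates = n_replicates, seed = seed)
    dplyr::filter(reps, .data$stress_type %in% keep_types,
                  .data$mirna %in% features)
  }

  wide <- tidyr::pivot_wider(
    long[c("treatment_label", "stress_type", "level_index", "level_value",
           "replicate_id", "mirna", "value_fM")],
    names_from = "mirna", values_from = "value_fM"
  )
  wide <- wide[c(setdiff(names(wide), features), features)]
  wide$treatment_label <- factor(wide$treatment_label,
                                 levels = treatment_labels)
  wide <- dplyr::arrange(wide, .data$treatment_label, .data$replicate_id)
  wide$treatment_label <- as.character(wide$treatment_label)

  enc_scope <- if (identical(scope, "all")) NULL else scope
  y <- vapply(seq_len(nrow(wide)), function(i) {
    encode_target(wide[i, ], encoding, scope = enc_scope)
  }, numeric(1))

  out <- tibble::tibble(
    treatment_label = wide$treatment_label,
    stress_type = wide$stress_type,
    replicate_id = wide$replicate_id,
    class_label = as.integer(wide$level_index),
    y = y
  )
  out <- dplyr::bind_cols(out, wide[features])
  if (provenance == "means") out$replicate_id <- NULL
  new_stress_dataset(out, features = features, encoding = encoding,
                     provenance = provenance, scope = scope)
}

#' @keywords internal
new_stress_dataset <- function(df, features, encoding, provenance, scope) {
  attr(df, "features") <- features
  attr(df, "encoding") <- encoding
  attr(df, "provenance") <- provenance
  attr(df, "scope") <- scope
  class(df) <- unique(c("stress_dataset", class(df)))
  df
}

#' Extract the feature matrix of a stress dataset
#'
#' @param data A `stress_dataset` (or any data frame; then `features`
#'   must be supplied).
#' @param features Optional character vector naming feature columns.
#' @return A numeric matrix, samples by features.
#' @export
feature_matrix <- function(data, features = NULL) {
  features <- features %||% attr(data, "features")
  if (is.null(features)) {
    abort("no feature columns: supply `features` or a stress_dataset")
  }
  as.matrix(as.data.frame(data)[, features, drop = FALSE])
}
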