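# Readers and writers for the two on-disk dataset dialects: plain delimited
# text (header + comma-separated numeric columns + a label column) and
# KEEL-style .dat files (@relation/@attribute/@data). Both map the rarer raw
# label to 1 unless told otherwise, following the convention that label 1 is
# the minority class.

map_labels <- function(raw, positive_label = "auto") {
  raw <- trimws(as.character(raw))
  values <- unique(raw)
  if (length(values) > 2L) {
    imb_stop("imbfuse_multiclass_error",
             sprintf("label column has %d distinct values (%s); only binary labels are supported",
                     length(values), paste(utils::head(values, 5L), collapse = ", ")))
  }
  if (length(values) < 2L) {
    imb_stop("imbfuse_format_error",
             "label column is constant; two classes are required")
  }
  if (identical(positive_label, "auto")) {
    counts <- table(raw)
    least <- names(counts)[counts == min(counts)]
    # equal counts: take the lexicographically larger value (so e.g.
    # "positive" beats "negative" in a balanced file), deterministically
    positive <- max(least)
  } else {
    positive <- trimws(as.character(positive_label))
    if (!positive %in% values) {
      imb_stop("imbfuse_format_error",
               sprintf("positive label '%s' not found among {%s}", positive,
                       paste(values, collapse = ", ")))
    }
  }
  labels <- as.integer(raw == positive)
  attr(labels, "label_mapping") <- stats::setNames(
    as.integer(values == positive), values)
  labels
}

parse_feature_columns <- function(df, feature_cols) {
  mats <- lapply(feature_cols, function(cn) {
    col <- df[[cn]]
    if (is.character(col)) col <- trimws(col)
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num))
    if (length(bad) > 0L) {
      imb_stop("imbfuse_parse_error",
               sprintf("non-numeric or non-finite value '%s' at row %d, column '%s'",
                       as.character(col[bad[1L]]), bad[1L], cn))
    }
    num
  })
  mat <- do.call(cbind, mats)
  colnames(mat) <- feature_cols
  mat
}

#' Read a delimited-text dataset
#'
#' Expects a header row, comma separation and numeric feature columns. The
#' label column may hold any raw values (numbers or strings) as long as
#' exactly two are present.
#'
#' @param path Path to the `.csv` file.
#' @param label_column Column name or index of the label column; default is
#'   the last column.
#' @param positive_label `"auto"` (the rarer raw label becomes class 1) or an
#'   explicit raw value to map to 1.
#' @return A [labeled_dataset()]; the raw-to-binary label mapping is attached
#'   as attribute `label_mapping`.
#' @export
read_delimited <- function(path, label_column = NULL,
                           positive_label = "auto") {
  if (!file.exists(path)) {
    imb_stop("imbfuse_format_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        strip.white = TRUE, check.names = FALSE)
  if (ncol(df) < 2L) {
    imb_stop("imbfuse_format_error",
             "need at least one feature column and one label column")
  }
  label_column <- label_column %||% ncol(df)
  if (is.numeric(label_column)) label_column <- names(df)[label_column]
  if (!label_column %in% names(df)) {
    imb_stop("imbfuse_format_error",
             sprintf("label column '%s' not present", label_column))
  }
  labels <- map_labels(df[[label_column]], positive_label)
  feats <- parse_feature_columns(df, setdiff(names(df), label_column))
  out <- labeled_dataset(feats, labels)
  attr(out, "label_mapping") <- attr(labels, "label_mapping")
  out
}

#' Write a dataset as delimited text
#'
#' Floats are printed with 17 significant digits so that a write/read
#' round-trip reproduces the matrix bit for bit.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path.
#' @param label_name Header name for the label column (written last).
#' @return `path`, invisibly.
#' @export
write_delimited <- function(dataset, path, label_name = "class") {
  header <- paste(c(dataset$feature_names, label_name), collapse = ",")
  rows <- apply(dataset$features, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  })
  lines <- paste0(rows, ",", dataset$labels)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a KEEL-style `.dat` file
#'
#' Supports the dialect used by the KEEL imbalanced-classification
#' repository: `@relation`, `@attribute <name> real/integer [lo, hi]` or
#' nominal `{a, b}` lines, optional `@inputs`/`@outputs`, then `@data` with
#' comma-separated rows. The output attribute must be nominal with exactly
#' two values; the rarer value maps to class 1. Whitespace around cells is
#' tolerated.
#'
#' @param path Path to the `.dat` file.
#' @return A [labeled_dataset()] with attribute `label_mapping`.
#' @export
read_keel_dat <- function(path) {
  if (!file.exists(path)) {
    imb_stop("imbfuse_format_error", sprintf("file not found: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  is_header <- grepl("^@", lines)
  data_at <- which(tolower(lines) == "@data")
  if (length(data_at) == 0L) {
    imb_stop("imbfuse_format_error", "missing @data section")
  }
  header <- lines[seq_len(data_at[1L] - 1L)]
  body <- lines[seq.int(data_at[1L] + 1L, length(lines))]
  body <- body[!grepl("^@", body)]

  attr_lines <- header[grepl("^@attribute", header, ignore.case = TRUE)]
  if (length(attr_lines) < 2L) {
    imb_stop("imbfuse_format_error", "need at least two @attribute lines")
  }
  attr_names <- vapply(attr_lines, function(l) {
    strsplit(sub("^@attribute\\s+", "", l, ignore.case = TRUE),
             "[\\s\\{\\[]", perl = TRUE)[[1L]][1L]
  }, character(1L), USE.NAMES = FALSE)

  outputs_line <- header[grepl("^@outputs?", header, ignore.case = TRUE)]
  output_name <- if (length(outputs_line) > 0L) {
    trimws(sub("^@outputs?\\s+", "", outputs_line[1L], ignore.case = TRUE))
  } else {
    attr_names[length(attr_names)]
  }
  out_idx <- match(output_name, attr_names)
  if (is.na(out_idx)) {
    imb_stop("imbfuse_format_error",
             sprintf("output attribute '%s' not declared", output_name))
  }
  out_line <- attr_lines[out_idx]
  if (grepl("\\{", out_line)) {
    nominal <- strsplit(sub(".*\\{([^}]*)\\}.*", "\\1", out_line), ",")[[1L]]
    if (length(trimws(nominal)) != 2L) {
      imb_stop("imbfuse_multiclass_error",
               "output attribute must be nominal with exactly 2 values")
    }
  }

  cells <- strsplit(body, ",")
  if (length(unique(lengths(cells))) != 1L ||
      lengths(cells)[1L] != length(attr_names)) {
    imb_stop("imbfuse_format_error",
             "data rows do not match the declared attribute count")
  }
  tab <- as.data.frame(do.call(rbind, lapply(cells, trimws)),
                       stringsAsFactors = FALSE)
  names(tab) <- attr_names
  labels <- map_labels(tab[[out_idx]], "auto")
  feats <- parse_feature_columns(tab, attr_names[-out_idx])
  out <- labeled_dataset(feats, labels)
  attr(out, "label_mapping") <- attr(labels, "label_mapping")
  out
}

#' Write a dataset as a KEEL-style `.dat` file
#'
#' Inverse of [read_keel_dat()]: numeric input attributes, a binary nominal
#' output attribute (`negative` for class 0, `positive` for class 1), floats
#' at 17 significant digits for bit-stable round-trips.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path.
#' @param relation Relation name written on the `@relation` line.
#' @return `path`, invisibly.
#' @export
write_keel_dat <- function(dataset, path, relation = "dataset") {
  rng <- apply(dataset$features, 2L, range)
  attr_lines <- sprintf("@attribute %s real [%.17g, %.17g]",
                        dataset$feature_names, rng[1L, ], rng[2L, ])
  # class 1 is written as 'positive'; auto-detection on re-read recovers it
  # both when it is rarer and (via the lexicographic tie-break) when counts tie
  out_values <- c("negative", "positive")
  lines <- c(
    sprintf("@relation %s", relation),
    attr_lines,
    "@attribute class {negative, positive}",
    sprintf("@inputs %s", paste(dataset$feature_names, collapse = ", ")),
    "@outputs class",
    "@data",
    paste0(apply(dataset$features, 1L, function(r) {
      paste(sprintf("%.17g", r), collapse = ", ")
    }), ", ", out_values[dataset$labels + 1L])
  )
  writeLines(lines, path)
  invisible(path)
}
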