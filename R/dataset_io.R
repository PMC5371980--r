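#' Construct a two-class marker dataset
#'
#' A `marker_dataset` holds a samples-by-markers numeric matrix together with
#' per-sample class labels and a designated positive (case/disease) class.
#' It is the input container for every downstream stage: preprocessing,
#' combinatorial analysis, ROC evaluation and validation.
#'
#' @param values Numeric matrix, one row per sample and one column per marker.
#'   Row names are taken as sample IDs when `sample_ids` is missing; column
#'   names as marker names when `marker_names` is missing.
#' @param classes Character vector of per-sample class labels; exactly two
#'   distinct labels must be present, each with at least one sample.
#' @param positive_label The label of the case (disease) class, or `"auto"`
#'   to use the lexicographically second label (a message is emitted).
#' @param sample_ids Optional character vector of unique sample identifiers.
#' @param marker_names Optional character vector of unique marker names.
#'
#' @return An object of class `marker_dataset`: a list with elements
#'   `values`, `classes`, `sample_ids`, `marker_names`, `positive_label`.
#' @export
marker_dataset <- function(values, classes, positive_label = "auto",
                           sample_ids = NULL, marker_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(values)
    if (is.null(marker_names)) marker_names <- paste0("marker", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  marker_names <- as.character(marker_names)
  classes <- as.character(classes)

  if (nrow(values) != length(sample_ids))
    stop("`values` has ", nrow(values), " rows but ", length(sample_ids), " sample IDs")
  if (ncol(values) != length(marker_names))
    stop("`values` has ", ncol(values), " columns but ", length(marker_names), " marker names")
  if (length(classes) != length(sample_ids))
    stop("`classes` must have one label per sample")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_names))
    stop("duplicate marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  if (any(!nzchar(marker_names))) stop("marker names must be non-empty")

  lev <- sort(unique(classes))
  if (length(lev) != 2)
    stop("expected exactly 2 distinct class labels, found ", length(lev),
         ": ", paste(lev, collapse = ", "))
  if (identical(positive_label, "auto")) {
    positive_label <- lev[2]
    message("positive class set automatically to '", positive_label,
            "' (lexicographically second label)")
  }
  if (!positive_label %in% lev)
    stop("positive_label '", positive_label, "' is not one of the class labels (",
         paste(lev, collapse = ", "), ")")

  rownames(values) <- sample_ids
  colnames(values) <- marker_names
  structure(
    list(values = values, classes = classes, sample_ids = sample_ids,
         marker_names = marker_names, positive_label = positive_label),
    class = "marker_dataset"
  )
}

#' @export
print.marker_dataset <- function(x, ...) {
  tab <- table(x$classes)
  cat("<marker_dataset> ", length(x$sample_ids), " samples x ",
      length(x$marker_names), " markers\n", sep = "")
  cat("  classes: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "; positive = '", x$positive_label, "'\n", sep = "")
  cat("  markers: ", paste(x$marker_names, collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("  missing cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' Number of samples / markers in a marker dataset
#' @param dataset A [marker_dataset()].
#' @return Integer count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' @rdname n_samples
#' @export
n_markers <- function(dataset) length(dataset$marker_names)

# Detect delimiter from the header line: count each candidate, pick the most
# frequent; a tie (including all-zero) is an error rather than a silent guess.
detect_delimiter <- function(header_line) {
  candidates <- c(comma = ",", tab = "\t", semicolon = ";")
  counts <- vapply(candidates, function(d)
    lengths(regmatches(header_line, gregexpr(d, header_line, fixed = TRUE))),
    integer(1))
  top <- which(counts == max(counts))
  if (max(counts) == 0L || length(top) > 1L)
    stop("cannot detect delimiter (counts in header: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         "); pass `delim` explicitly")
  candidates[[top]]
}

#' Read a two-class marker table from a delimited text file
#'
#' Expects a header row and one row per sample: column 1 = sample ID,
#' column 2 = class label, remaining columns = numeric marker values.
#' The delimiter (comma, tab or semicolon) is auto-detected from the header
#' by frequency; ties are an error. Missing marker cells are accepted with a
#' warning — analysis stages exclude incomplete samples listwise.
#'
#' @param path Path to the file.
#' @param positive_label Case-class label, or `"auto"` (see [marker_dataset()]).
#' @param delim Optional explicit delimiter, bypassing detection.
#' @param transpose If `TRUE` the file is marker-major (markers as rows) and is
#'   transposed after reading; the first column then holds marker names and the
#'   remaining columns one sample each, with a `class` row.
#' @return A [marker_dataset()].
#' @export
read_marker_dataset <- function(path, positive_label = "auto", delim = NULL,
                                transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- detect_delimiter(header)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (transpose) df <- transpose_marker_table(df)
  if (ncol(df) < 3)
    stop("expected at least 3 columns (sample ID, class, >=1 marker), found ", ncol(df))

  ids <- as.character(df[[1]])
  classes <- as.character(df[[2]])
  marker_cols <- names(df)[-(1:2)]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(marker_cols),
                 dimnames = list(ids, marker_cols))
  for (j in seq_along(marker_cols)) {
    col <- df[[j + 2L]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("non-numeric value '", col[bad[1]], "' in column '",
             marker_cols[j], "', row ", bad[1])
      col <- num
    }
    vals[, j] <- as.numeric(col)
  }
  nmiss <- sum(is.na(vals))
  if (nmiss > 0)
    warning(nmiss, " missing marker cell(s); incomplete samples are excluded ",
            "listwise by analysis stages", call. = FALSE)
  marker_dataset(vals, classes, positive_label = positive_label,
                 sample_ids = ids, marker_names = marker_cols)
}

# marker-major data frame -> sample-major layout
transpose_marker_table <- function(df) {
  rn <- as.character(df[[1]])
  body <- t(as.matrix(df[, -1, drop = FALSE]))
  out <- data.frame(sample = colnames(df)[-1], stringsAsFactors = FALSE)
  for (i in seq_along(rn)) out[[rn[i]]] <- unname(body[, i])
  # expect a 'class' row among the original rows
  cls_idx <- which(tolower(names(out)) == "class")
  if (length(cls_idx) != 1)
    stop("transposed input must contain exactly one 'class' row")
  out[, c(1, cls_idx, setdiff(seq_along(out), c(1, cls_idx)))]
}

#' Write a marker dataset to a delimited text file
#'
#' Emits the standard layout read by [read_marker_dataset()]: sample ID,
#' class label, then one numeric column per marker.
#'
#' @param dataset A [marker_dataset()].
#' @param path Output path.
#' @param delim Field delimiter: `","`, `"\t"` or `";"`.
#' @return `path`, invisibly.
#' @export
write_marker_dataset <- function(dataset, path, delim = ",") {
  stopifnot(delim %in% c(",", "\t", ";"))
  df <- data.frame(sample = dataset$sample_ids, class = dataset$classes,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (m in dataset$marker_names) df[[m]] <- dataset$values[, m]
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics of a marker dataset
#'
#' Per-marker, per-class minimum, maximum, mean, median and standard deviation
#' computed on non-missing values, alongside overall sample/marker/class and
#' missing-cell counts.
#'
#' @param dataset A [marker_dataset()].
#' @return A list of class `dataset_summary` with elements `n_samples`,
#'   `n_markers`, `n_per_class` (named integer vector), `n_missing`, and
#'   `stats`, a tibble with one row per (marker, class).
#' @export
summarize_dataset <- function(dataset) {
  long <- profile_table(dataset)
  stats <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$marker, .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value), median = stats::median(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    )
  structure(
    list(n_samples = n_samples(dataset),
         n_markers = n_markers(dataset),
         n_per_class = c(table(dataset$classes)),
         n_missing = sum(is.na(dataset$values)),
         stats = stats),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("<dataset_summary> ", x$n_samples, " samples, ", x$n_markers,
      " markers, ", x$n_missing, " missing cells\n", sep = "")
  cat("  per class: ",
      paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class), collapse = ", "),
      "\n", sep = "")
  print(x$stats, n = Inf)
  invisible(x)
}

#' Long-format marker profile table
#'
#' One row per (sample, marker) pair with the class label and signal value:
#' the plot-ready table behind marker profile and box plots.
#'
#' @param dataset A [marker_dataset()].
#' @return A tibble with columns `sample`, `class`, `marker`, `value` and
#'   `n_samples * n_markers` rows.
#' @export
profile_table <- function(dataset) {
  tibble::as_tibble(dataset$values) |>
    dplyr::mutate(sample = dataset$sample_ids, class = dataset$classes,
                  .before = 1) |>
    tidyr::pivot_longer(cols = dplyr::all_of(dataset$marker_names),
                        names_to = "marker", values_to = "value")
}

# Drop samples with any missing marker value; message when any are dropped.
# SE/SP under the stringency rule need every combo member defined.
drop_incomplete <- function(dataset) {
  keep <- stats::complete.cases(dataset$values)
  if (all(keep)) return(dataset)
  message(sum(!keep), " sample(s) with missing marker values excluded listwise")
  marker_dataset(dataset$values[keep, , drop = FALSE],
                 dataset$classes[keep],
                 positive_label = dataset$positive_label,
                 sample_ids = dataset$sample_ids[keep],
                 marker_names = dataset$marker_names)
}
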