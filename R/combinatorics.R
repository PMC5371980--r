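#' Number of non-empty marker combinations
#'
#' `n` markers can form `2^n - 1` distinct non-empty subsets (the sum of
#' binomial coefficients C(n, k) over k = 1..n).
#'
#' @param n Number of markers, integer >= 1.
#' @return `2^n - 1` as a double (exact for n <= 52).
#' @export
combination_count <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop("`n` must be a single integer >= 1")
  2^n - 1
}

#' Enumerate all non-empty marker subsets in a stable order
#'
#' Subsets are ordered by size ascending, then lexicographically by member
#' names; combo IDs ("Combo I", "Combo II", ...) are Roman numerals assigned
#' in that order, so membership is traceable from the ID alone.
#'
#' @param marker_names Character vector of unique marker names.
#' @param max_markers Soft cap on panel size; enumeration is exhaustive, so
#'   more than ~20 markers (about a million subsets) is refused unless
#'   `allow_large = TRUE`.
#' @param allow_large Override the cap.
#' @return A tibble with columns `combo_id`, `markers` (members joined by
#'   "-"), `members` (list column) and `size`; `2^N - 1` rows.
#' @export
enumerate_combinations <- function(marker_names, max_markers = 20,
                                   allow_large = FALSE) {
  marker_names <- as.character(marker_names)
  if (length(marker_names) < 1) stop("need at least one marker")
  if (anyDuplicated(marker_names))
    stop("duplicate marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  n <- length(marker_names)
  if (n > max_markers && !allow_large)
    stop("exhaustive enumeration of ", n, " markers means ", 2^n - 1,
         " combinations; pass allow_large = TRUE to proceed")
  sorted <- sort(marker_names)
  members <- list()
  for (k in seq_len(n)) {
    cmb <- utils::combn(sorted, k, simplify = FALSE)
    members <- c(members, cmb)
  }
  idx <- seq_along(members)
  # Roman numerals are undefined past 3899; large panels fall back to decimal
  label <- ifelse(idx <= 3899, as.character(utils::as.roman(idx)),
                  as.character(idx))
  tibble::tibble(
    combo_id = paste("Combo", label),
    markers = vapply(members, paste, character(1), collapse = "-"),
    members = members,
    size = lengths(members)
  )
}

#' Stringency settings for the positivity rule
#'
#' The test stringency is the pair `{thr, minf}`: a sample is called positive
#' for a marker subset when at least `minf` of the subset's markers have a
#' signal strictly greater than `thr`. `thr` is in the data's own units
#' (e.g. fluorescence intensity); `minf` is an integer count >= 1.
#'
#' @param thr Finite signal cutoff.
#' @param minf Minimum number of positive features, integer >= 1.
#' @return A list of class `stringency`.
#' @export
stringency <- function(thr, minf = 1) {
  if (!is.finite(thr)) stop("`thr` must be finite")
  if (length(minf) != 1 || is.na(minf) || minf < 1 || minf != floor(minf))
    stop("`minf` must be a single integer >= 1")
  structure(list(thr = thr, minf = as.integer(minf)), class = "stringency")
}

#' @export
print.stringency <- function(x, ...) {
  cat("<stringency> thr = ", x$thr, ", minf = ", x$minf, "\n", sep = "")
  invisible(x)
}

#' Classify samples under the stringency rule
#'
#' A sample is positive when at least `minf` of the given markers exceed
#' `thr` (strict inequality: a value exactly at the cutoff does not count).
#'
#' @param dataset A [marker_dataset()].
#' @param members Character vector of marker names (a subset of the panel).
#' @param stringency A [stringency()] object.
#' @return Logical vector, one call per sample; `NA` where a member value is
#'   missing.
#' @export
classify_samples <- function(dataset, members, stringency) {
  unknown <- setdiff(members, dataset$marker_names)
  if (length(unknown))
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "))
  if (stringency$minf > length(members))
    warning("minf = ", stringency$minf, " exceeds combo size ", length(members),
            "; no sample can be called positive", call. = FALSE)
  sub <- dataset$values[, members, drop = FALSE]
  pos <- rowSums(sub > stringency$thr)  # NA propagates from missing cells
  unname(pos >= stringency$minf)
}

#' Sensitivity and specificity of binary calls
#'
#' Sensitivity is the true-positive rate among case samples; specificity the
#' true-negative rate among controls. Both are reported in percent.
#'
#' @param calls Logical vector of per-sample positive/negative calls.
#' @param classes Character vector of true class labels, aligned with `calls`.
#' @param positive_label The case-class label.
#' @return Named numeric vector `c(se = ..., sp = ...)` in `[0, 100]`.
#' @export
compute_se_sp <- function(calls, classes, positive_label) {
  if (length(calls) != length(classes))
    stop("`calls` and `classes` must be aligned")
  if (anyNA(calls))
    stop("calls contain NA; exclude incomplete samples first")
  is_case <- classes == positive_label
  if (!any(is_case) || all(is_case)) stop("both classes must be non-empty")
  c(se = 100 * mean(calls[is_case]),
    sp = 100 * mean(!calls[!is_case]))
}

#' Exhaustive combinatorial sensitivity/specificity analysis
#'
#' Enumerates every non-empty subset of the dataset's markers, classifies each
#' sample under the stringency rule and scores the subset by SE/SP as
#' recognition frequencies. Samples with missing marker values are excluded
#' listwise first.
#'
#' @param dataset A [marker_dataset()].
#' @param stringency A [stringency()] object.
#' @inheritParams enumerate_combinations
#' @return A `combo_performance` tibble: `combo_id`, `markers`, `members`,
#'   `size`, `se`, `sp` (percent); `2^N - 1` rows.
#' @export
combinatorial_analysis <- function(dataset, stringency, max_markers = 20,
                                   allow_large = FALSE) {
  dataset <- drop_incomplete(dataset)
  combos <- enumerate_combinations(dataset$marker_names,
                                   max_markers = max_markers,
                                   allow_large = allow_large)
  # One boolean exceedance matrix; each combo is a column-sum over it.
  exceed <- dataset$values > stringency$thr
  is_case <- dataset$classes == dataset$positive_label
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  if (n_case == 0 || n_ctrl == 0) stop("both classes must be non-empty")
  if (stringency$minf > 1 && any(combos$size < stringency$minf))
    warning("minf = ", stringency$minf, " exceeds the size of some combos; ",
            "those combos score SE = 0", call. = FALSE)
  perf <- vapply(combos$members, function(m) {
    calls <- rowSums(exceed[, m, drop = FALSE]) >= stringency$minf
    c(100 * sum(calls & is_case) / n_case,
      100 * sum(!calls & !is_case) / n_ctrl)
  }, numeric(2))
  out <- combos
  out$se <- perf[1, ]
  out$sp <- perf[2, ]
  class(out) <- c("combo_performance", class(out))
  out
}

#' Flag and select gold combinations
#'
#' A combination is "gold" when its sensitivity and specificity both meet the
#' chosen minima (inclusive: at-least-equal). `flag_gold()` adds/updates a
#' logical `gold` column; `select_gold()` returns only the gold rows.
#'
#' @param combos Output of [combinatorial_analysis()].
#' @param se_min,sp_min Minimum SE and SP in percent, each in `[0, 100]`.
#' @return `flag_gold()`: the input tibble with a `gold` column;
#'   `select_gold()`: the gold subset.
#' @export
flag_gold <- function(combos, se_min, sp_min) {
  if (nrow(combos) == 0) stop("`combos` is empty")
  stopifnot(se_min >= 0, se_min <= 100, sp_min >= 0, sp_min <= 100)
  combos$gold <- combos$se >= se_min & combos$sp >= sp_min
  combos
}

#' @rdname flag_gold
#' @export
select_gold <- function(combos, se_min, sp_min) {
  flagged <- flag_gold(combos, se_min, sp_min)
  flagged[flagged$gold, , drop = FALSE]
}

#' Histogram of SE and SP across all combinations
#'
#' Bins combination sensitivities and specificities into intervals of
#' `bin_width` percent: `[0, w), [w, 2w), ..., [100 - w, 100]` (the last bin
#' is closed so that 100% is counted).
#'
#' @param combos Output of [combinatorial_analysis()].
#' @param bin_width Bin width in percent; must divide 100.
#' @return A tibble with columns `metric` ("se"/"sp"), `bin_lo`, `bin_hi`,
#'   `count`; counts per metric sum to the number of combos.
#' @export
se_sp_histogram <- function(combos, bin_width = 10) {
  if (length(bin_width) != 1 || !is.finite(bin_width) || bin_width <= 0 ||
      100 %% bin_width != 0)
    stop("`bin_width` must be a positive divisor of 100")
  breaks <- seq(0, 100, by = bin_width)
  bin_counts <- function(x) {
    idx <- pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                length(breaks) - 1L)
    tabulate(idx, nbins = length(breaks) - 1L)
  }
  tibble::tibble(
    metric = rep(c("se", "sp"), each = length(breaks) - 1L),
    bin_lo = rep(utils::head(breaks, -1), 2),
    bin_hi = rep(breaks[-1], 2),
    count = c(bin_counts(combos$se), bin_counts(combos$sp))
  )
}

#' Plot-ready bubble table of all combinations
#'
#' One row per combination with its SE, SP, size (bubble area) and gold flag —
#' the data behind the sensitivity/specificity bubble chart.
#'
#' @param combos Output of [combinatorial_analysis()].
#' @param se_min,sp_min Gold-filter minima in percent.
#' @return A tibble with columns `combo_id`, `markers`, `se`, `sp`, `size`,
#'   `gold`.
#' @export
bubble_table <- function(combos, se_min = 0, sp_min = 0) {
  flagged <- flag_gold(combos, se_min, sp_min)
  flagged[, c("combo_id", "markers", "se", "sp", "size", "gold")]
}
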