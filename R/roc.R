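#' Per-sample score for a marker combination
#'
#' Turns a multi-marker combination into a single continuous score so that a
#' ROC curve can be drawn. Two constructions are offered:
#' \describe{
#'   \item{`glm`}{Predicted case-probability from a binomial (logit) GLM with
#'     the member markers as covariates, fitted to the full dataset. The ROC
#'     curve only uses score order, so any monotone link works equally well.}
#'   \item{`count`}{The number of member markers whose signal exceeds `thr` —
#'     the same rule the combinatorial stage uses, as an integer score.}
#' }
#'
#' @param dataset A [marker_dataset()] (complete cases only; incomplete
#'   samples are excluded listwise with a message).
#' @param members Character vector of marker names.
#' @param method `"glm"` or `"count"`.
#' @param thr Signal cutoff, required for `method = "count"`.
#' @return Named numeric vector of per-sample scores (names = sample IDs).
#' @export
combo_score <- function(dataset, members, method = c("glm", "count"),
                        thr = NULL) {
  method <- match.arg(method)
  dataset <- drop_incomplete(dataset)
  unknown <- setdiff(members, dataset$marker_names)
  if (length(unknown))
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "))
  scores <- if (method == "count") {
    if (is.null(thr)) stop("`thr` is required for the count score")
    rowSums(dataset$values[, members, drop = FALSE] > thr)
  } else {
    model <- fit_glm_score(dataset, members)
    model(dataset$values)
  }
  stats::setNames(as.numeric(scores), dataset$sample_ids)
}

# Fit a binomial GLM on `dataset` and return a scorer for new value matrices.
# Non-convergence falls back to the linear predictor at the last iterate:
# ROC analysis only needs the ordering, which the linear predictor preserves.
fit_glm_score <- function(dataset, members) {
  df <- as.data.frame(dataset$values[, members, drop = FALSE])
  names(df) <- make.names(names(df))  # marker names like "miR-21" -> syntactic
  df$.y <- as.integer(dataset$classes == dataset$positive_label)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  )
  type <- "response"
  if (!fit$converged) {
    warning("GLM did not converge for combo '",
            paste(members, collapse = "-"),
            "'; using the linear predictor at the last iterate", call. = FALSE)
    type <- "link"
  }
  function(values) {
    nd <- as.data.frame(values[, members, drop = FALSE])
    names(nd) <- make.names(names(nd))
    as.numeric(suppressWarnings(stats::predict(fit, newdata = nd, type = type)))
  }
}

#' Empirical ROC curve, trapezoidal AUC and Youden optimal cutoff
#'
#' Sweeps the decision threshold over all unique score values (plus sentinels
#' above the maximum and below the minimum) with the convention "positive iff
#' score > threshold", yielding a curve from (0, 0) to (1, 1). The AUC is the
#' trapezoidal integral of TPR over FPR, which equals the tie-corrected
#' rank-sum concordance probability. The optimal cutoff maximizes the Youden
#' index J = SE + SP - 1; ties are broken by higher specificity, then by the
#' lower cutoff value.
#'
#' @param scores Finite numeric scores, one per sample.
#' @param classes Class labels aligned with `scores`.
#' @param positive_label The case-class label.
#' @return An object of class `panel_roc`: a list with `curve` (tibble:
#'   `threshold` descending, `fpr`, `tpr`, `se`, `sp`), `auc`, `n_cases`,
#'   `n_controls`, and `optimal` (list: `cutoff`, `se`, `sp`, `j`), all SE/SP
#'   as fractions in `[0, 1]`.
#' @export
roc_curve <- function(scores, classes, positive_label) {
  if (length(scores) != length(classes))
    stop("`scores` and `classes` must be aligned")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  is_case <- classes == positive_label
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thresholds, function(t) mean(scores[is_case] > t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!is_case] > t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  curve <- tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr,
                          se = tpr, sp = 1 - fpr)
  j <- curve$se + curve$sp - 1
  # max J, then higher sp, then lower cutoff; J and SP are compared after
  # rounding away float noise (1/3 + 1 vs 2/3 + 2/3 must tie), and the
  # +/-Inf sentinels are considered last.
  finite <- is.finite(curve$threshold)
  ord <- order(!finite, -round(j, 10), -round(curve$sp, 10), curve$threshold)
  best <- ord[1]
  structure(
    list(curve = curve, auc = auc, n_cases = n1, n_controls = n0,
         optimal = list(cutoff = curve$threshold[best], se = curve$se[best],
                        sp = curve$sp[best], j = j[best])),
    class = "panel_roc"
  )
}

#' @export
print.panel_roc <- function(x, ...) {
  cat(sprintf("<panel_roc> AUC = %.4f (%d cases vs %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  cat(sprintf("  optimal cutoff %.4g: SE = %.3f, SP = %.3f (J = %.3f)\n",
              x$optimal$cutoff, x$optimal$se, x$optimal$sp, x$optimal$j))
  invisible(x)
}

#' Optimal cutoff of a ROC curve
#'
#' Convenience accessor for the Youden-optimal operating point computed by
#' [roc_curve()].
#'
#' @param roc A `panel_roc` object.
#' @return Named numeric vector `c(cutoff, se, sp)` (SE/SP as fractions).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "panel_roc"))
  c(cutoff = roc$optimal$cutoff, se = roc$optimal$se, sp = roc$optimal$sp)
}

#' Prediction summary at a fixed cutoff
#'
#' Calls each sample positive iff its score exceeds `cutoff` and tallies the
#' 2x2 confusion table against the true classes, together with plot-ready
#' per-sample scores (violin plot) and per-class prediction fractions
#' (pie chart).
#'
#' @param scores Numeric scores, one per sample.
#' @param classes Class labels aligned with `scores`.
#' @param cutoff Finite decision threshold.
#' @param positive_label The case-class label.
#' @return An object of class `prediction_summary`: counts `tp`, `fp`, `tn`,
#'   `fn`; `samples`, a tibble (`score`, `class`, `predicted`, `category`);
#'   and `fractions`, per-class fractions of TP/FN (cases) and TN/FP
#'   (controls).
#' @export
predictions <- function(scores, classes, cutoff, positive_label) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite")
  called <- scores > cutoff
  is_case <- classes == positive_label
  category <- dplyr::case_when(
    called & is_case ~ "TP",
    called & !is_case ~ "FP",
    !called & !is_case ~ "TN",
    TRUE ~ "FN"
  )
  counts <- c(tp = sum(category == "TP"), fp = sum(category == "FP"),
              tn = sum(category == "TN"), fn = sum(category == "FN"))
  samples <- tibble::tibble(score = as.numeric(scores),
                            class = as.character(classes),
                            predicted = ifelse(called, "positive", "negative"),
                            category = category)
  fractions <- samples |>
    dplyr::count(.data$class, .data$category) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(tp = counts[["tp"]], fp = counts[["fp"]],
                 tn = counts[["tn"]], fn = counts[["fn"]],
                 cutoff = cutoff, samples = samples, fractions = fractions),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat(sprintf("<prediction_summary> cutoff %.4g: TP=%d FP=%d TN=%d FN=%d\n",
              x$cutoff, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC comparison table for a set of combinations
#'
#' Computes a score, ROC curve and Youden-optimal operating point for each
#' requested combination (typically the gold table) and summarizes them in
#' one row per combo. AUC, SE and SP are reported as fractions in `[0, 1]`.
#'
#' @param dataset A [marker_dataset()].
#' @param combos A `combo_performance` tibble (e.g. from [select_gold()]), or
#'   anything with `combo_id`, `markers` and `members` columns.
#' @param method Score construction, see [combo_score()].
#' @param thr Signal cutoff for the count score.
#' @return A tibble: `combo_id`, `markers`, `size`, `auc`, `se`, `sp`,
#'   `cutoff`, plus a `roc` list column holding each `panel_roc`.
#' @export
roc_report <- function(dataset, combos, method = c("glm", "count"),
                       thr = NULL) {
  method <- match.arg(method)
  if (nrow(combos) == 0) stop("`combos` is empty")
  dataset <- drop_incomplete(dataset)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    members <- combos$members[[i]]
    sc <- combo_score(dataset, members, method = method, thr = thr)
    roc <- roc_curve(sc, dataset$classes, dataset$positive_label)
    tibble::tibble(combo_id = combos$combo_id[i],
                   markers = combos$markers[i],
                   size = length(members),
                   auc = roc$auc,
                   se = roc$optimal$se, sp = roc$optimal$sp,
                   cutoff = roc$optimal$cutoff,
                   roc = list(roc))
  })
  dplyr::bind_rows(rows)
}
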