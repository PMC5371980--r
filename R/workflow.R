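#' Run the full marker-panel selection workflow
#'
#' Executes the two-phase pipeline end to end: optional preprocessing, then
#' exhaustive combinatorial SE/SP analysis under the stringency rule, gold
#' selection, ROC evaluation of every gold combination, and prediction
#' summaries at each combination's Youden-optimal cutoff. Optionally writes
#' all tables as CSV plus a JSON run manifest recording every parameter, so
#' inputs plus manifest fully determine the outputs.
#'
#' @param dataset A [marker_dataset()].
#' @param stringency A [stringency()] object.
#' @param se_min,sp_min Gold-filter minima in percent.
#' @param log,scaling Preprocessing options, see [transform_dataset()].
#' @param score Combination score construction, see [combo_score()].
#' @param out_dir Optional output directory; created if needed.
#' @return A list of class `panel_workflow`: `summary` (dataset summary),
#'   `combos` (all combinations with gold flags), `gold` (gold subset),
#'   `histogram`, `bubble`, `roc_report` (`NULL` when the gold set is empty),
#'   `predictions` (named list per gold combo), and `manifest` (parameters).
#' @export
run_workflow <- function(dataset, stringency, se_min, sp_min,
                         log = FALSE, scaling = "none",
                         score = c("glm", "count"), out_dir = NULL) {
  score <- match.arg(score)
  transformed <- transform_dataset(dataset, log = log, scaling = scaling)
  summary <- summarize_dataset(transformed)
  combos <- combinatorial_analysis(transformed, stringency)
  combos <- flag_gold(combos, se_min, sp_min)
  gold <- combos[combos$gold, , drop = FALSE]
  histogram <- se_sp_histogram(combos)
  bubble <- bubble_table(combos, se_min, sp_min)

  report <- NULL
  preds <- list()
  if (nrow(gold) == 0) {
    warning("gold set is empty at SE >= ", se_min, "%, SP >= ", sp_min,
            "%; ROC stage skipped", call. = FALSE)
  } else {
    report <- roc_report(transformed, gold, method = score,
                         thr = stringency$thr)
    complete <- drop_incomplete(transformed)
    preds <- lapply(seq_len(nrow(report)), function(i) {
      sc <- combo_score(complete, gold$members[[i]], method = score,
                        thr = stringency$thr)
      predictions(sc, complete$classes, report$cutoff[i],
                  complete$positive_label)
    })
    names(preds) <- report$combo_id
  }

  manifest <- list(
    n_samples = n_samples(dataset), n_markers = n_markers(dataset),
    positive_label = dataset$positive_label,
    thr = stringency$thr, minf = stringency$minf,
    se_min = se_min, sp_min = sp_min,
    log = log, scaling = scaling, score = score,
    n_combos = nrow(combos), n_gold = nrow(gold)
  )
  out <- structure(
    list(summary = summary, combos = combos, gold = gold,
         histogram = histogram, bubble = bubble, roc_report = report,
         predictions = preds, manifest = manifest),
    class = "panel_workflow"
  )
  if (!is.null(out_dir)) write_workflow(out, out_dir)
  out
}

#' @export
print.panel_workflow <- function(x, ...) {
  m <- x$manifest
  cat("<panel_workflow> ", m$n_samples, " samples x ", m$n_markers,
      " markers; thr = ", m$thr, ", minf = ", m$minf, "\n", sep = "")
  cat("  ", m$n_combos, " combinations, ", m$n_gold, " gold at SE >= ",
      m$se_min, "%, SP >= ", m$sp_min, "%\n", sep = "")
  if (!is.null(x$roc_report)) {
    top <- x$roc_report[order(-x$roc_report$auc), ]
    cat("  best by AUC: ", top$combo_id[1], " (", top$markers[1], "), AUC = ",
        sprintf("%.3f", top$auc[1]), "\n", sep = "")
  }
  invisible(x)
}

# Flatten tables to CSV plus a JSON manifest under `out_dir`.
write_workflow <- function(wf, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(df) df[, setdiff(names(df), c("members", "roc")), drop = FALSE]
  utils::write.csv(strip(wf$combos), file.path(out_dir, "combo_list.csv"),
                   row.names = FALSE)
  utils::write.csv(strip(wf$gold), file.path(out_dir, "gold_table.csv"),
                   row.names = FALSE)
  utils::write.csv(wf$histogram, file.path(out_dir, "se_sp_histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(wf$bubble, file.path(out_dir, "bubble_table.csv"),
                   row.names = FALSE)
  if (!is.null(wf$roc_report))
    utils::write.csv(strip(wf$roc_report), file.path(out_dir, "roc_report.csv"),
                     row.names = FALSE)
  if (length(wf$predictions)) {
    counts <- dplyr::bind_rows(lapply(names(wf$predictions), function(id) {
      p <- wf$predictions[[id]]
      tibble::tibble(combo_id = id, cutoff = p$cutoff,
                     tp = p$tp, fp = p$fp, tn = p$tn, fn = p$fn)
    }))
    utils::write.csv(counts, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(wf$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
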