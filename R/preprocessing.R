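#' Transform marker values before combinatorial analysis
#'
#' Applies an optional natural-log transform followed by optional per-marker
#' scaling. Autoscaling (unit-variance scaling) centres each marker and divides
#' by its standard deviation; Pareto scaling divides by the square root of the
#' standard deviation, damping — rather than removing — the dominance of
#' high-variance markers. The order of operations is fixed: log first, then
#' scaling. Scaling statistics are pooled over all samples (both classes),
#' since transforms precede any class-aware analysis, and standard deviations
#' use the n − 1 denominator.
#'
#' Note that scaling changes the meaning of a signal threshold: a `thr` chosen
#' in raw fluorescence units is not comparable to autoscaled values.
#'
#' @param dataset A [marker_dataset()].
#' @param log Apply `log()` elementwise first? Requires all values > 0.
#' @param scaling One of `"none"`, `"autoscale"`, `"pareto"`.
#' @return A transformed [marker_dataset()].
#' @export
transform_dataset <- function(dataset, log = FALSE,
                              scaling = c("none", "autoscale", "pareto")) {
  scaling <- match.arg(scaling)
  vals <- dataset$values
  if (log) {
    bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      show <- utils::head(bad, 5)
      stop("log transform requires strictly positive values; offending cells: ",
           paste(sprintf("[%s, %s]", rownames(vals)[show[, 1]],
                         colnames(vals)[show[, 2]]), collapse = ", "),
           if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5) else "")
    }
    vals <- base::log(vals)
  }
  if (scaling != "none") {
    mu <- colMeans(vals, na.rm = TRUE)
    sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
    zero <- which(sdv == 0 | is.na(sdv))
    if (length(zero))
      stop("cannot scale marker(s) with zero standard deviation: ",
           paste(colnames(vals)[zero], collapse = ", "))
    fac <- switch(scaling, autoscale = sdv, pareto = sqrt(sdv))
    vals <- sweep(sweep(vals, 2, mu, "-"), 2, fac, "/")
  }
  marker_dataset(vals, dataset$classes,
                 positive_label = dataset$positive_label,
                 sample_ids = dataset$sample_ids,
                 marker_names = dataset$marker_names)
}
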