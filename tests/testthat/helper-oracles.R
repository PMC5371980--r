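# Independent brute-force oracles, deliberately written against the raw data
# structures rather than through the package's own code paths.

# Explicit 2x2 contingency table for one marker subset under the stringency
# rule: loops over samples, counts exceedances one by one.
oracle_se_sp <- function(values, classes, positive_label, members, thr, minf) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(values))) {
    n_pos <- 0L
    for (m in members) if (values[i, m] > thr) n_pos <- n_pos + 1L
    call_pos <- n_pos >= minf
    is_case <- classes[i] == positive_label
    if (call_pos && is_case) tp <- tp + 1L
    else if (call_pos && !is_case) fp <- fp + 1L
    else if (!call_pos && !is_case) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(se = 100 * tp / (tp + fn), sp = 100 * tn / (tn + fp))
}

# Tie-corrected pairwise concordance probability: P(case > control) + 0.5
# P(case == control), enumerated over all case/control pairs.
oracle_auc <- function(scores, classes, positive_label) {
  cases <- scores[classes == positive_label]
  controls <- scores[classes != positive_label]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(cases) * length(controls))
}

# Exhaustive Youden scan over every candidate threshold (unique scores plus
# sentinels), applying the documented tie-breaks.
oracle_optimal_cutoff <- function(scores, classes, positive_label) {
  is_case <- classes == positive_label
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    calls <- scores > t
    se <- mean(calls[is_case]); sp <- mean(!calls[!is_case])
    j <- round(se + sp - 1, 10)
    if (is.null(best) || j > best$j ||
        (j == best$j && round(sp, 10) > round(best$sp, 10)) ||
        (j == best$j && round(sp, 10) == round(best$sp, 10) && t < best$cutoff))
      best <- list(cutoff = t, se = se, sp = sp, j = j)
  }
  best
}

# Small deterministic dataset: 3 cases, 3 controls, one marker.
tiny_dataset <- function() {
  marker_dataset(
    matrix(c(3, 5, 7, 1, 4, 6), ncol = 1,
           dimnames = list(paste0("s", 1:6), "m1")),
    classes = c("disease", "disease", "disease", "healthy", "healthy", "healthy"),
    positive_label = "disease"
  )
}

# Random multi-marker dataset for property tests.
random_dataset <- function(n_cases = 15, n_controls = 20, n_markers = 6,
                           seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rlnorm(n_markers * (n_cases + n_controls),
                          meanlog = 6, sdlog = 0.5),
                   ncol = n_markers,
                   dimnames = list(NULL, paste0("m", seq_len(n_markers))))
    vals[seq_len(n_cases), ] <- vals[seq_len(n_cases), ] * 1.5
    marker_dataset(vals,
                   classes = c(rep("case", n_cases), rep("ctrl", n_controls)),
                   positive_label = "case",
                   sample_ids = paste0("s", seq_len(n_cases + n_controls)))
  })
}

write_tmp_dataset <- function(dataset, delim = ",") {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  write_marker_dataset(dataset, path, delim = delim)
  path
}
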