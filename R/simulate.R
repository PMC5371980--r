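#' Simulate a two-class marker dataset
#'
#' Generates a case/control marker table with controlled statistical
#' structure, so every analysis stage can be exercised without external data.
#' Values are drawn per class from a multivariate location/scale model with an
#' equicorrelated dependence between markers, then clipped from below at a
#' detection floor, emulating the background signal of fluorescence assays.
#'
#' Under the default `model = "lognormal"`, `case_location`/`control_location`
#' and the `*_scale` parameters are the mean and SD of the markers on the
#' natural-log scale (the signal is `exp` of a correlated Gaussian): positive,
#' right-skewed intensities, as produced by protein microarrays. With
#' `model = "gaussian"` they are the mean and SD on the raw scale.
#'
#' The defaults mirror a serological screen: 40 cases vs 130 controls, five
#' markers. Control signal is a tight log-normal background centred near 300
#' fluorescence units (so a positivity threshold of 450, i.e. mean background
#' plus three SDs, is only rarely exceeded by controls), case signal is
#' centred near 700 units with much larger spread (heterogeneous patient
#' responses), markers are moderately correlated, and a detection floor of 50
#' units clips the left tail.
#'
#' @param n_cases,n_controls Per-class sample counts (>= 1).
#' @param n_markers Number of markers.
#' @param case_location,control_location Per-class marker locations; scalars
#'   are recycled to `n_markers`.
#' @param case_scale,control_scale Per-class marker scales (> 0); recycled.
#' @param correlation Common inter-marker correlation in `[-1, 1]`; must keep
#'   the equicorrelation matrix positive semi-definite
#'   (`correlation >= -1/(n_markers - 1)`).
#' @param floor Detection floor: values are clipped to `>= floor`.
#' @param model `"lognormal"` (default) or `"gaussian"`.
#' @param seed Integer RNG seed; the output is fully reproducible given it.
#' @param case_label,control_label Class labels.
#' @param marker_names Optional marker names (default `marker1..markerN`).
#' @return A [marker_dataset()] with `n_cases + n_controls` samples; cases
#'   first, the case label designated positive.
#' @export
simulate_marker_data <- function(n_cases = 40, n_controls = 130,
                                 n_markers = 5,
                                 case_location = log(700), control_location = log(300),
                                 case_scale = 0.9, control_scale = 0.35,
                                 correlation = 0.2, floor = 50,
                                 model = c("lognormal", "gaussian"),
                                 seed = 1,
                                 case_label = "case", control_label = "control",
                                 marker_names = NULL) {
  model <- match.arg(model)
  stopifnot(n_cases >= 1, n_controls >= 1, n_markers >= 1)
  if (n_markers > 1 && (correlation < -1 / (n_markers - 1) || correlation > 1))
    stop("equicorrelation ", correlation, " is not positive semi-definite for ",
         n_markers, " markers (needs >= ", round(-1 / (n_markers - 1), 4), ")")
  case_location <- rep_len(case_location, n_markers)
  control_location <- rep_len(control_location, n_markers)
  case_scale <- rep_len(case_scale, n_markers)
  control_scale <- rep_len(control_scale, n_markers)
  if (any(c(case_scale, control_scale) <= 0)) stop("scales must be > 0")
  if (is.null(marker_names)) marker_names <- paste0("marker", seq_len(n_markers))

  cor_mat <- matrix(correlation, n_markers, n_markers)
  diag(cor_mat) <- 1
  draw <- function(n, loc, scale) {
    sigma <- diag(scale, n_markers) %*% cor_mat %*% diag(scale, n_markers)
    x <- MASS::mvrnorm(n, mu = loc, Sigma = sigma)
    x <- matrix(x, nrow = n)  # mvrnorm drops to a vector when n = 1
    if (model == "lognormal") x <- exp(x)
    x
  }
  vals <- with_seed(seed, rbind(draw(n_cases, case_location, case_scale),
                                draw(n_controls, control_location, control_scale)))
  vals <- pmax(vals, floor)
  colnames(vals) <- marker_names
  marker_dataset(
    vals,
    classes = c(rep(case_label, n_cases), rep(control_label, n_controls)),
    positive_label = case_label,
    sample_ids = sprintf("s%03d", seq_len(n_cases + n_controls)),
    marker_names = marker_names
  )
}
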