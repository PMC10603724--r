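#' Predict body weight from heart girth
#'
#' Quadratic heart-girth predictor of live body weight for goats:
#' BW = 0.0127 HG^2 - 0.69 HG + 14.7, with HG in cm and BW in kg. The
#' curve is strictly increasing for HG above ~27.2 cm, i.e. over the whole
#' adult range.
#'
#' @param hg Heart girth in cm (non-negative, vectorized).
#' @return Predicted body weight in kg.
#' @examples
#' estimate_bw(c(79, 83, 86))
#' @export
estimate_bw <- function(hg) {
  if (any(is.na(hg)) || any(hg < 0)) {
    stop("heart girth must be non-negative", call. = FALSE)
  }
  0.0127 * hg^2 - 0.69 * hg + 14.7
}

#' Descriptive statistics for a morphometric trait
#'
#' Mean, quartiles, standard deviation, 95% confidence interval of the mean
#' (Student t), and sample-adjusted skewness and excess kurtosis for one
#' measurement column of a morphometrics table. Quartiles use linear
#' interpolation (quantile type 7) by default; `quantile_type = 2` matches
#' the SAS UNIVARIATE default.
#'
#' @param table Data frame of per-animal measurements.
#' @param trait Column name to summarize.
#' @param quantile_type Passed to [stats::quantile()] (default 7).
#' @return A one-row tibble: `trait`, `n`, `mean`, `q1`, `median`, `q3`,
#'   `sd`, `ci_lo`, `ci_hi`, `skewness`, `kurtosis` (excess; skewness and
#'   kurtosis are `NA` for constant data, and kurtosis needs at least four
#'   observations).
#' @export
describe_trait <- function(table, trait, quantile_type = 7) {
  if (!trait %in% names(table)) {
    stop("trait not found: ", trait, call. = FALSE)
  }
  x <- table[[trait]]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  s <- stats::sd(x)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  constant <- s == 0
  tibble::tibble(
    trait = trait, n = n, mean = mean(x),
    q1 = q[1], median = q[2], q3 = q[3], sd = s,
    ci_lo = mean(x) - half, ci_hi = mean(x) + half,
    skewness = if (constant) NA_real_ else e1071::skewness(x, type = 2),
    kurtosis = if (constant || n < 4) NA_real_ else
      e1071::kurtosis(x, type = 2))
}
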