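#' Sigmoidal membership normalization
#'
#' Maps a raw indicator value onto (0, 1) with the membership (affiliation)
#' function
#' \deqn{F(x) = E / (1 + (x / X_0)^i)}
#' where \eqn{E = 1} is the maximum membership degree, \eqn{X_0} a
#' per-indicator reference value (conventionally the indicator's mean across
#' evaluated objects), and the slope \eqn{i} encodes polarity: \eqn{i =
#' -2.5} for positive-effect indicators (F increases with x) and \eqn{i =
#' +2.5} for negative-effect indicators (F decreases with x). At \eqn{x =
#' X_0} the membership is 0.5 for either polarity, and the two polarities
#' are complementary: \eqn{F_{+}(r) + F_{-}(r) = 1} at any ratio
#' \eqn{r = x / X_0}.
#'
#' @param x Non-negative indicator value(s).
#' @param x0 Positive reference value.
#' @param polarity `"positive"` or `"negative"` effect direction.
#' @param slope Magnitude of the slope exponent (default 2.5).
#' @return Membership value(s) in \eqn{(0, 1)} (the limit 0 is returned for
#'   `x = 0` with positive polarity).
#' @export
#' @examples
#' membership_normalize(2, 1)                        # 0.8498
#' membership_normalize(2, 1, polarity = "negative") # 0.1502
membership_normalize <- function(x, x0, polarity = c("positive", "negative"),
                                 slope = 2.5) {
  polarity <- match.arg(polarity)
  if (any(x0 <= 0)) abort("reference value x0 must be positive.")
  if (any(x < 0)) abort("indicator values must be non-negative.")
  i <- if (polarity == "positive") -slope else slope
  r <- x / x0
  out <- 1 / (1 + r^i)
  # x = 0 with a positive-effect slope is the 0/0 limit of the ratio form
  out[r == 0] <- if (polarity == "positive") 0 else 1
  out
}

#' Membership-normalize an indicator matrix
#'
#' Applies [membership_normalize()] column-wise to a site x indicator
#' tibble, using each indicator's mean across rows as the reference value
#' \eqn{X_0} and the supplied polarity to choose the slope sign.
#'
#' @param data Tibble whose numeric indicator columns are to be normalized;
#'   identifier columns (`plot_id`, `land_type`, ...) pass through.
#' @param polarity Named character vector of `"positive"` / `"negative"`
#'   per indicator column; defaults to [indicator_polarity()] for the
#'   standard twenty indicators, `"positive"` for unknown columns.
#' @param x0 Optional named numeric of reference values, overriding the
#'   column means.
#' @param slope Slope magnitude, as in [membership_normalize()].
#' @return A tibble of the same shape with indicator columns in (0, 1), and
#'   the reference values in attribute `"x0"`.
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 5))
#' im <- build_indicator_matrix(study$quadrats, study$soil)
#' normalize_indicators(im)
normalize_indicators <- function(data, polarity = indicator_polarity(),
                                 x0 = NULL, slope = 2.5) {
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num_cols) == 0) abort("no numeric indicator columns found.")
  refs <- setNames(numeric(0), character(0))
  out <- data
  for (col in num_cols) {
    ref <- if (!is.null(x0) && col %in% names(x0)) x0[[col]]
           else mean(data[[col]])
    if (ref <= 0) {
      abort(paste0("reference mean for indicator '", col,
                   "' is not positive; cannot normalize."))
    }
    pol <- if (col %in% names(polarity)) polarity[[col]] else "positive"
    out[[col]] <- membership_normalize(data[[col]], ref, polarity = pol,
                                       slope = slope)
    refs[col] <- ref
  }
  attr(out, "x0") <- refs
  out
}
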