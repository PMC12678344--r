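#' Communalities, weights and variance contributions
#'
#' Small arithmetic helpers of the PCA-based weighting scheme, usable
#' directly on published loading tables:
#' `communalities_from_loadings()` sums squared loadings across the
#' retained components for every indicator; `weights_from_communalities()`
#' normalises communalities to weights summing to one;
#' `variance_contribution()` converts correlation-matrix eigenvalues to
#' percentage contributions (eigenvalue / number of indicators x 100).
#'
#' @param loadings Numeric matrix (indicators x retained components) or a
#'   data frame of loading columns.
#' @return `communalities_from_loadings()`: named numeric vector.
#' @export
#' @examples
#' communalities_from_loadings(rbind(silt = c(0.982, -0.047))) # 0.9665
communalities_from_loadings <- function(loadings) {
  m <- as.matrix(loadings)
  rowSums(m^2)
}

#' @rdname communalities_from_loadings
#' @param communalities Non-negative numeric vector.
#' @export
weights_from_communalities <- function(communalities) {
  if (any(communalities < 0)) abort("communalities must be non-negative.")
  if (sum(communalities) <= 0) abort("communalities must not all be zero.")
  communalities / sum(communalities)
}

#' @rdname communalities_from_loadings
#' @param eigenvalues Eigenvalues of the correlation matrix, descending.
#' @param n_indicators Number of indicators entering the PCA.
#' @export
variance_contribution <- function(eigenvalues, n_indicators) {
  eigenvalues / n_indicators * 100
}

#' PCA-communality indicator weights
#'
#' Derives objective indicator weights from a correlation-matrix principal
#' component analysis of the site-level indicator matrix. Components are
#' retained by the joint rule: every retained component has an eigenvalue
#' of at least `eigen_min` *and* the retained set reaches a cumulative
#' variance contribution of at least `cum_min` percent; if the
#' eigenvalue rule alone falls short of `cum_min`, further components are
#' added (with a warning) until the cumulative rule is met. Loadings are
#' eigenvectors scaled by the square root of their eigenvalue, each
#' component oriented so that its largest-magnitude loading is positive.
#' An indicator's communality is the sum of its squared retained loadings,
#' and its weight is its communality divided by the total communality.
#'
#' @param data Site x indicator tibble (identifier columns pass through);
#'   typically the membership-normalized matrix from
#'   [normalize_indicators()].
#' @param eigen_min Minimum eigenvalue of a retained component (default 1).
#' @param cum_min Minimum cumulative variance contribution in percent
#'   (default 85).
#'
#' @return An object of class `pca_weighting`: a list with `eigenvalues`,
#'   `contribution` and `cumulative` (percent), `retained`, `loadings`
#'   (indicators x retained matrix), `communalities`, `weights` (sums to
#'   1), and `n_indicators`.
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 6))
#' im <- build_indicator_matrix(study$quadrats, study$soil)
#' w <- pca_weights(normalize_indicators(im))
#' tidy(w)
pca_weights <- function(data, eigen_min = 1, cum_min = 85) {
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(data[num_cols])
  if (nrow(x) < 3) abort("PCA weighting needs at least 3 rows (sites).")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste("zero-variance indicator column(s):",
                paste(num_cols[sds == 0], collapse = ", ")))
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  p <- ncol(x)
  contrib <- variance_contribution(eig, p)
  cum <- cumsum(contrib)

  k_eigen <- sum(eig >= eigen_min)
  k <- max(k_eigen, 1L)
  if (cum[k] < cum_min) {
    k_cum <- which(cum >= cum_min)[1]
    if (is.na(k_cum)) k_cum <- length(eig)
    warn(sprintf(paste("components with eigenvalue >= %g reach only %.1f%%",
                       "cumulative contribution; extending retention from %d to %d",
                       "components to reach %g%%."),
                 eigen_min, cum[k], k, k_cum, cum_min))
    k <- k_cum
  }

  load <- pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig[seq_len(k)]), nrow = k)
  colnames(load) <- paste0("PC", seq_len(k))
  # component signs are arbitrary; orient the largest loading positive
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  comm <- communalities_from_loadings(load)
  structure(
    list(eigenvalues = eig, contribution = contrib, cumulative = cum,
         retained = k, loadings = load, communalities = comm,
         weights = weights_from_communalities(comm), n_indicators = p),
    class = "pca_weighting"
  )
}

#' @export
print.pca_weighting <- function(x, ...) {
  cat("<pca_weighting>\n")
  cat(sprintf("  %d indicators, %d retained component(s), cumulative contribution %.1f%%\n",
              x$n_indicators, x$retained, x$cumulative[x$retained]))
  cat("  top-weighted indicators:\n")
  top <- sort(x$weights, decreasing = TRUE)[seq_len(min(5, length(x$weights)))]
  for (nm in names(top)) cat(sprintf("    %-16s %.4f\n", nm, top[[nm]]))
  invisible(x)
}

#' @rdname pca_weights
#' @param x A `pca_weighting` object.
#' @param ... Unused.
#' @export
tidy.pca_weighting <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(indicator = rownames(x$loadings)),
    tibble::as_tibble(x$loadings),
    tibble::tibble(communality = unname(x$communalities),
                   weight = unname(x$weights))
  )
}

#' @rdname pca_weights
#' @export
glance.pca_weighting <- function(x, ...) {
  tibble::tibble(
    n_indicators = x$n_indicators,
    retained = x$retained,
    cumulative_contribution = x$cumulative[x$retained],
    total_communality = sum(x$communalities)
  )
}

#' @rdname pca_weights
#' @param object A `pca_weighting` object.
#' @export
autoplot.pca_weighting <- function(object, ...) {
  d <- tidy(object) |>
    mutate(indicator = stats::reorder(.data$indicator, .data$weight))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$indicator)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "indicator weight (communality share)", y = NULL) +
    ggplot2::theme_minimal()
}
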