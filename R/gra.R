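#' Grey relational coefficients
#'
#' Computes the grey relational coefficient of every evaluated sequence
#' against a reference sequence. With deviations
#' \eqn{\Delta_p(h) = |X_t(h) - X_p(h)|} and the two-level extrema
#' \eqn{\Delta_{min} = \min_p \min_h \Delta_p(h)},
#' \eqn{\Delta_{max} = \max_p \max_h \Delta_p(h)} taken over all objects
#' and indicators,
#' \deqn{\xi_p(h) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta_p(h) + \rho\,\Delta_{max}}}
#' where the resolution coefficient \eqn{\rho \in (0, 1)} damps the
#' influence of the maximum deviation (conventionally 0.5). If all
#' sequences equal the reference (\eqn{\Delta_{max} = 0}) every coefficient
#' is 1.
#'
#' @param x Numeric matrix (objects x indicators) of evaluated sequences,
#'   or a data frame whose numeric columns are the indicators.
#' @param reference Numeric vector, the reference sequence (one value per
#'   indicator).
#' @param rho Resolution coefficient in (0, 1).
#' @return Matrix of coefficients in (0, 1], same shape and dimnames as
#'   `x`.
#' @export
#' @examples
#' xi <- grey_relational_coefficients(rbind(A = c(1, 0.5), B = c(0.5, 1)),
#'                                    reference = c(1, 1))
#' xi  # A: (1, 1/3); B: (1/3, 1)
grey_relational_coefficients <- function(x, reference, rho = 0.5) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  }
  if (length(x) == 0 || nrow(x) == 0) abort("evaluated sequences are empty.")
  if (ncol(x) != length(reference)) {
    abort(sprintf("reference length (%d) does not match the number of indicators (%d).",
                  length(reference), ncol(x)))
  }
  if (rho <= 0 || rho >= 1) abort("rho must lie strictly between 0 and 1.")
  delta <- abs(sweep(x, 2, reference))
  dmin <- min(delta)
  dmax <- max(delta)
  if (dmax == 0) {
    xi <- delta + 1  # all sequences identical to the reference
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  xi
}

#' Grey relevance of evaluated objects
#'
#' Collapses a coefficient matrix to one score per object: the equal-weight
#' relevance \eqn{\gamma_p = \frac{1}{n}\sum_h \xi_p(h)} and, if indicator
#' weights are supplied, the weighted relevance
#' \eqn{R_p = \sum_h \xi_p(h) K(h)} with \eqn{\sum_h K(h) = 1}.
#'
#' @param xi Coefficient matrix from [grey_relational_coefficients()].
#' @param weights Optional numeric weights over indicators, summing to 1;
#'   `NULL` gives `weighted = gamma` (uniform weights).
#' @return A tibble with `object`, `gamma`, `weighted`.
#' @export
#' @examples
#' xi <- rbind(A = c(1, 1/3))
#' relevance(xi, weights = c(0.8, 0.2)) # gamma 0.667, weighted 0.867
relevance <- function(xi, weights = NULL) {
  if (is.null(weights)) {
    weights <- rep(1 / ncol(xi), ncol(xi))
  }
  if (length(weights) != ncol(xi)) {
    abort(sprintf("weight vector length (%d) does not match the number of indicators (%d).",
                  length(weights), ncol(xi)))
  }
  if (any(weights < 0)) abort("weights must be non-negative.")
  if (abs(sum(weights) - 1) > 1e-6) {
    abort(sprintf("weights must sum to 1 (got %.8f).", sum(weights)))
  }
  tibble::tibble(
    object = rownames(xi) %||% as.character(seq_len(nrow(xi))),
    gamma = unname(rowMeans(xi)),
    weighted = as.numeric(xi %*% weights)
  )
}

#' Rank objects by relevance
#'
#' Orders objects by decreasing relevance. Ties share the best applicable
#' rank and subsequent ranks are skipped (competition ranking: two objects
#' tied at rank 1 are followed by rank 3).
#'
#' @param relevances Named numeric vector, or a tibble with `object` and a
#'   relevance column (`weighted` preferred, else `gamma`).
#' @return A tibble `object`, `relevance`, `rank`, sorted best-first.
#' @export
#' @examples
#' rank_objects(c(CK = 0.8574, SP = 0.7790, HS = 0.6883, BS = 0.5637))
rank_objects <- function(relevances) {
  if (is.data.frame(relevances)) {
    col <- intersect(c("weighted", "gamma", "relevance"), names(relevances))[1]
    if (is.na(col)) abort("no relevance column found (weighted/gamma/relevance).")
    v <- setNames(relevances[[col]], relevances$object)
  } else {
    v <- relevances
    if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  }
  if (length(v) == 0) abort("at least one object is required.")
  tibble::tibble(
    object = names(v),
    relevance = unname(v),
    rank = unname(rank(-v, ties.method = "min"))
  ) |>
    arrange(.data$rank, .data$object)
}

#' Grey relational evaluation of an indicator matrix
#'
#' Runs the full comprehensive-evaluation stage: membership-normalizes the
#' site-level indicator matrix, derives PCA-communality weights from it,
#' aggregates the normalized values to evaluation objects (land types by
#' default, sites optionally), builds the reference sequence, and computes
#' grey relational coefficients, equal-weight relevance, weighted relevance
#' and ranks.
#'
#' The reference sequence defaults to the per-indicator maximum of the
#' normalized values across evaluated objects (an ideal object assembled
#' from the best observed value of every indicator); `reference = "ones"`
#' uses the membership function's upper limit 1 instead.
#'
#' @param indicators Site x indicator tibble from
#'   [build_indicator_matrix()] (columns `plot_id`, `land_type`, and
#'   numeric indicators).
#' @param polarity Named polarity vector, see [indicator_polarity()].
#' @param rho Resolution coefficient, default 0.5.
#' @param weights `"pca"` (default) for PCA-communality weights, `"equal"`
#'   for uniform weights, or a named numeric vector summing to 1.
#' @param objects `"land_type"` to evaluate the land types (site values
#'   averaged per type after normalization), `"site"` to evaluate the
#'   individual sites.
#' @param reference `"max"` or `"ones"` (see above).
#' @param eigen_min,cum_min Component retention thresholds for
#'   [pca_weights()].
#'
#' @return An object of class `gra_result`: list with `scores` (tibble:
#'   `object`, `gamma`, `weighted`, `rank`), `xi` (coefficient matrix),
#'   `site_scores` (per-site gamma/weighted relevance, always computed for
#'   downstream driver analysis), `weighting` (the `pca_weighting`, or
#'   `NULL`), `weights`, `reference`, `rho`, `normalized` (the site-level
#'   normalized matrix).
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 11))
#' im <- build_indicator_matrix(study$quadrats, study$soil)
#' res <- gra_evaluate(im)
#' tidy(res)
gra_evaluate <- function(indicators, polarity = indicator_polarity(),
                         rho = 0.5, weights = "pca",
                         objects = c("land_type", "site"),
                         reference = c("max", "ones"),
                         eigen_min = 1, cum_min = 85) {
  objects <- match.arg(objects)
  reference <- match.arg(reference)
  if (objects == "land_type" && !"land_type" %in% names(indicators)) {
    abort("indicators must carry a land_type column to evaluate land types.")
  }
  norm <- normalize_indicators(indicators, polarity = polarity)
  num_cols <- names(norm)[vapply(norm, is.numeric, logical(1))]

  weighting <- NULL
  if (identical(weights, "pca")) {
    weighting <- pca_weights(norm, eigen_min = eigen_min, cum_min = cum_min)
    w <- weighting$weights
  } else if (identical(weights, "equal")) {
    w <- setNames(rep(1 / length(num_cols), length(num_cols)), num_cols)
  } else {
    if (is.null(names(weights)) || !all(num_cols %in% names(weights))) {
      abort("numeric weights must be named by indicator.")
    }
    w <- weights[num_cols]
  }

  object_matrix <- function(group_col) {
    m <- norm |>
      group_by(across(all_of(group_col))) |>
      summarise(across(all_of(num_cols), mean), .groups = "drop")
    mat <- as.matrix(m[num_cols])
    rownames(mat) <- m[[group_col]]
    mat
  }
  eval_one <- function(mat) {
    ref <- if (reference == "max") apply(mat, 2, max) else rep(1, ncol(mat))
    xi <- grey_relational_coefficients(mat, ref, rho = rho)
    list(xi = xi, rel = relevance(xi, weights = w))
  }

  site_mat <- object_matrix("plot_id")
  site_eval <- eval_one(site_mat)
  site_scores <- site_eval$rel |>
    rename(plot_id = "object") |>
    left_join(distinct(indicators, .data$plot_id,
                       land_type = if ("land_type" %in% names(indicators))
                         .data$land_type else NA_character_),
              by = "plot_id") |>
    select("plot_id", "land_type", "gamma", "weighted")

  main <- if (objects == "land_type") {
    eval_one(object_matrix("land_type"))
  } else {
    site_eval
  }
  scores <- main$rel |>
    mutate(rank = rank(-.data$weighted, ties.method = "min")) |>
    arrange(.data$rank, .data$object)

  structure(
    list(scores = scores, xi = main$xi, site_scores = site_scores,
         weighting = weighting, weights = w, reference = reference,
         rho = rho, normalized = norm, objects = objects),
    class = "gra_result"
  )
}

#' @export
print.gra_result <- function(x, ...) {
  cat("<gra_result>  (rho =", x$rho, ", reference =", x$reference, ")\n")
  df <- as.data.frame(x$scores)
  df$gamma <- sprintf("%.4f", df$gamma)
  df$weighted <- sprintf("%.4f", df$weighted)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname gra_evaluate
#' @param x,object A `gra_result`.
#' @param ... Unused.
#' @export
tidy.gra_result <- function(x, ...) {
  x$scores |>
    rename(equal_weight_relevance = "gamma", weighted_relevance = "weighted")
}

#' @rdname gra_evaluate
#' @export
glance.gra_result <- function(x, ...) {
  tibble::tibble(
    n_objects = nrow(x$scores),
    n_indicators = ncol(x$xi),
    rho = x$rho,
    reference = x$reference,
    retained_components = if (is.null(x$weighting)) NA_integer_
                          else x$weighting$retained
  )
}

#' @rdname gra_evaluate
#' @export
autoplot.gra_result <- function(object, ...) {
  d <- object$scores |>
    tidyr::pivot_longer(c("gamma", "weighted"), names_to = "kind",
                        values_to = "relevance") |>
    mutate(kind = dplyr::recode(.data$kind, gamma = "equal weight",
                                weighted = "weighted"),
           object = stats::reorder(.data$object, -.data$relevance))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$object, y = .data$relevance,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "grey relevance", fill = NULL) +
    ggplot2::theme_minimal()
}
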