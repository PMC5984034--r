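#' Configuration for divergence-weighted map transformation
#'
#' @param gamma Negative exponent applied to divergences; weights are
#'   proportional to \eqn{D^\gamma} so they decay with divergence.  The
#'   default is \eqn{\gamma = -4}.
#' @param exclude_infinite If `TRUE` (default), sources at infinite
#'   divergence are dropped from the sums (with \eqn{\gamma < 0} their
#'   weight is zero in any case).
#' @param zero_tol Divergences at or below this tolerance (default
#'   `1e-12`) are treated as exactly zero: the predicted value is the mean
#'   of the source map over exactly those zero-divergence sources, the
#'   analytic limit of the weighted-mean formula as \eqn{D \to 0}.
#' @return Object of class `mapping_config`.
#' @export
mapping_config <- function(gamma = -4, exclude_infinite = TRUE,
                           zero_tol = 1e-12) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma >= 0)
    stop("gamma must be a single negative number (weights must decay with divergence)")
  if (zero_tol < 0) stop("zero_tol must be non-negative")
  structure(list(gamma = gamma, exclude_infinite = isTRUE(exclude_infinite),
                 zero_tol = zero_tol),
            class = "mapping_config")
}

#' Transform a cortical map between species by divergence-weighted interpolation
#'
#' Given the divergence matrix between a target and a source blueprint and
#' a scalar map \eqn{h} on the source surface, predicts the map on the
#' target surface as
#' \deqn{m_j = \frac{\sum_i D_{ji}^{\gamma} h_i}{\sum_i D_{ji}^{\gamma}}}
#' with \eqn{\gamma = -4} by default, i.e. each target vertex receives a
#' weighted mean of the source map with weights decaying steeply in
#' fingerprint divergence.  Target vertices with any zero divergence copy
#' the mean of exactly those zero-divergence sources (the limit of the
#' formula).  The output is a convex combination of `h`, so predicted
#' values always lie within `[min(h), max(h)]`.
#'
#' Weights are computed as `(d / min(d))^gamma` so that the steep exponent
#' cannot overflow for small divergences.
#'
#' @param D A `divergence_matrix`.
#' @param h `surface_scalar_map` (or numeric vector) on the source surface.
#' @param cfg A [mapping_config()].
#' @param sources Which dimension of `D` indexes the source map: `"cols"`
#'   (default; output has one value per row of `D`) or `"rows"`.
#' @return A `surface_scalar_map` on the target surface.
#' @export
transform_map <- function(D, h, cfg = mapping_config(),
                          sources = c("cols", "rows")) {
  sources <- match.arg(sources)
  if (!inherits(cfg, "mapping_config")) stop("cfg must be a mapping_config")
  hv <- if (inherits(h, "surface_scalar_map")) h$values else as.numeric(h)
  V <- if (sources == "cols") D$values else t(D$values)
  target_mask <- if (sources == "cols") D$row_mask else D$col_mask
  source_mask <- if (sources == "cols") D$col_mask else D$row_mask
  if (length(hv) != ncol(V))
    stop("source map length (", length(hv),
         ") does not match the divergence matrix source dimension (",
         ncol(V), ")")
  src_valid <- source_mask & !is.na(hv)
  if (!any(src_valid))
    stop("all source vertices are masked or NA: nothing to interpolate from")
  out <- rep(NA_real_, nrow(V))
  for (j in which(target_mask)) {
    d <- V[j, src_valid]
    hh <- hv[src_valid]
    ok <- !is.na(d)
    if (cfg$exclude_infinite) ok <- ok & is.finite(d)
    if (!any(ok)) next
    d <- d[ok]; hh <- hh[ok]
    zero <- d <= cfg$zero_tol
    if (any(zero)) {
      out[j] <- mean(hh[zero])
    } else {
      w <- (d / min(d))^cfg$gamma  # max weight 1, no overflow
      out[j] <- sum(w * hh) / sum(w)
    }
  }
  surface_scalar_map(out, name = "transformed_map",
                     units = if (inherits(h, "surface_scalar_map")) h$units else "")
}

#' Prediction variability across subject pairs
#'
#' Repeats the between-species map transformation with blueprints built
#' from every subject pair, then summarizes per-vertex variability of the
#' prediction: mean, standard deviation, and the deviation of the observed
#' map from the predicted distribution, \eqn{Z = (\mathrm{mean} -
#' \mathrm{data}) / \mathrm{std}}.
#'
#' @param blueprint_pairs List of length >= 2; each element is a list (or
#'   pair) whose first component is the target-species subject blueprint
#'   and second the source-species subject blueprint.
#' @param h `surface_scalar_map` on the source surface, transformed through
#'   each pair.
#' @param observed Observed `surface_scalar_map` on the target surface.
#' @param cfg A [mapping_config()].
#' @return List of class `prediction_variability` with
#'   `surface_scalar_map`s `mean`, `std` and `z` (vertices with zero
#'   standard deviation carry the `NA` sentinel in `z`), plus
#'   `predictions`, the (vertices x pairs) matrix of per-pair predictions.
#' @export
prediction_variability <- function(blueprint_pairs, h, observed,
                                   cfg = mapping_config()) {
  if (length(blueprint_pairs) < 2L)
    stop("need at least 2 subject pairs to estimate variability")
  preds <- NULL
  for (pair in blueprint_pairs) {
    target_bp <- pair[[1L]]
    source_bp <- pair[[2L]]
    D <- divergence_matrix(target_bp, source_bp)
    m <- transform_map(D, h, cfg, sources = "cols")
    preds <- cbind(preds, m$values)
  }
  obs <- if (inherits(observed, "surface_scalar_map")) observed$values
         else as.numeric(observed)
  if (length(obs) != nrow(preds))
    stop("observed map length (", length(obs),
         ") does not match the target surface (", nrow(preds), ")")
  mean_v <- rowMeans(preds)
  std_v <- apply(preds, 1L, sd)
  z_v <- (mean_v - obs) / std_v
  z_v[!is.na(std_v) & std_v == 0] <- NA_real_
  structure(
    list(mean = surface_scalar_map(mean_v, name = "prediction_mean"),
         std = surface_scalar_map(std_v, name = "prediction_std"),
         z = surface_scalar_map(z_v, name = "prediction_z"),
         predictions = preds, n_pairs = length(blueprint_pairs)),
    class = "prediction_variability")
}
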