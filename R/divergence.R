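# p * log2(p) with the 0 * log 0 = 0 convention, elementwise.
.xlog2x <- function(p) {
  out <- p * log2(p)
  out[p == 0] <- 0
  out
}

# log2 with log2(0) mapped to 0; only valid where multiplied by a factor
# that is itself 0 at those positions (support mismatches handled separately).
.safe_log2 <- function(p) {
  out <- log2(p)
  out[p == 0] <- 0
  out
}

#' One per-vertex scalar on a cortical surface
#'
#' @param values Numeric vector, one value per vertex; `NA` marks a masked
#'   (excluded) vertex.
#' @param mask Optional logical inclusion mask; defaults to `!is.na(values)`.
#'   Values at masked vertices are set to `NA`.
#' @param name Short map name.
#' @param units Free-text units (e.g. `"bits"`).
#' @return Object of class `surface_scalar_map` with fields `values`,
#'   `mask`, `name`, `units`.
#' @export
surface_scalar_map <- function(values, mask = NULL, name = "", units = "") {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.logical(mask)
  if (length(mask) != length(values))
    stop("mask length does not match vertex count")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, name = as.character(name),
                 units = as.character(units)),
            class = "surface_scalar_map")
}

#' @export
print.surface_scalar_map <- function(x, ...) {
  cat("surface_scalar_map '", x$name, "': ", length(x$values), " vertices (",
      sum(x$mask), " unmasked)", if (nzchar(x$units)) paste0(" [", x$units, "]"),
      "\n", sep = "")
  v <- x$values[x$mask]
  if (length(v)) cat("  range: ", format(min(v)), " .. ", format(max(v)), "\n",
                     sep = "")
  invisible(x)
}

#' @export
length.surface_scalar_map <- function(x) length(x$values)

# Validate a fingerprint vector: non-negative, sums to 1 within tol.
.check_fingerprint <- function(p, tol = 1e-6, what = "fingerprint") {
  if (anyNA(p)) stop(what, " contains NA")
  if (any(p < 0)) stop(what, " has negative entries")
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop(what, " is not normalized: sums to ", format(s),
         " (tolerance ", format(tol), ")")
  invisible(TRUE)
}

#' Symmetric Kullback-Leibler divergence between two fingerprints
#'
#' The dissimilarity measure used throughout the blueprint framework:
#' \deqn{D(p, q) = \sum_k p_k \log_2(p_k/q_k) + \sum_k q_k \log_2(q_k/p_k)}
#' in bits.  Terms with \eqn{p_k = 0} contribute 0 to the first sum (the
#' \eqn{0 \log 0 = 0} convention) and symmetrically for the second.  If one
#' distribution has support where the other is exactly zero the divergence
#' is infinite; blueprints built with the default epsilon floor never hit
#' this case.
#'
#' @param p,q Numeric probability vectors of equal length, each summing to
#'   1 within `tol`.
#' @param tol Normalization tolerance (default `1e-6`).
#' @return Non-negative divergence in bits; `Inf` (with a warning) on a
#'   support mismatch.
#' @examples
#' symmetric_kl(c(0.5, 0.5), c(0.25, 0.75))
#' @export
symmetric_kl <- function(p, q, tol = 1e-6) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    stop("fingerprints have different lengths (", length(p), " vs ",
         length(q), ")")
  .check_fingerprint(p, tol, "first fingerprint")
  .check_fingerprint(q, tol, "second fingerprint")
  dir_kl <- function(a, b) {
    i <- a > 0
    if (any(b[i] == 0)) return(Inf)
    sum(a[i] * log2(a[i] / b[i]))
  }
  d <- dir_kl(p, q) + dir_kl(q, p)
  if (!is.finite(d)) {
    warning("support mismatch between fingerprints: divergence is infinite ",
            "(consider an epsilon floor)")
    return(Inf)
  }
  max(d, 0)
}

# Vectorized symmetric KL between all rows of M (nA x K) and all rows of
# H (nB x K); rows assumed non-negative and normalized.  Decomposes
# D_ij = a_i + b_j - sum_k M_ik log2 H_jk - sum_k H_jk log2 M_ik,
# with support mismatches patched to +Inf afterwards.
.skl_cross <- function(M, H) {
  a <- rowSums(.xlog2x(M))
  b <- rowSums(.xlog2x(H))
  D <- outer(a, b, `+`) - M %*% t(.safe_log2(H)) - .safe_log2(M) %*% t(H)
  mzero <- M == 0
  hzero <- H == 0
  if (any(mzero) || any(hzero)) {
    mismatch <- ((!mzero) + 0) %*% t(hzero + 0) + (mzero + 0) %*% t((!hzero) + 0)
    D[mismatch > 0] <- Inf
  }
  D[D < 0] <- 0  # clip tiny negative rounding noise
  D
}

#' Pairwise divergence matrix between two blueprints
#'
#' Computes the symmetric KL divergence between every unmasked fingerprint
#' of blueprint `A` and every unmasked fingerprint of blueprint `B`.
#' Within-species usage (`A` identical to `B`) is permitted and yields a
#' zero diagonal.
#'
#' @param A,B `connectivity_blueprint`s over identical tract sets.
#' @param tol Row-normalization tolerance.
#' @return An object of class `divergence_matrix`: fields `values`
#'   (n_A x n_B, `NA` at masked rows/columns), `row_mask`, `col_mask`,
#'   `units = "bits"`.
#' @export
divergence_matrix <- function(A, B, tol = 1e-6) {
  .check_tracts_match(A$tracts, B$tracts)
  Msub <- A$matrix[A$vertex_mask, , drop = FALSE]
  Hsub <- B$matrix[B$vertex_mask, , drop = FALSE]
  if (nrow(Msub)) {
    bad <- which(abs(rowSums(Msub) - 1) > tol)
    if (length(bad)) stop("blueprint A row ", bad[1L], " is not normalized")
  }
  if (nrow(Hsub)) {
    bad <- which(abs(rowSums(Hsub) - 1) > tol)
    if (length(bad)) stop("blueprint B row ", bad[1L], " is not normalized")
  }
  vals <- base::matrix(NA_real_, n_vertices(A), n_vertices(B))
  vals[A$vertex_mask, B$vertex_mask] <- .skl_cross(Msub, Hsub)
  structure(list(values = vals, row_mask = A$vertex_mask,
                 col_mask = B$vertex_mask, units = "bits"),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat("divergence_matrix: ", nrow(x$values), " x ", ncol(x$values),
      " [", x$units, "], ", sum(x$row_mask), " x ", sum(x$col_mask),
      " unmasked\n", sep = "")
  invisible(x)
}

#' @export
dim.divergence_matrix <- function(x) dim(x$values)

#' Minimum-divergence (connectional dissimilarity) map
#'
#' For each vertex of one blueprint, the minimum divergence to all unmasked
#' vertices of the other species.  High values flag cortex whose
#' connectivity fingerprint has no good match in the other brain, i.e.
#' likely connectional reorganization since the common ancestor.
#'
#' @param D A `divergence_matrix`.
#' @param over `"rows"` (default) produces one value per row vertex
#'   (minimum over columns); `"cols"` the transpose direction.
#' @return A `surface_scalar_map` (units bits) with an `argmin` attribute:
#'   for every unmasked vertex, the index of the closest vertex in the
#'   other blueprint (smallest index on ties).
#' @export
min_divergence_map <- function(D, over = c("rows", "cols")) {
  over <- match.arg(over)
  V <- if (over == "rows") D$values else t(D$values)
  mask <- if (over == "rows") D$row_mask else D$col_mask
  other_mask <- if (over == "rows") D$col_mask else D$row_mask
  n <- nrow(V)
  vals <- rep(NA_real_, n)
  amin <- rep(NA_integer_, n)
  keep <- which(other_mask)
  for (i in which(mask)) {
    row <- V[i, keep]
    if (!length(row) || all(is.na(row))) next
    j <- which.min(row)       # first minimum = smallest index
    vals[i] <- row[j]
    amin[i] <- keep[j]
  }
  out <- surface_scalar_map(vals, name = "min_divergence", units = D$units)
  attr(out, "argmin") <- amin
  out
}

#' Search a blueprint for a given connectivity fingerprint
#'
#' Computes the symmetric KL divergence between a query fingerprint (e.g.
#' the fingerprint of a known area in one species) and every unmasked
#' vertex of a target blueprint, localizing the candidate homolog as the
#' low-divergence region.
#'
#' @param f Query fingerprint over `B`'s tract set (sums to 1).
#' @param B Target `connectivity_blueprint`.
#' @param threshold Threshold for the companion localization mask.  With
#'   `threshold_type = "percentile"` (default) the mask selects the lowest
#'   `threshold` fraction of unmasked divergence values (default 0.05);
#'   with `"absolute"` it selects values `<= threshold` bits.
#' @param threshold_type `"percentile"` or `"absolute"`.
#' @return A list of class `fingerprint_match`: `map` (divergence
#'   `surface_scalar_map`, bits), `selected` (logical per vertex inside the
#'   threshold), `threshold_value` (bits), `argmin` (best-matching vertex),
#'   and the resolved `threshold`/`threshold_type`.
#' @export
fingerprint_search <- function(f, B, threshold = 0.05,
                               threshold_type = c("percentile", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  f <- as.numeric(f)
  if (length(f) != length(B$tracts))
    stop("fingerprint length (", length(f), ") does not match tract set (",
         length(B$tracts), ")")
  .check_fingerprint(f, 1e-6, "query fingerprint")
  if (threshold_type == "percentile" && (threshold <= 0 || threshold > 1))
    stop("percentile threshold must be in (0, 1]")
  vals <- rep(NA_real_, n_vertices(B))
  sub <- B$matrix[B$vertex_mask, , drop = FALSE]
  vals[B$vertex_mask] <- as.vector(.skl_cross(base::matrix(f, 1L), sub))
  unmasked <- vals[B$vertex_mask]
  thr <- if (threshold_type == "percentile")
    as.numeric(quantile(unmasked, threshold, names = FALSE)) else threshold
  selected <- !is.na(vals) & vals <= thr
  amin <- which(B$vertex_mask)[which.min(unmasked)]
  structure(
    list(map = surface_scalar_map(vals, name = "fingerprint_divergence",
                                  units = "bits"),
         selected = selected, threshold_value = thr, argmin = amin,
         threshold = threshold, threshold_type = threshold_type),
    class = "fingerprint_match")
}

#' Average fingerprint of the most similar vertices
#'
#' Finds the `fraction` of unmasked vertices of `B` with the smallest
#' divergence to the query fingerprint and returns their mean fingerprint,
#' renormalized.  Used, e.g., to compare an area's fingerprint against the
#' average of the top 1% most similar vertices of the other species.
#'
#' @param f Query fingerprint over `B`'s tract set.
#' @param B Target `connectivity_blueprint`.
#' @param fraction Fraction in (0, 1]; `ceiling(fraction * n_unmasked)`
#'   vertices are averaged.  Ties in divergence are broken by smaller
#'   vertex index.
#' @return Named row-stochastic fingerprint vector.
#' @export
top_fraction_fingerprint <- function(f, B, fraction = 0.01) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  fs <- fingerprint_search(f, B, threshold = 1, threshold_type = "percentile")
  idx <- which(B$vertex_mask)
  divs <- fs$map$values[idx]
  k <- ceiling(fraction * length(idx))
  take <- idx[order(divs, idx)[seq_len(k)]]
  avg <- colMeans(B$matrix[take, , drop = FALSE])
  setNames(avg / sum(avg), B$tracts$names)
}

#' Shannon entropy map of tract distributions
#'
#' Per-vertex entropy \eqn{-\sum_k p_k \log_2 p_k} in bits of the
#' fingerprint distribution: low where a vertex is dominated by few tracts,
#' high (up to \eqn{\log_2 K}) where many tracts reach it with similar
#' probability.
#'
#' @param B A `connectivity_blueprint`.
#' @return A `surface_scalar_map` in bits.
#' @export
entropy_map <- function(B) {
  vals <- rep(NA_real_, n_vertices(B))
  sub <- B$matrix[B$vertex_mask, , drop = FALSE]
  vals[B$vertex_mask] <- pmax(-rowSums(.xlog2x(sub)), 0)
  surface_scalar_map(vals, name = "entropy", units = "bits")
}

#' Local (neighborhood-wise) correlation of two surface maps
#'
#' Pearson correlation of two scalar maps computed within each vertex's
#' mesh neighborhood, giving a surface map of where the two maps co-vary.
#'
#' @param h1,h2 `surface_scalar_map`s on the same surface.
#' @param neighborhoods List with one integer vector per vertex: the vertex
#'   indices of its neighborhood (see [ring_neighborhoods()]).
#' @return A `surface_scalar_map` of correlations in `[-1, 1]`; vertices
#'   whose neighborhood has fewer than 3 valid members or zero variance in
#'   either map carry the `NA` sentinel.
#' @export
local_correlation_map <- function(h1, h2, neighborhoods) {
  if (length(h1$values) != length(h2$values))
    stop("maps have different vertex counts (", length(h1$values), " vs ",
         length(h2$values), ")")
  n <- length(h1$values)
  if (length(neighborhoods) != n)
    stop("neighborhood list length does not match vertex count")
  vals <- rep(NA_real_, n)
  valid <- h1$mask & h2$mask
  for (i in which(valid)) {
    nb <- neighborhoods[[i]]
    nb <- nb[nb >= 1 & nb <= n]
    nb <- nb[valid[nb]]
    if (length(nb) < 3L) next
    a <- h1$values[nb]; b <- h2$values[nb]
    if (sd(a) == 0 || sd(b) == 0) next
    vals[i] <- cor(a, b)
  }
  surface_scalar_map(vals, name = "local_correlation", units = "r")
}

#' k-ring neighborhoods from a mesh edge list
#'
#' Expands mesh adjacency to k-ring neighborhoods (all vertices reachable
#' within `k` edges, including the vertex itself), the window used by
#' [local_correlation_map()].
#'
#' @param edges Two-column integer matrix of undirected mesh edges
#'   (1-based vertex indices).
#' @param n_vertices Total vertex count.
#' @param k Ring order (default 3).
#' @return List of integer vectors, one per vertex.
#' @export
ring_neighborhoods <- function(edges, n_vertices, k = 3L) {
  edges <- base::matrix(as.integer(edges), ncol = 2L)
  if (any(edges < 1L) || any(edges > n_vertices))
    stop("edge indices out of range")
  adj <- vector("list", n_vertices)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, unique)
  lapply(seq_len(n_vertices), function(v) {
    ring <- v
    frontier <- v
    for (step in seq_len(k)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), ring)
      if (!length(frontier)) break
      ring <- c(ring, frontier)
    }
    sort(ring)
  })
}
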