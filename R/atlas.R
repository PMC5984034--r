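#' Per-vertex region atlas
#'
#' @param labels Integer vector, one label per vertex; 0 = unlabeled.
#' @param names Optional region-name table: a named character vector whose
#'   names are label integers (as strings), or a two-column data frame
#'   (label, name).  Labels absent from the table get auto-generated names.
#' @param species Free-text species label.
#' @return Object of class `region_atlas` with fields `labels`, `names`
#'   (named character vector), `species`.
#' @export
region_atlas <- function(labels, names = NULL, species = "") {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative integers (0 = unlabeled)")
  present <- sort(unique(labels[labels > 0L]))
  tab <- setNames(paste0("region_", present), as.character(present))
  if (!is.null(names)) {
    if (is.data.frame(names))
      names <- setNames(as.character(names[[2L]]), as.character(names[[1L]]))
    known <- intersect(base::names(names), base::names(tab))
    tab[known] <- names[known]
  }
  structure(list(labels = labels, names = tab,
                 species = as.character(species)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas: ", length(x$labels), " vertices, ",
      length(x$names), " regions",
      if (nzchar(x$species)) paste0(" [", x$species, "]"), "\n", sep = "")
  invisible(x)
}

#' Region-level connectivity fingerprints
#'
#' Collapses a vertex-level blueprint to one fingerprint per atlas region:
#' the mean of the member vertices' fingerprints, renormalized.  Regions
#' with no unmasked vertices are dropped with a warning.
#'
#' @param B A `connectivity_blueprint`.
#' @param atlas A [region_atlas()] on the same surface.
#' @return Object of class `region_fingerprint_table`: `matrix`
#'   (regions x tracts, row-stochastic, rownames = region names), `labels`
#'   (the integer label of each row), `tracts`, `species`.
#' @export
region_fingerprints <- function(B, atlas) {
  if (length(atlas$labels) != n_vertices(B))
    stop("atlas has ", length(atlas$labels), " vertices but blueprint has ",
         n_vertices(B))
  present <- sort(unique(atlas$labels[atlas$labels > 0L]))
  rows <- list()
  kept <- integer(0)
  for (lab in present) {
    members <- which(atlas$labels == lab & B$vertex_mask)
    if (!length(members)) next
    fp <- colMeans(B$matrix[members, , drop = FALSE])
    rows[[length(rows) + 1L]] <- fp / sum(fp)
    kept <- c(kept, lab)
  }
  dropped <- setdiff(present, kept)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " region(s) with no unmasked vertices: ",
            paste(atlas$names[as.character(dropped)], collapse = ", "))
  if (!length(kept)) stop("no region has any unmasked vertex")
  m <- do.call(rbind, rows)
  rownames(m) <- unname(atlas$names[as.character(kept)])
  colnames(m) <- B$tracts$names
  structure(list(matrix = m, labels = kept, tracts = B$tracts,
                 species = if (nzchar(atlas$species)) atlas$species
                           else B$species),
            class = "region_fingerprint_table")
}

#' @export
print.region_fingerprint_table <- function(x, ...) {
  cat("region_fingerprint_table: ", nrow(x$matrix), " regions x ",
      length(x$tracts), " tracts",
      if (nzchar(x$species)) paste0(" [", x$species, "]"), "\n", sep = "")
  invisible(x)
}

#' Divergence between the regions of two atlases
#'
#' Pairwise symmetric KL divergence between every region fingerprint of
#' one species and every region fingerprint of the other, with best-match
#' (argmin) lists in both directions and the mutually-best pairs — the
#' operational homology candidates.
#'
#' @param T_A,T_B `region_fingerprint_table`s over identical tract sets.
#' @return List of class `cross_atlas_divergence`: `divergence` (a
#'   `divergence_matrix` with region dimnames), `best_ab` / `best_ba`
#'   (argmin index vectors), and `mutual_pairs` (data frame of region-name
#'   pairs that are each other's argmin).
#' @export
cross_atlas_divergence <- function(T_A, T_B) {
  .check_tracts_match(T_A$tracts, T_B$tracts, "region tables")
  vals <- .skl_cross(T_A$matrix, T_B$matrix)
  dimnames(vals) <- list(rownames(T_A$matrix), rownames(T_B$matrix))
  D <- structure(list(values = vals, row_mask = rep(TRUE, nrow(vals)),
                      col_mask = rep(TRUE, ncol(vals)), units = "bits"),
                 class = "divergence_matrix")
  best_ab <- apply(vals, 1L, which.min)
  best_ba <- apply(vals, 2L, which.min)
  mutual <- which(best_ba[best_ab] == seq_len(nrow(vals)))
  mutual_pairs <- data.frame(
    region_a = rownames(vals)[mutual],
    region_b = colnames(vals)[best_ab[mutual]],
    divergence = vals[cbind(mutual, best_ab[mutual])],
    stringsAsFactors = FALSE)
  structure(list(divergence = D, best_ab = best_ab, best_ba = best_ba,
                 mutual_pairs = mutual_pairs),
            class = "cross_atlas_divergence")
}

#' Spectral embedding of a divergence structure
#'
#' Projects items (e.g. the union of two species' atlas regions) into a
#' low-dimensional space in which small pairwise divergence means nearby
#' coordinates.  Divergences are converted to affinities
#' \eqn{A = \exp(-D/\sigma)} with \eqn{\sigma} defaulting to the median
#' off-diagonal divergence, and the coordinates are the eigenvectors of the
#' symmetric normalized graph Laplacian belonging to the 2nd and 3rd
#' smallest eigenvalues (and onward for `dims > 2`).  Eigenvector signs are
#' canonicalized so each vector's largest-magnitude entry is positive.
#'
#' @param D Symmetric divergence matrix (numeric matrix or
#'   `divergence_matrix`); must be symmetric to within `1e-9`.
#' @param dims Number of embedding dimensions (default 2).
#' @param sigma Affinity bandwidth; default is the median off-diagonal
#'   divergence (finite entries only).
#' @return Object of class `spectral_embedding`: `coords` (n x dims,
#'   rownames inherited from `D`), `eigenvalues` (the `dims` eigenvalues
#'   used, ascending), `sigma`.
#' @export
spectral_embed <- function(D, dims = 2L, sigma = NULL) {
  V <- if (inherits(D, "divergence_matrix")) D$values else as.matrix(D)
  n <- nrow(V)
  if (n != ncol(V)) stop("divergence matrix must be square")
  if (n < dims + 2L) stop("need at least dims + 2 items to embed")
  if (max(abs(V - t(V)), na.rm = TRUE) > 1e-9)
    stop("divergence matrix is not symmetric (beyond 1e-9)")
  off <- V[row(V) != col(V)]
  off <- off[is.finite(off)]
  if (is.null(sigma)) {
    sigma <- stats::median(off)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  A <- exp(-V / sigma)
  A[!is.finite(V)] <- 0
  diag(A) <- 0
  # connectivity check on the positive-affinity graph
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- which(comp == 0L & colSums(A[frontier, , drop = FALSE] > 0) > 0)
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  if (cid > 1L) {
    sizes <- table(comp)
    stop("affinity graph is disconnected: ", cid, " components of sizes ",
         paste(sizes, collapse = ", "))
  }
  d <- rowSums(A)
  isd <- 1 / sqrt(d)
  L <- diag(n) - (isd * A) * rep(isd, each = n)  # I - D^-1/2 A D^-1/2
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  # eigenvalues come in decreasing order; smallest are at the end
  take <- n - 1L - (seq_len(dims) - 1L)  # 2nd, 3rd, ... smallest
  coords <- eig$vectors[, take, drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    v <- coords[, j]
    if (v[which.max(abs(v))] < 0) coords[, j] <- -v
  }
  rownames(coords) <- rownames(V)
  colnames(coords) <- paste0("dim", seq_len(dims))
  structure(list(coords = coords, eigenvalues = rev(eig$values[take]),
                 sigma = sigma),
            class = "spectral_embedding")
}

#' Joint 2D embedding of two atlases' regions
#'
#' Stacks the region fingerprints of both species, computes the full
#' symmetric divergence matrix over the union (within- and between-species
#' blocks) and embeds it with [spectral_embed()], so that regions with
#' similar connectivity fingerprints land near each other in a shared 2D
#' space regardless of species.
#'
#' @param T_A,T_B `region_fingerprint_table`s over identical tract sets.
#' @param dims Embedding dimensionality (default 2).
#' @param sigma Affinity bandwidth passed to [spectral_embed()].
#' @return List of class `atlas_embedding`: `table` (data frame with
#'   columns region, species, and the embedding coordinates), `embedding`
#'   (the `spectral_embedding`), `divergence` (the joint matrix).
#' @export
atlas_embedding <- function(T_A, T_B, dims = 2L, sigma = NULL) {
  .check_tracts_match(T_A$tracts, T_B$tracts, "region tables")
  joint <- rbind(T_A$matrix, T_B$matrix)
  spA <- if (nzchar(T_A$species)) T_A$species else "A"
  spB <- if (nzchar(T_B$species)) T_B$species else "B"
  rownames(joint) <- c(paste0(spA, ":", rownames(T_A$matrix)),
                       paste0(spB, ":", rownames(T_B$matrix)))
  D <- .skl_cross(joint, joint)
  D <- (D + t(D)) / 2  # symmetric up to rounding; make it exact
  dimnames(D) <- list(rownames(joint), rownames(joint))
  emb <- spectral_embed(D, dims = dims, sigma = sigma)
  tab <- data.frame(
    region = c(rownames(T_A$matrix), rownames(T_B$matrix)),
    species = c(rep(spA, nrow(T_A$matrix)), rep(spB, nrow(T_B$matrix))),
    emb$coords, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, embedding = emb, divergence = D),
            class = "atlas_embedding")
}
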