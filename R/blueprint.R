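#' @importFrom stats quantile rnorm rgamma sd setNames cor median complete.cases
#' @importFrom utils head read.table write.table
NULL

#' Normalize matrix rows to probability distributions
#'
#' Divides each row with a positive sum by that sum, turning it into a
#' discrete probability distribution over the columns.  Rows summing to
#' zero cannot be normalized; they are returned unchanged and their indices
#' are attached as the `"degenerate"` attribute.
#'
#' @param m Numeric matrix with non-negative entries.
#' @return The row-normalized matrix, with attribute `degenerate` holding
#'   the indices of all-zero rows.
#' @examples
#' normalize_rows(rbind(c(2, 2, 4), c(0, 0, 0)))
#' @export
normalize_rows <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative entries are not allowed in a count/probability matrix")
  rs <- rowSums(m)
  degenerate <- which(rs <= 0)
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  attr(m, "degenerate") <- as.integer(degenerate)
  m
}

# Apply an epsilon floor to already-normalized rows and renormalize, so
# every fingerprint has full support and downstream KL stays finite.
.floor_rows <- function(m, epsilon) {
  if (epsilon <= 0) return(m)
  (m + epsilon) / (1 + ncol(m) * epsilon)
}

#' Construct a connectivity blueprint from a normalized matrix
#'
#' A connectivity blueprint is a (vertices x tracts) matrix whose rows,
#' once normalized, give the probability distribution of each cortical
#' vertex's streamlines over a fixed tract set.  Masked vertices (e.g. the
#' medial wall) carry `NA` rows and are excluded from every comparison.
#'
#' An epsilon floor (default `1e-8`) is added to every unmasked fingerprint
#' before the final renormalization so that all entries are strictly
#' positive and the symmetric KL divergence is always finite.  Set
#' `epsilon = 0` to disable flooring.
#'
#' @param matrix Numeric (vertices x tracts) matrix, non-negative.  Rows
#'   need not be normalized on input.
#' @param tracts A [tract_set()] whose length matches `ncol(matrix)`.
#' @param vertex_mask Logical per-vertex vector, `TRUE` = included cortical
#'   vertex.  Defaults to all `TRUE`.
#' @param species,subject Free-text labels carried in the object.
#' @param epsilon Non-negative floor added to each fingerprint entry before
#'   renormalization.
#' @return An object of class `connectivity_blueprint` with fields
#'   `matrix` (row-stochastic, `NA` rows where masked), `tracts`,
#'   `vertex_mask`, `species`, `subject`, `epsilon` and `degenerate`
#'   (indices of rows masked because their raw sum was zero).
#' @export
connectivity_blueprint <- function(matrix, tracts, vertex_mask = NULL,
                                   species = "", subject = "",
                                   epsilon = 1e-8) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("blueprint matrix must be numeric")
  if (ncol(m) != length(tracts))
    stop("blueprint has ", ncol(m), " columns but the tract set has ",
         length(tracts), " tracts")
  if (epsilon < 0) stop("epsilon must be non-negative")
  n <- nrow(m)
  if (is.null(vertex_mask)) vertex_mask <- rep(TRUE, n)
  vertex_mask <- as.logical(vertex_mask)
  if (length(vertex_mask) != n)
    stop("vertex_mask length (", length(vertex_mask),
         ") does not match vertex count (", n, ")")
  if (any(m[vertex_mask, , drop = FALSE] < 0, na.rm = TRUE))
    stop("negative entries are not allowed in a connectivity blueprint")

  rs <- rowSums(m)
  degenerate <- which(vertex_mask & (is.na(rs) | rs <= 0))
  if (length(degenerate)) {
    warning(length(degenerate),
            " vertex/vertices with all-zero fingerprints masked as degenerate")
    vertex_mask[degenerate] <- FALSE
  }
  out <- base::matrix(NA_real_, n, ncol(m), dimnames = list(NULL, tracts$names))
  if (any(vertex_mask)) {
    sub <- m[vertex_mask, , drop = FALSE] / rs[vertex_mask]
    out[vertex_mask, ] <- .floor_rows(sub, epsilon)
  }
  bad <- which(vertex_mask & abs(rowSums(out) - 1) > 1e-9)
  if (length(bad))
    stop("internal error: row ", bad[1L], " is not stochastic after normalization")
  structure(
    list(matrix = out, tracts = tracts, vertex_mask = vertex_mask,
         species = as.character(species), subject = as.character(subject),
         epsilon = epsilon, degenerate = as.integer(degenerate)),
    class = "connectivity_blueprint")
}

#' @export
print.connectivity_blueprint <- function(x, ...) {
  cat("connectivity_blueprint: ", nrow(x$matrix), " vertices x ",
      length(x$tracts), " tracts", sep = "")
  if (nzchar(x$species)) cat("  [", x$species,
                             if (nzchar(x$subject)) paste0("/", x$subject), "]",
                             sep = "")
  cat("\n  unmasked vertices: ", sum(x$vertex_mask),
      "; epsilon floor: ", format(x$epsilon), "\n", sep = "")
  invisible(x)
}

#' Number of vertices of a blueprint
#' @param bp A `connectivity_blueprint`.
#' @return Integer vertex count (masked vertices included).
#' @export
n_vertices <- function(bp) nrow(bp$matrix)

#' Extract one vertex's connectivity fingerprint
#'
#' @param bp A `connectivity_blueprint`.
#' @param vertex Vertex index (1-based).
#' @return Named numeric vector over the tract set; `NA`s if the vertex is
#'   masked.
#' @export
fingerprint <- function(bp, vertex) {
  bp$matrix[vertex, ]
}

#' Wrap a vertex-to-brain streamline count matrix
#'
#' The (cortex x whole-brain) matrix produced by seeding probabilistic
#' streamlines from every cortical vertex and recording the number of
#' samples reaching each brain voxel.
#'
#' @param matrix Numeric (vertices x brain-locations) matrix of
#'   non-negative streamline counts; may be a sparse `Matrix`.
#' @param vertex_mask Logical per-vertex inclusion mask (default all `TRUE`).
#' @return Object of class `vertex_to_brain_matrix`.  Unmasked all-zero
#'   rows are flagged in the `degenerate` field.
#' @export
vertex_to_brain_matrix <- function(matrix, vertex_mask = NULL) {
  if (min(matrix) < 0) stop("streamline counts must be non-negative")
  n <- nrow(matrix)
  if (is.null(vertex_mask)) vertex_mask <- rep(TRUE, n)
  if (length(vertex_mask) != n)
    stop("vertex_mask length does not match vertex count")
  rs <- Matrix::rowSums(matrix)
  structure(list(matrix = matrix, vertex_mask = as.logical(vertex_mask),
                 degenerate = as.integer(which(vertex_mask & rs <= 0))),
            class = "vertex_to_brain_matrix")
}

#' Wrap a brain-to-tract probability matrix
#'
#' The (brain-locations x tracts) matrix of tract visitation probabilities
#' whose columns define the blueprint's tract set.
#'
#' @param matrix Numeric (brain-locations x tracts) non-negative matrix;
#'   may be sparse.
#' @param tracts A [tract_set()]; its order defines the column order.
#' @return Object of class `brain_to_tract_matrix`.
#' @export
brain_to_tract_matrix <- function(matrix, tracts) {
  if (min(matrix) < 0) stop("tract probabilities must be non-negative")
  if (ncol(matrix) != length(tracts))
    stop("matrix has ", ncol(matrix), " columns but tract set has ",
         length(tracts), " tracts")
  structure(list(matrix = matrix, tracts = tracts),
            class = "brain_to_tract_matrix")
}

#' Build a connectivity blueprint from tractography matrices
#'
#' Multiplies the (cortex x brain) streamline-count matrix by the
#' (brain x tracts) tract-probability matrix and row-normalizes the product,
#' so each row becomes the probability distribution of that vertex's
#' streamlines over the tract set.  Vertices whose raw product is all zero
#' are masked as degenerate with a warning rather than assigned a uniform
#' fingerprint (a uniform row would silently match high-entropy cortex).
#'
#' @param vb A [vertex_to_brain_matrix()].
#' @param bt A [brain_to_tract_matrix()]; its tract order defines the
#'   output tract set.
#' @param species,subject Labels stored in the blueprint.
#' @param epsilon Epsilon floor passed to [connectivity_blueprint()].
#' @return A `connectivity_blueprint`.
#' @examples
#' ts <- tract_set(c("a", "b", "c"))
#' vb <- vertex_to_brain_matrix(rbind(c(1, 0), c(0, 1)))
#' bt <- brain_to_tract_matrix(rbind(c(1, 0, 0), c(0, 1, 1)), ts)
#' build_blueprint(vb, bt, epsilon = 0)$matrix
#' @export
build_blueprint <- function(vb, bt, species = "", subject = "",
                            epsilon = 1e-8) {
  if (!inherits(vb, "vertex_to_brain_matrix"))
    vb <- vertex_to_brain_matrix(vb)
  if (!inherits(bt, "brain_to_tract_matrix"))
    stop("bt must be a brain_to_tract_matrix (its tract set defines the columns)")
  if (ncol(vb$matrix) != nrow(bt$matrix))
    stop("dimension mismatch: vertex-to-brain matrix is ",
         nrow(vb$matrix), "x", ncol(vb$matrix),
         " but brain-to-tract matrix is ",
         nrow(bt$matrix), "x", ncol(bt$matrix))
  raw <- as.matrix(vb$matrix %*% bt$matrix)
  connectivity_blueprint(raw, bt$tracts, vertex_mask = vb$vertex_mask,
                         species = species, subject = subject,
                         epsilon = epsilon)
}

#' Average blueprints across subjects
#'
#' Pools subject-level blueprints of one species into a group blueprint:
#' the element-wise mean of the row-normalized matrices, renormalized per
#' row.  A vertex is masked in the output if it is masked in any input.
#'
#' @param blueprints List of `connectivity_blueprint`s sharing the same
#'   tract set and vertex count.
#' @param species,subject Labels for the pooled blueprint (defaults: the
#'   first input's species; subject `"group"`).
#' @return The group `connectivity_blueprint`.
#' @export
average_blueprints <- function(blueprints, species = NULL,
                               subject = "group") {
  if (!length(blueprints)) stop("need at least one blueprint")
  ref <- blueprints[[1L]]
  for (bp in blueprints[-1L]) {
    .check_tracts_match(ref$tracts, bp$tracts)
    if (n_vertices(bp) != n_vertices(ref))
      stop("blueprints have different vertex counts (",
           n_vertices(ref), " vs ", n_vertices(bp), ")")
  }
  mask <- Reduce(`&`, lapply(blueprints, `[[`, "vertex_mask"))
  acc <- base::matrix(0, n_vertices(ref), length(ref$tracts))
  for (bp in blueprints) acc[mask, ] <- acc[mask, , drop = FALSE] +
    bp$matrix[mask, , drop = FALSE]
  acc[!mask, ] <- NA_real_
  acc[mask, ] <- acc[mask, , drop = FALSE] / length(blueprints)
  connectivity_blueprint(
    ifelse(is.na(acc), 0, acc), ref$tracts, vertex_mask = mask,
    species = if (is.null(species)) ref$species else species,
    subject = subject, epsilon = 0)
}
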