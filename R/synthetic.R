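# One Dirichlet draw per row: rows of `alpha` are concentration vectors.
.rdirichlet_rows <- function(alpha) {
  n <- nrow(alpha); k <- ncol(alpha)
  g <- base::matrix(rgamma(n * k, shape = as.vector(alpha)), n, k)
  g / pmax(rowSums(g), .Machine$double.xmin)
}

#' Specify a synthetic paired-species dataset
#'
#' Defines the study conditions for the synthetic generator: two species
#' share a tract set and a region layout; most regions are homologous
#' (identical base fingerprint in both species), a few are divergent
#' (species A shifts a configurable share of its probability mass onto one
#' designated tract, emulating, e.g., a tract invading new cortical
#' territory in one lineage).  Vertex fingerprints are Dirichlet draws
#' around the region base, with the concentration parameter controlling
#' individual/vertex noise, and a scalar surface map is generated as a
#' fixed linear readout of the fingerprint plus Gaussian noise, emulating a
#' myelin-like map predictable from connectivity.
#'
#' @param n_vertices Vertices per species (default 2000).
#' @param n_tracts Number of tracts (default 39).
#' @param n_regions Number of regions per species (default 10, so each
#'   region is about a decile of the surface).
#' @param divergent_regions Integer vector of region ids that are divergent
#'   in species A (default: region 1).  Use `integer(0)` for none.
#' @param divergent_shift Fraction of probability mass moved onto the
#'   designated tract in divergent regions (default 0.5).
#' @param divergent_tract Optional tract index receiving the shifted mass;
#'   default: drawn per divergent region from the seed.
#' @param concentration Dirichlet concentration of vertex noise around the
#'   region base (default 200; larger = less noise).
#' @param scalar_noise_sd Additive Gaussian noise of the scalar map
#'   (default 0.1, on the scale of the unit-variance readout weights).
#' @param mask_fraction Fraction of vertices masked per species, emulating
#'   a medial wall (default 0).
#' @param seed Integer seed; fully determines all generator output.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_vertices = 2000L, n_tracts = 39L,
                           n_regions = 10L, divergent_regions = 1L,
                           divergent_shift = 0.5, divergent_tract = NULL,
                           concentration = 200, scalar_noise_sd = 0.1,
                           mask_fraction = 0, seed = 1L) {
  n_vertices <- as.integer(n_vertices)
  n_tracts <- as.integer(n_tracts)
  n_regions <- as.integer(n_regions)
  divergent_regions <- as.integer(divergent_regions)
  if (n_regions > n_vertices)
    stop("infeasible spec: more regions (", n_regions, ") than vertices (",
         n_vertices, ")")
  if (n_tracts < 2L) stop("need at least 2 tracts")
  if (length(divergent_regions) &&
      (any(divergent_regions < 1L) || any(divergent_regions > n_regions)))
    stop("divergent region ids must be in 1..n_regions")
  if (divergent_shift < 0 || divergent_shift >= 1)
    stop("divergent_shift must be in [0, 1)")
  if (!is.null(divergent_tract) &&
      (divergent_tract < 1L || divergent_tract > n_tracts))
    stop("divergent_tract out of range")
  if (concentration <= 0) stop("concentration must be positive")
  if (mask_fraction < 0 || mask_fraction >= 1)
    stop("mask_fraction must be in [0, 1)")
  structure(list(n_vertices = n_vertices, n_tracts = n_tracts,
                 n_regions = n_regions,
                 divergent_regions = divergent_regions,
                 divergent_shift = divergent_shift,
                 divergent_tract = divergent_tract,
                 concentration = concentration,
                 scalar_noise_sd = scalar_noise_sd,
                 mask_fraction = mask_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a paired-species synthetic dataset
#'
#' Draws region base fingerprints from a flat Dirichlet over the tract
#' set (shared between species for homologous regions; mass-shifted in
#' species A for divergent regions), then vertex fingerprints as
#' `Dirichlet(concentration * base)` draws, plus per-species atlases,
#' fingerprint-coupled scalar maps, and a ground-truth record.
#'
#' The region structure, base fingerprints and scalar readout weights
#' depend only on `spec$seed`; the vertex-level noise additionally depends
#' on `subject`, so different `subject` values emulate different
#' individuals of the same two species.
#'
#' @param spec A [synthetic_spec()].
#' @param subject Integer subject index (default 1).
#' @return List of class `synthetic_pair` with components `blueprint_A`,
#'   `blueprint_B` (`connectivity_blueprint`s), `atlas_A`, `atlas_B`
#'   (`region_atlas`), `scalar_A`, `scalar_B` (`surface_scalar_map`s) and
#'   `ground_truth` (region labels, homologous/divergent region ids,
#'   divergent tracts, base fingerprints, scalar weights).
#' @export
generate_pair <- function(spec, subject = 1L) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  n <- spec$n_vertices; K <- spec$n_tracts; R <- spec$n_regions

  # stage 1: population structure, determined by the spec seed alone
  set.seed(spec$seed)
  labels <- sort(rep(seq_len(R), length.out = n))
  base_B <- .rdirichlet_rows(base::matrix(1, R, K))
  base_A <- base_B
  div_tracts <- integer(0)
  if (length(spec$divergent_regions)) {
    div_tracts <- if (is.null(spec$divergent_tract))
      sample.int(K, length(spec$divergent_regions), replace = TRUE)
    else rep(as.integer(spec$divergent_tract), length(spec$divergent_regions))
    for (i in seq_along(spec$divergent_regions)) {
      r <- spec$divergent_regions[i]
      shifted <- base_B[r, ] * (1 - spec$divergent_shift)
      shifted[div_tracts[i]] <- shifted[div_tracts[i]] + spec$divergent_shift
      base_A[r, ] <- shifted
    }
  }
  scalar_w <- rnorm(K)

  # stage 2: subject-level noise
  set.seed((spec$seed + 104729L * (as.integer(subject) - 1L)) %%
             .Machine$integer.max)
  draw_species <- function(base) {
    P <- .rdirichlet_rows(spec$concentration * base[labels, , drop = FALSE])
    mask <- rep(TRUE, n)
    n_masked <- floor(spec$mask_fraction * n)
    if (n_masked > 0L) mask[sample.int(n, n_masked)] <- FALSE
    list(P = P, mask = mask)
  }
  a <- draw_species(base_A)
  b <- draw_species(base_B)
  tracts <- if (K == 39L) default_tract_set()
            else tract_set(sprintf("tract%02d", seq_len(K)),
                           rep("cross", K))
  subj <- paste0("subj", subject)
  bpA <- connectivity_blueprint(a$P, tracts, vertex_mask = a$mask,
                                species = "speciesA", subject = subj)
  bpB <- connectivity_blueprint(b$P, tracts, vertex_mask = b$mask,
                                species = "speciesB", subject = subj)
  scalar_of <- function(bp) {
    s <- as.vector(bp$matrix %*% scalar_w) +
      rnorm(n, 0, spec$scalar_noise_sd)
    surface_scalar_map(s, name = "synthetic_scalar")
  }
  sA <- scalar_of(bpA)
  sB <- scalar_of(bpB)
  structure(
    list(blueprint_A = bpA, blueprint_B = bpB,
         atlas_A = region_atlas(labels, species = "speciesA"),
         atlas_B = region_atlas(labels, species = "speciesB"),
         scalar_A = sA, scalar_B = sB,
         ground_truth = list(
           region_labels = labels,
           homologous_regions = setdiff(seq_len(R), spec$divergent_regions),
           divergent_regions = spec$divergent_regions,
           divergent_tracts = div_tracts,
           base_A = base_A, base_B = base_B,
           scalar_weights = scalar_w),
         spec = spec, subject = as.integer(subject)),
    class = "synthetic_pair")
}

#' Generate synthetic tractography input matrices
#'
#' Factorizes the species-A planted blueprint into a vertex-to-brain
#' streamline-count matrix and a brain-to-tract probability matrix whose
#' normalized product reproduces the blueprint, exercising
#' [build_blueprint()] end to end.  Each tract owns a block of
#' `voxels_per_tract` synthetic brain locations; per-vertex counts are
#' scaled by an arbitrary positive factor, which the row normalization
#' must cancel.
#'
#' @param spec A [synthetic_spec()].
#' @param voxels_per_tract Synthetic brain locations per tract (default 4).
#' @param sparse If `TRUE`, return sparse `Matrix` objects.
#' @return List with `vb` ([vertex_to_brain_matrix()]), `bt`
#'   ([brain_to_tract_matrix()]) and `blueprint` (the planted species-A
#'   `connectivity_blueprint` the product must reproduce).
#' @export
generate_tractography_inputs <- function(spec, voxels_per_tract = 4L,
                                         sparse = FALSE) {
  pair <- generate_pair(spec)
  bp <- pair$blueprint_A
  P <- bp$matrix
  P[!bp$vertex_mask, ] <- 0
  n <- nrow(P); K <- ncol(P); vpt <- as.integer(voxels_per_tract)
  n_loc <- K * vpt
  bt <- base::matrix(0, n_loc, K)
  for (k in seq_len(K)) bt[(k - 1L) * vpt + seq_len(vpt), k] <- 0.8
  vb <- base::matrix(0, n, n_loc)
  scale_v <- 1000 * (1 + (seq_len(n) %% 7))  # arbitrary per-vertex magnitudes
  for (k in seq_len(K))
    vb[, (k - 1L) * vpt + seq_len(vpt)] <- P[, k] * scale_v / vpt
  if (sparse) {
    vb <- Matrix::Matrix(vb, sparse = TRUE)
    bt <- Matrix::Matrix(bt, sparse = TRUE)
  }
  list(vb = vertex_to_brain_matrix(vb, vertex_mask = bp$vertex_mask),
       bt = brain_to_tract_matrix(bt, bp$tracts),
       blueprint = bp)
}

#' Ground-truth recovery statistics for a synthetic pair
#'
#' Runs the cross-species comparison on a synthetic pair and scores it
#' against the planted ground truth: the fraction of homologous-region
#' vertices whose minimum-divergence match lies in the planted homologous
#' region; the fraction of planted homologous region pairs recovered as
#' mutual argmins at the region level; and the share of the top decile of
#' the min-divergence map occupied by planted divergent-region vertices.
#'
#' @param pair A `synthetic_pair` from [generate_pair()].
#' @return Named list: `vertex_recovery`, `region_recovery`,
#'   `divergent_top_decile`, plus the underlying `min_map` and divergence
#'   objects.
#' @export
homolog_recovery_stats <- function(pair) {
  gt <- pair$ground_truth
  D <- divergence_matrix(pair$blueprint_A, pair$blueprint_B)
  mm <- min_divergence_map(D, over = "rows")
  amin <- attr(mm, "argmin")
  labels <- gt$region_labels
  hom <- which(labels %in% gt$homologous_regions &
                 pair$blueprint_A$vertex_mask & !is.na(amin))
  vertex_recovery <- mean(labels[amin[hom]] == labels[hom])

  TA <- region_fingerprints(pair$blueprint_A, pair$atlas_A)
  TB <- region_fingerprints(pair$blueprint_B, pair$atlas_B)
  cad <- cross_atlas_divergence(TA, TB)
  hom_names <- paste0("region_", gt$homologous_regions)
  mp <- cad$mutual_pairs
  region_recovery <- mean(hom_names %in%
                            mp$region_a[mp$region_a == mp$region_b])

  divergent_top_decile <- NA_real_
  if (length(gt$divergent_regions)) {
    v <- mm$values[mm$mask]
    idx <- which(mm$mask)
    k <- ceiling(0.1 * length(v))
    top <- idx[order(v, decreasing = TRUE)[seq_len(k)]]
    divergent_top_decile <- mean(labels[top] %in% gt$divergent_regions)
  }
  list(vertex_recovery = vertex_recovery,
       region_recovery = region_recovery,
       divergent_top_decile = divergent_top_decile,
       min_map = mm, divergence = D, cross_atlas = cad)
}
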