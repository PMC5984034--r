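test_that("symmetric KL matches the printed-formula oracle", {
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.25, 0.75)),
               oracle_symmetric_kl(c(0.5, 0.5), c(0.25, 0.75)),
               tolerance = 1e-12)
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.25, 0.75)), 0.39624,
               tolerance = 1e-4)
  set.seed(41)
  for (i in 1:50) {
    p <- rdirich(rep(1, 8)); q <- rdirich(rep(1, 8))
    expect_equal(symmetric_kl(p, q), oracle_symmetric_kl(p, q),
                 tolerance = 1e-10)
    expect_identical(symmetric_kl(p, q), symmetric_kl(q, p))
    expect_gt(symmetric_kl(p, q), 0)
    perm <- sample(8)
    expect_equal(symmetric_kl(p[perm], q[perm]), symmetric_kl(p, q),
                 tolerance = 1e-12)
  }
})

test_that("symmetric KL rejects malformed input and flags support mismatch", {
  expect_error(symmetric_kl(c(0.5, 0.5), c(1, 0, 0)), "different lengths")
  expect_error(symmetric_kl(c(0.6, 0.6), c(0.5, 0.5)), "not normalized")
  expect_error(symmetric_kl(c(-0.5, 1.5), c(0.5, 0.5)), "negative")
  expect_warning(d <- symmetric_kl(c(1, 0), c(0.5, 0.5)),
                 "support mismatch")
  expect_identical(d, Inf)
})

test_that("divergence matrices are zero on the diagonal, transpose-symmetric, and match brute force", {
  set.seed(43)
  A <- random_blueprint(20, 6, species = "A")
  B <- random_blueprint(15, 6, species = "B")
  D <- divergence_matrix(A, B)
  expect_equal(dim(D), c(20L, 15L))
  for (i in seq_len(20)) for (j in seq_len(15))
    expect_equal(D$values[i, j],
                 oracle_symmetric_kl(A$matrix[i, ], B$matrix[j, ]),
                 tolerance = 1e-10)
  expect_identical(t(divergence_matrix(B, A)$values), D$values)

  Dself <- divergence_matrix(A, A)      # within-species usage
  expect_equal(unname(diag(Dself$values)), rep(0, 20))
  expect_true(all(D$values >= 0))

  wrong <- random_blueprint(15, 6)
  wrong$tracts <- tract_set(c(sprintf("t%02d", 1:5), "other"))
  expect_error(divergence_matrix(A, wrong), "'t06' vs 'other'")
})

test_that("divergence matrices exclude masked vertices", {
  set.seed(47)
  mask <- rep(TRUE, 10); mask[c(2, 7)] <- FALSE
  A <- random_blueprint(10, 5, mask = mask)
  B <- random_blueprint(8, 5)
  D <- divergence_matrix(A, B)
  expect_true(all(is.na(D$values[c(2, 7), ])))
  expect_true(all(is.finite(D$values[mask, ])))
})

test_that("the min-divergence map finds planted matches and respects the min property", {
  set.seed(53)
  V <- matrix(runif(6 * 5, 1, 4), 6, 5)
  V[3, 4] <- 0
  mm <- min_divergence_map(manual_divergence(V))
  expect_equal(mm$values[3], 0)
  expect_equal(attr(mm, "argmin")[3], 4L)
  expect_true(all(mm$values <= apply(V, 1, min) + 1e-12))

  # masked columns cannot be argmins; fully masked rows carry the sentinel
  D2 <- manual_divergence(V)
  D2$col_mask[4] <- FALSE
  D2$row_mask[5] <- FALSE
  mm2 <- min_divergence_map(D2)
  expect_false(any(attr(mm2, "argmin") == 4L, na.rm = TRUE))
  expect_true(is.na(mm2$values[5]))

  # transposed direction
  mmc <- min_divergence_map(manual_divergence(V), over = "cols")
  expect_equal(mmc$values, apply(V, 2, min))
})

test_that("fingerprint search scores an exact row as the global zero minimum", {
  set.seed(59)
  B <- random_blueprint(40, 7)
  f <- B$matrix[17, ]
  fs <- fingerprint_search(f, B)
  expect_equal(fs$map$values[17], 0)
  expect_equal(fs$argmin, 17L)
  expect_equal(sum(!is.na(fs$map$values)), sum(B$vertex_mask))
  expect_true(fs$selected[17])
  expect_lte(sum(fs$selected), ceiling(0.05 * 40) + 1)
  expect_error(fingerprint_search(f, B, threshold = 0), "in \\(0, 1]")
  expect_error(fingerprint_search(f[-1], B), "does not match tract set")
})

test_that("searching with a planted region's mean fingerprint recovers the region", {
  # near-noiseless planted homology: every region vertex should fall
  # inside the default low-divergence threshold
  sp <- synthetic_spec(n_vertices = 400, n_tracts = 12, n_regions = 5,
                       divergent_regions = integer(0),
                       concentration = 1e6, seed = 61)
  pair <- generate_pair(sp)
  region <- which(pair$ground_truth$region_labels == 3)
  f <- colMeans(pair$blueprint_B$matrix[region, ])
  f <- f / sum(f)
  fs <- fingerprint_search(f, pair$blueprint_B, threshold = 0.2)
  expect_gte(mean(fs$selected[region]), 0.95)
})

test_that("top-fraction fingerprints interpolate between argmin and global mean", {
  set.seed(67)
  B <- random_blueprint(25, 5)
  f <- rdirich(rep(1, 5))
  full <- top_fraction_fingerprint(f, B, fraction = 1)
  gm <- colMeans(B$matrix)
  expect_equal(unname(full), unname(gm / sum(gm)), tolerance = 1e-12)

  single <- top_fraction_fingerprint(f, B, fraction = 1 / 25)
  fs <- fingerprint_search(f, B)
  expect_equal(unname(single), unname(B$matrix[fs$argmin, ]),
               tolerance = 1e-12)
  expect_equal(sum(top_fraction_fingerprint(f, B, 0.3)), 1,
               tolerance = 1e-12)
  expect_error(top_fraction_fingerprint(f, B, 0), "in \\(0, 1]")
  expect_error(top_fraction_fingerprint(f, B, 1.2), "in \\(0, 1]")
})

test_that("entropy maps hit the closed-form anchors and bounds", {
  K <- 39L
  ts <- default_tract_set()
  m <- rbind(c(1, rep(0, K - 1L)), rep(1 / K, K))
  bp <- connectivity_blueprint(m, ts, epsilon = 0)
  em <- entropy_map(bp)
  expect_equal(em$values[1], 0)
  expect_equal(em$values[2], log2(K), tolerance = 1e-12)
  expect_identical(em$units, "bits")

  set.seed(71)
  B <- random_blueprint(30, K)
  e <- entropy_map(B)$values
  expect_true(all(e >= 0 & e <= log2(K) + 1e-12))
  # invariant to tract reordering
  perm <- sample(K)
  B2 <- B
  B2$matrix <- B$matrix[, perm]
  B2$tracts <- tract_set(B$tracts$names[perm])
  expect_equal(entropy_map(B2)$values, e, tolerance = 1e-12)
})

test_that("local correlations are affine-exact and sentinel degenerate neighborhoods", {
  n <- 30L
  edges <- cbind(seq_len(n - 1L), 2:n)  # a chain mesh
  nb <- ring_neighborhoods(edges, n, k = 3L)
  expect_equal(nb[[10]], 7:13)
  h1 <- surface_scalar_map(sin(seq_len(n)))
  up <- surface_scalar_map(2 * h1$values + 1)
  down <- surface_scalar_map(-h1$values)
  flat <- surface_scalar_map(rep(2, n))
  expect_equal(local_correlation_map(h1, up, nb)$values, rep(1, n),
               tolerance = 1e-12)
  expect_equal(local_correlation_map(h1, down, nb)$values, rep(-1, n),
               tolerance = 1e-12)
  expect_true(all(is.na(local_correlation_map(flat, h1, nb)$values)))
  expect_error(local_correlation_map(h1, surface_scalar_map(1:5), nb),
               "different vertex counts")
})
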