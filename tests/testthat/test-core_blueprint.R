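test_that("tract sets enforce unique non-empty names and ordered identity", {
  expect_error(tract_set(c("a", "a")), "duplicate")
  expect_error(tract_set(c("a", "")), "non-empty")
  ts <- tract_set(c("AF_L", "AF_R", "FMI"))
  expect_equal(ts$hemisphere, c("left", "right", "cross"))
  expect_true(same_tract_set(ts, tract_set(c("AF_L", "AF_R", "FMI"))))
  expect_false(same_tract_set(ts, tract_set(c("AF_R", "AF_L", "FMI"))))
  d39 <- default_tract_set()
  expect_length(d39$names, 39L)
  expect_equal(table(d39$hemisphere)[["cross"]], 3L)
})

test_that("normalize_rows turns rows into distributions and flags zero rows", {
  m <- rbind(c(2, 2, 4), c(0, 0, 0), c(1e-12, 1e-12, 0))
  out <- normalize_rows(m)
  expect_equal(out[1, ], c(0.25, 0.25, 0.5))
  expect_equal(out[2, ], c(0, 0, 0))       # unchanged
  expect_equal(out[3, ], c(0.5, 0.5, 0))   # scale invariance
  expect_equal(attr(out, "degenerate"), 2L)
  expect_error(normalize_rows(rbind(c(-1, 2))), "negative")
})

test_that("build_blueprint reproduces hand-computed products", {
  ts <- tract_set(c("t1", "t2", "t3"))
  vb <- vertex_to_brain_matrix(rbind(c(1, 0), c(0, 1)))
  bt <- brain_to_tract_matrix(rbind(c(1, 0, 0), c(0, 1, 1)), ts)
  bp <- build_blueprint(vb, bt, epsilon = 0)
  expect_equal(unname(bp$matrix), rbind(c(1, 0, 0), c(0, 0.5, 0.5)))

  # identity vertex-to-brain seeding returns bt row-normalized
  vb_id <- vertex_to_brain_matrix(diag(2))
  expect_equal(unname(build_blueprint(vb_id, bt, epsilon = 0)$matrix),
               normalize_rows(rbind(c(1, 0, 0), c(0, 1, 1))),
               ignore_attr = TRUE)
})

test_that("all-zero vertex rows are masked degenerate without touching others", {
  ts <- tract_set(c("t1", "t2", "t3"))
  vb <- vertex_to_brain_matrix(rbind(c(2, 0), c(0, 0), c(0, 3)))
  bt <- brain_to_tract_matrix(rbind(c(1, 0, 0), c(0, 1, 1)), ts)
  expect_warning(bp <- build_blueprint(vb, bt, epsilon = 0), "degenerate")
  expect_false(bp$vertex_mask[2])
  expect_equal(bp$degenerate, 2L)
  expect_equal(unname(bp$matrix[c(1, 3), ]),
               rbind(c(1, 0, 0), c(0, 0.5, 0.5)))
  expect_true(all(is.na(bp$matrix[2, ])))
})

test_that("build_blueprint rejects shape mismatches and negative input", {
  ts <- tract_set(c("t1", "t2"))
  vb <- vertex_to_brain_matrix(matrix(1, 3, 4))
  bt <- brain_to_tract_matrix(matrix(1, 5, 2), ts)
  expect_error(build_blueprint(vb, bt), "3x4.*5x2")
  expect_error(vertex_to_brain_matrix(matrix(-1, 2, 2)), "non-negative")
  expect_error(brain_to_tract_matrix(matrix(-1, 2, 2), ts), "non-negative")
})

test_that("blueprints stay row-stochastic and invariant to row rescaling", {
  set.seed(11)
  ts <- tract_set(sprintf("t%d", 1:5))
  for (rep in 1:5) {
    vb_m <- matrix(rgamma(10 * 20, 2), 10, 20)
    bt_m <- matrix(rgamma(20 * 5, 2), 20, 5)
    bp <- build_blueprint(vertex_to_brain_matrix(vb_m),
                          brain_to_tract_matrix(bt_m, ts))
    expect_true(all(abs(rowSums(bp$matrix) - 1) < 1e-9))

    # positive rescaling of one vb row leaves that fingerprint unchanged
    vb_m2 <- vb_m
    vb_m2[3, ] <- vb_m2[3, ] * runif(1, 0.01, 100)
    bp2 <- build_blueprint(vertex_to_brain_matrix(vb_m2),
                           brain_to_tract_matrix(bt_m, ts))
    expect_equal(bp2$matrix[3, ], bp$matrix[3, ], tolerance = 1e-12)
  }
})

test_that("vectorized blueprint product equals the naive triple-loop oracle", {
  set.seed(21)
  ts <- tract_set(sprintf("t%d", 1:5))
  vb_m <- matrix(rgamma(10 * 20, 1), 10, 20)
  bt_m <- matrix(rgamma(20 * 5, 1), 20, 5)
  bp <- build_blueprint(vertex_to_brain_matrix(vb_m),
                        brain_to_tract_matrix(bt_m, ts), epsilon = 0)
  expect_equal(unname(bp$matrix), oracle_blueprint_product(vb_m, bt_m),
               tolerance = 1e-12)
})

test_that("averaging blueprints is idempotent, symmetric and stays stochastic", {
  ts <- tract_set(c("t1", "t2"))
  bp1 <- connectivity_blueprint(rbind(c(1, 0)), ts, epsilon = 0)
  bp2 <- connectivity_blueprint(rbind(c(0, 1)), ts, epsilon = 0)
  expect_equal(average_blueprints(list(bp1, bp1))$matrix, bp1$matrix)
  expect_equal(unname(average_blueprints(list(bp1, bp2))$matrix),
               rbind(c(0.5, 0.5)))

  # for already-stochastic rows, renormalizing the mean is the mean
  set.seed(31)
  a <- random_blueprint(8, 4)
  b <- random_blueprint(8, 4)
  avg <- average_blueprints(list(a, b))
  expect_equal(avg$matrix, (a$matrix + b$matrix) / 2, tolerance = 1e-12)
  expect_true(all(abs(rowSums(avg$matrix) - 1) < 1e-9))

  # vertex masked in any input is masked in the output
  c_bp <- connectivity_blueprint(rbind(c(1, 1), c(2, 2)),
                                 tract_set(c("t1", "t2")),
                                 vertex_mask = c(TRUE, FALSE))
  d_bp <- connectivity_blueprint(rbind(c(1, 3), c(1, 1)),
                                 tract_set(c("t1", "t2")))
  expect_equal(average_blueprints(list(c_bp, d_bp))$vertex_mask,
               c(TRUE, FALSE))

  expect_error(average_blueprints(list(a, random_blueprint(9, 4))),
               "vertex counts")
  wrong <- connectivity_blueprint(random_stochastic(8, 4),
                                  tract_set(sprintf("x%02d", 1:4)),
                                  epsilon = 0)
  expect_error(average_blueprints(list(a, wrong)), "mismatched tract")
})

test_that("the epsilon floor keeps fingerprints strictly positive and stochastic", {
  ts <- tract_set(c("t1", "t2", "t3"))
  bp <- connectivity_blueprint(rbind(c(1, 0, 0)), ts, epsilon = 1e-8)
  expect_true(all(bp$matrix > 0))
  expect_equal(sum(bp$matrix), 1, tolerance = 1e-12)
  expect_equal(unname(bp$matrix[1, 1]), (1 + 1e-8) / (1 + 3e-8))
})
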