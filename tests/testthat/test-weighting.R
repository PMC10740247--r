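test_that("frequencies count presences or sum abundances per row", {
  m <- sparse_data_matrix(rbind(c(1, 0, 1, 0, 1),
                                c(0, 0, 0, 0, 0),
                                c(0.2, 0, 0.5, 0, 0)))
  expect_equal(unname(compute_frequencies(m, "nonzero_count")), c(3, 0, 2))
  expect_equal(unname(compute_frequencies(m, "row_sum")), c(3, 0, 0.7))
})

test_that("polynomial evaluation is Horner-exact and rejects negatives", {
  quartic <- polynomial_spec()                    # eta^4
  expect_equal(unname(evaluate_polynomial(quartic, c(2, 1, 0))),
               c(16, 1, 0))
  linear <- polynomial_spec(c(1, 1))              # 1 + eta
  expect_equal(unname(evaluate_polynomial(linear, 3)), 4)
  falling <- polynomial_spec(c(1, -1))            # 1 - eta, negative at 3
  expect_error(evaluate_polynomial(falling, c(f1 = 3)), "negative value.*f1")
  expect_error(polynomial_spec(c(0, 0)), "non-zero")
})

test_that("weight normalization is proportional, sums to 1, rejects zeros", {
  expect_equal(normalize_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(normalize_weights(c(1, 16)), c(1 / 17, 16 / 17))
  expect_error(normalize_weights(c(0, 0, 0)), "no informative features")
  set.seed(11)
  for (i in 1:20) {
    v <- stats::rexp(sample(2:30, 1))
    expect_equal(sum(normalize_weights(v)), 1, tolerance = 1e-12)
  }
})

test_that("applying weights scales rows exactly and preserves shape", {
  m <- sparse_data_matrix(rbind(a = c(2, 4), b = c(1, 3), c = c(0, 0)))
  d <- apply_weights(m, c(0.5, 1, 0))
  expect_equal(d["a", ], c(1, 2), ignore_attr = TRUE)
  expect_equal(d["b", ], c(1, 3), ignore_attr = TRUE)
  expect_true(all(d["c", ] == 0))
  expect_identical(dimnames(d), dimnames(m))
  expect_error(apply_weights(m, c(0.5, 0.5)), "length of weights")
})

test_that("uniform frequencies give uniform weights and a rescaled matrix", {
  m <- sparse_data_matrix(rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0)))
  s <- weight_scheme(m)
  expect_equal(unname(s$weights), rep(1 / 3, 3))
  expect_equal(unclass(apply_weights(m, s)), unclass(m) / 3,
               ignore_attr = TRUE)
})

test_that("weights are invariant to positive rescaling of the polynomial", {
  set.seed(21)
  for (i in 1:10) {
    sim <- generate_planted(synthetic_spec(m = 30, n = 15, k_true = 2,
                                           n_signature = 5, seed = i))
    freq <- compute_frequencies(sim$matrix)
    p1 <- polynomial_spec(c(0, 0, 1, 2))
    p2 <- polynomial_spec(c(0, 0, 1, 2) * 7.3)
    w1 <- normalize_weights(evaluate_polynomial(p1, freq))
    w2 <- normalize_weights(evaluate_polynomial(p2, freq))
    expect_equal(w1, w2, tolerance = 1e-12)
  }
})

test_that("row-wise division by non-zero weights reconstructs the input", {
  sim <- generate_planted(synthetic_spec(m = 40, n = 25, k_true = 2,
                                         n_signature = 8, p_background = 0.1,
                                         seed = 5))
  s <- suppressWarnings(weight_scheme(sim$matrix))
  d <- apply_weights(sim$matrix, s)
  nz <- s$weights > 0
  expect_identical(unclass(d)[nz, ] / s$weights[nz],
                   unclass(sim$matrix)[nz, ])
})

test_that("even monomials weight strictly by frequency order", {
  freq <- c(0, 1, 3, 7, 7.5, 20)
  for (deg in c(2, 4, 6)) {
    poly <- polynomial_spec(c(rep(0, deg), 1))
    w <- normalize_weights(evaluate_polynomial(poly, freq))
    expect_true(all(diff(w) > 0))
  }
})

test_that("zero-frequency features are retained with weight zero, warned", {
  m <- sparse_data_matrix(rbind(a = c(1, 1), b = c(0, 0), c = c(1, 0)))
  expect_warning(s <- weight_scheme(m), "zero weight")
  expect_equal(unname(s$weights[2]), 0)
  expect_equal(sum(s$weights), 1)
  expect_identical(nrow(apply_weights(m, s)), 3L)
})
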