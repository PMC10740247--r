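test_that("degenerate and infeasible specifications are handled", {
  spec1 <- synthetic_spec(m = 20, n = 10, k_true = 1, n_signature = 5,
                          seed = 2)
  sim <- generate_planted(spec1)
  expect_true(all(sim$labels == 1L))
  expect_error(synthetic_spec(m = 10, n = 10, k_true = 3, n_signature = 5),
               "infeasible")
  expect_error(synthetic_spec(m = 20, n = 10, k_true = 2,
                              p_signature = 0.2, p_background = 0.5),
               "p_background < p_signature")
  expect_error(synthetic_spec(m = 20, n = 10, k_true = 2,
                              proportions = c(0.9, 0.2)), "sum to 1")
})

test_that("generation is deterministic per seed and respects the spec", {
  spec <- synthetic_spec(m = 50, n = 40, k_true = 3, n_signature = 8,
                         seed = 77)
  s1 <- generate_planted(spec)
  s2 <- generate_planted(spec)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$labels, s2$labels)
  expect_identical(dim(s1$matrix), c(50L, 40L))
  expect_length(s1$labels, 40L)
  expect_true(all(tabulate(s1$labels, 3L) >= 1L))
  # disjoint signature sets
  expect_identical(anyDuplicated(unlist(s1$signature_features)), 0L)
})

test_that("realized density matches its closed-form expectation", {
  spec <- synthetic_spec(m = 100, n = 60, k_true = 3, n_signature = 10,
                         p_signature = 0.5, p_background = 0.02)
  p <- expected_density(spec)
  expect_equal(p, (10 * 0.5 + 90 * 0.02) / 100)
  dens <- sapply(1:50, function(s) {
    spec$seed <- s
    matrix_density(generate_planted(spec)$matrix)
  })
  # 99% binomial band for the mean of 50 realizations of m*n Bernoulli draws
  se <- sqrt(p * (1 - p) / (100 * 60 * 50))
  expect_lt(abs(mean(dens) - p), 2.58 * se * 1.5)
})

test_that("abundance model yields positive continuous values at presences", {
  spec <- synthetic_spec(m = 40, n = 30, k_true = 2, n_signature = 6,
                         value_model = "lognormal_abundance", seed = 5)
  sim <- generate_planted(spec)
  vals <- unclass(sim$matrix)
  nz <- vals[vals > 0]
  expect_true(all(nz > 0))
  expect_gt(length(unique(nz)), length(nz) * 0.9)  # continuous, not 0/1
})

test_that("presets hit the cohort-like shapes and sparsities", {
  presets <- cohort_presets(seed = 1)
  expect_named(presets, c("gastric_like", "colon_like"))
  g <- presets$gastric_like
  expect_identical(c(g$m, g$n), c(69L, 331L))
  dens <- sapply(1:20, function(s) {
    g$seed <- s
    matrix_density(generate_planted(g)$matrix)
  })
  expect_true(all(dens >= 0.010 & dens <= 0.025))
  cl <- presets$colon_like
  expect_identical(c(cl$m, cl$n), c(221L, 195L))
  sim <- generate_planted(cl)
  expect_true(all(unclass(sim$matrix) >= 0))
  expect_equal(matrix_density(sim$matrix), expected_density(cl),
               tolerance = 0.25)
  # reproducible per seed
  expect_identical(unclass(generate_planted(cl)$matrix),
                   unclass(generate_planted(cl)$matrix))
})

test_that("strong planted signatures are recovered perfectly at k_true", {
  for (s in 1:5) {
    sim <- generate_planted(synthetic_spec(m = 60, n = 40, k_true = 2,
                                           n_signature = 10,
                                           p_signature = 0.9,
                                           p_background = 0.01, seed = s))
    a <- suppressWarnings(pwsc_cluster(sim$matrix, 2))
    expect_equal(mclust::adjustedRandIndex(a$labels, sim$labels), 1.0)
  }
})
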