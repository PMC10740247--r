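test_that("connectivity and indicator matrices follow the co-membership rule", {
  a <- cluster_assignment(c(1L, 1L, 2L))
  cm <- connectivity_matrix(a, 1:3, 3)
  expect_identical(cm$M, matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3))
  expect_identical(cm$U, matrix(1L, 3, 3))

  # sample 3 excluded: its rows/cols all zero, diagonal included
  a2 <- cluster_assignment(c(1L, 2L))
  cm2 <- connectivity_matrix(a2, c(1L, 2L), 3)
  expect_true(all(cm2$M[3, ] == 0L) && all(cm2$M[, 3] == 0L))
  expect_true(all(cm2$U[3, ] == 0L) && all(cm2$U[, 3] == 0L))

  # one cluster: M coincides with U on the subset
  a3 <- cluster_assignment(rep(1L, 3))
  cm3 <- connectivity_matrix(a3, 1:3, 3)
  expect_identical(cm3$M, cm3$U)

  expect_error(connectivity_matrix(a2, 1:3, 3), "covers 2 samples")
})

test_that("consensus entries are co-clustered over co-selected ratios", {
  M1 <- matrix(c(1L, 1L, 1L, 1L), 2); U1 <- matrix(1L, 2, 2)
  M2 <- matrix(c(1L, 0L, 0L, 1L), 2); U2 <- matrix(1L, 2, 2)
  res <- consensus_matrix(list(M1, M1), list(U1, U1))
  expect_equal(res$consensus[1, 2], 1)
  res <- consensus_matrix(list(M1, M2), list(U1, U2))
  expect_equal(res$consensus[1, 2], 0.5)
  # never co-selected -> 0 with a warning, diagonal forced to 1
  U0 <- diag(2L); M0 <- diag(2L)
  expect_warning(res <- consensus_matrix(list(M0), list(U0)),
                 "never co-selected")
  expect_equal(res$consensus[1, 2], 0)
  expect_equal(diag(res$consensus), c(1, 1))
  expect_error(consensus_matrix(list(), list()), "non-empty")
})

test_that("unperturbed resampling yields a binary consensus and PAC 0", {
  sim <- generate_planted(synthetic_spec(m = 30, n = 20, k_true = 2,
                                         n_signature = 6, seed = 2))
  plan <- resampling_plan(n_iterations = 10, sample_fraction = 1.0, seed = 4)
  res <- suppressWarnings(run_consensus(sim$matrix, 2:4, plan))
  for (r in res) {
    expect_true(all(r$consensus %in% c(0, 1)))
    expect_true(isSymmetric(r$consensus))
    expect_equal(diag(r$consensus), rep(1, 20), ignore_attr = TRUE)
    expect_equal(consensus_cdf(r)$pac, 0)
  }
})

test_that("consensus runs are deterministic given the plan seed", {
  sim <- generate_planted(synthetic_spec(m = 25, n = 18, k_true = 2,
                                         n_signature = 5, seed = 6))
  plan <- resampling_plan(n_iterations = 25, sample_fraction = 0.8, seed = 99)
  r1 <- suppressWarnings(run_consensus(sim$matrix, 2:3, plan))
  r2 <- suppressWarnings(run_consensus(sim$matrix, 2:3, plan))
  expect_identical(r1, r2)
})

test_that("consensus matrices are valid probability matrices", {
  sim <- generate_planted(synthetic_spec(m = 25, n = 18, k_true = 3,
                                         n_signature = 5, seed = 8))
  plan <- resampling_plan(n_iterations = 40, sample_fraction = 0.7, seed = 3)
  res <- suppressWarnings(run_consensus(sim$matrix, 2:4, plan))
  for (r in res) {
    C <- r$consensus
    expect_true(all(C >= 0 & C <= 1))
    expect_true(isSymmetric(C))
    expect_equal(diag(C), rep(1, 18), ignore_attr = TRUE)
    idx <- r$co_select_counts > 0
    expect_equal(C[idx & upper.tri(C)],
                 (r$co_cluster_counts / r$co_select_counts)[idx & upper.tri(C)])
  }
})

test_that("PAC reproduces closed forms on constructed consensus matrices", {
  make_C <- function(vals, n) {
    C <- matrix(0, n, n)
    C[upper.tri(C)] <- vals
    C <- C + t(C); diag(C) <- 1
    C
  }
  n <- 5; npair <- choose(n, 2)
  expect_equal(consensus_cdf(make_C(rep(c(0, 1), length.out = npair), n))$pac, 0)
  expect_equal(consensus_cdf(make_C(rep(0.5, npair), n))$pac, 1)
  expect_equal(consensus_cdf(make_C(rep(c(0.5, 1), each = 5), n))$pac, 0.5)
})

test_that("PAC falls as mass moves out of the ambiguous band", {
  n <- 9; npair <- choose(n, 2)
  frac_mid <- c(1, 0.75, 0.5, 0.25, 0)
  pacs <- sapply(frac_mid, function(f) {
    vals <- c(rep(0.5, round(f * npair)), rep(1, npair - round(f * npair)))
    C <- matrix(0, n, n); C[upper.tri(C)] <- vals
    C <- C + t(C); diag(C) <- 1
    consensus_cdf(C)$pac
  })
  expect_true(all(diff(pacs) < 0))
})

test_that("within-cluster consensus beats between and sharpens with H", {
  sim <- generate_planted(synthetic_spec(m = 60, n = 30, k_true = 3,
                                         n_signature = 10, p_signature = 0.6,
                                         p_background = 0.01, seed = 12))
  truth <- outer(sim$labels, sim$labels, "==")
  mean_sep <- function(H) {
    plan <- resampling_plan(H, 0.8, seed = 7)
    r <- suppressWarnings(run_consensus(sim$matrix, 3, plan))[[1]]
    C <- r$consensus
    ut <- upper.tri(C)
    mean(C[truth & ut]) - mean(C[!truth & ut])
  }
  sep25 <- mean_sep(25); sep200 <- mean_sep(200)
  expect_gt(sep25, 0)
  expect_gt(sep200, sep25)
})

test_that("k selection picks lowest PAC, ties toward smaller k", {
  mk <- function(k, pac, area) structure(list(k = k, pac = pac, area = area),
                                         class = "cdf_summary")
  sel <- select_optimal_k(list(mk(2, 0.4, 0.3), mk(3, 0.05, 0.5),
                               mk(4, 0.3, 0.6)))
  expect_identical(sel$k, 3)
  expect_equal(sel$table$delta_area,
               c(0.3, (0.5 - 0.3) / 0.3, (0.6 - 0.5) / 0.5))
  sel_tie <- select_optimal_k(list(mk(4, 0.1, 0.3), mk(6, 0.2, 0.4),
                                   mk(8, 0.1, 0.5)))
  expect_identical(sel_tie$k, 4)
  expect_error(select_optimal_k(list(mk(2, 0.1, 0.2))), "at least two")
})

test_that("plans and k ranges are validated", {
  sim <- generate_planted(synthetic_spec(m = 20, n = 12, k_true = 2,
                                         n_signature = 4, seed = 1))
  expect_error(resampling_plan(sample_fraction = 0), "sample_fraction")
  expect_error(
    suppressWarnings(run_consensus(sim$matrix, 2:12,
                                   resampling_plan(5, 0.8, 1))),
    "k_range")
  expect_error(
    suppressWarnings(run_consensus(sim$matrix, 2:9,
                                   resampling_plan(5, 0.5, 1))),
    "subsample size")
})
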