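test_that("truncated SVD satisfies its orthogonality and truncation contracts", {
  set.seed(101)
  for (dims in list(c(8, 30), c(12, 50))) {
    D <- matrix(runif(prod(dims)), dims[1], dims[2])
    s <- 4
    sv <- truncated_svd(D, s)
    expect_lt(max(abs(crossprod(sv$U) - diag(s))), 1e-10)
    expect_lt(max(abs(crossprod(sv$V) - diag(s))), 1e-10)
    expect_true(all(diff(sv$d) <= 1e-12 * sv$d[1]))
    # optimal truncation: Frobenius error equals the root-sum-square of the
    # discarded singular values
    err <- sqrt(sum((D - sv$US %*% t(sv$V))^2))
    expect_equal(err, sqrt(sum(sv$all_d[-seq_len(s)]^2)),
                 tolerance = 1e-8)
  }
})

test_that("rank-1 input yields a numerically zero second singular value", {
  u <- runif(10); v <- runif(25)
  sv <- truncated_svd(u %*% t(v), 2)
  expect_lt(sv$d[2], 1e-12 * sv$d[1])
})

test_that("noiseless three-component data reconstructs at rank 3", {
  set.seed(7)
  C <- matrix(runif(12 * 3), 12, 3)
  S <- matrix(runif(40 * 3), 40, 3)
  D <- C %*% t(S)
  sv <- truncated_svd(D, 3)
  expect_lt(sqrt(sum((D - sv$US %*% t(sv$V))^2)) / sqrt(sum(D^2)), 1e-10)
})

test_that("singular vector orientation is deterministic", {
  sim <- fx_noiseless()
  sv1 <- truncated_svd(sim$dataset, 3)
  sv2 <- truncated_svd(sim$dataset$absorbance, 3)
  expect_identical(sv1$V, sv2$V)
  for (i in 1:3) expect_gt(sv1$V[which.max(abs(sv1$V[, i])), i], 0)
})

test_that("truncated_svd rejects out-of-range component counts", {
  D <- matrix(runif(20), 4, 5)
  expect_error(truncated_svd(D, 0), "1 <= s")
  expect_error(truncated_svd(D, 5), "1 <= s")
})

test_that("estimate_rank implements the relative-threshold definition", {
  expect_identical(estimate_rank(c(10, 5, 1, 1e-6), 1e-3), 3L)
  expect_identical(estimate_rank(c(1, 0, 0), 1e-3), 1L)
  expect_identical(estimate_rank(c(0, 0), 1e-3), 0L)
  expect_error(estimate_rank(numeric(0)), "nonempty")
  expect_error(estimate_rank(c(1, 2), 1e-3), "nonincreasing")
  expect_error(estimate_rank(c(1, 0.5), 2), "in \\(0, 1\\)")
  # on a noiseless 3-component spectrum, any threshold between the noise
  # floor and sigma_3/sigma_1 yields 3
  d <- truncated_svd(fx_noiseless()$dataset, 3)$all_d
  for (thr in c(1e-8, 1e-4, 0.9 * d[3] / d[1]))
    expect_identical(estimate_rank(d, thr), 3L)
})

test_that("build_T assembles the all-ones-column transform", {
  T <- build_T(c(0, 0), diag(2))
  expect_equal(unclass(T), cbind(1, rbind(c(0, 0), diag(2))),
               ignore_attr = TRUE)
  # cofactor expansion along the first row: det = 1 * det(I) = 1
  expect_equal(det(T), 1)
  T2 <- build_T(0.3, matrix(0.8))
  expect_equal(unclass(T2), matrix(c(1, 1, 0.3, 0.8), 2, 2),
               ignore_attr = TRUE)
  expect_equal(det(T2), 0.8 - 0.3)
  Tsing <- build_T(c(1, 2), rbind(c(3, 4), c(3, 4)))
  expect_lt(abs(det(Tsing)), 1e-12)
  expect_error(build_T(c(1, 2), diag(3)), "2 x 2")
  expect_error(build_T(c(1, Inf), diag(2)), "finite")
})

test_that("factors_from_T reproduces the truncated data for any regular T", {
  sv <- fx_small()$svd
  # the identity transform returns the abstract factors U Sigma and V
  fp <- factors_from_T(sv, diag(3))
  expect_equal(fp$C, sv$US)
  expect_equal(fp$S, sv$V)
  D3 <- sv$US %*% t(sv$V)
  set.seed(5)
  for (i in 1:5) {
    T <- build_T(runif(2, -1, 1), matrix(runif(4, -1, 1), 2, 2))
    if (abs(det(T)) < 1e-3) next
    fp <- factors_from_T(sv, T)
    expect_lt(sqrt(sum((fp$C %*% t(fp$S) - D3)^2)) / sqrt(sum(D3^2)), 1e-10)
  }
  expect_error(factors_from_T(sv, build_T(c(1, 1), rbind(c(1, 1), c(1, 1)))),
               "singular")
})

test_that("a transform built from the true factors recovers the ground truth", {
  sim <- fx_small()
  sv <- sim$svd
  # rows of T are the AFS coordinates of the true spectra
  pts <- lapply(1:3, function(i)
    profile_to_afs_point(sv, sim$S_true[, i], "spectral"))
  T <- do.call(rbind, lapply(pts, function(p) c(1, p$point)))
  fp <- factors_from_T(sv, T)
  for (i in 1:3) {
    expect_gt(cos2(fp$S[, i], sim$S_true[, i]), 1 - 1e-10)
    expect_gt(cos2(fp$C[, i], sim$C_true[, i]), 1 - 1e-10)
  }
})

test_that("feasibility_violation implements the relative-negativity penalty", {
  sim <- fx_small()
  sv <- sim$svd
  pts <- lapply(1:3, function(i)
    profile_to_afs_point(sv, sim$S_true[, i], "spectral")$point)
  T_true <- do.call(rbind, lapply(pts, function(p) c(1, p)))
  # the exact nonnegative factorization has zero violation for any epsilon
  expect_equal(feasibility_violation(sv, T_true, feasibility_params(epsilon = 0)),
               0, tolerance = 1e-18)
  expect_identical(
    feasibility_violation(sv, build_T(c(1, 1), rbind(c(1, 1), c(1, 1)))),
    Inf)
})

test_that("violation equals the sum of squared shortfalls on a hand case", {
  # build a rank-2 dataset whose transform puts one entry of -0.01 into a
  # spectrum column with maximum 1
  s1 <- c(1, 0.5, 0.2, 0)
  s2 <- c(-0.01, 0.3, 1, 0.4)
  C <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1), c(0.2, 0.8), c(0.9, 0.1))
  D <- C %*% t(cbind(s1, s2))
  sv <- truncated_svd(D, 2)
  x2 <- profile_to_afs_point(sv, s2, "spectral")
  x1 <- profile_to_afs_point(sv, s1, "spectral")
  T <- rbind(c(1, x2$point), c(1, x1$point))
  v0 <- feasibility_violation(sv, T, feasibility_params(epsilon = 0))
  # only the s2 column violates: shortfall = 0.01 / 1 -> violation 1e-4
  expect_equal(v0, 1e-4, tolerance = 1e-6)
  expect_equal(
    feasibility_violation(sv, T, feasibility_params(epsilon = 2e-2)), 0)
})

test_that("violation is invariant under positive component rescaling", {
  sv <- fx_small()$svd
  set.seed(31)
  for (i in 1:10) {
    T <- build_T(runif(2, -1, 1), matrix(runif(4, -1, 1), 2, 2))
    if (abs(det(T)) < 1e-3) next
    v1 <- feasibility_violation(sv, T)
    # rescaling row j of T by gamma > 0 rescales S column j and the
    # compensating C column; the violation must not change
    gam <- diag(runif(3, 0.1, 10))
    v2 <- feasibility_violation(sv, gam %*% unclass(T))
    expect_equal(v1, v2, tolerance = 1e-10)
  }
})
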