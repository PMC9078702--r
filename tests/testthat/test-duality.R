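test_that("complementary columns of T^-1 lie on the dual line", {
  # the incidence theorem checked against explicit inversion
  set.seed(2024)
  for (rep in 1:20) {
    repeat {
      T <- cbind(1, matrix(runif(6, -2, 2), 3, 2))
      if (abs(det(T)) > 1e-3) break
    }
    Ti <- solve(T)
    for (row in 1:3) {
      ln <- dual_line(T[row, 2:3])
      for (col in setdiff(1:3, row)) {
        y <- Ti[2:3, col] / Ti[1, col]
        expect_lt(abs(sum(ln$normal * y) + ln$offset), 1e-8)
      }
    }
  }
})

test_that("duality is symmetric between the two factor sides", {
  # fixing a concentration point constrains spectral points on the same
  # line form: rows of T complementary to a column of T^-1 satisfy it
  set.seed(77)
  T <- cbind(1, matrix(runif(6, -1, 1), 3, 2))
  Ti <- solve(T)
  y2 <- Ti[2:3, 2] / Ti[1, 2]
  ln <- dual_line(y2)
  for (row in c(1, 3)) {
    x <- T[row, 2:3]
    expect_lt(abs(sum(ln$normal * x) + ln$offset), 1e-8)
  }
})

test_that("line intersection solves the 2 x 2 system", {
  l1 <- structure(list(normal = c(0, 1), offset = 0), class = "dual_line")
  l2 <- structure(list(normal = c(1, 0), offset = 0), class = "dual_line")
  expect_equal(intersect_lines(l1, l2), c(0, 0))
  l3 <- structure(list(normal = c(1, 1), offset = -1), class = "dual_line")
  l4 <- structure(list(normal = c(1, -1), offset = 0), class = "dual_line")
  expect_equal(intersect_lines(l3, l4), c(0.5, 0.5))
  expect_error(intersect_lines(l1, l1), "parallel")
  expect_error(dual_line(c(0, 0)), "degenerate")
})

test_that("profiles map to normalized expansion coefficients", {
  sim <- fx_small()
  sv <- sim$svd
  p0 <- profile_to_afs_point(sv, sv$V[, 1], "spectral")
  expect_equal(p0$point, c(0, 0), tolerance = 1e-12)
  # a measured spectrum lies in the truncated span of noiseless data
  row1 <- sim$dataset$absorbance[1, ]
  pr <- profile_to_afs_point(sv, row1, "spectral")
  expect_lt(pr$residual, 1e-10 * sqrt(sum(row1^2)))
  expect_true(point_feasible(sv, pr$point, feasibility_params())$feasible)
  # orthogonal input has no leading coefficient to normalize by
  expect_error(profile_to_afs_point(sv, sv$V[, 2], "spectral"),
               "leading expansion coefficient")
  expect_error(profile_to_afs_point(sv, rep(1, 5), "spectral"),
               "does not match")
})

test_that("the dual-line intersection pins the third component", {
  sim <- fx_small()
  sv <- sim$svd
  # fix the true spectra of components 1 and 3; their dual lines intersect
  # in the concentration point of the dimer
  x1 <- profile_to_afs_point(sv, sim$S_true[, 1], "spectral")$point
  x3 <- profile_to_afs_point(sv, sim$S_true[, 3], "spectral")$point
  y2_hat <- intersect_lines(dual_line(x1), dual_line(x3))
  y2 <- profile_to_afs_point(sv, sim$C_true[, 2], "concentrational")$point
  expect_lt(sqrt(sum((y2_hat - y2)^2)), 1e-6)
})

test_that("completion from two spectra and two profiles recovers the dimer", {
  sim <- fx_noiseless()
  sv <- truncated_svd(sim$dataset, 3)
  D <- sim$dataset$absorbance
  comp <- complete_factorization(
    sv,
    fixed_spectra = list(D[1, ], D[12, ]),
    fixed_profiles = list(sim$C_true[, 1], sim$C_true[, 3]),
    params = feasibility_params(epsilon = 0))
  expect_lt(comp$violation, 1e-12)
  # match output components to the ground truth by cosine
  best <- vapply(1:3, function(j)
    max(vapply(1:3, function(i) cos2(comp$S[, i], sim$S_true[, j]),
               numeric(1))), numeric(1))
  expect_true(all(best > 1 - 1e-8))
  bestC <- vapply(1:3, function(j)
    max(vapply(1:3, function(i) cos2(comp$C[, i], sim$C_true[, j]),
               numeric(1))), numeric(1))
  expect_true(all(bestC > 1 - 1e-8))
  # spectra are returned at unit maximum
  expect_equal(apply(comp$S, 2, max), rep(1, 3))
})

test_that("completion works from three fixes on one side", {
  sim <- fx_noiseless()
  sv <- truncated_svd(sim$dataset, 3)
  comp <- complete_factorization(
    sv,
    fixed_profiles = list(sim$C_true[, 1], sim$C_true[, 2], sim$C_true[, 3]),
    params = feasibility_params(epsilon = 0))
  for (j in 1:3) {
    expect_gt(max(vapply(1:3, function(i)
      cos2(comp$S[, i], sim$S_true[, j]), numeric(1))), 1 - 1e-8)
  }
})

test_that("two spectra plus one profile leave a line ambiguity", {
  # fixing the terminal spectra determines the dimer's concentration point
  # by duality, but the dimer's own spectrum still moves on a line: the
  # completion must refuse rather than guess
  sim <- fx_noiseless()
  sv <- truncated_svd(sim$dataset, 3)
  D <- sim$dataset$absorbance
  expect_error(
    complete_factorization(sv,
                           fixed_spectra = list(D[1, ], D[12, ]),
                           fixed_profiles = list(sim$C_true[, 1]),
                           params = feasibility_params(epsilon = 0)),
    "insufficient")
})

test_that("inconsistent or insufficient fixes are rejected", {
  sim <- fx_noiseless()
  sv <- truncated_svd(sim$dataset, 3)
  set.seed(9)
  bad <- lapply(1:3, function(i) runif(12, 0, 1e-3))
  expect_error(
    complete_factorization(sv, fixed_profiles = bad),
    "inconsistent")
  expect_error(
    complete_factorization(sv,
                           fixed_spectra = list(sim$dataset$absorbance[1, ])),
    "at least two")
})
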