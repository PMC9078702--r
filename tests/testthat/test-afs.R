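test_that("two-component intervals agree with the brute-force scan", {
  fx <- fx_two_comp()
  sv <- fx$svd
  reg <- afs_two_component(sv, feasibility_params(epsilon = 0))
  expect_length(reg$polygons, 2L)
  grid <- seq(-1.5, 2.5, length.out = 10000)
  oracle <- scan_two_component(sv, grid, eps = 0)
  runs <- rle(oracle)
  ends <- cumsum(runs$lengths)
  iv_oracle <- lapply(which(runs$values), function(i)
    c(grid[ends[i] - runs$lengths[i] + 1], grid[ends[i]]))
  expect_length(iv_oracle, 2L)
  spacing <- diff(grid[1:2])
  for (i in 1:2) {
    expect_lt(abs(min(reg$polygons[[i]]) - iv_oracle[[i]][1]), 2 * spacing)
    expect_lt(abs(max(reg$polygons[[i]]) - iv_oracle[[i]][2]), 2 * spacing)
  }
})

test_that("two-component intervals contain the true component coordinates", {
  fx <- fx_two_comp()
  reg <- afs_two_component(fx$svd, feasibility_params(epsilon = 0))
  x1 <- profile_to_afs_point(fx$svd, fx$S[, 1], "spectral")$point
  x2 <- profile_to_afs_point(fx$svd, fx$S[, 2], "spectral")$point
  expect_setequal(c(region_member(reg, x1, tol = 1e-6),
                    region_member(reg, x2, tol = 1e-6)), 1:2)
  # concentrational side contains the true profiles too (endpoint
  # resolution is eps_b scaled by the coordinate conversion)
  regc <- afs_two_component(fx$svd, feasibility_params(epsilon = 0),
                            "concentrational")
  y1 <- profile_to_afs_point(fx$svd, fx$C[, 1], "concentrational")$point
  y2 <- profile_to_afs_point(fx$svd, fx$C[, 2], "concentrational")$point
  tolc <- 1e-4 * fx$svd$d[1] / fx$svd$d[2]
  expect_setequal(c(region_member(regc, y1, tol = tolc),
                    region_member(regc, y2, tol = tolc)), 1:2)
})

test_that("two-component intervals weakly enlarge with epsilon", {
  fx <- fx_two_comp()
  r0 <- afs_two_component(fx$svd, feasibility_params(epsilon = 0))
  r1 <- afs_two_component(fx$svd, feasibility_params(epsilon = 2e-4))
  for (i in 1:2) {
    expect_lte(min(r1$polygons[[i]]), min(r0$polygons[[i]]) + 1e-4)
    expect_gte(max(r1$polygons[[i]]), max(r0$polygons[[i]]) - 1e-4)
  }
  expect_error(afs_two_component(fx_small()$svd), "s = 2")
})

test_that("point feasibility matches the interval characterization (s = 2)", {
  fx <- fx_two_comp()
  reg <- afs_two_component(fx$svd, feasibility_params(epsilon = 0))
  iv <- reg$polygons
  inside <- c(mean(iv[[1]]), mean(iv[[2]]))
  outside <- c(min(iv[[1]]) - 0.05, max(iv[[2]]) + 0.05,
               (max(iv[[1]]) + min(iv[[2]])) / 2)
  for (x in inside)
    expect_true(point_feasible(fx$svd, x, feasibility_params(epsilon = 0))$feasible)
  for (x in outside)
    expect_false(point_feasible(fx$svd, x, feasibility_params(epsilon = 0))$feasible)
})

test_that("three-component AFS has three isolated subsets containing truth", {
  sim <- fx_small()
  reg <- fx_small_region()
  expect_length(reg$polygons, 3L)
  # each true spectrum's coordinate lies inside exactly one polygon
  hits <- vapply(1:3, function(i) {
    x <- profile_to_afs_point(sim$svd, sim$S_true[, i], "spectral")$point
    region_member(reg, x, tol = 1e-4)
  }, integer(1))
  expect_setequal(hits, 1:3)
  # spot-check that traced boundary vertices are feasible
  pp <- reg$params
  some <- reg$polygons[[2]][round(seq(1, nrow(reg$polygons[[2]]),
                                      length.out = 5)), , drop = FALSE]
  for (v in seq_len(nrow(some)))
    expect_true(point_feasible(sim$svd, some[v, ], pp)$feasible)
})

test_that("points far outside the data simplex are infeasible", {
  sv <- fx_small()$svd
  far <- 1e3 * max(abs(sv$US[, 2:3] / sv$US[, 1]))
  res <- point_feasible(sv, c(far, far), feasibility_params())
  expect_false(res$feasible)
  expect_gt(res$value, feasibility_params()$delta^2)
})

test_that("unsupported component counts are rejected", {
  D <- matrix(runif(8 * 20), 8, 20)
  sv <- truncated_svd(D, 4)
  expect_error(point_feasible(sv, c(0, 0, 0)), "s = 2 or 3")
  expect_error(afs_three_component(truncated_svd(D, 2), "spectral"),
               "s = 3")
})

test_that("grid oracle is all-false far from the data and monotone in epsilon", {
  sv <- fx_small()$svd
  far_bbox <- c(50, 60, 50, 60)
  expect_false(any(afs_grid_oracle(sv, far_bbox, 10)))
  reg <- fx_small_region()
  bbox <- region_bbox(reg, 0.2)
  m0 <- afs_grid_oracle(sv, bbox, 40, feasibility_params(epsilon = 0))
  m1 <- afs_grid_oracle(sv, bbox, 40, feasibility_params(epsilon = 2e-4))
  expect_true(all(m1[m0]))        # pointwise containment
  expect_error(afs_grid_oracle(sv, bbox, 501), "<= 500")
})

test_that("mask component counting handles staircases and bridging", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE    # diagonal staircase: 1 subset
  m[7, 7] <- TRUE                          # isolated cell
  expect_identical(mask_components(m), 2L)
  m2 <- matrix(FALSE, 10, 10)
  m2[2, 2] <- m2[2, 5] <- TRUE             # 3-cell gap: bridged at 2
  expect_identical(mask_components(m2), 2L)
  expect_identical(mask_components(m2, bridge = 2), 1L)
  expect_identical(mask_components(matrix(FALSE, 3, 3)), 0L)
})

test_that("epsilon-monotonicity holds for the traced polygons", {
  r0 <- fx_small_region(eps = 0)
  r1 <- fx_small_region(eps = 2e-4)
  for (p in r0$polygons)
    for (v in seq_len(nrow(p)))
      expect_gt(region_member(r1, p[v, ], tol = 1e-4), 0)
})
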