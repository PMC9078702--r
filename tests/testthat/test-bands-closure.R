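test_that("a collapsed polygon yields a zero-width band", {
  sv <- fx_small()$svd
  pt <- profile_to_afs_point(sv, fx_small()$S_true[, 1], "spectral")$point
  reg <- afs_region("spectral", list(rbind(pt, pt, pt)),
                    params = feasibility_params(), validate = FALSE)
  env <- band_envelopes(sv, reg, 1, n_samples = 10, seed = 1)
  expect_equal(env$lower, env$upper, tolerance = 1e-12)
  expect_equal(env$upper, reconstruct_profile(sv, pt, "spectral"),
               tolerance = 1e-12)
})

test_that("band envelopes contain every sampled and held-out profile", {
  sim <- fx_small()
  reg <- fx_small_region()
  areas <- vapply(reg$polygons, function(p)
    abs(pracma::polyarea(p[, 1], p[, 2])), numeric(1))
  dimer <- which.max(areas)
  env <- band_envelopes(sim$svd, reg, dimer, n_samples = 150, seed = 3)
  expect_true(all(env$lower <= env$upper + 1e-12))
  expect_gte(env$n_samples, nrow(reg$polygons[[dimer]]))
  # held-out feasible points (fresh seed) stay inside the envelopes
  poly <- reg$polygons[[dimer]]
  set.seed(99)
  got <- 0
  while (got < 20) {
    p <- c(runif(1, min(poly[, 1]), max(poly[, 1])),
           runif(1, min(poly[, 2]), max(poly[, 2])))
    if (!pracma::inpolygon(p[1], p[2], poly[, 1], poly[, 2])) next
    got <- got + 1
    pr <- reconstruct_profile(sim$svd, p, "spectral")
    expect_true(all(pr >= env$lower - 1e-8 & pr <= env$upper + 1e-8))
  }
})

test_that("band width grows with the feasible region", {
  sim <- fx_small()
  r0 <- fx_small_region(eps = 0)
  r1 <- fx_small_region(eps = 2e-4)
  a0 <- vapply(r0$polygons, function(p) abs(pracma::polyarea(p[, 1], p[, 2])),
               numeric(1))
  i0 <- which.max(a0)
  e0 <- band_envelopes(sim$svd, r0, i0, n_samples = 120, seed = 5)
  # match the corresponding polygon in the enlarged region by its centroid
  ctr <- colMeans(r0$polygons[[i0]])
  i1 <- region_member(r1, ctr, tol = 1e-3)
  e1 <- band_envelopes(sim$svd, r1, i1, n_samples = 120, seed = 5)
  expect_gte(max(e1$upper - e1$lower), max(e0$upper - e0$lower) - 1e-6)
})

test_that("band_envelopes validates its inputs", {
  sv <- fx_small()$svd
  reg <- fx_small_region()
  expect_error(band_envelopes(sv, reg, 7), "no such component")
  empty <- afs_region("spectral", list(matrix(numeric(0), 0, 2)),
                      params = feasibility_params(), validate = FALSE)
  expect_error(band_envelopes(sv, empty, 1), "empty AFS subset")
})

test_that("closure scaling recovers constructed gammas exactly", {
  sim <- fx_noiseless()
  spec <- closure_spec(c(1, 2, 1), sim$config$c0)
  # already-consistent C: gammas are all one and the flag is off
  sc <- closure_scale(sim$C_true, spec)
  expect_equal(sc$gammas, rep(1, 3), tolerance = 1e-10)
  expect_false(sc$ambiguous_scale)
  # columns premultiplied by (2, 0.5, 3) are undone
  Cw <- sweep(sim$C_true, 2, c(2, 0.5, 3), `*`)
  sc2 <- closure_scale(Cw, spec)
  expect_equal(sc2$gammas, c(0.5, 2, 1 / 3), tolerance = 1e-10)
  expect_equal(sc2$C, sim$C_true, tolerance = 1e-12)
})

test_that("closure_ssq implements the weighted-sum residual", {
  spec <- closure_spec(c(1, 2, 1), 1e-3)
  C <- cbind(c(5e-4, 3e-4), c(1e-4, 2e-4), c(3e-4, 3e-4))
  expect_equal(closure_ssq(C, spec), 0)
  C2 <- C; C2[1, 1] <- C2[1, 1] + 2e-4
  expect_equal(closure_ssq(C2, spec), 4e-8)
  # hand case: deviations (1e-4, 2e-4) -> 5e-8
  C3 <- C; C3[1, 1] <- C3[1, 1] + 1e-4; C3[2, 1] <- C3[2, 1] + 2e-4
  expect_equal(closure_ssq(C3, spec), 5e-8)
})

test_that("the fitted gammas are least-squares optimal", {
  sim <- fx_noiseless()
  spec <- closure_spec(c(1, 2, 1), sim$config$c0)
  Cw <- sweep(sim$C_true, 2, c(1.7, 0.4, 2.2), `*`)
  sc <- closure_scale(Cw, spec)
  base <- closure_ssq(sc$C, spec)
  set.seed(12)
  for (i in 1:20) {
    gam <- sc$gammas * runif(3, 0.8, 1.25)
    expect_gte(closure_ssq(sweep(Cw, 2, gam, `*`), spec), base - 1e-20)
  }
})

test_that("rank-deficient closure systems raise the ambiguity flag", {
  # two proportional columns cannot be separated by one closure equation
  c1 <- seq(1e-4, 9e-4, length.out = 12)
  C <- cbind(c1, 2 * c1, c1)
  spec <- closure_spec(c(1, 2, 1), 9.84269e-4)
  res <- tryCatch(closure_scale(C, spec), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "positive")
  } else {
    expect_true(res$ambiguous_scale)
  }
  expect_error(closure_scale(cbind(c1, 0 * c1, c1), spec), "zero column")
  expect_error(closure_spec(c(1, -2, 1), 1e-3), "positive")
})
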