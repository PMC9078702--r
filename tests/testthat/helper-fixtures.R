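# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

cos2 <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# full-size (12 x 401) synthetic datasets
fx_noiseless <- function() fixture("noiseless", function() {
  generate_dataset(synthetic_config(noise_sigma = 0))
})

fx_noisy <- function() fixture("noisy", function() {
  generate_dataset(synthetic_config())      # default noise 1e-4, seed 1
})

# smaller noiseless instance for tracing-heavy unit tests
fx_small <- function() fixture("small", function() {
  sim <- generate_dataset(synthetic_config(noise_sigma = 0, n_channels = 201))
  sim$svd <- truncated_svd(sim$dataset, 3)
  sim
})

fx_small_region <- function(eps = 2e-4) {
  key <- paste0("small_region_", eps)
  fixture(key, function() {
    afs_three_component(fx_small()$svd, "spectral",
                        feasibility_params(epsilon = eps))
  })
}

# two-component system with partial conversion (both intervals have width)
fx_two_comp <- function() fixture("two_comp", function() {
  wl <- seq(200, 600, length.out = 201)
  S <- cbind(gaussian_spectrum(rbind(c(280, 25, 900), c(350, 30, 400)), wl),
             gaussian_spectrum(rbind(c(330, 25, 300), c(450, 35, 800)), wl))
  a <- seq(0, 1e-3, length.out = 10)
  c0 <- 8e-4
  f <- 0.1 + 0.8 * a / max(a)
  C <- cbind(c0 * (1 - f), c0 * f)
  ds <- spectral_dataset(C %*% t(S), wl, a, closure_c0 = c0)
  list(dataset = ds, C = C, S = S, c0 = c0,
       svd = truncated_svd(ds, 2))
})

# vectorized 1-D brute-force feasibility scan for two-component systems:
# checks explicit (epsilon-relaxed) nonnegativity of both completed
# profiles over a w-grid, independent of the closed-form construction
scan_two_component <- function(sv, grid, eps = 0, tolr = 1e-10) {
  okv <- function(M) apply(M, 2, function(v)
    min(v) >= -(eps + tolr) * max(abs(v)))
  Sg <- outer(sv$V[, 1], rep(1, length(grid))) + outer(sv$V[, 2], grid)
  G <- outer(sv$US[, 2], rep(1, length(grid))) - outer(sv$US[, 1], grid)
  A <- okv(Sg)              # candidate spectrum nonnegative
  Gp <- okv(G)              # complementary conc profile sign (+) branch
  Gm <- okv(-G)             # sign (-) branch
  right_ok <- rev(cumsum(rev(A & Gm))) > 0
  left_ok <- cumsum(A & Gp) > 0
  ex_right <- c(right_ok[-1], FALSE)
  ex_left <- c(FALSE, left_ok[-length(grid)])
  A & ((Gp & ex_right) | (Gm & ex_left))
}
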