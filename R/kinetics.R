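#' Kinetic model of the consecutive protonation/dimerization titration
#'
#' The three absorbing species are the free dye (component 1), the
#' protonated dimer (component 2) and the protonated monomer (component 3).
#' Added acid first protonates the dye, which dimerizes with a second dye
#' molecule; further acid splits the dimer into two protonated monomers.
#' Both back reactions are switched off by default (`k1_rev = k2_rev = 0`),
#' appropriate for titration with a superacid.
#'
#' @param k1 Rate coefficient of the protonation/dimerization step
#'   (l^2 mol^-2; acts on `c1^2`). Must be >= 0.
#' @param k2 Rate coefficient of the dimer-splitting step (l mol^-1; acts
#'   on `c2`). Must be >= 0.
#' @param c0 Initial dye concentration (mol/l), > 0.
#' @param k1_rev,k2_rev Back-reaction coefficients, fixed to 0 by default
#'   and currently required to be 0 (reversible fitting is out of scope).
#'
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(k1, k2, c0, k1_rev = 0, k2_rev = 0) {
  if (!is.numeric(k1) || length(k1) != 1 || k1 < 0)
    stop_arg("`k1` must be a single nonnegative number")
  if (!is.numeric(k2) || length(k2) != 1 || k2 < 0)
    stop_arg("`k2` must be a single nonnegative number")
  if (!is.numeric(c0) || length(c0) != 1 || c0 <= 0)
    stop_arg("`c0` must be a single positive number")
  if (k1_rev != 0 || k2_rev != 0)
    stop_arg("back reactions are not supported; k1_rev and k2_rev must be 0")
  structure(list(k1 = k1, k2 = k2, c0 = c0,
                 k1_rev = k1_rev, k2_rev = k2_rev),
            class = "kinetic_model")
}

#' Simulate equilibrium concentration profiles along the acid axis
#'
#' Integrates the competitive-consumption system in the added-acid
#' coordinate `a` (mol/l of acid added): each increment of acid is consumed
#' by the two reactions in proportion to their instantaneous rates,
#' \deqn{r_1 = \frac{k_1 c_1^2}{k_1 c_1^2 + k_2 c_2 + \eta},\qquad
#'       r_2 = \frac{k_2 c_2}{k_1 c_1^2 + k_2 c_2 + \eta}}
#' with a small guard \eqn{\eta = 10^{-30}}, and
#' \deqn{dc_1/da = -2 r_1,\quad dc_2/da = r_1 - r_2,\quad dc_3/da = 2 r_2}
#' from the initial state `(c0, 0, 0)`. The weighted sum
#' `c1 + 2 c2 + c3 = c0` (closure) is conserved exactly by construction and
#' to integrator precision numerically.
#'
#' @param model A [kinetic_model()].
#' @param acid_grid Nondecreasing added-acid concentrations (mol/l),
#'   starting at 0.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#'
#' @return A k x 3 matrix of concentrations (mol/l), one row per grid point,
#'   columns = components.
#' @export
simulate_titration <- function(model, acid_grid, rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(model, "kinetic_model"))
  a <- as.numeric(acid_grid)
  if (length(a) < 1 || a[1] != 0)
    stop_arg("`acid_grid` must start at 0")
  if (any(diff(a) < 0)) stop_arg("`acid_grid` must be nondecreasing")
  eta <- 1e-30
  deriv <- function(t, y, parms) {
    # clamp at zero so an exhausted species cannot drive its reaction
    c1 <- max(y[1], 0); c2 <- max(y[2], 0)
    den <- parms$k1 * c1^2 + parms$k2 * c2 + eta
    r1 <- parms$k1 * c1^2 / den
    r2 <- parms$k2 * c2 / den
    list(c(-2 * r1, r1 - r2, 2 * r2))
  }
  y0 <- c(model$c0, 0, 0)
  # the trajectory has a corner where both reactants are exhausted (total
  # remaining acid demand c1 + c2 reaches zero); stop there via a root
  # function and continue with the fully converted state
  rootf <- function(t, y, parms) y[1] + y[2] - 1e-6 * model$c0
  au <- unique(a)
  run <- function(rt, at) {
    out <- NULL
    # capture the Fortran solver's console chatter along with R warnings
    utils::capture.output(suppressWarnings(
      out <- deSolve::lsodar(y0, au, deriv, parms = model,
                             rootfunc = rootf, rtol = rt, atol = at)))
    out
  }
  sol <- run(rtol, atol)
  if (attr(sol, "istate")[1] < 0 &&
      sum(sol[nrow(sol), 2:3]) > 1e-4 * model$c0)
    sol <- run(rtol * 100, atol * 100)   # stiff retry
  if (attr(sol, "istate")[1] < 0) {
    # tolerate a stall at the exhaustion corner itself: everything beyond
    # it is the fully converted state anyway
    reached <- max(sol[, 1])
    last_y <- sol[nrow(sol), 2:3]
    if (sum(last_y) > 1e-4 * model$c0 && reached < max(au))
      stop("titration integration failed: lsodar istate = ",
           attr(sol, "istate")[1], " at a = ", reached, call. = FALSE)
  }
  Cu <- matrix(rep(c(0, 0, model$c0), each = length(au)), length(au), 3)
  got <- match(round(sol[, 1], 15), round(au, 15))
  keep <- !is.na(got)
  Cu[got[keep], ] <- unname(sol[keep, 2:4, drop = FALSE])
  C <- Cu[match(a, au), , drop = FALSE]
  # negative round-off from the integrator is clipped at -atol scale
  C[C < 0 & C > -1e-12 * model$c0] <- 0
  C
}

#' Fit the titration kinetics to recovered concentration profiles
#'
#' Least-squares fit of the two rate coefficients to a k x 3 matrix of
#' concentration profiles. Rates are parameterized on the log scale (which
#' enforces positivity without constraints) and the optimization is
#' multi-started from a fixed 4 x 4 grid of log-rate combinations spanning
#' four decades around the scale set by `c0`; the best start is polished
#' with a second Nelder-Mead run.
#'
#' Because the added-acid formulation of [simulate_titration()] normalizes
#' the two consumption rates (they always sum to 1 while reactants remain),
#' the trajectory depends on the rates only through the ratio `k1 / k2`:
#' the individual values are a gauge choice, not identifiable from the
#' profiles. The fit therefore reports the ratio explicitly; compare fits
#' through `ratio`, `C_kin` or `sse`, not through `k1` and `k2` alone.
#'
#' @param C_target k x 3 matrix of concentration profiles (mol/l),
#'   nonnegative up to small tolerance.
#' @param acid_grid Added-acid coordinates matching the rows of `C_target`.
#' @param c0 Total dye concentration (mol/l) for the closure/initial state.
#' @param maxit Nelder-Mead iteration cap per start.
#'
#' @return A list of class `kinetic_fit` with `model` (the fitted
#'   [kinetic_model()]), `ratio` (`k1 / k2`, the identifiable rate
#'   combination), `C_kin` (fitted trajectory), and `sse` (the minimized
#'   squared Frobenius misfit).
#' @export
fit_kinetics <- function(C_target, acid_grid, c0, maxit = 400) {
  C_target <- as.matrix(C_target)
  if (ncol(C_target) != 3) stop_arg("`C_target` must have 3 columns")
  k <- nrow(C_target)
  if (k < 4) stop_arg("need at least 4 condition points to fit two rates")
  if (length(acid_grid) != k)
    stop_arg("`acid_grid` length must match nrow(C_target)")
  if (min(C_target) < -0.05 * max(abs(C_target)))
    stop_arg("`C_target` has large negative entries; not a concentration factor")
  if (max(apply(C_target, 2, sd)) < 1e-12 * max(abs(C_target), 1e-300))
    stop_arg("`C_target` is flat along the acid axis; rates are not identifiable")
  sse_fun <- function(logk) {
    m <- kinetic_model(exp(logk[1]), exp(logk[2]), c0)
    Ck <- tryCatch(simulate_titration(m, acid_grid),
                   error = function(e) NULL)
    if (is.null(Ck)) return(1e30)
    sum((Ck - C_target)^2)
  }
  # start grid: k1*c0^2 and k2*c0 each spanning 1e-1 .. 1e2
  g <- log(10^seq(-1, 2, length.out = 4))
  starts <- expand.grid(lk1 = g - 2 * log(c0), lk2 = g - log(c0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(as.numeric(starts[i, ]), sse_fun, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e30)
    stop("kinetic fit failed from every start", call. = FALSE)
  best <- optim(best$par, sse_fun, method = "Nelder-Mead",
                control = list(maxit = 2 * maxit, reltol = 1e-14))
  model <- kinetic_model(exp(best$par[1]), exp(best$par[2]), c0)
  C_kin <- simulate_titration(model, acid_grid)
  structure(list(model = model, ratio = model$k1 / model$k2,
                 C_kin = C_kin, sse = best$value),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit: k1/k2 =", signif(x$ratio, 6),
      " (k1 =", signif(x$model$k1, 4),
      ", k2 =", signif(x$model$k2, 4), ")",
      " sse =", signif(x$sse, 4), "\n")
  invisible(x)
}

#' Per-component relative difference between two concentration factors
#'
#' For each component i, returns
#' `||C_kin[, i] - C_sol[, i]|| / ||C_sol[, i]||` in the selected norm:
#' `"max"` is the maximum absolute entry, `"euclidean"` the root sum of
#' squares.
#'
#' @param C_kin,C_sol Matrices of identical shape (k x 3).
#' @param norm `"max"` or `"euclidean"`.
#'
#' @return Numeric vector of length 3.
#' @export
reldiff <- function(C_kin, C_sol, norm = c("max", "euclidean")) {
  norm <- match.arg(norm)
  C_kin <- as.matrix(C_kin); C_sol <- as.matrix(C_sol)
  if (!all(dim(C_kin) == dim(C_sol)))
    stop_arg("`C_kin` and `C_sol` must have the same shape")
  nf <- switch(norm,
               max = function(v) max(abs(v)),
               euclidean = function(v) sqrt(sum(v^2)))
  vapply(seq_len(ncol(C_sol)), function(i) {
    ref <- nf(C_sol[, i])
    if (ref == 0) stop_arg("reference column ", i, " has zero norm")
    nf(C_kin[, i] - C_sol[, i]) / ref
  }, numeric(1))
}
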