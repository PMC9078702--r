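#' Closure (mass-balance) specification
#'
#' The stoichiometric constraint `sum_i weights[i] * c_i(a) = c0` that fixes
#' the absolute scale of the concentration profiles. For the titration
#' system this package targets the weights are `(1, 2, 1)` (the dimer binds
#' two dye molecules) and `c0` is the initial dye concentration.
#'
#' @param weights Positive stoichiometric weights, length s.
#' @param c0 Total concentration (mol/l), positive.
#'
#' @return An object of class `closure_spec`.
#' @export
closure_spec <- function(weights = c(1, 2, 1), c0) {
  weights <- as.numeric(weights)
  if (any(weights <= 0)) stop_arg("closure `weights` must be positive")
  if (!is.numeric(c0) || length(c0) != 1 || c0 <= 0)
    stop_arg("`c0` must be a single positive number")
  structure(list(weights = weights, c0 = c0), class = "closure_spec")
}

#' Scale concentration columns to satisfy the closure constraint
#'
#' Finds positive per-component scale factors `gamma` minimizing
#' `sum_j (sum_i weights[i] * gamma[i] * C[j, i] - c0)^2` (ordinary least
#' squares along the whole condition axis) and returns the rescaled
#' profiles. When the k x s design matrix is ill-conditioned (condition
#' number > 1e6) the closure cannot pin down all scales; the minimum-norm
#' solution is returned and `ambiguous_scale` is flagged instead of
#' silently committing to one gamma.
#'
#' @param C k x s matrix of concentration profiles.
#' @param spec A [closure_spec()].
#'
#' @return A list with `C` (scaled matrix), `gammas`, and
#'   `ambiguous_scale` (logical).
#' @export
closure_scale <- function(C, spec) {
  stopifnot(inherits(spec, "closure_spec"))
  C <- as.matrix(C)
  s <- ncol(C)
  if (length(spec$weights) != s)
    stop_arg("closure weights length must equal the component count")
  if (any(apply(C, 2, function(v) all(v == 0))))
    stop_arg("`C` has an identically zero column; cannot scale")
  A <- sweep(C, 2, spec$weights, `*`)
  sv <- svd(A)
  cond <- sv$d[1] / max(sv$d[s], 1e-300)
  ambiguous <- cond > 1e6
  # minimum-norm least squares via the pseudo-inverse
  dinv <- ifelse(sv$d > 1e-12 * sv$d[1], 1 / sv$d, 0)
  gam <- drop(sv$v %*% (dinv * crossprod(sv$u, rep(spec$c0, nrow(C)))))
  if (any(gam <= 0))
    stop("closure scaling has no positive solution (gammas: ",
         paste(signif(gam, 4), collapse = ", "), ")", call. = FALSE)
  list(C = sweep(C, 2, gam, `*`), gammas = gam, ambiguous_scale = ambiguous)
}

#' Squared closure residual of a concentration factor
#'
#' `sum_j (sum_i weights[i] * C[j, i] - c0)^2` over the k condition points.
#'
#' @param C k x s matrix of concentration profiles.
#' @param spec A [closure_spec()].
#'
#' @return A single nonnegative number.
#' @export
closure_ssq <- function(C, spec) {
  stopifnot(inherits(spec, "closure_spec"))
  C <- as.matrix(C)
  if (length(spec$weights) != ncol(C))
    stop_arg("closure weights length must equal the component count")
  sum((drop(C %*% spec$weights) - spec$c0)^2)
}

#' Bands of feasible profiles for one AFS subset
#'
#' Samples AFS points of one component's polygon (all boundary vertices
#' plus seeded rejection-sampled interior points), reconstructs the profile
#' of each point, and returns the pointwise minimum/maximum envelopes. Each
#' profile is normalized to unit maximum before enveloping, since AFS
#' points determine profiles only up to positive scale. Boundary vertices
#' are always included so the envelope extremes are not sampling-limited at
#' the boundary.
#'
#' @param svd An [truncated_svd()] result.
#' @param region An [afs_region()].
#' @param component Polygon index or component label within the region.
#' @param n_samples Total number of sampled points (>= number of vertices).
#' @param seed Seed of the private stream for interior sampling.
#'
#' @return A list of class `band_envelope` with `lower`, `upper` (length n
#'   or k), `component`, `n_samples` (points actually used), and `side`.
#' @export
band_envelopes <- function(svd, region, component = 1, n_samples = 100,
                           seed = 1) {
  stopifnot(inherits(svd, "mcr_svd"), inherits(region, "afs_region"))
  if (is.character(component))
    component <- match(component, region$component_labels)
  if (is.na(component) || component < 1 ||
      component > length(region$polygons))
    stop_arg("no such component polygon in the region")
  poly <- region$polygons[[component]]
  if (nrow(poly) == 0) stop_arg("empty AFS subset for this component")
  pts <- lapply(seq_len(nrow(poly)), function(i) poly[i, ])
  if (ncol(poly) == 2 && nrow(poly) >= 3 && n_samples > length(pts)) {
    need <- n_samples - length(pts)
    rx <- range(poly[, 1]); ry <- range(poly[, 2])
    extra <- with_private_seed(seed, {
      got <- list()
      tries <- 0
      while (length(got) < need && tries < 200 * need) {
        tries <- tries + 1
        p <- c(runif(1, rx[1], rx[2]), runif(1, ry[1], ry[2]))
        if (point_in_polygon(p, poly)) got[[length(got) + 1]] <- p
      }
      got
    })
    pts <- c(pts, extra)
  }
  profs <- vapply(pts, function(p) reconstruct_profile(svd, p, region$factor_side),
                  numeric(nrow(if (region$factor_side == "spectral") svd$V
                               else svd$U)))
  lower <- apply(profs, 1, min)
  upper <- apply(profs, 1, max)
  structure(list(lower = lower, upper = upper, component = component,
                 n_samples = length(pts), side = region$factor_side),
            class = "band_envelope")
}

#' Reconstruct the profile of an AFS point, normalized to unit maximum
#'
#' Spectral points map to `V (1, x)'`; concentrational points (scaled-basis
#' convention) map to `U Sigma (1, y)'`.
#'
#' @param svd An [truncated_svd()] result.
#' @param point AFS coordinates (length s-1).
#' @param side `"spectral"` or `"concentrational"`.
#'
#' @return Numeric profile with maximum 1.
#' @export
reconstruct_profile <- function(svd, point,
                                side = c("spectral", "concentrational")) {
  side <- match.arg(side)
  basis <- switch(side, spectral = svd$V, concentrational = svd$US)
  prof <- drop(basis %*% c(1, as.numeric(point)))
  mx <- max(prof)
  if (mx <= 0) stop_arg("AFS point reconstructs to a nonpositive profile")
  prof / mx
}
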