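#' AFS computation controls
#'
#' Tuning knobs of the boundary tracing and the inner W-optimization.
#' Defaults are sized for 3-component systems of the dimensions this
#' package targets (tens of conditions, hundreds of channels).
#'
#' @param n_start_dirs Initial number of equally spaced trace directions.
#' @param n_random_starts Number of random W starts (in addition to W = I
#'   and W = -I) for the inner minimization.
#' @param start_seed Seed of the private stream the random starts are drawn
#'   from (fixed so feasibility decisions are reproducible).
#' @param maxit Nelder-Mead iteration cap of the inner minimization.
#' @param max_vertices Hard cap on polygon vertices per component.
#' @param max_spacing_rel Maximum vertex spacing, relative to the polygon's
#'   maximum seed-to-boundary radius; edges longer than this are split.
#' @param seed_tries Attempts at finding a fully feasible seeding transform.
#'
#' @return An object of class `afs_control`.
#' @export
afs_control <- function(n_start_dirs = 24, n_random_starts = 8,
                        start_seed = 1721, maxit = 300,
                        max_vertices = 600, max_spacing_rel = 0.05,
                        seed_tries = 40) {
  structure(list(n_start_dirs = n_start_dirs,
                 n_random_starts = n_random_starts,
                 start_seed = start_seed, maxit = maxit,
                 max_vertices = max_vertices,
                 max_spacing_rel = max_spacing_rel,
                 seed_tries = seed_tries),
            class = "afs_control")
}

# Fixed multi-start set for the inner W minimization: W = I, W = -I, and
# n random regular 2x2 matrices from a private seeded stream.
# Column layout: (W11, W12, W21, W22).
make_w_starts <- function(control) {
  rand <- with_private_seed(control$start_seed, {
    cols <- list()
    while (length(cols) < control$n_random_starts) {
      w <- runif(4, -1.5, 1.5)
      if (abs(w[1] * w[4] - w[2] * w[3]) > 0.05) cols[[length(cols) + 1]] <- w
    }
    cols
  })
  do.call(cbind, c(list(c(1, 0, 0, 1), c(-1, 0, 0, -1)), rand))
}

#' Construct an AFS region
#'
#' A set of disjoint polygons (one per chemical component, in the ideal
#' well-separated case) in the (s-1)-dimensional AFS plane. For s = 2 the
#' "polygons" are intervals stored as 2 x 1 vertex matrices.
#'
#' @param factor_side `"spectral"` or `"concentrational"`.
#' @param polygons List of vertex matrices (m x (s-1)); implicitly closed,
#'   first vertex not repeated.
#' @param component_labels Character labels, one per polygon.
#' @param params The [feasibility_params()] the region was computed with.
#' @param validate Check pairwise disjointness (default TRUE).
#'
#' @return An object of class `afs_region`.
#' @export
afs_region <- function(factor_side = c("spectral", "concentrational"),
                       polygons, component_labels = NULL,
                       params = feasibility_params(), validate = TRUE) {
  factor_side <- match.arg(factor_side)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (any(!is.finite(p))) stop_arg("polygon vertices must be finite")
    p
  })
  if (is.null(component_labels))
    component_labels <- vapply(seq_along(polygons),
                               function(i) paste0("component_", i),
                               character(1))
  if (length(component_labels) != length(polygons))
    stop_arg("need one component label per polygon")
  if (validate && length(polygons) > 1 && ncol(polygons[[1]]) == 2) {
    for (i in seq_along(polygons)) for (j in seq_along(polygons)) {
      if (i >= j) next
      if (polygons_overlap(polygons[[i]], polygons[[j]]))
        stop_arg("polygons ", i, " and ", j, " overlap; components are not isolated")
    }
  }
  structure(list(factor_side = factor_side, polygons = polygons,
                 component_labels = as.character(component_labels),
                 params = params),
            class = "afs_region")
}

#' @export
print.afs_region <- function(x, ...) {
  cat("AFS region (", x$factor_side, " side): ",
      length(x$polygons), " subset(s)\n", sep = "")
  for (i in seq_along(x$polygons)) {
    p <- x$polygons[[i]]
    if (ncol(p) == 1)
      cat("  ", x$component_labels[i], ": interval [",
          signif(min(p), 6), ", ", signif(max(p), 6), "]\n", sep = "")
    else
      cat("  ", x$component_labels[i], ": ", nrow(p), " vertices, area ",
          signif(polygon_area(p), 4), "\n", sep = "")
  }
  invisible(x)
}

polygon_area <- function(poly) abs(pracma::polyarea(poly[, 1], poly[, 2]))

point_in_polygon <- function(pt, poly) {
  pracma::inpolygon(pt[1], pt[2], poly[, 1], poly[, 2], boundary = TRUE)
}

# distance from a point to a (closed) polygon boundary
point_polygon_dist <- function(pt, poly) {
  m <- nrow(poly)
  idx2 <- c(2:m, 1)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[idx2, 1]; by <- poly[idx2, 2]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- ((pt[1] - ax) * vx + (pt[2] - ay) * vy) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  px <- ax + t * vx; py <- ay + t * vy
  sqrt(min((pt[1] - px)^2 + (pt[2] - py)^2))
}

polygons_overlap <- function(a, b) {
  # disjointness test adequate for well-separated star-shaped subsets
  any(pracma::inpolygon(a[, 1], a[, 2], b[, 1], b[, 2], boundary = FALSE)) ||
    any(pracma::inpolygon(b[, 1], b[, 2], a[, 1], a[, 2], boundary = FALSE))
}

#' Membership of a point in an AFS region
#'
#' @param region An [afs_region()].
#' @param point Numeric AFS coordinates (length s-1).
#' @param tol Accept points within this distance of a polygon boundary.
#'
#' @return Integer index of the containing polygon, or 0 if none.
#' @export
region_member <- function(region, point, tol = 0) {
  for (i in seq_along(region$polygons)) {
    p <- region$polygons[[i]]
    if (ncol(p) == 1) {
      if (point[1] >= min(p) - tol && point[1] <= max(p) + tol) return(i)
    } else {
      if (point_in_polygon(point, p)) return(i)
      if (tol > 0 && point_polygon_dist(point, p) <= tol) return(i)
    }
  }
  0L
}

relative_shortfall <- function(v, eps) {
  mx <- max(abs(v))
  if (mx == 0) return(0)
  max(0, -min(v) / mx - eps)
}

#' Test feasibility of a single AFS point
#'
#' A point `x` in the (s-1)-dimensional AFS plane is feasible when the
#' transform matrix with first row `(1, x)` can be completed so that both
#' factors are nonnegative up to the relative tolerance `epsilon`; the test
#' accepts when the minimized [feasibility_violation()] drops below
#' `delta^2`. For s = 3 the inner minimization over the four entries of W
#' uses multi-start Nelder-Mead (starts: W = I, W = -I, and
#' `control$n_random_starts` random regular matrices from a fixed seeded
#' stream, plus an optional warm start). For s = 2 the exact interval
#' characterization is used.
#'
#' @param svd An [truncated_svd()] result with `s` of 2 or 3.
#' @param x Numeric AFS coordinates (length s-1).
#' @param params A [feasibility_params()].
#' @param warm Optional length-4 warm-start W (s = 3 only).
#' @param control An [afs_control()].
#'
#' @return A list with `feasible` (logical), `value` (attained violation,
#'   or its W-independent lower bound when that alone already exceeds
#'   `delta^2`), and `w` (best completion found, s = 3 only).
#' @export
point_feasible <- function(svd, x, params = feasibility_params(),
                           warm = NULL, control = afs_control()) {
  stopifnot(inherits(svd, "mcr_svd"))
  x <- as.numeric(x)
  if (length(x) != svd$s - 1)
    stop_arg("`x` must have length s - 1 = ", svd$s - 1)
  if (svd$s == 2) return(point_feasible2(svd, x, params))
  if (svd$s != 3)
    stop_arg("feasibility tests support s = 2 or 3 components, not s = ",
             svd$s)
  starts <- make_w_starts(control)
  res <- .cpp_point_feasible(svd$US, svd$V, x, params$epsilon, params$delta,
                             starts, warm %||% numeric(4), !is.null(warm),
                             control$maxit)
  list(feasible = res$feasible, value = res$value, w = res$w)
}

# ---- s = 2: exact interval machinery -------------------------------------

# epsilon = 0 anchors of the two AFS intervals (Lawton-Sylvestre geometry):
# the S-side interval [L_S, U_S] from ratios of right-singular-vector
# entries, the C-side split points (rho_min, rho_max) from ratios of the
# scaled left singular vectors.
afs2_anchors <- function(svd) {
  V <- svd$V; US <- svd$US
  if (min(US[, 1]) <= 0)
    stop_arg("leading concentration coefficients change sign; ",
             "two-component interval construction needs nonnegative-like data")
  pos <- V[, 2] > 0; neg <- V[, 2] < 0
  L_S <- if (any(pos)) max(-V[pos, 1] / V[pos, 2]) else -Inf
  U_S <- if (any(neg)) min(-V[neg, 1] / V[neg, 2]) else Inf
  rho <- US[, 2] / US[, 1]
  list(L_S = L_S, U_S = U_S, rho_min = min(rho), rho_max = max(rho))
}

# epsilon-relaxed feasibility of a single x, decomposed exactly:
# T = [1 x; 1 w], C columns are g(x)/(w-x) and -g(w)/(w-x) with
# g(t) = US[,2] - t*US[,1]; the relative shortfall of a column depends only
# on the sign of (w - x), so existence of w separates into the two branches.
point_feasible2 <- function(svd, x, params) {
  eps <- params$epsilon
  V <- svd$V; US <- svd$US
  sx <- V[, 1] + x * V[, 2]
  if (relative_shortfall(sx, eps) > 0)
    return(list(feasible = FALSE, value = relative_shortfall(sx, eps)^2))
  g <- function(t) US[, 2] - t * US[, 1]
  s_of <- function(t) V[, 1] + t * V[, 2]
  ok_right <- relative_shortfall(g(x), eps) == 0 &&
    !is.null(w <- afs2_find_w(svd, eps, side = "right", x = x))
  if (ok_right) return(list(feasible = TRUE, value = 0, w = w))
  ok_left <- relative_shortfall(-g(x), eps) == 0 &&
    !is.null(w <- afs2_find_w(svd, eps, side = "left", x = x))
  if (ok_left) return(list(feasible = TRUE, value = 0, w = w))
  # infeasible: report the violation at the best anchor completion
  anch <- afs2_anchors(svd)
  wbest <- if (abs(x - anch$rho_min) < abs(x - anch$rho_max))
    anch$rho_max else anch$rho_min
  v <- feasibility_violation(svd, build_T(x, matrix(wbest, 1, 1)), params)
  list(feasible = FALSE, value = v, w = wbest)
}

# find a w completing x on the requested side, or NULL
afs2_find_w <- function(svd, eps, side, x) {
  V <- svd$V; US <- svd$US
  g <- function(t) US[, 2] - t * US[, 1]
  cand <- if (side == "right") {
    # need w > x with s(w) >= -eps and -g(w) >= -eps (relative)
    grid <- afs2_anchors(svd)
    ws <- c(grid$rho_max, grid$U_S, (grid$rho_max + grid$U_S) / 2)
    ws[ws > x]
  } else {
    grid <- afs2_anchors(svd)
    ws <- c(grid$rho_min, grid$L_S, (grid$rho_min + grid$L_S) / 2)
    ws[ws < x]
  }
  for (w in cand) {
    if (!is.finite(w)) next
    okS <- relative_shortfall(V[, 1] + w * V[, 2], eps) == 0
    okC <- if (side == "right") relative_shortfall(-g(w), eps) == 0
           else relative_shortfall(g(w), eps) == 0
    if (okS && okC) return(w)
  }
  NULL
}

#' Two-component AFS in closed form
#'
#' For s = 2 the spectral AFS consists of two disjoint intervals whose
#' endpoints are extreme ratios of singular-vector entries: the outer
#' bounds come from nonnegativity of the candidate spectrum
#' `V[,1] + x V[,2]` (partitioned by the sign of `V[,2]`), the inner bounds
#' from single-signedness of the complementary concentration profile, i.e.
#' the extreme ratios of the scaled left singular vectors. For
#' `epsilon > 0` each endpoint is relaxed outward by bisection on the exact
#' epsilon-feasibility test, to `eps_b` precision.
#'
#' @param svd An [truncated_svd()] result with s = 2.
#' @param params A [feasibility_params()].
#' @param side `"spectral"` (default) or `"concentrational"` (computed by
#'   the identical construction on the transposed factor roles).
#'
#' @return An [afs_region()] with two 2 x 1 vertex matrices (intervals).
#' @export
afs_two_component <- function(svd, params = feasibility_params(),
                              side = c("spectral", "concentrational")) {
  stopifnot(inherits(svd, "mcr_svd"))
  side <- match.arg(side)
  if (svd$s != 2) stop_arg("`afs_two_component` requires s = 2")
  sv <- if (side == "spectral") svd else swap_svd(svd)
  anch <- afs2_anchors(sv)
  if (!(anch$L_S <= anch$rho_min && anch$rho_max <= anch$U_S))
    stop_arg("degenerate two-component geometry: intervals are empty")
  feas <- function(x) point_feasible2(sv, x, params)$feasible
  lo1 <- relax_endpoint(feas, anch$L_S, -1, params$eps_b)
  hi1 <- relax_endpoint(feas, anch$rho_min, +1, params$eps_b)
  lo2 <- relax_endpoint(feas, anch$rho_max, -1, params$eps_b)
  hi2 <- relax_endpoint(feas, anch$U_S, +1, params$eps_b)
  polys <- list(matrix(c(lo1, hi1), 2, 1), matrix(c(lo2, hi2), 2, 1))
  if (side == "concentrational") {
    # convert native U-basis coordinates to the scaled (U Sigma) convention
    polys <- lapply(polys, function(p) p * (svd$d[1] / svd$d[2]))
  }
  afs_region(side, polys, params = params, validate = FALSE)
}

# push an interval endpoint outward (direction dir) while `feas` holds;
# returns the boundary to eps_b precision
relax_endpoint <- function(feas, x0, dir, eps_b) {
  if (!feas(x0)) {
    # anchor itself infeasible (can happen for eps = 0 with noise): back off
    step <- eps_b
    while (!feas(x0 - dir * step) && step < 1) step <- step * 2
    if (step >= 1) stop_arg("could not locate a feasible interval endpoint")
    x0 <- x0 - dir * step
  }
  step <- max(eps_b, 1e-6 * max(1, abs(x0)))
  x_in <- x0
  while (feas(x_in + dir * step)) {
    x_in <- x_in + dir * step
    step <- step * 2
    if (abs(x_in) > 1e6) stop_arg("unbounded AFS interval")
  }
  x_out <- x_in + dir * step
  while (abs(x_out - x_in) > eps_b) {
    mid <- (x_in + x_out) / 2
    if (feas(mid)) x_in <- mid else x_out <- mid
  }
  x_in
}

# swap the factor roles: the SVD of t(D) inherits U <-> V with the same
# singular values and the sign conventions of the original decomposition
swap_svd <- function(svd) {
  structure(list(U = svd$V, d = svd$d, V = svd$U, all_d = svd$all_d,
                 s = svd$s, US = sweep(svd$V, 2, svd$d, `*`)),
            class = "mcr_svd")
}

# ---- s = 3: seeding and boundary tracing ---------------------------------

# normalized AFS-plane coordinates of the data rows (rows of U Sigma)
data_row_coords <- function(svd) {
  US <- svd$US
  if (min(US[, 1]) <= 0)
    stop_arg("leading expansion coefficients of the data rows change sign")
  cbind(US[, 2] / US[, 1], US[, 3] / US[, 1])
}

# Find one fully feasible transform: rows of T seed the three polygons.
# Strategy: cluster the data-row coordinates to 3 groups, inflate the
# cluster centers away from their centroid (the enclosing-triangle
# heuristic), then minimize the total violation over all 6 free entries.
find_seed_T <- function(svd, params, control) {
  pts <- data_row_coords(svd)
  centers <- with_private_seed(control$start_seed + 1, {
    km <- kmeans(pts, centers = 3, nstart = 10)
    km$centers
  })
  centroid <- colMeans(pts)
  obj <- function(par) {
    T <- build_T(par[1:2], matrix(par[3:6], 2, 2, byrow = TRUE))
    v <- .cpp_violation(svd$US, svd$V, unclass(T), params$epsilon)
    v
  }
  target <- params$delta^2
  best <- NULL
  tries <- 0
  lambdas <- c(1, 1.5, 2, 3, 4, 6)
  repeat {
    for (lam in lambdas) {
      tries <- tries + 1
      rows <- sweep(sweep(centers, 2, centroid) * lam, 2, centroid, `+`)
      par0 <- c(rows[1, ], rows[2, ], rows[3, ])
      fit <- optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value <= target) break
    }
    if (best$value <= target || tries >= control$seed_tries) break
    # jitter the centers and retry
    centers <- with_private_seed(control$start_seed + tries, {
      centers + matrix(rnorm(6, sd = 0.2 * max(abs(centers))), 3, 2)
    })
  }
  if (best$value > target)
    stop("AFS seeding failed: no fully feasible transform found (best ",
         "violation ", signif(best$value, 3), "); the system may not have ",
         "three isolatable components", call. = FALSE)
  rbind(best$par[1:2], best$par[3:4], best$par[5:6])
}

# Trace the boundary of one AFS subset by radial bisection from a feasible
# seed, with adaptive angular refinement (split an edge while the midpoint
# boundary point deviates from the chord by more than eps_b, or the chord
# is longer than the spacing cap).
trace_polygon <- function(svd, seed_pt, params, control, starts) {
  eps_b <- params$eps_b
  warm_env <- new.env()
  warm_env$w <- NULL
  feas <- function(p) {
    res <- .cpp_point_feasible(svd$US, svd$V, p, params$epsilon,
                               params$delta, starts,
                               warm_env$w %||% numeric(4),
                               !is.null(warm_env$w), control$maxit)
    if (res$feasible) warm_env$w <- res$w
    res$feasible
  }
  if (!feas(seed_pt)) stop_arg("internal: seed point is not feasible")
  scale0 <- max(sqrt(rowSums(sweep(data_row_coords(svd), 2, seed_pt)^2)), 1e-3)
  bdry <- function(theta) {
    dir <- c(cos(theta), sin(theta))
    r_lo <- 0
    r_hi <- 0.05 * scale0
    while (feas(seed_pt + r_hi * dir)) {
      r_lo <- r_hi
      r_hi <- r_hi * 2
      if (r_hi > 200 * scale0) stop_arg("AFS boundary not found along a ray")
    }
    while (r_hi - r_lo > eps_b) {
      mid <- (r_lo + r_hi) / 2
      if (feas(seed_pt + mid * dir)) r_lo <- mid else r_hi <- mid
    }
    seed_pt + r_lo * dir
  }
  n0 <- control$n_start_dirs
  thetas <- seq(0, 2 * pi, length.out = n0 + 1)[-(n0 + 1)]
  pts <- lapply(thetas, bdry)
  max_r <- max(vapply(pts, function(p) sqrt(sum((p - seed_pt)^2)), 0))
  max_spacing <- control$max_spacing_rel * max_r
  min_dtheta <- 2 * pi / 4096
  budget <- new.env()
  budget$n <- length(pts)
  # recursively subdivide the arc (th1, th2) while the midpoint boundary
  # point deviates from the chord by more than eps_b or the chord exceeds
  # the spacing cap; returns the interior points in angular order
  refine <- function(th1, p1, th2, p2) {
    chord <- sqrt(sum((p2 - p1)^2))
    if (th2 - th1 <= min_dtheta || budget$n >= control$max_vertices ||
        (chord <= 2 * eps_b))
      return(list())
    thm <- (th1 + th2) / 2
    pm <- bdry(thm)
    v <- p2 - p1
    tt <- sum((pm - p1) * v) / max(sum(v^2), 1e-300)
    devi <- sqrt(sum((pm - (p1 + max(min(tt, 1), 0) * v))^2))
    if (devi <= eps_b && chord <= max_spacing) return(list())
    budget$n <- budget$n + 1L
    c(refine(th1, p1, thm, pm), list(pm), refine(thm, pm, th2, p2))
  }
  out <- list()
  for (i in seq_along(thetas)) {
    j <- if (i == length(thetas)) 1 else i + 1
    th2 <- if (j == 1) thetas[j] + 2 * pi else thetas[j]
    out <- c(out, list(pts[[i]]),
             refine(thetas[i], pts[[i]], th2, pts[[j]]))
  }
  do.call(rbind, out)
}

#' Three-component AFS by adaptive boundary tracing
#'
#' Computes the spectral or the concentrational AFS of a three-component
#' system as up to three disjoint polygons. A fully feasible transform is
#' seeded from the data-row coordinates (k-means clustering to 3 groups,
#' enclosing-triangle inflation, then minimization of the total violation);
#' its three rows give one interior point per component. Each subset
#' boundary is then traced by radial bisection from its seed, refining the
#' angular subdivision until the traced points deviate from the polygon
#' chords by less than `eps_b`.
#'
#' The concentrational AFS runs the identical machinery on the transposed
#' factor roles (left and right singular vectors swapped) and converts the
#' resulting coordinates to the scaled-basis convention in which the
#' duality line of [dual_line()] is exact (expansion in the columns of
#' `U Sigma`, leading coefficient normalized to 1).
#'
#' @param svd An [truncated_svd()] result with s = 3.
#' @param side `"spectral"` or `"concentrational"`.
#' @param params A [feasibility_params()].
#' @param control An [afs_control()].
#'
#' @return An [afs_region()] with one polygon per isolated subset found.
#' @export
afs_three_component <- function(svd, side = c("spectral", "concentrational"),
                                params = feasibility_params(),
                                control = afs_control()) {
  stopifnot(inherits(svd, "mcr_svd"))
  side <- match.arg(side)
  if (svd$s != 3) stop_arg("`afs_three_component` requires s = 3")
  sv <- if (side == "spectral") svd else swap_svd(svd)
  starts <- make_w_starts(control)
  seeds <- find_seed_T(sv, params, control)
  ord <- order(seeds[, 1])
  seeds <- seeds[ord, , drop = FALSE]
  polys <- lapply(seq_len(3), function(i)
    trace_polygon(sv, seeds[i, ], params, control, starts))
  if (side == "concentrational") {
    fac <- c(svd$d[1] / svd$d[2], svd$d[1] / svd$d[3])
    polys <- lapply(polys, function(p)
      cbind(p[, 1] * fac[1], p[, 2] * fac[2]))
  }
  afs_region(side, polys, params = params, validate = TRUE)
}

#' Brute-force grid oracle for the three-component AFS
#'
#' Evaluates [point_feasible()] at every cell center of a regular grid.
#' Intended as an independent cross-check of the traced polygons in tests;
#' quadratic cost in `resolution`.
#'
#' @param svd An [truncated_svd()] result with s = 3.
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param resolution Grid cells per axis (<= 500).
#' @param params A [feasibility_params()].
#' @param control An [afs_control()].
#'
#' @return A `resolution` x `resolution` logical matrix; entry `[i, j]` is
#'   the feasibility at the center of cell (i, j), `i` indexing x and `j`
#'   indexing y. The cell-center axes are attached as attributes `xc`, `yc`.
#' @export
afs_grid_oracle <- function(svd, bbox, resolution = 200,
                            params = feasibility_params(),
                            control = afs_control()) {
  stopifnot(inherits(svd, "mcr_svd"))
  if (svd$s != 3) stop_arg("`afs_grid_oracle` requires s = 3")
  if (resolution > 500) stop_arg("`resolution` must be <= 500")
  bbox <- as.numeric(bbox)
  dx <- (bbox[2] - bbox[1]) / resolution
  dy <- (bbox[4] - bbox[3]) / resolution
  xc <- bbox[1] + (seq_len(resolution) - 0.5) * dx
  yc <- bbox[3] + (seq_len(resolution) - 0.5) * dy
  # serpentine order so neighbouring evaluations chain warm starts
  pts <- matrix(0, resolution^2, 2)
  idx <- matrix(0L, resolution^2, 2)
  r <- 1
  for (j in seq_len(resolution)) {
    xs <- if (j %% 2 == 1) seq_len(resolution) else rev(seq_len(resolution))
    for (i in xs) {
      pts[r, ] <- c(xc[i], yc[j])
      idx[r, ] <- c(i, j)
      r <- r + 1
    }
  }
  starts <- make_w_starts(control)
  res <- .cpp_points_feasible(svd$US, svd$V, pts, params$epsilon,
                              params$delta, starts, control$maxit)
  mask <- matrix(FALSE, resolution, resolution)
  mask[idx] <- res$feasible
  attr(mask, "xc") <- xc
  attr(mask, "yc") <- yc
  mask
}

#' Rasterize an AFS region on a grid
#'
#' Marks every cell whose center lies inside any polygon of the region;
#' the counterpart of [afs_grid_oracle()] for symmetric-difference
#' comparisons.
#'
#' @param region An [afs_region()] with 2-D polygons.
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param resolution Grid cells per axis.
#'
#' @return Logical `resolution` x `resolution` matrix (x by y).
#' @export
region_raster <- function(region, bbox, resolution = 200) {
  bbox <- as.numeric(bbox)
  dx <- (bbox[2] - bbox[1]) / resolution
  dy <- (bbox[4] - bbox[3]) / resolution
  xc <- bbox[1] + (seq_len(resolution) - 0.5) * dx
  yc <- bbox[3] + (seq_len(resolution) - 0.5) * dy
  gx <- rep(xc, times = resolution)
  gy <- rep(yc, each = resolution)
  inside <- rep(FALSE, length(gx))
  for (p in region$polygons)
    inside <- inside | pracma::inpolygon(gx, gy, p[, 1], p[, 2],
                                         boundary = TRUE)
  matrix(inside, resolution, resolution)
}

#' Count 8-connected components of a logical mask
#'
#' Diagonal adjacency counts as connected, so a compact feasible subset that
#' rasterizes to a staircase of cells is one component. A feasible subset
#' much thinner than a grid cell can still rasterize to scattered cells;
#' `bridge` dilates the mask by that many cells before counting, merging
#' gaps of up to about `2 * bridge + 1` cells. Use a `bridge` far below the
#' cell separation of distinct subsets.
#'
#' @param mask Logical matrix.
#' @param bridge Dilation radius in cells (default 0: plain count).
#' @return Integer component count.
#' @export
mask_components <- function(mask, bridge = 0L) {
  for (b in seq_len(bridge)) {
    grown <- mask
    nr <- nrow(mask); nc <- ncol(mask)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      src_i <- max(1, 1 - di):min(nr, nr - di)
      src_j <- max(1, 1 - dj):min(nc, nc - dj)
      grown[src_i + di, src_j + dj] <- grown[src_i + di, src_j + dj] |
        mask[src_i, src_j]
    }
    mask <- grown
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- comp
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        nb <- c(i + di, j + dj)
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= nc) {
          id <- (nb[2] - 1L) * nr + nb[1]
          if (mask[id] && lab[id] == 0L) stack <- c(stack, id)
        }
      }
    }
  }
  comp
}

#' Bounding box of an AFS region, optionally padded
#'
#' @param region An [afs_region()] with 2-D polygons.
#' @param pad Relative padding per side (default 0.2).
#' @return Numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
region_bbox <- function(region, pad = 0.2) {
  allv <- do.call(rbind, region$polygons)
  rx <- range(allv[, 1]); ry <- range(allv[, 2])
  wx <- diff(rx); wy <- diff(ry)
  c(rx[1] - pad * wx, rx[2] + pad * wx, ry[1] - pad * wy, ry[2] + pad * wy)
}
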