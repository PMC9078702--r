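#' Map a measured profile to its AFS point
#'
#' Expands the profile in the truncated singular basis by least squares and
#' normalizes to leading coefficient 1. On the spectral side the basis is
#' the columns of `V`; on the concentrational side it is the columns of
#' `U Sigma`, the scaled-basis convention under which the duality line of
#' [dual_line()] is exact (the point of a concentration profile is then the
#' normalized column of `T^{-1}` it corresponds to).
#'
#' @param svd An [truncated_svd()] result.
#' @param profile Numeric vector: length n for `side = "spectral"`, length
#'   k for `side = "concentrational"`.
#' @param side `"spectral"` or `"concentrational"`.
#'
#' @return A list with `point` (length s-1 AFS coordinates), `coeffs` (the
#'   raw expansion coefficients), and `residual` (norm of the out-of-span
#'   part of the profile).
#' @export
profile_to_afs_point <- function(svd, profile,
                                 side = c("spectral", "concentrational")) {
  stopifnot(inherits(svd, "mcr_svd"))
  side <- match.arg(side)
  profile <- as.numeric(profile)
  basis <- switch(side, spectral = svd$V, concentrational = svd$US)
  if (length(profile) != nrow(basis))
    stop_arg("profile length ", length(profile), " does not match the ",
             side, " dimension ", nrow(basis))
  # columns of V are orthonormal; columns of U*Sigma are orthogonal with
  # norms Sigma, so least squares is a scaled projection in both cases
  coeffs <- switch(side,
    spectral = drop(crossprod(basis, profile)),
    concentrational = drop(crossprod(svd$U, profile)) / svd$d)
  resid <- sqrt(sum((profile - basis %*% coeffs)^2))
  if (abs(coeffs[1]) < 1e-10 * sqrt(sum(coeffs^2)))
    stop_arg("profile has a (near-)zero leading expansion coefficient; ",
             "its AFS point cannot be normalized")
  list(point = coeffs[-1] / coeffs[1], coeffs = coeffs, residual = resid)
}

#' Dual line of an AFS point (three-component systems)
#'
#' Fixing one pure profile at AFS point `x` constrains the two
#' complementary components on the other side of the factorization to the
#' affine line `{y : 1 + x[1] y[1] + x[2] y[2] = 0}`. This is the
#' complementarity/duality relation in the coordinate conventions of this
#' package: it follows from `T^{-1} T = I`, since the first row `(1, x)` of
#' `T` is orthogonal to the complementary columns of `T^{-1}`, whose
#' normalizations are exactly the AFS points of the other side. The same
#' formula applies in both directions (spectral point to concentrational
#' line and vice versa).
#'
#' @param point Numeric AFS coordinates (length 2), not the origin.
#'
#' @return A list of class `dual_line` with `normal` (length 2) and
#'   `offset`, describing `{y : normal . y + offset = 0}`.
#' @export
dual_line <- function(point) {
  if (is.list(point) && !is.null(point$point)) point <- point$point
  point <- as.numeric(point)
  if (length(point) != 2)
    stop_arg("`dual_line` requires a 2-coordinate point (s = 3)")
  if (sqrt(sum(point^2)) == 0)
    stop_arg("the origin has no affine dual line (degenerate normal)")
  structure(list(normal = point, offset = 1), class = "dual_line")
}

#' Intersect two dual lines
#'
#' @param a,b `dual_line` objects.
#'
#' @return Numeric length-2 intersection point.
#' @export
intersect_lines <- function(a, b) {
  stopifnot(inherits(a, "dual_line"), inherits(b, "dual_line"))
  A <- rbind(a$normal, b$normal)
  cr <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  scale <- sqrt(sum(a$normal^2)) * sqrt(sum(b$normal^2))
  if (abs(cr) <= 1e-12 * scale)
    stop_arg("dual lines are (numerically) parallel; no intersection")
  drop(solve(A, -c(a$offset, b$offset)))
}

# derive all AFS points obtainable from the fixed ones by repeated duality:
# any two points on one side give, via the intersection of their dual
# lines, one point on the other side
propagate_duality <- function(sp_pts, cp_pts, tol = 1e-8) {
  add_new <- function(lst, p) {
    for (q in lst) if (sqrt(sum((p - q)^2)) < tol * (1 + sqrt(sum(q^2))))
      return(lst)
    c(lst, list(p))
  }
  repeat {
    n_before <- length(sp_pts) + length(cp_pts)
    if (length(sp_pts) >= 2 && length(cp_pts) < 3) {
      for (i in seq_along(sp_pts)) for (j in seq_along(sp_pts)) {
        if (i >= j) next
        y <- tryCatch(intersect_lines(dual_line(sp_pts[[i]]),
                                      dual_line(sp_pts[[j]])),
                      error = function(e) NULL)
        if (!is.null(y)) cp_pts <- add_new(cp_pts, y)
      }
    }
    if (length(cp_pts) >= 2 && length(sp_pts) < 3) {
      for (i in seq_along(cp_pts)) for (j in seq_along(cp_pts)) {
        if (i >= j) next
        x <- tryCatch(intersect_lines(dual_line(cp_pts[[i]]),
                                      dual_line(cp_pts[[j]])),
                      error = function(e) NULL)
        if (!is.null(x)) sp_pts <- add_new(sp_pts, x)
      }
    }
    if (length(sp_pts) + length(cp_pts) == n_before) break
  }
  list(spectral = sp_pts, concentrational = cp_pts)
}

#' Complete a factorization from known spectra and/or profiles
#'
#' Maps each fixed pure spectrum and fixed concentration profile to its AFS
#' point, derives the missing points by duality (two points on one side
#' determine, through the intersection of their dual lines, one point on
#' the other side; the propagation is iterated to a fixed point), assembles
#' the transform matrix, and returns the factor pair. The result is unique
#' up to positive column scaling and component permutation; spectra are
#' normalized to unit maximum with the concentration columns absorbing the
#' reciprocal scale, and components are ordered to match the fixed inputs
#' by maximal cosine similarity (spectra first, then profiles; ties broken
#' by input order).
#'
#' @param svd An [truncated_svd()] result with s = 3.
#' @param fixed_spectra List of length-n pure spectra (possibly empty).
#' @param fixed_profiles List of length-k concentration profiles (possibly
#'   empty).
#' @param params A [feasibility_params()].
#'
#' @return A list of class `mcr_completion` with `C`, `S`, `T`, `violation`
#'   (the [feasibility_violation()] of the assembled transform), and
#'   `order` (component order applied).
#' @export
complete_factorization <- function(svd, fixed_spectra = list(),
                                   fixed_profiles = list(),
                                   params = feasibility_params()) {
  stopifnot(inherits(svd, "mcr_svd"))
  if (svd$s != 3) stop_arg("`complete_factorization` requires s = 3")
  if (!is.list(fixed_spectra)) fixed_spectra <- list(fixed_spectra)
  if (!is.list(fixed_profiles)) fixed_profiles <- list(fixed_profiles)
  n_fix <- length(fixed_spectra) + length(fixed_profiles)
  if (n_fix < 2)
    stop_arg("need at least two fixed profiles/spectra (or three on one side)")
  sp_pts <- lapply(fixed_spectra, function(p)
    profile_to_afs_point(svd, p, "spectral")$point)
  cp_pts <- lapply(fixed_profiles, function(p)
    profile_to_afs_point(svd, p, "concentrational")$point)
  got <- propagate_duality(sp_pts, cp_pts)
  if (length(got$spectral) >= 3) {
    x3 <- got$spectral[1:3]
    T <- rbind(c(1, x3[[1]]), c(1, x3[[2]]), c(1, x3[[3]]))
  } else if (length(got$concentrational) >= 3) {
    y3 <- got$concentrational[1:3]
    M <- cbind(c(1, y3[[1]]), c(1, y3[[2]]), c(1, y3[[3]]))
    if (rcond(M) < 1e-12)
      stop_arg("derived concentration points are collinear; cannot complete")
    Tr <- solve(M)
    T <- Tr / Tr[, 1]          # rescale rows to leading coefficient 1
  } else {
    stop_arg("fixed information is insufficient: duality propagation ",
             "yielded ", length(got$spectral), " spectral and ",
             length(got$concentrational), " concentrational points")
  }
  if (rcond(T) < 1e-12)
    stop_arg("assembled transform is singular; fixed inputs are degenerate")
  viol <- feasibility_violation(svd, T, params)
  if (!is.finite(viol) || viol > 100 * params$delta^2)
    stop("fixed spectra/profiles are mutually inconsistent: violation = ",
         signif(viol, 4), " exceeds 100 * delta^2 = ",
         signif(100 * params$delta^2, 4), call. = FALSE)
  fp <- factors_from_T(svd, T)
  C <- fp$C; S <- fp$S
  # match components to the fixed inputs by cosine similarity
  targets <- c(lapply(fixed_spectra, function(p) list(side = "S", p = p)),
               lapply(fixed_profiles, function(p) list(side = "C", p = p)))
  ord <- integer(0)
  avail <- seq_len(3)
  for (tg in targets) {
    if (length(avail) == 0) break
    sims <- vapply(avail, function(i) {
      m <- if (tg$side == "S") S[, i] else C[, i]
      abs(cosine_sim(m, tg$p))
    }, numeric(1))
    pick <- avail[which.max(sims)]
    if (!(pick %in% ord)) { ord <- c(ord, pick); avail <- setdiff(avail, pick) }
  }
  ord <- c(ord, setdiff(seq_len(3), ord))
  C <- C[, ord, drop = FALSE]
  S <- S[, ord, drop = FALSE]
  T <- T[ord, , drop = FALSE]
  # scale: unit-maximum spectra, concentrations absorb the reciprocal
  # (feasible spectra have positive maxima, so no sign flips arise here)
  for (i in seq_len(3)) {
    mx <- max(S[, i])
    if (mx > 0) {
      S[, i] <- S[, i] / mx
      C[, i] <- C[, i] * mx
    }
  }
  structure(list(C = C, S = S, T = T, violation = viol, order = ord),
            class = "mcr_completion")
}

#' @export
print.mcr_completion <- function(x, ...) {
  cat("Completed factorization:", ncol(x$C), "components,",
      nrow(x$C), "conditions x", nrow(x$S), "channels\n")
  cat("Feasibility violation:", signif(x$violation, 4), "\n")
  invisible(x)
}
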