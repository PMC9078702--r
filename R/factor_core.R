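#' Feasibility control parameters
#'
#' Bundles the three tolerances that control the feasibility test and the
#' AFS boundary computation.
#'
#' @param epsilon Relative negativity tolerance \eqn{\epsilon \ge 0}: a
#'   profile (column of C or S) is accepted when its most negative entry is
#'   no smaller than \eqn{-\epsilon} times its maximum absolute entry.
#'   Default `2e-4`.
#' @param delta Inner-optimization tolerance \eqn{\delta > 0}: a candidate
#'   AFS point counts as feasible when the minimized violation drops below
#'   \eqn{\delta^2}. Default `1e-4`.
#' @param eps_b Boundary precision \eqn{\epsilon_b > 0} for the traced AFS
#'   polygons (radial bisection tolerance, in AFS coordinates).
#'   Default `1e-4`.
#'
#' @return An object of class `feasibility_params`.
#' @export
feasibility_params <- function(epsilon = 2e-4, delta = 1e-4, eps_b = 1e-4) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0)
    stop_arg("`epsilon` must be a single nonnegative number")
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop_arg("`delta` must be a single positive number")
  if (!is.numeric(eps_b) || length(eps_b) != 1 || eps_b <= 0)
    stop_arg("`eps_b` must be a single positive number")
  structure(list(epsilon = epsilon, delta = delta, eps_b = eps_b),
            class = "feasibility_params")
}

#' Truncated singular value decomposition of a spectral dataset
#'
#' Computes the rank-`s` truncated SVD \eqn{D \approx U \Sigma V^T} that all
#' downstream factor computations are based on. The full singular spectrum is
#' retained for rank diagnostics. Each of the leading `s` right singular
#' vectors is oriented so that its largest-magnitude entry is positive (the
#' left vector takes the compensating sign), which makes AFS coordinates
#' reproducible across platforms.
#'
#' @param dataset A [spectral_dataset()], or a plain numeric matrix.
#' @param s Number of components to retain, `1 <= s <= min(k, n)`.
#'
#' @return An object of class `mcr_svd` with fields `U` (k x s), `d`
#'   (length-s singular values), `V` (n x s), `all_d` (full singular
#'   spectrum), `s`, and `US = U %*% diag(d)`.
#' @export
truncated_svd <- function(dataset, s) {
  D <- if (inherits(dataset, "spectral_dataset")) dataset$absorbance
       else as.matrix(dataset)
  if (!is.numeric(s) || length(s) != 1 || s != round(s))
    stop_arg("`s` must be a single integer")
  s <- as.integer(s)
  if (s < 1 || s > min(dim(D)))
    stop_arg("`s` must satisfy 1 <= s <= min(k, n); got s = ", s,
             " for a ", nrow(D), " x ", ncol(D), " matrix")
  sv <- svd(D, nu = s, nv = s)
  U <- sv$u
  V <- sv$v
  # orient: largest-|entry| of each right singular vector positive
  for (i in seq_len(s)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) {
      V[, i] <- -V[, i]
      U[, i] <- -U[, i]
    }
  }
  d <- sv$d[seq_len(s)]
  structure(list(U = U, d = d, V = V, all_d = sv$d, s = s,
                 US = sweep(U, 2, d, `*`)),
            class = "mcr_svd")
}

#' @export
print.mcr_svd <- function(x, ...) {
  cat("Truncated SVD: s =", x$s, "components,",
      nrow(x$U), "conditions x", nrow(x$V), "channels\n")
  cat("Leading singular values:",
      paste(signif(x$d, 6), collapse = ", "), "\n")
  if (length(x$all_d) > x$s)
    cat("Next singular value:", signif(x$all_d[x$s + 1], 6), "\n")
  invisible(x)
}

#' Estimate the number of significant components
#'
#' Returns the largest `s` such that `sigma_s / sigma_1 >= ratio_threshold`,
#' i.e. the count of singular values that stand above the relative
#' threshold. For an all-zero spectrum of values the result is 0.
#'
#' @param all_singular_values Nonincreasing, nonnegative numeric vector of
#'   singular values.
#' @param ratio_threshold Relative threshold in (0, 1). Default `1e-2`,
#'   which cleanly separates signal from noise-floor singular values at the
#'   noise levels this package's generator emulates.
#'
#' @return Integer component count.
#' @export
estimate_rank <- function(all_singular_values, ratio_threshold = 1e-2) {
  v <- all_singular_values
  if (length(v) == 0) stop_arg("`all_singular_values` must be nonempty")
  if (any(!is.finite(v)) || any(v < 0))
    stop_arg("singular values must be finite and nonnegative")
  if (any(diff(v) > 1e-12 * max(v, 1)))
    stop_arg("singular values must be nonincreasing")
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 0 ||
      ratio_threshold >= 1)
    stop_arg("`ratio_threshold` must lie in (0, 1)")
  if (v[1] == 0) return(0L)
  as.integer(sum(v / v[1] >= ratio_threshold))
}

#' Assemble a transform matrix T from an AFS point and a completion
#'
#' Builds the s x s matrix with all-ones first column, first row
#' `(1, x)` and lower-right (s-1) x (s-1) block `W`:
#' \deqn{T = \begin{pmatrix} 1 & x^T \\ 1 & W \end{pmatrix}}
#' Regularity is not checked here; use sites test it.
#'
#' @param x Numeric vector of length s-1.
#' @param W Numeric (s-1) x (s-1) matrix (a scalar is accepted for s = 2).
#'
#' @return An s x s matrix of class `transform_matrix`.
#' @export
build_T <- function(x, W) {
  x <- as.numeric(x)
  W <- as.matrix(W)
  m <- length(x)
  if (nrow(W) != m || ncol(W) != m)
    stop_arg("`W` must be ", m, " x ", m, " to match length(x) = ", m)
  if (any(!is.finite(x)) || any(!is.finite(W)))
    stop_arg("`x` and `W` must be finite")
  T <- cbind(1, rbind(x, W, deparse.level = 0))
  dimnames(T) <- NULL
  structure(T, class = c("transform_matrix", "matrix", "array"))
}

#' Reconstruct the factor pair (C, S) from a transform matrix
#'
#' Given the truncated SVD and a regular transform `T`, returns
#' `C = U Sigma T^{-1}` and `S = V T'`. The product `C S'` always equals the
#' rank-s truncation of the data; no nonnegativity is implied.
#'
#' @param svd An [truncated_svd()] result.
#' @param T An s x s transform matrix (e.g. from [build_T()]).
#'
#' @return A list of class `factor_pair` with `C` (k x s) and `S` (n x s).
#' @export
factors_from_T <- function(svd, T) {
  stopifnot(inherits(svd, "mcr_svd"))
  T <- unclass(T)
  if (!is.matrix(T) || nrow(T) != svd$s || ncol(T) != svd$s)
    stop_arg("`T` must be a ", svd$s, " x ", svd$s, " matrix")
  rc <- rcond(T)
  if (!is.finite(rc) || rc < 1e-14)
    stop_arg("singular transform matrix (rcond = ", signif(rc, 3), ")")
  Tinv <- solve(T)
  structure(list(C = svd$US %*% Tinv, S = svd$V %*% t(T)),
            class = "factor_pair")
}

#' Relative-negativity violation of a transform matrix
#'
#' The scalar penalty used throughout the AFS machinery. For each component
#' profile (column of `C = U Sigma T^{-1}` and of `S = V T'`), the relative
#' shortfall is `max(0, -min(col)/max(abs(col)) - epsilon)`; the violation is
#' the sum of squared shortfalls over all 2s profiles. It is 0 exactly when
#' every profile is nonnegative up to the relative tolerance `epsilon`, and
#' `Inf` (a documented sentinel, not an error) when `T` is singular so that
#' optimizers can penalize singular transforms smoothly.
#'
#' The violation is invariant under positive rescaling of any component
#' (column of C with the compensating row of S').
#'
#' @param svd An [truncated_svd()] result.
#' @param T An s x s transform matrix.
#' @param params A [feasibility_params()] object (only `epsilon` is used).
#'
#' @return A single nonnegative number (possibly `Inf`).
#' @export
feasibility_violation <- function(svd, T, params = feasibility_params()) {
  stopifnot(inherits(svd, "mcr_svd"))
  T <- unclass(T)
  if (!is.matrix(T) || nrow(T) != svd$s || ncol(T) != svd$s)
    stop_arg("`T` must be a ", svd$s, " x ", svd$s, " matrix")
  if (any(!is.finite(T))) return(Inf)
  rc <- rcond(T)
  if (!is.finite(rc) || rc < 1e-14) return(Inf)
  v <- .cpp_violation(svd$US, svd$V, T, params$epsilon)
  if (v >= 1e11) Inf else v
}
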