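#' Rank-1 downdate of a data matrix
#'
#' Subtracts the rank-1 contribution of one component,
#' `D - conc_profile %*% t(spectrum)`.
#'
#' @param D k x n data matrix.
#' @param conc_profile Length-k concentration profile.
#' @param spectrum Length-n spectrum.
#'
#' @return The downdated k x n matrix.
#' @export
rank1_downdate <- function(D, conc_profile, spectrum) {
  D <- as.matrix(D)
  if (length(conc_profile) != nrow(D))
    stop_arg("`conc_profile` length must equal nrow(D)")
  if (length(spectrum) != ncol(D))
    stop_arg("`spectrum` length must equal ncol(D)")
  D - tcrossprod(as.numeric(conc_profile), as.numeric(spectrum))
}

#' Extract the middle component by double rank annihilation
#'
#' For a three-component titration whose first and last measured spectra
#' are pure (first and last rows of `D`), the contributions of those two
#' terminal components can be removed by two rank-1 downdates, leaving a
#' residual that is rank 1 up to noise and contains only the intermediate
#' component. The downdate concentration profiles can be supplied or
#' derived:
#'
#' * When the terminal components' concentration profiles are known (e.g.
#'   measured by fluorescence), pass them as `first_profile` and
#'   `last_profile`: the downdates remove exactly those contributions, and
#'   on noiseless data the residual is exactly the dimer's rank-1 term, so
#'   both its profile and its spectrum are recovered exactly.
#' * Otherwise the downdate profiles are obtained by ordinary least-squares
#'   regression of the rows of `D` onto the two fixed spectra, scaled so
#'   the first and last rows correspond to the pure states `(c0, 0, 0)` and
#'   `(0, 0, c0)`. The residual is then `c2 (s2 - P s2)'` with `P` the
#'   orthogonal projector onto the fixed spectra's span: the middle
#'   component's concentration profile is still exact (and the residual
#'   exactly rank 1 on noiseless data), but its spectrum carries an oblique
#'   contamination `-P s2`, visible as negative dips where the terminal
#'   spectra peak -- the characteristic nonnegativity defect of rank
#'   annihilation. The middle spectrum is structurally unidentifiable from
#'   `(D, s1, s3)` alone.
#'
#' The leading singular pair of the residual gives the middle component's
#' concentration profile and spectrum; the second-to-first singular value
#' ratio of the residual is returned as a quality measure (0 for exact
#' rank-3 data).
#'
#' @param dataset A [spectral_dataset()] or plain matrix.
#' @param first_spectrum Pure spectrum of the initial component (length n);
#'   defaults to the first row of `D`.
#' @param last_spectrum Pure spectrum of the final component (length n);
#'   defaults to the last row of `D`.
#' @param c0 Total concentration (mol/l) fixing the downdate profile scale;
#'   taken from the dataset's `closure_c0` when absent.
#' @param first_profile,last_profile Optional known concentration profiles
#'   (length k, mol/l) of the terminal components; both must be given to
#'   enable the profile-based downdates.
#'
#' @return A list of class `rank_annihilation` with `conc_profile` (length
#'   k, scaled by the residual's leading singular value), `spectrum`
#'   (length n, unit Euclidean norm, largest-magnitude entry positive),
#'   `quality` (`sigma_2 / sigma_1` of the residual), `min_negative`
#'   (most negative entry of the spectrum after unit-maximum scaling, a
#'   diagnostic of the method's nonnegativity defect), `residual` (the
#'   downdated matrix), and `C_anni` (k x 3: the two downdate profiles and
#'   the recovered middle profile, in component order).
#' @export
middle_component_by_annihilation <- function(dataset,
                                             first_spectrum = NULL,
                                             last_spectrum = NULL,
                                             c0 = NULL,
                                             first_profile = NULL,
                                             last_profile = NULL) {
  D <- if (inherits(dataset, "spectral_dataset")) dataset$absorbance
       else as.matrix(dataset)
  if (is.null(c0) && inherits(dataset, "spectral_dataset"))
    c0 <- dataset$closure_c0
  if (is.null(c0)) stop_arg("`c0` is required (no closure constant found)")
  k <- nrow(D); n <- ncol(D)
  s1 <- as.numeric(first_spectrum %||% D[1, ])
  s3 <- as.numeric(last_spectrum %||% D[k, ])
  if (length(s1) != n || length(s3) != n)
    stop_arg("fixed spectra must have length ncol(D)")
  # consistency of the fixed spectra with the row space of D
  rs <- svd(D)
  keep <- rs$d > 1e-12 * rs$d[1]
  Vr <- rs$v[, keep, drop = FALSE]
  for (nm in c("first", "last")) {
    sp <- if (nm == "first") s1 else s3
    res <- sqrt(sum((sp - Vr %*% crossprod(Vr, sp))^2))
    if (res > 0.1 * sqrt(sum(sp^2)))
      warning(nm, " spectrum lies ", signif(100 * res / sqrt(sum(sp^2)), 3),
              "% outside the row space of D", call. = FALSE)
  }
  if (xor(is.null(first_profile), is.null(last_profile)))
    stop_arg("supply both `first_profile` and `last_profile`, or neither")
  if (!is.null(first_profile)) {
    c1 <- as.numeric(first_profile); c3 <- as.numeric(last_profile)
    if (length(c1) != k || length(c3) != k)
      stop_arg("known profiles must have length nrow(D)")
    if (abs(c1[1]) < 1e-12 * max(abs(c1)) ||
        abs(c3[k]) < 1e-12 * max(abs(c3)))
      stop_arg("known profiles must be nonzero at their pure endpoints")
    # the fixed spectra are measured rows, i.e. (endpoint concentration)
    # times the molar spectrum; pair scales so row 1 / row k cancel exactly
    Dt <- rank1_downdate(D, c1, s1 / c1[1])
    Dt <- rank1_downdate(Dt, c3, s3 / c3[k])
  } else {
    # regression of the rows of D onto span{s1, s3}
    B <- t(qr.solve(cbind(s1, s3), t(D)))     # k x 2 coefficients
    if (abs(B[1, 1]) < 1e-12 || abs(B[k, 2]) < 1e-12)
      stop_arg("endpoint rows carry no weight on the fixed spectra; ",
               "cannot anchor the downdate scale")
    c1 <- B[, 1] / B[1, 1] * c0               # first row -> (c0, 0, 0)
    c3 <- B[, 2] / B[k, 2] * c0               # last row  -> (0, 0, c0)
    Dt <- rank1_downdate(D, c1, s1 * B[1, 1] / c0)
    Dt <- rank1_downdate(Dt, c3, s3 * B[k, 2] / c0)
  }
  sv <- svd(Dt, nu = 2, nv = 2)
  if (sv$d[1] <= 1e-12 * rs$d[1])
    stop("degenerate residual: no middle component present (sigma_1 of ",
         "the downdate is numerically zero)", call. = FALSE)
  quality <- sv$d[2] / sv$d[1]
  u <- sv$u[, 1]; v <- sv$v[, 1]
  j <- which.max(abs(v))
  if (v[j] < 0) { v <- -v; u <- -u }
  spectrum <- v
  conc <- u * sv$d[1]
  spec_unitmax <- spectrum / max(spectrum)
  structure(list(conc_profile = conc, spectrum = spectrum,
                 quality = quality,
                 min_negative = min(spec_unitmax),
                 residual = Dt,
                 C_anni = cbind(c1, conc, c3, deparse.level = 0)),
            class = "rank_annihilation")
}

#' @export
print.rank_annihilation <- function(x, ...) {
  cat("Rank annihilation: residual sigma2/sigma1 =",
      signif(x$quality, 4), "\n")
  cat("Most negative spectrum entry (unit-max scale):",
      signif(x$min_negative, 4), "\n")
  invisible(x)
}
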