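#' Configuration for the synthetic titration generator
#'
#' Defaults define the reference titration scenario the package is exercised on:
#' 12 UV/Vis spectra over 401 channels in the 200-600 nm window, added-acid
#' concentrations in [0, 1.264e-3] mol/l, three absorbing species obeying
#' the closure c1 + 2 c2 + c3 = c0 with c0 = 9.84269e-4 mol/l, Gaussian-band
#' pure spectra and additive Gaussian noise of 1e-4 relative to the maximum
#' absorbance. The default noise sits below the default negativity
#' tolerance `epsilon = 2e-4` of [feasibility_params()]; this ordering is a
#' consistency requirement, not a convenience: epsilon bounds the relative
#' size of the negative entries that the rank-s truncation of a noisy D
#' forces into every factorization, so an AFS computed with `epsilon` below
#' the relative noise level is empty (see the methods vignette).
#'
#' The default peak tables give each terminal species a selective wavelength
#' region while the intermediate dimer (component 2) absorbs strictly inside
#' the union of the other two supports, mimicking the mixed signatures that
#' make the dimer the ambiguous component.
#'
#' @param n_conditions Number of titration points k (default 12).
#' @param n_channels Number of wavelength channels n (default 401).
#' @param wavelength_range Length-2 vector, nm (default `c(200, 600)`).
#' @param acid_max Largest added-acid concentration, mol/l
#'   (default 1.264e-3).
#' @param c0 Total dye concentration, mol/l (default 9.84269e-4).
#' @param k1,k2 Rate coefficients of the titration model (defaults chosen so
#'   the dimer peaks near mid-titration at roughly a quarter of c0).
#' @param peaks List of 3 data frames / matrices with columns
#'   (center, width, height): Gaussian bands per component. Heights are
#'   molar-absorptivity-like (l mol^-1 cm^-1 scale) so absorbances are O(1).
#' @param noise_sigma Noise standard deviation relative to `max(C S')`
#'   (default 1e-4; keep below the `epsilon` used downstream).
#' @param seed Integer seed for the noise stream (default 1).
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_conditions = 12L,
                             n_channels = 401L,
                             wavelength_range = c(200, 600),
                             acid_max = 1.264e-3,
                             c0 = 9.84269e-4,
                             k1 = 4e7,
                             k2 = 1e4,
                             peaks = default_peaks(),
                             noise_sigma = 1e-4,
                             seed = 1L) {
  if (n_conditions < 2 || n_channels < 2)
    stop_arg("need at least 2 conditions and 2 channels")
  if (acid_max <= 0 || c0 <= 0 || k1 <= 0 || k2 <= 0)
    stop_arg("acid_max, c0, k1, k2 must be positive")
  if (noise_sigma < 0) stop_arg("`noise_sigma` must be >= 0")
  if (length(peaks) != 3) stop_arg("`peaks` must list bands for 3 components")
  for (p in peaks) {
    p <- as.matrix(p)
    if (ncol(p) != 3) stop_arg("each peak table needs (center, width, height)")
    if (any(p[, 1] < wavelength_range[1]) || any(p[, 1] > wavelength_range[2]))
      stop_arg("peak centers must lie within `wavelength_range`")
    if (any(p[, 2:3] <= 0)) stop_arg("peak widths and heights must be positive")
  }
  structure(list(n_conditions = as.integer(n_conditions),
                 n_channels = as.integer(n_channels),
                 wavelength_range = as.numeric(wavelength_range),
                 acid_max = acid_max, c0 = c0, k1 = k1, k2 = k2,
                 peaks = lapply(peaks, function(p) {
                   p <- as.matrix(p); colnames(p) <- c("center", "width", "height"); p
                 }),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default Gaussian band tables of the three synthetic species
#'
#' @return A list of three (center, width, height) matrices.
#' @export
default_peaks <- function() {
  list(
    rbind(c(250, 22, 900), c(315, 28, 520), c(370, 40, 120)),   # free dye
    rbind(c(300, 25, 400), c(345, 30, 750), c(395, 35, 300)),   # dimer
    rbind(c(280, 20, 350), c(430, 32, 800), c(505, 38, 260))    # protonated
  )
}

#' Sum of Gaussian absorption bands on a wavelength grid
#'
#' @param peaks Matrix/data frame with columns (center, width, height); the
#'   width is the Gaussian standard deviation in nm.
#' @param wavelengths Numeric vector of wavelengths (nm).
#'
#' @return Nonnegative numeric vector, one value per wavelength.
#' @export
gaussian_spectrum <- function(peaks, wavelengths) {
  p <- as.matrix(peaks)
  if (nrow(p) == 0) stop_arg("`peaks` must contain at least one band")
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(p)))
    out <- out + p[i, 3] * exp(-0.5 * ((wavelengths - p[i, 1]) / p[i, 2])^2)
  out
}

#' Generate a ground-truthed synthetic titration dataset
#'
#' Simulates the concentration profiles with [simulate_titration()] on a
#' uniform acid grid, builds the pure spectra from the configured Gaussian
#' bands, and returns `D = C_true S_true' + noise` together with the ground
#' truth. The noise is additive Gaussian with standard deviation
#' `noise_sigma * max(C_true S_true')`, drawn from the configured seed
#' (bit-identical across runs; the caller's RNG state is left untouched).
#'
#' @param config A [synthetic_config()].
#'
#' @return A list with `dataset` (a [spectral_dataset()]), `C_true`
#'   (k x 3, mol/l), `S_true` (n x 3), and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- seq(config$wavelength_range[1], config$wavelength_range[2],
            length.out = config$n_channels)
  acid <- seq(0, config$acid_max, length.out = config$n_conditions)
  model <- kinetic_model(config$k1, config$k2, config$c0)
  C_true <- simulate_titration(model, acid)
  S_true <- vapply(config$peaks, gaussian_spectrum, numeric(length(wl)),
                   wavelengths = wl)
  D0 <- C_true %*% t(S_true)
  D <- if (config$noise_sigma > 0) {
    sd_abs <- config$noise_sigma * max(D0)
    with_private_seed(config$seed,
      D0 + matrix(rnorm(length(D0), sd = sd_abs), nrow(D0), ncol(D0)))
  } else D0
  ds <- spectral_dataset(D, wavelengths = wl, conditions = acid,
                         closure_c0 = config$c0)
  list(dataset = ds, C_true = C_true, S_true = S_true, config = config)
}
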