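#' Construct a spectral dataset
#'
#' The central data container: a k x n absorbance matrix with a wavelength
#' axis (columns) and a titration/condition axis (rows), plus an optional
#' closure constant. Rows are measured spectra, columns are wavelength
#' channels; the transpose layout is rejected, not guessed. Entries may be
#' slightly negative (preprocessed data); no lower bound is enforced.
#'
#' @param absorbance Numeric k x n matrix of absorbances.
#' @param wavelengths Strictly increasing numeric vector of length n (nm).
#' @param conditions Nondecreasing numeric vector of length k (mol/l added
#'   acid, or any monotone condition coordinate).
#' @param closure_c0 Optional total-concentration constant (mol/l) for
#'   closure scaling.
#'
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(absorbance, wavelengths, conditions,
                             closure_c0 = NULL) {
  D <- as.matrix(absorbance)
  if (nrow(D) < 2 || ncol(D) < 2)
    stop_arg("absorbance matrix must be at least 2 x 2")
  if (any(!is.finite(D))) stop_arg("absorbance entries must be finite")
  wavelengths <- as.numeric(wavelengths)
  conditions <- as.numeric(conditions)
  if (length(wavelengths) != ncol(D))
    stop_arg("length(wavelengths) must equal ncol(absorbance); ",
             "rows are spectra, columns are channels")
  if (length(conditions) != nrow(D))
    stop_arg("length(conditions) must equal nrow(absorbance)")
  if (any(diff(wavelengths) <= 0))
    stop_arg("`wavelengths` must be strictly increasing")
  if (any(diff(conditions) < 0))
    stop_arg("`conditions` must be nondecreasing")
  if (!is.null(closure_c0)) {
    if (!is.numeric(closure_c0) || length(closure_c0) != 1 || closure_c0 <= 0)
      stop_arg("`closure_c0` must be a single positive number")
  }
  structure(list(absorbance = unname(D), wavelengths = wavelengths,
                 conditions = conditions, closure_c0 = closure_c0),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("Spectral dataset:", nrow(x$absorbance), "spectra x",
      ncol(x$absorbance), "channels\n")
  cat("Wavelengths:", min(x$wavelengths), "-", max(x$wavelengths), "nm;",
      "conditions:", signif(min(x$conditions), 6), "-",
      signif(max(x$conditions), 6), "\n")
  if (!is.null(x$closure_c0))
    cat("Closure c0:", signif(x$closure_c0, 6), "mol/l\n")
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

guess_delim <- function(dialect) {
  switch(dialect,
         comma = ",", csv = ",", "," = ",",
         tab = "\t", tsv = "\t", "\t" = "\t",
         stop_arg("unknown dialect '", dialect, "'; use \"comma\" or \"tab\""))
}

#' Read a spectral dataset from delimited text
#'
#' Expected layout: the first row holds a corner label followed by the n
#' wavelengths; each subsequent row holds the condition value followed by
#' the n absorbances of one spectrum. Written by [write_dataset()].
#'
#' @param path File path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @param closure_c0 Optional closure constant attached to the result.
#'
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, dialect = "comma", closure_c0 = NULL) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  sep <- guess_delim(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3)
    stop_arg("parse error in ", path, ": need a header row and >= 2 data rows")
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncols <- length(parts[[1]])
  wl <- suppressWarnings(as.numeric(parts[[1]][-1]))
  if (any(is.na(wl)))
    stop_arg("parse error in ", path, " line 1: non-numeric wavelength entry")
  k <- length(lines) - 1
  cond <- numeric(k)
  D <- matrix(NA_real_, k, ncols - 1)
  for (i in seq_len(k)) {
    row <- parts[[i + 1]]
    if (length(row) != ncols)
      stop_arg("parse error in ", path, " line ", i + 1, ": expected ",
               ncols, " fields, found ", length(row))
    v <- suppressWarnings(as.numeric(row))
    if (any(is.na(v)))
      stop_arg("parse error in ", path, " line ", i + 1,
               ": non-numeric entry")
    cond[i] <- v[1]
    D[i, ] <- v[-1]
  }
  spectral_dataset(D, wavelengths = wl, conditions = cond,
                   closure_c0 = closure_c0)
}

#' Write a spectral dataset as delimited text
#'
#' Numbers are printed with 17 significant digits so that a read/write
#' round trip reproduces the doubles bit-identically.
#'
#' @param dataset A [spectral_dataset()].
#' @param path Output file path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @export
write_dataset <- function(dataset, path, dialect = "comma") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  sep <- guess_delim(dialect)
  header <- paste(c("condition", fmt17(dataset$wavelengths)), collapse = sep)
  rows <- vapply(seq_along(dataset$conditions), function(i) {
    paste(c(fmt17(dataset$conditions[i]), fmt17(dataset$absorbance[i, ])),
          collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a delimited-text profile matrix (profiles in columns)
#'
#' Helper for concentration-profile / spectra tables: first column is the
#' axis, remaining columns the profiles.
#'
#' @param axis Numeric axis vector.
#' @param profiles Matrix with `length(axis)` rows.
#' @param path Output file path.
#' @param axis_label Name of the axis column.
#' @param dialect `"comma"` or `"tab"`.
#' @export
write_profiles <- function(axis, profiles, path, axis_label = "axis",
                           dialect = "comma") {
  sep <- guess_delim(dialect)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(axis))
    stop_arg("`profiles` must have one row per axis value")
  labs <- colnames(profiles) %||% paste0("profile", seq_len(ncol(profiles)))
  header <- paste(c(axis_label, labs), collapse = sep)
  rows <- vapply(seq_along(axis), function(i) {
    paste(c(fmt17(axis[i]), fmt17(profiles[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a profile matrix written by [write_profiles()]
#'
#' @param path File path.
#' @param dialect `"comma"` or `"tab"`.
#' @return A list with `axis` and `profiles` (matrix).
#' @export
read_profiles <- function(path, dialect = "comma") {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  sep <- guess_delim(dialect)
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  list(axis = tab[[1]], profiles = as.matrix(tab[, -1, drop = FALSE]))
}

#' Write an AFS region to a structured-text (JSON) file
#'
#' The schema is a JSON object with fields `factor_side`, `params`
#' (epsilon, delta, eps_b), and `polygons`: a list of records each holding
#' `component` and `vertices` (an m x 2 array; polygons are implicitly
#' closed, the first vertex is not repeated). Vertex coordinates are written
#' at full double precision (17 significant digits) and round-trip
#' losslessly through [read_region()].
#'
#' @param region An [afs_region()].
#' @param path Output file path.
#' @export
write_region <- function(region, path) {
  stopifnot(inherits(region, "afs_region"))
  obj <- list(
    factor_side = region$factor_side,
    closed = TRUE,
    params = list(epsilon = region$params$epsilon,
                  delta = region$params$delta,
                  eps_b = region$params$eps_b),
    polygons = lapply(seq_along(region$polygons), function(i) {
      list(component = region$component_labels[i],
           vertices = unname(region$polygons[[i]]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an AFS region written by [write_region()]
#'
#' @param path File path.
#' @return An [afs_region()].
#' @export
read_region <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- list()
  labels <- character(0)
  np <- if (is.data.frame(obj$polygons)) nrow(obj$polygons)
        else length(obj$polygons)
  as_vertices <- function(v) {
    if (is.matrix(v)) return(unname(v))
    if (is.list(v)) return(do.call(rbind, lapply(v, as.numeric)))
    matrix(as.numeric(v), nrow = 1)
  }
  if (np > 0) {
    for (i in seq_len(np)) {
      if (is.data.frame(obj$polygons)) {
        labels[i] <- obj$polygons$component[i]
        polys[[i]] <- as_vertices(obj$polygons$vertices[[i]])
      } else {
        labels[i] <- obj$polygons[[i]]$component
        polys[[i]] <- as_vertices(obj$polygons[[i]]$vertices)
      }
    }
  }
  afs_region(factor_side = obj$factor_side, polygons = polys,
             component_labels = labels,
             params = feasibility_params(epsilon = obj$params$epsilon,
                                         delta = obj$params$delta,
                                         eps_b = obj$params$eps_b),
             validate = FALSE)
}
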