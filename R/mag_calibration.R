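# Hard-/soft-iron magnetometer calibration by least-squares ellipsoid fitting.
#
# An error-free magnetometer swung through all orientations traces a sphere
# centred on the origin. A hard-iron bias displaces the sphere; soft-iron
# distortion stretches it into an ellipsoid. The calibration estimates both
# and maps raw readings back onto a sphere.

#' Fit an ellipsoid calibration to raw magnetometer readings
#'
#' Least-squares algebraic fit of the general quadric
#' `x'Ax + 2b'x = 1` to the sample cloud, constrained to an ellipsoid,
#' followed by extraction of the centre (hard-iron offset `b`) and of the
#' symmetric positive-definite correction matrix `W` (the matrix square root
#' of the ellipsoid shape) that maps readings onto a sphere:
#' `corrected(x) = W (x - b)`. `W` is scaled so the mean corrected norm over
#' the fitting data is exactly 1; heading is invariant to this global scale.
#'
#' @param samples N x 3 matrix of raw magnetometer readings spanning diverse
#'   orientations (N >= 10).
#' @return a `calibration_model` with fields `b` (offset, raw units), `W`
#'   (3 x 3 SPD matrix), `magnitude` (geometric-mean ellipsoid semi-axis, the
#'   fitted field magnitude in raw units) and `cv` (coefficient of variation
#'   of the corrected norms, the fit-quality figure).
#' @export
fit_ellipsoid <- function(samples) {
  samples <- as.matrix(samples)
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (ncol(samples) != 3) stop("'samples' must be an N x 3 matrix")
  n <- nrow(samples)
  if (n < 10) stop("need at least 10 magnetometer samples, got ", n)
  ctr <- scale(samples, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1e-300)) {
    stop("insufficient orientation coverage: samples are rank-deficient (near-planar)")
  }
  x <- samples[, 1]; y <- samples[, 2]; z <- samples[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z, 2 * x, 2 * y, 2 * z)
  v <- tryCatch(qr.solve(D, rep(1, n)),
                error = function(e) stop("insufficient orientation coverage: ",
                                         conditionMessage(e)))
  A <- matrix(c(v[1], v[4], v[5],
                v[4], v[2], v[6],
                v[5], v[6], v[3]), 3, 3)
  b <- v[7:9]
  centre <- -solve(A, b)
  # completing the square: (x-c)'A(x-c) = 1 + c'Ac when b = -Ac
  k <- 1 + drop(crossprod(centre, A %*% centre))
  Q <- A / k
  eq <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (any(eq <= 0)) stop("insufficient orientation coverage: fitted quadric is not an ellipsoid")
  W0 <- sqrtm_spd(Q)
  corrected <- sweep(samples, 2, centre) %*% W0
  norms <- sqrt(rowSums(corrected^2))
  mn <- mean(norms)
  W <- W0 / mn
  magnitude <- prod(1 / sqrt(eq))^(1 / 3)
  model <- structure(list(b = as.numeric(centre), W = W,
                          magnitude = magnitude,
                          cv = stats::sd(norms) / mn),
                     class = "calibration_model")
  model
}

#' Apply a calibration model to raw readings
#'
#' @param x N x 3 matrix of raw magnetometer readings.
#' @param model a `calibration_model`.
#' @return N x 3 matrix of corrected readings `W (x - b)`; rows with missing
#'   values propagate missing values.
#' @export
calibrate_mag <- function(x, model) {
  stopifnot(inherits(model, "calibration_model"))
  x <- as.matrix(x)
  sweep(x, 2, model$b) %*% t(model$W)
}

#' Append calibrated magnetometer channels to a sensor table
#'
#' The exported model from one calibration run can be applied to any other
#' data set from the same deployment.
#'
#' @param table a [sensor_table] with `mag-x/y/z` channels.
#' @param model a `calibration_model` from [fit_ellipsoid] or [load_model].
#' @param names names for the three appended corrected channels.
#' @return the table with corrected channels appended; nulls propagate.
#' @export
apply_calibration <- function(table, model,
                              names = c("mag_x_cal", "mag_y_cal", "mag_z_cal")) {
  m <- sensor_matrix(table, "mag")
  cal <- calibrate_mag(m, model)
  append_channels(table, stats::setNames(
    list(cal[, 1], cal[, 2], cal[, 3]), names))
}

#' Save / load a calibration model as labelled plain text
#'
#' The file holds 13 numbers (offset, row-major correction matrix, field
#' magnitude) plus the fit CV, in a human-editable labelled layout so the
#' correction matrix can be viewed and adjusted by hand.
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model, with an error on malformed or truncated files.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  lines <- c(
    "# magnetometer calibration model",
    paste("offset:", paste(fmt_num(model$b), collapse = " ")),
    paste("W:", paste(fmt_num(model$W[1, ]), collapse = " ")),
    paste("W:", paste(fmt_num(model$W[2, ]), collapse = " ")),
    paste("W:", paste(fmt_num(model$W[3, ]), collapse = " ")),
    paste("magnitude:", fmt_num(model$magnitude)),
    paste("cv:", fmt_num(model$cv)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model file: ", path)
  lines <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  grab <- function(key, n) {
    hits <- grep(paste0("^", key, ":"), lines, value = TRUE)
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(sub(paste0("^", key, ":"), "", hits)), "\\s+"))))
    if (length(vals) != n || anyNA(vals)) {
      stop("malformed calibration model file: field '", key, "'")
    }
    vals
  }
  b <- grab("offset", 3)
  W <- matrix(grab("W", 9), 3, 3, byrow = TRUE)
  structure(list(b = b, W = W, magnitude = grab("magnitude", 1),
                 cv = grab("cv", 1)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat("offset b:   ", paste(signif(x$b, 6), collapse = "  "), "\n")
  cat("W (soft-iron correction):\n")
  print(signif(x$W, 6))
  cat("field magnitude (raw units):", signif(x$magnitude, 6), "\n")
  cat("fit CV of corrected norms:  ", signif(x$cv, 6), "\n")
  invisible(x)
}
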