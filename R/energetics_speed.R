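# Dynamic body acceleration energetics (VeDBA / ODBA) and the thresholded
# linear VeDBA -> speed proxy.

#' Dynamic body acceleration metrics
#'
#' The dynamic acceleration on each axis is the absolute residual of the raw
#' signal about its windowed running mean, `DA = |raw - running mean|`;
#' VeDBA is the vectorial sum `sqrt(DA_x^2 + DA_y^2 + DA_z^2)` and ODBA the
#' overall sum `DA_x + DA_y + DA_z`. VeDBA is used downstream both as a
#' proxy for metabolic rate (VO2) and, for terrestrial locomotion, as a
#' speed proxy; it cannot capture metabolic costs with no mechanical
#' signature (e.g. digestion, non-shivering thermogenesis).
#'
#' @param accel N x 3 raw acceleration matrix (g).
#' @param window odd running-mean window in samples (as in
#'   [static_acceleration]; the same window is used for both by default but
#'   they may be set independently).
#' @return data frame with `DA_x`, `DA_y`, `DA_z`, `VeDBA`, `ODBA` (g);
#'   missing inputs propagate. For every sample
#'   `ODBA / sqrt(3) <= VeDBA <= ODBA`.
#' @export
dynamic_acceleration <- function(accel, window) {
  st <- static_acceleration(accel, window)
  da <- abs(st$dynamic)
  data.frame(DA_x = da[, 1], DA_y = da[, 2], DA_z = da[, 3],
             VeDBA = sqrt(rowSums(da^2)),
             ODBA = rowSums(da))
}

#' VeDBA -> speed model
#'
#' Linear speed proxy with a noise threshold: `s = VeDBA * m + c` when
#' `VeDBA > t` (strictly), otherwise `s = 0`. For volant species, whose
#' airspeed VeDBA cannot capture, the constant-speed mode returns a fixed
#' speed for every sample (to be refined later against positional fixes).
#'
#' @param m speed coefficient (m/s per g), >= 0.
#' @param c speed constant (m/s), >= 0.
#' @param t VeDBA threshold (g), >= 0.
#' @param mode `"vedba"` or `"constant"`.
#' @param constant the constant speed (m/s) used in constant mode.
#' @return a `speed_model` object.
#' @export
speed_model <- function(m = 1, c = 0, t = 0, mode = c("vedba", "constant"),
                        constant = 0) {
  mode <- match.arg(mode)
  if (m < 0 || c < 0 || t < 0 || constant < 0) {
    stop("speed model parameters must be non-negative")
  }
  structure(list(m = m, c = c, t = t, mode = mode, constant = constant),
            class = "speed_model")
}

#' Convert a VeDBA series to speed
#'
#' @param vedba numeric VeDBA series (g).
#' @param model a [speed_model].
#' @return speed in m/s per sample, monotone non-decreasing in VeDBA;
#'   missing VeDBA propagates (in VeDBA mode).
#' @export
speed_from_vedba <- function(vedba, model) {
  stopifnot(inherits(model, "speed_model"))
  if (model$mode == "constant") {
    return(rep(model$constant, length(vedba)))
  }
  ifelse(vedba > model$t, vedba * model$m + model$c, 0)
}

#' @export
print.speed_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat("<speed_model> constant speed ", x$constant, " m/s\n", sep = "")
  } else {
    cat("<speed_model> s = VeDBA * ", x$m, " + ", x$c,
        " if VeDBA > ", x$t, " else 0\n", sep = "")
  }
  invisible(x)
}
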