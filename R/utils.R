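# Internal numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#' @param x angles in degrees.
#' @return angles wrapped to [0, 360).
#' @keywords internal
wrap360 <- function(x) {
  out <- x %% 360
  # -1e-14 %% 360 == 360 in floating point; fold the boundary back
  out[out >= 360] <- 0
  out
}

#' Wrap angles into (-180, 180]
#' @param x angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap180 <- function(x) {
  out <- x %% 360
  out[!is.na(out) & out > 180] <- out[!is.na(out) & out > 180] - 360
  out
}

#' Centred running mean with truncated edges
#'
#' Windowed moving average used to split raw acceleration into its static
#' (gravity-dominated) and dynamic components. The window is centred on each
#' sample; at the series edges the window is truncated to the samples that
#' exist. Missing values are skipped: each mean is taken over the non-missing
#' samples in the window, and is `NA` only when the whole window is missing.
#'
#' @param x numeric vector.
#' @param window odd window length in samples (`window = 1` returns `x`).
#' @return numeric vector of the same length as `x`.
#' @export
running_mean <- function(x, window) {
  n <- length(x)
  if (window < 1 || window != round(window)) {
    stop("'window' must be a positive integer number of samples")
  }
  if (window %% 2 == 0) stop("'window' must be odd so the window is centred")
  if (window > n) stop("'window' (", window, ") exceeds series length (", n, ")")
  if (window == 1) return(x)
  half <- (window - 1) / 2
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  tot <- cs[hi + 1] - cs[lo]
  cnt <- cn[hi + 1] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# rotation matrices (angles in radians), right-handed
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# SPD matrix square root via eigendecomposition
sqrtm_spd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
}

is_signed_permutation <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3))) return(FALSE)
  if (!all(m %in% c(-1, 0, 1))) return(FALSE)
  all(colSums(abs(m)) == 1) && all(rowSums(abs(m)) == 1)
}

# deterministic numeric formatting used by all text writers so that
# export -> import -> export round trips byte-identically
fmt_num <- function(x) {
  # 17 significant digits: doubles survive the text round trip exactly
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
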