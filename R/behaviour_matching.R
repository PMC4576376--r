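# Query-by-example behaviour classification: multichannel template matching
# by (normalized) cross-correlation, match extraction and boosting.

#' A multichannel behaviour template
#'
#' A query waveform drawn from one positive example of a behaviour. Any data
#' attribute can serve as a search channel (accelerometer axes for gaits,
#' magnetometer for thermalling cycles, pressure for dive cycles, ...).
#'
#' @param channels named list of equal-length numeric waveforms (L >= 2).
#' @param animal,behaviour metadata labels used as the template-store key.
#' @param p,q integer interpolation / decimation factors describing any
#'   resampling already applied (both >= 1).
#' @return a `dd_template` object.
#' @export
dd_template <- function(channels, animal = "unknown", behaviour = "unknown",
                        p = 1L, q = 1L) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  L <- unique(lengths(channels))
  if (length(L) != 1) stop("all template channels must have the same length")
  if (L < 2) stop("template length must be >= 2")
  if (p < 1 || q < 1 || p != round(p) || q != round(q)) {
    stop("resample factors p, q must be integers >= 1")
  }
  structure(list(channels = lapply(channels, as.numeric),
                 animal = animal, behaviour = behaviour,
                 p = as.integer(p), q = as.integer(q)),
            class = "dd_template")
}

#' Cut a template from a sensor table
#'
#' @param table a [sensor_table].
#' @param start,end inclusive sample range exemplifying the behaviour.
#' @param channels character vector of column names to search with.
#' @inheritParams dd_template
#' @export
template_from_table <- function(table, start, end, channels,
                                animal = "unknown", behaviour = "unknown") {
  stopifnot(start >= 1, end <= nrow(table), start < end)
  df <- as.data.frame(table)
  dd_template(stats::setNames(lapply(channels, function(ch) df[start:end, ch]),
                              channels),
              animal = animal, behaviour = behaviour)
}

#' Resample a waveform by a rational factor p/q
#'
#' Low-pass polyphase resampling: the signal is interpolated by the integer
#' factor `p` (zero-stuffing plus a linear-phase FIR low-pass, with the
#' group delay compensated and the edges extended by first-derivative
#' reflection to suppress end transients) and then decimated by `q`.
#' Resampling by 1/2 halves the sampling rate, resampling by 2/1 doubles
#' the duration. Used to search for a behaviour occurring at a different
#' speed than the stored example.
#'
#' @param x numeric waveform or a [dd_template] (all channels resampled).
#' @param p,q integer interpolation and decimation factors (>= 1).
#' @return the resampled waveform of length `round(L * p / q)` (identical to
#'   the input when `p == q`); an error if the result would be shorter than
#'   2 samples.
#' @export
resample_waveform <- function(x, p, q) {
  if (inherits(x, "dd_template")) {
    out <- x
    out$channels <- lapply(x$channels, resample_waveform, p = p, q = q)
    out$p <- as.integer(p); out$q <- as.integer(q)
    return(out)
  }
  stopifnot(p >= 1, q >= 1, p == round(p), q == round(q))
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q); p <- p / d; q <- q / d
  L <- length(x)
  target <- round(L * p / q)
  if (target < 2) stop("resampled length ", target, " is below 2 samples")
  if (p == q) return(x)
  # anti-alias/anti-image FIR at the upsampled rate, even order for an
  # integer group delay of n/2
  n <- 20 * max(p, q)
  h <- signal::fir1(n, 1 / max(p, q)) * p
  r <- ceiling(n / (2 * p)) + 2
  if (r >= L) { # short waveform: gentler padding from the available samples
    r <- L - 1
  }
  left <- 2 * x[1] - x[(r + 1):2]
  right <- 2 * x[L] - x[(L - 1):(L - r)]
  xp <- c(left, x, right)
  up <- numeric(length(xp) * p)
  up[seq(1, by = p, length.out = length(xp))] <- xp
  y <- stats::convolve(up, rev(h), type = "open")
  idx <- r * p + (seq_len(target) - 1) * q + 1 + n / 2
  if (max(idx) > length(y)) stop("waveform too short to resample by ", p, "/", q)
  y[idx]
}

# sliding dot products of template t against series x via frequency-space
# correlation; returns n - L + 1 values, sum_j x[k+j-1] * t[j]
fft_crosscorr <- function(x, t) {
  n <- length(x); L <- length(t)
  m <- stats::nextn(n + L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  T <- stats::fft(c(t, numeric(m - L)))
  full <- Re(stats::fft(X * Conj(T), inverse = TRUE)) / m
  full[seq_len(n - L + 1)]
}

#' Slide a template along a series, scoring similarity at every position
#'
#' Computes one similarity value per valid start position
#' (`N - L + 1` values). In normalized mode each channel's template and each
#' window are zero-meaned and unit-normed before correlating, so gain and
#' offset shifts of the signal do not affect the score; the per-channel
#' correlations r are averaged and mapped to a percentage via
#' `(r + 1) / 2 * 100`, with 100% an exact shape match. In unnormalized mode
#' the raw sliding dot product (amplitude-sensitive) is returned, averaged
#' over channels. The sliding products are evaluated in frequency space,
#' which is equivalent to the direct sliding dot product to machine
#' precision but linear-time per transform.
#'
#' @param series a [sensor_table], data frame or named list of channels.
#' @param template a [dd_template] whose channels all occur in `series`.
#' @param normalized use normalized cross-correlation (percent similarity).
#' @return numeric vector of similarities (percent in normalized mode). A
#'   zero-variance window has no defined correlation and scores 0; windows
#'   containing missing values score `NA`.
#' @export
sliding_similarity <- function(series, template, normalized = TRUE) {
  stopifnot(inherits(template, "dd_template"))
  df <- as.data.frame(series)
  chans <- names(template$channels)
  missing_ch <- setdiff(chans, names(df))
  if (length(missing_ch)) {
    stop("series lacks template channel(s): ", paste(missing_ch, collapse = ", "))
  }
  L <- length(template$channels[[1]])
  n <- nrow(df)
  if (L > n) stop("template (", L, ") is longer than the series (", n, ")")
  nv <- n - L + 1
  acc <- numeric(nv)
  na_win <- rep(FALSE, nv)
  for (ch in chans) {
    x <- as.numeric(df[[ch]])
    t <- template$channels[[ch]]
    isna <- is.na(x)
    if (any(isna)) {
      # windows touching a missing sample are undefined
      cnt <- c(0, cumsum(as.numeric(isna)))
      na_win <- na_win | (cnt[(L + 1):(n + 1)] - cnt[seq_len(nv)]) > 0
      x[isna] <- 0
    }
    cc <- fft_crosscorr(x, t)
    if (!normalized) {
      acc <- acc + cc
      next
    }
    st <- sum(t); stt <- sum(t^2)
    vt <- stt - st^2 / L
    if (vt <= 0) stop("template channel '", ch, "' has zero variance")
    cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x^2))
    sx <- cx[(L + 1):(n + 1)] - cx[seq_len(nv)]
    sxx <- cxx[(L + 1):(n + 1)] - cxx[seq_len(nv)]
    vx <- sxx - sx^2 / L
    num <- cc - sx * st / L
    r <- numeric(nv)
    ok <- vx > .Machine$double.eps * pmax(sxx, 1)
    r[ok] <- num[ok] / sqrt(vx[ok] * vt)
    r <- pmin(pmax(r, -1), 1)
    # zero-variance window: similarity defined as 0 -> r = -1 contributes 0%
    r[!ok] <- -1
    acc <- acc + r
  }
  out <- acc / length(chans)
  if (normalized) out <- (out + 1) / 2 * 100
  out[na_win] <- NA_real_
  out
}

#' Extract non-overlapping matches above a similarity threshold
#'
#' Keeps every start position whose similarity strictly exceeds the
#' threshold, then applies non-maximum suppression so accepted windows do
#' not overlap: candidates are taken in decreasing similarity (ties broken
#' by earliest start) and a candidate is dropped when it overlaps an already
#' accepted window. Suppression can be disabled to inspect raw crossings.
#'
#' @param similarity vector from [sliding_similarity].
#' @param threshold similarity threshold (percent in normalized mode).
#' @param width template length L in samples.
#' @param suppress apply non-maximum suppression (default `TRUE`).
#' @param rejected optional data frame of `start`, `end` intervals (e.g. the
#'   rejected record of a [label_set]); matches overlapping them are dropped
#'   so re-running a search does not resurrect rejected intervals.
#' @param template id recorded on each match.
#' @return a `match_results` data frame (`id`, `start`, `length`,
#'   `similarity`, `template`), sorted by start.
#' @export
extract_matches <- function(similarity, threshold, width, suppress = TRUE,
                            rejected = NULL, template = 1L) {
  cand <- which(!is.na(similarity) & similarity > threshold)
  res <- data.frame(start = cand,
                    length = rep_len(as.integer(width), length(cand)),
                    similarity = similarity[cand],
                    template = rep_len(as.integer(template), length(cand)))
  if (nrow(res) && suppress) {
    res <- res[order(-res$similarity, res$start), , drop = FALSE]
    taken_end <- integer(0); taken_start <- integer(0)
    keep <- logical(nrow(res))
    for (i in seq_len(nrow(res))) {
      s <- res$start[i]; e <- s + width - 1
      if (!any(s <= taken_end & e >= taken_start)) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
      }
    }
    res <- res[keep, , drop = FALSE]
  }
  if (!is.null(rejected) && nrow(res) && NROW(rejected)) {
    e <- res$start + res$length - 1
    hit <- vapply(seq_len(nrow(res)), function(i) {
      any(res$start[i] <= rejected$end & e[i] >= rejected$start)
    }, logical(1))
    res <- res[!hit, , drop = FALSE]
  }
  res <- res[order(res$start), , drop = FALSE]
  res <- data.frame(id = seq_len(nrow(res)), res, row.names = NULL)
  class(res) <- c("match_results", "data.frame")
  res
}

#' Search with several templates of the same behaviour (boosting)
#'
#' Secondary examples widen the search span: each template is slid over the
#' series independently, the candidate matches are pooled, and overlaps are
#' suppressed jointly (highest similarity wins). The boosted match count is
#' never below the best single template's count for the same threshold.
#'
#' @param templates list of [dd_template]s (>= 1) of the same behaviour.
#' @param series series to search (see [sliding_similarity]).
#' @param threshold similarity threshold.
#' @param normalized passed to [sliding_similarity].
#' @param rejected see [extract_matches].
#' @return a `match_results` data frame; `template` records which template
#'   produced each match.
#' @export
boost <- function(templates, series, threshold, normalized = TRUE,
                  rejected = NULL) {
  stopifnot(length(templates) >= 1)
  pooled <- do.call(rbind, lapply(seq_along(templates), function(ti) {
    tpl <- templates[[ti]]
    sim <- sliding_similarity(series, tpl, normalized)
    extract_matches(sim, threshold, length(tpl$channels[[1]]),
                    suppress = FALSE, template = ti)
  }))
  if (!nrow(pooled)) {
    return(extract_matches(numeric(0), threshold, 1L))
  }
  pooled <- pooled[order(-pooled$similarity, pooled$start), , drop = FALSE]
  keep <- logical(nrow(pooled))
  taken_start <- integer(0); taken_end <- integer(0)
  ends <- pooled$start + pooled$length - 1
  for (i in seq_len(nrow(pooled))) {
    if (!any(pooled$start[i] <= taken_end & ends[i] >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, pooled$start[i])
      taken_end <- c(taken_end, ends[i])
    }
  }
  res <- pooled[keep, , drop = FALSE]
  if (!is.null(rejected) && nrow(res) && NROW(rejected)) {
    e <- res$start + res$length - 1
    hit <- vapply(seq_len(nrow(res)), function(i) {
      any(res$start[i] <= rejected$end & e[i] >= rejected$start)
    }, logical(1))
    res <- res[!hit, , drop = FALSE]
  }
  res <- res[order(res$start), , drop = FALSE]
  res$id <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("match_results", "data.frame")
  res
}
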