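# Continuous Morlet wavelet transform, smoothing and wavelet coherence for
# pairs of resting-state network time series. The coherence estimator follows
# the standard construction: scale-normalised auto/cross spectra smoothed in
# time (Gaussian of width ~ scale) and in scale (boxcar over 0.6 octave),
# coherence = |S(W_xy/s)|^2 / (S(|W_x|^2/s) S(|W_y|^2/s)).

#' Default wavelet scales for fMRI-band coherence
#'
#' Geometric scale grid covering the fMRI band-pass window used upstream of
#' network extraction (0.01-0.2 Hz by default), expressed as Morlet scales.
#'
#' @param dt sampling interval in seconds.
#' @param f_min,f_max frequency band limits in Hz.
#' @param dj scale resolution in octaves (default 1/8 octave steps).
#' @param omega0 Morlet central frequency (default 6).
#' @return Numeric vector of scales (seconds).
#' @export
wca_scales <- function(dt, f_min = 0.01, f_max = 0.2, dj = 1 / 8, omega0 = 6) {
  if (f_max >= 1 / (2 * dt))
    stop("band above Nyquist: f_max must be < 1/(2*dt)")
  ff <- fourier_factor(omega0)
  s_min <- (1 / f_max) / ff
  s_max <- (1 / f_min) / ff
  n <- ceiling(log2(s_max / s_min) / dj)
  s_min * 2^(dj * (0:n))
}

fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous wavelet transform with a Morlet mother wavelet
#'
#' @param x numeric series.
#' @param dt sampling interval (seconds).
#' @param scales numeric vector of scales (seconds).
#' @param omega0 Morlet central frequency.
#' @return Complex matrix, `length(scales)` rows x `length(x)` columns.
#' @export
morlet_cwt <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  xh <- stats::fft(x - mean(x))
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  omega <- 2 * pi * k / (n * dt)
  W <- matrix(0i, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) * exp(-(s * omega - omega0)^2 / 2)
    psi[omega <= 0] <- 0
    W[si, ] <- stats::fft(xh * psi, inverse = TRUE) / n
  }
  W
}

# Edge-normalised smoothing in time (Gaussian of sd = scale, per scale row)
# and in scale (boxcar over 0.6 octave). Operates on real or complex grids.
smooth_grid <- function(M, dt, scales, dj) {
  nr <- nrow(M); nc <- ncol(M)
  out <- M
  for (si in seq_len(nr)) {
    s <- scales[si]
    hw <- max(1L, ceiling(3 * s / dt))
    t <- (-hw):hw
    w <- exp(-(t * dt)^2 / (2 * s^2))
    out[si, ] <- conv_same(M[si, ], w)
  }
  # boxcar across scales, width 0.6 octave
  bw <- max(1L, round(0.6 / dj / 2))
  if (nr > 1L) {
    res <- out
    for (si in seq_len(nr)) {
      lo <- max(1L, si - bw); hi <- min(nr, si + bw)
      res[si, ] <- colMeans(out[lo:hi, , drop = FALSE])
    }
    out <- res
  }
  out
}

# 'same' convolution with per-position renormalisation so edges are unbiased
conv_same <- function(x, w) {
  n <- length(x); m <- length(w); hw <- (m - 1L) %/% 2L
  pad <- c(rep(0, hw), x, rep(0, hw + 1L))
  ones <- c(rep(0, hw), rep(1, n), rep(0, hw + 1L))
  num <- stats::convolve(pad, rev(w), type = "open")
  den <- stats::convolve(ones, rev(w), type = "open")
  idx <- (m - 1L) + seq_len(n)
  num[idx] / den[idx]
}

#' Wavelet coherence between two series
#'
#' Computes the magnitude-squared wavelet coherence and the phase difference
#' between `x` and `y` on a time x scale grid, flags cells inside the cone
#' of influence (COI), and derives a significance mask from a fixed coherence
#' cutoff with COI exclusion. Positive phase means `x` leads `y`.
#'
#' @param x,y numeric series of equal length.
#' @param dt sampling interval (seconds).
#' @param scales scale grid; defaults to [wca_scales()].
#' @param omega0 Morlet central frequency.
#' @param dj scale resolution used for the scale smoothing window.
#' @param sig_threshold coherence cutoff defining the significance mask.
#' @param pair optional character/integer pair identifier `c(i, j)`.
#' @return A `coherence_map` object: list with matrices `coh` (in `[0,1]`),
#'   `phase` (in `(-pi, pi]`), logical `mask` and `in_coi`, plus `scales`,
#'   `periods`, `times`, `coi` (COI period per time point) and `threshold`.
#' @export
wavelet_coherence <- function(x, y, dt, scales = NULL, omega0 = 6,
                              dj = 1 / 8, sig_threshold = 0.7,
                              pair = c("x", "y")) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (is.null(scales)) scales <- wca_scales(dt, omega0 = omega0, dj = dj)
  if (2 * sqrt(2) * max(scales) > (n - 1) * dt)
    stop("series shorter than the support of the largest scale")
  Wx <- morlet_cwt(x, dt, scales, omega0)
  Wy <- morlet_cwt(y, dt, scales, omega0)
  inv_s <- 1 / scales
  Sx <- smooth_grid(Re(Wx * Conj(Wx)) * inv_s, dt, scales, dj)
  Sy <- smooth_grid(Re(Wy * Conj(Wy)) * inv_s, dt, scales, dj)
  cross <- Wx * Conj(Wy) * inv_s
  Sxy <- smooth_grid(Re(cross), dt, scales, dj) +
    1i * smooth_grid(Im(cross), dt, scales, dj)
  coh <- Mod(Sxy)^2 / (Sx * Sy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  phase <- Arg(Sxy)
  times <- (seq_len(n) - 1L) * dt
  # e-folding time sqrt(2)*s: cell inside COI if far enough from both edges
  edge_dist <- pmin(times, (n - 1L) * dt - times)
  in_coi <- outer(sqrt(2) * scales, edge_dist, FUN = "<=")
  coi_period <- pmin(edge_dist / sqrt(2), max(scales)) * fourier_factor(omega0)
  structure(list(
    coh = coh, phase = phase,
    mask = (coh >= sig_threshold) & in_coi,
    in_coi = in_coi, scales = scales,
    periods = scales * fourier_factor(omega0),
    times = times, coi = coi_period,
    threshold = sig_threshold, pair = pair
  ), class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf(
    "<coherence_map %s -> %s: %d scales x %d times, %.1f%% significant>\n",
    x$pair[1], x$pair[2], nrow(x$coh), ncol(x$coh), 100 * mean(x$mask)
  ))
  invisible(x)
}

# phase categories used to split coherence clusters:
# 1 in-phase |phi| < pi/4; 2 leading phi in [pi/4, 3pi/4];
# 3 out-of-phase |phi| > 3pi/4; 4 lagging phi in [-3pi/4, -pi/4]
phase_category <- function(phase) {
  cat <- integer(length(phase))
  a <- abs(phase)
  cat[a < pi / 4] <- 1L
  cat[a > 3 * pi / 4] <- 3L
  mid <- a >= pi / 4 & a <= 3 * pi / 4
  cat[mid & phase > 0] <- 2L
  cat[mid & phase <= 0] <- 4L
  cat
}

# 4-neighbour connected-component count of a category-labelled grid
# (components cannot span different categories). Vectorised minimum-label
# propagation; 0 marks background.
count_components <- function(cat) {
  nr <- nrow(cat); nc <- ncol(cat)
  sig <- cat != 0L
  if (!any(sig)) return(0L)
  lab <- matrix(seq_along(cat), nr, nc)
  lab[!sig] <- NA_integer_
  shift <- function(M, dr, dc) {
    out <- matrix(NA_integer_, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    new <- lab
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- shift(lab, d[1L], d[2L])
      nbc <- shift(cat, d[1L], d[2L])
      ok <- !is.na(nb) & sig & nbc == cat & nb < new
      ok[is.na(ok)] <- FALSE
      new[ok] <- nb[ok]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[sig]))
}

#' Number of coherence clusters (nCC) of a coherence map
#'
#' Counts the connected components (4-neighbour connectivity on the
#' time x scale grid) of significant coherence cells, with components split
#' by phase category (in-phase, out-of-phase, leading, lagging), i.e. the
#' number of distinct coherent interactions between the two networks.
#'
#' @param map a `coherence_map`.
#' @return Non-negative integer count.
#' @export
count_coherence_clusters <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  cat <- phase_category(map$phase)
  cat[!map$mask] <- 0L
  count_components(matrix(cat, nrow(map$coh), ncol(map$coh)))
}

#' Lead coherence (leadCoh) of a coherence map
#'
#' Directed coupling measure: the extent to which the source network (first
#' element of the ordered pair) leads the target in phase over significant
#' coherence cells. `"binary"` (default) is the fraction of significant
#' cells with positive phase; `"weighted"` additionally weights each leading
#' cell by `sin(phase)`.
#'
#' @param map a `coherence_map` for the ordered pair (source, target).
#' @param mode `"binary"` or `"weighted"`.
#' @return Value in `[0, 1]`; 0 when no cell is significant.
#' @export
lead_coherence <- function(map, mode = c("binary", "weighted")) {
  stopifnot(inherits(map, "coherence_map"))
  mode <- match.arg(mode)
  ph <- map$phase[map$mask]
  if (length(ph) == 0L) return(0)
  if (mode == "binary") mean(ph > 0) else mean((ph > 0) * sin(ph))
}
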