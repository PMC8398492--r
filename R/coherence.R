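#' Wavelet-coherence configuration
#'
#' @param omega0 dimensionless center frequency of the complex Morlet mother
#'   wavelet. The default 6 gives a Fourier-period/scale ratio of
#'   \code{4*pi/(6 + sqrt(38))}, about 1.03, so scales read almost directly as
#'   periods.
#' @param voices_per_octave number of scales per octave of period (default 12).
#' @param period_range length-2 numeric, analyzed Fourier-period range in
#'   seconds; NULL (default) means \code{c(2*tr, n*tr/4)} chosen at transform
#'   time.
#' @param smoothing_time_factor SD of the Gaussian time-smoothing kernel, in
#'   units of the wavelet scale (default 1).
#' @param smoothing_scale_decades width of the boxcar scale-smoothing window in
#'   decades of scale (default 0.6).
#' @param image_size length-2 integer, output raster size (default 224 x 224).
#' @param colormap name of the rendering palette; any \code{grDevices::hcl.colors}
#'   palette (default "Viridis"). Fixed 256-level lookup anchored to [0, 1].
#' @return An object of class \code{coherence_config}.
#' @export
coherence_config <- function(omega0 = 6, voices_per_octave = 12L,
                             period_range = NULL,
                             smoothing_time_factor = 1,
                             smoothing_scale_decades = 0.6,
                             image_size = c(224L, 224L),
                             colormap = "Viridis") {
  if (omega0 <= 0) stop_field("omega0", "must be > 0")
  if (voices_per_octave < 1) stop_field("voices_per_octave", "must be >= 1")
  if (!is.null(period_range)) {
    if (length(period_range) != 2 || period_range[1] <= 0 ||
        period_range[2] <= period_range[1]) {
      stop_field("period_range", "must be increasing positive (min, max)")
    }
  }
  if (length(image_size) != 2 || any(image_size < 8)) {
    stop_field("image_size", "must be two integers >= 8")
  }
  structure(list(omega0 = omega0,
                 voices_per_octave = as.integer(voices_per_octave),
                 period_range = period_range,
                 smoothing_time_factor = smoothing_time_factor,
                 smoothing_scale_decades = smoothing_scale_decades,
                 image_size = as.integer(image_size),
                 colormap = colormap),
            class = "coherence_config")
}

#' Fourier-period/scale ratio of the complex Morlet wavelet
#'
#' The equivalent Fourier period of a Morlet wavelet at scale \eqn{a} is
#' \eqn{a \cdot 4\pi / (\omega_0 + \sqrt{2 + \omega_0^2})}. At the default
#' \eqn{\omega_0 = 6} this ratio is approximately 1.03.
#'
#' @param omega0 dimensionless center frequency.
#' @return The period/scale ratio (scalar).
#' @export
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

resolve_period_range <- function(config, n, tr_seconds) {
  pr <- config$period_range
  if (is.null(pr)) pr <- c(2 * tr_seconds, n * tr_seconds / 4)
  if (pr[1] < 2 * tr_seconds - 1e-12) {
    stop_field("period_range", sprintf("min period %.3g below 2*TR = %.3g",
                                       pr[1], 2 * tr_seconds))
  }
  if (pr[2] > n * tr_seconds + 1e-9) {
    stop_field("period_range", sprintf("max period %.3g beyond record length %.3g",
                                       pr[2], n * tr_seconds))
  }
  pr
}

#' Continuous wavelet transform with a complex Morlet mother wavelet
#'
#' FFT-based CWT with \eqn{1/\sqrt{a}} normalization and zero-padded
#' boundaries (padding to the next power of two). Scales are log-spaced with
#' \code{voices_per_octave} voices per octave across the configured Fourier
#' period range. The cone of influence records, per time point, the maximum
#' period free of edge effects (e-folding time \eqn{\sqrt{2} a} of the Morlet
#' envelope).
#'
#' @param x finite numeric vector, length >= 16. The mean is removed before
#'   transforming.
#' @param tr_seconds sampling interval in seconds.
#' @param config a \code{\link{coherence_config}}.
#' @return An object of class \code{cwt_result}: complex \code{coefficients}
#'   (scales x time), \code{scales}, \code{periods} (seconds),
#'   \code{coi} (seconds, per time point), \code{tr_seconds}.
#' @export
cwt_morlet <- function(x, tr_seconds, config = coherence_config()) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16) stop("signal must have length >= 16", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  pr <- resolve_period_range(config, n, tr_seconds)
  ff <- morlet_fourier_factor(config$omega0)
  dj <- 1 / config$voices_per_octave
  s0 <- pr[1] / ff
  n_scales <- floor(log2(pr[2] / pr[1]) / dj) + 1L
  scales <- s0 * 2^((seq_len(n_scales) - 1) * dj)
  periods <- ff * scales

  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  fx <- stats::fft(xp)
  # angular frequency grid of the padded series
  k <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1, length.out = npad / 2 - 1))
  omega <- 2 * pi * k / (npad * tr_seconds)

  coef <- matrix(0 + 0i, n_scales, n)
  norm0 <- pi^(-1 / 4)
  for (i in seq_len(n_scales)) {
    a <- scales[i]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- norm0 * sqrt(2 * pi * a / tr_seconds) *
      exp(-(a * omega[pos] - config$omega0)^2 / 2)
    w <- stats::fft(fx * psi_hat, inverse = TRUE) / npad
    coef[i, ] <- w[seq_len(n)]
  }
  dist <- pmin(seq_len(n) - 1, n - seq_len(n)) * tr_seconds
  coi <- ff / sqrt(2) * dist
  structure(list(coefficients = coef, scales = scales, periods = periods,
                 coi = coi, tr_seconds = tr_seconds, n = n,
                 config = config),
            class = "cwt_result")
}

# Gaussian smoothing along time, SD proportional to scale, then boxcar along
# scale. Kernels are renormalized at the boundaries so constants are exact
# fixed points. Works on real or complex matrices (scales x time).
smooth_scalogram <- function(m, scales, tr_seconds, config) {
  n <- ncol(m)
  out <- m
  # time smoothing, row by row (kernel depends on scale)
  for (i in seq_len(nrow(m))) {
    sd_samp <- config$smoothing_time_factor * scales[i] / tr_seconds
    if (sd_samp < 1e-8) next
    half <- max(1L, ceiling(3 * sd_samp))
    kern <- exp(-((-half:half)^2) / (2 * sd_samp^2))
    row <- m[i, ]
    sm <- complex_conv_norm(row, kern)
    out[i, ] <- sm
  }
  # scale smoothing: boxcar of fixed width in log10(scale)
  dj_dec <- log10(2) / config$voices_per_octave
  w <- max(1L, round(config$smoothing_scale_decades / dj_dec))
  if (w > 1 && nrow(m) > 1) {
    half <- w %/% 2
    res <- out
    for (i in seq_len(nrow(m))) {
      lo <- max(1L, i - half)
      hi <- min(nrow(m), i + half)
      res[i, ] <- colMeans(out[lo:hi, , drop = FALSE])
    }
    out <- res
  }
  out
}

# normalized "same" convolution with boundary renormalization; accepts
# complex input (stats::convolve drops imaginary parts, so split them)
complex_conv_norm <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1L) %/% 2L
  conv1 <- function(v) {
    vp <- c(rep(0, half), v, rep(0, half))
    stats::convolve(vp, kern, type = "filter")
  }
  wp <- conv1(rep(1, n))
  if (is.complex(x)) {
    (conv1(Re(x)) + 1i * conv1(Im(x))) / wp
  } else {
    conv1(x) / wp
  }
}

#' Smoothed cross-wavelet spectrum
#'
#' Applies the smoothing operator S (Gaussian in time with SD proportional to
#' scale; boxcar in log-scale) to the cross-spectrum
#' \eqn{C_x^*(a,b) C_y(a,b)} of two CWTs on matching grids.
#'
#' @param cwt_x,cwt_y \code{\link{cwt_morlet}} results on identical grids.
#' @param config a \code{\link{coherence_config}}; defaults to the transform's.
#' @return Complex matrix (scales x time).
#' @export
smooth_cross_spectrum <- function(cwt_x, cwt_y, config = NULL) {
  stopifnot(inherits(cwt_x, "cwt_result"), inherits(cwt_y, "cwt_result"))
  if (length(cwt_x$scales) != length(cwt_y$scales) ||
      any(abs(cwt_x$scales - cwt_y$scales) > 1e-12) ||
      ncol(cwt_x$coefficients) != ncol(cwt_y$coefficients)) {
    stop("CWT grids do not match", call. = FALSE)
  }
  if (is.null(config)) config <- cwt_x$config
  cross <- Conj(cwt_x$coefficients) * cwt_y$coefficients
  smooth_scalogram(cross, cwt_x$scales, cwt_x$tr_seconds, config)
}

#' Squared wavelet coherence between two signals
#'
#' Computes
#' \deqn{WCT_{xy}(a,b) = \frac{|S(C_x^* C_y)|^2}{S(|C_x|^2)\, S(|C_y|^2)}}
#' where S smooths in time and scale. Values are clipped to [0, 1] after
#' floating point. Without smoothing the ratio degenerates to exactly 1
#' everywhere; \code{smoothing = "none"} exposes that diagnostic mode.
#'
#' @param x,y equal-length finite numeric signals with nonzero variance.
#' @param tr_seconds sampling interval in seconds.
#' @param config a \code{\link{coherence_config}}.
#' @param smoothing \code{"gaussian"} (default) or \code{"none"} (diagnostic:
#'   the smoothing operator is the identity).
#' @return An object of class \code{coherence_map}: \code{values} (scales x
#'   time in [0,1]), \code{periods}, \code{times}, \code{coi}, \code{config}.
#' @export
wavelet_coherence <- function(x, y, tr_seconds, config = coherence_config(),
                              smoothing = c("gaussian", "none")) {
  smoothing <- match.arg(smoothing)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("signals must have equal length", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant input signal: coherence undefined", call. = FALSE)
  }
  wx <- cwt_morlet(x, tr_seconds, config)
  wy <- cwt_morlet(y, tr_seconds, config)
  coherence_from_cwt(wx, wy, smoothing = smoothing)
}

# core of Eq.-style coherence; reusable with cached per-node CWTs and cached
# smoothed auto-spectra (sxx/syy)
coherence_from_cwt <- function(wx, wy, smoothing = "gaussian",
                               sxx = NULL, syy = NULL) {
  config <- wx$config
  if (smoothing == "none") {
    cross <- Conj(wx$coefficients) * wy$coefficients
    num <- Mod(cross)^2
    den <- (Mod(wx$coefficients)^2) * (Mod(wy$coefficients)^2)
  } else {
    if (is.null(sxx)) {
      sxx <- Re(smooth_scalogram(Mod(wx$coefficients)^2, wx$scales,
                                 wx$tr_seconds, config))
    }
    if (is.null(syy)) {
      syy <- Re(smooth_scalogram(Mod(wy$coefficients)^2, wy$scales,
                                 wy$tr_seconds, config))
    }
    sxy <- smooth_cross_spectrum(wx, wy, config)
    num <- Mod(sxy)^2
    den <- sxx * syy
  }
  eps <- .Machine$double.eps
  vals <- num / pmax(den, eps)
  vals[den <= eps & num <= eps] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(values = vals, periods = wx$periods,
                 times = (seq_len(wx$n) - 1) * wx$tr_seconds,
                 coi = wx$coi, config = config),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("<coherence_map> %d scales x %d times, periods %.3g-%.3g s\n",
              nrow(x$values), ncol(x$values), min(x$periods), max(x$periods)))
  invisible(x)
}

# fixed 256-level RGB lookup table (0..255 integers), anchored to [0,1]
coherence_palette <- function(name = "Viridis") {
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(64, name), space = "rgb")
  round(ramp(seq(0, 1, length.out = 256)))
}

# bilinear resampling of a matrix onto an nr x nt grid of fractional indices
bilinear_resample <- function(m, nr, nt) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nt)
  r0 <- pmin(floor(ri), max(nrow(m) - 1L, 1L))
  c0 <- pmin(floor(ci), max(ncol(m) - 1L, 1L))
  fr <- ri - r0
  fc <- ci - c0
  m00 <- m[r0, c0, drop = FALSE]
  m10 <- m[pmin(r0 + 1, nrow(m)), c0, drop = FALSE]
  m01 <- m[r0, pmin(c0 + 1, ncol(m)), drop = FALSE]
  m11 <- m[pmin(r0 + 1, nrow(m)), pmin(c0 + 1, ncol(m)), drop = FALSE]
  fr_m <- matrix(fr, nr, nt)
  fc_m <- matrix(fc, nr, nt, byrow = TRUE)
  m00 * (1 - fr_m) * (1 - fc_m) + m10 * fr_m * (1 - fc_m) +
    m01 * (1 - fr_m) * fc_m + m11 * fr_m * fc_m
}

#' Render a coherence map as a fixed-size RGB scalogram image
#'
#' The period axis is log-scaled (the scale grid is log-uniform, so rows are
#' resampled uniformly in log-period), short periods at the top. Values are
#' mapped through a fixed 256-level palette anchored to [0, 1] — identical
#' maps render byte-identically. The cone of influence is stored in the map
#' but not masked in the image.
#'
#' @param map a \code{\link{wavelet_coherence}} result.
#' @param config a \code{\link{coherence_config}} (for image size/palette);
#'   defaults to the map's own config.
#' @return An object of class \code{scalogram_image}: \code{pixels} (integer
#'   array height x width x 3, values 0..255) plus \code{subject_id},
#'   \code{seed_node}, \code{partner_node}, \code{group} metadata slots
#'   (NA until set by \code{\link{pairwise_scalograms}}).
#' @export
render_scalogram <- function(map, config = NULL) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(config)) config <- map$config
  h <- config$image_size[1]; wdt <- config$image_size[2]
  vals <- bilinear_resample(map$values, h, wdt)
  vals <- pmin(pmax(vals, 0), 1)
  idx <- pmin(255L, as.integer(floor(vals * 256))) + 1L
  pal <- coherence_palette(config$colormap)
  px <- array(0L, dim = c(h, wdt, 3))
  for (ch in 1:3) {
    px[, , ch] <- matrix(as.integer(pal[idx, ch]), h, wdt)
  }
  structure(list(pixels = px,
                 subject_id = NA_character_, seed_node = NA_integer_,
                 partner_node = NA_integer_, group = NA_character_,
                 site = NA_character_),
            class = "scalogram_image")
}

#' @export
print.scalogram_image <- function(x, ...) {
  cat(sprintf("<scalogram_image> %dx%dx3  subject=%s seed=%s partner=%s group=%s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$subject_id,
              x$seed_node, x$partner_node, x$group))
  invisible(x)
}

#' Write a scalogram image to a PNG file
#'
#' @param image a \code{\link{render_scalogram}} result.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_scalogram_png <- function(image, path) {
  stopifnot(inherits(image, "scalogram_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' All pairwise scalograms between seed nodes and the remaining nodes
#'
#' For each seed node, one coherence scalogram is computed against every other
#' node (no self-pair): a recording with \eqn{n} nodes and one seed node
#' yields \eqn{n - 1} images. Per-node CWTs and smoothed auto-spectra are
#' computed once and reused across pairs.
#'
#' @param recording a \code{\link{roi_time_series}}.
#' @param seed_nodes integer indices of the seed node(s).
#' @param config a \code{\link{coherence_config}}.
#' @return List of \code{scalogram_image}, each labeled with the subject id,
#'   seed node, partner node, group and site.
#' @export
pairwise_scalograms <- function(recording, seed_nodes,
                                config = coherence_config()) {
  stopifnot(inherits(recording, "roi_ts"))
  n_nodes <- ncol(recording$data)
  seed_nodes <- as.integer(seed_nodes)
  if (any(seed_nodes < 1 | seed_nodes > n_nodes)) {
    stop(sprintf("seed node out of range 1..%d", n_nodes), call. = FALSE)
  }
  needed <- seq_len(n_nodes)
  cwts <- vector("list", n_nodes)
  autos <- vector("list", n_nodes)
  for (j in needed) {
    xj <- recording$data[, j]
    if (sd(xj) == 0) {
      stop(sprintf("node %d is constant: coherence undefined", j), call. = FALSE)
    }
    cwts[[j]] <- cwt_morlet(xj, recording$tr_seconds, config)
    autos[[j]] <- Re(smooth_scalogram(Mod(cwts[[j]]$coefficients)^2,
                                      cwts[[j]]$scales, recording$tr_seconds,
                                      config))
  }
  out <- vector("list", length(seed_nodes) * (n_nodes - 1L))
  k <- 0L
  for (sn in seed_nodes) {
    for (j in setdiff(seq_len(n_nodes), sn)) {
      map <- coherence_from_cwt(cwts[[sn]], cwts[[j]],
                                sxx = autos[[sn]], syy = autos[[j]])
      img <- render_scalogram(map, config)
      img$subject_id <- recording$subject_id
      img$seed_node <- sn
      img$partner_node <- j
      img$group <- recording$group
      img$site <- recording$site
      k <- k + 1L
      out[[k]] <- img
    }
  }
  out
}
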