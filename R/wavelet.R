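# Daubechies-8 orthonormal scaling filter, natural order h0..h15.
# The 16 constants are standard tabulated values; the test suite verifies
# them against the defining properties (sum sqrt(2), unit norm, even-shift
# orthogonality, vanishing moments of the associated wavelet).
DB8_H <- c(
   0.05441584224310401,   0.31287159091429995,   0.6756307362972898,
   0.5853546836542067,   -0.015829105256349306, -0.2840155429615469,
   0.0004724845739132828, 0.12874742662047847,  -0.017369301001807547,
  -0.044088253930794755,  0.013981027917398282,  0.008746094047405777,
  -0.004870352993451574, -0.00039174037337694705, 0.0006754494064505693,
  -0.00011747678412476953)

#' Evaluate a mother wavelet on a dense grid
#'
#' For the Daubechies-8 wavelet (which has no closed-form continuous
#' expression) the wavelet function is computed by the cascade algorithm:
#' the scaling function is refined `level` times through the two-scale
#' relation with the db8 scaling filter, and the final refinement uses the
#' quadrature-mirror highpass filter to produce the wavelet on a dyadic
#' grid of spacing `2^-level` over the support \[0, 15\]. A real Morlet
#' wavelet (`exp(-t^2/2) * cos(5 t)`, truncated to \[-5, 5\]) is available
#' as an analytic alternative.
#'
#' @param wavelet `"db8"` or `"morlet"`.
#' @param level Cascade refinement depth (db8 only).
#' @return List with `x` (grid), `psi` (values), `t_min`, `t_max`,
#'   `center` (temporal center used to align CWT output).
#' @export
wavelet_function <- function(wavelet = c("db8", "morlet"), level = 8) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "morlet") {
    x <- seq(-5, 5, by = 1 / 64)
    psi <- pi^(-0.25) * exp(-x^2 / 2) * cos(5 * x)
    return(list(x = x, psi = psi, t_min = -5, t_max = 5, center = 0,
                name = "morlet"))
  }
  h <- DB8_H
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror highpass
  up2 <- function(v) {
    out <- numeric(2 * length(v) - 1)
    out[seq(1, length(out), by = 2)] <- v
    out
  }
  conv_full <- function(a, b) {
    # linear convolution via FFT
    n <- length(a) + length(b) - 1L
    n2 <- stats::nextn(n, 2)
    re <- Re(stats::fft(stats::fft(c(a, numeric(n2 - length(a)))) *
                        stats::fft(c(b, numeric(n2 - length(b)))),
                        inverse = TRUE)) / n2
    re[seq_len(n)]
  }
  # wavelet = inverse transform of a single detail coefficient at the
  # coarsest level: one highpass step first, then lowpass refinements
  v <- sqrt(2) * g
  for (j in seq_len(level - 1)) v <- conv_full(up2(v), sqrt(2) * h)
  psi <- v / sqrt(sum(v^2) / 2^level)   # unit L2 norm on the dyadic grid
  x <- (seq_along(psi) - 1) / 2^level
  list(x = x, psi = psi, t_min = 0, t_max = max(x), center = max(x) / 2,
       name = "db8")
}

#' Default CWT scale set for normalized beats
#'
#' Log-spaced scales whose pseudo-frequencies (`f = fc / (scale * dt)`,
#' with wavelet center frequency `fc ~ 0.67` for db8) span `fmin`-`fmax`
#' Hz at the beat's effective sampling rate `target_len / duration`. The
#' defaults cover the pulse fundamental (around 1 Hz) and its harmonics
#' up to 20 Hz.
#'
#' @param target_len Samples per normalized beat.
#' @param duration Nominal beat duration, s.
#' @param fmin,fmax Pseudo-frequency range, Hz.
#' @param n_scales Number of scales.
#' @param fc Wavelet center frequency (cycles per unit of wavelet time).
#' @return Increasing vector of `n_scales` scales (samples).
#' @export
default_scales <- function(target_len = 128, duration = 0.8,
                           fmin = 0.5, fmax = 20, n_scales = 64, fc = 0.67) {
  dt <- duration / target_len
  f <- exp(seq(log(fmax), log(fmin), length.out = n_scales))
  fc / (f * dt)
}

#' Continuous wavelet transform scalogram of one beat
#'
#' Cross-correlates the beat with L2-normalized, rescaled copies of the
#' mother wavelet (db8 via the cascade approximation by default) and takes
#' coefficient magnitudes, giving an `n_scales x length(beat)` scale-time
#' image. The transform is linear in the input before the magnitude step;
#' boundaries are zero-padded.
#'
#' @param beat Numeric vector (a normalized beat).
#' @param scales Strictly positive, increasing scale vector.
#' @param wavelet `"db8"` (default) or `"morlet"`.
#' @param wf Optional precomputed [wavelet_function()] (re-used across
#'   beats for speed).
#' @return Object of class `scalogram`: list with `coeffs`
#'   (`n_scales x length(beat)` magnitude matrix), `scales`,
#'   `wavelet_name`.
#' @export
cwt_scalogram <- function(beat, scales = default_scales(length(beat)),
                          wavelet = c("db8", "morlet"), wf = NULL) {
  wavelet <- match.arg(wavelet)
  if (any(!is.finite(beat))) stop("beat must be finite", call. = FALSE)
  if (any(scales <= 0)) stop("scales must be strictly positive", call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing", call. = FALSE)
  }
  if (is.null(wf)) wf <- wavelet_function(wavelet)
  n <- length(beat)
  coeffs <- matrix(0, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    k <- cwt_kernel(wf, scales[i])
    coeffs[i, ] <- abs(xcorr_centered(beat, k$kernel, k$center_idx))
  }
  structure(list(coeffs = coeffs, scales = scales, wavelet_name = wf$name),
            class = "scalogram")
}

# Sample the mother wavelet at unit (sample) spacing for one scale and
# L2-normalize; center_idx is the kernel index aligned with the output time.
cwt_kernel <- function(wf, scale) {
  m <- floor((wf$t_max - wf$t_min) * scale) + 1L
  tt <- wf$t_min + (seq_len(m) - 1) / scale
  kern <- stats::approx(wf$x, wf$psi, xout = tt, rule = 2)$y
  nrm <- sqrt(sum(kern^2))
  if (nrm > 0) kern <- kern / nrm
  list(kernel = kern,
       center_idx = min(m, max(1L, round((wf$center - wf$t_min) * scale) + 1L)))
}

# Cross-correlation of x with kernel, output aligned so out[t] =
# sum_u x[t + u - center_idx] * kernel[u], zero-padded boundaries.
# Computed via circular FFT correlation with enough zero padding that
# positive lags (front of the buffer) and negative lags (back of the
# buffer) never alias.
xcorr_centered <- function(x, kernel, center_idx) {
  n <- length(x); m <- length(kernel)
  n2 <- stats::nextn(n + m, 2)
  circ <- Re(stats::fft(stats::fft(c(x, numeric(n2 - n))) *
                        Conj(stats::fft(c(kernel, numeric(n2 - m)))),
                        inverse = TRUE)) / n2
  lag <- seq_len(n) - center_idx          # lag ell: sum_u x[ell + u] k[u]
  idx <- ifelse(lag >= 0, lag + 1L, n2 + lag + 1L)
  circ[idx]
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("CWT scalogram (%s): %d scales x %d samples, scale range %.1f-%.1f\n",
              x$wavelet_name, nrow(x$coeffs), ncol(x$coeffs),
              min(x$scales), max(x$scales)))
  invisible(x)
}

# Separable bilinear resize of a matrix, pixel-center aligned.
bilinear_resize <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  map <- function(n_out, n_in) {
    if (n_in == 1L) rep(1, n_out)
    else pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out + 0.5, 1), n_in)
  }
  xi <- map(out_h, in_h); yi <- map(out_w, in_w)
  tmp <- apply(m, 2, function(col) {
    if (in_h == 1L) rep(col, out_h) else stats::approx(seq_len(in_h), col, xout = xi)$y
  })
  tmp <- matrix(tmp, nrow = out_h)
  out <- t(apply(tmp, 1, function(row) {
    if (in_w == 1L) rep(row, out_w) else stats::approx(seq_len(in_w), row, xout = yi)$y
  }))
  matrix(out, nrow = out_h, ncol = out_w)
}

#' Convert a scalogram to a fixed-size model input image
#'
#' Bilinear resize to `out_shape` followed by per-image min-max
#' normalization to \[0, 1\] (a constant scalogram maps to the zero image).
#'
#' @param sc A [cwt_scalogram()] result or a plain matrix.
#' @param out_shape `c(H, W)` output size.
#' @return `H x W` numeric matrix in \[0, 1\].
#' @export
scalogram_to_image <- function(sc, out_shape = c(32, 32)) {
  m <- if (inherits(sc, "scalogram")) sc$coeffs else sc
  img <- bilinear_resize(m, out_shape[1], out_shape[2])
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(matrix(0, out_shape[1], out_shape[2]))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Compute model input images for a set of beats
#'
#' Applies [cwt_scalogram()] and [scalogram_to_image()] to every row of a
#' beat matrix, caching the cascade wavelet across beats.
#'
#' @param beats An `ipg_beats` object from [extract_beats()] or a numeric
#'   matrix (one beat per row).
#' @param scales CWT scales (defaults to [default_scales()] for the beat
#'   length).
#' @param wavelet Mother wavelet name.
#' @param out_shape Image size `c(H, W)`.
#' @return Array `H x W x n_beats`.
#' @export
beats_to_images <- function(beats, scales = NULL,
                            wavelet = c("db8", "morlet"),
                            out_shape = c(32, 32)) {
  wavelet <- match.arg(wavelet)
  mat <- if (inherits(beats, "ipg_beats")) beats$beats else beats
  if (is.null(scales)) scales <- default_scales(ncol(mat))
  wf <- wavelet_function(wavelet)
  out <- array(0, dim = c(out_shape[1], out_shape[2], nrow(mat)))
  for (i in seq_len(nrow(mat))) {
    sc <- cwt_scalogram(mat[i, ], scales = scales, wavelet = wavelet, wf = wf)
    out[, , i] <- scalogram_to_image(sc, out_shape)
  }
  out
}

#' Write and read a scalogram-image feature set
#'
#' Stores the image stack in `images.rds` (R binary array container) and
#' an index CSV linking each image to its trial and cuff reference.
#'
#' @param images `H x W x N` array from [beats_to_images()].
#' @param meta Beat metadata (`ipg_beats$meta`), one row per image.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_feature_set <- function(images, meta, dir) {
  stopifnot(dim(images)[3] == nrow(meta))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  paths <- file.path(dir, c("feature_index.csv", "images.rds"))
  idx <- cbind(image_index = seq_len(nrow(meta)), meta)
  utils::write.csv(idx, paths[1], row.names = FALSE)
  saveRDS(images, paths[2])
  invisible(paths)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(dir) {
  list(images = readRDS(file.path(dir, "images.rds")),
       index = utils::read.csv(file.path(dir, "feature_index.csv")))
}
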