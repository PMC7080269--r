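#' Butterworth filter specification
#'
#' Describes the zero-phase Butterworth filters used throughout the pipeline:
#' a 6th-order design applied forward and backward (so the net phase is zero
#' and the effective magnitude response is the square of the designed one).
#'
#' @param order Filter order of the designed filter (default 6).
#' @param band Numeric length-2 vector `c(low, high)` in Hz for a bandpass
#'   filter, or a single cutoff in Hz for a lowpass filter.
#' @param type `"pass"` (bandpass) or `"low"` (lowpass).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#'
#' @return A `filter_spec` object.
#' @export
#' @examples
#' filter_spec(band = c(1, 50))          # EEG broadband
#' filter_spec(band = c(0.01, 0.09))     # fNIRS hemodynamic band
filter_spec <- function(order = 6L, band, type = c("pass", "low"),
                        zero_phase = TRUE) {
  type <- match.arg(type)
  stopifnot(is.numeric(band), order >= 1)
  if (type == "pass") {
    if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
      stop("bandpass `band` must be c(low, high) with 0 < low < high")
  } else {
    if (length(band) != 1L || band <= 0)
      stop("lowpass `band` must be a single positive cutoff")
  }
  structure(list(order = as.integer(order), band = band, type = type,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Butterworth %s filter: order %d, band %s Hz, %s\n",
              x$type, x$order, paste(signif(x$band, 4), collapse = "-"),
              if (x$zero_phase) "zero-phase (forward-backward)" else "causal"))
  invisible(x)
}

# Analytic Butterworth design as cascaded second-order sections.
#
# signal::butter() returns a flat transfer-function polynomial; for narrow
# bands at low normalized frequency (the 0.01-0.09 Hz hemodynamic band at
# 10 Hz sampling) the 12th-order polynomial is numerically unstable. Designing
# in zero-pole-gain form and filtering through biquads is stable for every
# band this package uses.
butter_sos <- function(spec, fs) {
  n <- spec$order
  nyq <- fs / 2
  if (any(spec$band >= nyq))
    stop(sprintf("filter band edge (%g Hz) must be below Nyquist (%g Hz)",
                 max(spec$band), nyq))
  # analog lowpass prototype poles on the unit circle (left half-plane)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  warp <- function(f) 2 * fs * tan(pi * f / fs)  # bilinear prewarp
  if (spec$type == "pass") {
    wl <- warp(spec$band[1]); wh <- warp(spec$band[2])
    bw <- wh - wl; w0 <- sqrt(wl * wh)
    # s -> (s^2 + w0^2) / (bw * s): each prototype pole becomes a quadratic pair
    p <- c()
    for (pk in p_lp) {
      disc <- sqrt((pk * bw / 2)^2 - w0^2 + 0i)
      p <- c(p, pk * bw / 2 + disc, pk * bw / 2 - disc)
    }
    z_analog <- rep(0, n)  # n zeros at s = 0 (and n at infinity)
  } else {
    wc <- warp(spec$band[1])
    p <- p_lp * wc
    z_analog <- numeric(0)
  }

  # bilinear transform: s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd_p <- (fs2 + p) / (fs2 - p)
  if (spec$type == "pass") {
    zd_z <- c(rep(1, n), rep(-1, n))    # n zeros at z=1, n at z=-1
    f_ref <- sqrt(prod(spec$band))      # normalize gain at geometric center
  } else {
    zd_z <- rep(-1, n)                  # zeros at infinity map to z=-1
    f_ref <- 0                          # normalize at DC
  }

  # pair conjugate poles into biquads; attach zeros (1, -1) or (-1, -1)
  ord <- order(-abs(zd_p))  # pair high-Q poles first with their conjugates
  zd_p <- zd_p[ord]
  used <- rep(FALSE, length(zd_p))
  sections <- list()
  zi <- 1
  for (i in seq_along(zd_p)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & abs(zd_p - Conj(zd_p[i])) < 1e-8)[1]
    if (is.na(j)) {  # real pole: find another real pole or use alone
      j <- which(!used & abs(Im(zd_p)) < 1e-8)[1]
    }
    if (!is.na(j)) {
      used[j] <- TRUE
      a <- Re(c(1, -(zd_p[i] + zd_p[j]), zd_p[i] * zd_p[j]))
      zz <- zd_z[c(zi, zi + 1)]; zi <- zi + 2
      b <- Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2]))
    } else {
      a <- Re(c(1, -zd_p[i], 0))
      zz <- zd_z[zi]; zi <- zi + 1
      b <- Re(c(1, -zz, 0))
    }
    sections[[length(sections) + 1]] <- list(b = b, a = a)
  }

  # overall gain so that |H| = 1 at the reference frequency
  zref <- exp(1i * 2 * pi * f_ref / fs)
  h <- prod(vapply(sections, function(s) {
    abs(sum(s$b * zref^(0:-2)) / sum(s$a * zref^(0:-2)))
  }, numeric(1)))
  list(sections = sections, gain = 1 / h)
}

# single forward pass through cascaded biquads (direct form II transposed)
sos_filter <- function(x, sos) {
  y <- x
  for (s in sos$sections) {
    b <- s$b; a <- s$a
    y <- biquad_filter(y, b, a)
  }
  y * sos$gain
}

biquad_filter <- function(x, b, a) {
  # numerator (vectorized FIR part), then recursive AR part in C via stats::filter
  n <- length(x)
  v <- b[1] * x
  if (n > 1) v[2:n] <- v[2:n] + b[2] * x[1:(n - 1)]
  if (n > 2) v[3:n] <- v[3:n] + b[3] * x[1:(n - 2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

# zero-phase filtering with reflection padding at the record edges
filtfilt_sos <- function(x, sos, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sos_filter(xp, sos)
  y <- rev(sos_filter(rev(y), sos))
  y[(pad + 1):(pad + n)]
}

# default pad: ~3 time constants of the slowest band edge
default_pad <- function(spec, fs, n) {
  f_slow <- min(spec$band)
  min(n - 1L, as.integer(ceiling(3 * fs / f_slow)))
}

#' Zero-phase Butterworth filtering of a signal
#'
#' Designs the Butterworth filter described by `spec` for sampling rate `fs`
#' and applies it forward and backward (zero net phase shift). The record
#' edges are reflection-padded to suppress filter transients.
#'
#' @param x Numeric vector (one channel) or channels-by-samples matrix.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @return Filtered data with the same shape as `x`.
#' @export
apply_filter <- function(x, spec, fs) {
  sos <- butter_sos(spec, fs)
  if (is.matrix(x)) {
    pad <- default_pad(spec, fs, ncol(x))
    t(apply(x, 1, function(ch) {
      if (spec$zero_phase) filtfilt_sos(ch, sos, pad) else sos_filter(ch, sos)
    }))
  } else {
    pad <- default_pad(spec, fs, length(x))
    if (spec$zero_phase) filtfilt_sos(x, sos, pad) else sos_filter(x, sos)
  }
}
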