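# Zero-phase IIR filtering for multichannel data.
#
# `stats::filter` runs its C loop over every column of a matrix at once, so
# a forward-backward pass over channels-in-columns is far cheaper than
# per-channel calls.  Both the measurement pipeline and the simulator's
# calibration forward model go through this one implementation, so their
# filter behaviour is identical by construction.

# One causal pass of the rational filter b/a along the rows (time) of a
# samples x channels matrix.
filt_ba <- function(flt, x) {
  b <- flt$b
  a <- flt$a
  b <- b / a[1]
  a <- a / a[1]
  x <- as.matrix(x)
  # moving-average part; sides = 1 leaves leading NAs -> prime with zeros
  nb <- length(b)
  if (nb > 1) {
    xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
    z <- stats::filter(xp, b, method = "convolution", sides = 1)
    z <- z[nb:nrow(xp), , drop = FALSE]
  } else {
    z <- x * b
  }
  if (length(a) > 1) {
    z <- stats::filter(z, -a[-1], method = "recursive")
  }
  matrix(as.numeric(z), nrow(x), ncol(x))
}

# Forward-backward (zero-phase) pass; `x` is samples x channels.
filtfilt_mat <- function(flt, x) {
  y <- filt_ba(flt, x)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- filt_ba(flt, y)
  y[rev(seq_len(nrow(y))), , drop = FALSE]
}

# Butterworth design as second-order sections (biquads).  A direct
# transfer-function realisation of an order-4 high-pass with a 0.01 Hz edge
# at fs = 500 has four poles clustered at radius ~0.9999, which amplifies
# input rounding noise by ~1e11; cascaded biquads keep the error near
# machine precision.  Even orders only (Butterworth poles then come in
# conjugate pairs).
butter_sos <- function(order, w, type) {
  if (order %% 2 != 0) stop("even Butterworth orders only")
  wc <- tan(pi * w / 2) # prewarped analog cutoff (bilinear, T = 2)
  k <- seq_len(order / 2)
  theta <- pi * (2 * k + order - 1) / (2 * order) # upper-half-plane poles
  s <- complex(modulus = 1, argument = theta) # analog prototype
  pa <- switch(type, low = wc * s, high = wc / s, stop("unsupported type"))
  z <- (1 + pa) / (1 - pa) # digital poles
  zb <- if (type == "high") c(1, -2, 1) else c(1, 2, 1)
  lapply(z, function(zk) {
    a <- c(1, -2 * Re(zk), Mod(zk)^2)
    # unit gain at the reference frequency: DC for low-pass, Nyquist for high
    g <- if (type == "low") sum(a) / sum(zb) else
      sum(a * c(1, -1, 1)) / sum(zb * c(1, -1, 1))
    list(b = zb * g, a = a)
  })
}

# One causal pass of a section cascade along the rows (time).
sos_pass <- function(sections, x) {
  for (s in sections) x <- filt_ba(s, x)
  x
}

# Zero-phase (forward-backward) section-cascade filtering.
sos_filtfilt <- function(sections, x) {
  x <- as.matrix(x)
  y <- sos_pass(sections, x)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- sos_pass(sections, y)
  y[rev(seq_len(nrow(y))), , drop = FALSE]
}

# Apply the high-pass/low-pass cascade (as from calib_filters()) to a
# samples x channels matrix.
apply_cascade <- function(filters, x) {
  if (!is.null(filters$hp)) x <- sos_filtfilt(filters$hp, x)
  if (!is.null(filters$lp)) x <- sos_filtfilt(filters$lp, x)
  x
}
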