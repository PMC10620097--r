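# Differentiable layer primitives for the toy staged models.
#
# Each layer is a plain list with a `type` field plus parameters. A layer
# supports three operations:
#   layer_forward(layer, x)                      -> list(out, cache)
#   layer_backward(layer, dout, cache, identity_relu) -> dx
#   layer_grad_params(layer, dout, cache)        -> list of parameter gradients
# All gradients are exact (hand-derived adjoints) and are verified against
# central finite differences in the test suite.

layer_forward <- function(layer, x) {
  switch(layer$type,
    normalize = {
      # per-channel (x - mean) / sd, applied inside the differentiable graph
      out <- x
      if (length(dim(x)) == 3L) {
        for (c in seq_len(dim(x)[3])) {
          out[, , c] <- (x[, , c] - layer$mean[c]) / layer$sd[c]
        }
      } else {
        out <- (x - layer$mean[1]) / layer$sd[1]
      }
      list(out = out, cache = NULL)
    },
    conv2d = {
      cols <- im2col(x, layer$kh, layer$kw)
      wmat <- matrix(layer$w, nrow = layer$kh * layer$kw * layer$cin)
      outm <- cols %*% wmat
      outm <- sweep(outm, 2L, layer$b, "+")
      d <- dim(x)
      list(out = array(outm, c(d[1], d[2], layer$cout)),
           cache = list(cols = cols, dim_in = d))
    },
    relu = list(out = pmax(x, 0), cache = x),
    avgpool2 = {
      d <- dim(x)
      io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
      out <- (x[io, jo, , drop = FALSE] + x[io + 1L, jo, , drop = FALSE] +
              x[io, jo + 1L, , drop = FALSE] + x[io + 1L, jo + 1L, , drop = FALSE]) / 4
      list(out = out, cache = d)
    },
    flatten = list(out = as.vector(x), cache = dim(x)),
    as_image = {
      # matrix (e.g. a cochleagram) viewed as a 1-channel image
      list(out = array(x, c(dim(x), 1L)), cache = dim(x))
    },
    dense = {
      xv <- as.vector(x)
      list(out = drop(xv %*% layer$w) + layer$b, cache = xv)
    },
    fir_bank = fir_bank_forward(layer, x),
    stopf("unknown layer type '%s'", layer$type)
  )
}

layer_backward <- function(layer, dout, cache, identity_relu = FALSE) {
  switch(layer$type,
    normalize = {
      dx <- dout
      if (length(dim(dout)) == 3L) {
        for (c in seq_len(dim(dout)[3])) dx[, , c] <- dout[, , c] / layer$sd[c]
      } else {
        dx <- dout / layer$sd[1]
      }
      dx
    },
    conv2d = {
      wmat <- matrix(layer$w, nrow = layer$kh * layer$kw * layer$cin)
      doutm <- matrix(dout, ncol = layer$cout)
      dcols <- doutm %*% t(wmat)
      col2im(dcols, cache$dim_in, layer$kh, layer$kw)
    },
    relu = if (identity_relu) dout else dout * (cache > 0),
    avgpool2 = {
      d <- cache
      dx <- array(0, d)
      io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
      g <- dout / 4
      dx[io, jo, ] <- g; dx[io + 1L, jo, ] <- g
      dx[io, jo + 1L, ] <- g; dx[io + 1L, jo + 1L, ] <- g
      dx
    },
    flatten = array(dout, cache),
    as_image = array(dout, cache),
    dense = drop(layer$w %*% dout),
    fir_bank = fir_bank_backward(layer, dout, cache),
    stopf("unknown layer type '%s'", layer$type)
  )
}

layer_grad_params <- function(layer, dout, cache) {
  switch(layer$type,
    conv2d = {
      doutm <- matrix(dout, ncol = layer$cout)
      dw <- t(cache$cols) %*% doutm
      list(w = array(dw, dim(layer$w)), b = colSums(doutm))
    },
    dense = list(w = outer(cache, dout), b = dout),
    NULL
  )
}

has_params <- function(layer) layer$type %in% c("conv2d", "dense")

# ---- conv utilities ---------------------------------------------------------

# Extract zero-padded kh x kw patches; column order matches the linear order of
# the weight array (row offset fastest, then column offset, then input channel).
im2col <- function(x, kh, kw) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(h + 2L * ph, w + 2L * pw, cin))
  xp[ph + seq_len(h), pw + seq_len(w), ] <- x
  cols <- matrix(0, h * w, kh * kw * cin)
  q <- 0L
  for (c in seq_len(cin)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        q <- q + 1L
        cols[, q] <- xp[di - 1L + seq_len(h), dj - 1L + seq_len(w), c]
      }
    }
  }
  cols
}

col2im <- function(dcols, dim_in, kh, kw) {
  h <- dim_in[1]; w <- dim_in[2]; cin <- dim_in[3]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dxp <- array(0, c(h + 2L * ph, w + 2L * pw, cin))
  q <- 0L
  for (c in seq_len(cin)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        q <- q + 1L
        dxp[di - 1L + seq_len(h), dj - 1L + seq_len(w), c] <-
          dxp[di - 1L + seq_len(h), dj - 1L + seq_len(w), c] + dcols[, q]
      }
    }
  }
  dxp[ph + seq_len(h), pw + seq_len(w), , drop = FALSE]
}

# ---- FIR filterbank front end ----------------------------------------------

# Centered same-length FIR convolution (odd filter length); its adjoint is
# convolution with the time-reversed filter, which backprop relies on.
fir_same <- function(x, h) {
  n <- length(x); l <- length(h)
  full <- stats::convolve(x, rev(h), type = "open")
  half <- (l - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}

# Centered moving average of odd width (self-adjoint under zero padding).
moving_average <- function(x, width) {
  fir_same(x, rep(1 / width, width))
}

fir_bank_forward <- function(layer, x) {
  n <- length(x)
  k <- ncol(layer$filters)
  dec <- layer$decimation
  nd <- n %/% dec
  out <- matrix(0, nd, k)
  bands <- matrix(0, n, k)
  envs <- matrix(0, nd, k)
  for (j in seq_len(k)) {
    band <- fir_same(x, layer$filters[, j])
    env <- moving_average(abs(band), layer$env_width)
    envd <- colMeans(matrix(env[seq_len(nd * dec)], nrow = dec))
    bands[, j] <- band
    envs[, j] <- envd
    out[, j] <- ifelse(envd > 0, envd^layer$compression, 0)
  }
  list(out = out, cache = list(bands = bands, envs = envs, n = n))
}

fir_bank_backward <- function(layer, dout, cache) {
  n <- cache$n
  dec <- layer$decimation
  nd <- nrow(dout)
  p <- layer$compression
  dx <- numeric(n)
  for (j in seq_len(ncol(dout))) {
    envd <- cache$envs[, j]
    # clamp the power-law derivative near zero to keep gradients finite
    denvd <- dout[, j] * p * pmax(envd, layer$eps)^(p - 1)
    denv <- numeric(n)
    denv[seq_len(nd * dec)] <- rep(denvd / dec, each = dec)
    dabs <- moving_average(denv, layer$env_width)
    dband <- dabs * sign(cache$bands[, j])
    dx <- dx + fir_same(dband, rev(layer$filters[, j]))
  }
  dx
}

# Windowed-sinc bandpass filters on a log-spaced grid of center frequencies.
design_filterbank <- function(n_channels, sample_rate, filter_length = 101L,
                              f_lo = 60, f_hi = 0.4 * sample_rate) {
  stopifnot(filter_length %% 2L == 1L)
  centers <- exp(seq(log(f_lo * 1.3), log(f_hi / 1.3), length.out = n_channels))
  # proportional bandwidth with a floor keeping low channels resolvable by a
  # filter_length-tap FIR
  half_bw <- pmax(0.18 * centers, 40)
  m <- filter_length
  t <- seq_len(m) - (m + 1) / 2
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  filters <- matrix(0, m, n_channels)
  for (j in seq_len(n_channels)) {
    fl <- max(centers[j] - half_bw[j], 1) / sample_rate
    fh <- min(centers[j] + half_bw[j], sample_rate / 2 - 1) / sample_rate
    lp <- function(fc) {
      h <- 2 * fc * sinc(2 * fc * t)
      h
    }
    h <- (lp(fh) - lp(fl)) * win
    # unit gain at the channel's center frequency
    gain <- Mod(sum(h * exp(-2i * pi * centers[j] / sample_rate * t)))
    filters[, j] <- h / gain
  }
  list(filters = filters, centers = centers)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
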