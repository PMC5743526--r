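# Internal FFT plumbing. Convention: DC at the corner (unshifted layout)
# everywhere inside the package; centred views only at I/O boundaries.

fft3 <- function(x) stats::fft(x)

ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Frequencies in cycles/sample for an n-point DFT, unshifted layout.
fft_freq <- function(n) {
  i <- 0:(n - 1)
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i / n
}

# Three full-grid frequency arrays (cycles/sample per axis), unshifted.
freq_grids <- function(shape) {
  f1 <- fft_freq(shape[1])
  f2 <- fft_freq(shape[2])
  f3 <- fft_freq(shape[3])
  list(
    array(f1, shape),
    array(rep(f2, each = shape[1]), shape),
    array(rep(f3, each = shape[1] * shape[2]), shape)
  )
}

# Block-average downsampling by an integer factor along every axis.
block_mean <- function(a, factor) {
  d <- dim(a)
  if (any(d %% factor != 0)) {
    stop("array dimensions must be divisible by the shrink factor")
  }
  dn <- d %/% factor
  dim(a) <- c(factor, dn[1], factor, dn[2], factor, dn[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(dn))
  array(colMeans(a), dn)
}

# Shift an array by (dx, dy, dz) voxels, zero-filling the exposed boundary:
# out[i] = x[i - d] where defined, 0 otherwise.
shift3 <- function(x, dx, dy, dz) {
  d <- dim(x)
  out <- array(0, d)
  src <- function(n, s) max(1, 1 - s):min(n, n - s)
  dst <- function(n, s) max(1, 1 + s):min(n, n + s)
  out[dst(d[1], dx), dst(d[2], dy), dst(d[3], dz)] <-
    x[src(d[1], dx), src(d[2], dy), src(d[3], dz)]
  out
}
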