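# Zero-phase IIR filtering with steady-state initial conditions and odd
# reflection padding, so constant inputs filter to their exact steady state
# (no edge transients). Needed because the slow-time ensembles are short.

lfilter_zi <- function(b, a) {
  la <- length(a); lb <- length(b)
  m <- max(la, lb) - 1
  b <- c(b, rep(0, m + 1 - lb)) / a[1]
  a <- c(a, rep(0, m + 1 - la)) / a[1]
  if (m == 0) return(numeric(0))
  # companion matrix of a, transposed
  A <- matrix(0, m, m)
  A[1, ] <- -a[-1]
  if (m > 1) A[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(A), B)
}

filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  m <- max(length(a), length(b))
  padlen <- min(3 * m, n - 1)
  if (padlen < 1) return(x)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .cpp_iir(b / a[1], a / a[1], ext, zi * ext[1])
  y <- rev(y)
  y <- .cpp_iir(b / a[1], a / a[1], y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

# complex-capable wrapper
zerophase_filter <- function(b, a, x) {
  if (is.complex(x))
    filtfilt_ss(b, a, Re(x)) + 1i * filtfilt_ss(b, a, Im(x))
  else filtfilt_ss(b, a, x)
}
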