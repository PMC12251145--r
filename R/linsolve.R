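# Exact propagation of constant-coefficient linear label systems forced by
# the piecewise-exponential body-water availability S(t).
#
# Every label system in the package has the form
#     x'(t) = M x(t) + v * S(t - shift),    x(0) = 0,
# where S(t) = a_j + b_j exp(-delta (t - tau_j)) on segment j (and 0 for
# t < 0). Augmenting the state with the segment exponential u = exp(-delta
# (t - tau_j)) (u' = -delta u, reset to 1 at each segment start) and a
# constant gives an autonomous linear system whose flow is a matrix
# exponential; the solution is therefore exact up to expm() accuracy, with
# no step-size or stiffness considerations. deSolve integration of the same
# systems is used as an independent oracle in the test suite.

# times: non-negative, any order. Returns a matrix length(times) x nrow(M).
piecewise_exp_solve <- function(M, v, saliva, times, shift = 0) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), length(v) == nrow(M))
  if (any(times < 0)) rlang::abort("times must be non-negative")
  ph <- saliva_phases(saliva)
  starts <- ph$start + shift
  a <- ph$a; b <- ph$b
  if (shift > 0) {           # no inflow before the delayed forcing arrives
    starts <- c(0, starts)
    a <- c(0, a); b <- c(0, b)
  }
  n <- nrow(M)
  ord <- order(times)
  ts <- times[ord]
  out <- matrix(0, length(times), n)
  x <- rep(0, n)
  i <- 1
  for (j in seq_along(starts)) {
    t0 <- starts[j]
    t1 <- if (j < length(starts)) starts[j + 1] else Inf
    A <- rbind(
      cbind(M, v * b[j], v * a[j]),
      c(rep(0, n), -ph$delta, 0),
      rep(0, n + 2)
    )
    x_aug <- c(x, 1, 1)
    while (i <= length(ts) && ts[i] <= t1) {
      if (ts[i] <= t0) {
        out[ord[i], ] <- x      # times at/before segment start (incl. t = 0)
      } else {
        sol <- as.numeric(Matrix::expm(A * (ts[i] - t0)) %*% x_aug)
        out[ord[i], ] <- sol[seq_len(n)]
      }
      i <- i + 1
    }
    if (is.finite(t1)) {
      x <- as.numeric(Matrix::expm(A * (t1 - t0)) %*% x_aug)[seq_len(n)]
    }
  }
  out
}
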