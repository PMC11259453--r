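# Layer primitives and the Adamax optimizer used by the FDU-net.  All
# volumetric tensors are column-major arrays [nx, ny, nz, C, N]; the C++
# kernels in src/ do the convolution heavy lifting.

relu_fw <- function(x) { x[x < 0] <- 0; x }
relu_bw <- function(dy, y) { dy[y <= 0] <- 0; dy }
tanh_bw <- function(dy, y) dy * (1 - y^2)

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv3 <- function(cin, cout) {
  list(w = glorot(27 * cin, 27 * cout, c(3, 3, 3, cin, cout)),
       b = numeric(cout))
}
init_convtrans <- function(cin, cout) {
  list(w = glorot(8 * cin, 8 * cout, c(2, 2, 2, cin, cout)),
       b = numeric(cout))
}
init_dense <- function(din, dout) {
  list(w = glorot(din, dout, c(din, dout)), b = numeric(dout))
}

# inverted dropout mask with the same shape as x
dropout_mask <- function(x, rate) {
  if (rate <= 0) return(NULL)
  array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(first = x[, , , seq_len(n_first), , drop = FALSE],
       second = x[, , , n_first + seq_len(d[4] - n_first), , drop = FALSE])
}

# Adamax: infinity-norm variant of Adam
adamax_init <- function(params) {
  if (is.list(params)) return(lapply(params, adamax_init))
  list(m = params * 0, u = params * 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamax_step <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    u <- pmax(beta2 * s$u, abs(g))
    p_new <- p - (lr / (1 - beta1^t)) * m / (u + eps)
    list(p = p_new, s = list(m = m, u = u))
  }
  walk(params, grads, state)
}
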