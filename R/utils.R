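# internal helpers

stopf <- function(fmt, ..., class = "cerebropwv_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) rlang::warn(sprintf(fmt, ...))

# population standard deviation (divisor n)
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

vec3 <- function(x, name = "voxel_size") {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("`%s` must be a positive numeric scalar or 3-vector", name)
  as.numeric(x)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}

# orthonormal in-plane basis completing a unit direction vector; deterministic
plane_basis <- function(direction) {
  d <- unit(direction)
  ref <- diag(3L)[, which.min(abs(d))]
  e1 <- unit(cross3(d, ref))
  e2 <- cross3(d, e1)
  list(e1 = e1, e2 = e2)
}

# uniform frame times starting at 0: t_j = (j-1) * T / M
frame_times_uniform <- function(M, period) (seq_len(M) - 1) * period / M

# infer the cardiac period from frame times (uniform spacing assumed:
# T = M * spacing); used when no explicit period is supplied
infer_period <- function(frame_times) {
  M <- length(frame_times)
  if (M < 2L) stopf("need at least 2 frame times")
  dt <- diff(frame_times)
  if (any(dt <= 0)) stopf("`frame_times` must be strictly increasing")
  M * mean(dt)
}
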