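# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up, deterministic across platforms (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# shift a logical matrix by (dx, dy), padding with `fill`
shift_mat <- function(m, dx, dy, fill = FALSE) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- seq_len(nx) + dx
  ys <- seq_len(ny) + dy
  okx <- xs >= 1L & xs <= nx
  oky <- ys >= 1L & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# derive a per-task integer seed from a base seed, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}
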