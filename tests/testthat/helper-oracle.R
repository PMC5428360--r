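# Sequential quality-guided phase unwrapper: an independent (slow, path-based)
# oracle for the vectorized DLPU. Region growing from the highest-quality
# pixel; each new pixel is unwrapped against an already-visited neighbour.

wrap_to_pi <- function(x) pi - ((pi - x) %% (2 * pi))

quality_guided_unwrap <- function(w) {
  n1 <- nrow(w); n2 <- ncol(w); n <- n1 * n2
  shift_edge <- function(m, dr, dc) {
    m[pmin(pmax(row(m) + dr, 1), n1) + (pmin(pmax(col(m) + dc, 1), n2) - 1) * n1]
  }
  q <- -(wrap_to_pi(w - shift_edge(w, 0, -1))^2 +
         wrap_to_pi(w - shift_edge(w, 0, 1))^2 +
         wrap_to_pi(w - shift_edge(w, -1, 0))^2 +
         wrap_to_pi(w - shift_edge(w, 1, 0))^2)
  dim(q) <- c(n1, n2)

  out <- matrix(NA_real_, n1, n2)
  visited <- rep(FALSE, n)
  frontier_q <- rep(-Inf, n)
  neighbours <- function(i) {
    r <- (i - 1) %% n1 + 1; cc <- (i - 1) %/% n1 + 1
    c(if (r > 1) i - 1, if (r < n1) i + 1,
      if (cc > 1) i - n1, if (cc < n2) i + n1)
  }
  start <- which.max(q)
  out[start] <- w[start]
  visited[start] <- TRUE
  nb <- neighbours(start)
  frontier_q[nb] <- q[nb]
  for (step in seq_len(n - 1)) {
    i <- which.max(frontier_q)
    nb <- neighbours(i)
    ref <- nb[visited[nb]][1]
    out[i] <- out[ref] + wrap_to_pi(w[i] - w[ref])
    visited[i] <- TRUE
    frontier_q[i] <- -Inf
    new_nb <- nb[!visited[nb]]
    frontier_q[new_nb] <- q[new_nb]
  }
  out
}

# smooth random band-limited phase field (periodic), peak-to-valley ~ p2v rad
random_smooth_phase <- function(n, p2v, seed, modes = 3) {
  set.seed(seed)
  f <- matrix(0 + 0i, n, n)
  for (i in seq_len(modes)) {
    kx <- sample(-3:3, 1); ky <- sample(-3:3, 1)
    a <- complex(real = rnorm(1), imaginary = rnorm(1))
    f[(ky %% n) + 1, (kx %% n) + 1] <- f[(ky %% n) + 1, (kx %% n) + 1] + a
    f[((-ky) %% n) + 1, ((-kx) %% n) + 1] <-
      f[((-ky) %% n) + 1, ((-kx) %% n) + 1] + Conj(a)
  }
  v <- Re(stats::fft(f, inverse = TRUE))
  v <- v - mean(v)
  v * (p2v / diff(range(v)))
}

centered_gaussian <- function(n, p2v, width_frac = 0.15) {
  cc <- seq_len(n) - (n + 1) / 2
  g <- exp(-outer(cc^2, cc^2, "+") / (2 * (width_frac * n)^2))
  g * p2v
}
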