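# Shared fixture builders for the test suite (all generated in code).

regular_polygon_loop <- function(n, radius = 1, kappa = 0.01, ...) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cortex_loop(cbind(radius * cos(ang), radius * sin(ang)), kappa = kappa,
              ...)
}

open_rod <- function(n = 21, length = 10, x = 0, kappa = 0.01,
                     cell_id = 1L) {
  y <- seq(0, length, length.out = n)
  cortex_loop(cbind(x, y), cell_id = cell_id, kappa = kappa,
              closed = FALSE, check = FALSE)
}

# small random wiggly closed loop for gradient checks
random_loop <- function(n = 6, seed = 1, kappa = 0.3) {
  set.seed(seed)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  xy <- cbind(cos(ang), sin(ang)) + matrix(rnorm(2 * n, 0, 0.05), n)
  lp <- cortex_loop(xy, kappa = kappa, check = FALSE)
  lp$gamma[] <- runif(length(lp$gamma), 0.92, 1)
  lp
}

fd_gradient <- function(loop, h = 1e-7) {
  n <- nrow(loop$xy)
  g <- matrix(0, n, 2)
  for (i in seq_len(n)) for (k in 1:2) {
    lp <- loop; lp$xy[i, k] <- lp$xy[i, k] + h
    lm <- loop; lm$xy[i, k] <- lm$xy[i, k] - h
    g[i, k] <- (elastic_energy(lp) - elastic_energy(lm)) / (2 * h)
  }
  g
}

# two parallel open rods coupled by adhesions (friction fixtures)
two_rod_tissue <- function(gap = 1, n = 25, spacing = 0.5, ...) {
  y <- seq(0, (n - 1) * spacing, by = spacing)
  r1 <- cortex_loop(cbind(0, y), cell_id = 1L, closed = FALSE,
                    check = FALSE)
  r2 <- cortex_loop(cbind(gap, y), cell_id = 2L, closed = FALSE,
                    check = FALSE)
  acam_tissue(list(r1, r2), params = list(...))
}

# cached standard T1 runs shared across acceptance tests (computed once)
t1_cache <- new.env(parent = emptyenv())
cached_t1 <- function(key, fun) {
  if (is.null(t1_cache[[key]])) t1_cache[[key]] <- fun()
  t1_cache[[key]]
}
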