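# Shared fixtures, computed lazily once per test session.  All stimuli are
# generated in code; the recurrent runs here use reduced problem sizes
# (64 x 64 images, 4 pyramid levels, 6 iterations) except where a check is
# explicitly about the full-scale fixture.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

square64 <- function() fixture("square64", function() {
  make_square_stimulus(64, 24, polarity = "light-on-dark")
})

square64_run <- function() fixture("square64_run", function() {
  fg_run(square64(), n_iterations = 6, n_levels = 4)
})

square64_dark_run <- function() fixture("square64_dark_run", function() {
  fg_run(make_square_stimulus(64, 24, polarity = "dark-on-light"),
         n_iterations = 6, n_levels = 4)
})

square128_run <- function() fixture("square128_run", function() {
  st <- make_square_stimulus(128, 32, polarity = "light-on-dark")
  t0 <- Sys.time()
  res <- fg_run(st, n_iterations = 10, n_levels = 5)
  attr(res, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
})

# Tiny deterministic S volume for direct recurrent-core checks: one channel,
# small image, few levels.
tiny_edge_volume <- function(n = 33, n_levels = 2) {
  px <- matrix(0.25, n, n)
  px[12:22, 12:22] <- 0.75
  edge_volume(px, n_levels = n_levels)
}

# Brute-force cross-correlation oracle (direct double loop, zero padding).
xcorr2_naive <- function(A, K, center = NULL) {
  na <- dim(A); nk <- dim(K)
  if (is.null(center)) center <- (nk + 1L) %/% 2L
  out <- matrix(0, na[1], na[2])
  for (x in seq_len(na[1])) for (y in seq_len(na[2])) {
    acc <- 0
    for (i in seq_len(nk[1])) for (j in seq_len(nk[2])) {
      r <- x + i - center[1]; c <- y + j - center[2]
      if (r >= 1 && r <= na[1] && c >= 1 && c <= na[2])
        acc <- acc + K[i, j] * A[r, c]
    }
    out[x, y] <- acc
  }
  out
}
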