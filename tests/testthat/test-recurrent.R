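# Direct checks of the recurrent core operations on small volumes.

make_b_volume <- function(levels) structure(list(levels = levels), class = "b_volume")

test_that("feedforward grouping of an impulse reproduces the translated kernel", {
  n <- 21
  kb <- kernel_bank(c(n, n), n_levels = 1, support_radius = 8)
  b <- array(0, c(n, n, 16, 2))
  b[11, 11, 3, 1] <- 1    # single light-polarity impulse, one directed channel
  G <- feedforward_grouping(make_b_volume(list(b)), kb, first_iteration = TRUE)
  expected <- xcorr2_naive(b[, , 3, 1], kb$levels[[1]]$kernels[[3]])
  expect_equal(G$levels[[1]][, , 1], pmax(expected, 0), tolerance = 1e-9)
  expect_equal(G$levels[[1]][, , 2], matrix(0, n, n))
})

test_that("feedforward grouping: zero input and exact opponent cancellation", {
  n <- 17
  kb <- kernel_bank(c(n, n), n_levels = 1, support_radius = 6)
  zero <- array(0, c(n, n, 16, 2))
  G0 <- feedforward_grouping(make_b_volume(list(zero)), kb)
  expect_equal(max(abs(G0$levels[[1]])), 0)

  # B_theta = B_theta+pi everywhere cancels exactly before rectification
  b <- array(0, c(n, n, 16, 2))
  set.seed(2)
  m <- matrix(runif(n * n), n, n)
  b[, , 4, 1] <- m; b[, , 12, 1] <- m
  G <- feedforward_grouping(make_b_volume(list(b)), kb, first_iteration = FALSE)
  expect_lt(max(abs(G$levels[[1]][, , 1])), 1e-10)
})

test_that("winner-take-all keeps the strict winner and zeroes ties", {
  g <- array(0, c(1, 3, 2))
  g[1, , 1] <- c(0.5, 0.3, 0.4)
  g[1, , 2] <- c(0.3, 0.5, 0.4)
  out <- winner_take_all(structure(list(levels = list(g)),
                                   class = "grouping_pyramid"))$levels[[1]]
  expect_equal(out[1, , 1], c(0.5, 0, 0))
  expect_equal(out[1, , 2], c(0, 0.5, 0))
})

test_that("zero grouping feedback returns B = S exactly (logistic at 0)", {
  S <- tiny_edge_volume(n = 33, n_levels = 2)
  kb <- kernel_bank(c(33, 33), n_levels = 2, support_radius = 10)
  Gz <- structure(list(levels = lapply(S$levels, function(s)
    array(0, c(dim(s)[1], dim(s)[2], 2)))), class = "grouping_pyramid")
  B <- feedback_modulation(S, Gz, kb)
  for (k in 1:2) for (d in 1:16) {
    expect_equal(B$levels[[k]][, , d, ],
                 S$levels[[k]][, , ((d - 1) %% 8) + 1, ],
                 tolerance = 1e-12)
  }
})

test_that("feedback saturation respects the [0, 2S] bound", {
  S <- tiny_edge_volume(n = 33, n_levels = 1)
  kb <- kernel_bank(c(33, 33), n_levels = 1, support_radius = 10)
  # enormous one-sided grouping activity drives the logistic to saturation
  Gbig <- structure(list(levels = list(array(c(1e6, 0), c(33, 33, 2)))),
                    class = "grouping_pyramid")
  Gbig$levels[[1]][, , 1] <- 1e6
  Gbig$levels[[1]][, , 2] <- 0
  B <- feedback_modulation(S, Gbig, kb)
  s_rep <- S$levels[[1]][, , rep(1:8, 2), ]
  expect_true(all(B$levels[[1]] >= 0))
  expect_true(all(B$levels[[1]] <= 2 * s_rep + 1e-9))
  # light-polarity cells with input are driven to (nearly) 2S
  sel <- S$levels[[1]][, , 1, 1] > 0
  expect_equal(B$levels[[1]][, , 1, 1][sel],
               2 * S$levels[[1]][, , 1, 1][sel], tolerance = 1e-6)
})

test_that("blank input stays silent through the full recurrence", {
  S <- edge_volume(matrix(0.5, 32, 32), n_levels = 3)
  res <- run_recurrence(S, n_iterations = 3, keep_trace = FALSE)
  expect_equal(max(abs(res$B$levels[[1]])), 0)
  expect_equal(max(abs(res$G$levels[[1]])), 0)
})

test_that("B stays within [0, 2S] at every iteration of a square run", {
  res <- square64_run()
  tr <- res$recurrence$intensity$trace
  expect_true(all(tr$max_b_over_2s <= 1 + 1e-12))
})

test_that("polarity exchange symmetry: inverted stimulus swaps L and D exactly", {
  r1 <- square64_run()
  r2 <- square64_dark_run()
  B1 <- r1$recurrence$intensity$B$levels[[1]]
  B2 <- r2$recurrence$intensity$B$levels[[1]]
  expect_equal(B1[, , , 1], B2[, , , 2], tolerance = 1e-9)
  expect_equal(B1[, , , 2], B2[, , , 1], tolerance = 1e-9)
  G1 <- r1$recurrence$intensity$G$levels[[1]]
  G2 <- r2$recurrence$intensity$G$levels[[1]]
  expect_equal(G1[, , 1], G2[, , 2], tolerance = 1e-9)
})

test_that("winner-take-all exclusivity holds in the final grouping pyramid", {
  res <- square64_run()
  for (g in res$recurrence$intensity$G$levels) {
    expect_true(all(g >= 0))
    expect_equal(max(abs(g[, , 1] * g[, , 2])), 0)
  }
})

test_that("square stimulus: decoded BOS points into the square and stabilizes", {
  res <- square64_run()
  expect_true(all(res$scene_bos$bos > 0))
  stab <- bos_sign_stabilization(res)
  expect_lte(stab$iteration, 3)
})

test_that("early stopping honors the convergence tolerance", {
  S <- edge_volume(matrix(0.5, 32, 32), n_levels = 2)  # blank: converges at once
  res <- run_recurrence(S, n_iterations = 8, convergence_tol = 1e-6)
  expect_lt(res$n_iterations_run, 8)
  last <- res$trace$max_delta_bos[res$n_iterations_run]
  expect_lt(last, 1e-6)
})
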