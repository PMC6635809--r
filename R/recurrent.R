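# The recurrent border ownership core: feedforward grouping, light/dark
# winner-take-all, cross-scale modulatory feedback, and the iteration loop.
#
# Representations (internal):
#   S volume: list over pyramid levels of arrays [row, col, orientation, polarity]
#             (8 undirected orientations; polarity 1 = L, 2 = D)
#   B volume: list over levels of arrays [row, col, directed channel, polarity]
#             (16 directed channels, channel d has border orientation
#              (d-1)*pi/8; d and d+8 form an opponent pair)
#   G pyramid: list over levels of arrays [row, col, polarity]

new_edge_volume <- function(levels) structure(list(levels = levels), class = "edge_volume")

#' Build an S-cell volume from a channel raster
#'
#' Runs the oriented edge front end at full resolution, then propagates the
#' signed orientation responses down an anti-aliased pyramid (the image is
#' edge filtered first and the edge signals are downsampled), applying the
#' winner-orientation rule and the contrast-polarity split independently at
#' each level.
#'
#' @param channel numeric matrix (one feature channel).
#' @param n_levels,factor pyramid geometry.
#' @param bank oriented filter bank (see [gabor_bank()]); default bank if NULL.
#' @param n_orientations number of undirected orientations.
#' @return An `edge_volume`: list with element `levels`, arrays
#'   `row x col x n_orientations x 2` per pyramid level.
#' @export
edge_volume <- function(channel, n_levels = 5L, factor = 2, bank = NULL,
                        n_orientations = 8L) {
  if (is.null(bank)) bank <- gabor_bank(n_orientations)
  signed0 <- oriented_responses(channel, bank)
  pyrs <- lapply(seq_len(dim(signed0)[3]), function(i)
    build_pyramid(signed0[, , i], n_levels = n_levels, factor = factor))
  levels <- lapply(seq_len(n_levels), function(k) {
    d <- dim(pyrs[[1]]$levels[[k]])
    signed <- array(0, c(d[1], d[2], length(bank)))
    for (i in seq_along(bank)) signed[, , i] <- pyrs[[i]]$levels[[k]]
    split_polarity(winner_orientation(signed))
  })
  new_edge_volume(levels)
}

# Initial B volume: both members of each opponent pair start numerically
# identical, equal to their shared bottom-up S input.
init_b_volume <- function(S) {
  n_or <- dim(S$levels[[1]])[3]
  levels <- lapply(S$levels, function(s) {
    d <- dim(s)
    b <- array(0, c(d[1], d[2], 2L * n_or, 2L))
    for (dd in seq_len(2L * n_or)) b[, , dd, ] <- s[, , undirected_index(dd, n_or), ]
    b
  })
  structure(list(levels = levels), class = "b_volume")
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Feedforward grouping: B cells to G cells
#'
#' Per pyramid level and contrast polarity, grouping activity is the
#' half-wave-rectified sum over directed channels of the opponent B-cell
#' difference correlated with the matching grouping kernel:
#' `G = max(0, sum_theta (B_theta - B_theta+pi) * v_theta)` (correlation, no
#' kernel flip).  On the first model iteration the two members of every
#' opponent pair are numerically identical, so the inhibitory term is
#' dropped and only the preferred B cells drive G.
#'
#' @param B a `b_volume` (list of `row x col x 16 x 2` arrays per level).
#' @param bank a [kernel_bank()] matching the volume's level shapes.
#' @param first_iteration drop the opponent-inhibition term?
#' @return List of class `grouping_pyramid`: per level, arrays
#'   `row x col x 2` (polarity L, D), non-negative.
#' @export
feedforward_grouping <- function(B, bank, first_iteration = FALSE) {
  n_or <- bank$n_orientations
  nd <- 2L * n_or
  levels <- lapply(seq_along(B$levels), function(k) {
    b <- B$levels[[k]]
    lv <- bank$levels[[k]]
    if (!all(dim(b)[1:2] == lv$plan$img_dim))
      abort("B volume and kernel bank have mismatched level shapes.")
    g <- array(0, c(dim(b)[1], dim(b)[2], 2))
    for (P in 1:2) {
      acc <- matrix(0 + 0i, lv$plan$p[1], lv$plan$p[2])
      if (first_iteration) {
        for (d in seq_len(nd))
          acc <- acc + plan_fft_image(lv$plan, b[, , d, P]) * lv$fk[[d]]
      } else {
        for (d in seq_len(n_or)) {
          M <- b[, , d, P] - b[, , d + n_or, P]
          acc <- acc + plan_fft_image(lv$plan, M) * (lv$fk[[d]] - lv$fk[[d + n_or]])
        }
      }
      g[, , P] <- pmax(plan_ifft(lv$plan, acc), 0)
    }
    g
  })
  structure(list(levels = levels), class = "grouping_pyramid")
}

#' Light/dark winner-take-all between grouping pyramids
#'
#' At each location and level only one polarity of grouping activity may
#' survive: the strictly larger of `G_L` and `G_D` is kept, the other is
#' zeroed, and exact ties zero both (both strict inequalities fail).
#'
#' @param G a `grouping_pyramid`.
#' @return A `grouping_pyramid` with `G_L * G_D = 0` everywhere.
#' @export
winner_take_all <- function(G) {
  levels <- lapply(G$levels, function(g) {
    gl <- g[, , 1]; gd <- g[, , 2]
    out <- array(0, dim(g))
    out[, , 1] <- ifelse(gl > gd, gl, 0)
    out[, , 2] <- ifelse(gd > gl, gd, 0)
    out
  })
  structure(list(levels = levels), class = "grouping_pyramid")
}

#' Modulatory feedback: G cells to B cells
#'
#' Each B cell's activity is its bottom-up S input gated by a logistic of the
#' cross-scale feedback drive: facilitation by same-polarity grouping
#' activity on its preferred side (through the opponent kernel
#' `v_theta+pi`) minus suppression by opposite-polarity grouping activity on
#' its non-preferred side (through `v_theta`).  Contributions from coarser
#' levels `j >= k` are correlated at level `j`, upsampled to level `k`, and
#' summed with weight `2^-(j-k)`:
#'
#' `B_theta,L^k = 2 S_theta,L^k * logistic( sum_j 2^-(j-k) up_j->k[
#'    v_theta+pi * G_L^j - v_theta * G_D^j ] )`
#'
#' (and with L and D exchanged for dark-polarity B cells).  Activity is
#' therefore bounded between 0 and twice the bottom-up input.
#'
#' @param S an `edge_volume`.
#' @param G a `grouping_pyramid` (all levels present).
#' @param bank a [kernel_bank()].
#' @return A `b_volume`.
#' @export
feedback_modulation <- function(S, G, bank) {
  n_or <- bank$n_orientations
  nd <- 2L * n_or
  n_levels <- length(S$levels)
  if (length(G$levels) != n_levels) abort("G must be available at all levels.")
  factor <- bank$factor
  base_dim <- dim(S$levels[[1]])[1:2]

  # Per level j: H[[j]][[d]] = v_{d+pi} * G_L^j - v_d * G_D^j  (the feedback
  # integrand for light-polarity channel d).  The dark-polarity integrand is
  # its opponent negation: H_D[d] = -H[[j]][[opponent(d)]].
  H <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    lv <- bank$levels[[j]]
    fgl <- plan_fft_image(lv$plan, G$levels[[j]][, , 1])
    fgd <- plan_fft_image(lv$plan, G$levels[[j]][, , 2])
    H[[j]] <- lapply(seq_len(nd), function(d) {
      plan_ifft(lv$plan, fgl * lv$fk[[opponent_index(d, n_or)]] - fgd * lv$fk[[d]])
    })
  }

  levels <- lapply(seq_len(n_levels), function(k) {
    s <- S$levels[[k]]
    dk <- dim(s)[1:2]
    # Cross-scale feedback drive for every light-polarity channel at level k.
    U <- lapply(seq_len(nd), function(d) {
      A <- matrix(0, dk[1], dk[2])
      for (j in k:n_levels) {
        A <- A + 2^(-(j - k)) *
          upsample_to(H[[j]][[d]], j - 1L, k - 1L, base_dim, factor)
      }
      A
    })
    b <- array(0, c(dk[1], dk[2], nd, 2))
    for (d in seq_len(nd)) {
      su <- s[, , undirected_index(d, n_or), ]
      b[, , d, 1] <- 2 * su[, , 1] * logistic(U[[d]])
      # dark polarity: the integrand is the opponent negation of the light one
      b[, , d, 2] <- 2 * su[, , 2] * logistic(-U[[opponent_index(d, n_or)]])
    }
    b
  })
  structure(list(levels = levels), class = "b_volume")
}

#' Run the recurrent B/G loop
#'
#' Initializes every opponent B-cell pair to its shared bottom-up S input,
#' then alternates one feedforward pass (B to G, with the first-iteration
#' preferred-only rule), light/dark winner-take-all, and one feedback pass
#' (G to B) per iteration.  The per-iteration trace records the decoded
#' finest-level BOS field, for timing analyses in which one full pass is
#' mapped to roughly 10 ms of cortical latency.
#'
#' @param S an `edge_volume` (see [edge_volume()]).
#' @param bank optional [kernel_bank()]; built to match `S` when `NULL`.
#' @param n_iterations number of feedforward/feedback iterations (>= 1).
#' @param convergence_tol optional early-stopping tolerance on the maximum
#'   absolute change of the decoded BOS vector components between
#'   iterations.
#' @param keep_trace record the per-iteration decoded field? (slightly
#'   faster when `FALSE`).
#' @return List of class `recurrence_result`: final `B` (`b_volume`), `G`
#'   (`grouping_pyramid`), `trace` (tibble with `iteration`, `max_delta_b`,
#'   `max_delta_bos`, and `max_b_over_2s`, the largest ratio of B activity
#'   to twice its bottom-up input), `fields` (per-iteration decoded
#'   `fg_field`s when `keep_trace`), `n_iterations_run`.
#' @export
run_recurrence <- function(S, bank = NULL, n_iterations = 10L,
                           convergence_tol = NULL, keep_trace = TRUE) {
  stopifnot(n_iterations >= 1)
  base_dim <- dim(S$levels[[1]])[1:2]
  n_or <- dim(S$levels[[1]])[3]
  if (is.null(bank))
    bank <- kernel_bank(base_dim, n_levels = length(S$levels),
                        n_orientations = n_or)
  B <- init_b_volume(S)
  prev_field <- NULL
  fields <- list()
  tr_it <- integer(0); tr_db <- numeric(0); tr_dbos <- numeric(0)
  tr_ratio <- numeric(0)
  n_run <- 0L
  for (it in seq_len(n_iterations)) {
    G <- winner_take_all(feedforward_grouping(B, bank, first_iteration = (it == 1L)))
    Bnew <- feedback_modulation(S, G, bank)
    max_db <- max(vapply(seq_along(B$levels), function(k)
      max(abs(Bnew$levels[[k]] - B$levels[[k]])), numeric(1)))
    # largest B/(2S) across all cells this iteration (logistic gating keeps
    # this <= 1 exactly; recorded so the bound can be audited per iteration)
    max_ratio <- max(vapply(seq_along(B$levels), function(k) {
      s <- S$levels[[k]]; b <- Bnew$levels[[k]]
      n_or_k <- dim(s)[3]
      mx <- 0
      for (d in seq_len(dim(b)[3])) {
        su <- s[, , undirected_index(d, n_or_k), ]
        sel <- su > 0
        if (any(sel)) mx <- max(mx, max(b[, , d, ][sel] / (2 * su[sel])))
      }
      mx
    }, numeric(1)))
    field <- population_vector(combine_polarity(Bnew$levels[[1]]))
    max_dbos <- if (is.null(prev_field)) Inf else
      max(abs(field$vx - prev_field$vx), abs(field$vy - prev_field$vy))
    B <- Bnew
    n_run <- it
    tr_it <- c(tr_it, it); tr_db <- c(tr_db, max_db); tr_dbos <- c(tr_dbos, max_dbos)
    tr_ratio <- c(tr_ratio, max_ratio)
    if (keep_trace) fields[[it]] <- field
    prev_field <- field
    if (!is.null(convergence_tol) && is.finite(max_dbos) &&
        max_dbos < convergence_tol) break
  }
  structure(
    list(B = B, G = G,
         trace = tibble(iteration = tr_it, max_delta_b = tr_db,
                        max_delta_bos = tr_dbos, max_b_over_2s = tr_ratio),
         fields = if (keep_trace) fields else NULL,
         n_iterations_run = n_run, bank_config = list(
           R0 = bank$R0, n_orientations = bank$n_orientations,
           n_levels = bank$n_levels, factor = bank$factor)),
    class = "recurrence_result")
}
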