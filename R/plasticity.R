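# BCM-like Hebbian plasticity consolidating the novel map: bounded coupling
# updates driven by a sliding postsynaptic threshold (running mean of squared
# sigmoidal recurrent drive) and a presynaptic deviation from recent activity.

#' Plasticity state: learning parameters and activity histories
#'
#' Carries the learning-rule parameters and the per-unit ring buffers: the
#' presynaptic activity history over the last `tau_learn` steps and the
#' squared sigmoidal recurrent drive over the last `tau_bcm + 1` steps
#' feeding the sliding threshold. Buffers are zero-initialised; coupling
#' updates are permitted from step `tau_learn` onward.
#'
#' @param n_units Number of units tracked.
#' @param eta Learning rate.
#' @param tau_learn Presynaptic history window (steps).
#' @param tau_bcm Sliding-threshold window (steps; the sum runs over
#'   `tau_bcm + 1` values, normalised by `tau_bcm`).
#' @param c Sliding-threshold gain.
#' @param apply_stride Steps between coupling updates.
#' @return A `learning_state` list.
#' @export
learning_state <- function(n_units, eta = 0.1, tau_learn = 22, tau_bcm = 400,
                           c = 9.5, apply_stride = 2) {
  structure(list(n_units = n_units, eta = eta, tau_learn = tau_learn,
                 tau_bcm = tau_bcm, c = c, apply_stride = apply_stride,
                 pre_hist = matrix(0, tau_learn, n_units), pre_ptr = 0L,
                 pre_sum = numeric(n_units),
                 bcm_hist = matrix(0, tau_bcm + 1L, n_units), bcm_ptr = 0L,
                 bcm_sum_sq = numeric(n_units),
                 t = 0L),
            class = "learning_state")
}

#' Sigmoidal postsynaptic drive of the plasticity rule
#'
#' The BCM drive is the activation sigmoid of the recurrent input alone:
#' `h_BCM = L(h_RC)`, elementwise, in (0, 1).
#'
#' @param h_rc Per-unit recurrent input.
#' @param G,T Sigmoid threshold and noise parameters.
#' @return Numeric vector in (0, 1).
#' @export
bcm_drive <- function(h_rc, G = 2.31, T = 0.1) {
  activation_probability(h_rc, G, T)
}

#' Sliding plasticity threshold
#'
#' `Phi_i = (c / tau_bcm) * sum_{t'=0}^{tau_bcm} h_BCM_i(t - t')^2`, computed
#' from the (zero-padded) history currently held in the state. A history
#' constant at `h` over the full window gives
#' `Phi = c * h^2 * (tau_bcm + 1) / tau_bcm`.
#'
#' @param state A `learning_state` (after the current step's drive has been
#'   recorded).
#' @return Nonnegative per-unit threshold vector.
#' @export
sliding_threshold <- function(state) {
  state$c / state$tau_bcm * state$bcm_sum_sq
}

# push the current step's BCM drive into the threshold buffer
push_bcm <- function(state, h_bcm) {
  state$bcm_ptr <- state$bcm_ptr %% nrow(state$bcm_hist) + 1L
  old <- state$bcm_hist[state$bcm_ptr, ]
  state$bcm_hist[state$bcm_ptr, ] <- h_bcm^2
  state$bcm_sum_sq <- state$bcm_sum_sq - old + h_bcm^2
  state
}

# push the current step's activity into the presynaptic buffer
push_pre <- function(state, s) {
  state$pre_ptr <- state$pre_ptr %% nrow(state$pre_hist) + 1L
  old <- state$pre_hist[state$pre_ptr, ]
  s <- as.numeric(s)
  state$pre_hist[state$pre_ptr, ] <- s
  state$pre_sum <- state$pre_sum - old + s
  state
}

#' One plasticity step: advance histories and (optionally) update couplings
#'
#' Implements the bounded Hebbian update
#' `J <- clip01(J + eta * C * sigma_post %o% sigma_pre)` with
#' `sigma_post = (h_BCM / Phi) * (h_BCM - Phi)` (defined as 0 where
#' `Phi < 1e-12`, the limit of the product form as activity vanishes) and
#' `sigma_pre = s - mean(s over the last tau_learn steps)`. Histories advance
#' on every call; the coupling update is applied only when `apply = TRUE` and
#' at least `tau_learn` steps of history have accumulated.
#'
#' @param J Coupling matrix (dense or sparse, square over the tracked units).
#' @param C 0/1 connectivity mask of the same shape.
#' @param s Current binary activity of the tracked units.
#' @param h_rc Current recurrent input of the tracked units.
#' @param state A `learning_state`.
#' @param apply Whether to apply the coupling update this step.
#' @param G,T Sigmoid parameters of the BCM drive.
#' @return List with the (possibly updated) `J` and advanced `state`.
#' @export
plasticity_step <- function(J, C, s, h_rc, state, apply = TRUE,
                            G = 2.31, T = 0.1) {
  stopifnot(inherits(state, "learning_state"))
  if (length(s) != state$n_units || length(h_rc) != state$n_units) {
    stop("`s` and `h_rc` must match the number of tracked units")
  }
  h_bcm <- bcm_drive(h_rc, G, T)
  state <- push_bcm(state, h_bcm)
  if (apply && state$t >= state$tau_learn) {
    phi <- sliding_threshold(state)
    sigma_post <- ifelse(phi < 1e-12, 0, (h_bcm / phi) * (h_bcm - phi))
    sigma_pre <- as.numeric(s) - state$pre_sum / state$tau_learn
    nz_pre <- which(sigma_pre != 0)
    if (length(nz_pre)) {
      dJ <- state$eta * outer(sigma_post, sigma_pre[nz_pre])
      block <- as.matrix(J[, nz_pre, drop = FALSE]) +
        dJ * as.matrix(C[, nz_pre, drop = FALSE])
      J[, nz_pre] <- pmin(1, pmax(0, block))
    }
  }
  state <- push_pre(state, s)
  state$t <- state$t + 1L
  list(J = J, state = state)
}
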