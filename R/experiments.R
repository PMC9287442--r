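# Simulation protocols: teleportation experiments with the full model and its
# ablations, position decoding, bump metrics, and snapshot histograms.

#' Define a teleportation simulation protocol
#'
#' A protocol is a sequence of phases (environment + number of laps). The
#' virtual rodent advances one track point per cue update; a lap therefore
#' lasts `p * cue_update_stride` network steps and ends with a teleportation
#' back to the track start (possibly switching environment). At every
#' teleportation the feed-forward DG inhibition is cued once; on entering the
#' novel environment from the familiar one, the transient DG excitation train
#' is scheduled (15 cues, one every 5 steps) - unless ablated.
#'
#' @param phases List of `list(env=, laps=)` entries; `env` is `"F"` or `"N"`.
#' @param ablations Character subset of `"no_dg_excit"`, `"no_dg_inhib"`.
#' @param learning Whether BCM-like Hebbian learning runs while in
#'   environment N.
#' @param dg_excit_trigger `"enter_N"` (burst on every teleportation into the
#'   novel environment) or `"first_N"` (burst only on the first entrance,
#'   as in the consolidation experiments where later laps must stand on the
#'   recurrent couplings alone).
#' @param seed Simulation seed.
#' @return A `ca3_protocol` list.
#' @export
#' @examples
#' ca3_protocol()   # 2 F laps then 3 N laps, full model
ca3_protocol <- function(phases = list(list(env = "F", laps = 2),
                                       list(env = "N", laps = 3)),
                         ablations = character(0), learning = FALSE,
                         dg_excit_trigger = c("enter_N", "first_N"),
                         seed = 1) {
  known <- c("no_dg_excit", "no_dg_inhib")
  bad <- setdiff(ablations, known)
  if (length(bad)) stop("unknown ablation key(s): ", paste(bad, collapse = ", "))
  envs <- vapply(phases, `[[`, character(1), "env")
  if (!all(envs %in% c("F", "N"))) stop("phase environments must be 'F' or 'N'")
  structure(list(phases = phases, ablations = ablations,
                 learning = learning,
                 dg_excit_trigger = match.arg(dg_excit_trigger),
                 seed = seed),
            class = "ca3_protocol")
}

#' Decode position from the population activity of one map
#'
#' The decoded position is the mean place-field centre of the active units
#' carrying a field in the map; the spread is their standard deviation.
#'
#' @param s Binary/logical activity vector.
#' @param patterns A `pattern_set` (its `centres` are used).
#' @return Named numeric `c(estimate=, spread=)` in track points; both `NA`
#'   when no active unit has a field in the map.
#' @export
decode_position <- function(s, patterns) {
  centres <- patterns$centres[which(as.logical(s))]
  centres <- centres[!is.na(centres)]
  if (!length(centres)) return(c(estimate = NA_real_, spread = NA_real_))
  c(estimate = mean(centres),
    spread = if (length(centres) > 1) sd(centres) else 0)
}

#' Histogram of active place cells by field centre
#'
#' @param s Binary/logical activity vector.
#' @param patterns A `pattern_set`.
#' @param n_bins Number of equal bins; must divide the number of track points.
#' @return Integer vector of per-bin counts of active place cells of the map.
#' @export
snapshot_histogram <- function(s, patterns, n_bins) {
  p <- patterns$p
  if (p %% n_bins != 0) stop("`n_bins` must divide the number of track points")
  centres <- patterns$centres[which(as.logical(s))]
  centres <- centres[!is.na(centres)]
  bw <- p / n_bins
  tabulate(ceiling(centres / bw), nbins = n_bins)
}

#' Run a teleportation protocol on a CA3 network
#'
#' Executes the phases of `protocol` under the stochastic synchronous
#' dynamics: cue and position updates every `cue_update_stride` steps,
#' teleportation-triggered DG inputs, optional plasticity in environment N,
#' and full per-step recording of per-map active counts, inhibition, and
#' cued vs decoded positions.
#'
#' @param network A `ca3_network`.
#' @param protocol A [ca3_protocol()].
#' @return A `ca3_simulation`: `record` (per-step data frame), `snapshots`
#'   (mid-lap and post-teleport activity index sets), `lap_envs`,
#'   `coupling_totals` (per-lap summed plastic coupling weight, when
#'   learning), and the centres needed for decoding.
#' @export
run_protocol <- function(network, protocol) {
  stopifnot(inherits(network, "ca3_network"), inherits(protocol, "ca3_protocol"))
  cfg <- network$config
  stride <- cfg$cue_update_stride
  p <- cfg$p
  lap_envs <- unlist(lapply(protocol$phases,
                            function(ph) rep(ph$env, ph$laps)))
  n_laps <- length(lap_envs)
  steps_per_lap <- p * stride
  total <- n_laps * steps_per_lap
  set.seed(protocol$seed)

  lstate <- NULL
  if (protocol$learning) {
    P <- if (cfg$scenario == "random") network$patterns_N$units else
      sort(union(network$patterns_F$units, network$patterns_N$units))
    Jp <- as.matrix(network$J[P, P])
    Cp <- as.matrix(network$C[P, P])
    J_static <- network$J
    J_static[P, P] <- 0
    J_static <- Matrix::drop0(J_static)
    network$plastic <- list(idx = P, Jp = Jp, Cp = Cp, J_static = J_static)
    lstate <- learning_state(length(P))
  }

  state <- init_network_state(network, env = lap_envs[1], pos = 1L)
  state <- refresh_mec_cues(state, network)
  state <- refresh_dg_base_cue(state, network)

  rec <- data.frame(step = seq_len(total), lap = 0L, env = "", pos = 0L,
                    n_F = 0L, n_N = 0L, n_F_only = 0L, n_N_only = 0L,
                    n_shared = 0L, S = 0, inhib = 0,
                    dec_F = NA_real_, sd_F = NA_real_,
                    dec_N = NA_real_, sd_N = NA_real_)
  snapshots <- list()
  coupling_totals <- if (protocol$learning) numeric(n_laps) else NULL

  fm <- network$f_member
  nm <- network$n_member
  mid_pos <- ceiling(p / 2)

  for (step in seq_len(total)) {
    boundary <- (step - 1L) %% stride == 0L
    pu <- (step - 1L) %/% stride          # 0-based position-update counter
    lap <- pu %/% p + 1L
    pos_in_lap <- pu %% p + 1L
    if (boundary) {
      if (pos_in_lap == 1L && step > 1L) {      # teleportation at lap start
        type <- paste0(lap_envs[lap - 1L], lap_envs[lap])
        state$env <- lap_envs[lap]
        if (!("no_dg_inhib" %in% protocol$ablations)) {
          state <- trigger_dg_inhib(state, network)
        }
        enters_N <- lap_envs[lap] == "N"
        first_N <- enters_N && !any(lap_envs[seq_len(lap - 1L)] == "N")
        trigger <- if (protocol$dg_excit_trigger == "enter_N") enters_N else first_N
        if (trigger && !("no_dg_excit" %in% protocol$ablations)) {
          state$dg_excit_left <- cfg$dg_excit_updates + 1L
        }
      }
      state$pos <- pos_in_lap
      state <- refresh_mec_cues(state, network)
      state <- refresh_dg_base_cue(state, network)
      if (state$dg_excit_left > 0L) {
        state <- refresh_dg_excit_cue(state, network)
        state$dg_excit_left <- state$dg_excit_left - 1L
      }
    }

    s_prev <- state$s
    state <- step_network(state, network)

    if (protocol$learning) {
      Pidx <- network$plastic$idx
      apply_now <- state$env == "N" && step %% lstate$apply_stride == 0L
      res <- plasticity_step(network$plastic$Jp, network$plastic$Cp,
                             s_prev[Pidx], state$last_inputs$h_rc[Pidx],
                             lstate, apply = apply_now, G = cfg$G, T = cfg$T)
      network$plastic$Jp <- res$J
      lstate <- res$state
    }

    s <- state$s
    rec$lap[step] <- lap
    rec$env[step] <- state$env
    rec$pos[step] <- pos_in_lap
    rec$n_F[step] <- sum(s & fm)
    rec$n_N[step] <- sum(s & nm)
    rec$n_F_only[step] <- sum(s & fm & !nm)
    rec$n_N_only[step] <- sum(s & !fm & nm)
    rec$n_shared[step] <- sum(s & fm & nm)
    rec$S[step] <- state$last_inputs$S
    rec$inhib[step] <- mean(state$last_inputs$inhibition +
                              state$last_inputs$h_dg_inhib)
    dF <- decode_position(s, network$patterns_F)
    dN <- decode_position(s, network$patterns_N)
    rec$dec_F[step] <- dF[1]; rec$sd_F[step] <- dF[2]
    rec$dec_N[step] <- dN[1]; rec$sd_N[step] <- dN[2]

    if (boundary && pos_in_lap == mid_pos) {
      snapshots[[length(snapshots) + 1]] <-
        list(step = step, lap = lap, label = "mid_lap", active = which(s))
    }
    if (boundary && pos_in_lap == 3L) {
      snapshots[[length(snapshots) + 1]] <-
        list(step = step, lap = lap, label = "post_teleport", active = which(s))
    }
    if (protocol$learning && step %% steps_per_lap == 0L) {
      coupling_totals[lap] <- sum(network$plastic$Jp)
    }
  }

  structure(list(record = rec, snapshots = snapshots, lap_envs = lap_envs,
                 steps_per_lap = steps_per_lap,
                 coupling_totals = coupling_totals,
                 patterns_F = network$patterns_F,
                 patterns_N = network$patterns_N,
                 config = cfg, protocol = protocol),
            class = "ca3_simulation")
}

#' @export
print.ca3_simulation <- function(x, ...) {
  cat(sprintf("CA3 simulation: %d laps (%s), %d steps%s\n",
              length(x$lap_envs), paste(x$lap_envs, collapse = ""),
              nrow(x$record),
              if (length(x$protocol$ablations))
                paste0(", ablations: ",
                       paste(x$protocol$ablations, collapse = ", "))
              else ""))
  print(bump_metrics(x))
  invisible(x)
}

#' @export
plot.ca3_simulation <- function(x, ...) {
  r <- x$record
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(r$step, r$n_F_only, type = "l", col = "blue", xlab = "step",
       ylab = "active units", ylim = range(0, r$n_F, r$n_N))
  lines(r$step, r$n_N_only, col = "red")
  lines(r$step, r$n_shared, col = "purple")
  abline(v = which(diff(r$lap) > 0), lty = 3, col = "grey")
  legend("topright", c("F only", "N only", "shared"), lty = 1,
         col = c("blue", "red", "purple"), bty = "n", cex = 0.8)
  plot(r$step, r$pos, type = "l", xlab = "step", ylab = "position (pts)")
  lines(r$step, r$dec_F, col = "blue")
  lines(r$step, r$dec_N, col = "red")
  invisible(x)
}

#' Per-phase bump summary of a simulation
#'
#' For each protocol phase: the fraction of steps each map's bump dominates
#' (its active count exceeds the floor and the other map's count), the median
#' absolute decoding error (cm) of each map over its dominant steps, and the
#' overall dominant map.
#'
#' @param sim A `ca3_simulation`.
#' @param floor Minimum active count for a bump (defaults to `S_min`).
#' @return Data frame with one row per phase.
#' @export
bump_metrics <- function(sim, floor = NULL) {
  stopifnot(inherits(sim, "ca3_simulation"))
  if (is.null(floor)) floor <- sim$config$S_min
  r <- sim$record
  cmpt <- sim$config$cm_per_point
  phase_of_lap <- rep(seq_along(sim$protocol$phases),
                      vapply(sim$protocol$phases, `[[`, numeric(1), "laps"))
  r$phase <- phase_of_lap[r$lap]
  dom_F <- r$n_F > floor & r$n_F > r$n_N
  dom_N <- r$n_N > floor & r$n_N >= r$n_F
  out <- lapply(split(seq_len(nrow(r)), r$phase), function(i) {
    err_F <- median(abs(r$dec_F[i][dom_F[i]] - r$pos[i][dom_F[i]]),
                    na.rm = TRUE) * cmpt
    err_N <- median(abs(r$dec_N[i][dom_N[i]] - r$pos[i][dom_N[i]]),
                    na.rm = TRUE) * cmpt
    data.frame(phase = r$phase[i[1]], env = r$env[i[1]],
               laps = length(unique(r$lap[i])),
               persistence_F = mean(dom_F[i]), persistence_N = mean(dom_N[i]),
               track_err_F_cm = err_F, track_err_N_cm = err_N)
  })
  res <- do.call(rbind, out)
  res$dominant_map <- ifelse(res$persistence_F >= res$persistence_N, "F", "N")
  rownames(res) <- NULL
  res
}

#' Did the network switch to a persistent, position-tracking novel-map bump?
#'
#' Operational success criterion for the teleportation experiment: over the
#' first N phase (excluding a short transition window after the
#' teleportation), the N-map bump dominates at least `min_persistence` of the
#' steps and its median decoding error stays below `max_error_cm`.
#'
#' @param sim A `ca3_simulation` whose protocol contains an N phase.
#' @param min_persistence Minimum dominant-step fraction.
#' @param max_error_cm Maximum median decoding error (cm).
#' @param settle_steps Steps after the F-to-N teleportation excluded as
#'   transition.
#' @param floor Minimum active count for the novel-map bump. The novel map is
#'   a weak, mEC-anchored representation of roughly `S_min` units, so the
#'   default floor is half the bump floor used for the consolidated map.
#' @return Logical.
#' @export
map_switch_success <- function(sim, min_persistence = 0.5, max_error_cm = 20,
                               settle_steps = 50, floor = NULL) {
  r <- sim$record
  i_N <- which(r$env == "N")
  if (!length(i_N)) stop("protocol has no N phase")
  i_N <- i_N[i_N > min(i_N) + settle_steps]
  if (is.null(floor)) floor <- sim$config$S_min / 2
  dom_N <- r$n_N[i_N] > floor & r$n_N[i_N] >= r$n_F[i_N]
  if (mean(dom_N) < min_persistence) return(FALSE)
  err <- median(abs(r$dec_N[i_N][dom_N] - r$pos[i_N][dom_N]), na.rm = TRUE) *
    sim$config$cm_per_point
  is.finite(err) && err <= max_error_cm
}
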