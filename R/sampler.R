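#' Metropolis acceptance for a bias-exchange swap
#'
#' Two replicas sharing the same physical potential and temperature but
#' carrying different bias potentials may exchange their CV-space states.
#' The potential energy cancels, leaving only the bias terms:
#' `min(1, exp((V_a(x_a) + V_b(x_b) - V_a(x_b) - V_b(x_a)) / kT))`.
#'
#' @param bias_a_at_a,bias_a_at_b Replica a's bias at its own state and at
#'   replica b's state (kJ/mol).
#' @param bias_b_at_b,bias_b_at_a Likewise for replica b.
#' @param kT Thermal energy in kJ/mol (> 0).
#' @return Acceptance probability in \[0, 1\].
#' @examples
#' swap_acceptance(0, 1, 0, 0, kT = 2.5775) # exp(-1/kT) ~ 0.678
#' @export
swap_acceptance <- function(bias_a_at_a, bias_a_at_b,
                            bias_b_at_b, bias_b_at_a, kT) {
  if (kT <= 0) abort("kT must be positive")
  min(1, exp((bias_a_at_a + bias_b_at_b - bias_a_at_b - bias_b_at_a) / kT))
}

#' One Metropolis step of the CV-space toy sampler
#'
#' Gaussian random-walk proposal with acceptance on the total energy
#' (potential + bias + any extra restraint); proposals outside the CV
#' domain are rejected outright. Satisfies detailed balance for a fixed
#' bias, so long unbiased runs sample `exp(-U/kT)`.
#'
#' @param state Current CV-space point.
#' @param energy_fn Function mapping a point to its total energy (kJ/mol).
#' @param proposal_sigma Random-walk width (CV units).
#' @param kT Thermal energy (kJ/mol).
#' @param domain_lo,domain_hi Sampling domain per dimension.
#' @return List with the new `state` and logical `accepted`.
#' @export
mc_step <- function(state, energy_fn, proposal_sigma = 2, kT = KT_310,
                    domain_lo = 0, domain_hi = 32) {
  d <- length(state)
  prop <- state + rnorm(d, 0, proposal_sigma)
  if (any(prop < domain_lo) || any(prop > domain_hi)) {
    return(list(state = state, accepted = FALSE))
  }
  de <- energy_fn(prop) - energy_fn(state)
  if (de <= 0 || runif(1) < exp(-de / kT)) {
    list(state = prop, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

## raw linear interpolation helpers (no validation; engine internals)
interp1_raw <- function(values, lower, dx, n, x) {
  u <- (x - lower) / dx
  i0 <- min(max(floor(u), 0), n - 2)
  f <- u - i0
  i <- i0 + 1L
  values[i] * (1 - f) + values[i + 1L] * f
}
interp2_raw <- function(values, lower, dx, n, x, y) {
  u <- (x - lower[1]) / dx[1]
  v <- (y - lower[2]) / dx[2]
  i0 <- min(max(floor(u), 0), n[1] - 2)
  j0 <- min(max(floor(v), 0), n[2] - 2)
  fx <- u - i0; fy <- v - j0
  i <- i0 + 1L; j <- j0 + 1L
  values[i, j] * (1 - fx) * (1 - fy) + values[i + 1L, j] * fx * (1 - fy) +
    values[i, j + 1L] * (1 - fx) * fy + values[i + 1L, j + 1L] * fx * fy
}

replica_bias_dims <- function(kind, d) {
  switch(kind,
         neutral = integer(0),
         alpha_only = , biased = 1L,
         beta_only = { if (d < 2) abort("beta_only needs a 2D potential"); 2L },
         both = { if (d < 2) abort("both needs a 2D potential"); c(1L, 2L) },
         abort(paste0("unknown replica kind: ", kind)))
}

#' Run a bias-exchange metadynamics simulation on a toy potential
#'
#' The reference setup uses four replicas of the same system: one
#' unbiased, one biased along alpha_RMSD, one along beta_RMSD, and one
#' along both. Here each replica is a Metropolis random walk in CV space
#' on an analytic toy potential; biased replicas deposit a
#' boundary-corrected Gaussian hill on their own grid(s) at a fixed pace,
#' and neighbouring replicas periodically attempt to exchange states with
#' the bias-only Metropolis criterion of [swap_acceptance()]. One RNG
#' stream per replica plus one for the exchange schedule makes runs fully
#' reproducible and independent of replica count.
#'
#' @param potential A [toy_potential_wells()] or [toy_potential_mixture()].
#' @param replicas Character vector of replica kinds from `"neutral"`,
#'   `"alpha_only"` (alias `"biased"` in 1D), `"beta_only"`, `"both"`.
#' @param n_steps Number of MC steps per replica (1 step = `dt` ps).
#' @param kT Thermal energy in kJ/mol.
#' @param proposal_sigma Random-walk width in CV units. The default 2.0
#'   matches the hill width: one MC step then decorrelates the CV by
#'   about as much as one hill-deposition interval (1 ps) of molecular
#'   dynamics, keeping deposition quasi-adiabatic. Much smaller widths
#'   make the walker deposit many overlapping hills per correlation
#'   length, which degrades the free-energy estimate.
#' @param exchange_interval Steps between exchange attempts (neighbour
#'   pairs in cyclic order); 0 disables exchange.
#' @param hill_pace Steps between hill deposits (0 disables deposition,
#'   freezing any initial bias).
#' @param hill_height,hill_sigma Hill height (kJ/mol) and width (CV units).
#' @param stride Steps between trajectory records.
#' @param seed Integer seed.
#' @param init_state Starting point (recycled per replica); defaults to
#'   the domain centre.
#' @param init_grids Optional named list (by replica index as character)
#'   of pre-filled bias grids, e.g. to continue or freeze a bias.
#' @param corrected Use boundary-corrected hill kernels.
#' @param bias_grid_nodes Nodes per dimension for 1D replica grids
#'   (default 2351 over \[-5, 42\]) and 2D grids (default 471).
#' @param extra_energy Optional function adding a restraint energy
#'   (e.g. a [wall_energy()] term) to a point's total energy.
#' @param dt Time per step in ps.
#' @return A `bemd_run`: trajectories tibble (`replica`, `time`, `alpha`
#'   and, in 2D, `beta`), per-replica hills tibbles, final grids, and
#'   acceptance statistics.
#' @export
run_bias_exchange <- function(potential, replicas = c("neutral", "alpha_only",
                                                      "beta_only", "both"),
                              n_steps, kT = KT_310, proposal_sigma = 2,
                              exchange_interval = 100L, hill_pace = 1L,
                              hill_height = 0.1, hill_sigma = 2,
                              stride = 10L, seed = 1L, init_state = NULL,
                              init_grids = NULL, corrected = TRUE,
                              bias_grid_nodes = NULL, extra_energy = NULL,
                              dt = 1) {
  d <- potential$dims
  R <- length(replicas)
  stopifnot(n_steps >= 1, R >= 1)
  dom_lo <- potential$domain_lo
  dom_hi <- potential$domain_hi
  bias_dims <- lapply(replicas, replica_bias_dims, d = d)

  grids <- vector("list", R)
  for (r in seq_len(R)) {
    bd <- bias_dims[[r]]
    if (length(bd) == 0) next
    if (!is.null(init_grids) && !is.null(init_grids[[as.character(r)]])) {
      grids[[r]] <- init_grids[[as.character(r)]]
    } else {
      nn <- bias_grid_nodes %||% if (length(bd) == 1L) 2351L else 471L
      grids[[r]] <- bias_grid(dims = length(bd), lower = -5, upper = 42,
                              n_nodes = nn, domain_lo = 0, domain_hi = 32)
    }
  }

  ## bias of replica r at point x (vector length d)
  bias_at <- function(r, x) {
    bd <- bias_dims[[r]]
    if (length(bd) == 0) return(0)
    g <- grids[[r]]
    if (length(bd) == 1L) {
      interp1_raw(g$values, g$lower[1], g$dx[1], g$n_nodes[1], x[bd])
    } else {
      interp2_raw(g$values, g$lower, g$dx, g$n_nodes, x[1], x[2])
    }
  }
  u_at <- function(x) {
    u <- potential_energy(potential, x)
    if (!is.null(extra_energy)) u <- u + extra_energy(x)
    u
  }

  ## RNG streams: one per replica, one for the exchange schedule
  old_rng <- get_rng_state()
  on.exit(set_rng_state(old_rng), add = TRUE)
  streams <- vector("list", R + 1L)
  for (r in seq_len(R + 1L)) {
    set.seed((seed * 1000L + r) %% .Machine$integer.max)
    streams[[r]] <- get_rng_state()
  }

  states <- matrix(rep(rep_len(init_state %||% ((dom_lo + dom_hi) / 2), d),
                       R), nrow = R, byrow = TRUE)
  energies <- vapply(seq_len(R), function(r) u_at(states[r, ]), 0)

  n_rec <- n_steps %/% stride
  traj <- lapply(seq_len(R), function(r) matrix(NA_real_, n_rec, d + 1L))
  n_hills_max <- if (hill_pace > 0) n_steps %/% hill_pace else 0L
  hill_rec <- lapply(seq_len(R), function(r) {
    if (length(bias_dims[[r]]) > 0 && n_hills_max > 0) {
      matrix(NA_real_, n_hills_max, 1L + length(bias_dims[[r]]))
    } else NULL
  })
  n_hills <- integer(R)
  acc_mc <- att_mc <- acc_sw <- att_sw <- 0

  block <- if (exchange_interval > 0) exchange_interval else n_steps
  n_blocks <- ceiling(n_steps / block)
  exch_event <- 0L

  for (bk in seq_len(n_blocks)) {
    s0 <- (bk - 1L) * block
    s1 <- min(bk * block, n_steps)
    for (r in seq_len(R)) {
      set_rng_state(streams[[r]])
      x <- states[r, ]
      ex <- energies[r]
      bd <- bias_dims[[r]]
      has_bias <- length(bd) > 0
      bx <- if (has_bias) bias_at(r, x) else 0
      for (step in (s0 + 1L):s1) {
        prop <- x + rnorm(d, 0, proposal_sigma)
        att_mc <- att_mc + 1
        if (all(prop >= dom_lo) && all(prop <= dom_hi)) {
          ep <- u_at(prop)
          bp <- if (has_bias) bias_at(r, prop) else 0
          de <- (ep + bp) - (ex + bx)
          if (de <= 0 || runif(1) < exp(-de / kT)) {
            x <- prop; ex <- ep; bx <- bp
            acc_mc <- acc_mc + 1
          }
        }
        if (has_bias && hill_pace > 0 && step %% hill_pace == 0L) {
          ctr <- x[bd]
          grids[[r]] <- deposit_one(grids[[r]], ctr,
                                    rep_len(hill_sigma, length(bd)),
                                    hill_height, corrected, 6)
          n_hills[r] <- n_hills[r] + 1L
          hill_rec[[r]][n_hills[r], ] <- c(step * dt, ctr)
          bx <- bias_at(r, x)
        }
        if (step %% stride == 0L) {
          traj[[r]][step %/% stride, ] <- c(step * dt, x)
        }
      }
      states[r, ] <- x
      energies[r] <- ex
      streams[[r]] <- get_rng_state()
    }
    ## exchange attempt: neighbour pairs in cyclic order
    if (exchange_interval > 0 && R >= 2 && s1 < n_steps) {
      set_rng_state(streams[[R + 1L]])
      exch_event <- exch_event + 1L
      a <- ((exch_event - 1L) %% (R - 1L)) + 1L
      b <- a + 1L
      p <- swap_acceptance(bias_at(a, states[a, ]), bias_at(a, states[b, ]),
                           bias_at(b, states[b, ]), bias_at(b, states[a, ]),
                           kT)
      att_sw <- att_sw + 1
      if (runif(1) < p) {
        tmp <- states[a, ]; states[a, ] <- states[b, ]; states[b, ] <- tmp
        ea <- energies[a]; energies[a] <- energies[b]; energies[b] <- ea
        acc_sw <- acc_sw + 1
      }
      streams[[R + 1L]] <- get_rng_state()
    }
  }

  cvn <- if (d == 1L) "alpha" else c("alpha", "beta")
  trajectories <- purrr::map_dfr(seq_len(R), function(r) {
    m <- traj[[r]]
    out <- tibble(replica = replicas[r], replica_id = r, time = m[, 1])
    for (k in seq_len(d)) out[[cvn[k]]] <- m[, 1 + k]
    out
  })
  hills_out <- setNames(lapply(seq_len(R), function(r) {
    m <- hill_rec[[r]]
    if (is.null(m) || n_hills[r] == 0) return(NULL)
    m <- m[seq_len(n_hills[r]), , drop = FALSE]
    if (ncol(m) == 2L) {
      hills_tibble(time = m[, 1], center = m[, 2],
                   sigma = hill_sigma, height = hill_height)
    } else {
      hills_tibble(time = m[, 1], center = m[, 2:3, drop = FALSE],
                   sigma = hill_sigma, height = hill_height)
    }
  }), replicas)

  structure(list(
    trajectories = trajectories, hills = hills_out,
    grids = setNames(grids, replicas), replicas = replicas,
    potential = potential, kT = kT, n_steps = n_steps, seed = seed,
    acceptance = tibble(
      move = c("mc", "swap"),
      attempts = c(att_mc, att_sw),
      accepted = c(acc_mc, acc_sw),
      rate = c(if (att_mc > 0) acc_mc / att_mc else NA_real_,
               if (att_sw > 0) acc_sw / att_sw else NA_real_))),
    class = "bemd_run")
}

#' @export
print.bemd_run <- function(x, ...) {
  cat("<bemd_run> ", length(x$replicas), " replica(s) [",
      paste(x$replicas, collapse = ", "), "], ", x$n_steps,
      " steps, mc acceptance ",
      format(x$acceptance$rate[1], digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname run_bias_exchange
#' @param x A `bemd_run`.
#' @param ... Unused.
#' @method tidy bemd_run
#' @export
tidy.bemd_run <- function(x, ...) x$trajectories

#' @rdname run_bias_exchange
#' @method glance bemd_run
#' @export
glance.bemd_run <- function(x, ...) {
  tibble(n_replicas = length(x$replicas), n_steps = x$n_steps,
         mc_acceptance = x$acceptance$rate[1],
         swap_acceptance = x$acceptance$rate[2],
         n_hills = sum(vapply(x$hills, function(h) {
           if (is.null(h)) 0L else nrow(h)
         }, 0L)),
         seed = x$seed, kT = x$kT)
}

#' Count barrier crossings of a 1D trajectory
#'
#' Number of times the trajectory crosses a dividing point, ignoring
#' recrossings within a tolerance band around it (a crossing is counted
#' when the walker passes from below `divide - band` to above
#' `divide + band` or vice versa).
#'
#' @param x Numeric trajectory of CV values.
#' @param divide Dividing point (e.g. the barrier top).
#' @param band Half-width of the ignored band.
#' @return Integer crossing count.
#' @export
count_crossings <- function(x, divide, band = 0) {
  side <- ifelse(x < divide - band, -1L, ifelse(x > divide + band, 1L, 0L))
  side <- side[side != 0L]
  if (length(side) < 2) return(0L)
  sum(diff(side) != 0L)
}
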