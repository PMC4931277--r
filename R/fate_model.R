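#' Parameters of the Delta-Notch lateral-inhibition switch
#'
#' The two daughters interact through a Collier-type lateral-inhibition
#' pair: Notch is activated by the neighbour's Delta through the saturating
#' increasing function `F(x) = x^2 / (a + x^2)` and decays linearly; Delta
#' relaxes at rate `nu` toward `G(Not) = 1 / (1 + b * Not^2)`, a decreasing
#' function of the cell's own Notch. Large `b` and small `a` make the
#' switch sharp enough that the fate thresholds (Notch > 0.98 and
#' Delta < 0.02 for the losing, V2b, daughter) are reachable from initial
#' Delta splits near 0.5. One fixed-step 4th-order Runge-Kutta step of size
#' `dt` is taken per Monte Carlo step of the lattice clock.
#'
#' @param a half-saturation constant of the Notch activation `F` (must be
#'   <= 0.02 so that `F(1) > 0.98`).
#' @param b inhibition strength in `G`.
#' @param nu Delta relaxation rate.
#' @param dt ODE time advanced per Monte Carlo step.
#' @param notch_threshold,delta_threshold V2b call thresholds.
#' @param max_mcs give up (unresolved) after this many steps.
#' @return A list of class `fate_params`.
#' @export
fate_params <- function(a = 0.01, b = 100, nu = 1, dt = 0.5,
                        notch_threshold = 0.98, delta_threshold = 0.02,
                        max_mcs = 500L) {
  stopifnot(a > 0, b > 0, nu >= 0, dt > 0,
            notch_threshold > 0, notch_threshold < 1,
            delta_threshold > 0, delta_threshold < 1)
  structure(list(a = a, b = b, nu = nu, dt = dt,
                 notch_threshold = notch_threshold,
                 delta_threshold = delta_threshold,
                 max_mcs = as.integer(max_mcs)), class = "fate_params")
}

f_act <- function(x, a) x^2 / (a + x^2)
g_inh <- function(x, b) 1 / (1 + b * x^2)

#' Initial fate state from the yellow-particle split
#'
#' The Delta activity of each daughter is initialized to its share of the
#' yellow particles, `n / N_yellow`; Notch starts at zero in both.
#'
#' @param n_plus,n_minus yellow-particle counts of the two daughters.
#' @param n_yellow total yellow-particle count (must equal the sum).
#' @param normalization `"sum1"` (`n / N`, shares summing to 1) or
#'   `"mean1"` (`2n / N`, mean 1).
#' @return A list of class `fate_state` with `del`, `not` (each length-2,
#'   plus then minus), `resolved`, `fate`.
#' @export
initial_conditions <- function(n_plus, n_minus, n_yellow = n_plus + n_minus,
                               normalization = "sum1") {
  if (n_plus + n_minus != n_yellow)
    stop("daughter counts must sum to the total yellow-particle count")
  if (n_yellow <= 0) stop("no yellow particles: fate cannot be initialized")
  del <- c(plus = n_plus, minus = n_minus) / n_yellow
  if (normalization == "mean1") del <- 2 * del
  structure(list(del = del, not = c(plus = 0, minus = 0),
                 resolved = FALSE, fate = c(plus = "unresolved",
                                            minus = "unresolved")),
            class = "fate_state")
}

#' One integration step of the lateral-inhibition pair
#'
#' Advances both daughters by one 4th-order Runge-Kutta step of size `dt`:
#' `d(Not)/dt = F(Del_neighbour) - Not`, `d(Del)/dt = nu * (G(Not) - Del)`.
#' Values are clipped to be nonnegative.
#'
#' @param state a `fate_state`.
#' @param params [fate_params()].
#' @param dt step size (defaults to `params$dt`).
#' @return The advanced `fate_state`.
#' @export
step_lateral_inhibition <- function(state, params, dt = params$dt) {
  if (any(!is.finite(c(state$del, state$not)))) stop("non-finite fate state")
  y <- c(state$del, state$not)  # del_p, del_m, not_p, not_m
  deriv <- function(y) {
    del <- y[1:2]; nt <- y[3:4]
    c(params$nu * (g_inh(nt, params$b) - del),
      f_act(rev(del), params$a) - nt)
  }
  k1 <- deriv(y)
  k2 <- deriv(y + dt / 2 * k1)
  k3 <- deriv(y + dt / 2 * k2)
  k4 <- deriv(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  y <- pmax(y, 0)
  state$del[] <- y[1:2]
  state$not[] <- y[3:4]
  state
}

#' Integrate until a fate resolves
#'
#' Runs the lateral-inhibition pair one step per Monte Carlo step until one
#' daughter crosses both thresholds (Notch above, Delta below): that
#' daughter is the V2b, the other the V2a, and integration stops. An exact
#' initial tie cannot resolve (the dynamics are symmetric) and is broken by
#' a coin flip using the current RNG stream, flagged in the result; if
#' neither daughter resolves within `max_mcs` the outcome is `"unresolved"`.
#' Should both daughters cross in the same step, the one with lower Delta
#' takes the V2b fate (flagged).
#'
#' @param state initial `fate_state` from [initial_conditions()].
#' @param params [fate_params()].
#' @param record keep the per-step trajectory.
#' @return List with `fate` (named, `"V2a"`/`"V2b"`/`"unresolved"`),
#'   `resolved`, `mcs` steps used, `tie`, `simultaneous`, and optionally
#'   `trajectory` (data frame).
#' @export
resolve_fate <- function(state, params, record = FALSE) {
  tie <- abs(state$del[1] - state$del[2]) < 1e-12
  if (tie) {
    winner <- if (runif(1) < 0.5) "plus" else "minus"
    fate <- c(plus = "V2b", minus = "V2b")
    fate[winner] <- "V2a"
    return(list(fate = fate, resolved = TRUE, mcs = 0L, tie = TRUE,
                simultaneous = FALSE,
                trajectory = if (record) trajectory_row(state, 0L)))
  }
  traj <- if (record) vector("list", params$max_mcs + 1L)
  if (record) traj[[1]] <- trajectory_row(state, 0L)
  simultaneous <- FALSE
  for (m in seq_len(params$max_mcs)) {
    state <- step_lateral_inhibition(state, params)
    if (record) traj[[m + 1L]] <- trajectory_row(state, m)
    v2b <- state$not > params$notch_threshold &
           state$del < params$delta_threshold
    if (any(v2b)) {
      if (all(v2b)) {
        simultaneous <- TRUE
        v2b <- state$del == min(state$del)
        if (all(v2b)) v2b <- c(TRUE, FALSE)
      }
      fate <- ifelse(v2b, "V2b", "V2a")
      names(fate) <- names(state$del)
      return(list(fate = fate, resolved = TRUE, mcs = m, tie = FALSE,
                  simultaneous = simultaneous,
                  trajectory = if (record) do.call(rbind, traj[1:(m + 1L)])))
    }
  }
  list(fate = c(plus = "unresolved", minus = "unresolved"), resolved = FALSE,
       mcs = params$max_mcs, tie = FALSE, simultaneous = FALSE,
       trajectory = if (record) do.call(rbind, traj))
}

trajectory_row <- function(state, m) {
  data.frame(mcs = m, del_plus = state$del[[1]], not_plus = state$not[[1]],
             del_minus = state$del[[2]], not_minus = state$not[[2]])
}

#' Check that the switch is a mutually exclusive binary system
#'
#' Scans initial Delta asymmetries and confirms that, for every asymmetry at
#' or above some minimal value, the pair resolves with the majority daughter
#' taking the V2a fate. Used to vet `a`, `b`, `nu`, `dt` before running
#' ensembles; parameter sets without mutually exclusive attractors are
#' rejected with an error.
#'
#' @param params [fate_params()].
#' @param eps asymmetries to scan (initial Delta `0.5 + eps/2` vs
#'   `0.5 - eps/2`).
#' @return Data frame with `eps`, `resolved`, `majority_v2a`,
#'   `mcs_to_resolution`, plus attribute `eps_min` (smallest asymmetry that
#'   resolves).
#' @export
verify_bistability <- function(params = fate_params(),
                               eps = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)) {
  rows <- lapply(eps, function(e) {
    st <- initial_conditions(round(1e6 * (0.5 + e / 2)),
                             round(1e6 * (0.5 - e / 2)))
    r <- resolve_fate(st, params)
    data.frame(eps = e, resolved = r$resolved,
               majority_v2a = identical(unname(r$fate[["plus"]]), "V2a"),
               mcs_to_resolution = r$mcs)
  })
  out <- do.call(rbind, rows)
  ok <- out$resolved & out$majority_v2a
  if (!any(ok))
    stop("no scanned asymmetry resolves with the majority daughter V2a: ",
         "parameters do not form a mutually exclusive switch")
  eps_min <- min(out$eps[ok])
  if (!all(out$resolved[out$eps >= eps_min] & out$majority_v2a[out$eps >= eps_min]))
    stop("resolution is not monotone in the initial asymmetry: rejected")
  attr(out, "eps_min") <- eps_min
  out
}
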