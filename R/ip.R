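#' Intrinsic-plasticity state
#'
#' Per-neuron state of the homeostatic intrinsic-plasticity rule: a calcium
#' trace and the derived firing-rate estimate, plus the adaptive intrinsic
#' parameters (leak resistance `R` and membrane time constant `tau`). The
#' rule performs online gradient descent on the KL divergence from the
#' neuron's output-rate distribution (exponential with its current mean
#' rate) to a target exponential with mean `mu`, chained through the
#' deterministic LIF rate map; see [ip_step()].
#'
#' @param n number of neurons.
#' @param mu target mean firing rate (spikes/step).
#' @param tau_cal calcium time constant (steps).
#' @param gamma learning rate of the rule.
#' @param R0,tau0 initial intrinsic parameters.
#' @param tau_avg time constant of the second low-pass applied to the rate
#'   estimate before it enters the update. The raw calcium trace ripples
#'   strongly under periodic firing (its time constant is comparable to the
#'   target inter-spike interval) and the update is nonlinear in the rate,
#'   which biases the closed-loop fixed point; the extra smoothing removes
#'   that bias.
#' @param r_gain relative gain of the `R` update. `tau` carries the fine
#'   rate regulation (its stationary point is exactly `y = mu`); `R` adapts
#'   more slowly and brings the operating point into range.
#' @param clamp_R,clamp_tau validity ranges enforced after every update.
#' @param rate_floor lower bound substituted for the rate estimate of silent
#'   neurons, keeping the update finite.
#' @return Object of class `ip_state`.
#' @export
ip_state <- function(n, mu = 0.05, tau_cal = 16, gamma = 0.01,
                     R0 = 1, tau0 = 16, tau_avg = 64, r_gain = 0.1,
                     clamp_R = c(0.1, 10), clamp_tau = c(2, 256),
                     rate_floor = 1e-4) {
  stopifnot(tau_cal > 1, tau_avg >= 1, mu > 0, gamma >= 0)
  structure(list(phi = numeric(n), y = numeric(n), ybar = numeric(n),
                 R = rep(R0, n), tau = rep(tau0, n),
                 mu = mu, tau_cal = tau_cal, gamma = gamma,
                 tau_avg = tau_avg, r_gain = r_gain,
                 clamp_R = clamp_R, clamp_tau = clamp_tau,
                 rate_floor = rate_floor),
            class = "ip_state")
}

# Unvalidated trace update; s may be a batch-mean spike fraction in [0, 1].
calcium_update <- function(state, s) {
  state$phi <- (1 - 1 / state$tau_cal) * state$phi + s
  state$y <- state$phi / state$tau_cal
  state$ybar <- (1 - 1 / state$tau_avg) * state$ybar + state$y / state$tau_avg
  state
}

#' Advance the calcium trace by one step
#'
#' `phi[t] = (1 - 1/tau_cal) * phi[t-1] + s[t]`; the rate estimate is
#' `y = phi / tau_cal`, which converges to the true firing rate under
#' stationary firing.
#'
#' @param state an [ip_state()].
#' @param s binary spike vector.
#' @return Updated state (fields `phi`, `y`, `ybar`).
#' @export
calcium_step <- function(state, s) {
  if (!is_binary(s)) stop("spike vector s must be binary (0/1)")
  calcium_update(state, s)
}

#' Deterministic LIF rate map
#'
#' Continuous-time firing rate of a LIF neuron under constant drive `x`:
#' zero when `R * x <= v_th`, else `1 / (tau * log(Rx / (Rx - v_th)))`.
#'
#' @param R leak resistance. @param tau membrane time constant.
#' @param x constant input drive. @param v_th firing threshold.
#' @return Firing rate (spikes/step).
#' @export
lif_rate <- function(R, tau, x, v_th) {
  z <- R * x
  ifelse(z <= v_th, 0, 1 / (tau * log(z / (z - v_th))))
}

#' Intrinsic-plasticity objective
#'
#' The sample objective minimized by the rule: the KL divergence between an
#' exponential rate distribution with the neuron's current mean rate
#' `y(R, tau, x)` and the target exponential with mean `mu`,
#' `D = log(mu / y) + y / mu - 1`. Nonnegative, zero iff `y == mu`.
#'
#' @inheritParams lif_rate
#' @param mu target mean firing rate.
#' @return Objective value (`Inf` for a silent neuron).
#' @export
ip_objective <- function(R, tau, x, v_th, mu) {
  y <- lif_rate(R, tau, x, v_th)
  ifelse(y <= 0, Inf, log(mu / y) + y / mu - 1)
}

#' Gradient of the intrinsic-plasticity objective
#'
#' Exact gradient of [ip_objective()] with respect to `(R, tau)`, expressed
#' through the measured rate `y` via `W = exp(1/(tau*y)) - 1`:
#' `dR = y*tau*W*(y/mu - 1)/R` and `dtau = (1 - y/mu)/tau`. The applied
#' update scales `dR` by `r_gain` and clips both components.
#'
#' @param R,tau intrinsic parameters (vectors).
#' @param y firing-rate estimate (floored at `rate_floor`).
#' @param mu target mean rate.
#' @param rate_floor substitute rate for silent neurons.
#' @param r_gain relative gain on the `R` component.
#' @param clip magnitude bound applied to each component.
#' @return List with exact components `dR`, `dtau` and applied (scaled,
#'   clipped) components `dR_applied`, `dtau_applied`.
#' @export
ip_gradient <- function(R, tau, y, mu, rate_floor = 1e-4,
                        r_gain = 0.1, clip = 10) {
  y <- pmax(y, rate_floor)
  W <- expm1(pmin(1 / (tau * y), 50))
  dR <- y * tau * W * (y / mu - 1) / R
  dtau <- (1 - y / mu) / tau
  list(dR = dR, dtau = dtau,
       dR_applied = clamp(r_gain * dR, -clip, clip),
       dtau_applied = clamp(dtau, -clip, clip))
}

#' One intrinsic-plasticity update
#'
#' Applies `R <- R - gamma * dR` and `tau <- tau - gamma * dtau` using the
#' smoothed rate estimate, then clamps both parameters to their validity
#' ranges. With `gamma = 0` the state is returned unchanged.
#'
#' @param state an [ip_state()].
#' @param v_th firing threshold of the adapted neurons (unused by the
#'   update itself, kept for interface stability).
#' @return Updated state.
#' @export
ip_step <- function(state, v_th = NULL) {
  if (state$gamma == 0) return(state)
  g <- ip_gradient(state$R, state$tau, state$ybar, state$mu,
                   rate_floor = state$rate_floor, r_gain = state$r_gain)
  state$R <- clamp(state$R - state$gamma * g$dR_applied,
                   state$clamp_R[1L], state$clamp_R[2L])
  state$tau <- clamp(state$tau - state$gamma * g$dtau_applied,
                     state$clamp_tau[1L], state$clamp_tau[2L])
  state
}
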