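#' LIF neuron parameters
#'
#' Bundle of the intrinsic constants of a discrete-time leaky
#' integrate-and-fire neuron integrated with a fixed 1 ms Euler step. All
#' time constants are expressed in simulation steps, so millisecond values
#' from the usual parameter tables divide through directly.
#'
#' @param tau_m membrane time constant (steps, > 1).
#' @param tau_syn synaptic time constant of the first-order synapse
#'   (steps, > 1).
#' @param R leak resistance (dimensionless, > 0).
#' @param v_th firing threshold (> 0).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 16, tau_syn = 8, R = 1, v_th = 1) {
  if (any(tau_m <= 1) || any(tau_syn <= 1))
    stop("time constants must exceed 1 step (decay factor 1 - 1/tau in (0,1))")
  if (any(R <= 0)) stop("leak resistance R must be positive")
  if (any(v_th <= 0)) stop("firing threshold v_th must be positive")
  structure(list(tau_m = tau_m, tau_syn = tau_syn, R = R, v_th = v_th),
            class = "neuron_params")
}

#' One step of the first-order synapse
#'
#' Advances the unweighted postsynaptic current (PSC) trace by one step:
#' `a[t] = (1 - 1/tau_syn) * a[t-1] + s[t]`. An impulse therefore decays
#' geometrically with ratio `1 - 1/tau_syn` and its infinite-horizon sum is
#' `tau_syn`.
#'
#' @param a_prev PSC at the previous step (numeric vector).
#' @param s binary spike indicator vector at the current step.
#' @param tau_syn synaptic time constant (steps, > 1).
#' @return Updated PSC vector.
#' @export
psc_step <- function(a_prev, s, tau_syn) {
  if (tau_syn <= 1) stop("tau_syn must exceed 1")
  if (!all(is.finite(a_prev))) stop("a_prev must be finite")
  if (!is_binary(s)) stop("spike vector s must be binary (0/1)")
  (1 - 1 / tau_syn) * a_prev + s
}

#' One Euler step of the LIF neuron
#'
#' Computes the pre-reset membrane potential
#' `u_minus = (1 - 1/tau_m) * u_prev + (R/tau_m) * current`, emits a spike
#' where `u_minus >= v_th`, and resets the potential to zero for spiking
#' neurons. Spike and reset share the same condition, so the firing
#' indicator and the reset branch can never disagree. The PSC trace in the
#' state is advanced with [psc_step()].
#'
#' @param state list with elements `u` (membrane potential), `a` (PSC) and
#'   `s` (last spike output), as produced by [lif_init()].
#' @param weighted_current already-summed synaptic drive per neuron.
#' @param params a [neuron_params()] object.
#' @return Updated state list with elements `u`, `a`, `s` and the pre-reset
#'   potential `u_minus`.
#' @export
lif_step <- function(state, weighted_current, params) {
  if (!all(is.finite(weighted_current))) stop("non-finite input current")
  if (length(weighted_current) != length(state$u))
    stop("current and state dimensions disagree")
  u_minus <- (1 - 1 / params$tau_m) * state$u +
    (params$R / params$tau_m) * weighted_current
  s <- as.numeric(u_minus >= params$v_th)
  list(u = u_minus * (1 - s),
       a = psc_step(state$a, s, params$tau_syn),
       s = s,
       u_minus = u_minus)
}

#' @rdname lif_step
#' @param n number of neurons.
#' @export
lif_init <- function(n) {
  list(u = numeric(n), a = numeric(n), s = numeric(n))
}

#' Filter a spike train into its PSC trace
#'
#' Applies the first-order synapse along the last (time) dimension of a
#' `channels x T` matrix or `samples x channels x T` array of binary spikes.
#'
#' @param spikes binary matrix or 3-d array with time as last dimension.
#' @param tau_syn synaptic time constant (steps, > 1).
#' @return PSC trace with the same shape as `spikes`.
#' @export
psc_filter <- function(spikes, tau_syn) {
  if (tau_syn <= 1) stop("tau_syn must exceed 1")
  lam <- 1 - 1 / tau_syn
  d <- dim(spikes)
  if (is.null(d)) stop("spikes must be a matrix or 3-d array")
  out <- spikes * 0
  nt <- d[length(d)]
  if (length(d) == 2L) {
    acc <- numeric(d[1L])
    for (t in seq_len(nt)) {
      acc <- lam * acc + spikes[, t]
      out[, t] <- acc
    }
  } else if (length(d) == 3L) {
    acc <- matrix(0, d[1L], d[2L])
    for (t in seq_len(nt)) {
      acc <- lam * acc + spikes[, , t]
      out[, , t] <- acc
    }
  } else stop("spikes must have 2 or 3 dimensions")
  out
}

#' Surrogate derivative of the spike function
#'
#' Smooth stand-in for the derivative of the Heaviside spike nonlinearity,
#' used during backpropagation through time. All kernels are unimodal,
#' centred at `v_th`, and integrate to 1 over the membrane potential, so the
#' backward pass sees a smeared threshold of width `width`.
#'
#' @param u_minus pre-reset membrane potential (any numeric shape).
#' @param v_th firing threshold.
#' @param kind `"bump"` (Gaussian, default), `"sigmoid"` (logistic
#'   derivative) or `"triangle"`.
#' @param width kernel width (> 0), in potential units.
#' @return Kernel values with the shape of `u_minus`.
#' @export
spike_pseudo_grad <- function(u_minus, v_th, kind = c("bump", "sigmoid", "triangle"),
                              width = 0.5) {
  kind <- match.arg(kind)
  if (width <= 0) stop("width must be positive")
  x <- (u_minus - v_th) / width
  switch(kind,
    bump = exp(-x^2 / 2) / (width * sqrt(2 * pi)),
    sigmoid = {
      p <- stats::plogis(x)
      p * (1 - p) / width
    },
    triangle = pmax(0, 1 - abs(x)) / width
  )
}

# Smooth (logistic) spike activation used by the fully differentiable
# forward mode; its exact derivative is spike_pseudo_grad(kind = "sigmoid").
smooth_spike <- function(u_minus, v_th, width) {
  stats::plogis((u_minus - v_th) / width)
}
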