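#' Desired output-PSC sequences for a batch of labels
#'
#' The target neuron of each sample is asked to fire at every timestep, so
#' its desired PSC is the trace of the all-ones spike train,
#' `d[t] = tau_syn * (1 - (1 - 1/tau_syn)^t)`; all other output neurons are
#' silenced (all-zero target).
#'
#' @param labels integer class labels in `1..n_out` (vector: one per sample).
#' @param n_out number of output neurons.
#' @param T_steps number of timesteps.
#' @param tau_syn synaptic time constant of the output layer.
#' @return `length(labels) x n_out x T_steps` array of desired PSCs.
#' @export
target_psc <- function(labels, n_out, T_steps, tau_syn) {
  if (any(labels < 1 | labels > n_out)) stop("label out of range")
  d_t <- tau_syn * (1 - (1 - 1 / tau_syn)^(seq_len(T_steps)))
  D <- array(0, c(length(labels), n_out, T_steps))
  for (b in seq_along(labels)) D[b, labels[b], ] <- d_t
  D
}

#' Squared-error loss on accumulated output PSCs
#'
#' `L = (1/B) * sum_t sum_o 0.5 * (d_o[t] - a_o[t])^2`, averaged over the
#' batch.
#'
#' @param a_out actual output PSCs, `B x n_out x T` array.
#' @param targets desired output PSCs of the same shape.
#' @return Scalar loss.
#' @export
psc_loss <- function(a_out, targets) {
  if (!identical(dim(a_out), dim(targets))) stop("output/target shape mismatch")
  0.5 * sum((targets - a_out)^2) / dim(a_out)[1L]
}
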