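#' Backpropagation through time for weights and architecture logits
#'
#' Reverse sweep over the retained forward histories. The non-differentiable
#' spike is handled by a surrogate kernel ([spike_pseudo_grad()]); in
#' `"smooth"` forward mode the kernel is the exact derivative of the
#' logistic spike activation, so the returned gradients are the exact
#' gradients of the smooth graph (checkable against finite differences).
#' The recursion carries the next-layer term and the one-step-delayed
#' recurrent term; when intrinsic plasticity adapted `R` and `tau` during
#' the forward pass, the stored per-timestep values enter the chain as
#' time-varying coefficients (their own dependence on past activity is not
#' differentiated).
#'
#' Per-slot architecture gradients aggregate the effective-matrix gradient
#' over candidate pairs; the mixture structure yields
#' `dL/dw_exc[i,r] = G[i,r] * sum_v p_v * p_exc(slot)`,
#' `dL/dp_v = sum_(i,r) G[i,r] * A_v[i,r]`, and per-slot type-probability
#' gradients, all pulled back through the softmax to logit space.
#'
#' @param net an `rsnn`.
#' @param fwd forward histories from [rsnn_forward()].
#' @param targets desired output PSCs, `batch x n_out x T` array.
#' @param relaxed the relaxed probabilities used in the forward pass.
#' @param surrogate surrogate kernel for `"hard"` mode.
#' @return List with `loss` and gradients `W_in`, `w_rec`, `W_out`
#'   (matrices), `alpha_v` (vector) and `alpha_c` (list of matrices),
#'   all in logit space for the architecture parameters.
#' @export
rsnn_backward <- function(net, fwd, targets, relaxed = NULL,
                          surrogate = "bump") {
  if (is.null(relaxed)) relaxed <- relax(net$arch)
  spec <- net$spec
  B <- fwd$B; Tt <- fwd$Tt; n <- spec$n
  ph <- net$prm_h; po <- net$prm_o
  lam_s <- 1 - 1 / ph$tau_syn
  lam_so <- 1 - 1 / po$tau_syn
  lam_mo <- 1 - 1 / po$tau_m
  kind_h <- if (fwd$mode == "smooth") "sigmoid" else surrogate
  W_e <- fwd$W_e
  loss <- 0

  gW_in <- net$W_in * 0
  gW_out <- net$W_out * 0
  Geff <- matrix(0, n, n)

  Abar_o_next <- matrix(0, B, net$n_out)
  Ubm_o_next <- matrix(0, B, net$n_out)
  Abar_h_next <- matrix(0, B, n)
  Ubm_h_next <- matrix(0, B, n)
  Ibar_h_next <- matrix(0, B, n)
  lam_m_next <- rep(0, n)

  for (t in rev(seq_len(Tt))) {
    Dm <- mat_slice(targets, t)
    err <- fwd$A_o[[t]] - Dm
    loss <- loss + 0.5 * sum(err^2) / B
    Abar_o <- err / B + lam_so * Abar_o_next
    Ubar_o <- lam_mo * Ubm_o_next
    Sbar_o <- Abar_o - Ubar_o * fwd$Um_o[[t]]
    fpo <- spike_pseudo_grad(fwd$Um_o[[t]], po$v_th, kind_h, fwd$width)
    Ubm_o <- Sbar_o * fpo + Ubar_o * (1 - fwd$S_o[[t]])
    Ibar_o <- Ubm_o * (po$R / po$tau_m)
    gW_out <- gW_out + crossprod(Ibar_o, fwd$A_h[[t]])

    Abar_h <- lam_s * Abar_h_next + Ibar_h_next %*% W_e + Ibar_o %*% net$W_out
    Ubar_h <- Ubm_h_next * rowb(lam_m_next, B)
    Sbar_h <- Abar_h - Ubar_h * fwd$Um_h[[t]]
    fph <- spike_pseudo_grad(fwd$Um_h[[t]], ph$v_th, kind_h, fwd$width)
    Ubm_h <- Sbar_h * fph + Ubar_h * (1 - fwd$S_h[[t]])
    Ibar_h <- Ubm_h * rowb(fwd$R_t[, t] / fwd$tau_t[, t], B)
    gW_in <- gW_in + crossprod(Ibar_h, mat_slice(fwd$A_in, t))
    if (t > 1L) Geff <- Geff + crossprod(Ibar_h, fwd$A_h[[t - 1L]])

    Abar_o_next <- Abar_o; Ubm_o_next <- Ubm_o
    Abar_h_next <- Abar_h; Ubm_h_next <- Ubm_h
    Ibar_h_next <- Ibar_h
    lam_m_next <- 1 - 1 / fwd$tau_t[, t]
  }

  # Map the effective-matrix gradient onto weights and architecture logits.
  gw_rec <- net$w_rec * 0
  g_pv <- numeric(length(spec$V))
  galpha_c <- vector("list", length(spec$V))
  for (k in seq_along(spec$V)) {
    cd <- spec$cand[[k]]
    P <- relaxed$p_c[[k]]
    pv <- relaxed$p_v[[k]]
    g_idx <- Geff[cd$idx]
    w_idx <- net$w_rec[cd$idx]
    A_vals <- P[cd$slot, 1L] * w_idx + P[cd$slot, 2L] * spec$w_inh
    g_pv[k] <- sum(g_idx * A_vals)
    gw_rec[cd$idx] <- gw_rec[cd$idx] + pv * P[cd$slot, 1L] * g_idx
    gP <- cbind(
      exc = pv * rowsum_by(g_idx * w_idx, cd$slot, cd$n_slots),
      inh = pv * spec$w_inh * rowsum_by(g_idx, cd$slot, cd$n_slots),
      none = 0
    )
    galpha_c[[k]] <- softmax_vjp_rows(P, gP)
  }
  names(galpha_c) <- as.character(spec$V)
  galpha_v <- if (!is.null(net$arch$frozen_v)) g_pv * 0
              else softmax_vjp(relaxed$p_v, g_pv)
  list(loss = loss,
       W_in = gW_in, w_rec = gw_rec, W_out = gW_out,
       alpha_v = galpha_v, alpha_c = galpha_c)
}

# Sum values by integer group id into a vector of fixed length.
rowsum_by <- function(x, g, ngroups) {
  out <- numeric(ngroups)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Loss and gradients for one batch
#'
#' Convenience wrapper: forward pass (histories retained) plus backward
#' sweep.
#'
#' @inheritParams rsnn_forward
#' @param y integer labels for the batch.
#' @param surrogate surrogate kernel for `"hard"` mode.
#' @return The [rsnn_backward()] gradient list (includes `loss`).
#' @export
rsnn_grads <- function(net, X, y, relaxed = NULL, mode = "hard",
                       width = 0.5, surrogate = "bump", ip_on = FALSE) {
  if (is.null(relaxed)) relaxed <- relax(net$arch)
  fwd <- rsnn_forward(net, X, relaxed = relaxed, mode = mode, width = width,
                      ip_on = ip_on)
  D <- target_psc(y, net$n_out, fwd$Tt, net$prm_o$tau_syn)
  g <- rsnn_backward(net, fwd, D, relaxed = relaxed, surrogate = surrogate)
  g$ip_state <- fwd$ip_state
  g
}
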