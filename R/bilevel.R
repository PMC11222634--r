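# Weight-list helpers: the trainable weights are the two feedforward
# matrices and the excitatory candidate recurrent weights.

weights_get <- function(net) list(W_in = net$W_in, w_rec = net$w_rec,
                                  W_out = net$W_out)

weights_set <- function(net, w) {
  net$W_in <- w$W_in; net$w_rec <- w$w_rec; net$W_out <- w$W_out
  net
}

weights_add <- function(net, g, scale) {
  net$W_in <- net$W_in + scale * g$W_in
  net$w_rec <- net$w_rec + scale * g$w_rec
  net$W_out <- net$W_out + scale * g$W_out
  net
}

weights_norm <- function(g) {
  sqrt(sum(g$W_in^2) + sum(g$w_rec^2) + sum(g$W_out^2))
}

alpha_get <- function(arch) {
  p <- list(alpha_v = arch$alpha_v)
  for (nm in names(arch$alpha_c)) p[[paste0("alpha_c_", nm)]] <- arch$alpha_c[[nm]]
  p
}

alpha_set <- function(arch, p) {
  arch$alpha_v <- p$alpha_v
  for (nm in names(arch$alpha_c)) arch$alpha_c[[nm]] <- p[[paste0("alpha_c_", nm)]]
  arch
}

alpha_from_grads <- function(g) {
  p <- list(alpha_v = g$alpha_v)
  for (nm in names(g$alpha_c)) p[[paste0("alpha_c_", nm)]] <- g$alpha_c[[nm]]
  p
}

#' Second-order bi-level update of the architecture logits
#'
#' One-step look-ahead architecture gradient: with
#' `w' = w - eta * grad_w L_train(w, alpha)`, the update direction is
#' `grad_alpha L_valid(alpha, w')` minus the second-order correction
#' `(eta / 2 eps) * (grad_alpha L_train(w+, alpha) - grad_alpha L_train(w-, alpha))`
#' where `w± = w ± eps * grad_w L_valid(alpha, w')` — the finite-difference
#' approximation of the mixed second derivative times the validation weight
#' gradient. With `eta = 0` the update reduces exactly to the first-order
#' validation gradient. One Adam step is then applied to the logits (the
#' motif-size logits are skipped once frozen).
#'
#' @param net an `rsnn`.
#' @param Xt,yt training batch (spikes and labels).
#' @param Xv,yv validation batch.
#' @param eta inner (look-ahead) learning rate.
#' @param epsilon finite-difference perturbation; a number, or `"auto"` for
#'   `0.01 / ||grad_w L_valid||`.
#' @param lr_alpha Adam learning rate for the logits.
#' @param opt Adam state for the logits (`NULL` to initialize).
#' @param mode,width,surrogate forward/backward settings.
#' @return List with the updated `net` (new logits), `opt`, the validation
#'   loss `loss_valid`, and the raw update direction `g_alpha`.
#' @export
bilevel_arch_step <- function(net, Xt, yt, Xv, yv, eta, epsilon = "auto",
                              lr_alpha = 5e-4, opt = NULL,
                              mode = "hard", width = 0.5, surrogate = "bump") {
  if (is.numeric(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  if (length(yt) == 0L || length(yv) == 0L) stop("empty batch")
  relaxed <- relax(net$arch)
  gt <- rsnn_grads(net, Xt, yt, relaxed = relaxed, mode = mode, width = width,
                   surrogate = surrogate)
  net1 <- weights_add(net, gt, -eta)
  gv <- rsnn_grads(net1, Xv, yv, relaxed = relaxed, mode = mode, width = width,
                   surrogate = surrogate)
  g_alpha <- alpha_from_grads(gv)
  if (eta > 0) {
    eps_val <- if (identical(epsilon, "auto")) {
      nrm <- weights_norm(gv)
      if (nrm == 0) 1e-3 else 0.01 / nrm
    } else epsilon
    netp <- weights_add(net, gv, eps_val)
    netm <- weights_add(net, gv, -eps_val)
    gap <- alpha_from_grads(rsnn_grads(netp, Xt, yt, relaxed = relaxed,
                                       mode = mode, width = width,
                                       surrogate = surrogate))
    gam <- alpha_from_grads(rsnn_grads(netm, Xt, yt, relaxed = relaxed,
                                       mode = mode, width = width,
                                       surrogate = surrogate))
    for (nm in names(g_alpha))
      g_alpha[[nm]] <- g_alpha[[nm]] - (eta / (2 * eps_val)) * (gap[[nm]] - gam[[nm]])
  }
  params <- alpha_get(net$arch)
  if (is.null(opt)) opt <- adam_init(params)
  if (!is.null(net$arch$frozen_v)) g_alpha$alpha_v <- NULL
  st <- adam_step(opt, params, g_alpha, lr_alpha)
  net$arch <- alpha_set(net$arch, st$params)
  list(net = net, opt = st$state, loss_valid = gv$loss, g_alpha = g_alpha)
}

#' One Adam step on the synaptic weights
#'
#' Gradient step on the training loss of one batch; excitatory recurrent
#' candidates, feedforward and readout weights are updated, inhibitory
#' weights stay fixed.
#'
#' @inheritParams bilevel_arch_step
#' @param lr Adam learning rate.
#' @return List with updated `net`, `opt` and the batch `loss`.
#' @export
weight_step <- function(net, Xt, yt, lr, opt = NULL,
                        mode = "hard", width = 0.5, surrogate = "bump") {
  g <- rsnn_grads(net, Xt, yt, mode = mode, width = width, surrogate = surrogate)
  params <- weights_get(net)
  if (is.null(opt)) opt <- adam_init(params)
  st <- adam_step(opt, params, list(W_in = g$W_in, w_rec = g$w_rec,
                                    W_out = g$W_out), lr)
  list(net = weights_set(net, st$params), opt = st$state, loss = g$loss)
}
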