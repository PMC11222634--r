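# Shared fixtures: tiny networks and batches built in code, plus a central
# finite-difference utility used by the gradient-oracle tests.

# internal helpers exercised directly by the tests
with_seed <- hrmas:::with_seed
onehot_relaxed <- hrmas:::onehot_relaxed
w_eff <- hrmas:::w_eff
weights_add <- hrmas:::weights_add
alpha_from_grads <- hrmas:::alpha_from_grads
child_seed <- hrmas:::child_seed
slot_table <- hrmas:::slot_table

toy_net <- function(n_in = 2, n_hidden = 4, n_out = 2, V = c(2, 4),
                    v_th = 0.4, seed = 3, randomize_arch = TRUE) {
  net <- new_rsnn(n_in, n_hidden, n_out, V, v_th = v_th, seed = seed)
  if (randomize_arch) {
    net <- with_seed(seed + 1, {
      net$arch$alpha_v[] <- stats::rnorm(length(net$arch$alpha_v), 0, 0.5)
      for (nm in names(net$arch$alpha_c))
        net$arch$alpha_c[[nm]][] <- net$arch$alpha_c[[nm]] +
          stats::rnorm(length(net$arch$alpha_c[[nm]]), 0, 0.5)
      net
    })
  }
  net
}

toy_batch <- function(B = 3, n_in = 2, Tt = 8, n_out = 2, rate = 0.4, seed = 11) {
  with_seed(seed, {
    X <- array(as.numeric(stats::runif(B * n_in * Tt) < rate), c(B, n_in, Tt))
    y <- sample.int(n_out, B, replace = TRUE)
    list(X = X, y = y, Tt = Tt)
  })
}

toy_loss <- function(net, X, y, width = 0.3) {
  rsnn_grads(net, X, y, mode = "smooth", width = width)$loss
}

# Central finite differences of the smooth-graph loss with respect to one
# parameter container, addressed by a setter.
fd_grad <- function(net, X, y, n_par, setter, width = 0.3, eps = 1e-5) {
  vapply(seq_len(n_par), function(i) {
    lp <- toy_loss(setter(net, i, +eps), X, y, width)
    lm <- toy_loss(setter(net, i, -eps), X, y, width)
    (lp - lm) / (2 * eps)
  }, numeric(1))
}

max_rel_err <- function(analytic, numeric) {
  max(abs(analytic - numeric)) / max(max(abs(numeric)), 1e-8)
}

# Reference forward pass of a fixed discrete recurrent architecture, written
# directly from the update equations without the mixture machinery; used as
# the independent oracle for mixture/discrete equivalence.
reference_discrete_forward <- function(net, X, W_rec) {
  d <- dim(X); B <- d[1L]; Tt <- d[3L]
  ph <- net$prm_h; po <- net$prm_o
  A_in <- psc_filter(X, ph$tau_syn)
  U <- matrix(0, B, net$spec$n); A <- matrix(0, B, net$spec$n)
  Uo <- matrix(0, B, net$n_out); Ao <- matrix(0, B, net$n_out)
  S_hist <- vector("list", Tt); Ao_hist <- vector("list", Tt)
  A_prev <- A
  for (t in seq_len(Tt)) {
    Ih <- matrix(A_in[, , t], B, d[2L]) %*% t(net$W_in) + A_prev %*% t(W_rec)
    um <- (1 - 1 / ph$tau_m) * U + (ph$R / ph$tau_m) * Ih
    S <- (um >= ph$v_th) * 1
    U <- um * (1 - S)
    A_prev <- A <- (1 - 1 / ph$tau_syn) * A + S
    Io <- A %*% t(net$W_out)
    umo <- (1 - 1 / po$tau_m) * Uo + (po$R / po$tau_m) * Io
    So <- (umo >= po$v_th) * 1
    Uo <- umo * (1 - So)
    Ao <- (1 - 1 / po$tau_syn) * Ao + So
    S_hist[[t]] <- S; Ao_hist[[t]] <- Ao
  }
  list(S_h = S_hist, A_o = Ao_hist)
}
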