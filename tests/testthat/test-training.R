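test_that("target PSC is the trace of an always-firing neuron", {
  D <- target_psc(1L, n_out = 2, T_steps = 10, tau_syn = 8)
  expect_equal(D[1, 1, 1], 1)
  expect_equal(D[1, 1, 2], 1.875)
  expect_equal(D[1, 2, ], numeric(10))          # silenced class
  Dlong <- target_psc(1L, 1, 500, 8)
  expect_equal(Dlong[1, 1, 500], 8, tolerance = 1e-6)  # geometric limit
  expect_error(target_psc(3L, 2, 10, 8), "range")
})

test_that("squared-error PSC loss matches direct summation", {
  a <- array(0, c(1, 1, 10))
  d <- array(1, c(1, 1, 10))
  expect_equal(psc_loss(a, d), 5)
  expect_equal(psc_loss(d, d), 0)
  # 2-neuron, 3-step case against a hand summation
  a2 <- array(c(0.5, 1.0, 0.2, 0.4, 0.9, 0.1), c(1, 2, 3))
  d2 <- array(c(1.0, 0.0, 0.5, 0.5, 0.3, 0.3), c(1, 2, 3))
  expect_equal(psc_loss(a2, d2), 0.5 * sum((a2 - d2)^2))
  expect_error(psc_loss(a, array(0, c(1, 1, 9))), "mismatch")
})

test_that("analytic BPTT gradients match central finite differences", {
  net <- toy_net(n_in = 2, n_hidden = 4, n_out = 2, V = c(2, 4), seed = 3)
  b <- toy_batch(B = 3, n_in = 2, Tt = 8, seed = 11)
  g <- rsnn_grads(net, b$X, b$y, mode = "smooth", width = 0.3)

  gn <- fd_grad(net, b$X, b$y, length(net$W_in),
                function(n, i, e) { n$W_in[i] <- n$W_in[i] + e; n })
  expect_lt(max_rel_err(as.numeric(g$W_in), gn), 1e-4)

  gn <- fd_grad(net, b$X, b$y, length(net$W_out),
                function(n, i, e) { n$W_out[i] <- n$W_out[i] + e; n })
  expect_lt(max_rel_err(as.numeric(g$W_out), gn), 1e-4)

  mask <- which(net$spec$union_mask)
  gn <- fd_grad(net, b$X, b$y, length(mask),
                function(n, i, e) { n$w_rec[mask[i]] <- n$w_rec[mask[i]] + e; n })
  expect_lt(max_rel_err(g$w_rec[mask], gn), 1e-4)

  gn <- fd_grad(net, b$X, b$y, length(net$arch$alpha_v),
                function(n, i, e) { n$arch$alpha_v[i] <- n$arch$alpha_v[i] + e; n })
  expect_lt(max_rel_err(g$alpha_v, gn), 1e-4)

  for (k in seq_along(net$arch$alpha_c)) {
    gn <- fd_grad(net, b$X, b$y, length(net$arch$alpha_c[[k]]),
                  function(n, i, e) { n$arch$alpha_c[[k]][i] <- n$arch$alpha_c[[k]][i] + e; n })
    expect_lt(max_rel_err(as.numeric(g$alpha_c[[k]]), gn), 1e-4)
  }
})

test_that("zero loss implies zero gradients", {
  # a silent network whose target is all-zero PSC reaches exactly zero loss
  net <- toy_net(n_in = 2, n_hidden = 4, n_out = 1, V = 2, seed = 5,
                 randomize_arch = FALSE)
  X <- array(0, c(2, 2, 6))
  fwd <- rsnn_forward(net, X, mode = "hard")
  D <- array(0, c(2, 1, 6))
  g <- rsnn_backward(net, fwd, D)
  expect_equal(g$loss, 0)
  expect_equal(max(abs(g$W_in)), 0)
  expect_equal(max(abs(g$W_out)), 0)
  expect_equal(max(abs(g$alpha_v)), 0)
})

test_that("single-step network reduces to the feedforward delta rule", {
  net <- toy_net(n_in = 2, n_hidden = 3, n_out = 2, V = 3, seed = 7)
  b <- toy_batch(B = 2, n_in = 2, Tt = 1, seed = 13)
  g <- rsnn_grads(net, b$X, b$y, mode = "smooth", width = 0.3)
  # recurrence is unreachable at T = 1: no recurrent or architecture gradient
  expect_equal(max(abs(g$w_rec)), 0)
  expect_equal(max(abs(g$alpha_v)), 0)
  for (gc in g$alpha_c) expect_equal(max(abs(gc)), 0)
  # the readout gradient equals the direct one-step chain written by hand:
  # dL/dW_out[o,h] = mean_b err_o * f'(um_o) * (R/tau) * a_h
  rel <- relax(net$arch)
  fwd <- rsnn_forward(net, b$X, relaxed = rel, mode = "smooth", width = 0.3)
  D <- target_psc(b$y, 2, 1, net$prm_o$tau_syn)
  err <- fwd$A_o[[1]] - matrix(D[, , 1], 2, 2)
  fpo <- spike_pseudo_grad(fwd$Um_o[[1]], net$prm_o$v_th, "sigmoid", 0.3)
  delta <- err * fpo * (net$prm_o$R / net$prm_o$tau_m)
  manual <- crossprod(delta, fwd$A_h[[1]]) / 2
  expect_equal(g$W_out, manual, tolerance = 1e-12)
})

test_that("forcing every connection type to 'none' yields a feedforward network", {
  net <- toy_net(n_in = 3, n_hidden = 4, n_out = 2, V = c(2, 4), seed = 9,
                 randomize_arch = FALSE)
  cd1 <- net$spec$cand[[1]]
  rel_none <- onehot_relaxed(net$spec, 1, rep(3L, cd1$n_slots))
  b <- toy_batch(B = 2, n_in = 3, Tt = 10, seed = 17)
  fwd <- rsnn_forward(net, b$X, relaxed = rel_none, mode = "hard")
  ref <- reference_discrete_forward(net, b$X, matrix(0, 4, 4))
  expect_identical(fwd$S_h, ref$S_h)
  # excitatory-weight gradients vanish: no path through the recurrence
  D <- target_psc(b$y, 2, 10, net$prm_o$tau_syn)
  g <- rsnn_backward(net, fwd, D, relaxed = rel_none)
  expect_equal(max(abs(g$w_rec)), 0)
})

test_that("training loss decreases on a separable task (smoke property)", {
  ds <- make_pattern_task(n_classes = 2, n_in = 8, T_steps = 30,
                          spikes_per_template = 20, jitter_sd = 0,
                          n_per_class = 10, seed = 23)
  net <- new_rsnn(8, 8, 2, V = c(2, 4), v_th = 0.3, seed = 29)
  fit <- train_weights(net, ds, epochs = 10, batch_size = 10, lr = 0.005,
                       seed = 31)
  # 50 weight-only steps: loss trend is non-increasing overall
  expect_lt(fit$loss_trace[10], fit$loss_trace[1])
  expect_true(all(is.finite(fit$loss_trace)))
})
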