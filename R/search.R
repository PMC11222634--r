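#' Train the synaptic weights of a network
#'
#' Plain epoch loop: shuffled mini-batches, one Adam step per batch on the
#' output-PSC squared-error loss. Architecture probabilities stay fixed
#' (pass `relaxed` for a discrete/one-hot architecture).
#'
#' @param net an `rsnn`.
#' @param ds a [spike_dataset()].
#' @param epochs full passes over the data.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param relaxed optional fixed relaxed architecture probabilities.
#' @param mode,width,surrogate forward/backward settings.
#' @param ip_on adapt intrinsic parameters online while training.
#' @param seed RNG seed for batch shuffling.
#' @return List with the trained `net`, Adam state `opt` and a numeric
#'   vector `loss_trace` (mean batch loss per epoch).
#' @export
train_weights <- function(net, ds, epochs, batch_size, lr,
                          relaxed = NULL, mode = "hard", width = 0.5,
                          surrogate = "bump", ip_on = FALSE, seed = 1) {
  if (is.null(relaxed)) relaxed <- relax(net$arch)
  S <- length(ds$y)
  opt <- NULL
  loss_trace <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(S)
      losses <- c()
      for (start in seq(1L, S, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, S)]
        Xb <- ds$X[idx, , , drop = FALSE]
        g <- rsnn_grads(net, Xb, ds$y[idx], relaxed = relaxed, mode = mode,
                        width = width, surrogate = surrogate, ip_on = ip_on)
        if (ip_on) net$ip_state <- g$ip_state
        if (!is.finite(g$loss)) stop("training loss diverged (non-finite)")
        params <- weights_get(net)
        if (is.null(opt)) opt <- adam_init(params)
        st <- adam_step(opt, params, list(W_in = g$W_in, w_rec = g$w_rec,
                                          W_out = g$W_out), lr)
        opt <- st$state
        net <- weights_set(net, st$params)
        losses <- c(losses, g$loss)
      }
      loss_trace[ep] <- mean(losses)
    }
  })
  list(net = net, opt = opt, loss_trace = loss_trace)
}

#' Accuracy of a network on a dataset
#'
#' @inheritParams train_weights
#' @return Fraction of correctly classified samples.
#' @export
evaluate_accuracy <- function(net, ds, relaxed = NULL) {
  mean(rsnn_predict(net, ds_X(ds), relaxed = relaxed) == ds_y(ds))
}

net_from_config <- function(cfg, seed) {
  nw <- cfg$network
  new_rsnn(nw$n_in, nw$n_hidden, nw$n_out, nw$V,
           tau_m = nw$tau_m, tau_syn = nw$tau_syn,
           v_th = nw$v_th, v_th_out = nw$v_th_out %||% nw$v_th,
           tying = nw$tying, w_exc_init = nw$w_exc_init, w_inh = nw$w_inh,
           include_inter = nw$inter %||% TRUE,
           ip = cfg$ip, seed = seed)
}

#' Hybrid risk-mitigating architecture search
#'
#' The alternating two-step optimization. Each iteration performs: step 1,
#' one bi-level architecture update on a validation batch
#' ([bilevel_arch_step()]) plus one Adam weight update on a training batch;
#' step 2, an intrinsic-plasticity window — one mini-batch run with online
#' adaptation of each recurrent neuron's `R` and `tau` — which the next
#' iteration's gradients then see as the current intrinsic parameters. The
#' incremental schedule searches motif size and connection types jointly
#' for `stage1_iters` iterations, then freezes the motif size at its argmax
#' and continues with connection types only for `stage2_iters`. Finally the
#' architecture is discretized, all weights are reinitialized, and the
#' network is retrained on the full training set before a single evaluation
#' on the held-out test set.
#'
#' @param ds_train training dataset (internally split 50/50 into training
#'   and validation subsets, stratified).
#' @param ds_test held-out test dataset; touched exactly once, at the end.
#' @param config configuration list, see [default_config()].
#' @param seed master seed for this run.
#' @return Object of class `search_result`: discrete architecture, chosen
#'   motif size, per-iteration traces, test accuracy of the retrained
#'   network, and bookkeeping.
#' @export
hrmas_search <- function(ds_train, ds_test, config = default_config(), seed = 1) {
  cfg <- validate_config(config)
  tr <- cfg$training; sch <- cfg$schedule
  ds_test <- attach_counter(ds_test)
  halves <- split_dataset(ds_train, 0.5, seed = child_seed(seed, 1))
  sub_t <- halves$a; sub_v <- halves$b
  net <- net_from_config(cfg, seed = child_seed(seed, 2))
  opt_w <- NULL; opt_a <- NULL
  av_bar <- NULL   # iterate-averaged motif-size logits for the freeze decision
  total <- sch$stage1_iters + sch$stage2_iters
  trace <- data.frame(iteration = seq_len(total), train_loss = NA_real_,
                      valid_loss = NA_real_, valid_acc = NA_real_)
  with_seed(child_seed(seed, 3), {
    # weight-only warm-up: architecture gradients on near-random weights
    # mostly reward expressiveness, so the relaxed choices only start
    # training once the inner weights carry signal
    for (wu in seq_len(sch$warmup_iters %||% 0L)) {
      bt <- sample.int(length(sub_t$y), min(tr$batch_size, length(sub_t$y)))
      ws <- weight_step(net, sub_t$X[bt, , , drop = FALSE], sub_t$y[bt],
                        lr = tr$lr, opt = opt_w, mode = tr$mode,
                        width = tr$width, surrogate = tr$surrogate)
      net <- ws$net; opt_w <- ws$opt
    }
    for (it in seq_len(total)) {
      bt <- sample.int(length(sub_t$y), min(tr$batch_size, length(sub_t$y)))
      bv <- sample.int(length(sub_v$y), min(tr$batch_size, length(sub_v$y)))
      Xt <- sub_t$X[bt, , , drop = FALSE]; yt <- sub_t$y[bt]
      Xv <- sub_v$X[bv, , , drop = FALSE]; yv <- sub_v$y[bv]
      eta <- if (identical(tr$eta, "lr")) tr$lr else tr$eta
      st <- bilevel_arch_step(net, Xt, yt, Xv, yv, eta = eta,
                              epsilon = tr$epsilon, lr_alpha = tr$lr_alpha,
                              opt = opt_a, mode = tr$mode, width = tr$width,
                              surrogate = tr$surrogate)
      net <- st$net; opt_a <- st$opt
      # Polyak-style average of the motif-size logits: the freeze decision
      # reads the averaged iterate, damping mini-batch noise in alpha_v
      av_bar <- if (is.null(av_bar)) net$arch$alpha_v
                else 0.9 * av_bar + 0.1 * net$arch$alpha_v
      ws <- weight_step(net, Xt, yt, lr = tr$lr, opt = opt_w, mode = tr$mode,
                        width = tr$width, surrogate = tr$surrogate)
      net <- ws$net; opt_w <- ws$opt
      if (!is.finite(ws$loss) || !is.finite(st$loss_valid))
        stop("search diverged (non-finite loss) at iteration ", it)
      if (!is.null(net$ip_state) && isTRUE(cfg$ip$enabled)) {
        bi <- sample.int(length(sub_t$y), min(tr$batch_size, length(sub_t$y)))
        fwd <- rsnn_forward(net, sub_t$X[bi, , , drop = FALSE], ip_on = TRUE,
                            mode = tr$mode, width = tr$width)
        net$ip_state <- fwd$ip_state
      }
      trace$train_loss[it] <- ws$loss
      trace$valid_loss[it] <- st$loss_valid
      if (it %% sch$eval_every == 0L || it == total)
        trace$valid_acc[it] <- rsnn_accuracy(net, sub_v$X, sub_v$y)
      if (it == sch$stage1_iters && is.null(net$arch$frozen_v)) {
        net$arch$frozen_v <- net$spec$V[which.max(softmax(av_bar))]
      }
    }
  })
  if (is.null(net$arch$frozen_v)) {
    p_v <- relax(net$arch)$p_v
    net$arch$frozen_v <- net$spec$V[which.max(p_v)]
  }
  arch_d <- discretize(net$arch, net$spec, net$w_rec)
  re <- retrain_and_eval(arch_d, ds_train, ds_test, cfg,
                         seed = child_seed(seed, 4))
  structure(list(architecture = arch_d, motif_size = arch_d$motif_size,
                 trace = trace, test_accuracy = re$accuracy,
                 retrained_net = re$net, search_net = net, seed = seed,
                 test_accesses = access_count(ds_test)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> motif size %d, test accuracy %.3f (seed %d)\n",
              x$motif_size, x$test_accuracy, x$seed))
  invisible(x)
}

#' Retrain a discrete architecture from scratch and evaluate it
#'
#' All weights are reinitialized (He-normal feedforward, `w_exc_init`
#' excitatory, fixed inhibitory), the network is trained on the full
#' training set under the fixed discrete architecture, and accuracy is
#' measured on the held-out test set.
#'
#' @param arch_d a discrete architecture ([discretize()] /
#'   [arch_from_json()]).
#' @param ds_train,ds_test datasets.
#' @param config configuration list.
#' @param seed RNG seed for reinitialization and batching.
#' @return List with `accuracy`, the retrained `net` and the one-hot
#'   `relaxed` probabilities used.
#' @export
retrain_and_eval <- function(arch_d, ds_train, ds_test, config = default_config(),
                             seed = 1) {
  cfg <- validate_config(config)
  nw <- cfg$network
  if (arch_d$n != nw$n_hidden) stop("architecture/layer size mismatch")
  ip_cfg <- cfg$ip
  ip_cfg$enabled <- isTRUE(ip_cfg$retrain)   # IP off in retraining by default
  net <- new_rsnn(nw$n_in, nw$n_hidden, nw$n_out, V = arch_d$motif_size,
                  tau_m = nw$tau_m, tau_syn = nw$tau_syn, v_th = nw$v_th,
                  v_th_out = nw$v_th_out %||% nw$v_th, tying = arch_d$tying,
                  w_exc_init = nw$w_exc_init, w_inh = nw$w_inh,
                  include_inter = nw$inter %||% TRUE,
                  ip = ip_cfg, seed = child_seed(seed, 1))
  relaxed <- onehot_relaxed(net$spec, 1L, arch_d$slot_types)
  fit <- train_weights(net, ds_train, epochs = cfg$schedule$finetune_epochs,
                       batch_size = cfg$training$batch_size, lr = cfg$training$lr,
                       relaxed = relaxed, mode = cfg$training$mode,
                       width = cfg$training$width,
                       surrogate = cfg$training$surrogate,
                       ip_on = isTRUE(ip_cfg$enabled),
                       seed = child_seed(seed, 2))
  acc <- evaluate_accuracy(fit$net, ds_test, relaxed = relaxed)
  list(accuracy = acc, net = fit$net, relaxed = relaxed,
       loss_trace = fit$loss_trace)
}

#' Random-search baseline over the same architecture space
#'
#' Samples discrete architectures uniformly (motif size from `V`, slot types
#' uniform over the three connection types), trains each briefly on the
#' training subset, keeps the best by validation accuracy, then retrains the
#' winner from scratch on the full training set and evaluates it once on the
#' test set.
#'
#' @inheritParams hrmas_search
#' @return Object of class `search_result` (with `trace = NULL`).
#' @export
random_search_baseline <- function(ds_train, ds_test, config = default_config(),
                                   seed = 1) {
  cfg <- validate_config(config)
  sch <- cfg$schedule
  ds_test <- attach_counter(ds_test)
  halves <- split_dataset(ds_train, 0.5, seed = child_seed(seed, 1))
  spec <- scml_spec(cfg$network$n_hidden, cfg$network$V,
                    tying = cfg$network$tying,
                    w_exc_init = cfg$network$w_exc_init,
                    w_inh = cfg$network$w_inh,
                    include_inter = cfg$network$inter %||% TRUE)
  best <- NULL
  for (j in seq_len(sch$random_archs)) {
    sd_j <- child_seed(seed, 10 + j)
    cand <- with_seed(sd_j, {
      k <- sample.int(length(spec$V), 1L)
      types <- sample.int(3L, spec$cand[[k]]$n_slots, replace = TRUE)
      list(k = k, types = types)
    })
    sub_spec <- scml_spec(spec$n, spec$V[cand$k], tying = spec$tying,
                          w_exc_init = spec$w_exc_init, w_inh = spec$w_inh,
                          include_inter = cfg$network$inter %||% TRUE)
    arch_d <- discretize_from_types(sub_spec, cand$types, spec$w_exc_init)
    cfg_j <- cfg
    cfg_j$ip$retrain <- FALSE
    cfg_j$schedule$finetune_epochs <- sch$random_train_epochs
    net <- new_rsnn(cfg$network$n_in, spec$n, cfg$network$n_out,
                    V = spec$V[cand$k], tau_m = cfg$network$tau_m,
                    tau_syn = cfg$network$tau_syn, v_th = cfg$network$v_th,
                    tying = spec$tying, w_exc_init = spec$w_exc_init,
                    w_inh = spec$w_inh,
                    include_inter = cfg$network$inter %||% TRUE,
                    seed = child_seed(sd_j, 1))
    relaxed <- onehot_relaxed(net$spec, 1L, cand$types)
    fit <- train_weights(net, halves$a, epochs = sch$random_train_epochs,
                         batch_size = cfg$training$batch_size,
                         lr = cfg$training$lr, relaxed = relaxed,
                         seed = child_seed(sd_j, 2))
    va <- rsnn_accuracy(fit$net, halves$b$X, halves$b$y, relaxed = relaxed)
    if (is.null(best) || va > best$va) best <- list(arch_d = arch_d, va = va)
  }
  re <- retrain_and_eval(best$arch_d, ds_train, ds_test, cfg,
                         seed = child_seed(seed, 4))
  structure(list(architecture = best$arch_d,
                 motif_size = best$arch_d$motif_size, trace = NULL,
                 test_accuracy = re$accuracy, retrained_net = re$net,
                 seed = seed, test_accesses = access_count(ds_test)),
            class = "search_result")
}

# Discrete architecture directly from slot types (no logits involved).
discretize_from_types <- function(spec, slot_types, w_exc) {
  cd <- spec$cand[[1L]]
  n <- spec$n
  pair_types <- slot_types[cd$slot]
  W <- matrix(0, n, n)
  W[cd$idx[pair_types == 1L]] <- w_exc
  W[cd$idx[pair_types == 2L]] <- spec$w_inh
  tm <- matrix("", n, n)
  tm[cd$idx] <- c("E", "I", "N")[pair_types]
  structure(list(motif_size = spec$V[1L], v_index = 1L,
                 slot_types = as.integer(slot_types), type_matrix = tm,
                 W = W, n = n, tying = spec$tying),
            class = "scml_arch")
}

#' Run an ablation variant of the search end-to-end
#'
#' Configurable switches mirroring the usual ablations of the method:
#' `"no_ip"` drops the intrinsic-plasticity step; `"no_motif"` removes the
#' motif structure (a single layer-sized motif, i.e. all pairwise
#' connection types are searched); `"no_inter_motif"` removes the
#' corresponding-neuron links between adjacent motifs; `"fully_connected"`
#' skips the search and trains a dense all-excitatory recurrent layer;
#' `"random"` runs the random-search baseline.
#'
#' @param mode one of `"no_ip"`, `"no_motif"`, `"no_inter_motif"`,
#'   `"fully_connected"`, `"random"`.
#' @inheritParams hrmas_search
#' @return A `search_result`.
#' @export
hrmas_ablate <- function(mode, ds_train, ds_test, config = default_config(),
                         seed = 1) {
  cfg <- validate_config(config)
  switch(mode,
    no_ip = {
      cfg$ip$enabled <- FALSE
      hrmas_search(ds_train, ds_test, cfg, seed)
    },
    no_motif = {
      cfg$network$V <- cfg$network$n_hidden
      hrmas_search(ds_train, ds_test, cfg, seed)
    },
    no_inter_motif = {
      cfg$network$inter <- FALSE
      hrmas_search(ds_train, ds_test, cfg, seed)
    },
    fully_connected = {
      spec <- scml_spec(cfg$network$n_hidden, cfg$network$n_hidden,
                        tying = "untied", w_exc_init = cfg$network$w_exc_init,
                        w_inh = cfg$network$w_inh)
      arch_d <- discretize_from_types(spec, rep(1L, spec$cand[[1L]]$n_slots),
                                      cfg$network$w_exc_init)
      ds_test <- attach_counter(ds_test)
      re <- retrain_and_eval(arch_d, ds_train, ds_test, cfg,
                             seed = child_seed(seed, 4))
      structure(list(architecture = arch_d, motif_size = arch_d$motif_size,
                     trace = NULL, test_accuracy = re$accuracy,
                     retrained_net = re$net, seed = seed,
                     test_accesses = access_count(ds_test)),
                class = "search_result")
    },
    random = random_search_baseline(ds_train, ds_test, cfg, seed),
    stop("unknown ablation mode: ", mode)
  )
}
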