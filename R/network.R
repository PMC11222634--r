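#' Construct a recurrent spiking network with one SC-ML hidden layer
#'
#' Input channels project feedforward (zero delay) onto a recurrent hidden
#' layer structured as a sparsely-connected motif layer; a purely
#' feedforward LIF output layer reads the hidden PSCs out. Feedforward
#' weights are He-normal initialized; candidate excitatory recurrent
#' weights start at `w_exc_init` and inhibitory candidates are fixed at
#' `w_inh`.
#'
#' @param n_in number of input channels.
#' @param n_hidden hidden-layer size; every motif-size option must divide it.
#' @param n_out number of output neurons (classes).
#' @param V motif-size options.
#' @param tau_m,tau_syn,v_th hidden-layer LIF constants.
#' @param v_th_out output-layer threshold (defaults to `v_th`).
#' @param tying,w_exc_init,w_inh,include_inter see [scml_spec()].
#' @param ip list of intrinsic-plasticity settings
#'   (`enabled`, `mu`, `tau_cal`, `gamma`, `tau_avg`, `r_gain`), or `NULL`.
#' @param seed RNG seed for the weight draw.
#' @return Object of class `rsnn`.
#' @export
new_rsnn <- function(n_in, n_hidden, n_out, V,
                     tau_m = 16, tau_syn = 8, v_th = 0.3, v_th_out = v_th,
                     tying = "shared_topology", w_exc_init = 0.2, w_inh = -2,
                     include_inter = TRUE, ip = NULL, seed = 1) {
  spec <- scml_spec(n_hidden, V, tying = tying,
                    w_exc_init = w_exc_init, w_inh = w_inh,
                    include_inter = include_inter)
  net <- with_seed(seed, {
    W_in <- matrix(stats::rnorm(n_hidden * n_in, 0, sqrt(2 / n_in)), n_hidden, n_in)
    W_out <- matrix(stats::rnorm(n_out * n_hidden, 0, sqrt(2 / n_hidden)), n_out, n_hidden)
    list(W_in = W_in, W_out = W_out)
  })
  net$w_rec <- spec$union_mask * w_exc_init
  net$spec <- spec
  net$n_in <- n_in
  net$n_out <- n_out
  net$prm_h <- neuron_params(tau_m, tau_syn, R = 1, v_th = v_th)
  net$prm_o <- neuron_params(tau_m, tau_syn, R = 1, v_th = v_th_out)
  net$arch <- arch_params(spec)
  net$ip <- ip
  net$ip_state <- if (!is.null(ip) && isTRUE(ip$enabled))
    ip_state(n_hidden, mu = ip$mu %||% 0.05, tau_cal = ip$tau_cal %||% 16,
             gamma = ip$gamma %||% 0.01, R0 = 1, tau0 = tau_m,
             tau_avg = ip$tau_avg %||% 64, r_gain = ip$r_gain %||% 0.1)
    else NULL
  structure(net, class = "rsnn")
}

# Reinitialize all weights of a network (fresh He-normal feedforward draws,
# excitatory recurrent weights back to w_exc_init), keeping spec and arch.
reinit_weights <- function(net, seed) {
  fresh <- with_seed(seed, {
    list(W_in = matrix(stats::rnorm(length(net$W_in), 0, sqrt(2 / net$n_in)),
                       nrow(net$W_in), ncol(net$W_in)),
         W_out = matrix(stats::rnorm(length(net$W_out), 0, sqrt(2 / net$spec$n)),
                        nrow(net$W_out), ncol(net$W_out)))
  })
  net$W_in <- fresh$W_in
  net$W_out <- fresh$W_out
  net$w_rec <- net$spec$union_mask * net$spec$w_exc_init
  if (!is.null(net$ip_state)) {
    ip <- net$ip
    net$ip_state <- ip_state(net$spec$n, mu = ip$mu %||% 0.05,
                             tau_cal = ip$tau_cal %||% 16,
                             gamma = ip$gamma %||% 0.01,
                             R0 = 1, tau0 = net$prm_h$tau_m,
                             tau_avg = ip$tau_avg %||% 64,
                             r_gain = ip$r_gain %||% 0.1)
  }
  net
}

mat_slice <- function(A, t) matrix(A[, , t], dim(A)[1L], dim(A)[2L])

#' Run the network forward over a spike batch
#'
#' Simulates the full network for all timesteps, retaining the histories
#' needed for backpropagation through time. Feedforward connections act
#' without delay; recurrent connections act with a one-step delay through
#' the mixed (softmax-relaxed) recurrent weight matrix. In `"hard"` mode
#' spikes are binary threshold crossings with reset; in `"smooth"` mode the
#' spike nonlinearity is replaced by a logistic of width `width`, making the
#' whole forward map differentiable (used by the gradient checks).
#'
#' @param net an [new_rsnn()] network.
#' @param X binary spike input, `batch x n_in x T` array.
#' @param relaxed relaxed architecture probabilities; default `relax(net$arch)`.
#' @param mode `"hard"` or `"smooth"`.
#' @param width surrogate / smoothing width.
#' @param ip_on adapt intrinsic parameters online during this run
#'   (requires `net$ip_state`).
#' @return List with per-timestep histories (`Um_h`, `S_h`, `A_h`, `Um_o`,
#'   `S_o`, `A_o` as lists of `batch x n` matrices), the input PSC `A_in`,
#'   the effective recurrent matrix `W_e`, per-step intrinsic parameters
#'   (`R_t`, `tau_t`, `n x T`) and the updated `ip_state`.
#' @export
rsnn_forward <- function(net, X, relaxed = NULL, mode = c("hard", "smooth"),
                         width = 0.5, ip_on = FALSE) {
  mode <- match.arg(mode)
  if (is.null(relaxed)) relaxed <- relax(net$arch)
  d <- dim(X)
  if (length(d) != 3L || d[2L] != net$n_in) stop("X must be batch x n_in x T")
  B <- d[1L]; Tt <- d[3L]
  n <- net$spec$n
  ph <- net$prm_h; po <- net$prm_o
  A_in <- psc_filter(X, ph$tau_syn)
  W_e <- w_eff(net$spec, relaxed, net$w_rec)
  tW_in <- t(net$W_in); tW_e <- t(W_e); tW_out <- t(net$W_out)
  lam_s <- 1 - 1 / ph$tau_syn
  lam_so <- 1 - 1 / po$tau_syn
  lam_mo <- 1 - 1 / po$tau_m

  ip <- if (ip_on) {
    if (is.null(net$ip_state)) stop("ip_on = TRUE but net has no ip_state")
    net$ip_state
  } else net$ip_state
  R_vec <- if (!is.null(ip)) ip$R else rep(ph$R, n)
  tau_vec <- if (!is.null(ip)) ip$tau else rep(ph$tau_m, n)

  Um_h <- S_h <- A_h <- vector("list", Tt)
  Um_o <- S_o <- A_o <- vector("list", Tt)
  R_t <- matrix(0, n, Tt); tau_t <- matrix(0, n, Tt)
  Uh <- matrix(0, B, n); Ah <- matrix(0, B, n)
  Uo <- matrix(0, B, net$n_out); Ao <- matrix(0, B, net$n_out)
  for (t in seq_len(Tt)) {
    R_t[, t] <- R_vec; tau_t[, t] <- tau_vec
    Ih <- mat_slice(A_in, t) %*% tW_in
    if (t > 1L) Ih <- Ih + A_h[[t - 1L]] %*% tW_e
    um <- Uh * rowb(1 - 1 / tau_vec, B) + Ih * rowb(R_vec / tau_vec, B)
    S <- if (mode == "hard") (um >= ph$v_th) * 1 else smooth_spike(um, ph$v_th, width)
    Uh <- um * (1 - S)
    Ah <- lam_s * Ah + S
    Um_h[[t]] <- um; S_h[[t]] <- S; A_h[[t]] <- Ah
    if (ip_on) {
      ip <- calcium_update(ip, colMeans(S))
      ip <- ip_step(ip, ph$v_th)
      R_vec <- ip$R; tau_vec <- ip$tau
    }
    Io <- Ah %*% tW_out
    umo <- lam_mo * Uo + (po$R / po$tau_m) * Io
    So <- if (mode == "hard") (umo >= po$v_th) * 1 else smooth_spike(umo, po$v_th, width)
    Uo <- umo * (1 - So)
    Ao <- lam_so * Ao + So
    Um_o[[t]] <- umo; S_o[[t]] <- So; A_o[[t]] <- Ao
  }
  list(Um_h = Um_h, S_h = S_h, A_h = A_h,
       Um_o = Um_o, S_o = S_o, A_o = A_o,
       A_in = A_in, W_e = W_e, R_t = R_t, tau_t = tau_t,
       B = B, Tt = Tt, mode = mode, width = width,
       ip_state = ip)
}

#' Run an SC-ML layer alone over a feedforward drive
#'
#' Simulates just the recurrent hidden layer: at each step the given
#' feedforward input current is combined with the one-step-delayed mixed
#' recurrent drive, and LIF + synapse dynamics are advanced.
#'
#' @param drive feedforward input current per neuron, `batch x n x T` array.
#' @param spec an [scml_spec()].
#' @param relaxed relaxed architecture probabilities.
#' @param w_rec `n x n` excitatory candidate weight matrix.
#' @param params a [neuron_params()] for the layer.
#' @param ip optional [ip_state()] adapted online while the layer runs.
#' @return List with spike and PSC histories (`S`, `A`, lists over time),
#'   per-step intrinsic parameters and the final `ip_state`.
#' @export
scml_forward <- function(drive, spec, relaxed, w_rec, params, ip = NULL) {
  d <- dim(drive)
  if (length(d) != 3L || d[2L] != spec$n) stop("drive must be batch x n x T")
  B <- d[1L]; Tt <- d[3L]; n <- spec$n
  W_e <- w_eff(spec, relaxed, w_rec); tW_e <- t(W_e)
  lam_s <- 1 - 1 / params$tau_syn
  R_vec <- if (!is.null(ip)) ip$R else rep(params$R, n)
  tau_vec <- if (!is.null(ip)) ip$tau else rep(params$tau_m, n)
  S_l <- A_l <- vector("list", Tt)
  U <- matrix(0, B, n); A <- matrix(0, B, n)
  for (t in seq_len(Tt)) {
    I <- mat_slice(drive, t)
    if (t > 1L) I <- I + A_l[[t - 1L]] %*% tW_e
    um <- U * rowb(1 - 1 / tau_vec, B) + I * rowb(R_vec / tau_vec, B)
    S <- (um >= params$v_th) * 1
    U <- um * (1 - S)
    A <- lam_s * A + S
    S_l[[t]] <- S; A_l[[t]] <- A
    if (!is.null(ip)) {
      ip <- calcium_update(ip, colMeans(S))
      ip <- ip_step(ip, params$v_th)
      R_vec <- ip$R; tau_vec <- ip$tau
    }
  }
  list(S = S_l, A = A_l, ip_state = ip)
}

# Accumulated output PSC per class: B x n_out matrix.
output_scores <- function(fwd) {
  Reduce(`+`, fwd$A_o)
}

#' Classify a spike batch and score accuracy
#'
#' Classification is the argmax over output neurons of the accumulated
#' output PSC.
#'
#' @param net an `rsnn`. @param X spike batch. @param y true labels.
#' @param relaxed optional relaxed architecture probabilities.
#' @return `rsnn_predict()`: integer labels; `rsnn_accuracy()`: fraction
#'   correct.
#' @export
rsnn_predict <- function(net, X, relaxed = NULL) {
  fwd <- rsnn_forward(net, X, relaxed = relaxed, mode = "hard")
  max.col(output_scores(fwd), ties.method = "first")
}

#' @rdname rsnn_predict
#' @export
rsnn_accuracy <- function(net, X, y, relaxed = NULL) {
  mean(rsnn_predict(net, X, relaxed) == y)
}
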