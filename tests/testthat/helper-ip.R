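# Scalar closed-loop LIF simulation with online intrinsic plasticity,
# vectorized over neurons so one run sweeps several drive amplitudes.
ip_closed_loop <- function(drive, steps = 20000, mu = 0.05, gamma = 0.01,
                           v_th = 1, ip_on = TRUE, seed = NULL,
                           jitter = 0) {
  n <- length(drive)
  st <- ip_state(n, mu = mu, gamma = gamma)
  u <- numeric(n)
  spikes <- matrix(0, steps, n)
  if (!is.null(seed)) set.seed(seed)
  for (t in seq_len(steps)) {
    x <- if (jitter > 0) drive * (1 + stats::rnorm(n, 0, jitter)) else drive
    um <- (1 - 1 / st$tau) * u + (st$R / st$tau) * x
    s <- as.numeric(um >= v_th)
    u <- um * (1 - s)
    st <- calcium_step(st, s)
    if (ip_on) st <- ip_step(st, v_th)
    spikes[t, ] <- s
  }
  colMeans(spikes[(steps / 2):steps, , drop = FALSE])
}
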