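# Internal numeric helpers shared across modules.

softmax <- function(x) {
  stopifnot(all(is.finite(x)))
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise softmax of a matrix of logits.
softmax_rows <- function(m) {
  stopifnot(all(is.finite(m)))
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# Vector-Jacobian product of softmax: gradient w.r.t. logits given gradient
# w.r.t. probabilities. Works row-wise when given matrices.
softmax_vjp <- function(p, gp) {
  p * (gp - sum(p * gp))
}

softmax_vjp_rows <- function(p, gp) {
  p * (gp - rowSums(p * gp))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Broadcast a length-n vector across B rows of a B x n matrix.
rowb <- function(v, B) matrix(v, nrow = B, ncol = length(v), byrow = TRUE)

is_binary <- function(s) all(s %in% c(0, 1))

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed; double arithmetic (exact below 2^53)
# keeps nested derivations free of integer overflow, result < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(k) * 12347) %% 2147480017)
}

# --- minimal Adam optimizer over a named list of numeric arrays -------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
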