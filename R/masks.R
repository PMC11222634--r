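#' Candidate connectivity masks of an SC-ML layer
#'
#' For each motif size `v` the layer admits two groups of candidate
#' recurrent connections: full within-motif connectivity (self-recurrent
#' connections included) and mutual links between corresponding neurons of
#' the two adjacent motifs, truncated at the layer edges (no wrap-around).
#' Masks are returned as `n x n` logical matrices indexed
#' `[postsynaptic i, presynaptic r]` (0-based neuron `i` sits in motif
#' `floor(i/v)`; its inter-motif partners are `r = i - v` and `r = i + v`).
#'
#' @param n layer size (neuron count).
#' @param V vector of motif-size options; every element must divide `n`.
#' @return Named list (one element per motif size) of lists with logical
#'   matrices `intra` and `inter`. The two masks are disjoint;
#'   `sum(intra) == (n/v) * v^2` and `sum(inter) == 2 * (n - v)`.
#' @export
build_candidate_masks <- function(n, V) {
  stopifnot(n >= 1, length(V) >= 1)
  out <- list()
  for (v in V) {
    if (v < 1 || n %% v != 0)
      stop(sprintf("motif size %s does not divide layer size %s", v, n))
    idx <- 0:(n - 1)
    motif <- idx %/% v
    intra <- outer(motif, motif, `==`)
    inter <- outer(idx, idx, function(i, r) abs(i - r) == v & ((i - r) %% v == 0))
    # corresponding-neuron rule: offset exactly +/- v, so (i - r) %% v == 0
    # is implied; kept explicit for clarity.
    dimnames(intra) <- dimnames(inter) <- NULL
    out[[as.character(v)]] <- list(intra = intra, inter = inter)
  }
  out
}

#' Candidate-slot counts of an SC-ML layer
#'
#' Closed-form counts of the candidate recurrent slots at motif size `v`:
#' `(n/v) * v^2` intra-motif plus `2 * (n - v)` inter-motif directed pairs,
#' which grows linearly in `n` at fixed `v` (against `n^2` for a dense
#' recurrent matrix).
#'
#' @param n layer size.
#' @param v motif size (must divide `n`).
#' @return List with elements `intra`, `inter`, `total` and `dense`
#'   (`n^2`, for reference).
#' @export
parameter_count <- function(n, v) {
  if (n %% v != 0) stop(sprintf("motif size %s does not divide layer size %s", v, n))
  intra <- (n / v) * v^2
  inter <- 2 * (n - v)
  list(intra = intra, inter = inter, total = intra + inter, dense = n^2)
}

# Slot-index table for one motif size. In the default "shared_topology"
# tying, architecture logits are shared across motifs by relative position:
# intra slot (i mod v, r mod v), inter slots one per direction (+v / -v), so
# the searched topology is a single motif template. "untied" gives every
# candidate pair its own logit row.
slot_table <- function(n, v, tying, include_inter = TRUE) {
  m <- build_candidate_masks(n, v)[[1L]]
  if (!include_inter) m$inter[] <- FALSE
  un <- m$intra | m$inter
  idx <- which(un)
  i0 <- (idx - 1L) %% n        # 0-based postsynaptic index
  r0 <- (idx - 1L) %/% n       # 0-based presynaptic index
  if (tying == "shared_topology") {
    slot <- integer(length(idx))
    intra_sel <- m$intra[idx]
    slot[intra_sel] <- (i0[intra_sel] %% v) * v + (r0[intra_sel] %% v) + 1L
    slot[!intra_sel] <- ifelse(r0[!intra_sel] < i0[!intra_sel], v^2 + 1L, v^2 + 2L)
    n_slots <- if (n > v && include_inter) v^2 + 2L else v^2
  } else {
    slot <- seq_along(idx)
    n_slots <- length(idx)
  }
  list(idx = idx, slot = as.integer(slot), n_slots = as.integer(n_slots),
       intra = m$intra, inter = m$inter)
}

#' SC-ML layer specification
#'
#' Describes the search space of one sparsely-connected recurrent motif
#' layer: layer size, motif-size options, connection-type set (excitatory /
#' inhibitory / non-existent), the candidate masks per option and the
#' parameter-tying mode of the architecture logits.
#'
#' @param n layer size; every motif-size option must divide it.
#' @param V ordered vector of motif-size options.
#' @param tying `"shared_topology"` (logits tied across motifs by relative
#'   position, the default) or `"untied"` (one logit row per candidate pair).
#' @param w_exc_init initial excitatory weight (trainable).
#' @param w_inh fixed inhibitory weight (negative, never trained).
#' @param include_inter keep the inter-motif candidate links (`FALSE` is the
#'   "no inter-motif connections" ablation).
#' @return An object of class `scml_spec`.
#' @export
scml_spec <- function(n, V, tying = c("shared_topology", "untied"),
                      w_exc_init = 0.2, w_inh = -2, include_inter = TRUE) {
  tying <- match.arg(tying)
  if (w_inh >= 0) stop("inhibitory weight must be negative")
  masks <- build_candidate_masks(n, V)   # validates divisibility
  if (!include_inter)
    masks <- lapply(masks, function(m) { m$inter[] <- FALSE; m })
  cand <- lapply(V, function(v) slot_table(n, v, tying, include_inter))
  names(cand) <- as.character(V)
  union_mask <- Reduce(`|`, lapply(masks, function(m) m$intra | m$inter))
  structure(list(n = n, V = V, tying = tying,
                 w_exc_init = w_exc_init, w_inh = w_inh,
                 masks = masks, cand = cand, union_mask = union_mask,
                 types = c("exc", "inh", "none")),
            class = "scml_spec")
}
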