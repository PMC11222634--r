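#' Architecture parameters (logits) of an SC-ML layer
#'
#' Raw logits for the categorical architecture choices: one logit per
#' motif-size option and, for every option, one row of three logits
#' (excitatory / inhibitory / none) per candidate slot. All logits start at
#' zero, i.e. uniform selection probabilities.
#'
#' The inhibitory logit starts at `log(w_exc_init / |w_inh|)` rather than
#' zero, so each slot's initial expected weight
#' `p_exc * w_exc + p_inh * w_inh` is exactly zero: at the start of a search
#' no motif-size option carries a net excitatory or inhibitory load, and the
#' early motif-size gradients reflect fit rather than total drive.
#'
#' @param spec an [scml_spec()].
#' @return Object of class `arch_params` with fields `alpha_v`, `alpha_c`
#'   (list of `n_slots x 3` matrices, one per motif size) and `frozen_v`
#'   (`NULL` until the motif size is committed).
#' @export
arch_params <- function(spec) {
  inh0 <- log(spec$w_exc_init / abs(spec$w_inh))
  alpha_c <- lapply(spec$cand, function(cd) {
    m <- matrix(0, cd$n_slots, 3L, dimnames = list(NULL, spec$types))
    m[, 2L] <- inh0
    m
  })
  structure(list(alpha_v = stats::setNames(numeric(length(spec$V)),
                                           as.character(spec$V)),
                 alpha_c = alpha_c,
                 frozen_v = NULL),
            class = "arch_params")
}

#' Relax architecture logits to selection probabilities
#'
#' Softmax over the motif-size logits and, independently, over each slot's
#' connection-type logits. Each simplex sums to one; the values can be read
#' as the probability of selecting the option. When the motif size is
#' frozen, its distribution is the exact one-hot vector.
#'
#' @param arch an [arch_params()] object.
#' @return List with `p_v` (probabilities per motif size) and `p_c`
#'   (list of `n_slots x 3` probability matrices).
#' @export
relax <- function(arch) {
  if (!is.null(arch$frozen_v)) {
    p_v <- stats::setNames(as.numeric(names(arch$alpha_v) == as.character(arch$frozen_v)),
                           names(arch$alpha_v))
  } else {
    p_v <- softmax(arch$alpha_v)
  }
  list(p_v = p_v, p_c = lapply(arch$alpha_c, softmax_rows))
}

# Exact one-hot relaxation: motif size v_index selected with probability
# exactly 1, and each slot's type given by `types` (integer codes 1 = exc,
# 2 = inh, 3 = none per slot). Used for mixture/discrete equivalence and to
# run discrete architectures through the mixture forward pass bit-for-bit.
onehot_relaxed <- function(spec, v_index, types) {
  p_v <- stats::setNames(numeric(length(spec$V)), as.character(spec$V))
  p_v[v_index] <- 1
  p_c <- lapply(seq_along(spec$V), function(k) {
    cd <- spec$cand[[k]]
    m <- matrix(0, cd$n_slots, 3L, dimnames = list(NULL, spec$types))
    if (k == v_index) {
      stopifnot(length(types) == cd$n_slots)
      m[cbind(seq_len(cd$n_slots), types)] <- 1
    } else {
      m[, 3L] <- 1   # unselected options: all "none"; weight is zero anyway
    }
    m
  })
  names(p_c) <- as.character(spec$V)
  list(p_v = p_v, p_c = p_c)
}

# Mixture recurrent weight matrix: for each motif size v, the per-slot mix
# of excitatory (trainable) and inhibitory (fixed) weights, combined over
# motif sizes with the motif-size probabilities.
w_eff <- function(spec, relaxed, w_rec) {
  n <- spec$n
  W <- matrix(0, n, n)
  for (k in seq_along(spec$V)) {
    pv <- relaxed$p_v[[k]]
    if (pv == 0) next
    cd <- spec$cand[[k]]
    P <- relaxed$p_c[[k]]
    W[cd$idx] <- W[cd$idx] +
      pv * (P[cd$slot, 1L] * w_rec[cd$idx] + P[cd$slot, 2L] * spec$w_inh)
  }
  W
}

#' Mixed recurrent drive of an SC-ML layer
#'
#' Input current contributed by the layer's own previous-step PSC through
#' all candidate connections, weighted by the relaxed architecture
#' probabilities: for neuron `i`,
#' `sum_v p_v * sum_(r in I_i^v) sum_c p_c[i,r] * w_c[i,r] * a_r[t-1]`.
#' Recurrent links carry a one-step delay, so `a_prev` is the PSC of the
#' previous timestep.
#'
#' @param relaxed relaxed probabilities from [relax()].
#' @param w_rec `n x n` matrix of excitatory candidate weights.
#' @param a_prev layer PSC at the previous step: vector of length `n` or a
#'   `batch x n` matrix.
#' @param spec an [scml_spec()].
#' @return Drive with the shape of `a_prev`.
#' @export
recurrent_drive <- function(relaxed, w_rec, a_prev, spec) {
  W <- w_eff(spec, relaxed, w_rec)
  if (is.matrix(a_prev)) {
    if (ncol(a_prev) != spec$n) stop("a_prev has wrong number of columns")
    a_prev %*% t(W)
  } else {
    if (length(a_prev) != spec$n) stop("a_prev has wrong length")
    drop(W %*% a_prev)
  }
}

#' Commit the relaxed architecture to a discrete one
#'
#' Picks the motif size with the highest selection probability (or the
#' frozen one) and, for every candidate slot of that size, the
#' highest-probability connection type. Exact ties resolve to the
#' lowest-index option. Returns the explicit sparse recurrent weight matrix
#' (excitatory entries carry the current trainable weight, inhibitory the
#' fixed negative weight).
#'
#' @param arch an [arch_params()] object.
#' @param spec an [scml_spec()].
#' @param w_rec `n x n` excitatory weight matrix.
#' @return Object of class `scml_arch`: list with `motif_size`,
#'   `slot_types` (integer per slot, 1 = exc / 2 = inh / 3 = none),
#'   `type_matrix` (`n x n` character, `""` off-candidate), `W` (discrete
#'   recurrent matrix) and `tying`.
#' @export
discretize <- function(arch, spec, w_rec) {
  relaxed <- relax(arch)
  k <- if (!is.null(arch$frozen_v)) which(spec$V == arch$frozen_v)
       else which.max(relaxed$p_v)
  v <- spec$V[k]
  P <- relaxed$p_c[[k]]
  slot_types <- apply(P, 1L, which.max)   # which.max: lowest index on ties
  cd <- spec$cand[[k]]
  pair_types <- slot_types[cd$slot]
  n <- spec$n
  W <- matrix(0, n, n)
  W[cd$idx[pair_types == 1L]] <- w_rec[cd$idx[pair_types == 1L]]
  W[cd$idx[pair_types == 2L]] <- spec$w_inh
  tm <- matrix("", n, n)
  tm[cd$idx] <- c("E", "I", "N")[pair_types]
  structure(list(motif_size = v, v_index = k, slot_types = as.integer(slot_types),
                 type_matrix = tm, W = W, n = n, tying = spec$tying),
            class = "scml_arch")
}

#' Export / import a discrete architecture as JSON
#'
#' The document records the layer size, chosen motif size, the motif
#' template (`v x v` matrix of `"E"`/`"I"`/`"N"` for tied topologies, or the
#' full per-pair type triplets when untied), the inter-motif type
#' assignments and the nonzero recurrent weights as sparse triplets.
#' Round-trips are lossless.
#'
#' @param arch_d an [discretize()] result.
#' @param path file path; when `NULL`, the JSON string is returned.
#' @return `arch_to_json()`: the path (or JSON string); `arch_from_json()`:
#'   an object of class `scml_arch`.
#' @export
arch_to_json <- function(arch_d, path = NULL) {
  n <- arch_d$n
  v <- arch_d$motif_size
  nz <- which(arch_d$W != 0)
  doc <- list(
    n = n,
    motif_size = v,
    tying = arch_d$tying,
    slot_types = arch_d$slot_types,
    weight_triplets = list(
      i = as.integer((nz - 1L) %% n),        # 0-based postsynaptic
      r = as.integer((nz - 1L) %/% n),       # 0-based presynaptic
      w = as.numeric(arch_d$W[nz])
    )
  )
  if (arch_d$tying == "shared_topology") {
    st <- arch_d$slot_types
    doc$intra_type_matrix <- matrix(c("E", "I", "N")[st[seq_len(v * v)]], v, v)
    doc$inter_type_assignments <- if (length(st) > v * v)
      c("E", "I", "N")[st[v * v + 1:2]] else character(0)
  }
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname arch_to_json
#' @param json a path to a JSON file, or a JSON string.
#' @export
arch_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  n <- doc$n
  W <- matrix(0, n, n)
  tr <- doc$weight_triplets
  W[cbind(tr$i + 1L, tr$r + 1L)] <- tr$w
  cd <- slot_table(n, doc$motif_size, doc$tying)
  pair_types <- as.integer(doc$slot_types)[cd$slot]
  tm <- matrix("", n, n)
  tm[cd$idx] <- c("E", "I", "N")[pair_types]
  structure(list(motif_size = doc$motif_size,
                 v_index = NA_integer_,
                 slot_types = as.integer(doc$slot_types),
                 type_matrix = tm, W = W, n = n, tying = doc$tying),
            class = "scml_arch")
}
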