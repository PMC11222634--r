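#' Spike-train dataset container
#'
#' A labelled set of binary spike tensors: `X` is `samples x channels x T`
#' with entries in `{0, 1}`, `y` holds integer class labels, and `meta`
#' records the generator and its parameters, so a dataset is fully
#' determined by `(parameters, seed)`.
#'
#' @param X binary array `S x C x T`. @param y integer labels.
#' @param meta named list of generator metadata.
#' @return Object of class `spike_dataset`.
#' @export
spike_dataset <- function(X, y, meta = list()) {
  stopifnot(length(dim(X)) == 3L, dim(X)[1L] == length(y))
  if (!all(X %in% c(0, 1))) stop("X must be binary")
  structure(list(X = X, y = as.integer(y), meta = meta),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<spike_dataset> %d samples x %d channels x %d steps, %d classes (%s)\n",
              d[1L], d[2L], d[3L], length(unique(x$y)),
              x$meta$generator %||% "unknown generator"))
  invisible(x)
}

# Access-counted views used to assert protocol hygiene (the held-out test
# set must be read exactly once, after all search decisions).
attach_counter <- function(ds) {
  attr(ds, "access") <- new.env(parent = emptyenv())
  attr(ds, "access")$n <- 0L
  ds
}

access_count <- function(ds) {
  a <- attr(ds, "access")
  if (is.null(a)) NA_integer_ else a$n
}

ds_X <- function(ds) {
  a <- attr(ds, "access")
  if (!is.null(a)) a$n <- a$n + 1L
  ds$X
}

ds_y <- function(ds) ds$y

#' Jittered spatiotemporal pattern task
#'
#' Draws one random spatiotemporal spike template per class and emits
#' samples as the template with Gaussian time-jitter (rounded and clipped to
#' the simulation window) plus optional Poisson background noise. With zero
#' jitter and zero noise every sample equals its class template exactly.
#'
#' @param n_classes number of classes.
#' @param n_in number of input channels.
#' @param T_steps timesteps per sample.
#' @param spikes_per_template spikes in each class template (at most
#'   `n_in * T_steps`).
#' @param jitter_sd standard deviation of the time-jitter (steps).
#' @param n_per_class samples per class.
#' @param noise_rate probability of a background spike per (channel, step).
#' @param timing_only make all class templates share one channel multiset so
#'   that only spike *timing* separates the classes; channel-count profiles
#'   are then uninformative and classification genuinely degrades with
#'   jitter. With the default (`FALSE`) each class draws its own
#'   channel-time template.
#' @param seed RNG seed; the dataset is a pure function of the arguments.
#' @return A [spike_dataset()].
#' @export
make_pattern_task <- function(n_classes = 2, n_in = 16, T_steps = 50,
                              spikes_per_template = 40, jitter_sd = 2,
                              n_per_class = 50, noise_rate = 0,
                              timing_only = FALSE, seed = 1) {
  stopifnot(n_classes >= 1, n_in >= 1, T_steps >= 1, n_per_class >= 1,
            jitter_sd >= 0, noise_rate >= 0, noise_rate <= 1)
  if (spikes_per_template > n_in * T_steps)
    stop("spikes_per_template exceeds the n_in * T capacity")
  S <- n_classes * n_per_class
  with_seed(seed, {
    # round-robin channel assignment: every channel carries the same number
    # of template spikes, so channel counts are uninformative by construction
    shared_ch <- rep(seq_len(n_in), length.out = spikes_per_template)
    templates <- lapply(seq_len(n_classes), function(k) {
      if (timing_only) {
        cbind(ch = shared_ch,
              t = sample.int(T_steps, spikes_per_template, replace = TRUE))
      } else {
        pos <- sample.int(n_in * T_steps, spikes_per_template)
        cbind(ch = (pos - 1L) %% n_in + 1L, t = (pos - 1L) %/% n_in + 1L)
      }
    })
    X <- array(0, c(S, n_in, T_steps))
    y <- rep(seq_len(n_classes), each = n_per_class)
    for (b in seq_len(S)) {
      tpl <- templates[[y[b]]]
      tj <- tpl[, "t"]
      if (jitter_sd > 0)
        tj <- pmin(pmax(round(tj + stats::rnorm(nrow(tpl), 0, jitter_sd)), 1L), T_steps)
      X[cbind(b, tpl[, "ch"], tj)] <- 1
      if (noise_rate > 0) {
        noise <- matrix(stats::runif(n_in * T_steps) < noise_rate, n_in, T_steps)
        X[b, , ][noise] <- 1
      }
    }
    spike_dataset(X, y, meta = list(
      generator = "pattern", n_classes = n_classes, n_in = n_in,
      T_steps = T_steps, spikes_per_template = spikes_per_template,
      jitter_sd = jitter_sd, n_per_class = n_per_class,
      noise_rate = noise_rate, timing_only = timing_only, seed = seed))
  })
}

#' Teacher-network task with a planted motif size
#'
#' Builds a random discrete SC-ML network (the "teacher") whose hidden layer
#' uses the requested motif size, drives it with random Poisson input
#' spikes, and labels each sample by the teacher's readout argmax. The
#' teacher's architecture is therefore the ground truth an architecture
#' search should recover. Draws whose label distribution is degenerate (any
#' class below 10% prevalence) are rejected and redrawn.
#'
#' @param n_in,T_steps input geometry.
#' @param n_hidden teacher hidden-layer size.
#' @param motif_size_star planted motif size (must divide `n_hidden`).
#' @param n_classes number of classes (teacher readout size).
#' @param n_samples total samples.
#' @param input_rate Poisson spike probability per (channel, step).
#' @param type_probs sampling probabilities of (excitatory, inhibitory,
#'   none) for each candidate slot of the teacher motif.
#' @param seed RNG seed.
#' @param max_redraws redraw budget before giving up.
#' @return A [spike_dataset()]; the teacher network and its relaxed
#'   (one-hot) architecture are attached as attributes `teacher` and
#'   `teacher_relaxed`.
#' @export
make_teacher_task <- function(n_in = 16, n_hidden = 16, motif_size_star = 8,
                              T_steps = 50, n_classes = 2, n_samples = 200,
                              input_rate = 0.1, type_probs = c(0.55, 0.2, 0.25),
                              seed = 1, max_redraws = 20) {
  if (n_hidden %% motif_size_star != 0)
    stop("motif_size_star must divide n_hidden")
  for (attempt in seq_len(max_redraws)) {
    sd_a <- child_seed(seed, attempt)
    teacher <- new_rsnn(n_in, n_hidden, n_classes, V = motif_size_star,
                        v_th = 0.3, seed = sd_a)
    drawn <- with_seed(sd_a + 1L, {
      cd <- teacher$spec$cand[[1L]]
      types <- sample.int(3L, cd$n_slots, replace = TRUE, prob = type_probs)
      w <- teacher$w_rec
      w[w != 0] <- stats::runif(sum(w != 0), 0.1, 0.5)
      X <- array(as.numeric(stats::runif(n_samples * n_in * T_steps) < input_rate),
                 c(n_samples, n_in, T_steps))
      list(types = types, w = w, X = X)
    })
    teacher$w_rec <- drawn$w
    relaxed <- onehot_relaxed(teacher$spec, 1L, drawn$types)
    y <- rsnn_predict(teacher, drawn$X, relaxed = relaxed)
    prev <- tabulate(y, n_classes) / n_samples
    if (all(prev >= 0.1)) {
      ds <- spike_dataset(drawn$X, y, meta = list(
        generator = "teacher", n_in = n_in, n_hidden = n_hidden,
        motif_size_star = motif_size_star, T_steps = T_steps,
        n_classes = n_classes, n_samples = n_samples,
        input_rate = input_rate, seed = seed, attempt = attempt))
      attr(ds, "teacher") <- teacher
      attr(ds, "teacher_relaxed") <- relaxed
      return(ds)
    }
  }
  stop(sprintf("teacher task degenerate after %d redraws", max_redraws))
}

#' Stratified split of a spike dataset
#'
#' Deterministic under `seed`; the two halves are disjoint and their union
#' is the original multiset. Used both for the train/validation split of
#' the search and for carving out held-out test sets.
#'
#' @param ds a [spike_dataset()].
#' @param frac fraction of each class assigned to the first half.
#' @param seed RNG seed.
#' @param stratified split within each class (requires every class to hold
#'   at least 2 samples).
#' @return List with `spike_dataset` elements `a` and `b`.
#' @export
split_dataset <- function(ds, frac = 0.5, seed = 1, stratified = TRUE) {
  S <- length(ds$y)
  if (S < 2L) stop("dataset must contain at least 2 samples")
  idx_a <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(unique(ds$y), function(k) {
        idx <- which(ds$y == k)
        if (length(idx) < 2L)
          stop(sprintf("class %d has fewer than 2 samples; cannot stratify", k))
        sample(idx, round(length(idx) * frac))
      }))
    } else sample.int(S, round(S * frac))
  })
  idx_a <- sort(idx_a)
  idx_b <- setdiff(seq_len(S), idx_a)
  subset_ds <- function(idx) {
    spike_dataset(ds$X[idx, , , drop = FALSE], ds$y[idx],
                  meta = c(ds$meta, list(subset_of = ds$meta$generator %||% "dataset")))
  }
  list(a = subset_ds(idx_a), b = subset_ds(idx_b))
}
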