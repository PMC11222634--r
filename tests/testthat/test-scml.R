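# Brute-force enumeration of the candidate index rules, independent of the
# package implementation: same motif for intra, offset exactly +/- v for inter.
brute_pairs <- function(n, v) {
  pairs_intra <- pairs_inter <- matrix(0L, 0, 2)
  for (i in 0:(n - 1)) for (r in 0:(n - 1)) {
    if (i %/% v == r %/% v) pairs_intra <- rbind(pairs_intra, c(i, r))
    else if (r == i - v || r == i + v) pairs_inter <- rbind(pairs_inter, c(i, r))
  }
  list(intra = pairs_intra, inter = pairs_inter)
}

test_that("candidate masks match brute-force enumeration on the 4-neuron example", {
  m <- build_candidate_masks(4, 2)[["2"]]
  intra_pairs <- which(m$intra, arr.ind = TRUE) - 1L
  inter_pairs <- which(m$inter, arr.ind = TRUE) - 1L
  expected_intra <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1),
                          c(2, 2), c(2, 3), c(3, 2), c(3, 3))
  expected_inter <- rbind(c(0, 2), c(1, 3), c(2, 0), c(3, 1))
  sort_pairs <- function(p) p[order(p[, 1], p[, 2]), , drop = FALSE]
  expect_equal(sort_pairs(unname(cbind(intra_pairs[, "row"], intra_pairs[, "col"]))),
               expected_intra)
  expect_equal(sort_pairs(unname(cbind(inter_pairs[, "row"], inter_pairs[, "col"]))),
               expected_inter)
})

test_that("slot counts equal closed forms and mask popcounts across a grid", {
  grid <- list(c(4, 2), c(12, 3), c(16, 8), c(16, 16), c(24, 4), c(800, 2))
  for (g in grid) {
    n <- g[1]; v <- g[2]
    m <- build_candidate_masks(n, v)[[1]]
    bp <- brute_pairs(n, v)
    pc <- parameter_count(n, v)
    expect_equal(sum(m$intra), nrow(bp$intra))
    expect_equal(sum(m$inter), nrow(bp$inter))
    expect_equal(pc$intra, (n / v) * v^2)
    expect_equal(pc$inter, 2 * (n - v))
    expect_equal(pc$intra, sum(m$intra))
    expect_equal(pc$inter, sum(m$inter))
    expect_false(any(m$intra & m$inter))  # masks disjoint
  }
  # single motif: no neighbour exists
  expect_equal(sum(build_candidate_masks(8, 8)[[1]]$inter), 0)
  expect_equal(parameter_count(8, 8)$total, 64)  # n^2: dense limit
  expect_error(build_candidate_masks(10, 3), "divide")
})

test_that("candidate slots grow linearly in layer size at fixed motif size", {
  v <- 4
  base <- parameter_count(16, v)
  for (k in c(2, 5, 10)) {
    pk <- parameter_count(16 * k, v)
    expect_equal(pk$intra, k * base$intra)
    expect_equal(pk$inter, 2 * (16 * k - v))
    expect_lt(pk$total, pk$dense)
  }
})

test_that("softmax relaxation lands on the simplex with known closed forms", {
  spec <- scml_spec(8, c(2, 4, 8))
  arch <- arch_params(spec)
  # five zero logits -> uniform
  arch5 <- arch
  arch5$alpha_v <- stats::setNames(numeric(5), 1:5)
  expect_equal(unname(relax(arch5)$p_v), rep(0.2, 5))
  # logits (ln 2, 0) -> (2/3, 1/3)
  arch$alpha_v[] <- c(log(2), 0, 0)
  p <- relax(arch)$p_v
  expect_equal(unname(p[1] / p[2]), 2)
  # any logits: every simplex sums to 1
  arch <- with_seed(5, {
    arch$alpha_v[] <- stats::rnorm(3, 0, 3)
    for (nm in names(arch$alpha_c))
      arch$alpha_c[[nm]][] <- stats::rnorm(length(arch$alpha_c[[nm]]), 0, 3)
    arch
  })
  rel <- relax(arch)
  expect_equal(sum(rel$p_v), 1, tolerance = 1e-12)
  for (P in rel$p_c)
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
})

test_that("recurrent drive is linear, silent for 'none', and matches Eq-level toy", {
  spec <- scml_spec(4, 2)
  cd <- spec$cand[[1]]
  w_rec <- spec$union_mask * 0.2
  # zero PSC in, zero drive out
  rel_any <- onehot_relaxed(spec, 1, rep(1L, cd$n_slots))
  expect_equal(recurrent_drive(rel_any, w_rec, numeric(4), spec), numeric(4))
  # all types "none": non-existence contributes nothing
  rel_none <- onehot_relaxed(spec, 1, rep(3L, cd$n_slots))
  expect_equal(recurrent_drive(rel_none, w_rec, rep(1, 4), spec), numeric(4))
  # single excitatory slot i=0 <- r=1 (tied slot (0 mod 2, 1 mod 2) = slot 3... )
  # use untied tying for an unambiguous single pair
  spec_u <- scml_spec(4, 2, tying = "untied")
  cd_u <- spec_u$cand[[1]]
  types <- rep(3L, cd_u$n_slots)
  # pair (i = 0, r = 1) zero-based sits at matrix position [1, 2]
  types[which(cd_u$idx == (2 - 1) * 4 + 1)] <- 1L
  rel_one <- onehot_relaxed(spec_u, 1, types)
  a_prev <- c(0, 1, 0, 0)
  drive <- recurrent_drive(rel_one, spec_u$union_mask * 0.2, a_prev, spec_u)
  expect_equal(drive, c(0.2, 0, 0, 0))
})

test_that("discretization is idempotent, argmax-correct and tie-breaks low", {
  spec <- scml_spec(6, c(2, 3))
  arch <- arch_params(spec)
  arch$alpha_v[] <- c(log(0.5), log(0.3))  # p = (0.625, 0.375)
  d <- discretize(arch, spec, spec$union_mask * 0.2)
  expect_equal(d$motif_size, 2)
  # exact tie resolves to the lowest-index option
  arch$alpha_v[] <- c(0, 0)
  expect_equal(discretize(arch, spec, spec$union_mask * 0.2)$motif_size, 2)
  # one-hot relaxation reproduces the discrete architecture exactly
  types <- with_seed(9, sample.int(3, spec$cand[[2]]$n_slots, replace = TRUE))
  arch2 <- arch_params(spec)
  arch2$frozen_v <- 3
  arch2$alpha_c[["3"]] <- matrix(-40, spec$cand[[2]]$n_slots, 3)
  arch2$alpha_c[["3"]][cbind(seq_along(types), types)] <- 40
  d2 <- discretize(arch2, spec, spec$union_mask * 0.2)
  expect_equal(d2$slot_types, types)
  d3 <- discretize(arch2, spec, spec$union_mask * 0.2)
  expect_identical(d2$W, d3$W)  # idempotent
})

test_that("discretized recurrent matrix is band-limited to |i-r| < 2v", {
  for (cfg in list(c(16, 2), c(16, 4), c(24, 3))) {
    n <- cfg[1]; v <- cfg[2]
    spec <- scml_spec(n, v)
    arch <- arch_params(spec)
    arch <- with_seed(n + v, {
      arch$alpha_c[[1]][] <- stats::rnorm(length(arch$alpha_c[[1]]))
      arch
    })
    W <- discretize(arch, spec, spec$union_mask * 0.2)$W
    off <- abs(row(W) - col(W))
    expect_true(all(W[off >= 2 * v] == 0))
  }
})

test_that("architecture JSON export round-trips losslessly", {
  for (tying in c("shared_topology", "untied")) {
    spec <- scml_spec(8, c(2, 4), tying = tying)
    arch <- arch_params(spec)
    arch <- with_seed(21, {
      arch$alpha_v[] <- stats::rnorm(2)
      for (nm in names(arch$alpha_c))
        arch$alpha_c[[nm]][] <- stats::rnorm(length(arch$alpha_c[[nm]]))
      arch
    })
    w_rec <- spec$union_mask * 0.2
    d <- discretize(arch, spec, w_rec)
    path <- tempfile(fileext = ".json")
    on.exit(unlink(path), add = TRUE)
    arch_to_json(d, path)
    d2 <- arch_from_json(path)
    expect_identical(d2$W, d$W)
    expect_identical(d2$slot_types, d$slot_types)
    expect_identical(d2$type_matrix, d$type_matrix)
    expect_equal(d2$motif_size, d$motif_size)
  }
})

test_that("one-hot mixture forward equals independently assembled discrete forward", {
  for (seed in 1:3) {
    net <- toy_net(n_in = 3, n_hidden = 8, n_out = 2, V = c(2, 4),
                   seed = seed)
    d <- discretize(net$arch, net$spec, net$w_rec)
    rel <- onehot_relaxed(net$spec, d$v_index, d$slot_types)
    # the mixture's effective matrix must equal the discrete assembly exactly
    expect_identical(w_eff(net$spec, rel, net$w_rec), d$W)
    b <- toy_batch(B = 2, n_in = 3, Tt = 12, seed = 30 + seed)
    fwd <- rsnn_forward(net, b$X, relaxed = rel, mode = "hard")
    ref <- reference_discrete_forward(net, b$X, d$W)
    expect_identical(fwd$S_h, ref$S_h)
    expect_identical(fwd$A_o, ref$A_o)
  }
})
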