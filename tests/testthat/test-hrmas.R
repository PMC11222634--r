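small_cfg <- function(...) {
  cfg <- default_config()
  cfg$network$n_in <- 8L; cfg$network$n_hidden <- 8L
  cfg$network$V <- c(2L, 4L)
  cfg$training$T_steps <- 30L
  cfg$schedule$warmup_iters <- 3L
  cfg$schedule$stage1_iters <- 6L
  cfg$schedule$stage2_iters <- 4L
  cfg$schedule$finetune_epochs <- 4L
  cfg$schedule$random_archs <- 2L
  cfg$schedule$random_train_epochs <- 2L
  upd <- list(...)
  for (blk in names(upd)) cfg[[blk]][names(upd[[blk]])] <- upd[[blk]]
  cfg
}

small_task <- function(seed = 201, n_per_class = 20) {
  ds <- make_pattern_task(n_classes = 2, n_in = 8, T_steps = 30,
                          spikes_per_template = 20, jitter_sd = 2,
                          n_per_class = n_per_class, seed = seed)
  split_dataset(ds, 0.5, seed = seed + 1)
}

test_that("search runs end-to-end, touches the test set exactly once, and is reproducible", {
  sp <- small_task()
  cfg <- small_cfg()
  r1 <- hrmas_search(sp$a, sp$b, cfg, seed = 11)
  expect_s3_class(r1, "search_result")
  expect_true(r1$motif_size %in% cfg$network$V)
  expect_equal(r1$test_accesses, 1L)   # protocol hygiene
  expect_equal(nrow(r1$trace), 10)
  expect_true(all(is.finite(r1$trace$train_loss)))
  r2 <- hrmas_search(sp$a, sp$b, cfg, seed = 11)
  expect_identical(r1$motif_size, r2$motif_size)
  expect_identical(r1$test_accuracy, r2$test_accuracy)
})

test_that("motif-size freezing is irreversible during stage 2", {
  sp <- small_task(211)
  cfg <- small_cfg()
  res <- hrmas_search(sp$a, sp$b, cfg, seed = 13)
  net <- res$search_net
  expect_false(is.null(net$arch$frozen_v))
  # frozen distribution is exactly one-hot and alpha_v receives no updates:
  # relax() pins the frozen option at probability 1
  expect_equal(unname(relax(net$arch)$p_v[as.character(net$arch$frozen_v)]), 1)
  g <- rsnn_grads(net, sp$a$X[1:4, , , drop = FALSE], sp$a$y[1:4])
  expect_equal(max(abs(g$alpha_v)), 0)
})

test_that("degenerate search space reduces to plain weight training", {
  # |V| = 1 and all type logits pinned: nothing left to search
  sp <- small_task(221)
  cfg <- small_cfg()
  cfg$network$V <- 4L
  res <- hrmas_search(sp$a, sp$b, cfg, seed = 17)
  expect_equal(res$motif_size, 4)
  # the retrained accuracy equals running the discrete trainer directly
  direct <- retrain_and_eval(res$architecture, sp$a, sp$b, cfg,
                             seed = child_seed(17, 4))
  expect_identical(res$test_accuracy, direct$accuracy)
})

test_that("single-class data yields perfect accuracy", {
  X <- array(as.numeric(stats::runif(10 * 8 * 30) < 0.1), c(10, 8, 30))
  ds <- spike_dataset(X, rep(1L, 10))
  cfg <- small_cfg()
  cfg$network$n_out <- 1L
  spec <- scml_spec(8, 4)
  arch_d <- hrmas:::discretize_from_types(spec, rep(1L, spec$cand[[1]]$n_slots), 0.2)
  re <- retrain_and_eval(arch_d, ds, ds, cfg, seed = 19)
  expect_equal(re$accuracy, 1)
})

test_that("every ablation mode runs end-to-end and respects its switch", {
  sp <- small_task(231)
  for (mode in c("no_ip", "no_motif", "no_inter_motif", "fully_connected",
                 "random")) {
    cfg <- small_cfg()
    res <- hrmas_ablate(mode, sp$a, sp$b, cfg, seed = 23)
    expect_s3_class(res, "search_result")
    expect_true(res$test_accuracy >= 0 && res$test_accuracy <= 1)
    if (mode == "no_motif") expect_equal(res$motif_size, 8)
    if (mode == "fully_connected") {
      expect_equal(res$motif_size, 8)
      expect_true(all(res$architecture$slot_types == 1L))
    }
    if (mode == "no_inter_motif")
      expect_equal(sum(res$architecture$W[abs(row(res$architecture$W) -
                                                col(res$architecture$W)) >=
                                            res$motif_size]), 0)
  }
  expect_error(hrmas_ablate("bogus", sp$a, sp$b, small_cfg(), 1), "unknown")
})

test_that("searched architecture beats a purely feedforward network on a separable task", {
  ds <- make_pattern_task(n_classes = 2, n_in = 8, T_steps = 30,
                          spikes_per_template = 20, jitter_sd = 1,
                          n_per_class = 30, seed = 241)
  sp <- split_dataset(ds, 2 / 3, seed = 242)
  cfg <- small_cfg()
  cfg$schedule$finetune_epochs <- 8L
  res <- hrmas_search(sp$a, sp$b, cfg, seed = 29)
  spec <- scml_spec(8, cfg$network$V[1])
  ff <- hrmas:::discretize_from_types(spec,
                                      rep(3L, spec$cand[[1]]$n_slots), 0.2)
  ff_acc <- retrain_and_eval(ff, sp$a, sp$b, cfg, seed = 29)$accuracy
  expect_gte(res$test_accuracy, ff_acc - 0.1)  # no worse than feedforward (noise margin)
})
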