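# Unit tests use deliberately tiny networks; the study-scale protocol
# (20 epochs, learning-rate 0.001, batch one) is exercised at desk
# scale in the acceptance suite.

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(levels = 2L, base_filters = 2L,
                                 epochs = 1L, seed = 3L), list(...))
  do.call(model_config, args)
}

test_that("forward pass preserves slice shape, including non-multiples", {
  model <- build_multiresunet(tiny_cfg())
  ct <- image_volume(array(stats::rnorm(24 * 24 * 2, 40, 5), c(24, 24, 2)),
                     c(0, 0, 0), c(1, 1, 3), "CT")
  p <- predict_slices(model, ct)
  expect_identical(dim(p$voxels), c(24L, 24L, 2L))
  expect_true(all(p$voxels >= 0 & p$voxels <= 1))

  # 30 is not divisible by 2^levels: padded internally, cropped back
  ct2 <- image_volume(array(stats::rnorm(30 * 26 * 1, 40, 5), c(30, 26, 1)),
                      c(0, 0, 0), c(1, 1, 3), "CT")
  expect_identical(dim(predict_slices(model, ct2)$voxels), c(30L, 26L, 1L))
})

test_that("initialization is seeded and grows with base_filters", {
  a <- build_multiresunet(tiny_cfg())
  b <- build_multiresunet(tiny_cfg())
  expect_identical(as.list(a$params), as.list(b$params))
  c4 <- build_multiresunet(model_config(levels = 2L, base_filters = 4L,
                                        seed = 3L))
  expect_gt(tubseg:::n_parameters(c4), tubseg:::n_parameters(a))
  d <- build_multiresunet(model_config(levels = 2L, base_filters = 2L,
                                       seed = 4L))
  expect_false(identical(as.list(a$params), as.list(d$params)))
})

test_that("identical input slices give identical predictions", {
  model <- build_multiresunet(tiny_cfg())
  sl <- matrix(stats::rnorm(24 * 24, 40, 20), 24, 24)
  ct <- image_volume(array(c(sl, sl), c(24, 24, 2)), c(0, 0, 0),
                     c(1, 1, 3), "CT")
  p <- predict_slices(model, ct)
  expect_identical(p$voxels[, , 1], p$voxels[, , 2])
})

test_that("a zero learning rate leaves parameters untouched", {
  cfg <- tiny_cfg(learning_rate = 0, epochs = 3L)
  model <- build_multiresunet(cfg)
  before <- as.list(model$params)
  s <- training_sample(matrix(0.5, 16, 16),
                       matrix(rbinom(256, 1, 0.2), 16, 16), "P1", 1)
  model <- train_multiresunet(model, list(s), cfg)
  expect_identical(as.list(model$params), before)
  expect_length(model$loss_history, 3)
  expect_equal(diff(model$loss_history), c(0, 0), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_cfg()
  model <- build_multiresunet(cfg)
  set.seed(11)
  x <- matrix(stats::runif(64), 8, 8)
  y <- array(as.numeric(matrix(stats::runif(64), 8, 8) > 0.5), c(8, 8, 1))
  loss_at <- function() {
    saved <- as.list(model$bn)
    tape <- tubseg:::new_tape(model$params, model$bn, training = TRUE)
    lid <- tubseg:::tv_bce(tape, tubseg:::mru_forward(tape, x, cfg), y)
    for (n in names(saved)) model$bn[[n]] <- saved[[n]]
    list(tape = tape, lid = lid, loss = tubseg:::node_val(tape, lid))
  }
  r <- loss_at()
  pg <- tubseg:::tape_backward(r$tape, r$lid)
  expect_setequal(ls(pg), ls(model$params))   # every parameter reached
  h <- 1e-5
  for (pn in ls(pg)) {
    i <- which.max(abs(pg[[pn]]))
    orig <- model$params[[pn]][i]
    model$params[[pn]][i] <- orig + h
    lp <- loss_at()$loss
    model$params[[pn]][i] <- orig - h
    lm <- loss_at()$loss
    model$params[[pn]][i] <- orig
    num <- (lp - lm) / (2 * h)
    ana <- pg[[pn]][i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
  }
})

test_that("a tiny network overfits a single sample", {
  m <- disc_mask(5, n = 32L)
  msk <- m$voxels[, , 1]
  img <- 0.3 + 0.3 * msk
  s <- training_sample(img, msk, "P1", 1)
  cfg <- model_config(levels = 3L, base_filters = 8L, epochs = 60L,
                      seed = 2L)
  model <- build_multiresunet(cfg)
  model <- train_multiresunet(model, list(s), cfg)
  expect_lt(tail(model$loss_history, 1), model$loss_history[1])
  ct <- image_volume(array(img * 400 - 100, c(32, 32, 1)), c(0, 0, 0),
                     c(1, 1, 3), "CT")
  p <- predict_slices(model, ct)
  pred <- (p$voxels[, , 1] >= 0.5) + 0L
  expect_gte(2 * sum(pred & msk) / (sum(pred) + sum(msk)), 0.9)
})

test_that("training aborts on a degenerate configuration", {
  expect_error(model_config(epochs = 0), "epochs")
  expect_error(model_config(batch_size = 2), "batch_size")
  model <- build_multiresunet(tiny_cfg())
  expect_error(train_multiresunet(model, list()), "non-empty")
})
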