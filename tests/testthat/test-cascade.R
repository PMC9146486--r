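# Cascade training and inference: the IS input contract, early stopping,
# a small overfit run, and inference determinism/robustness.

test_that("make_is_input encodes the retina map into [0,1] channel 2", {
  img <- matrix(runif(16), 4, 4)
  rs <- matrix(2L, 4, 4)
  x <- make_is_input(img, rs)
  expect_identical(dim(x), c(16L, 2L))
  expect_true(all(x[, 2] == 0.5))
  rs2 <- matrix(c(1L, 2L, 3L, 2L), 4, 4)
  x2 <- make_is_input(img, rs2)
  expect_setequal(unique(x2[, 2]), c(0, 0.5, 1))
  expect_error(make_is_input(img, matrix(1L, 3, 3)), "shape")
  # ground-truth 3-class maps are valid teacher-forcing inputs
  g <- generate_bscan(tiny_params(), 1L)
  xt <- make_is_input(g$image, g$gt$classmap3)
  expect_identical(ncol(xt), 2L)
})

test_that("early stopping obeys the patience contract", {
  g <- generate_volume(tiny_params(n_bscans = 2L, seed = 3L))
  x <- lapply(g$volume$bscans, function(b) matrix(as.vector(b), ncol = 1))
  y <- g$gt$classmap3
  m <- build_compressed_unet(net_config(h = 64, w = 64, n = 1, o = 3,
                                        f = 3, c = 2), seed = 1)
  # lr = 0 freezes the model, so validation accuracy is constant:
  # epoch 1 improves over -Inf, then `patience` stale epochs -> patience + 1
  sp <- train_spec(learning_rate = 0, max_epochs = 10L, patience = 3L,
                   batch_size = 2L, seed = 2L)
  fit <- train_stage(m, list(train = list(x = x, y = y)), sp)
  expect_identical(fit$stopped_epoch, 4L)
  expect_identical(nrow(fit$history), 4L)
  # max_epochs = 1 -> history of length 1
  sp1 <- train_spec(max_epochs = 1L, patience = 0L, batch_size = 2L)
  fit1 <- train_stage(m, list(train = list(x = x, y = y)), sp1)
  expect_identical(nrow(fit1$history), 1L)
  expect_error(train_stage(m, list(train = list(x = list(), y = list())), sp1),
               "empty")
  expect_error(train_spec(max_epochs = 5L, patience = 10L))
})

test_that("a 5-phantom overfit run reaches training DSC > 0.95", {
  p <- phantom_params(image_height = 64L, image_width = 64L,
                      axial_scale = 3.87 * 8, lateral_scale = 11.7 * 8,
                      n_bscans = 5L, seed = 5L)
  g <- generate_volume(p)
  x <- lapply(g$volume$bscans, function(b) matrix(as.vector(b), ncol = 1))
  y <- g$gt$classmap3
  m <- build_compressed_unet(net_config(h = 64, w = 64, n = 1, o = 3, f = 5,
                                        c = 4, dropout_rate = 0.25), seed = 3)
  # 5 images x 40 epochs at batch size 1 = 200 optimizer steps
  sp <- train_spec(max_epochs = 40L, patience = 39L, batch_size = 1L, seed = 9L)
  fit <- train_stage(m, list(train = list(x = x, y = y)), sp)
  dscs <- vapply(seq_along(x), function(i)
    mean(dice(predict_classmap(fit$model, x[[i]]), y[[i]], n_classes = 3L)),
    numeric(1))
  expect_gt(mean(dscs), 0.95)
})

test_that("inference is deterministic and survives blank input", {
  m_rs <- build_compressed_unet(net_config(h = 32, w = 32, n = 1, o = 3,
                                           f = 3, c = 2), seed = 4)
  m_is <- build_compressed_unet(net_config(h = 32, w = 32, n = 2, o = 9,
                                           f = 3, c = 2), seed = 5)
  vol <- oct_volume(list(matrix(runif(1024), 32, 32), matrix(0, 32, 32)),
                    3.87, 11.7, 240)
  r1 <- predict_volume(m_rs, m_is, vol)
  r2 <- predict_volume(m_rs, m_is, vol)
  expect_identical(r1, r2)
  expect_true(all(vapply(r1, function(m) all(m %in% 1:9), logical(1))))
  # wrong input size is an error
  bad <- oct_volume(list(matrix(0, 16, 16)), 3.87, 11.7, 240)
  expect_error(predict_volume(m_rs, m_is, bad), "input size")
})

test_that("weighted focal loss does not trail plain focal loss on thin layers", {
  # scaled-down trend check: same data, same seeds, only the loss differs
  p <- phantom_params(image_height = 64L, image_width = 64L,
                      axial_scale = 3.87 * 8, lateral_scale = 11.7 * 8,
                      n_bscans = 8L, seed = 31L)
  g <- generate_volume(p)
  x <- mapply(make_is_input, g$volume$bscans, g$gt$classmap3, SIMPLIFY = FALSE)
  y <- g$gt$classmap9
  data <- list(train = list(x = x, y = y))
  cfg <- net_config(h = 64, w = 64, n = 2, o = 9, f = 5, c = 4,
                    dropout_rate = 0.25)
  run <- function(loss_type) {
    m <- build_compressed_unet(cfg, seed = 13)
    sp <- train_spec(max_epochs = 25L, patience = 24L, batch_size = 1L,
                     seed = 17L, loss_type = loss_type)
    fit <- train_stage(m, data, sp)
    d <- sapply(seq_along(x), function(i)
      dice(predict_classmap(fit$model, x[[i]]), y[[i]], n_classes = 9L))
    rowMeans(d)
  }
  dsc_w <- run("weighted_focal")
  dsc_f <- run("focal")
  thin <- c(5L, 7L)  # OPL and MZ rows of the 9-class vocabulary
  expect_gte(mean(dsc_w[thin]), mean(dsc_f[thin]) - 0.05)
})
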