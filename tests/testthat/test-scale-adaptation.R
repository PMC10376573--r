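test_that("config invariants are enforced", {
  expect_error(ae_config(target_scales = list(c(56L, 56L, 3L), c(56L, 56L, 3L))),
               "decreasing")
  expect_error(ae_config(delta = 0), "delta")
  expect_error(ae_config(loss_weights = c(0, 0)), "loss_weights")
  expect_error(ae_config(target_scales = list(c(4096L, 4096L, 3L))), "bound")
})

test_that("forward pass is size-agnostic with invariant output shapes", {
  ae <- build_ae(tiny_ae_config())
  for (sz in list(c(20L, 24L), c(16L, 16L), c(33L, 17L))) {
    out <- ae_forward(ae, matrix(runif(prod(sz)), sz[1], sz[2]))
    expect_identical(dim(out$f_ae), c(16L, 16L, 3L))
    expect_identical(dim(out$processed), c(16L, 16L, 12L))
    expect_identical(dim(out$high_res), c(16L, 16L, 3L))
    expect_identical(dim(out$low_res_reconstruction), c(sz, 3L))
    expect_true(all(is.finite(unlist(out[1:4]))))
  }
  # inference determinism and degenerate input safety
  img <- matrix(runif(20 * 24), 20, 24)
  expect_identical(ae_forward(ae, img), ae_forward(ae, img))
  out0 <- ae_forward(ae, matrix(0, 16, 16))
  expect_true(all(is.finite(unlist(out0[1:4]))))
  # same seed, same parameters
  expect_identical(build_ae(tiny_ae_config()), build_ae(tiny_ae_config()))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_ae_config(seed = 17L)
  ae <- build_ae(cfg)
  img <- array(runif(20 * 24 * 3), c(20, 24, 3))
  tgt <- octpyramid:::ae_target_hi(img, c(16L, 16L))
  lossfun <- function(a) ae_loss(ae_forward(a, img), img, tgt, cfg)
  out <- ae_forward(ae, img, cache = TRUE)
  g <- octpyramid:::ae_backward(ae, out, tgt, img)
  set.seed(1)
  for (nm in c("enc1", "proj", "tconv", "expand", "high", "low")) {
    arr <- ae$params[[nm]]$w
    i <- sample(length(arr), 1L)
    eps <- 1e-6
    ap <- ae; ap$params[[nm]]$w[i] <- arr[i] + eps
    am <- ae; am$params[[nm]]$w[i] <- arr[i] - eps
    num <- (lossfun(ap) - lossfun(am)) / (2 * eps)
    expect_equal(g[[nm]]$w[i], num, tolerance = 1e-4)
  }
})

test_that("training reduces reconstruction loss and is reproducible", {
  ds <- tiny_image_set(2, h = 24L, w = 32L)
  cfg <- tiny_ae_config(seed = 23L)
  res <- train_ae(build_ae(cfg), ds, cfg)
  expect_length(res$history, cfg$epochs + 1L)
  expect_lte(res$history[length(res$history)], res$history[1])
  # same seed twice: identical final loss, bit-identical parameters
  res2 <- train_ae(build_ae(cfg), ds, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$ae$params, res2$ae$params)
  # null-update limit: zero learning rate leaves loss constant
  cfg0 <- tiny_ae_config(seed = 23L, learning_rate = 0, epochs = 2L)
  res0 <- train_ae(build_ae(cfg0), ds, cfg0)
  expect_equal(max(abs(diff(res0$history))), 0, tolerance = 1e-12)
  expect_identical(res0$ae$params, build_ae(cfg0)$params)
  expect_error(train_ae(build_ae(cfg), list(matrix(0.5, 24, 24))), "2 images")
})

test_that("the pyramid has exactly the configured scales", {
  ae <- build_ae(tiny_ae_config())
  pyr <- emit_pyramid(ae, matrix(runif(20 * 28), 20, 28))
  expect_length(pyr, 3L)
  expect_identical(dim(pyr[["16"]]), c(16L, 16L, 3L))
  expect_identical(dim(pyr[["8"]]), c(8L, 8L, 3L))
  expect_identical(dim(pyr[["4"]]), c(4L, 4L, 3L))
  expect_true(all(vapply(pyr, function(p) all(is.finite(p)), logical(1))))
  pyr0 <- emit_pyramid(ae, matrix(0, 16, 16))
  expect_true(all(vapply(pyr0, function(p) all(is.finite(p)), logical(1))))
})

test_that("trained per-scale outputs track naive downsampling", {
  # sanity oracle: after brief training the smaller scales correlate with
  # plain bilinear downsamples of the first-scale branch
  ds <- tiny_image_set(2, h = 24L, w = 32L)
  cfg <- tiny_ae_config(seed = 29L, epochs = 2L)
  ae <- train_ae(build_ae(cfg), ds, cfg)$ae
  pyr <- emit_pyramid(ae, ds$images[[1]])
  hi <- pyr[["16"]]
  for (tag in c("8", "4")) {
    s <- as.integer(tag)
    naive <- octpyramid:::cpp_resize(hi, s, s, 0L)
    expect_gt(stats::cor(as.numeric(pyr[[tag]]), as.numeric(naive)), 0.5)
  }
})

test_that("checkpoints round-trip", {
  ae <- build_ae(tiny_ae_config(seed = 31L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_ae(ae, path)
  ae2 <- load_ae(path)
  img <- matrix(runif(18 * 20), 18, 20)
  expect_identical(ae_forward(ae, img), ae_forward(ae2, img))
})
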