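test_that("the proposed CNN reproduces its printed architecture facts", {
  spec <- build_proposed_cnn(224L, 2L)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_identical(sum(kinds == "conv"), 5L)

  pool1 <- spec$layers[[which(kinds == "maxpool")[1]]]
  expect_equal(pool1$out_shape[1:2], c(112, 112))

  flat <- spec$layers[[which(kinds == "flatten")]]
  expect_equal(flat$out_shape, 25088)

  dense <- spec$layers[[which(kinds == "dense")]]
  expect_equal(dense$units, 64)

  drop <- spec$layers[[which(kinds == "dropout")]]
  expect_equal(drop$rate, 0.5)

  # spatial chain halves five times: 224 -> 112 -> 56 -> 28 -> 14 -> 7
  sides <- vapply(spec$layers[kinds == "maxpool"],
                  function(l) l$out_shape[1], 0)
  expect_equal(sides, c(112, 56, 28, 14, 7))

  expect_error(build_proposed_cnn(100L), "divisible by 32")
})

test_that("parameter counting matches hand-computed layer totals", {
  one_conv <- build_proposed_cnn(224L, 2L)
  first <- one_conv$layers[[1]]
  expect_equal(prod(first$kernel) * first$filters + first$filters, 4864)

  empty <- dedscreen:::new_cnn_spec(list(), c(1, 1, 1), 2, "empty")
  expect_equal(count_parameters(empty), 0)
})

test_that("transfer bases reproduce the published ImageNet parameter counts", {
  v <- build_transfer_model(transfer_spec("vgg16"), n_classes = 1000L)
  expect_equal(count_parameters(v), 138357544)
  x <- build_transfer_model(transfer_spec("xception"), n_classes = 1000L)
  expect_equal(count_parameters(x), 22910480)
  d <- build_transfer_model(transfer_spec("densenet121"), n_classes = 1000L)
  expect_equal(count_parameters(d), 8062504)
})

test_that("trainable flags follow the customization mode", {
  fe <- build_transfer_model(transfer_spec("vgg16", "feature_extraction"), 2L)
  base_trainable <- vapply(fe$layers, function(l)
    isTRUE(l$trainable) && l$kind %in% c("conv", "sepconv", "dense", "batchnorm"),
    TRUE)
  head_kinds <- vapply(fe$layers, `[[`, "", "kind")
  expect_equal(sum(base_trainable & head_kinds != "output"), 0)

  ft0 <- build_transfer_model(transfer_spec("vgg16", "fine_tune", 0L), 2L)
  expect_identical(lapply(fe$layers, `[[`, "trainable"),
                   lapply(ft0$layers, `[[`, "trainable"))

  # unfreezing strictly grows the trainable subset; totals never change
  prev <- count_parameters(ft0, trainable_only = TRUE)
  for (k in c(2L, 5L)) {
    ft <- build_transfer_model(transfer_spec("vgg16", "fine_tune", k), 2L)
    cur <- count_parameters(ft, trainable_only = TRUE)
    expect_gt(cur, prev)
    expect_equal(count_parameters(ft), count_parameters(ft0))
    prev <- cur
  }
  expect_error(build_transfer_model(transfer_spec("vgg16", "fine_tune", 999L), 2L),
               "exceeds base depth")
  expect_error(transfer_spec("resnet50"))
})

test_that("a forward pass realizes exactly the recorded shapes", {
  spec <- build_proposed_cnn(32L, 2L, filters_scale = 1 / 16)
  model <- init_cnn_model(spec, seed = 5L)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fw <- cnn_forward(model, x)
  for (i in seq_along(spec$layers))
    expect_equal(unname(fw$shapes[[i]]), unname(spec$layers[[i]]$out_shape))
  # sigmoid head probabilities
  expect_true(all(fw$out >= 0 & fw$out <= 1))
})

test_that("a softmax head produces a probability simplex per sample", {
  spec <- build_proposed_cnn(32L, 4L, filters_scale = 1 / 16)
  model <- init_cnn_model(spec, seed = 3L)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  out <- cnn_forward(model, x)$out
  expect_equal(dim(out), c(4L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(colSums(out), rep(1, 3))
})

test_that("the engine refuses declarative-only topologies", {
  x <- build_transfer_model(transfer_spec("xception"), 1000L)
  expect_error(init_cnn_model(x), "does not support")
})
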