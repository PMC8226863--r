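test_that("balance_classes downsamples every class to the minimum", {
  # the published class inventory: min class 5899 governs the balanced size
  m <- label_manifest(c(21377, 19751, 7163, 5899))
  b <- balance_classes(m, "min_class", seed = 1)
  expect_equal(as.integer(table(b$label)[beat_classes()]), rep(5899L, 4))
  expect_true(all(b$path %in% m$path))
  expect_false(any(duplicated(b$path)))

  # already balanced input keeps its membership
  m2 <- label_manifest(c(8, 8, 8, 8))
  b2 <- balance_classes(m2, "min_class", seed = 3)
  expect_setequal(b2$path, m2$path)

  expect_error(balance_classes(label_manifest(c(5, 10, 10, 10)), 10),
               "only 5")
})

test_that("split_half gives ceil/floor halves that partition each class", {
  m <- label_manifest(c(5899, 5899, 5899, 5899))
  sp <- split_half(m, seed = 2)
  expect_equal(as.integer(table(sp$train$label)[beat_classes()]), rep(2950L, 4))
  expect_equal(as.integer(table(sp$test$label)[beat_classes()]), rep(2949L, 4))
  expect_length(intersect(sp$train$path, sp$test$path), 0L)
  expect_setequal(c(sp$train$path, sp$test$path), m$path)

  # even class splits evenly; deterministic under the seed
  m2 <- label_manifest(c(10, 10, 10, 10))
  sp2 <- split_half(m2, seed = 5)
  expect_equal(nrow(sp2$train), 20L)
  expect_equal(nrow(sp2$test), 20L)
  sp3 <- split_half(m2, seed = 5)
  expect_identical(sp2, sp3)

  expect_error(split_half(label_manifest(c(1, 4, 4, 4))), "at least 2")
})

test_that("training requires all four classes and tracks its history", {
  man <- synthetic_manifest(6, size = 48, seed = 41)
  short <- man[man$label != "ST_ELEVATION", ]
  cfg <- train_config(epochs = 1, image_size = 48, seed = 1)
  expect_error(train_beat_classifier(short, cfg), "ST_ELEVATION")

  model <- train_beat_classifier(man, cfg)
  expect_s3_class(model, "ecg_cnn")
  expect_equal(nrow(model$history), 1L)
  expect_identical(model$classes, beat_classes())
})

test_that("untrained network emits proper probabilities summing to one", {
  man <- synthetic_manifest(6, size = 48, seed = 41)
  params <- ecgflow:::cnn_init(c(8L, 16L, 32L), 1L, 4L, seed = 7)
  X <- ecgflow:::images_from_manifest(man[1:5, ], 48L)
  fw <- ecgflow:::cnn_forward(params, X, 3L)
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-12)
  expect_true(all(fw$probs >= 0))
})

test_that("training is reproducible: same seed, same confusion table", {
  man <- synthetic_manifest(8, size = 48, seed = 42)
  sp <- split_half(man, seed = 9)
  cfg <- train_config(epochs = 2, image_size = 48, seed = 17)
  m1 <- train_beat_classifier(sp$train, cfg)
  m2 <- train_beat_classifier(sp$train, cfg)
  expect_identical(evaluate_classifier(m1, sp$test),
                   evaluate_classifier(m2, sp$test))
})

test_that("training loss decreases on a learnable dataset", {
  man <- synthetic_manifest(12, size = 48, seed = 43)
  cfg <- train_config(epochs = 5, image_size = 48, seed = 3)
  model <- train_beat_classifier(man, cfg)
  h <- model$history$loss
  expect_lt(h[5], h[1])
})

test_that("evaluation produces a conservation-respecting confusion table", {
  man <- synthetic_manifest(8, size = 48, seed = 42)
  sp <- split_half(man, seed = 9)
  model <- train_beat_classifier(sp$train,
                                 train_config(epochs = 2, image_size = 48,
                                              seed = 17))
  ct <- evaluate_classifier(model, sp$test)
  expect_s3_class(ct, "confusion_table")
  expect_equal(unname(rowSums(ct)), rep(4, 4))     # per-class test counts
  expect_equal(sum(ct), nrow(sp$test))

  bad <- sp$test
  bad$label[1] <- NA
  expect_error(evaluate_classifier(model, bad), "labeled")
})

test_that("checkpoints reload to identical predictions", {
  man <- synthetic_manifest(8, size = 48, seed = 42)
  model <- train_beat_classifier(man, train_config(epochs = 1,
                                                   image_size = 48, seed = 2))
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(predict(back, man, type = "prob"),
                   predict(model, man, type = "prob"))
  expect_equal(back$deep_layers, model$deep_layers)
})

test_that("architecture presets report their nominal layer counts", {
  expect_equal(ecgflow:::architecture_preset("resnet_tl")$deep_layers, 177L)
  expect_equal(ecgflow:::architecture_preset("alexnet_tl")$deep_layers, 25L)
  expect_equal(ecgflow:::architecture_preset("squeezenet_tl")$deep_layers, 68L)
  expect_error(ecgflow:::architecture_preset("vgg"), "unknown architecture")
})
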