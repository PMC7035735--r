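test_that("train_config validates its fields", {
  expect_error(train_config(batch_size = 1), "at least 2")
  expect_error(train_config(learning_rate = 0), "positive")
  expect_error(train_config(objective = "hinge"), "arg")
  expect_error(train_config(loss_weights = c(reconstruction = 1)), "loss_weights")
})

test_that("training is bit-reproducible from the seed", {
  fix <- tiny_data()
  m1 <- train_model(fix$proc, config = tiny_config())
  m2 <- train_model(fix$proc, config = tiny_config())
  expect_identical(m1$history, m2$history)
  expect_identical(project(m1, fix$proc), project(m2, fix$proc))
  # a different seed changes the trajectory
  m3 <- train_model(fix$proc, config = tiny_config(seed = 2))
  expect_false(identical(m1$history$reconstruction, m3$history$reconstruction))
})

test_that("the ablation switch removes D2 terms and changes the trajectory", {
  fix <- tiny_data()
  dm <- train_model(fix$proc, config = tiny_config())
  av <- train_model(fix$proc, config = tiny_config(dual_matching = FALSE))
  expect_true(all(is.na(av$history$d2_loss)))
  expect_true(all(is.na(av$history$gen2_loss)))
  expect_true(all(is.finite(dm$history$d2_loss)))
  expect_false(identical(dm$history$reconstruction, av$history$reconstruction))
})

test_that("batch size larger than the dataset is rejected", {
  fix <- tiny_data(n_cells = 10)
  expect_error(train_model(fix$proc, config = tiny_config(batch_size = 128)),
               "exceeds")
})

test_that("all four objectives run and keep finite histories", {
  fix <- tiny_data()
  for (obj in c("standard", "wasserstein", "wasserstein_gp", "bhattacharyya")) {
    m <- train_model(fix$proc, config = tiny_config(objective = obj, epochs = 2))
    expect_true(all(is.finite(m$history$reconstruction)), info = obj)
    expect_true(all(is.finite(m$history$d1_loss)), info = obj)
  }
})

test_that("projection is deterministic with the configured dimensionality", {
  fix <- tiny_data()
  m <- train_model(fix$proc, config = tiny_config())
  z1 <- project(m, fix$proc)
  expect_equal(dim(z1), c(60L, 2L))
  expect_identical(z1, project(m, fix$proc))
  expect_error(project(m, matrix(0, 5, 7)), "genes")
})

test_that("reconstruction loss decreases over early training", {
  m <- fixture_dm_model()
  r <- m$history$reconstruction
  # moving-average comparison: around epoch 5 vs around epoch 20
  expect_gt(mean(r[3:7]), mean(r[18:22]))
})

test_that("adversarial matching pulls the aggregate posterior toward N(0, I)", {
  # mechanism check under the Wasserstein critic (see the methods vignette on
  # why the Bhattacharyya objective matches more loosely)
  fix <- fixture_data()
  tr <- subset_processed(fix$proc, fix$split$train)
  cfg <- train_config(latent_dim = 2, objective = "wasserstein", epochs = 300,
                      seed = 0, early_stopping_patience = Inf)
  m <- train_model(tr, config = cfg)
  post <- encode(m$encoder, tr$values)
  z <- .with_seed(99, reparameterize(post))
  expect_true(all(abs(colMeans(z)) <= 0.5))
  v <- apply(z, 2, stats::var)
  expect_true(all(v >= 0.3 & v <= 3))
})

test_that("learned embeddings beat random Gaussian embeddings across seeds", {
  runs <- fixture_seed_runs()
  for (r in runs) {
    expect_gt(r$nmi_dm, r$nmi_random)
  }
})

test_that("presets reproduce the published per-dataset hyperparameters", {
  cfg <- preset_config("zeisel3k", K = 2)
  expect_equal(cfg$encoder_spec$layer_sizes, rep(512L, 4))
  expect_equal(cfg$d1_spec$layer_sizes, rep(32L, 4))
  expect_equal(cfg$learning_rate, 8e-4)
  expect_equal(cfg$batch_size, 128L)
  cfg <- preset_config("zheng68k", K = 20)
  expect_equal(cfg$encoder_spec$layer_sizes, 256L)
  expect_equal(cfg$d1_spec$layer_sizes, 256L)
  expect_equal(cfg$learning_rate, 2e-5)
  cfg <- preset_config("macosko44k", K = 10)
  expect_equal(cfg$encoder_spec$layer_sizes, c(512L, 256L, 256L, 128L))
  expect_equal(cfg$d1_spec$layer_sizes, c(256L, 128L, 128L, 64L))
  expect_equal(cfg$learning_rate, 7e-5)
  expect_equal(nrow(list_presets()), 15)
  expect_error(preset_config("zeisel3k", K = 5), "K = 5")
  expect_error(preset_config("unknown", K = 2), "unknown dataset")
})
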