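# joint loss evaluated in training mode (batch statistics); dropout is 0 in
# the configs used here so the forward pass is RNG-free and differentiable
dlse_loss <- function(modules, cfg, X, Tmat) {
  enc <- ecmlse:::nn_forward(modules$encoder, X, training = TRUE)
  dec <- ecmlse:::nn_forward(modules$decoder, enc$out, training = TRUE)
  clf <- ecmlse:::nn_forward(modules$classifier, enc$out, training = TRUE)
  P <- ecmlse:::nn_softmax(clf$out)
  ce <- -mean(log(pmax(rowSums(P * Tmat), 1e-12)))
  mse <- mean((dec$out - X)^2)
  cfg$classification_weight * ce + cfg$reconstruction_weight * mse
}

dlse_grads <- function(modules, cfg, X, Tmat) {
  enc <- ecmlse:::nn_forward(modules$encoder, X, training = TRUE)
  dec <- ecmlse:::nn_forward(modules$decoder, enc$out, training = TRUE)
  clf <- ecmlse:::nn_forward(modules$classifier, enc$out, training = TRUE)
  P <- ecmlse:::nn_softmax(clf$out)
  m <- nrow(X)
  dlogits <- cfg$classification_weight * (P - Tmat) / m
  dXhat <- cfg$reconstruction_weight * 2 * (dec$out - X) / length(X)
  bd <- ecmlse:::nn_backward(modules$decoder, dec$caches, dXhat)
  bc <- ecmlse:::nn_backward(modules$classifier, clf$caches, dlogits)
  be <- ecmlse:::nn_backward(modules$encoder, enc$caches, bd$dX + bc$dX)
  list(encoder = be$grads, decoder = bd$grads, classifier = bc$grads)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(input_dim = 12L, latent_dim = 3L, encoder_hidden = c(6L, 4L),
         classifier_hidden = c(4L, 4L, 4L), dropout_rate = 0,
         max_epochs = 5L, seed = 2L),
    list(...))
  do.call(model_config, args)
}

test_that("built models have the specified layer architecture", {
  cfg <- model_config(input_dim = 3600L, latent_dim = 7L)  # k = 8, LV = 7
  m <- build_model(cfg)
  kinds <- function(mod) vapply(m$modules[[mod]], `[[`, "", "kind")
  dense_dims <- function(mod) {
    lapply(Filter(function(l) l$kind == "dense", m$modules[[mod]]),
           function(l) dim(l$W))
  }
  # encoder 3600 -> 50 -> 10 -> 7, hidden: dense/bnorm/relu/dropout,
  # latent: sigmoid with no normalization or dropout after it
  expect_equal(kinds("encoder"),
               c("dense", "bnorm", "relu", "dropout",
                 "dense", "bnorm", "relu", "dropout", "dense", "sigmoid"))
  expect_equal(dense_dims("encoder"),
               list(c(3600L, 50L), c(50L, 10L), c(10L, 7L)))
  # mirror decoder 7 -> 10 -> 50 -> 3600, linear output
  expect_equal(dense_dims("decoder"),
               list(c(7L, 10L), c(10L, 50L), c(50L, 3600L)))
  expect_equal(tail(kinds("decoder"), 1), "dense")
  # classifier 7 -> 10 -> 10 -> 10 -> 2
  expect_equal(dense_dims("classifier"),
               list(c(7L, 10L), c(10L, 10L), c(10L, 10L), c(10L, 2L)))
  expect_equal(kinds("classifier"),
               c("dense", "relu", "dense", "relu", "dense", "relu", "dense"))
})

test_that("parameter count equals the shape-sum oracle", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  # dense: w*h + h; bnorm: 2h
  enc <- 12 * 6 + 6 + 2 * 6 + 6 * 4 + 4 + 2 * 4 + 4 * 3 + 3
  dec <- 3 * 4 + 4 + 2 * 4 + 4 * 6 + 6 + 2 * 6 + 6 * 12 + 12
  clf <- 3 * 4 + 4 + 4 * 4 + 4 + 4 * 4 + 4 + 4 * 2 + 2
  expect_equal(count_parameters(m), enc + dec + clf)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  withr::with_seed(4, {
    X <- matrix(stats::runif(6 * cfg$input_dim), 6, cfg$input_dim)
    labels <- c("ECM", "non-ECM", "ECM", "non-ECM", "ECM", "non-ECM")
  })
  Tmat <- ecmlse:::label_onehot(labels)
  grads <- dlse_grads(m$modules, cfg, X, Tmat)
  h <- 1e-5
  withr::with_seed(9, {
    for (mod in names(m$modules)) {
      for (li in seq_along(m$modules[[mod]])) {
        g <- grads[[mod]][[li]]
        if (is.null(g)) next
        for (p in names(g)) {
          n_par <- length(m$modules[[mod]][[li]][[p]])
          for (ci in sample.int(n_par, min(4L, n_par))) {
            mm <- m$modules
            mm[[mod]][[li]][[p]][ci] <- mm[[mod]][[li]][[p]][ci] + h
            up <- dlse_loss(mm, cfg, X, Tmat)
            mm[[mod]][[li]][[p]][ci] <- mm[[mod]][[li]][[p]][ci] - 2 * h
            dn <- dlse_loss(mm, cfg, X, Tmat)
            numeric_g <- (up - dn) / (2 * h)
            expect_equal(as.numeric(g[[p]])[ci], numeric_g,
                         tolerance = 1e-4,
                         label = sprintf("%s layer %d %s[%d]", mod, li, p, ci))
          }
        }
      }
    }
  })
})

separable_data <- function(n, d, seed) {
  # two linearly separable clusters in feature space
  withr::with_seed(seed, {
    labels <- rep(c("ECM", "non-ECM"), length.out = n)
    X <- matrix(stats::runif(n * d, 0, 0.2), n, d)
    X[labels == "ECM", 1:3] <- X[labels == "ECM", 1:3] + 0.6
    rownames(X) <- sprintf("s%03d", seq_len(n))
    list(X = X, labels = labels)
  })
}

test_that("training separates separable data and is bit-reproducible", {
  tr <- separable_data(80, 30, seed = 1)
  va <- separable_data(40, 30, seed = 2)
  cfg <- model_config(input_dim = 30L, latent_dim = 3L, max_epochs = 60L,
                      patience = 10L, seed = 5L)
  run <- function() {
    train_model(build_model(cfg), tr$X, tr$labels, va$X, va$labels)
  }
  m1 <- run()
  expect_gte(max(m1$history$val_balanced_accuracy), 0.95)
  m2 <- run()
  expect_identical(m1$modules, m2$modules)
  expect_identical(m1$history, m2$history)

  # loss decomposition at every logged epoch
  expect_equal(m1$history$val_loss,
               cfg$classification_weight * m1$history$val_ce +
                 cfg$reconstruction_weight * m1$history$val_mse,
               tolerance = 1e-6)
  expect_equal(m1$history$train_loss,
               m1$history$train_ce + m1$history$train_mse, tolerance = 1e-6)
})

test_that("prediction scores normalize, ties go positive, widths are checked", {
  tr <- separable_data(60, 20, seed = 3)
  cfg <- model_config(input_dim = 20L, latent_dim = 2L, max_epochs = 10L,
                      seed = 7L)
  m <- train_model(build_model(cfg), tr$X, tr$labels, tr$X, tr$labels)
  p <- predict(m, tr$X)
  expect_equal(p$score_ECM + p$score_non_ECM, rep(1, 60), tolerance = 1e-6)
  expect_true(all(p$label %in% c("ECM", "non-ECM")))
  expect_error(predict(m, tr$X[, 1:10]), "input_dim")

  # zero the final classifier layer -> exact 0.5/0.5 ties -> positive call
  tied <- m
  last <- length(tied$modules$classifier)
  tied$modules$classifier[[last]]$W[] <- 0
  tied$modules$classifier[[last]]$b[] <- 0
  pt <- predict(tied, tr$X[1:5, ])
  expect_equal(pt$score_ECM, rep(0.5, 5))
  expect_equal(pt$label, rep("ECM", 5))
})

test_that("embed is a deterministic sigmoid bottleneck of the right shape", {
  tr <- separable_data(50, 16, seed = 8)
  cfg <- model_config(input_dim = 16L, latent_dim = 4L, max_epochs = 8L,
                      seed = 9L)
  m <- train_model(build_model(cfg), tr$X, tr$labels, tr$X, tr$labels)
  Z <- embed(m, tr$X)
  expect_equal(dim(Z), c(50L, 4L))
  expect_true(all(Z > 0 & Z < 1))
  expect_identical(embed(m, tr$X), Z)
})

test_that("training improves reconstruction over the untrained model", {
  tr <- separable_data(80, 24, seed = 10)
  cfg <- model_config(input_dim = 24L, latent_dim = 3L, max_epochs = 40L,
                      patience = 40L, monitor = "val_loss", seed = 11L)
  m0 <- build_model(cfg)
  m1 <- train_model(m0, tr$X, tr$labels, tr$X, tr$labels)
  expect_equal(dim(reconstruct(m1, tr$X)), dim(tr$X))
  expect_lt(mse_db(tr$X, reconstruct(m1, tr$X)),
            mse_db(tr$X, reconstruct(m0, tr$X)))
})

test_that("loss-weight limits degenerate to pure classifier / pure autoencoder", {
  tr <- separable_data(80, 24, seed = 12)
  va <- separable_data(40, 24, seed = 13)
  # classifier-only: still learns the classes
  cfg_c <- model_config(input_dim = 24L, latent_dim = 3L,
                        reconstruction_weight = 0, learning_rate = 1e-2,
                        max_epochs = 150L, patience = 40L, seed = 14L)
  m_c <- train_model(build_model(cfg_c), tr$X, tr$labels, va$X, va$labels)
  expect_gte(max(m_c$history$val_balanced_accuracy), 0.95)
  # autoencoder-only: labels never influence the weights, and the
  # reconstruction error trends down after the batch-norm running
  # statistics settle (plateaus allowed)
  cfg_a <- model_config(input_dim = 24L, latent_dim = 3L,
                        classification_weight = 0, monitor = "val_loss",
                        learning_rate = 3e-3, max_epochs = 80L,
                        patience = 80L, seed = 15L)
  m_a <- train_model(build_model(cfg_a), tr$X, tr$labels, va$X, va$labels)
  shuffled <- withr::with_seed(1, sample(tr$labels))
  m_a2 <- train_model(build_model(cfg_a), tr$X, shuffled, va$X, va$labels)
  expect_identical(m_a$modules, m_a2$modules)
  mses <- m_a$history$val_mse
  expect_lt(mean(utils::tail(mses, 10)), mean(mses[5:15]))
  expect_lt(mses[length(mses)], max(mses))
})

test_that("model bundles round-trip bit-identically", {
  tr <- separable_data(40, 18, seed = 16)
  cfg <- model_config(input_dim = 18L, latent_dim = 2L, max_epochs = 6L,
                      seed = 17L)
  m <- train_model(build_model(cfg), tr$X, tr$labels, tr$X, tr$labels)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(paste0(path, ".history.csv")))
  back <- load_model(path)
  expect_identical(unclass(back$config), unclass(m$config))
  expect_identical(predict(back, tr$X), predict(m, tr$X))
  expect_identical(embed(back, tr$X), embed(m, tr$X))
  expect_error(load_model(tempfile()), "no such model")
})

test_that("non-finite losses abort training with a diagnostic", {
  tr <- separable_data(40, 10, seed = 18)
  cfg <- model_config(input_dim = 10L, latent_dim = 2L, max_epochs = 5L,
                      seed = 19L)
  poisoned <- tr$X
  poisoned[3, 5] <- NaN
  expect_error(
    train_model(build_model(cfg), poisoned, tr$labels, tr$X, tr$labels),
    "non-finite")
  expect_error(train_model(build_model(tiny_config()),
                           matrix(0, 0, 12), character(), tr$X, tr$labels),
               "empty")
})
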