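#' DeepLSE model configuration
#'
#' Hyperparameters of the joint autoencoder + classifier. The encoder maps
#' the CKSAAP feature vector through hidden layers of widths
#' `encoder_hidden` (each with batch normalization, ReLU and dropout) to a
#' sigmoid latent layer of `latent_dim` units (no normalization or dropout
#' there); the decoder mirrors the encoder back to `input_dim`; the
#' classifier reads the latent vector through `classifier_hidden` ReLU
#' layers into a 2-unit softmax over ECM / non-ECM. Training minimizes
#' `classification_weight * cross-entropy + reconstruction_weight * MSE`
#' with Adam, early-stopping on a validation criterion.
#'
#' @param input_dim Feature dimension, `(k_max + 1) * 400` for CKSAAP.
#' @param latent_dim Number of latent variables (LV), >= 1.
#' @param encoder_hidden Encoder hidden-layer widths (decoder mirrors them).
#' @param classifier_hidden Classifier hidden-layer widths.
#' @param dropout_rate Dropout rate on autoencoder hidden layers.
#' @param batch_norm Batch-normalize autoencoder hidden layers.
#' @param classification_weight,reconstruction_weight Loss mixing weights.
#' @param decoder_output `"linear"` (default) or `"sigmoid"` output
#'   activation for the reconstruction.
#' @param learning_rate,batch_size,max_epochs,patience Adam learning rate,
#'   minibatch size, epoch cap and early-stopping patience.
#' @param monitor Early-stopping criterion: `"val_balanced_accuracy"`
#'   (maximized, default) or `"val_loss"` (minimized).
#' @param seed Integer seed; weight initialization and the training loop
#'   derive their RNG streams from it.
#' @return A `model_config` object.
#' @export
model_config <- function(input_dim,
                         latent_dim = 7L,
                         encoder_hidden = c(50L, 10L),
                         classifier_hidden = c(10L, 10L, 10L),
                         dropout_rate = 0.3,
                         batch_norm = TRUE,
                         classification_weight = 1,
                         reconstruction_weight = 1,
                         decoder_output = c("linear", "sigmoid"),
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         max_epochs = 500L,
                         patience = 20L,
                         monitor = c("val_balanced_accuracy", "val_loss"),
                         seed = 1L) {
  cfg <- list(
    input_dim = check_count(input_dim, "input_dim", min = 1L),
    latent_dim = check_count(latent_dim, "latent_dim", min = 1L),
    encoder_hidden = vapply(encoder_hidden, check_count, integer(1), name = "encoder_hidden", min = 1L),
    classifier_hidden = vapply(classifier_hidden, check_count, integer(1), name = "classifier_hidden", min = 1L),
    dropout_rate = check_fraction(dropout_rate, "dropout_rate"),
    batch_norm = isTRUE(batch_norm),
    classification_weight = check_fraction(classification_weight, "classification_weight"),
    reconstruction_weight = check_fraction(reconstruction_weight, "reconstruction_weight"),
    decoder_output = match.arg(decoder_output),
    learning_rate = check_fraction(learning_rate, "learning_rate"),
    batch_size = check_count(batch_size, "batch_size", min = 2L),
    max_epochs = check_count(max_epochs, "max_epochs", min = 1L),
    patience = check_count(patience, "patience", min = 0L),
    monitor = match.arg(monitor),
    seed = check_count(seed, "seed")
  )
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

ae_hidden_stack <- function(d_in, widths, rate, batch_norm) {
  layers <- list()
  for (h in widths) {
    layers <- c(layers, list(nn_dense(d_in, h)))
    if (batch_norm) layers <- c(layers, list(nn_bnorm(h)))
    layers <- c(layers, list(nn_relu()))
    if (rate > 0) layers <- c(layers, list(nn_dropout(rate)))
    d_in <- h
  }
  list(layers = layers, d_out = d_in)
}

#' Build an untrained DeepLSE model
#'
#' Weight initialization (Glorot uniform) is drawn under `config$seed`, so
#' building twice from the same config yields identical weights.
#'
#' @param config A [model_config()].
#' @return A `deep_lse` object with encoder, decoder and classifier modules.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, {
    enc <- ae_hidden_stack(config$input_dim, config$encoder_hidden,
                           config$dropout_rate, config$batch_norm)
    encoder <- c(enc$layers,
                 list(nn_dense(enc$d_out, config$latent_dim), nn_sigmoid()))
    dec <- ae_hidden_stack(config$latent_dim, rev(config$encoder_hidden),
                           config$dropout_rate, config$batch_norm)
    decoder <- c(dec$layers, list(nn_dense(dec$d_out, config$input_dim)))
    if (config$decoder_output == "sigmoid") {
      decoder <- c(decoder, list(nn_sigmoid()))
    }
    d <- config$latent_dim
    classifier <- list()
    for (h in config$classifier_hidden) {
      classifier <- c(classifier, list(nn_dense(d, h), nn_relu()))
      d <- h
    }
    classifier <- c(classifier, list(nn_dense(d, 2L)))
    structure(
      list(config = config,
           modules = list(encoder = encoder, decoder = decoder,
                          classifier = classifier),
           history = NULL, selected = NA, trained = FALSE),
      class = "deep_lse"
    )
  })
}

#' Total number of trainable parameters
#'
#' @param model A `deep_lse` model.
#' @return Integer parameter count over dense weights/biases and batch-norm
#'   scale/shift vectors.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "deep_lse"))
  sum(vapply(model$modules, nn_count_params, numeric(1)))
}

label_onehot <- function(labels) {
  pos <- labels == "ECM"
  cbind(ECM = as.numeric(pos), `non-ECM` = as.numeric(!pos))
}

# forward all three modules in inference mode and compute losses/metrics
dlse_evaluate <- function(modules, config, X, Tmat) {
  Z <- nn_forward(modules$encoder, X, training = FALSE)$out
  Xhat <- nn_forward(modules$decoder, Z, training = FALSE)$out
  P <- nn_softmax(nn_forward(modules$classifier, Z, training = FALSE)$out)
  ce <- -mean(log(pmax(rowSums(P * Tmat), 1e-12)))
  mse <- mean((Xhat - X)^2)
  pred <- ifelse(P[, 1L] >= P[, 2L], "ECM", "non-ECM")
  truth <- ifelse(Tmat[, 1L] == 1, "ECM", "non-ECM")
  ba <- if (length(unique(truth)) == 2L) {
    compute_metrics(confusion(truth, pred))$balanced_accuracy
  } else NA_real_
  list(ce = ce, mse = mse,
       loss = config$classification_weight * ce + config$reconstruction_weight * mse,
       balanced_accuracy = ba)
}

#' Train a DeepLSE model
#'
#' Joint optimization of the reconstruction and classification losses with
#' Adam. Each epoch shuffles the training rows into minibatches; after each
#' epoch the validation set is evaluated in inference mode and early
#' stopping tracks the configured monitor with `config$patience`, restoring
#' the best epoch's weights at the end. The whole run is driven by
#' `config$seed`, so identical calls produce identical models.
#'
#' @param model An untrained `deep_lse` from [build_model()].
#' @param train_features,train_labels Training feature matrix and
#'   `"ECM"`/`"non-ECM"` labels.
#' @param val_features,val_labels Validation set, same feature width.
#' @return The trained `deep_lse`, with `history` (one row per epoch) and
#'   `best_epoch` filled in.
#' @export
train_model <- function(model, train_features, train_labels,
                        val_features, val_labels) {
  stopifnot(inherits(model, "deep_lse"))
  config <- model$config
  if (nrow(train_features) == 0L) stop("empty training set", call. = FALSE)
  if (ncol(train_features) != config$input_dim ||
      ncol(val_features) != config$input_dim) {
    stop("feature width does not match model input_dim (",
         config$input_dim, ")", call. = FALSE)
  }
  Ttrain <- label_onehot(check_labels(train_labels, nrow(train_features)))
  Tval <- label_onehot(check_labels(val_labels, nrow(val_features)))
  X <- as.matrix(train_features)
  Xval <- as.matrix(val_features)
  cw <- config$classification_weight
  rw <- config$reconstruction_weight

  with_seed(config$seed + 1L, {
    modules <- model$modules
    adam <- lapply(modules, nn_adam_init)
    t_step <- 0L
    n <- nrow(X)
    maximize <- config$monitor == "val_balanced_accuracy"
    best <- if (maximize) -Inf else Inf
    best_modules <- modules
    best_epoch <- 0L
    wait <- 0L
    hist <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = config$batch_size)
      # fold a trailing singleton into the previous batch: batch-norm needs >= 2 rows
      if (length(starts) > 1L && n - starts[length(starts)] + 1L < 2L) {
        starts <- starts[-length(starts)]
      }
      ep_ce <- 0; ep_mse <- 0; ep_n <- 0L
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        if (s == starts[length(starts)]) rows <- ord[s:n]
        Xb <- X[rows, , drop = FALSE]
        Tb <- Ttrain[rows, , drop = FALSE]
        m <- nrow(Xb)

        enc <- nn_forward(modules$encoder, Xb, training = TRUE)
        modules$encoder <- enc$layers
        dec <- nn_forward(modules$decoder, enc$out, training = TRUE)
        modules$decoder <- dec$layers
        clf <- nn_forward(modules$classifier, enc$out, training = TRUE)
        P <- nn_softmax(clf$out)
        ce <- -mean(log(pmax(rowSums(P * Tb), 1e-12)))
        mse <- mean((dec$out - Xb)^2)
        if (!is.finite(ce) || !is.finite(mse)) {
          stop(sprintf("non-finite loss at epoch %d (ce=%g, mse=%g)",
                       epoch, ce, mse), call. = FALSE)
        }
        dlogits <- cw * (P - Tb) / m
        dXhat <- rw * 2 * (dec$out - Xb) / length(Xb)
        back_dec <- nn_backward(modules$decoder, dec$caches, dXhat)
        back_clf <- nn_backward(modules$classifier, clf$caches, dlogits)
        back_enc <- nn_backward(modules$encoder, enc$caches,
                                back_dec$dX + back_clf$dX)

        t_step <- t_step + 1L
        up <- nn_adam_step(modules$encoder, back_enc$grads, adam$encoder,
                           config$learning_rate, t_step)
        modules$encoder <- up$layers; adam$encoder <- up$state
        up <- nn_adam_step(modules$decoder, back_dec$grads, adam$decoder,
                           config$learning_rate, t_step)
        modules$decoder <- up$layers; adam$decoder <- up$state
        up <- nn_adam_step(modules$classifier, back_clf$grads, adam$classifier,
                           config$learning_rate, t_step)
        modules$classifier <- up$layers; adam$classifier <- up$state

        ep_ce <- ep_ce + ce * m
        ep_mse <- ep_mse + mse * m
        ep_n <- ep_n + m
      }
      val <- dlse_evaluate(modules, config, Xval, Tval)
      hist[[epoch]] <- data.frame(
        epoch = epoch,
        train_ce = ep_ce / ep_n, train_mse = ep_mse / ep_n,
        train_loss = cw * ep_ce / ep_n + rw * ep_mse / ep_n,
        val_ce = val$ce, val_mse = val$mse, val_loss = val$loss,
        val_balanced_accuracy = val$balanced_accuracy)

      score <- if (maximize) val$balanced_accuracy else val$loss
      if (is.na(score)) score <- if (maximize) -Inf else Inf
      improved <- if (maximize) score > best else score < best
      if (improved) {
        best <- score
        best_modules <- modules
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > config$patience) break
      }
    }

    model$modules <- best_modules
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    model$best_epoch <- best_epoch
    model$trained <- TRUE
    model
  })
}

check_feature_width <- function(model, features) {
  if (ncol(features) != model$config$input_dim) {
    stop("feature width ", ncol(features), " does not match model input_dim ",
         model$config$input_dim, call. = FALSE)
  }
  as.matrix(features)
}

#' Class scores and hard labels for a feature matrix
#'
#' Deterministic inference pass (running batch-norm statistics, no
#' dropout). Softmax scores sum to 1; the hard label is the argmax with
#' ties resolved to the positive (ECM) class.
#'
#' @param object A trained `deep_lse`.
#' @param features Feature matrix of matching width.
#' @param ... Unused.
#' @return Data frame with columns `id`, `score_ECM`, `score_non_ECM`,
#'   `label`.
#' @export
predict.deep_lse <- function(object, features, ...) {
  X <- check_feature_width(object, features)
  Z <- nn_forward(object$modules$encoder, X, training = FALSE)$out
  P <- nn_softmax(nn_forward(object$modules$classifier, Z, training = FALSE)$out)
  data.frame(
    id = rownames(features) %||% as.character(seq_len(nrow(X))),
    score_ECM = P[, 1L], score_non_ECM = P[, 2L],
    label = ifelse(P[, 1L] >= P[, 2L], "ECM", "non-ECM"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Latent embedding of a feature matrix
#'
#' @param model A trained `deep_lse`.
#' @param features Feature matrix of matching width.
#' @return Numeric matrix of shape (n_records, latent_dim), entries in
#'   (0, 1) by the sigmoid latent activation.
#' @export
embed <- function(model, features) {
  stopifnot(inherits(model, "deep_lse"))
  X <- check_feature_width(model, features)
  Z <- nn_forward(model$modules$encoder, X, training = FALSE)$out
  rownames(Z) <- rownames(features)
  colnames(Z) <- paste0("LV", seq_len(ncol(Z)))
  Z
}

#' Autoencoder reconstruction of a feature matrix
#'
#' @param model A trained `deep_lse`.
#' @param features Feature matrix of matching width.
#' @return Matrix of the same shape as `features`.
#' @export
reconstruct <- function(model, features) {
  stopifnot(inherits(model, "deep_lse"))
  X <- check_feature_width(model, features)
  Z <- nn_forward(model$modules$encoder, X, training = FALSE)$out
  out <- nn_forward(model$modules$decoder, Z, training = FALSE)$out
  dimnames(out) <- dimnames(X)
  out
}

#' Save / load a model bundle
#'
#' Writes the weights container plus a JSON sidecar of the configuration
#' and a CSV of the training history next to it. `load_model(save_model(m))`
#' reproduces `predict` and `embed` outputs bit-identically.
#'
#' @param model A trained `deep_lse`.
#' @param path Path for the weights file (sidecars get `.json` /
#'   `.history.csv` suffixes).
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deep_lse"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, paste0(path, ".history.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("unreadable model file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
  if (!inherits(model, "deep_lse")) {
    stop("file does not contain a DeepLSE model: ", path, call. = FALSE)
  }
  model
}

#' @export
print.deep_lse <- function(x, ...) {
  cfg <- x$config
  cat("DeepLSE model: input", cfg$input_dim,
      "-> encoder [", paste(cfg$encoder_hidden, collapse = ", "), "]",
      "-> latent", cfg$latent_dim, "(sigmoid)\n")
  cat("  classifier [", paste(c(cfg$classifier_hidden, 2L), collapse = ", "),
      "] softmax;", count_parameters(x), "parameters;",
      if (isTRUE(x$trained)) sprintf("trained (best epoch %d)", x$best_epoch)
      else "untrained", "\n")
  invisible(x)
}
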