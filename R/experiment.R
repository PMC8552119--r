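#' Train/validation/test split specification
#'
#' The benchmark protocol draws a balanced training set (270 + 270 by
#' default, 540 samples), a validation set of 30 positives and 810
#' negatives, and leaves everything else as the test set; with the
#' benchmark pool of 445 ECM / 3,327 non-ECM proteins the test remainder
#' is 145 positives and 2,247 negatives.
#'
#' @param train_pos,train_neg Training counts per class (must be equal:
#'   training is balanced).
#' @param val_pos,val_neg Validation counts per class.
#' @param seed Integer seed for the random draw.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train_pos = 270L, train_neg = 270L,
                       val_pos = 30L, val_neg = 810L, seed = 1L) {
  spec <- list(train_pos = check_count(train_pos, "train_pos"),
               train_neg = check_count(train_neg, "train_neg"),
               val_pos = check_count(val_pos, "val_pos"),
               val_neg = check_count(val_neg, "val_neg"),
               seed = check_count(seed, "seed"))
  if (spec$train_pos != spec$train_neg) {
    stop("training split must be balanced (train_pos == train_neg)",
         call. = FALSE)
  }
  structure(spec, class = "split_spec")
}

#' Draw disjoint train/validation/test splits from a labelled pool
#'
#' Uniform sampling without replacement within each class under
#' `spec$seed`; the test set is everything left over. Splits are disjoint
#' and exhaustive, and the same seed always reproduces the same split.
#'
#' @param pool A labelled `protein_records` data frame (or any data frame
#'   with `id` and `label` columns).
#' @param spec A [split_spec()].
#' @return List of data frames `train`, `validation`, `test`.
#' @export
make_splits <- function(pool, spec = split_spec()) {
  stopifnot(is.data.frame(pool), inherits(spec, "split_spec"))
  if (anyNA(pool$label)) stop("pool contains unlabelled records", call. = FALSE)
  pos <- which(pool$label == "ECM")
  neg <- which(pool$label == "non-ECM")
  need <- c(pos = spec$train_pos + spec$val_pos,
            neg = spec$train_neg + spec$val_neg)
  if (length(pos) < need["pos"] || length(neg) < need["neg"]) {
    stop(sprintf(
      "pool too small: need %d positives (have %d) and %d negatives (have %d)",
      need["pos"], length(pos), need["neg"], length(neg)), call. = FALSE)
  }
  with_seed(spec$seed, {
    pos_perm <- sample(pos)
    neg_perm <- sample(neg)
    train_idx <- c(pos_perm[seq_len(spec$train_pos)],
                   neg_perm[seq_len(spec$train_neg)])
    val_idx <- c(pos_perm[spec$train_pos + seq_len(spec$val_pos)],
                 neg_perm[spec$train_neg + seq_len(spec$val_neg)])
    test_idx <- setdiff(seq_len(nrow(pool)), c(train_idx, val_idx))
    if (length(test_idx) == 0L) {
      warning("pool exactly covers train+validation: empty test set",
              call. = FALSE)
    }
    lapply(list(train = train_idx, validation = val_idx, test = test_idx),
           function(i) {
             out <- pool[sort(i), , drop = FALSE]
             rownames(out) <- NULL
             out
           })
  })
}

trial_metric_names <- c("sensitivity", "specificity", "accuracy",
                        "balanced_accuracy", "youden_index", "mcc", "f1",
                        "mse_db")

# evaluate a trained model on an encoded split
evaluate_split <- function(model, features, labels) {
  pred <- predict(model, features)
  rep <- compute_metrics(confusion(labels, pred$label))
  rep_mse <- mse_db(as.matrix(features), reconstruct(model, features))
  c(sensitivity = rep$sensitivity, specificity = rep$specificity,
    accuracy = rep$accuracy, balanced_accuracy = rep$balanced_accuracy,
    youden_index = rep$youden_index, mcc = rep$mcc, f1 = rep$f1,
    mse_db = rep_mse)
}

aggregate_trials <- function(trials, selected) {
  sel <- trials[selected, trial_metric_names, drop = FALSE]
  if (nrow(sel) == 0L) {
    return(list(mean = NULL, sd = NULL, empty = TRUE))
  }
  sds <- if (nrow(sel) == 1L) {
    stats::setNames(numeric(ncol(sel)), colnames(sel))
  } else {
    apply(sel, 2L, stats::sd)
  }
  list(mean = colMeans(sel), sd = sds, empty = FALSE)
}

#' Run repeated randomized training trials
#'
#' Implements the repeated-trial protocol: each trial redraws the
#' train/validation/test split (unless `freeze_split`) and re-initializes
#' the model weights under a trial-specific seed (`base_seed + trial`). A
#' trial is selected iff its validation balanced accuracy reaches
#' `filter_threshold`; the summary aggregates test metrics over selected
#' trials (mean and standard deviation), with the unfiltered aggregate
#' also reported for comparison.
#'
#' @param pool Labelled `protein_records` pool.
#' @param encoding A [cksaap_config()]; the pool is encoded once.
#' @param model_options Named list of [model_config()] overrides (e.g.
#'   `latent_dim`, `max_epochs`); `input_dim` and `seed` are supplied
#'   internally.
#' @param splits A [split_spec()] (its `seed` is replaced per trial unless
#'   `freeze_split`).
#' @param n_trials Number of trials (protocol default 20).
#' @param filter_threshold Validation balanced-accuracy threshold for
#'   model selection (protocol default 0.75).
#' @param base_seed Base of the per-trial seed sequence.
#' @param freeze_split Keep one split (drawn under `splits$seed`) for all
#'   trials instead of redrawing.
#' @return A `trial_summary` list: `trials` (per-trial data frame),
#'   `n_trials`, `n_selected`, `mean`/`sd` over selected trials, the
#'   unfiltered `mean_all`/`sd_all`, and `empty` when no trial passed the
#'   filter.
#' @export
run_trials <- function(pool, encoding = cksaap_config(),
                       model_options = list(), splits = split_spec(),
                       n_trials = 20L, filter_threshold = 0.75,
                       base_seed = 0L, freeze_split = FALSE) {
  n_trials <- check_count(n_trials, "n_trials", min = 1L)
  features <- encode_dataset(pool, encoding)
  run_trials_encoded(pool, features, model_options, splits, n_trials,
                     filter_threshold, base_seed, freeze_split)
}

run_trials_encoded <- function(pool, features, model_options, splits,
                               n_trials, filter_threshold, base_seed,
                               freeze_split = FALSE) {
  rows <- vector("list", n_trials)
  failures <- character()
  frozen <- if (freeze_split) make_splits(pool, splits) else NULL
  for (trial in seq_len(n_trials)) {
    seed_t <- as.integer(base_seed) + trial
    parts <- if (freeze_split) frozen else {
      sp <- splits
      sp$seed <- seed_t
      make_splits(pool, sp)
    }
    idx <- function(d) match(d$id, rownames(features))
    cfg <- do.call(model_config, c(
      list(input_dim = ncol(features), seed = seed_t), model_options))
    res <- tryCatch({
      model <- build_model(cfg)
      model <- train_model(model,
                           features[idx(parts$train), , drop = FALSE],
                           parts$train$label,
                           features[idx(parts$validation), , drop = FALSE],
                           parts$validation$label)
      val_ba <- max(model$history$val_balanced_accuracy, na.rm = TRUE)
      test_f <- features[idx(parts$test), , drop = FALSE]
      c(list(trial = trial, seed = seed_t, val_balanced_accuracy = val_ba,
             selected = val_ba >= filter_threshold,
             epochs = nrow(model$history)),
        as.list(evaluate_split(model, test_f, parts$test$label)))
    }, error = function(e) {
      failures <<- c(failures, sprintf("trial %d: %s", trial,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[trial]] <- as.data.frame(res)
  }
  trials <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(trials)) {
    trials <- data.frame(trial = integer(), seed = integer(),
                         val_balanced_accuracy = numeric(),
                         selected = logical(), epochs = integer())
  }
  agg <- aggregate_trials(trials, trials$selected)
  agg_all <- aggregate_trials(trials, rep(TRUE, nrow(trials)))
  structure(
    list(trials = trials, n_trials = n_trials,
         n_selected = sum(trials$selected),
         filter_threshold = filter_threshold,
         mean = agg$mean, sd = agg$sd, empty = agg$empty,
         mean_all = agg_all$mean, sd_all = agg_all$sd,
         failures = failures),
    class = "trial_summary")
}

#' Cardinalities of an ablation grid
#'
#' @param k_values,lv_values Grid axes (defaults: gaps 0..10, latent
#'   dimensions 2..9).
#' @param n_trials Trials per cell (default 20).
#' @return List with `n_cells` and `n_trials_total` (88 and 1,760 at the
#'   defaults).
#' @export
ablation_schedule <- function(k_values = 0:10, lv_values = 2:9,
                              n_trials = 20L) {
  n_cells <- length(k_values) * length(lv_values)
  list(n_cells = n_cells,
       n_trials_total = n_cells * check_count(n_trials, "n_trials", min = 1L))
}

#' Run the k-by-latent-dimension ablation grid
#'
#' For every (k, LV) cell the pool is encoded at that k and
#' [run_trials()] is executed. The best cell maximizes mean test balanced
#' accuracy over selected trials; ties break toward smaller k, then
#' smaller LV (cheaper models). Cells whose trials all failed, or where no
#' trial passed the validation filter, are kept in the grid but marked and
#' never chosen as best unless no cell qualifies.
#'
#' @param pool Labelled `protein_records` pool.
#' @param k_values,lv_values Grid axes (defaults: 0..10 and 2..9 — the
#'   88-configuration grid).
#' @param n_trials Trials per cell (default 20; 1,760 trials at the full
#'   grid).
#' @param encoding_mode Passed to [cksaap_config()].
#' @param model_options,splits,filter_threshold,base_seed As
#'   [run_trials()]; each cell offsets `base_seed` so cells are
#'   independently reproducible.
#' @return An `ablation_result` with the per-cell summaries, a `grid` data
#'   frame of means/sds, and `best` (k, LV).
#' @export
run_ablation <- function(pool, k_values = 0:10, lv_values = 2:9,
                         n_trials = 20L, encoding_mode = "composition",
                         model_options = list(), splits = split_spec(),
                         filter_threshold = 0.75, base_seed = 0L) {
  stopifnot(length(k_values) > 0L, length(lv_values) > 0L)
  k_values <- sort(unique(as.integer(k_values)))
  lv_values <- sort(unique(as.integer(lv_values)))
  cells <- list()
  grid_rows <- list()
  cell_i <- 0L
  for (k in k_values) {
    features <- encode_dataset(pool, cksaap_config(k_max = k,
                                                   mode = encoding_mode))
    for (lv in lv_values) {
      cell_i <- cell_i + 1L
      opts <- model_options
      opts$latent_dim <- lv
      summary_kl <- tryCatch(
        run_trials_encoded(pool, features, opts, splits, n_trials,
                           filter_threshold,
                           base_seed = as.integer(base_seed) + 10000L * cell_i),
        error = function(e) e)
      key <- sprintf("k%d_lv%d", k, lv)
      cells[[key]] <- summary_kl
      failed <- inherits(summary_kl, "error")
      empty <- failed || isTRUE(summary_kl$empty)
      grid_rows[[key]] <- data.frame(
        k = k, lv = lv,
        n_selected = if (failed) NA_integer_ else summary_kl$n_selected,
        mean_balanced_accuracy =
          if (empty) NA_real_ else summary_kl$mean[["balanced_accuracy"]],
        sd_balanced_accuracy =
          if (empty) NA_real_ else summary_kl$sd[["balanced_accuracy"]],
        invalid = failed)
    }
  }
  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL
  structure(list(cells = cells, grid = grid, best = select_best_cell(grid),
                 k_values = k_values, lv_values = lv_values,
                 n_trials = n_trials),
            class = "ablation_result")
}

#' Pick the best ablation cell
#'
#' Maximizes mean balanced accuracy; ties break toward smaller k, then
#' smaller LV (cheaper models). Cells with no aggregate (failed or empty)
#' never win.
#'
#' @param grid Ablation grid data frame with columns `k`, `lv`,
#'   `mean_balanced_accuracy`.
#' @return List with `k`, `lv`, `mean_balanced_accuracy`, or `NULL` if no
#'   cell qualifies.
#' @export
select_best_cell <- function(grid) {
  ok <- !is.na(grid$mean_balanced_accuracy)
  if (!any(ok)) return(NULL)
  cand <- grid[ok, ]
  cand <- cand[order(-cand$mean_balanced_accuracy, cand$k, cand$lv), ]
  list(k = cand$k[1], lv = cand$lv[1],
       mean_balanced_accuracy = cand$mean_balanced_accuracy[1])
}

#' Write ablation outputs
#'
#' Emits the mean±sd balanced-accuracy table (rows k, columns LV), the
#' per-cell grid data, the raw per-trial metrics and the chosen best
#' configuration as TSV/JSON under `out_dir`.
#'
#' @param ablation An `ablation_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
report_ablation <- function(ablation, out_dir) {
  stopifnot(inherits(ablation, "ablation_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  g <- ablation$grid
  tab <- matrix(NA_character_, length(ablation$k_values),
                length(ablation$lv_values),
                dimnames = list(paste0("k=", ablation$k_values),
                                ablation$lv_values))
  for (i in seq_len(nrow(g))) {
    if (!is.na(g$mean_balanced_accuracy[i])) {
      tab[paste0("k=", g$k[i]), as.character(g$lv[i])] <-
        sprintf("%.3f ± %.3f", g$mean_balanced_accuracy[i],
                g$sd_balanced_accuracy[i])
    }
  }
  paths <- c(
    table = file.path(out_dir, "balanced_accuracy_table.tsv"),
    grid = file.path(out_dir, "ablation_grid.tsv"),
    trials = file.path(out_dir, "trial_metrics.tsv"),
    best = file.path(out_dir, "best_configuration.json"))
  utils::write.table(data.frame(gap = rownames(tab), tab, check.names = FALSE),
                     paths["table"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g, paths["grid"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  trial_tabs <- lapply(names(ablation$cells), function(key) {
    cell <- ablation$cells[[key]]
    if (inherits(cell, "error") || nrow(cell$trials) == 0L) return(NULL)
    cbind(cell = key, cell$trials)
  })
  trials <- do.call(rbind, trial_tabs[!vapply(trial_tabs, is.null, logical(1))])
  if (is.null(trials)) trials <- data.frame(cell = character())
  utils::write.table(trials, paths["trials"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(ablation$best %||% list(), paths["best"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
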