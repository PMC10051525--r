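# Training protocol: Adam with a staged learning-rate decay, global-norm
# gradient clipping, oversampling, stratified folds/splits, and a
# reproducible seeded loop.

#' Training configuration
#'
#' Task presets follow the published protocol: MIT-BIH-style runs use 50
#' epochs with the learning rate multiplied by 0.1 at epochs 20 and 40 and
#' 5-fold cross-validation; PTB-style runs use 150 epochs with milestones 40
#' and 120, focal loss and 10-fold CV; Challenge-2017-style runs use 25
#' epochs, batch 64, binary cross-entropy, a 75/10/15 split and
#' reduce-on-plateau (factor 0.9) with early stopping.  The `synthetic`
#' preset is a desk-scale five-class run (30 epochs, milestone 20).
#'
#' @param task One of `"synthetic"`, `"mitbih"`, `"ptb"`, `"challenge2017"`.
#' @param epochs,batch_size,lr0,milestones,lr_factor Optimizer schedule
#'   settings; `lr = lr0 * lr_factor^(#milestones <= epoch)` (epochs are
#'   0-based).
#' @param clip_norm Global L2 gradient-clipping threshold (default 0.001).
#' @param use_gc Apply gradient clipping? (ablation switch)
#' @param oversample Oversample minority classes in the training set?
#' @param oversample_val Also oversample the validation set (the published
#'   protocol does; default off to keep model selection unbiased).
#' @param folds Number of stratified CV folds.
#' @param split Train/validation/test fractions summing to 1.
#' @param repeats Number of repeated runs (distinct seeds) for mean +/- sd
#'   reporting.
#' @param seed Base RNG seed.
#' @param loss `"ce"`, `"focal"` or `"bce"`.
#' @param plateau_decay,plateau_patience Reduce-on-plateau factor and
#'   patience in epochs (Challenge preset: 0.9 / 2).
#' @param early_stop_patience Stop after this many epochs without validation
#'   improvement (`Inf` disables).
#' @param focal_alpha,focal_gamma Focal-loss hyperparameters (0.25 / 2).
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("synthetic", "mitbih", "ptb", "challenge2017"),
                         epochs = NULL, batch_size = 64L, lr0 = 1e-3,
                         milestones = NULL, lr_factor = 0.1,
                         clip_norm = 0.001, use_gc = TRUE,
                         oversample = TRUE, oversample_val = FALSE,
                         folds = NULL, split = c(0.75, 0.10, 0.15),
                         repeats = 1L, seed = 0L, loss = NULL,
                         plateau_decay = NULL, plateau_patience = 2L,
                         early_stop_patience = Inf,
                         focal_alpha = 0.25, focal_gamma = 2) {
  task <- match.arg(task)
  defaults <- switch(task,
    mitbih = list(epochs = 50L, milestones = c(20L, 40L), folds = 5L, loss = "ce"),
    ptb = list(epochs = 150L, milestones = c(40L, 120L), folds = 10L, loss = "focal"),
    challenge2017 = list(epochs = 25L, milestones = integer(0), folds = 1L,
                         loss = "bce", plateau_decay = 0.9,
                         early_stop_patience = 5L),
    synthetic = list(epochs = 30L, milestones = 20L, folds = 5L, loss = "ce")
  )
  epochs <- as.integer(epochs %||% defaults$epochs)
  milestones <- as.integer(milestones %||% defaults$milestones)
  folds <- as.integer(folds %||% defaults$folds)
  loss <- loss %||% defaults$loss
  plateau_decay <- plateau_decay %||% defaults$plateau_decay
  if (is.infinite(early_stop_patience) && !is.null(defaults$early_stop_patience)) {
    early_stop_patience <- defaults$early_stop_patience
  }
  if (abs(sum(split) - 1) > 1e-8) stop_invalid("`split` fractions must sum to 1")
  if (clip_norm <= 0) stop_invalid("`clip_norm` must be positive")
  if (length(milestones)) {
    if (any(diff(milestones) <= 0)) stop_invalid("milestones must be strictly increasing")
    if (max(milestones) >= epochs) stop_invalid("milestones must be < epochs")
  }
  loss <- match.arg(loss, c("ce", "focal", "bce"))
  structure(list(task = task, epochs = epochs, batch_size = as.integer(batch_size),
                 lr0 = lr0, milestones = milestones, lr_factor = lr_factor,
                 clip_norm = clip_norm, use_gc = use_gc,
                 oversample = oversample, oversample_val = oversample_val,
                 folds = folds, split = split, repeats = as.integer(repeats),
                 seed = as.integer(seed), loss = loss,
                 plateau_decay = plateau_decay,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = early_stop_patience,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma),
            class = "train_config")
}

#' Staircase learning-rate schedule
#'
#' `lr = lr0 * lr_factor^(number of milestones <= epoch)` with 0-based
#' epochs, reproducing the published staircase (1e-3 -> 1e-4 -> 1e-5).
#'
#' @param epoch 0-based epoch index, `0 <= epoch < cfg$epochs`.
#' @param cfg A [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch < 0 || epoch >= cfg$epochs) {
    stop_invalid("`epoch` must lie in [0, %d)", cfg$epochs)
  }
  cfg$lr0 * cfg$lr_factor^sum(cfg$milestones <= epoch)
}

#' Clip gradients by global L2 norm
#'
#' Computes the joint L2 norm over all gradient entries; if it exceeds
#' `clip_norm` every gradient is rescaled by `clip_norm / norm` (so the
#' post-clip norm equals the threshold exactly), otherwise gradients pass
#' through unchanged.
#'
#' @param grads Numeric vector, or (nested) list of numeric arrays.
#' @param clip_norm Positive clipping threshold.
#' @return List with `grads` (same structure as the input), `scale` (the
#'   factor applied) and `norm` (the pre-clip global norm).
#' @export
clip_gradients <- function(grads, clip_norm) {
  if (clip_norm <= 0) stop_invalid("`clip_norm` must be positive")
  flat <- unlist(grads, use.names = FALSE)
  if (any(!is.finite(flat))) {
    stop_invalid("non-finite gradient encountered; step must be skipped")
  }
  gn <- sqrt(sum(flat^2))
  scale <- if (gn > clip_norm) clip_norm / gn else 1
  if (scale < 1) {
    grads <- if (is.list(grads)) rapply(grads, function(g) g * scale, how = "replace")
             else grads * scale
  }
  list(grads = grads, scale = scale, norm = gn)
}

dataset_labels <- function(dataset) {
  if (inherits(dataset, "beat_dataset") || inherits(dataset, "segment_dataset")) {
    dataset$labels
  } else {
    stop_invalid("expected a beat_dataset or segment_dataset")
  }
}

dataset_subset <- function(dataset, idx) {
  if (inherits(dataset, "beat_dataset")) {
    beat_dataset(dataset$beats[idx, , drop = FALSE], dataset$labels[idx],
                 dataset$task)
  } else {
    segment_dataset(dataset$segments[idx, , , drop = FALSE],
                    dataset$labels[idx], dataset$source_id[idx])
  }
}

#' Oversample minority classes to the majority count
#'
#' Minority classes are resampled with replacement until every class matches
#' the majority class count; the result is shuffled.  The test set must never
#' be passed through this.
#'
#' @param dataset A [beat_dataset()] or [segment_dataset()].
#' @param seed RNG seed.
#' @return A resampled dataset of size `n_classes * majority_count`.
#' @export
oversample <- function(dataset, seed = 0L) {
  labels <- dataset_labels(dataset)
  if (!length(labels)) stop_invalid("cannot oversample an empty dataset")
  with_seed(seed, {
    counts <- table(labels)
    target <- max(counts)
    idx <- unlist(lapply(names(counts), function(cl) {
      members <- which(labels == as.integer(cl))
      extra <- target - length(members)
      # index into `members` to avoid sample()'s length-1 expansion
      c(members, members[sample.int(length(members), extra, replace = TRUE)])
    }))
    dataset_subset(dataset, idx[sample.int(length(idx))])
  })
}

#' Stratified k-fold assignment
#'
#' Partitions the index set into `k` folds preserving each class's
#' proportion; per-fold class counts differ from the ideal by at most one.
#'
#' @param labels Integer class ids.
#' @param k Number of folds (every class must have at least `k` members).
#' @param seed RNG seed.
#' @return An object of class `fold_plan`: list with `assignments` (fold id
#'   in `1..k` per sample) and `k`.
#' @export
make_folds <- function(labels, k, seed = 0L) {
  k <- as.integer(k)
  if (k < 1L) stop_invalid("`k` must be >= 1")
  if (k == 1L) warning("k = 1 gives a single fold containing everything", call. = FALSE)
  counts <- table(labels)
  small <- counts[counts < k]
  if (length(small)) {
    stop_invalid("class %s has only %d member(s), fewer than k = %d",
                 names(small)[1L], small[1L], k)
  }
  with_seed(seed, {
    assignments <- integer(length(labels))
    for (cl in names(counts)) {
      members <- sample(which(labels == as.integer(cl)))
      assignments[members] <- rep_len(seq_len(k), length(members))
    }
    structure(list(assignments = assignments, k = k), class = "fold_plan")
  })
}

#' Stratified train/validation/test split
#'
#' Splits indices by class with largest-remainder rounding so that per-class
#' ratios are preserved within one sample.  For segment-level tasks apply
#' this to *recordings* before segmentation so no recording contributes to
#' two sets.
#'
#' @param labels Integer class ids (one per sample or per recording).
#' @param fractions Train/val/test fractions summing to 1 (default
#'   0.75/0.10/0.15).
#' @param seed RNG seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_holdout <- function(labels, fractions = c(0.75, 0.10, 0.15), seed = 0L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_invalid("`fractions` must sum to 1")
  with_seed(seed, {
    out <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cl in unique(labels)) {
      members <- sample(which(labels == cl))
      n <- length(members)
      want <- fractions * n
      base <- floor(want)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(want - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      ends <- cumsum(base)
      out$train <- c(out$train, members[seq_len(base[1L])])
      if (base[2L] > 0) out$val <- c(out$val, members[(ends[1L] + 1L):ends[2L]])
      if (base[3L] > 0) out$test <- c(out$test, members[(ends[2L] + 1L):ends[3L]])
    }
    out
  })
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

batch_loss <- function(cfg, logits, labels) {
  switch(cfg$loss,
         ce = softmax_ce_batch(logits, labels),
         focal = sigmoid_focal_batch(logits, labels, cfg$focal_alpha, cfg$focal_gamma),
         bce = sigmoid_bce_batch(logits, labels))
}

dataset_inputs <- function(dataset, idx) {
  if (inherits(dataset, "beat_dataset")) {
    x <- dataset$beats[idx, , drop = FALSE]
    array(x, c(nrow(x), ncol(x), 1L))
  } else {
    dataset$segments[idx, , , drop = FALSE]
  }
}

eval_on <- function(model, dataset, cfg, batch_size = 256L) {
  labels <- dataset_labels(dataset)
  n <- length(labels)
  loss <- 0
  correct <- 0L
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    idx <- s:e
    fw <- model_forward(model, dataset_inputs(dataset, idx))
    bl <- batch_loss(cfg, fw$logits, labels[idx])
    loss <- loss + bl$loss * length(idx)
    pred <- if (model$cfg$n_classes == 1L) as.integer(bl$probs > 0.5)
            else max.col(fw$probs) - 1L
    correct <- correct + sum(pred == labels[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the network
#'
#' Runs the full protocol: per-epoch seeded shuffling, Adam updates under the
#' staircase learning-rate schedule, global-norm gradient clipping (when
#' `cfg$use_gc`), the task's loss, optional reduce-on-plateau (factor
#' `plateau_decay`, patience `plateau_patience`) and early stopping, and
#' best-validation-accuracy checkpoint selection.  Fully reproducible given
#' `cfg$seed` (single-threaded BLAS assumed for bitwise identity).
#'
#' @param model A [build_model()] object.
#' @param train_data,val_data [beat_dataset()] or [segment_dataset()]
#'   (validation optional).  Oversampling is the caller's choice via
#'   [oversample()] or the `cfg` flags inside [run_task()].
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch?
#' @return List with `model` (best-validation weights when validation data
#'   are given, else final), `final_model`, `history` (data.frame of
#'   per-epoch learning rate, losses, accuracies, max post-clip gradient
#'   norm) and `best_epoch`.
#' @export
train_model <- function(model, train_data, val_data = NULL, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  labels <- dataset_labels(train_data)
  n <- length(labels)
  if (!n) stop_invalid("empty training set")
  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    hist <- vector("list", cfg$epochs)
    plateau_scale <- 1
    best <- list(acc = -Inf, params = model$params, state = model$state,
                 epoch = NA_integer_)
    stall <- 0L
    for (epoch in 0:(cfg$epochs - 1L)) {
      lr <- lr_schedule(epoch, cfg) * plateau_scale
      ord <- sample(n)
      ep_loss <- 0
      ep_correct <- 0L
      max_gnorm <- 0
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        x <- dataset_inputs(train_data, idx)
        fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
        model$state <- fw$state
        bl <- batch_loss(cfg, fw$logits, labels[idx])
        if (!is.finite(bl$loss)) {
          stop_invalid("training diverged: non-finite loss at epoch %d", epoch)
        }
        grads <- model_backward(model, fw$caches, bl$dlogits)
        if (cfg$use_gc) {
          cl <- clip_gradients(grads, cfg$clip_norm)
          grads <- cl$grads
          max_gnorm <- max(max_gnorm, min(cl$norm, cfg$clip_norm))
        } else {
          max_gnorm <- max(max_gnorm, sqrt(sum(unlist(grads, use.names = FALSE)^2)))
        }
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params
        opt <- st$opt
        ep_loss <- ep_loss + bl$loss * length(idx)
        pred <- if (model$cfg$n_classes == 1L) as.integer(bl$probs > 0.5)
                else max.col(bl$probs) - 1L
        ep_correct <- ep_correct + sum(pred == labels[idx])
      }
      row <- data.frame(epoch = epoch, lr = lr,
                        train_loss = ep_loss / n, train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_,
                        max_grad_norm = max_gnorm)
      improved <- FALSE
      if (!is.null(val_data)) {
        ev <- eval_on(model, val_data, cfg)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
        if (ev$acc > best$acc) {
          best <- list(acc = ev$acc, params = model$params,
                       state = model$state, epoch = epoch)
          improved <- TRUE
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        if (!is.null(cfg$plateau_decay) && stall > 0L &&
            stall %% cfg$plateau_patience == 0L) {
          plateau_scale <- plateau_scale * cfg$plateau_decay
        }
      }
      hist[[epoch + 1L]] <- row
      if (verbose) {
        message(sprintf("epoch %3d lr=%.2e loss=%.4f acc=%.4f val_acc=%s",
                        epoch, lr, row$train_loss, row$train_acc,
                        ifelse(is.na(row$val_acc), "-", sprintf("%.4f", row$val_acc))))
      }
      if (!is.null(val_data) && is.finite(cfg$early_stop_patience) &&
          stall >= cfg$early_stop_patience) {
        break
      }
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    final_model <- model
    if (!is.null(val_data) && is.finite(best$acc)) {
      model$params <- best$params
      model$state <- best$state
    }
    list(model = model, final_model = final_model, history = history,
         best_epoch = best$epoch)
  })
}

#' Train/evaluate on a dataset with the full protocol
#'
#' Convenience wrapper: stratified holdout split, optional oversampling of
#' the training (and validation) set, training, and a test-set report.
#'
#' @param dataset A labelled [beat_dataset()] or [segment_dataset()].
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @param verbose Passed to [train_model()].
#' @return List with `fit` (the [train_model()] result), `report` (test-set
#'   [eval_metrics()]), `split` indices and `test_acc`.
#' @export
run_task <- function(dataset, model_cfg, cfg, verbose = FALSE) {
  labels <- dataset_labels(dataset)
  sp <- split_holdout(labels, cfg$split, seed = cfg$seed)
  tr <- dataset_subset(dataset, sp$train)
  va <- if (length(sp$val)) dataset_subset(dataset, sp$val) else NULL
  te <- dataset_subset(dataset, sp$test)
  if (cfg$oversample) tr <- oversample(tr, seed = cfg$seed + 1L)
  if (!is.null(va) && cfg$oversample_val) va <- oversample(va, seed = cfg$seed + 2L)
  model <- build_model(model_cfg, seed = cfg$seed)
  fit <- train_model(model, tr, va, cfg, verbose = verbose)
  pr <- predict_model(fit$model, te)
  nclass <- if (inherits(dataset, "beat_dataset") && dataset$task == "five_class") 5L else 2L
  report <- eval_metrics(pr$pred, dataset_labels(te), nclass)
  list(fit = fit, report = report, split = sp, test_acc = report$accuracy)
}

#' Repeat a run with distinct seeds and summarize
#'
#' @param dataset,model_cfg,cfg As in [run_task()].
#' @param repeats Number of runs; seeds are `cfg$seed + 0:(repeats-1)`.
#' @return List with `runs`, `mean_test_acc`, `sd_test_acc`.
#' @export
run_repeated <- function(dataset, model_cfg, cfg, repeats = cfg$repeats) {
  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    runs[[r]] <- run_task(dataset, model_cfg, cfg_r)
  }
  accs <- vapply(runs, function(r) r$test_acc, numeric(1))
  list(runs = runs, test_accs = accs,
       mean_test_acc = mean(accs), sd_test_acc = stats::sd(accs))
}

#' Run the four ablation configurations
#'
#' Trains the full model and the three single-component ablations (without
#' EvoNorm, without SE, without gradient clipping) on the same dataset and
#' split.
#'
#' @param dataset,model_cfg,cfg As in [run_task()].
#' @return data.frame with one row per configuration (`full`, `no_evo`,
#'   `no_se`, `no_gc`) and train/test accuracies.
#' @export
run_ablation <- function(dataset, model_cfg, cfg) {
  variants <- list(
    full = model_cfg,
    no_evo = utils::modifyList(model_cfg, list(use_evo = FALSE)),
    no_se = utils::modifyList(model_cfg, list(use_se = FALSE)),
    no_gc = model_cfg
  )
  out <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    mc <- variants[[i]]
    class(mc) <- "model_config"
    cfg_i <- cfg
    cfg_i$use_gc <- names(variants)[i] != "no_gc"
    res <- run_task(dataset, mc, cfg_i)
    out[[i]] <- data.frame(
      config = names(variants)[i],
      train_acc = utils::tail(res$fit$history$train_acc, 1L),
      test_acc = res$test_acc)
  }
  do.call(rbind, out)
}
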