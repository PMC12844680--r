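# Training engine: pixelwise cross-entropy, Adam, cosine-annealed
# learning rate stepped per epoch, early stopping on validation mean
# IoU, all fully seeded.

#' Training configuration
#'
#' Defaults are the reference recipe: Adam (beta1 0.9, beta2 0.999,
#' weight decay 1e-4), learning rate cosine-annealed from 1e-4 to 1e-6
#' over 200 epochs, batch size 4, early stopping after 5 epochs without
#' validation mIoU improvement.
#'
#' @param lr_init,lr_min cosine schedule endpoints.
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param beta1,beta2,weight_decay Adam hyperparameters; decay is
#'   applied to all parameters.
#' @param patience epochs without val-mIoU improvement before stopping
#'   ("no improvement" means <= best so far).
#' @param amp_enabled mixed-precision request flag; recorded in the
#'   run configuration, but the CPU kernels always compute in double
#'   precision, so it does not alter numerics here.
#' @param class_weights optional length-2 cross-entropy class weights.
#' @param seed master seed for shuffling.
#' @param checkpoint_dir optional directory for the best checkpoint
#'   (saved with [saveRDS()]).
#' @export
train_config <- function(lr_init = 1e-4, lr_min = 1e-6, epochs = 200L,
                         batch_size = 4L, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, patience = 5L,
                         amp_enabled = FALSE, class_weights = NULL,
                         seed = 1L, checkpoint_dir = NULL) {
  if (lr_min >= lr_init) stop("lr_min must be below lr_init")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (patience < 1L) stop("patience must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(lr_init = lr_init, lr_min = lr_min,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, weight_decay = weight_decay,
                 patience = as.integer(patience),
                 amp_enabled = isTRUE(amp_enabled),
                 class_weights = class_weights, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr = lr_min + (lr_init - lr_min) * (1 + cos(pi * epoch / total)) / 2`,
#' monotone non-increasing from `lr_init` at epoch 0 to `lr_min` at
#' `total_epochs`.
#'
#' @param epoch current epoch, 0-based, in \[0, total_epochs\].
#' @param total_epochs schedule length.
#' @param lr_init initial rate.
#' @param lr_min floor rate.
#' @export
cosine_lr <- function(epoch, total_epochs, lr_init = 1e-4, lr_min = 1e-6) {
  if (epoch < 0 || epoch > total_epochs)
    stop("epoch ", epoch, " outside [0, ", total_epochs, "]")
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * epoch / total_epochs))
}

adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0, t = 1L) {
  for (m in collect_mods(model)) {
    if (is.null(m$opt))
      m$opt <- list(m = lapply(m$p, function(p) p * 0),
                    v = lapply(m$p, function(p) p * 0))
    for (nm in names(m$p)) {
      g <- m$g[[nm]]
      if (is.null(g)) next
      m$p[[nm]] <- cpp_adam_step(m$p[[nm]], g, m$opt$m[[nm]],
                                 m$opt$v[[nm]], lr, beta1, beta2, eps,
                                 weight_decay, t)
    }
  }
  invisible(model)
}

# Early-stopping bookkeeping on a sequence of validation metrics:
# strict improvement over the best resets the counter; `patience`
# consecutive non-improvements stop the run. Returns the best epoch
# and the epoch after which training halts (NA = runs to the limit).
early_stop_trace <- function(metrics, patience) {
  best <- -Inf; best_epoch <- NA_integer_; wait <- 0L
  stop_epoch <- NA_integer_
  for (e in seq_along(metrics)) {
    if (!is.na(metrics[e]) && metrics[e] > best) {
      best <- metrics[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= patience) {
      stop_epoch <- e
      break
    }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch,
       best = best)
}

train_one_batch <- function(model, samples, lr, cfg, t, ms_noise = FALSE) {
  batch <- stack_samples(samples)
  if (ms_noise)
    batch$ms <- array(runif(length(batch$ms)), dim(batch$ms))
  zero_grads(model)
  fw <- model_fwd(model, batch$rgb, batch$ms, train = TRUE)
  ls <- softmax_ce(fw$logits, batch$mask, cfg$class_weights)
  if (!is.finite(ls$loss))
    stop("non-finite training loss at optimizer step ", t,
         " (lr = ", lr, "); logits range: ",
         paste(signif(range(fw$logits), 4), collapse = " .. "))
  model_bwd(model, fw$cache, ls$dlogits)
  adam_step(model, lr, cfg$beta1, cfg$beta2, 1e-8, cfg$weight_decay, t)
  ls$loss
}

#' Train a model with the full epoch-based recipe
#'
#' Per epoch: seeded shuffled mini-batches, two-class cross-entropy,
#' Adam updates at the cosine-annealed rate for that epoch; after each
#' epoch the validation mean IoU is computed, the best-mIoU parameter
#' snapshot is retained, and training halts once the metric fails to
#' improve for `patience` consecutive epochs (or at the epoch limit).
#' The returned model carries the best checkpoint's weights.
#'
#' @param model a model from [build_model()].
#' @param train_samples,val_samples non-empty lists of
#'   `multimodal_sample` objects.
#' @param config a [train_config()].
#' @return list with `model` (best weights restored), `history`
#'   (data.frame: epoch, train_loss, val_miou, lr), `best_epoch`,
#'   `best_val_miou` and `stop_reason`.
#' @export
train_model <- function(model, train_samples, val_samples,
                        config = train_config()) {
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    stop("train and validation sets must be non-empty")
  cfg <- config
  n <- length(train_samples)
  best <- -Inf; best_state <- NULL; best_epoch <- NA_integer_
  wait <- 0L; t <- 0L
  hist <- vector("list", cfg$epochs)
  stop_reason <- "completed"
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg$epochs, cfg$lr_init, cfg$lr_min)
    ord <- with_seed(derive_seed(cfg$seed, epoch), sample.int(n))
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      t <- t + 1L
      losses <- c(losses, train_one_batch(model, train_samples[b], lr,
                                          cfg, t))
    }
    miou <- evaluate_dataset(model, val_samples,
                             cfg$batch_size)$pooled[["mIoU"]]
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                val_miou = miou, lr = lr)
    if (!is.na(miou) && miou > best) {
      best <- miou; best_epoch <- epoch; wait <- 0L
      best_state <- model_state(model)
    } else {
      wait <- wait + 1L
    }
    if (wait >= cfg$patience) {
      stop_reason <- "early-stopped"
      break
    }
  }
  if (!is.null(best_state)) load_state(model, best_state)
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(list(config = model$config, mode = model$mode,
                 state = model_state(model), history = history),
            file.path(cfg$checkpoint_dir, "best_checkpoint.rds"))
  }
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_miou = best, stop_reason = stop_reason)
}

#' Step-capped training loop for overfit and diagnostic runs
#'
#' Runs a fixed number of Adam steps at a constant learning rate over
#' seeded shuffled batches, optionally monitoring the training-set
#' crown IoU every `eval_every` steps and stopping once `stop_iou` is
#' reached.
#'
#' @param model a model from [build_model()].
#' @param samples training samples.
#' @param steps maximum optimizer steps.
#' @param lr constant learning rate.
#' @param batch_size mini-batch size.
#' @param seed shuffle seed.
#' @param eval_every evaluation cadence in steps (0 = never).
#' @param stop_iou optional early-exit threshold on train crown IoU
#'   (percent).
#' @param weight_decay,class_weights see [train_config()].
#' @param ms_noise when `TRUE`, the multispectral batch is replaced by
#'   fresh uniform noise at every optimizer step — the
#'   modality-ablation condition used to study how the learned fusion
#'   weights react to an uninformative branch.
#' @return list with `model`, `losses`, `iou_trace` (data.frame:
#'   step, crown_iou) and `steps_run`.
#' @export
train_steps <- function(model, samples, steps, lr = 1e-3, batch_size = 4L,
                        seed = 1L, eval_every = 25L, stop_iou = NULL,
                        weight_decay = 1e-4, class_weights = NULL,
                        ms_noise = FALSE) {
  cfg <- train_config(lr_init = lr, lr_min = lr / 100, epochs = 1L,
                      batch_size = batch_size,
                      weight_decay = weight_decay,
                      class_weights = class_weights, seed = seed)
  n <- length(samples)
  t <- 0L; losses <- numeric(0)
  trace <- list()
  repeat {
    ord <- with_seed(derive_seed(seed, 1000L + t), sample.int(n))
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      t <- t + 1L
      losses <- c(losses, train_one_batch(model, samples[b], lr, cfg, t,
                                          ms_noise = ms_noise))
      if (eval_every > 0L && t %% eval_every == 0L) {
        ev <- evaluate_dataset(model, samples, batch_size)
        ci <- ev$pooled[["IoU"]]
        trace[[length(trace) + 1L]] <- data.frame(step = t,
                                                  crown_iou = ci)
        if (!is.null(stop_iou) && !is.na(ci) && ci >= stop_iou) {
          return(list(model = model, losses = losses,
                      iou_trace = do.call(rbind, trace), steps_run = t))
        }
      }
      if (t >= steps)
        return(list(model = model, losses = losses,
                    iou_trace = if (length(trace)) do.call(rbind, trace),
                    steps_run = t))
    }
  }
}
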