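#' Optimiser / training-loop configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 0.005, mini-batches of 16, and 200 epochs with no early stopping (the
#' validation split is monitored only).
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param seed base seed: controls fold assignment, weight initialisation
#'   (via per-fold derived seeds), batch shuffling and dropout.
#' @param beta1,beta2,eps Adam moment decays and denominator floor
#'   (framework-typical defaults).
#' @param clipnorm global gradient-norm ceiling (the usual LSTM training
#'   safeguard; default 1). `Inf` disables clipping.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 0.005, batch_size = 16,
                         epochs = 200, seed = 1L, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, clipnorm = 1) {
  assert_that(learning_rate > 0 && batch_size > 0 && epochs > 0,
              "learning rate, batch size and epochs must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 clipnorm = clipnorm),
            class = "train_config")
}

# Scale the whole gradient list so its global L2 norm is at most `clipnorm`.
clip_gradients <- function(grads, clipnorm) {
  if (!is.finite(clipnorm)) return(grads)
  sq <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else sq <<- sq + sum(as.numeric(x)^2)
    invisible(NULL)
  }
  walk(grads)
  nrm <- sqrt(sq)
  if (nrm <= clipnorm) return(grads)
  scale_fn <- function(x) if (is.list(x)) lapply(x, scale_fn) else
    x * (clipnorm / nrm)
  scale_fn(grads)
}

# ---- Adam over the nested parameter list -----------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, tc) {
  state$t <- state$t + 1L
  bc1 <- 1 - tc$beta1^state$t
  bc2 <- 1 - tc$beta2^state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      nms <- names(p)
      keys <- if (is.null(nms)) seq_along(p) else nms
      for (key in keys) {
        gk <- g[[key]]
        if (is.null(gk)) next
        r <- step(p[[key]], gk, m[[key]], v[[key]])
        out$p[[key]] <- r$p; out$m[[key]] <- r$m; out$v[[key]] <- r$v
      }
      return(out)
    }
    m2 <- tc$beta1 * m + (1 - tc$beta1) * as.numeric(g)
    v2 <- tc$beta2 * v + (1 - tc$beta2) * as.numeric(g)^2
    upd <- tc$learning_rate * (m2 / bc1) / (sqrt(v2 / bc2) + tc$eps)
    pd <- p - array(upd, dim = if (is.null(dim(p))) length(p) else dim(p))
    list(p = pd, m = m2, v = v2)
  }
  # lstm params are an unnamed list of layers: give them names for traversal
  r <- step(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- training and evaluation ----------------------------------------------

#' Train a model on one fold
#'
#' Mini-batch Adam on the cross-entropy loss for `tc$epochs` epochs. The
#' validation set, when given, is scored after every epoch but never used
#' to stop training or select weights.
#'
#' @param model an `e2ennet_model` (freshly built; trained in place
#'   functionally -- the trained model is returned).
#' @param train,val `segment_set`s (`val` may be `NULL`).
#' @param tc a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` (trained) and `history` (one row per epoch:
#'   loss, acc, val_loss, val_acc).
#' @export
train_fold <- function(model, train, val = NULL, tc = train_config(),
                       verbose = FALSE) {
  n <- dim(train$segments)[1]
  assert_that(n > 0, "empty training split")
  assert_that(max(train$labels) < model$config$n_classes,
              "labels exceed the model's class count")
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  opt <- adam_init(model$params)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      at <- 1L
      while (at <= n) {
        idx <- ord[at:min(n, at + tc$batch_size - 1L)]
        lg <- net_loss_grads(model,
                             train$segments[idx, , , drop = FALSE],
                             train$labels[idx], training = TRUE)
        model <- lg$model          # carries updated BN running moments
        up <- adam_update(model$params,
                          clip_gradients(lg$grads, tc$clipnorm), opt, tc)
        model$params <- up$params
        opt$m <- up$state$m; opt$v <- up$state$v; opt$t <- up$state$t
        ep_loss <- ep_loss + lg$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(lg$probs) - 1L == train$labels[idx])
        at <- at + tc$batch_size
      }
      vl <- va <- NA_real_
      if (!is.null(val) && dim(val$segments)[1] > 0) {
        pv <- predict_proba(model, val)
        vl <- cross_entropy_loss(pv, val$labels)
        va <- mean(max.col(pv) - 1L == val$labels)
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                     acc = ep_correct / n,
                                     val_loss = vl, val_acc = va))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s",
                        ep, ep_loss / n, ep_correct / n,
                        ifelse(is.na(va), "-", sprintf("%.3f", va))))
    }
  })
  list(model = model, history = hist)
}

#' Evaluate a trained model on a test segment set
#'
#' Segment-level accuracy (each 1-s segment votes independently), the
#' `N x N` confusion matrix (true classes in rows), and as a secondary
#' metric the trial-level accuracy under majority voting of a trial's
#' segments.
#'
#' @param model a trained `e2ennet_model`.
#' @param test a `segment_set`.
#' @return list with `accuracy`, `confusion`, `trial_accuracy`,
#'   `predictions`.
#' @export
evaluate <- function(model, test) {
  probs <- predict_proba(model, test)
  pred <- max.col(probs) - 1L
  N <- model$config$n_classes
  confusion <- matrix(0L, N, N,
                      dimnames = list(true = 0:(N - 1), pred = 0:(N - 1)))
  for (i in seq_along(pred))
    confusion[test$labels[i] + 1L, pred[i] + 1L] <-
      confusion[test$labels[i] + 1L, pred[i] + 1L] + 1L
  trial_ok <- vapply(unique(test$trial_index), function(tr) {
    sel <- test$trial_index == tr
    vote <- as.integer(names(which.max(table(pred[sel]))))
    vote == test$labels[sel][1]
  }, logical(1))
  list(accuracy = mean(pred == test$labels), confusion = confusion,
       trial_accuracy = mean(trial_ok), predictions = pred)
}

# ---- fold construction -----------------------------------------------------

#' Trial-wise cross-validation fold plans
#'
#' Builds the subject-dependent fold schemes: `deap5` (40 trials, 5 folds
#' of 8 test trials, 8 validation trials drawn from the 32 training
#' trials), `dreamer6` (18 trials, 6 folds of 3, 3 validation trials),
#' `mped4` (28 trials = 7 emotion classes x 4 clips; 4 folds whose test
#' sets hold exactly one clip of every class, 7 class-balanced validation
#' trials) and `generic` (`k` near-equal folds). Validation trials are
#' drawn from -- and remain part of -- the training set; they are monitored
#' only. Test sets are disjoint across folds and jointly cover every trial.
#'
#' @param n_trials number of trials.
#' @param scheme `"deap5"`, `"dreamer6"`, `"mped4"` or `"generic"`.
#' @param labels per-trial 0-based classes; required for `mped4`.
#' @param seed integer seed for the trial permutation.
#' @param k fold count for `generic` (default 5).
#' @return a `fold_plan`: list with `k`, `scheme`, `seed` and `folds`, each
#'   fold a list of `train`, `val`, `test` trial indices.
#' @export
make_folds <- function(n_trials, scheme = c("deap5", "dreamer6", "mped4",
                                            "generic"),
                       labels = NULL, seed = 1L, k = 5L) {
  scheme <- match.arg(scheme)
  spec <- switch(scheme,
    deap5    = list(n = 40L, k = 5L, n_val = 8L),
    dreamer6 = list(n = 18L, k = 6L, n_val = 3L),
    mped4    = list(n = 28L, k = 4L, n_val = 7L),
    generic  = list(n = n_trials, k = as.integer(k),
                    n_val = max(1L, n_trials %/% as.integer(k))))
  assert_that(n_trials == spec$n,
              "scheme '%s' expects %d trials, got %d",
              scheme, spec$n, n_trials)
  kk <- spec$k
  with_seed(seed, {
    folds <- vector("list", kk)
    if (scheme == "mped4") {
      assert_that(!is.null(labels) && length(labels) == n_trials,
                  "mped4 needs per-trial class labels")
      cls <- sort(unique(labels))
      assert_that(length(cls) == 7L &&
                    all(table(labels) == n_trials / 7L),
                  "mped4 expects 7 classes with equally many clips each")
      # one clip of each class per test fold
      assign <- matrix(0L, nrow = kk, ncol = length(cls))
      for (j in seq_along(cls)) {
        tr <- which(labels == cls[j])
        assign[, j] <- sample(tr)
      }
      for (f in seq_len(kk)) {
        test <- sort(assign[f, ])
        train <- setdiff(seq_len(n_trials), test)
        # class-balanced validation: one training clip per class
        val <- vapply(cls, function(cl)
          sample(intersect(train, which(labels == cl)), 1L), integer(1))
        folds[[f]] <- list(train = train, val = sort(val), test = test)
      }
    } else {
      perm <- sample.int(n_trials)
      sizes <- rep(n_trials %/% kk, kk)
      extra <- n_trials %% kk
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      at <- 0L
      for (f in seq_len(kk)) {
        test <- sort(perm[at + seq_len(sizes[f])])
        at <- at + sizes[f]
        train <- setdiff(seq_len(n_trials), test)
        val <- sort(sample(train, min(spec$n_val, length(train))))
        folds[[f]] <- list(train = train, val = val, test = test)
      }
    }
    structure(list(k = kk, scheme = scheme, seed = as.integer(seed),
                   folds = folds),
              class = "fold_plan")
  })
}

# ---- the full subject-dependent protocol -----------------------------------

#' Subject-dependent trial-wise cross-validation
#'
#' The complete protocol: preprocess the recording (baseline removal +
#' 1-s slicing), derive per-trial labels (binarised at the dialect's
#' threshold for continuous ratings), build the dialect's fold plan, and
#' for every fold train a freshly initialised network on the training
#' trials' segments and score it on the held-out test trials. Whole trials
#' -- never individual segments -- move between train and test, so no
#' within-trial leakage can occur.
#'
#' @param rec a [recording_set()].
#' @param dimension rating dimension for 2-class tasks (`"valence"`,
#'   `"arousal"`, `"dominance"`); ignored for discrete labels.
#' @param mc optional [model_config()]; sized from the data when omitted.
#' @param tc a [train_config()].
#' @param scheme fold scheme; defaults to the dialect's
#'   (deap5 / dreamer6 / mped4, generic 5-fold otherwise).
#' @param input_mode model input: `"raw"` segments, `"de"` / `"psd"`
#'   feature maps, or `"raw+psd+de"`.
#' @param k fold count when `scheme = "generic"`.
#' @param keep_models keep each fold's trained model in the result
#'   (off by default; models are large).
#' @param verbose print per-epoch progress.
#' @return a `cv_result`: per-fold accuracies, their mean and sd, the
#'   pooled segment-level accuracy, the summed confusion matrix, per-fold
#'   training histories, the fold plan and config snapshots.
#' @export
run_subject_dependent_cv <- function(rec, dimension = "valence", mc = NULL,
                                     tc = train_config(), scheme = NULL,
                                     input_mode = "raw", k = 5L,
                                     keep_models = FALSE,
                                     verbose = FALSE) {
  stopifnot(inherits(rec, "recording_set"))
  if (is.null(scheme))
    scheme <- switch(rec$dialect, deap = "deap5", dreamer = "dreamer6",
                     mped = "mped4", "generic")
  seg <- preprocess_recording(rec, dimension = dimension)
  if (input_mode != "raw") {
    inp <- assemble_model_input(seg, mode = input_mode)
    seg <- segment_set(inp$x, inp$labels, inp$trial_index, seg$fs,
                       seg$n_classes)
  }
  trial_labels <- recording_labels(rec, dimension)
  plan <- make_folds(n_trials(rec), scheme, labels = trial_labels,
                     seed = tc$seed, k = k)
  if (is.null(mc)) {
    d <- dim(seg$segments)
    pools <- default_pools(d[3])
    mc <- model_config(C = d[2], T = d[3], n_classes = seg$n_classes,
                       pool1 = pools[1], pool2 = pools[2], seed = tc$seed)
  }

  fold_acc <- numeric(plan$k)
  fold_trial_acc <- numeric(plan$k)
  histories <- vector("list", plan$k)
  models <- if (keep_models) vector("list", plan$k) else NULL
  confusion <- NULL
  n_correct <- 0L; n_total <- 0L
  for (f in seq_len(plan$k)) {
    fold <- plan$folds[[f]]
    tr_seg <- subset_segments(seg, segments_of_trials(seg, fold$train))
    va_seg <- subset_segments(seg, segments_of_trials(seg, fold$val))
    te_seg <- subset_segments(seg, segments_of_trials(seg, fold$test))
    mcf <- mc
    mcf$seed <- derive_seed(tc$seed, f)
    tcf <- tc
    tcf$seed <- derive_seed(tc$seed, 1000L + f)
    model <- build_model(mcf)
    tr <- train_fold(model, tr_seg, va_seg, tcf, verbose = verbose)
    ev <- evaluate(tr$model, te_seg)
    fold_acc[f] <- ev$accuracy
    fold_trial_acc[f] <- ev$trial_accuracy
    histories[[f]] <- tr$history
    if (keep_models) models[[f]] <- tr$model
    confusion <- if (is.null(confusion)) ev$confusion
                 else confusion + ev$confusion
    n_correct <- n_correct + sum(diag(ev$confusion))
    n_total <- n_total + sum(ev$confusion)
  }
  structure(list(fold_accuracy = fold_acc, mean = mean(fold_acc),
                 sd = stats::sd(fold_acc),
                 pooled_accuracy = n_correct / n_total,
                 trial_accuracy = fold_trial_acc,
                 confusion = confusion, histories = histories,
                 models = models,
                 fold_plan = plan, model_config = mc, train_config = tc,
                 dimension = dimension, input_mode = input_mode),
            class = "cv_result")
}

# Pool sizes that tile a given input width: the architecture's (4, 8) when
# it divides evenly, degrading gracefully for feature-map inputs.
default_pools <- function(T) {
  if (T %% 32 == 0) return(c(4L, 8L))
  for (p in list(c(2L, 3L), c(2L, 2L), c(1L, 2L), c(1L, 1L)))
    if (T %% (p[1] * p[2]) == 0) return(p)
  c(1L, 1L)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s, %d folds: mean accuracy %.2f%% +/- %.2f%% (pooled %.2f%%)\n",
    x$fold_plan$scheme, x$fold_plan$k, 100 * x$mean, 100 * x$sd,
    100 * x$pooled_accuracy))
  cat("  per fold:", paste(sprintf("%.1f%%", 100 * x$fold_accuracy),
                           collapse = " "), "\n")
  invisible(x)
}
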