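# Episodic N-way K-shot training with the MSE relation loss (relation and
# Siamese heads) or prototypical negative log-likelihood, Adam optimisation,
# channel-shuffle augmentation and periodic evaluation on the meta-test
# bundle.

#' Mean-squared-error relation loss of an episode
#'
#' Sum (default) over every (class, query) pair of the squared difference
#' between the predicted relation score and the 0/1 label-match target.
#'
#' @param scores numeric matrix `[n_way x n_query]` of relation scores.
#' @param targets matching 0/1 matrix from [relation_targets()].
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return nonnegative loss.
#' @export
mse_episode_loss <- function(scores, targets, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!all(dim(as.matrix(scores)) == dim(as.matrix(targets))))
    stop("shape mismatch between scores and targets")
  se <- (scores - targets)^2
  if (reduction == "sum") sum(se) else mean(se)
}

#' Training configuration
#'
#' Defaults follow the reference hyperparameters for this model family:
#' Adam, MSE loss, 1001 training epochs with one episode per epoch, a
#' 50-episode test every 20 epochs, 20 queries per class, learning rate 1e-4
#' (1e-5 for the prototypical baseline), seed 512, dropout 0.3 and SE ratio
#' 16 (the last two live in the model configs).
#'
#' @param model_kind `"relation"`, `"siamese"` or `"proto"`.
#' @param spec an [episode_spec()].
#' @param learning_rate Adam step size; `NULL` picks the per-model default.
#' @param epochs training epochs (default 1001).
#' @param episodes_per_epoch episodes (optimizer steps) per epoch (default 1).
#' @param eval_every run a test every this many epochs (default 20).
#' @param test_episodes episodes per test (default 50).
#' @param seed RNG seed controlling initialisation, episode sampling,
#'   augmentation and dropout (default 512).
#' @param augment apply channel-shuffle augmentation to training episodes
#'   (default TRUE; never applied at test time).
#' @param loss_reduction `"sum"` (default) or `"mean"` for the MSE losses.
#' @param pooled_metrics pool predictions across a test's episodes into one
#'   accuracy/F1 per test (default TRUE); otherwise average per-episode
#'   metrics.
#' @param embed_cfg,metric_cfg model architecture configurations.
#' @param siamese_hidden hidden width of the Siamese head (default 64).
#' @return list of class `train_config`.
#' @export
train_config <- function(model_kind = c("relation", "siamese", "proto"),
                         spec = episode_spec(),
                         learning_rate = NULL, epochs = 1001L,
                         episodes_per_epoch = 1L, eval_every = 20L,
                         test_episodes = 50L, seed = 512L, augment = TRUE,
                         loss_reduction = c("sum", "mean"),
                         pooled_metrics = TRUE,
                         embed_cfg = embedding_config(),
                         metric_cfg = metric_config(),
                         siamese_hidden = 64L) {
  model_kind <- match.arg(model_kind)
  loss_reduction <- match.arg(loss_reduction)
  if (is.null(learning_rate))
    learning_rate <- switch(model_kind, relation = 1e-4, siamese = 1e-4,
                            proto = 1e-5)
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(model_kind = model_kind, spec = spec,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 eval_every = as.integer(eval_every),
                 test_episodes = as.integer(test_episodes),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 loss_reduction = loss_reduction,
                 pooled_metrics = isTRUE(pooled_metrics),
                 embed_cfg = embed_cfg, metric_cfg = metric_cfg,
                 siamese_hidden = as.integer(siamese_hidden)),
            class = "train_config")
}

# ---- shared helpers ---------------------------------------------------------

# Flattened support list (class-major) followed by queries.
episode_batch <- function(ep) {
  c(unlist(ep$support, recursive = FALSE), ep$query)
}

# Apply one channel permutation to every sample of the episode.
shuffle_episode <- function(ep) {
  K <- ep$spec$k_shot; N <- ep$spec$n_way
  batch <- channel_shuffle(episode_batch(ep))
  ep$support <- lapply(seq_len(N), function(i)
    batch[((i - 1L) * K + 1L):(i * K)])
  ep$query <- batch[N * K + seq_along(ep$query)]
  ep
}

# Flatten [To, B, Fc] embeddings to a [B, To*Fc] matrix (time fastest).
flatten_embeddings <- function(E) {
  d <- dim(E)
  t(matrix(aperm(E, c(1L, 3L, 2L)), d[1] * d[3], d[2]))
}

unflatten_embeddings <- function(M, To, Fc) {
  B <- nrow(M)
  aperm(array(t(M), c(To, Fc, B)), c(1L, 3L, 2L))
}

# Per-class mean over support embeddings. E_sup: [To, N*K, Fc], class-major.
support_class_means <- function(E_sup, N, K) {
  d <- dim(E_sup)
  Ec <- array(0, c(d[1], N, d[3]))
  for (k in seq_len(K))
    Ec <- Ec + E_sup[, (seq_len(N) - 1L) * K + k, , drop = FALSE]
  Ec / K
}

# ---- relation model step ----------------------------------------------------

relation_forward <- function(model, ep, train = FALSE) {
  N <- ep$spec$n_way; K <- ep$spec$k_shot
  nq <- length(ep$query)
  X <- batch_array(episode_batch(ep))
  ef <- embed_fwd(model$params$embed, model$state$embed, model$embed_cfg,
                  X, train)
  E <- ef$out
  To <- dim(E)[1]; Fc <- dim(E)[3]
  Ec <- support_class_means(E[, seq_len(N * K), , drop = FALSE], N, K)
  Eq <- E[, N * K + seq_len(nq), , drop = FALSE]
  iidx <- rep(seq_len(N), times = nq)
  jidx <- rep(seq_len(nq), each = N)
  M <- array(0, c(To, N * nq, 2L * Fc))
  M[, , seq_len(Fc)] <- Ec[, iidx, , drop = FALSE]
  M[, , Fc + seq_len(Fc)] <- Eq[, jidx, , drop = FALSE]
  hf <- relation_head_fwd(model$params$head, model$state$head,
                          model$metric_cfg, M, train)
  list(scores = matrix(hf$scores, N, nq),
       ef = ef, hf = hf, N = N, K = K, nq = nq, To = To, Fc = Fc,
       state = list(embed = ef$state, head = hf$state))
}

relation_backward <- function(model, fw, dscores) {
  N <- fw$N; K <- fw$K; nq <- fw$nq; To <- fw$To; Fc <- fw$Fc
  hb <- relation_head_bwd(as.vector(dscores), fw$hf$cache,
                          model$params$head, model$metric_cfg)
  dM <- hb$dm
  dMc <- dM[, , seq_len(Fc), drop = FALSE]
  dMq <- dM[, , Fc + seq_len(Fc), drop = FALSE]
  dim(dMc) <- c(To, N, nq, Fc)
  dim(dMq) <- c(To, N, nq, Fc)
  dEc <- colSums(aperm(dMc, c(3L, 1L, 2L, 4L)), dims = 1L)  # sum over queries
  dEq <- colSums(aperm(dMq, c(2L, 1L, 3L, 4L)), dims = 1L)  # sum over classes
  B <- N * K + nq
  dE <- array(0, c(To, B, Fc))
  dE[, seq_len(N * K), ] <- (dEc / K)[, rep(seq_len(N), each = K), ,
                                      drop = FALSE]
  dE[, N * K + seq_len(nq), ] <- dEq
  eb <- embed_bwd(dE, fw$ef$cache, model$params$embed, model$embed_cfg)
  list(embed = eb$grads, head = hb$grads)
}

relation_step <- function(model, ep, train = TRUE) {
  fw <- relation_forward(model, ep, train)
  targets <- relation_targets(ep)
  loss <- mse_episode_loss(fw$scores, targets)
  dscores <- 2 * (fw$scores - targets)
  grads <- relation_backward(model, fw, dscores)
  list(loss = loss, grads = grads, state = fw$state, scores = fw$scores)
}

# ---- siamese model step -----------------------------------------------------

siamese_forward <- function(model, ep, train = FALSE) {
  N <- ep$spec$n_way; K <- ep$spec$k_shot
  nq <- length(ep$query)
  X <- batch_array(episode_batch(ep))
  ef <- embed_fwd(model$params$embed, model$state$embed, model$embed_cfg,
                  X, train)
  E <- ef$out
  To <- dim(E)[1]; Fc <- dim(E)[3]
  Em <- flatten_embeddings(E)
  Vsup <- Em[seq_len(N * K), , drop = FALSE]
  V <- rowsum(Vsup, rep(seq_len(N), each = K)) / K
  U <- Em[N * K + seq_len(nq), , drop = FALSE]
  iidx <- rep(seq_len(N), times = nq)
  jidx <- rep(seq_len(nq), each = N)
  diffs <- V[iidx, , drop = FALSE] - U[jidx, , drop = FALSE]
  h <- abs(diffs)
  p <- model$params$head
  a1 <- sweep(h %*% p$fc1$W, 2L, p$fc1$b, "+")
  h1 <- pmax(a1, 0)
  logit <- sweep(h1 %*% p$fc2$W, 2L, p$fc2$b, "+")
  scores <- .sigmoid(drop(logit))
  list(scores = matrix(scores, N, nq), ef = ef, h = h, a1 = a1, h1 = h1,
       diffs = diffs, iidx = iidx, jidx = jidx, N = N, K = K, nq = nq,
       To = To, Fc = Fc, state = list(embed = ef$state))
}

siamese_backward <- function(model, fw, dscores) {
  p <- model$params$head
  s <- as.vector(fw$scores)
  dlogit <- matrix(as.vector(dscores) * s * (1 - s), ncol = 1L)
  gfc2 <- list(W = crossprod(fw$h1, dlogit), b = colSums(dlogit))
  dh1 <- dlogit %*% t(p$fc2$W)
  da1 <- dh1 * (fw$a1 > 0)
  gfc1 <- list(W = crossprod(fw$h, da1), b = colSums(da1))
  dh <- da1 %*% t(p$fc1$W)
  ddiff <- dh * sign(fw$diffs)
  dV <- rowsum(ddiff, fw$iidx)
  dU <- -rowsum(ddiff, fw$jidx)
  N <- fw$N; K <- fw$K
  dEm <- rbind((dV / K)[rep(seq_len(N), each = K), , drop = FALSE], dU)
  dE <- unflatten_embeddings(dEm, fw$To, fw$Fc)
  eb <- embed_bwd(dE, fw$ef$cache, model$params$embed, model$embed_cfg)
  list(embed = eb$grads, head = list(fc1 = gfc1, fc2 = gfc2))
}

siamese_step <- function(model, ep, train = TRUE) {
  fw <- siamese_forward(model, ep, train)
  targets <- relation_targets(ep)
  loss <- mse_episode_loss(fw$scores, targets)
  dscores <- 2 * (fw$scores - targets)
  grads <- siamese_backward(model, fw, dscores)
  list(loss = loss, grads = grads, state = fw$state, scores = fw$scores)
}

# ---- prototypical model step ------------------------------------------------

proto_forward <- function(model, ep, train = FALSE) {
  N <- ep$spec$n_way; K <- ep$spec$k_shot
  nq <- length(ep$query)
  X <- batch_array(episode_batch(ep))
  ef <- embed_fwd(model$params$embed, model$state$embed, model$embed_cfg,
                  X, train)
  E <- ef$out
  To <- dim(E)[1]; Fc <- dim(E)[3]
  Em <- flatten_embeddings(E)
  P <- rowsum(Em[seq_len(N * K), , drop = FALSE],
              rep(seq_len(N), each = K)) / K
  U <- Em[N * K + seq_len(nq), , drop = FALSE]
  d2 <- outer(rowSums(U^2), rep(1, N)) + outer(rep(1, nq), rowSums(P^2)) -
    2 * U %*% t(P)
  z <- -d2
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  prob <- e / rowSums(e)                      # [nq x N]
  list(prob = prob, P = P, U = U, ef = ef, N = N, K = K, nq = nq,
       To = To, Fc = Fc, state = list(embed = ef$state))
}

proto_step <- function(model, ep, train = TRUE) {
  fw <- proto_forward(model, ep, train)
  true_idx <- match(ep$query_labels, ep$class_order)
  picked <- fw$prob[cbind(seq_len(fw$nq), true_idx)]
  loss <- -sum(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, fw$nq, fw$N)
  onehot[cbind(seq_len(fw$nq), true_idx)] <- 1
  dlogits <- fw$prob - onehot                 # logits = -d2
  dd2 <- -dlogits
  dU <- 2 * (rowSums(dd2) * fw$U - dd2 %*% fw$P)
  dP <- -2 * (crossprod(dd2, fw$U) - colSums(dd2) * fw$P)
  dEm <- rbind((dP / fw$K)[rep(seq_len(fw$N), each = fw$K), , drop = FALSE],
               dU)
  dE <- unflatten_embeddings(dEm, fw$To, fw$Fc)
  eb <- embed_bwd(dE, fw$ef$cache, model$params$embed, model$embed_cfg)
  list(loss = loss, grads = list(embed = eb$grads), state = fw$state,
       scores = t(fw$prob))
}

model_step <- function(model, ep, train = TRUE) {
  switch(model$kind,
         relation = relation_step(model, ep, train),
         siamese = siamese_step(model, ep, train),
         proto = proto_step(model, ep, train))
}

#' Classify the queries of one episode
#'
#' Evaluation mode: deterministic, no augmentation, no dropout. Ties at the
#' argmax go to the lowest class index.
#'
#' @param model a trained `fewshot_model`.
#' @param ep an episode from [sample_episode()].
#' @return list with `predicted` and `reference` label vectors and the raw
#'   `[n_way x n_query]` score matrix.
#' @export
predict_episode <- function(model, ep) {
  fw <- switch(model$kind,
               relation = relation_forward(model, ep, train = FALSE),
               siamese = siamese_forward(model, ep, train = FALSE),
               proto = proto_forward(model, ep, train = FALSE))
  scores <- if (model$kind == "proto") t(fw$prob) else fw$scores
  pred_idx <- apply(scores, 2L, which.max)
  list(predicted = ep$class_order[pred_idx],
       reference = ep$query_labels,
       scores = scores)
}

#' Evaluate a model over repeated episodes
#'
#' Runs `n_episodes` freshly sampled N-way K-shot tasks and either pools all
#' query predictions into one confusion matrix (one accuracy/F1 per test,
#' the default) or averages per-episode metrics.
#'
#' @param model a `fewshot_model`.
#' @param bundle the meta-test [dataset_bundle].
#' @param spec an [episode_spec()].
#' @param n_episodes episodes per test (default 50).
#' @param pooled pool predictions before computing metrics (default TRUE).
#' @param seed optional private RNG seed for the episode draws.
#' @return list with `accuracy`, `macro_f1` and the pooled `confusion`
#'   matrix.
#' @export
evaluate_few_shot <- function(model, bundle, spec, n_episodes = 50L,
                              pooled = TRUE, seed = NULL) {
  with_seed(seed, {
    y_true <- character(0); y_pred <- character(0)
    per_acc <- numeric(0); per_f1 <- numeric(0)
    for (e in seq_len(n_episodes)) {
      ep <- sample_episode(bundle, spec)
      pr <- predict_episode(model, ep)
      y_true <- c(y_true, pr$reference)
      y_pred <- c(y_pred, pr$predicted)
      if (!pooled) {
        cm_e <- confusion(pr$reference, pr$predicted, bundle$classes)
        per_acc <- c(per_acc, accuracy(cm_e))
        per_f1 <- c(per_f1, macro_f1(cm_e))
      }
    }
    cm <- confusion(y_true, y_pred, bundle$classes)
    if (pooled)
      list(accuracy = accuracy(cm), macro_f1 = macro_f1(cm), confusion = cm)
    else
      list(accuracy = mean(per_acc), macro_f1 = mean(per_f1), confusion = cm)
  })
}

#' Train a few-shot model episodically
#'
#' Per epoch, samples `episodes_per_epoch` N-way K-shot episodes from the
#' meta-training bundle, applies channel-shuffle augmentation (one shared
#' permutation per episode), computes the model loss (MSE relation loss for
#' the relation and Siamese heads, prototypical negative log-likelihood for
#' the prototypical model) and takes one Adam step per episode. Every
#' `eval_every` epochs the model is tested on the meta-testing bundle with
#' `test_episodes` episodes and the result appended to the history. The
#' whole run is reproducible from `config$seed`.
#'
#' @param bundle_train meta-training [dataset_bundle].
#' @param bundle_test meta-testing [dataset_bundle].
#' @param config a [train_config()].
#' @param verbose print progress at every evaluation point (default FALSE).
#' @return list with the trained `model` and `history`, a data.frame with
#'   one row per evaluation point (`epoch`, `loss`, `accuracy`, `macro_f1`).
#' @export
train_few_shot <- function(bundle_train, bundle_test, config,
                           verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  set.seed(config$seed)
  model <- switch(config$model_kind,
    relation = relation_net(config$embed_cfg, config$metric_cfg),
    siamese = siamese_net(config$embed_cfg, config$siamese_hidden),
    proto = proto_net(config$embed_cfg))
  adam <- adam_init(model$params)
  hist_epoch <- integer(0); hist_loss <- numeric(0)
  hist_acc <- numeric(0); hist_f1 <- numeric(0)
  loss <- NA_real_
  for (epoch in seq_len(config$epochs)) {
    for (r in seq_len(config$episodes_per_epoch)) {
      ep <- sample_episode(bundle_train, config$spec)
      if (config$augment) ep <- shuffle_episode(ep)
      st <- model_step(model, ep, train = TRUE)
      loss <- st$loss
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (model ", config$model_kind, ", lr ", config$learning_rate, ")")
      model$state$embed <- st$state$embed
      if (!is.null(st$state$head)) model$state$head <- st$state$head
      if (config$learning_rate > 0) {
        upd <- adam_step(model$params, st$grads, adam, config$learning_rate)
        model$params <- upd$params
        adam <- upd$state
      }
    }
    if (epoch %% config$eval_every == 0L) {
      ev <- evaluate_few_shot(model, bundle_test, config$spec,
                              config$test_episodes,
                              pooled = config$pooled_metrics)
      hist_epoch <- c(hist_epoch, epoch)
      hist_loss <- c(hist_loss, loss)
      hist_acc <- c(hist_acc, ev$accuracy)
      hist_f1 <- c(hist_f1, ev$macro_f1)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f F1 %.3f",
                        epoch, loss, ev$accuracy, ev$macro_f1))
    }
  }
  list(model = model,
       history = data.frame(epoch = hist_epoch, loss = hist_loss,
                            accuracy = hist_acc, macro_f1 = hist_f1))
}

#' Aggregate the stable tail of a training history
#'
#' Summarises the evaluation records whose epoch lies in
#' `[epoch_lo, epoch_hi]` (default 700-1000, the post-convergence window)
#' with means and 95% t-interval half-widths.
#'
#' @param history history data.frame from [train_few_shot()].
#' @param epoch_lo,epoch_hi inclusive epoch window.
#' @return list with `mean_accuracy`, `h_accuracy`, `mean_f1`, `h_f1` and
#'   `n_records`.
#' @export
aggregate_window <- function(history, epoch_lo = 700L, epoch_hi = 1000L) {
  rows <- history[history$epoch >= epoch_lo & history$epoch <= epoch_hi, ]
  if (nrow(rows) == 0L) stop("no evaluation records in epoch window [",
                             epoch_lo, ", ", epoch_hi, "]")
  a <- mean_and_h(rows$accuracy)
  f <- mean_and_h(rows$macro_f1)
  list(mean_accuracy = a$mean, h_accuracy = a$h,
       mean_f1 = f$mean, h_f1 = f$h, n_records = nrow(rows))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration and parameter arrays; loading
#' validates the embedding shape contract by running a zero sample through
#' the network.
#'
#' @param model a `fewshot_model`.
#' @param path file path.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fewshot_model")) stop("not a model checkpoint")
  cfg <- model$embed_cfg
  probe <- matrix(0, cfg$in_timesteps, cfg$in_channels)
  fm <- embed(model, probe)
  if (!all(dim(fm) == c(cfg$out_timesteps, cfg$feature_channels)))
    stop("checkpoint violates the embedding shape contract")
  model
}
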