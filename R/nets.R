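# SE-RelationNet and baseline architectures for [240 x 8] sensor samples.
#
# The embedding module maps a normalised sample to a [63 x 30] feature map:
# stem convolution -> three residual blocks (pathway F1 = three convolutions
# + one squeeze-excitation block, pathway F2 = one projection convolution,
# summed) -> stride-3 temporal pooling -> an un-padded kernel-18 convolution
# reaching exactly 63 time steps. The relation head concatenates a class
# feature map with a query feature map along channels, extracts features
# with a convolution + SE block, summarises time with a single-hidden-layer
# bidirectional GRU, and maps the final states through dropout + a fully
# connected layer + sigmoid to a similarity score in (0, 1).

#' Embedding-module configuration
#'
#' @param n_residual_blocks residual blocks in the embedding (default 3).
#' @param f1_convs_per_block convolutions on the long pathway F1 of each
#'   block (default 3; together with the SE block and the one-convolution
#'   shortcut F2 this makes the 5-layer residual structure).
#' @param se_ratio squeeze-excitation bottleneck reduction ratio (default 16).
#' @param leaky_slope negative-side slope of the leaky ReLU (default 0.01).
#' @param feature_channels embedding width (default 30).
#' @param out_timesteps embedding output length (default 63).
#' @param in_channels,in_timesteps input sample shape (default 8 x 240).
#' @param pool_stride stride/width of the temporal pooling stage (default 3).
#' @param batchnorm batch-normalise after each convolution (default TRUE).
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(n_residual_blocks = 3L, f1_convs_per_block = 3L,
                             se_ratio = 16L, leaky_slope = 0.01,
                             feature_channels = 30L, out_timesteps = 63L,
                             in_channels = 8L, in_timesteps = 240L,
                             pool_stride = 3L, batchnorm = TRUE) {
  cfg <- list(n_residual_blocks = as.integer(n_residual_blocks),
              f1_convs_per_block = as.integer(f1_convs_per_block),
              se_ratio = as.integer(se_ratio), leaky_slope = leaky_slope,
              feature_channels = as.integer(feature_channels),
              out_timesteps = as.integer(out_timesteps),
              in_channels = as.integer(in_channels),
              in_timesteps = as.integer(in_timesteps),
              pool_stride = as.integer(pool_stride),
              batchnorm = isTRUE(batchnorm))
  if (cfg$se_ratio < 1L) stop("se_ratio must be >= 1")
  if (cfg$leaky_slope <= 0 || cfg$leaky_slope >= 1)
    stop("leaky_slope must be in (0, 1)")
  pooled <- cfg$in_timesteps %/% cfg$pool_stride
  cfg$final_kernel <- pooled - cfg$out_timesteps + 1L
  if (cfg$final_kernel < 1L)
    stop("out_timesteps (", cfg$out_timesteps,
         ") unreachable from pooled length ", pooled)
  structure(cfg, class = "embedding_config")
}

#' Metric (relation head) configuration
#'
#' @param conv_channels channels after the head convolution (default 30).
#' @param kernel head convolution kernel (default 3, zero-padded).
#' @param se_ratio SE bottleneck ratio (default 16).
#' @param gru_hidden BiGRU hidden width per direction (default 32).
#' @param dropout dropout rate before the final fully connected layer
#'   (default 0.3).
#' @param leaky_slope leaky ReLU slope (default 0.01).
#' @param batchnorm batch-normalise after the head convolution (default TRUE).
#' @return list of class `metric_config`.
#' @export
metric_config <- function(conv_channels = 30L, kernel = 3L, se_ratio = 16L,
                          gru_hidden = 32L, dropout = 0.3,
                          leaky_slope = 0.01, batchnorm = TRUE) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), se_ratio = as.integer(se_ratio),
                 gru_hidden = as.integer(gru_hidden), dropout = dropout,
                 leaky_slope = leaky_slope, batchnorm = isTRUE(batchnorm)),
            class = "metric_config")
}

# ---- parameter initialisation ----------------------------------------------

init_embed_params <- function(cfg) {
  Fc <- cfg$feature_channels
  blocks <- lapply(seq_len(cfg$n_residual_blocks), function(i) {
    list(convs = lapply(seq_len(cfg$f1_convs_per_block),
                        function(j) init_conv_params(3L, Fc, Fc)),
         bns = lapply(seq_len(cfg$f1_convs_per_block),
                      function(j) init_bn_params(Fc)),
         se = init_se_params(Fc, cfg$se_ratio),
         short = init_conv_params(1L, Fc, Fc))
  })
  names(blocks) <- paste0("block", seq_along(blocks))
  list(stem = init_conv_params(3L, cfg$in_channels, Fc),
       stem_bn = init_bn_params(Fc),
       blocks = blocks,
       final = init_conv_params(cfg$final_kernel, Fc, Fc))
}

init_embed_state <- function(cfg) {
  Fc <- cfg$feature_channels
  blocks <- lapply(seq_len(cfg$n_residual_blocks), function(i)
    lapply(seq_len(cfg$f1_convs_per_block), function(j) init_bn_state(Fc)))
  names(blocks) <- paste0("block", seq_along(blocks))
  list(stem_bn = init_bn_state(Fc), blocks = blocks)
}

init_relation_head_params <- function(cfg, in_channels) {
  H2 <- 2L * cfg$gru_hidden
  list(conv = init_conv_params(cfg$kernel, in_channels, cfg$conv_channels),
       bn = init_bn_params(cfg$conv_channels),
       se = init_se_params(cfg$conv_channels, cfg$se_ratio),
       gru = list(fwd = init_gru_params(cfg$conv_channels, cfg$gru_hidden),
                  bwd = init_gru_params(cfg$conv_channels, cfg$gru_hidden)),
       fc = list(W = matrix(stats::rnorm(H2, sd = 0.05), H2, 1L),
                 b = numeric(1L)))
}

# ---- embedding forward / backward ------------------------------------------

embed_fwd <- function(params, state, cfg, x, train = FALSE) {
  a <- cfg$leaky_slope
  caches <- list()
  cv <- conv1d_fwd(x, params$stem$W, params$stem$b, pad = 1L)
  caches$stem <- cv$cache
  h <- cv$y
  if (cfg$batchnorm) {
    bn <- bn_fwd(h, params$stem_bn$gamma, params$stem_bn$beta,
                 state$stem_bn, train)
    state$stem_bn <- bn$state; caches$stem_bn <- bn$cache; h <- bn$y
  }
  caches$stem_pre <- h
  h <- leaky_relu(h, a)
  for (bi in seq_len(cfg$n_residual_blocks)) {
    bp <- params$blocks[[bi]]
    bcache <- list(x_in = h)
    f1 <- h
    for (ci in seq_len(cfg$f1_convs_per_block)) {
      cv <- conv1d_fwd(f1, bp$convs[[ci]]$W, bp$convs[[ci]]$b, pad = 1L)
      bcache[[paste0("conv", ci)]] <- cv$cache
      f1 <- cv$y
      if (cfg$batchnorm) {
        bn <- bn_fwd(f1, bp$bns[[ci]]$gamma, bp$bns[[ci]]$beta,
                     state$blocks[[bi]][[ci]], train)
        state$blocks[[bi]][[ci]] <- bn$state
        bcache[[paste0("bn", ci)]] <- bn$cache
        f1 <- bn$y
      }
      bcache[[paste0("pre", ci)]] <- f1
      f1 <- leaky_relu(f1, a)
    }
    se <- se_fwd(f1, bp$se)
    bcache$se <- se$cache
    f1 <- se$y
    sh <- conv1d_fwd(bcache$x_in, bp$short$W, bp$short$b)
    bcache$short <- sh$cache
    h <- f1 + sh$y
    caches[[paste0("block", bi)]] <- bcache
  }
  pl <- pool_fwd(h, cfg$pool_stride, cfg$pool_stride)
  caches$pool <- pl$cache
  cv <- conv1d_fwd(pl$y, params$final$W, params$final$b)
  caches$final <- cv$cache
  caches$final_pre <- cv$y
  out <- leaky_relu(cv$y, a)
  list(out = out, cache = caches, state = state)
}

embed_bwd <- function(dout, caches, params, cfg) {
  a <- cfg$leaky_slope
  g <- list()
  dh <- .lrelu_bwd(dout, caches$final_pre, a)
  bw <- conv1d_bwd(dh, caches$final, params$final$W)
  g$final <- list(W = bw$dW, b = bw$db)
  dh <- pool_bwd(bw$dx, caches$pool)
  g$blocks <- vector("list", cfg$n_residual_blocks)
  names(g$blocks) <- paste0("block", seq_len(cfg$n_residual_blocks))
  for (bi in rev(seq_len(cfg$n_residual_blocks))) {
    bp <- params$blocks[[bi]]
    bc <- caches[[paste0("block", bi)]]
    gb <- list(convs = vector("list", cfg$f1_convs_per_block),
               bns = vector("list", cfg$f1_convs_per_block))
    # shortcut pathway
    bws <- conv1d_bwd(dh, bc$short, bp$short$W)
    gb$short <- list(W = bws$dW, b = bws$db)
    dx_total <- bws$dx
    # F1 pathway
    se_b <- se_bwd(dh, bc$se, bp$se)
    gb$se <- se_b$grads
    df1 <- se_b$dx
    for (ci in rev(seq_len(cfg$f1_convs_per_block))) {
      df1 <- .lrelu_bwd(df1, bc[[paste0("pre", ci)]], a)
      if (cfg$batchnorm) {
        bnb <- bn_bwd(df1, bc[[paste0("bn", ci)]])
        gb$bns[[ci]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
        df1 <- bnb$dx
      } else {
        gb$bns[[ci]] <- list(gamma = numeric(cfg$feature_channels),
                             beta = numeric(cfg$feature_channels))
      }
      cvb <- conv1d_bwd(df1, bc[[paste0("conv", ci)]], bp$convs[[ci]]$W)
      gb$convs[[ci]] <- list(W = cvb$dW, b = cvb$db)
      df1 <- cvb$dx
    }
    dh <- dx_total + df1
    # same field order as the parameter tree
    g$blocks[[bi]] <- list(convs = gb$convs, bns = gb$bns, se = gb$se,
                           short = gb$short)
  }
  dh <- .lrelu_bwd(dh, caches$stem_pre, a)
  if (cfg$batchnorm) {
    bnb <- bn_bwd(dh, caches$stem_bn)
    g$stem_bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dh <- bnb$dx
  } else {
    g$stem_bn <- list(gamma = numeric(cfg$feature_channels),
                      beta = numeric(cfg$feature_channels))
  }
  bw <- conv1d_bwd(dh, caches$stem, params$stem$W)
  g$stem <- list(W = bw$dW, b = bw$db)
  # reorder to match the parameter tree layout
  list(grads = list(stem = g$stem, stem_bn = g$stem_bn, blocks = g$blocks,
                    final = g$final),
       dx = bw$dx)
}

# ---- relation head ----------------------------------------------------------

relation_head_fwd <- function(params, state, cfg, m, train = FALSE) {
  a <- cfg$leaky_slope
  caches <- list()
  pad <- (cfg$kernel - 1L) %/% 2L
  cv <- conv1d_fwd(m, params$conv$W, params$conv$b, pad = pad)
  caches$conv <- cv$cache
  h <- cv$y
  if (cfg$batchnorm) {
    bn <- bn_fwd(h, params$bn$gamma, params$bn$beta, state$bn, train)
    state$bn <- bn$state; caches$bn <- bn$cache; h <- bn$y
  }
  caches$pre <- h
  h <- leaky_relu(h, a)
  se <- se_fwd(h, params$se)
  caches$se <- se$cache
  h <- se$y
  gr <- bigru_fwd(h, params$gru)
  caches$gru <- gr$cache
  u <- gr$h_last
  dp <- dropout_fwd(u, cfg$dropout, train)
  caches$drop <- dp$cache
  fc <- dense_fwd(dp$y, params$fc$W, params$fc$b)
  caches$fc <- fc$cache
  scores <- .sigmoid(drop(fc$y))
  caches$scores <- scores
  list(scores = scores, cache = caches, state = state)
}

relation_head_bwd <- function(dscores, caches, params, cfg) {
  a <- cfg$leaky_slope
  s <- caches$scores
  dlogit <- matrix(dscores * s * (1 - s), ncol = 1L)
  fcb <- dense_bwd(dlogit, caches$fc, params$fc$W)
  g <- list()
  g$fc <- list(W = fcb$dW, b = fcb$db)
  du <- dropout_bwd(fcb$dx, caches$drop)
  gb <- bigru_bwd(du, caches$gru, params$gru)
  g$gru <- gb$grads
  dh <- gb$dx
  seb <- se_bwd(dh, caches$se, params$se)
  g$se <- seb$grads
  dh <- .lrelu_bwd(seb$dx, caches$pre, a)
  if (cfg$batchnorm) {
    bnb <- bn_bwd(dh, caches$bn)
    g$bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dh <- bnb$dx
  } else {
    g$bn <- list(gamma = numeric(cfg$conv_channels),
                 beta = numeric(cfg$conv_channels))
  }
  cvb <- conv1d_bwd(dh, caches$conv, params$conv$W)
  g$conv <- list(W = cvb$dW, b = cvb$db)
  list(grads = list(conv = g$conv, bn = g$bn, se = g$se, gru = g$gru,
                    fc = g$fc),
       dm = cvb$dx)
}

# ---- model constructors -----------------------------------------------------

#' Construct an SE-RelationNet model
#'
#' @param embed_cfg an [embedding_config()].
#' @param metric_cfg a [metric_config()].
#' @param seed optional integer; when given, parameters are initialised from
#'   a private RNG stream.
#' @return object of class `c("relation_net", "fewshot_model")`.
#' @export
relation_net <- function(embed_cfg = embedding_config(),
                         metric_cfg = metric_config(), seed = NULL) {
  with_seed(seed, {
    params <- list(embed = init_embed_params(embed_cfg),
                   head = init_relation_head_params(
                     metric_cfg, 2L * embed_cfg$feature_channels))
    state <- list(embed = init_embed_state(embed_cfg),
                  head = list(bn = init_bn_state(metric_cfg$conv_channels)))
    structure(list(kind = "relation", embed_cfg = embed_cfg,
                   metric_cfg = metric_cfg, params = params, state = state),
              class = c("relation_net", "fewshot_model"))
  })
}

#' Construct a Siamese baseline model
#'
#' Shares the embedding architecture; the head takes the elementwise absolute
#' difference between the mean support vector and the query vector (both
#' flattened feature maps) through two fully connected layers and a sigmoid.
#'
#' @param embed_cfg an [embedding_config()].
#' @param hidden width of the first fully connected layer (default 64).
#' @param seed optional integer seed for initialisation.
#' @return object of class `c("siamese_net", "fewshot_model")`.
#' @export
siamese_net <- function(embed_cfg = embedding_config(), hidden = 64L,
                        seed = NULL) {
  with_seed(seed, {
    D <- embed_cfg$out_timesteps * embed_cfg$feature_channels
    params <- list(
      embed = init_embed_params(embed_cfg),
      head = list(
        fc1 = list(W = matrix(stats::rnorm(D * hidden, sd = sqrt(2 / D)),
                              D, hidden),
                   b = numeric(hidden)),
        fc2 = list(W = matrix(stats::rnorm(hidden, sd = 0.05), hidden, 1L),
                   b = numeric(1L))))
    state <- list(embed = init_embed_state(embed_cfg))
    structure(list(kind = "siamese", embed_cfg = embed_cfg,
                   hidden = as.integer(hidden), params = params,
                   state = state),
              class = c("siamese_net", "fewshot_model"))
  })
}

#' Construct a prototypical baseline model
#'
#' Shares the embedding architecture; classification is by softmax over
#' negative squared Euclidean distances between a flattened query embedding
#' and the class prototypes (mean support embeddings). No head parameters.
#'
#' @param embed_cfg an [embedding_config()].
#' @param seed optional integer seed for initialisation.
#' @return object of class `c("proto_net", "fewshot_model")`.
#' @export
proto_net <- function(embed_cfg = embedding_config(), seed = NULL) {
  with_seed(seed, {
    params <- list(embed = init_embed_params(embed_cfg))
    state <- list(embed = init_embed_state(embed_cfg))
    structure(list(kind = "proto", embed_cfg = embed_cfg, params = params,
                   state = state),
              class = c("proto_net", "fewshot_model"))
  })
}

#' @export
print.fewshot_model <- function(x, ...) {
  n_par <- sum(unlist(param_map(x$params, length)))
  cat(sprintf("<%s> %d parameters; embedding [%d x %d] -> [%d x %d]\n",
              class(x)[1], n_par, x$embed_cfg$in_timesteps,
              x$embed_cfg$in_channels, x$embed_cfg$out_timesteps,
              x$embed_cfg$feature_channels))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

# ---- user-facing functional operations --------------------------------------

# Stack a list of [T x C] matrices (or enose_samples) into a [T, B, C] array.
batch_array <- function(samples) {
  mats <- lapply(samples, function(s)
    if (inherits(s, "enose_sample")) s$matrix else as.matrix(s))
  d <- dim(mats[[1]])
  x <- array(0, c(d[1], length(mats), d[2]))
  for (i in seq_along(mats)) x[, i, ] <- mats[[i]]
  x
}

#' Embed samples into feature maps
#'
#' Runs the embedding module in evaluation mode (deterministic). A single
#' `[240 x 8]` sample yields a `[63 x 30]` feature map under the default
#' configuration.
#'
#' @param model a `fewshot_model`.
#' @param x an [enose_sample], a `[T x C]` matrix, or a list of either.
#' @return a `[out_timesteps x feature_channels]` matrix for single input, or
#'   a list of such matrices for list input.
#' @export
embed <- function(model, x) {
  single <- !is.list(x) || inherits(x, "enose_sample")
  xs <- if (single) list(x) else x
  arr <- batch_array(xs)
  if (dim(arr)[1] != model$embed_cfg$in_timesteps ||
      dim(arr)[3] != model$embed_cfg$in_channels)
    stop("input shape [", dim(arr)[1], " x ", dim(arr)[3],
         "] does not match the configured [",
         model$embed_cfg$in_timesteps, " x ", model$embed_cfg$in_channels, "]")
  fw <- embed_fwd(model$params$embed, model$state$embed, model$embed_cfg,
                  arr, train = FALSE)
  maps <- lapply(seq_len(dim(arr)[2]), function(b)
    matrix(fw$out[, b, ], dim(fw$out)[1], dim(fw$out)[3]))
  if (single) maps[[1]] else maps
}

#' Class feature map: elementwise mean of K support feature maps
#'
#' @param support_embeddings list of equally shaped feature-map matrices.
#' @return their elementwise mean (identity for K = 1).
#' @export
class_feature <- function(support_embeddings) {
  if (length(support_embeddings) == 0L) stop("empty support set")
  Reduce(`+`, support_embeddings) / length(support_embeddings)
}

#' Merge a class feature map with a query feature map
#'
#' Concatenation along the channel axis, class features first — the input
#' expected by the relation head.
#'
#' @param f_class,f_query `[T x C]` feature-map matrices of equal shape.
#' @return `[T x 2C]` merged matrix.
#' @export
merge_features <- function(f_class, f_query) {
  if (!all(dim(f_class) == dim(f_query))) stop("shape mismatch")
  cbind(f_class, f_query)
}

#' Squeeze-and-excitation recalibration of a feature map
#'
#' Squeeze: per-channel mean over time. Excitation: a bottleneck pair of
#' fully connected maps (ReLU then sigmoid) produces per-channel weights in
#' (0, 1). Scale: each channel is multiplied by its weight.
#'
#' @param x `[T x C]` feature-map matrix.
#' @param params SE parameters (`W1`, `b1`, `W2`, `b2`); freshly initialised
#'   for `ratio` when omitted.
#' @param ratio bottleneck reduction ratio used when `params` is missing.
#' @return the recalibrated `[T x C]` matrix with the channel weights
#'   attached as attribute `"weights"`.
#' @export
se_block <- function(x, params = NULL, ratio = 16L) {
  x <- as.matrix(x)
  if (is.null(params)) params <- init_se_params(ncol(x), ratio)
  arr <- array(x, c(nrow(x), 1L, ncol(x)))
  fw <- se_fwd(arr, params)
  out <- matrix(fw$y[, 1L, ], nrow(x), ncol(x))
  attr(out, "weights") <- drop(fw$weights)
  out
}

#' Residual block: y = F1(x) + F2(x)
#'
#' Pathway F1 applies `f1_convs` zero-padded convolutions with leaky-ReLU
#' activations followed by one SE block; pathway F2 is a single projection
#' convolution. The two outputs are summed elementwise.
#'
#' @param x `[T x C]` feature-map matrix.
#' @param params block parameters (as built inside [relation_net()]); freshly
#'   initialised when omitted.
#' @param f1_convs convolutions on pathway F1 (default 3).
#' @param se_ratio SE bottleneck ratio (default 16).
#' @param leaky_slope activation slope (default 0.01).
#' @return `[T x C]` output matrix.
#' @export
residual_block <- function(x, params = NULL, f1_convs = 3L, se_ratio = 16L,
                           leaky_slope = 0.01) {
  x <- as.matrix(x)
  C <- ncol(x)
  if (is.null(params))
    params <- list(convs = lapply(seq_len(f1_convs),
                                  function(j) init_conv_params(3L, C, C)),
                   se = init_se_params(C, se_ratio),
                   short = init_conv_params(1L, C, C))
  arr <- array(x, c(nrow(x), 1L, C))
  f1 <- arr
  for (cp in params$convs) {
    f1 <- leaky_relu(conv1d_fwd(f1, cp$W, cp$b, pad = 1L)$y, leaky_slope)
  }
  f1 <- se_fwd(f1, params$se)$y
  f2 <- conv1d_fwd(arr, params$short$W, params$short$b)$y
  y <- f1 + f2
  matrix(y[, 1L, ], nrow(x), C)
}

#' Bidirectional GRU layer
#'
#' A single hidden layer run in both time directions over the sequence; per
#' time step the reset and update gates blend the previous hidden state with
#' a tanh candidate. Outputs are the per-direction hidden states concatenated
#' along the channel axis (forward direction first).
#'
#' @param x `[T x D]` sequence matrix.
#' @param params BiGRU parameters (`fwd`/`bwd` gate matrices); freshly
#'   initialised for `hidden` units when omitted.
#' @param hidden hidden width per direction used when `params` is missing.
#' @param h0 optional initial hidden state (length `hidden`), applied to both
#'   directions.
#' @return `[T x 2*hidden]` matrix of hidden states, with the concatenated
#'   final states (forward last, backward last) as attribute `"h_last"`.
#' @export
bigru_layer <- function(x, params = NULL, hidden = 32L, h0 = NULL) {
  x <- as.matrix(x)
  if (is.null(params))
    params <- list(fwd = init_gru_params(ncol(x), hidden),
                   bwd = init_gru_params(ncol(x), hidden))
  H <- length(params$fwd$br)
  arr <- array(x, c(nrow(x), 1L, ncol(x)))
  h0m <- if (is.null(h0)) NULL else matrix(h0, 1L, H)
  f <- gru_fwd(arr, params$fwd, h0m)
  b <- gru_fwd(arr[rev(seq_len(nrow(x))), , , drop = FALSE], params$bwd, h0m)
  out <- cbind(matrix(f$h_all[, 1L, ], nrow(x), H),
               matrix(b$h_all[, 1L, ], nrow(x), H)[rev(seq_len(nrow(x))), ,
                                                   drop = FALSE])
  attr(out, "h_last") <- c(f$h_last[1L, ], b$h_last[1L, ])
  out
}

#' Relation score of merged feature maps
#'
#' Runs the metric module of a relation model on one or more merged feature
#' maps (evaluation mode: deterministic, dropout off).
#'
#' @param model a `relation_net`.
#' @param merged a `[T x 2C]` merged matrix from [merge_features()], or a
#'   list of them.
#' @return similarity score(s) in (0, 1).
#' @export
relation_score <- function(model, merged) {
  stopifnot(inherits(model, "relation_net"))
  single <- !is.list(merged)
  ms <- if (single) list(merged) else merged
  arr <- batch_array(ms)
  fw <- relation_head_fwd(model$params$head, model$state$head,
                          model$metric_cfg, arr, train = FALSE)
  if (single) fw$scores[1L] else fw$scores
}

#' Siamese similarity score
#'
#' Elementwise absolute difference between the mean flattened support
#' embedding and the flattened query embedding, passed through two fully
#' connected layers and a sigmoid.
#'
#' @param model a `siamese_net`.
#' @param support_embeddings list of `[T x C]` feature-map matrices.
#' @param query_embedding one `[T x C]` feature-map matrix.
#' @return similarity score in (0, 1).
#' @export
siamese_score <- function(model, support_embeddings, query_embedding) {
  stopifnot(inherits(model, "siamese_net"))
  v <- as.vector(class_feature(support_embeddings))
  u <- as.vector(query_embedding)
  h <- matrix(abs(v - u), 1L)
  h1 <- pmax(sweep(h %*% model$params$head$fc1$W, 2L,
                   model$params$head$fc1$b, "+"), 0)
  drop(.sigmoid(h1 %*% model$params$head$fc2$W + model$params$head$fc2$b))
}

#' Prototypical class probabilities
#'
#' Softmax over negative squared Euclidean distances from a query embedding
#' to each class prototype.
#'
#' @param prototypes numeric matrix `[N x D]`, one prototype per row, or a
#'   list of feature maps (flattened).
#' @param query_embedding numeric vector of length `D` or a feature map.
#' @return probability vector over the N classes (sums to 1).
#' @export
proto_probabilities <- function(prototypes, query_embedding) {
  if (is.list(prototypes))
    prototypes <- do.call(rbind, lapply(prototypes, as.vector))
  q <- as.vector(query_embedding)
  if (nrow(prototypes) < 2L) stop("need at least 2 prototypes")
  d2 <- rowSums(sweep(prototypes, 2L, q)^2)
  z <- -d2
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
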