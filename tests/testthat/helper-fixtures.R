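# Shared fixtures: everything is generated in code at test time.

# Small synthetic bundles with well-separated classes, cheap to generate.
tiny_bundles <- function(seed = 11L, separation = 1.5, noise_sd = 0.05,
                         n_points = 1200L, target = 240L,
                         n_train_classes = 6L, train_per_class = 12L) {
  train_cfg <- synth_config(
    n_classes = n_train_classes, samples_per_class = train_per_class,
    n_points = n_points, separation = separation, noise_sd = noise_sd,
    source = "meta_train",
    class_names = paste0("gas_", seq_len(n_train_classes)), seed = seed)
  test_cfg <- synth_config(
    n_classes = 4L, samples_per_class = c(12L, 8L, 10L, 9L),
    n_points = n_points, separation = separation, noise_sd = noise_sd,
    source = "meta_test",
    class_names = c("copd", "smokers", "control", "air"), seed = seed + 1L)
  list(train = generate_dataset(train_cfg, target = target),
       test = generate_dataset(test_cfg, target = target))
}

# Reduced architecture for fast training tests: [60 x 8] -> [12 x 8].
tiny_embed_cfg <- function() {
  embedding_config(n_residual_blocks = 2L, f1_convs_per_block = 2L,
                   feature_channels = 8L, out_timesteps = 12L,
                   in_channels = 8L, in_timesteps = 60L, se_ratio = 4L)
}

tiny_metric_cfg <- function() {
  metric_config(conv_channels = 8L, gru_hidden = 8L, se_ratio = 4L,
                dropout = 0.3)
}

# Hand-build an episode from explicit sample lists (class-major support).
manual_episode <- function(support, query, query_labels, class_order,
                           k_shot) {
  structure(list(support = support, query = query,
                 query_labels = query_labels, class_order = class_order,
                 spec = episode_spec(length(class_order), k_shot,
                                     max(1L, length(query)))),
            class = "episode")
}

# Central-difference numerical gradient of scalar f at vector x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_relerr <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# Refill a parameter tree from a flat vector (tree order).
refill_params <- function(p, vec) {
  i <- 0L
  enosefs:::param_map(p, function(w) {
    out <- w
    out[] <- vec[i + seq_along(w)]
    i <<- i + length(w)
    out
  })
}
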