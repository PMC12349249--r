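test_that("leaky ReLU follows max(ax, x)", {
  expect_equal(leaky_relu(5), 5)
  expect_equal(leaky_relu(-10), -0.1)
  expect_equal(leaky_relu(0), 0)
  expect_equal(leaky_relu(c(-2, 3), a = 0.2), c(-0.4, 3))
})

test_that("SE block squeezes, excites and rescales channels", {
  set.seed(14)
  x <- matrix(rnorm(20 * 6), 20, 6)
  p <- enosefs:::init_se_params(6L, 2L)
  # excitation forced to ~1 (huge positive bias) gives the identity map
  p1 <- p; p1$W2[] <- 0; p1$b2[] <- 1e3
  expect_equal(se_block(x, p1), x, ignore_attr = TRUE)
  # squeeze of a constant channel is that constant
  xc <- matrix(rep(c(2, -1, 0.5, 3, 1, -2), each = 20), 20, 6)
  fw <- enosefs:::se_fwd(array(xc, c(20, 1, 6)), p)
  expect_equal(as.vector(fw$cache$z), c(2, -1, 0.5, 3, 1, -2))
  # weights in (0, 1) shrink every element
  out <- se_block(x, p)
  w <- attr(out, "weights")
  expect_true(all(w > 0 & w < 1))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("residual block output is F1(x) + F2(x)", {
  set.seed(15)
  x <- matrix(rnorm(12 * 5), 12, 5)
  p <- list(convs = lapply(1:3, function(j) enosefs:::init_conv_params(3L, 5L, 5L)),
            se = enosefs:::init_se_params(5L, 2L),
            short = enosefs:::init_conv_params(1L, 5L, 5L))
  # zeroing pathway F1 leaves only the shortcut convolution
  p0 <- p
  for (j in 1:3) { p0$convs[[j]]$W[] <- 0; p0$convs[[j]]$b[] <- 0 }
  y0 <- residual_block(x, p0)
  f2 <- enosefs:::conv1d_fwd(array(x, c(12, 1, 5)), p$short$W, p$short$b)$y
  expect_equal(y0, matrix(f2[, 1, ], 12, 5))
  # shape preserved
  expect_equal(dim(residual_block(x, p)), dim(x))
})

test_that("embedding satisfies the [240 x 8] -> [63 x 30] shape contract", {
  model <- relation_net(seed = 512)
  s <- matrix(runif(240 * 8), 240, 8)
  fm <- embed(model, s)
  expect_equal(dim(fm), c(63L, 30L))
  # deterministic in evaluation mode
  expect_identical(embed(model, s), fm)
  # two identical samples embed identically within one batch
  maps <- embed(model, list(s, s))
  expect_identical(maps[[1]], maps[[2]])
  expect_error(embed(model, matrix(0, 100, 8)), "does not match")
})

test_that("shape contract propagates across block counts", {
  set.seed(16)
  s <- matrix(runif(240 * 8), 240, 8)
  for (nb in c(2L, 4L, 6L)) {
    cfg <- embedding_config(n_residual_blocks = nb, feature_channels = 10L)
    m <- relation_net(cfg, metric_config(conv_channels = 6L,
                                         gru_hidden = 4L), seed = 1)
    expect_equal(dim(embed(m, s)), c(63L, 10L))
  }
})

test_that("class feature is the elementwise support mean", {
  a <- matrix(0, 4, 3); b <- matrix(2, 4, 3)
  expect_equal(class_feature(list(a, b)), matrix(1, 4, 3))
  expect_equal(class_feature(list(b)), b)
  expect_equal(class_feature(list(b, b, b)), b)
  expect_error(class_feature(list()), "empty")
})

test_that("feature merging concatenates class-first along channels", {
  a <- matrix(1:12, 4, 3); b <- matrix(13:24, 4, 3)
  m <- merge_features(a, b)
  expect_equal(dim(m), c(4L, 6L))
  expect_equal(m[, 1], a[, 1])
  expect_equal(m[, 4], b[, 1])
  expect_false(isTRUE(all.equal(merge_features(a, b), merge_features(b, a))))
  expect_error(merge_features(a, matrix(0, 5, 3)), "mismatch")
})

test_that("BiGRU matches the gate equations and their closed forms", {
  # all-zero parameters: r = z = 0.5, candidate 0, so h_t = h_0 / 2^t
  D <- 3L; H <- 4L; T_ <- 6L
  pz <- list(fwd = enosefs:::init_gru_params(D, H),
             bwd = enosefs:::init_gru_params(D, H))
  pz <- enosefs:::param_map(pz, function(w) { w[] <- 0; w })
  x <- matrix(rnorm(T_ * D), T_, D)
  h0 <- c(1, -2, 0.5, 4)
  out <- bigru_layer(x, pz, h0 = h0)
  for (t in seq_len(T_))
    expect_equal(out[t, 1:H], h0 / 2^t, tolerance = 1e-12)
  # zero initial state stays zero
  out0 <- bigru_layer(x, pz)
  expect_true(all(out0 == 0))

  # single-step oracle: direct evaluation of the gate equations
  set.seed(17)
  p1 <- list(fwd = enosefs:::init_gru_params(D, H),
             bwd = enosefs:::init_gru_params(D, H))
  x1 <- matrix(rnorm(D), 1, D)
  sig <- function(v) 1 / (1 + exp(-v))
  gate_oracle <- function(p, xt, hprev) {
    r <- sig(xt %*% p$Wr + hprev %*% p$Ur + p$br)
    z <- sig(xt %*% p$Wz + hprev %*% p$Uz + p$bz)
    hp <- tanh(xt %*% p$Wh + (r * hprev) %*% p$Uh + p$bh)
    z * hprev + (1 - z) * hp
  }
  got <- bigru_layer(x1, p1)
  expect_equal(got[1, 1:H], drop(gate_oracle(p1$fwd, x1, matrix(0, 1, H))),
               tolerance = 1e-12)
  expect_equal(got[1, H + 1:H], drop(gate_oracle(p1$bwd, x1, matrix(0, 1, H))),
               tolerance = 1e-12)

  # multi-step: unroll the recursion by hand and compare both directions
  xT <- matrix(rnorm(4 * D), 4, D)
  h <- matrix(0, 1, H)
  for (t in 1:4) h <- gate_oracle(p1$fwd, xT[t, , drop = FALSE], h)
  gotT <- bigru_layer(xT, p1)
  expect_equal(gotT[4, 1:H], drop(h), tolerance = 1e-6)
  hb <- matrix(0, 1, H)
  for (t in 4:1) hb <- gate_oracle(p1$bwd, xT[t, , drop = FALSE], hb)
  expect_equal(gotT[1, H + 1:H], drop(hb), tolerance = 1e-6)
  expect_equal(attr(gotT, "h_last"), c(gotT[4, 1:H], gotT[1, H + 1:H]))
})

test_that("relation scores live in (0, 1), are deterministic and sensitive", {
  set.seed(18)
  ecfg <- tiny_embed_cfg()
  model <- relation_net(ecfg, tiny_metric_cfg(), seed = 3)
  s1 <- matrix(runif(60 * 8), 60, 8)
  s2 <- matrix(runif(60 * 8), 60, 8)
  f1 <- embed(model, s1); f2 <- embed(model, s2)
  sc <- relation_score(model, merge_features(f1, f2))
  expect_true(sc > 0 && sc < 1)
  expect_identical(relation_score(model, merge_features(f1, f2)), sc)
  # changing the query features changes the score
  sc2 <- relation_score(model, merge_features(f1, f2 + 0.3))
  expect_false(identical(sc, sc2))
  # batched input returns one score per merged map
  scs <- relation_score(model, list(merge_features(f1, f2),
                                    merge_features(f1, f1)))
  expect_length(scs, 2L)
  expect_true(all(scs > 0 & scs < 1))
})

test_that("siamese score is support-permutation invariant and bounded", {
  set.seed(19)
  model <- siamese_net(tiny_embed_cfg(), hidden = 16L, seed = 4)
  es <- lapply(1:3, function(i) matrix(rnorm(12 * 8), 12, 8))
  q <- matrix(rnorm(12 * 8), 12, 8)
  s1 <- siamese_score(model, es, q)
  s2 <- siamese_score(model, es[c(3, 1, 2)], q)
  expect_equal(s1, s2)
  expect_true(s1 > 0 && s1 < 1)
  # query at the support mean: zero difference vector, bias-only path
  m <- class_feature(es)
  s0 <- siamese_score(model, es, m)
  h1 <- pmax(model$params$head$fc1$b, 0)
  expect_equal(s0, drop(1 / (1 + exp(-(h1 %*% model$params$head$fc2$W +
                                         model$params$head$fc2$b)))))
})

test_that("prototypical probabilities are a softmax over negative distances", {
  protos <- rbind(c(0, 0), c(10, 0), c(0, 10))
  p <- proto_probabilities(protos, c(0.1, 0))
  expect_equal(sum(p), 1)
  expect_equal(which.max(p), 1L)
  expect_true(p[1] > 0.99)
  # brute-force oracle
  set.seed(20)
  pr <- matrix(rnorm(8), 4, 2)
  q <- rnorm(2)
  d2 <- apply(pr, 1, function(r) sum((r - q)^2))
  expect_equal(proto_probabilities(pr, q), exp(-d2) / sum(exp(-d2)),
               tolerance = 1e-12)
  expect_error(proto_probabilities(pr[1, , drop = FALSE], q), "2 prototypes")
})

test_that("layer backward passes agree with finite differences", {
  set.seed(23)
  loss_of <- function(y) sum(sin(y))
  T_ <- 6L; B <- 2L; Cin <- 3L; Cout <- 4L
  x <- array(rnorm(T_ * B * Cin), c(T_, B, Cin))

  W <- array(rnorm(3 * Cin * Cout) * 0.3, c(3, Cin, Cout)); bb <- rnorm(Cout) * 0.1
  fw <- enosefs:::conv1d_fwd(x, W, bb, 1L, 1L)
  bw <- enosefs:::conv1d_bwd(cos(fw$y), fw$cache, W)
  gx <- num_grad(function(v) { xx <- x; xx[] <- v
    loss_of(enosefs:::conv1d_fwd(xx, W, bb, 1L, 1L)$y) }, as.vector(x))
  gW <- num_grad(function(v) { WW <- W; WW[] <- v
    loss_of(enosefs:::conv1d_fwd(x, WW, bb, 1L, 1L)$y) }, as.vector(W))
  expect_lt(max_relerr(as.vector(bw$dx), gx), 1e-7)
  expect_lt(max_relerr(as.vector(bw$dW), gW), 1e-7)

  g_ <- rnorm(Cin) * 0.5 + 1; be <- rnorm(Cin) * 0.2
  st <- enosefs:::init_bn_state(Cin)
  bnf <- enosefs:::bn_fwd(x, g_, be, st, train = TRUE)
  bnb <- enosefs:::bn_bwd(cos(bnf$y), bnf$cache)
  gxb <- num_grad(function(v) { xx <- x; xx[] <- v
    loss_of(enosefs:::bn_fwd(xx, g_, be, st, TRUE)$y) }, as.vector(x))
  expect_lt(max_relerr(as.vector(bnb$dx), gxb), 1e-6)

  p <- enosefs:::init_se_params(Cin, 2L)
  sef <- enosefs:::se_fwd(x, p)
  seb <- enosefs:::se_bwd(cos(sef$y), sef$cache, p)
  gxs <- num_grad(function(v) { xx <- x; xx[] <- v
    loss_of(enosefs:::se_fwd(xx, p)$y) }, as.vector(x))
  expect_lt(max_relerr(as.vector(seb$dx), gxs), 1e-7)

  gp <- enosefs:::init_gru_params(Cin, 4L)
  gf <- enosefs:::gru_fwd(x, gp)
  gb <- enosefs:::gru_bwd(cos(gf$h_all), -sin(gf$h_last), gf$cache, gp)
  l_gru <- function(pp, xx) {
    r <- enosefs:::gru_fwd(xx, pp)
    sum(sin(r$h_all)) + sum(cos(r$h_last))
  }
  gxg <- num_grad(function(v) { xx <- x; xx[] <- v; l_gru(gp, xx) },
                  as.vector(x))
  expect_lt(max_relerr(as.vector(gb$dx), gxg), 1e-6)
  for (nm in c("Wr", "Uz", "Uh", "bh")) {
    gn <- num_grad(function(v) { pp <- gp; pp[[nm]][] <- v; l_gru(pp, x) },
                   as.vector(gp[[nm]]))
    expect_lt(max_relerr(as.vector(gb$grads[[nm]]), gn), 1e-6)
  }
})

test_that("full relation-net gradient matches finite differences", {
  set.seed(24)
  ecfg <- embedding_config(n_residual_blocks = 2L, f1_convs_per_block = 2L,
                           feature_channels = 5L, out_timesteps = 4L,
                           in_channels = 3L, in_timesteps = 18L,
                           se_ratio = 2L)
  mcfg <- metric_config(conv_channels = 4L, gru_hidden = 3L, dropout = 0,
                        se_ratio = 2L)
  model <- relation_net(ecfg, mcfg, seed = 7)
  mk <- function(lab) enose_sample(matrix(runif(18 * 3), 18, 3), lab,
                                   "meta_train")
  ep <- manual_episode(list(list(mk("a")), list(mk("b"))),
                       list(mk("a"), mk("b"), mk("b")),
                       c("a", "b", "b"), c("a", "b"), 1L)
  st <- enosefs:::relation_step(model, ep, train = TRUE)
  v0 <- unlist(model$params, use.names = FALSE)
  loss_with <- function(vec) {
    m <- model
    m$params <- refill_params(m$params, vec)
    fw <- enosefs:::relation_forward(m, ep, train = TRUE)
    mse_episode_loss(fw$scores, relation_targets(ep))
  }
  gnum <- num_grad(loss_with, v0)
  gana <- unlist(st$grads, use.names = FALSE)
  expect_lt(max_relerr(gana, gnum), 1e-6)
})

test_that("K identical support samples collapse to the K = 1 scores", {
  set.seed(25)
  model <- relation_net(tiny_embed_cfg(), tiny_metric_cfg(), seed = 5)
  mk <- function(lab) enose_sample(matrix(runif(60 * 8), 60, 8), lab,
                                   "meta_test")
  sup <- list(mk("a"), mk("b"), mk("c"))
  qry <- list(mk("a"), mk("b"), mk("c"), mk("a"))
  labs <- c("a", "b", "c", "a")
  ep1 <- manual_episode(lapply(sup, list), qry, labs, c("a", "b", "c"), 1L)
  ep4 <- manual_episode(lapply(sup, function(s) list(s, s, s, s)),
                        qry, labs, c("a", "b", "c"), 4L)
  s1 <- enosefs:::relation_forward(model, ep1, train = FALSE)$scores
  s4 <- enosefs:::relation_forward(model, ep4, train = FALSE)$scores
  expect_equal(s4, s1, tolerance = 1e-6)
})

test_that("checkpoints round-trip and validate the shape contract", {
  model <- relation_net(tiny_embed_cfg(), tiny_metric_cfg(), seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  s <- matrix(runif(60 * 8), 60, 8)
  expect_identical(embed(back, s), embed(model, s))
})
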