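test_that("model_config validates sizes and rates; defaults match the design", {
  cfg <- model_config()
  expect_equal(cfg$num_layers, 1L)
  expect_equal(cfg$hidden_units, 64L)
  expect_equal(cfg$embedding_dim, 50L)
  expect_equal(cfg$vocab_size, 22L)
  expect_error(model_config(num_layers = 3), "single-layer")
  expect_error(model_config(dropout = list(embedding = 1, input = 0,
                                           weight = 0, output = 0)),
               "\\[0, 1\\)")
  expect_error(model_config(dropout = list(input = 0.1)), "dropout")
})

test_that("parameter counts of the default models are pinned", {
  set.seed(1)
  # frozen from the architecture: emb 22x50, Wx 50x256, Wh 64x256, b 256,
  # plus LM head 64x22+22 or reg head (192x64 + 64 + 64 + 1)
  expect_equal(mhcbindr:::n_parameters(build_language_model(model_config())),
               31970)
  expect_equal(mhcbindr:::n_parameters(build_regressor(model_config())),
               42957)
})

test_that("language model emits one next-token distribution per position", {
  set.seed(2)
  lm <- build_language_model(model_config())
  probs <- lm_next_token_probs(lm, c("SIINFEKL", "ACD"))
  expect_equal(nrow(probs[[1]]), 9L)   # L residues + bos
  expect_equal(nrow(probs[[2]]), 4L)
  for (p in probs) {
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("evaluation-mode forward passes are deterministic", {
  set.seed(3)
  lm <- build_language_model(tiny_cfg())
  p1 <- lm_next_token_probs(lm, "ACDEF")  # tokens within the tiny vocabulary
  p2 <- lm_next_token_probs(lm, "ACDEF")
  expect_identical(p1, p2)
  reg <- build_regressor(model_config())
  y1 <- mhcbindr:::predict_y(reg$params, reg$cfg, "SIINFEKL")
  y2 <- mhcbindr:::predict_y(reg$params, reg$cfg, "SIINFEKL")
  expect_identical(y1, y2)
})

test_that("regressor maps a batch of n peptides to n scalars, both variants alike", {
  set.seed(4)
  lm <- build_language_model(model_config())
  scratch <- build_regressor(model_config())
  warm <- build_regressor(model_config(), pretrained = lm)
  expect_identical(lapply(scratch$params, dim), lapply(warm$params, dim))
  peps <- c("SIINFEKL", "ACDEFGHIK", "LLDVTAAVL")
  expect_length(mhcbindr:::predict_y(warm$params, warm$cfg, peps), 3L)
})

test_that("pretrained backbone weights are copied exactly; shape mismatch is named", {
  set.seed(5)
  lm <- build_language_model(model_config())
  reg <- build_regressor(model_config(), pretrained = lm)
  for (nm in c("emb", "Wx", "Wh", "b")) {
    expect_identical(reg$params[[nm]], lm$params[[nm]])
  }
  # extract -> load -> extract is the identity
  bb <- extract_backbone(lm)
  expect_identical(extract_backbone(build_regressor(model_config(), bb)), bb)
  expect_error(build_regressor(tiny_cfg(), pretrained = lm), "emb")
  expect_error(extract_backbone(lm$params[c("emb", "Wx")]), "Wh")
})

test_that("concat_pool matches the naive loop oracle and its degenerate cases", {
  set.seed(6)
  hs <- matrix(rnorm(20), 5, 4)
  for (len in 1:5) {
    expect_equal(concat_pool(hs, len), oracle_concat_pool(hs, len))
  }
  # all positions identical: concat(h, h, h)
  h <- rnorm(4)
  same <- matrix(h, 5, 4, byrow = TRUE)
  expect_equal(concat_pool(same, 5), c(h, h, h))
  # length 1: last = max = mean = first row
  expect_equal(concat_pool(hs, 1), rep(hs[1, ], 3))
  expect_error(concat_pool(hs, 0), ">= 1")
  expect_error(concat_pool(hs, 6), "fewer")
})

test_that("padding positions never influence outputs", {
  set.seed(7)
  cfg <- model_config()
  reg <- build_regressor(cfg)
  peps <- rand_peps(6, 8, 12)
  enc <- lapply(peps, tokenize)
  batch <- pad_batch(enc)
  y0 <- mhcbindr:::reg_forward_eval(reg$params, cfg, batch)
  # append five extra pad columns
  wide <- cbind(batch$indices,
                matrix(aa_vocabulary()$pad, nrow(batch$indices), 5))
  y1 <- mhcbindr:::reg_forward_eval(reg$params, cfg,
                                    list(indices = wide,
                                         lengths = batch$lengths))
  expect_equal(y0, y1, tolerance = 1e-12)
  # batched and one-at-a-time prediction agree
  singles <- vapply(peps, function(p) {
    mhcbindr:::reg_forward_eval(reg$params, cfg, pad_batch(list(tokenize(p))))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(y0, singles, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences (regressor)", {
  set.seed(8)
  cfg <- tiny_cfg()
  X <- rbind(c(2, 3, 4, 5, 6), c(2, 7, 8, 1, 1), c(2, 3, 8, 4, 1))
  lens <- c(5L, 3L, 4L)
  reg <- build_regressor(cfg)
  p <- reg$params
  inmask <- matrix(1, 3, cfg$embedding_dim)
  headmask <- matrix(1, 3, cfg$head_hidden)
  y <- c(0.3, 0.9, 0.5)
  br <- c(0L, 1L, 2L)  # one record per censoring branch
  loss_at <- function(p) {
    mhcbindr:::cpp_reg_step(X, lens, p$emb, inmask, p$Wx, p$Wh, p$b, p$W1,
                            p$b1, p$W2, p$b2, headmask, y, br, FALSE)$loss
  }
  g <- mhcbindr:::cpp_reg_step(X, lens, p$emb, inmask, p$Wx, p$Wh, p$b,
                               p$W1, p$b1, p$W2, p$b2, headmask, y, br,
                               TRUE)$grads
  eps <- 1e-6
  for (nm in c("emb", "Wx", "Wh", "b", "W1", "b1", "W2", "b2")) {
    num <- vapply(seq_along(p[[nm]]), function(i) {
      pp <- p
      pp[[nm]][i] <- p[[nm]][i] + eps
      up <- loss_at(pp)
      pp[[nm]][i] <- p[[nm]][i] - eps
      (up - loss_at(pp)) / (2 * eps)
    }, numeric(1))
    expect_equal(as.numeric(g[[nm]]), num, tolerance = 1e-5,
                 label = paste("grad", nm))
  }
})

test_that("analytic gradients match central finite differences (language model)", {
  set.seed(9)
  cfg <- tiny_cfg()
  X <- rbind(c(2, 3, 4, 5, 6), c(2, 7, 8, 1, 1))
  lens <- c(5L, 3L)
  lm <- build_language_model(cfg)
  p <- lm$params
  inmask <- matrix(1, 2, cfg$embedding_dim)
  outmask <- matrix(1, 2, cfg$hidden_units)
  loss_at <- function(p) {
    mhcbindr:::cpp_lm_step(X, lens, p$emb, inmask, p$Wx, p$Wh, p$b, p$Wlm,
                           p$blm, outmask, FALSE)$loss
  }
  g <- mhcbindr:::cpp_lm_step(X, lens, p$emb, inmask, p$Wx, p$Wh, p$b,
                              p$Wlm, p$blm, outmask, TRUE)$grads
  eps <- 1e-6
  for (nm in c("emb", "Wx", "Wh", "b", "Wlm", "blm")) {
    num <- vapply(seq_along(p[[nm]]), function(i) {
      pp <- p
      pp[[nm]][i] <- p[[nm]][i] + eps
      up <- loss_at(pp)
      pp[[nm]][i] <- p[[nm]][i] - eps
      (up - loss_at(pp)) / (2 * eps)
    }, numeric(1))
    expect_equal(as.numeric(g[[nm]]), num, tolerance = 1e-5,
                 label = paste("grad", nm))
  }
})

test_that("the C++ training-step forward agrees with the R evaluation path", {
  set.seed(10)
  cfg <- model_config()
  reg <- build_regressor(cfg)
  peps <- rand_peps(5, 8, 11)
  batch <- mhcbindr:::encode_batch(peps)
  p <- reg$params
  res <- mhcbindr:::cpp_reg_step(
    batch$indices, batch$lengths, p$emb,
    matrix(1, 5, cfg$embedding_dim), p$Wx, p$Wh, p$b, p$W1, p$b1, p$W2,
    p$b2, matrix(1, 5, cfg$head_hidden), rep(0, 5), rep(0L, 5), FALSE
  )
  expect_equal(as.numeric(res$pred),
               mhcbindr:::reg_forward_eval(p, cfg, batch),
               tolerance = 1e-12)
})
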