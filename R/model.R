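#' Model architecture configuration
#'
#' Fixed hyperparameters of the recurrent backbone shared by the peptide
#' language model and the affinity regressor: a single-layer weight-dropped
#' LSTM (64 hidden units) over a learned 50-dimensional amino-acid embedding.
#' These sizes are deliberately small: peptide sequences are short (8-37
#' residues), so large contexts cannot build up and a downsized network
#' avoids overfitting while training in seconds on a CPU.
#'
#' Dropout defaults (embedding-row 0.05, variational input 0.10, weight-drop
#' 0.20 on the recurrent matrix, output 0.05) are this package's fixed
#' regularisation recipe, chosen once on a synthetic benchmark allele and
#' applied unchanged everywhere; all are configurable.
#'
#' @param vocab_size Token-vocabulary size (20 amino acids + pad + bos = 22).
#' @param embedding_dim Learned embedding width. Default 50.
#' @param hidden_units LSTM hidden width. Default 64.
#' @param num_layers Recurrent layers; this architecture is single-layer by
#'   design and only `1` is accepted.
#' @param dropout Named list of rates in \[0, 1): `embedding` (whole-row drop
#'   on the embedding matrix), `input` (variational mask on embedded inputs),
#'   `weight` (weight-drop on the recurrent matrix, one mask per batch),
#'   `output` (on pooled features / pre-projection states).
#' @param head_hidden Width of the first fully connected head layer (the
#'   regression head is `3*hidden_units -> head_hidden -> 1` with a ReLU and
#'   dropout in between). Default 64.
#' @return A list of class `pep_model_config`.
#' @export
model_config <- function(vocab_size = 22L, embedding_dim = 50L,
                         hidden_units = 64L, num_layers = 1L,
                         dropout = list(embedding = 0.05, input = 0.10,
                                        weight = 0.20, output = 0.05),
                         head_hidden = 64L) {
  if (num_layers != 1L) {
    stop("this architecture is single-layer; num_layers must be 1", call. = FALSE)
  }
  need <- c("embedding", "input", "weight", "output")
  if (!all(need %in% names(dropout))) {
    stop("dropout must name rates: ", paste(need, collapse = ", "), call. = FALSE)
  }
  rates <- unlist(dropout[need])
  if (any(rates < 0 | rates >= 1)) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (vocab_size < 3 || embedding_dim < 1 || hidden_units < 1 || head_hidden < 1) {
    stop("invalid architecture sizes", call. = FALSE)
  }
  structure(
    list(
      vocab_size = as.integer(vocab_size),
      embedding_dim = as.integer(embedding_dim),
      hidden_units = as.integer(hidden_units),
      num_layers = 1L,
      dropout = as.list(rates),
      head_hidden = as.integer(head_hidden)
    ),
    class = "pep_model_config"
  )
}

#' @export
print.pep_model_config <- function(x, ...) {
  cat("<pep_model_config>\n")
  cat(sprintf("  vocab %d | embedding %d | hidden %d | layers %d | head %d\n",
              x$vocab_size, x$embedding_dim, x$hidden_units, x$num_layers,
              x$head_hidden))
  cat(sprintf("  dropout: embedding %.2f input %.2f weight %.2f output %.2f\n",
              x$dropout$embedding, x$dropout$input, x$dropout$weight,
              x$dropout$output))
  invisible(x)
}

runif_mat <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)

init_backbone <- function(cfg) {
  H <- cfg$hidden_units
  s <- 1 / sqrt(H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias: remember by default
  list(
    emb = runif_mat(cfg$vocab_size, cfg$embedding_dim, 0.1),
    Wx = runif_mat(cfg$embedding_dim, 4 * H, s),
    Wh = runif_mat(H, 4 * H, s),
    b = b
  )
}

backbone_names <- c("emb", "Wx", "Wh", "b")

check_backbone_shapes <- function(params, cfg) {
  expect <- list(
    emb = c(cfg$vocab_size, cfg$embedding_dim),
    Wx = c(cfg$embedding_dim, 4 * cfg$hidden_units),
    Wh = c(cfg$hidden_units, 4 * cfg$hidden_units),
    b = c(4 * cfg$hidden_units)
  )
  for (nm in backbone_names) {
    got <- if (nm == "b") length(params[[nm]]) else dim(params[[nm]])
    if (!identical(as.integer(got), as.integer(expect[[nm]]))) {
      stop(sprintf(
        "pretrained weight shape mismatch in layer '%s': expected [%s], got [%s]",
        nm, paste(expect[[nm]], collapse = "x"), paste(got, collapse = "x")
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a peptide language model
#'
#' Constructs an untrained next-token language model: embedding layer,
#' single weight-dropped LSTM layer, and a linear projection onto the
#' vocabulary. At every position the model emits a probability distribution
#' over the next token. Weights are drawn from the current RNG state
#' (training functions seed it explicitly).
#'
#' @param cfg A [model_config()].
#' @return An object of class `pep_lm`: list with `cfg` and `params`
#'   (`emb`, `Wx`, `Wh`, `b`, `Wlm`, `blm`).
#' @export
build_language_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "pep_model_config"))
  params <- init_backbone(cfg)
  params$Wlm <- runif_mat(cfg$hidden_units, cfg$vocab_size, 0.1)
  params$blm <- rep(0, cfg$vocab_size)
  structure(list(cfg = cfg, params = params), class = "pep_lm")
}

#' Build an affinity regressor
#'
#' Constructs the regression model: the same backbone as the language model
#' (embedding + weight-dropped LSTM), with the output layer replaced by a
#' concat pooling layer ([concat_pool()]) and two fully connected layers
#' ending in a single unconstrained real output, interpreted on the
#' transformed-affinity scale of [ic50_to_target()] and clipped to \[0, 1\]
#' only at reporting time. When `pretrained` is supplied (a `pep_lm` or its
#' backbone parameter list), the embedding and recurrent weights are copied
#' in after shape validation; the head is always freshly initialised.
#'
#' @inheritParams build_language_model
#' @param pretrained Optional pretrained language model (`pep_lm`, a
#'   [pretrain_lm()] fit, or a backbone parameter list).
#' @return An object of class `pep_regressor`: list with `cfg`, `params`
#'   (`emb`, `Wx`, `Wh`, `b`, `W1`, `b1`, `W2`, `b2`) and `pretrained` flag.
#' @export
build_regressor <- function(cfg = model_config(), pretrained = NULL) {
  stopifnot(inherits(cfg, "pep_model_config"))
  params <- init_backbone(cfg)
  if (!is.null(pretrained)) {
    src <- extract_backbone(pretrained)
    check_backbone_shapes(src, cfg)
    params[backbone_names] <- src[backbone_names]
  }
  H <- cfg$hidden_units
  D <- cfg$head_hidden
  params$W1 <- runif_mat(3 * H, D, 1 / sqrt(3 * H))
  params$b1 <- rep(0, D)
  params$W2 <- matrix(stats::runif(D, -1 / sqrt(D), 1 / sqrt(D)), D, 1)
  params$b2 <- 0
  structure(
    list(cfg = cfg, params = params, pretrained = !is.null(pretrained)),
    class = "pep_regressor"
  )
}

#' Extract backbone weights from a model
#'
#' Returns the shared backbone (embedding + recurrent) weight blocks, e.g.
#' to hand a pretrained language model to [build_regressor()]. Extracting
#' and re-loading is the identity on those blocks.
#'
#' @param x A `pep_lm`, `pep_regressor`, [pretrain_lm()] fit, or a bare
#'   parameter list containing `emb`, `Wx`, `Wh`, `b`.
#' @return Named list `emb`, `Wx`, `Wh`, `b`.
#' @export
extract_backbone <- function(x) {
  params <- if (inherits(x, "pep_lm_fit")) {
    x$model$params
  } else if (inherits(x, c("pep_lm", "pep_regressor"))) {
    x$params
  } else if (is.list(x)) {
    x
  } else {
    stop("cannot extract backbone weights from ", class(x)[1], call. = FALSE)
  }
  missing <- setdiff(backbone_names, names(params))
  if (length(missing) > 0L) {
    stop("backbone weights missing block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params[backbone_names]
}

#' Concat pooling over recurrent hidden states
#'
#' Pools a sequence of per-position hidden-state vectors into a single
#' feature vector: the concatenation of the last valid hidden state, the
#' elementwise maximum over the first `length` positions, and the
#' elementwise mean over the same. Positions beyond `length` (padding) never
#' contribute, which is what makes the regressor invariant to padding.
#'
#' @param hidden Numeric matrix, positions x hidden-units.
#' @param length Number of valid leading positions, >= 1.
#' @return Numeric vector of size `3 * ncol(hidden)`:
#'   `c(last, max, mean)`.
#' @export
concat_pool <- function(hidden, length) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (nrow(hidden) < length) {
    stop("fewer hidden states than `length`", call. = FALSE)
  }
  hs <- hidden[seq_len(length), , drop = FALSE]
  c(hs[length, ], apply(hs, 2, max), colMeans(hs))
}

# Deterministic (no-dropout) hidden states for a padded batch.
# Returns B x H x T array.
eval_hidden <- function(params, cfg, batch) {
  B <- nrow(batch$indices)
  inmask <- matrix(1, B, cfg$embedding_dim)
  cpp_lstm_hidden(batch$indices, batch$lengths, params$emb, inmask,
                  params$Wx, params$Wh, params$b)
}

# Deterministic regression forward for a padded batch: pooled features
# through the two-layer head. Returns numeric vector of raw outputs.
reg_forward_eval <- function(params, cfg, batch) {
  Hs <- eval_hidden(params, cfg, batch)
  B <- nrow(batch$indices)
  P <- t(vapply(
    seq_len(B),
    function(i) concat_pool(t(Hs[i, , , drop = TRUE]), batch$lengths[i]),
    numeric(3 * cfg$hidden_units)
  ))
  z1 <- sweep(P %*% params$W1, 2, params$b1, "+")
  a1 <- pmax(z1, 0) + 0.01 * pmin(z1, 0)  # leaky rectifier, as in the C++ core
  drop(a1 %*% params$W2) + params$b2
}

#' Per-position next-token distributions of a language model
#'
#' Runs the language model in evaluation mode (no dropout) and returns, for
#' each input position, the predicted probability distribution over the next
#' token. Each row is a valid probability distribution (non-negative,
#' sums to 1).
#'
#' @param lm A `pep_lm` or [pretrain_lm()] fit.
#' @param peptides Character vector of peptides.
#' @return A list (one element per peptide) of `L x vocab_size` matrices,
#'   where `L = nchar(peptide) + 1` counts the bos token; row t is the
#'   distribution of the token following position t.
#' @export
lm_next_token_probs <- function(lm, peptides) {
  if (inherits(lm, "pep_lm_fit")) lm <- lm$model
  stopifnot(inherits(lm, "pep_lm"))
  batch <- encode_batch(peptides)
  Hs <- eval_hidden(lm$params, lm$cfg, batch)
  lapply(seq_along(peptides), function(i) {
    L <- batch$lengths[i]
    h <- matrix(Hs[i, , seq_len(L)], nrow = lm$cfg$hidden_units)
    logits <- t(h) %*% lm$params$Wlm
    logits <- sweep(logits, 2, lm$params$blm, "+")
    logits <- logits - apply(logits, 1, max)
    ex <- exp(logits)
    p <- ex / rowSums(ex)
    if (lm$cfg$vocab_size == length(aa_vocabulary()$tokens)) {
      colnames(p) <- aa_vocabulary()$tokens
    }
    p
  })
}

# Count free parameters of a model.
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p), numeric(1)))
}

#' @export
print.pep_lm <- function(x, ...) {
  cat("<pep_lm> untrained/raw language model,", n_parameters(x), "parameters\n")
  print(x$cfg)
  invisible(x)
}

#' @export
print.pep_regressor <- function(x, ...) {
  cat("<pep_regressor>", n_parameters(x), "parameters;",
      if (isTRUE(x$pretrained)) "backbone from pretrained LM" else "from scratch",
      "\n")
  print(x$cfg)
  invisible(x)
}
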