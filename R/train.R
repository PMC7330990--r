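#' Training configuration
#'
#' Optimisation hyperparameters for language-model pretraining and regressor
#' finetuning. The optimiser is stochastic gradient descent with momentum
#' under a 1-cycle policy: the learning rate ramps from `max_lr / div` up to
#' `max_lr` over the first `pct_start` fraction of steps and anneals to
#' `max_lr / div_final` (cosine in both phases) while momentum is cycled
#' inversely between `momentum[1]` and `momentum[2]`. During finetuning from
#' a pretrained backbone, layer groups receive discriminative learning
#' rates: the head trains at the scheduled rate, the recurrent block at
#' `1 / discriminative_factor` of it, and the embedding at
#' `1 / discriminative_factor^2`.
#'
#' Epoch counts and the batch size are this package's defaults, fixed once
#' (see the methods vignette) and applied unchanged to every allele and
#' dataset; `max_lr` defaults to the value suggested by the learning-rate
#' range test ([lr_range_test()]) on a synthetic benchmark allele.
#'
#' @param epochs Finetuning epochs. Default 60.
#' @param lm_epochs Language-model pretraining epochs. Default 20.
#' @param batch_size Minibatch size. Default 32 (peptide datasets are small;
#'   small batches give the schedule enough optimiser steps to converge).
#' @param max_lr Peak learning rate of the 1-cycle schedule. Default 0.5.
#' @param pct_start Fraction of steps in the ramp-up phase. Default 0.3.
#' @param div,div_final Initial and final learning-rate divisors. Defaults
#'   10 and 100.
#' @param momentum Length-2 vector: initial/final and mid-cycle momentum.
#' @param discriminative_factor Per-layer-group learning-rate divisor used
#'   when finetuning from pretrained weights. Default 1 (no discounting): in
#'   this small-model, short-schedule regime backbone discounting measurably
#'   slows adaptation; the 2.6 of transfer-learning convention is available
#'   for longer schedules.
#' @param grad_clip Global gradient-norm clip. Default 5.
#' @param valid_frac Held-out fraction for monitoring metrics. Default 0.1.
#' @param seed Master seed; every stochastic choice (initialisation, batch
#'   order, dropout masks, ensemble-member seeds, data splits) derives from
#'   it, so a (seed, data, config) triple fully determines the fit.
#' @param ensemble_size Number of ensemble members. Default 10.
#' @return A list of class `pep_train_config`.
#' @export
train_config <- function(epochs = 60L, lm_epochs = 20L, batch_size = 32L,
                         max_lr = 0.5, pct_start = 0.3, div = 10,
                         div_final = 100, momentum = c(0.95, 0.85),
                         discriminative_factor = 1, grad_clip = 5,
                         valid_frac = 0.1, seed = 1L, ensemble_size = 10L) {
  stopifnot(epochs >= 1, lm_epochs >= 1, batch_size >= 1, max_lr > 0,
            pct_start > 0, pct_start < 1, div >= 1, div_final >= 1,
            length(momentum) == 2, discriminative_factor >= 1,
            grad_clip > 0, valid_frac >= 0, valid_frac < 1,
            ensemble_size >= 1)
  structure(
    list(
      epochs = as.integer(epochs), lm_epochs = as.integer(lm_epochs),
      batch_size = as.integer(batch_size), max_lr = max_lr,
      pct_start = pct_start, div = div, div_final = div_final,
      momentum = momentum, discriminative_factor = discriminative_factor,
      grad_clip = grad_clip, valid_frac = valid_frac,
      seed = as.integer(seed), ensemble_size = as.integer(ensemble_size)
    ),
    class = "pep_train_config"
  )
}

# Derived per-member / per-split seeds: distinct, deterministic, < 2^31.
# derive_seed(s, 1) == s so an ensemble of one reproduces the single model.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + (i - 1) * 104729) %% 2147483647)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 1-cycle learning-rate / momentum schedule at step `step` of `total`.
one_cycle_at <- function(step, total, tcfg) {
  cos_interp <- function(a, b, q) a + (b - a) * (1 - cos(pi * q)) / 2
  split <- max(1, round(tcfg$pct_start * total))
  if (step <= split) {
    q <- step / split
    list(lr = cos_interp(tcfg$max_lr / tcfg$div, tcfg$max_lr, q),
         mom = cos_interp(tcfg$momentum[1], tcfg$momentum[2], q))
  } else {
    q <- (step - split) / max(1, total - split)
    list(lr = cos_interp(tcfg$max_lr, tcfg$max_lr / tcfg$div_final, q),
         mom = cos_interp(tcfg$momentum[2], tcfg$momentum[1], q))
  }
}

# --- dropout machinery ------------------------------------------------------
# All masks are pre-scaled by 1/(1-p) (inverted dropout); identity at p = 0.

bern_mask <- function(n, p) {
  if (p <= 0) rep(1, n) else stats::rbinom(n, 1, 1 - p) / (1 - p)
}

sample_dropout <- function(cfg, B) {
  list(
    emb_rows = bern_mask(cfg$vocab_size, cfg$dropout$embedding),
    inmask = matrix(bern_mask(B * cfg$embedding_dim, cfg$dropout$input),
                    B, cfg$embedding_dim),
    wmask = matrix(bern_mask(cfg$hidden_units * 4 * cfg$hidden_units,
                             cfg$dropout$weight),
                   cfg$hidden_units, 4 * cfg$hidden_units),
    out = cfg$dropout$output
  )
}

identity_dropout <- function(cfg, B) {
  list(
    emb_rows = rep(1, cfg$vocab_size),
    inmask = matrix(1, B, cfg$embedding_dim),
    wmask = matrix(1, cfg$hidden_units, 4 * cfg$hidden_units),
    out = 0
  )
}

# --- optimiser --------------------------------------------------------------

param_group <- function(name) {
  switch(name, emb = "embedding", Wx = , Wh = , b = "recurrent", "head")
}

init_velocity <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

sgd_update <- function(params, vel, grads, lr, mom, group_mult, clip) {
  gn <- grad_global_norm(grads)
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    lr_g <- lr * group_mult[[param_group(nm)]]
    vel[[nm]] <- mom * vel[[nm]] - lr_g * g
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

# --- language-model training ------------------------------------------------

lm_eval_batches <- function(params, cfg, encoded, batch_size) {
  n <- length(encoded)
  loss_sum <- 0
  n_pos <- 0
  n_correct <- 0
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    batch <- pad_batch(encoded[idx])
    dm <- identity_dropout(cfg, length(idx))
    res <- cpp_lm_step(batch$indices, batch$lengths, params$emb, dm$inmask,
                       params$Wx, params$Wh, params$b, params$Wlm,
                       params$blm, matrix(1, length(idx), cfg$hidden_units),
                       FALSE)
    loss_sum <- loss_sum + res$loss * res$n_positions
    n_pos <- n_pos + res$n_positions
    n_correct <- n_correct + res$n_correct
  }
  list(ce = loss_sum / n_pos, perplexity = exp(loss_sum / n_pos),
       accuracy = n_correct / n_pos, n_positions = n_pos)
}

#' Evaluate a language model on a peptide set
#'
#' Computes next-token perplexity (`exp` of the mean cross-entropy) and
#' argmax accuracy over all prediction positions of the given peptides, in
#' evaluation mode (no dropout). Perplexity 1 is perfect; under uniform
#' prediction it equals the vocabulary size and accuracy sits at chance
#' level (1/20 on uniform-random peptides).
#'
#' @param lm A `pep_lm` or [pretrain_lm()] fit.
#' @param peptides Character vector of peptides.
#' @param batch_size Evaluation batch size.
#' @return A tibble with `perplexity`, `accuracy`, `n_positions`.
#' @export
evaluate_lm <- function(lm, peptides, batch_size = 256L) {
  if (inherits(lm, "pep_lm_fit")) lm <- lm$model
  stopifnot(inherits(lm, "pep_lm"))
  enc <- lapply(peptides, tokenize)
  m <- lm_eval_batches(lm$params, lm$cfg, enc, batch_size)
  tibble::tibble(perplexity = m$perplexity, accuracy = m$accuracy,
                 n_positions = m$n_positions)
}

#' Pretrain a next-token language model on a peptide corpus
#'
#' Trains the language model to predict each residue from the sequence
#' before it, on an unlabeled peptide corpus (typically simulated
#' proteasome-cleaved fragments, see [simulate_cleavage()]). A held-out
#' fraction is split off deterministically from the seed; reported
#' perplexity and accuracy are computed on held-out peptides only.
#'
#' @param corpus Character vector of peptides (or a `pep_corpus`).
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()]; uses `lm_epochs`, `batch_size`, the
#'   1-cycle schedule and `seed`.
#' @return An object of class `pep_lm_fit`: list with `model` (`pep_lm`),
#'   `metrics` (held-out perplexity/accuracy tibble), `history`
#'   (per-epoch training loss) and `tcfg`.
#' @export
pretrain_lm <- function(corpus, cfg = model_config(), tcfg = train_config()) {
  corpus <- as.character(corpus)
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  with_seed(tcfg$seed, {
    n <- length(corpus)
    n_hold <- max(1L, round(tcfg$valid_frac * n))
    hold_idx <- sample(n, n_hold)
    train_pep <- corpus[-hold_idx]
    hold_pep <- corpus[hold_idx]
    if (length(train_pep) < tcfg$batch_size) {
      stop(sprintf(
        "training corpus (%d peptides after held-out split) is smaller than one batch (%d); reduce batch_size",
        length(train_pep), tcfg$batch_size
      ), call. = FALSE)
    }
    enc_train <- lapply(train_pep, tokenize)
    enc_hold <- lapply(hold_pep, tokenize)

    model <- build_language_model(cfg)
    params <- model$params
    vel <- init_velocity(params)
    group_mult <- list(embedding = 1, recurrent = 1, head = 1)
    n_batches <- ceiling(length(enc_train) / tcfg$batch_size)
    total_steps <- tcfg$lm_epochs * n_batches
    step <- 0
    history <- numeric(tcfg$lm_epochs)

    for (epoch in seq_len(tcfg$lm_epochs)) {
      ord <- sample(length(enc_train))
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1) * tcfg$batch_size + 1):min(bi * tcfg$batch_size,
                                                        length(ord))]
        batch <- pad_batch(enc_train[idx])
        B <- length(idx)
        dm <- sample_dropout(cfg, B)
        outmask <- matrix(bern_mask(B * cfg$hidden_units, dm$out),
                          B, cfg$hidden_units)
        emb_eff <- params$emb * dm$emb_rows
        wh_eff <- params$Wh * dm$wmask
        res <- cpp_lm_step(batch$indices, batch$lengths, emb_eff, dm$inmask,
                           params$Wx, wh_eff, params$b, params$Wlm,
                           params$blm, outmask, TRUE)
        grads <- res$grads
        grads$emb <- grads$emb * dm$emb_rows
        grads$Wh <- grads$Wh * dm$wmask
        names(grads) <- c("emb", "Wx", "Wh", "b", "Wlm", "blm")
        step <- step + 1
        sched <- one_cycle_at(step, total_steps, tcfg)
        upd <- sgd_update(params, vel, grads, sched$lr, sched$mom,
                          group_mult, tcfg$grad_clip)
        params <- upd$params
        vel <- upd$vel
        epoch_loss <- epoch_loss + res$loss * res$n_positions
      }
      history[epoch] <- epoch_loss /
        sum(vapply(enc_train, function(e) e$length - 1, numeric(1)))
    }
    model$params <- params
    m <- lm_eval_batches(params, cfg, enc_hold, tcfg$batch_size)
    structure(
      list(
        model = model,
        metrics = tibble::tibble(perplexity = m$perplexity,
                                 accuracy = m$accuracy,
                                 n_holdout = length(hold_pep)),
        history = tibble::tibble(epoch = seq_len(tcfg$lm_epochs),
                                 train_ce = history),
        tcfg = tcfg
      ),
      class = "pep_lm_fit"
    )
  })
}

#' @export
print.pep_lm_fit <- function(x, ...) {
  cat("<pep_lm_fit> peptide language model\n")
  cat(sprintf("  held-out perplexity %.3f | accuracy %.3f (n = %d peptides)\n",
              x$metrics$perplexity, x$metrics$accuracy, x$metrics$n_holdout))
  invisible(x)
}

# --- regressor training -----------------------------------------------------

# Deterministic ~10% split by a string hash of the peptide, so the split is
# reproducible without storing files and stable under record reordering.
peptide_hash <- function(peptides, mod = 997L) {
  vapply(peptides, function(p) {
    h <- 0
    for (c in utf8ToInt(p)) h <- (h * 31 + c) %% 1048573
    h %% mod
  }, numeric(1), USE.NAMES = FALSE)
}

hash_validation_split <- function(peptides, frac = 0.1) {
  peptide_hash(peptides) < frac * 997
}

check_single_allele <- function(records) {
  alleles <- unique(records$allele)
  if (length(alleles) != 1L) {
    stop("records span ", length(alleles),
         " alleles; train one predictor per allele (split the table first)",
         call. = FALSE)
  }
  alleles
}

branch_code <- function(bound) {
  unname(c(point = 0L, at_least = 1L, at_most = 2L)[bound])
}

reg_train_loop <- function(records, cfg, tcfg, pretrained, cap_nm,
                           lr_override = NULL) {
  allele <- check_single_allele(records)
  if (nrow(records) < 2L) {
    stop("need at least 2 records to train a regressor", call. = FALSE)
  }
  with_seed(tcfg$seed, {
    tgt <- records_to_targets(records, cap_nm)
    in_valid <- hash_validation_split(tgt$peptide, tcfg$valid_frac)
    if (all(in_valid)) in_valid[] <- FALSE  # degenerate hash split: train on all
    tr <- which(!in_valid)
    va <- which(in_valid)
    enc <- lapply(tgt$peptide, tokenize)
    y <- tgt$y
    br <- branch_code(tgt$bound)

    reg <- build_regressor(cfg, pretrained = pretrained)
    params <- reg$params
    vel <- init_velocity(params)
    group_mult <- if (!is.null(pretrained)) {
      list(head = 1,
           recurrent = 1 / tcfg$discriminative_factor,
           embedding = 1 / tcfg$discriminative_factor^2)
    } else {
      list(head = 1, recurrent = 1, embedding = 1)
    }
    n_batches <- ceiling(length(tr) / tcfg$batch_size)
    total_steps <- tcfg$epochs * n_batches
    step <- 0
    hist_train <- numeric(tcfg$epochs)
    hist_valid <- rep(NA_real_, tcfg$epochs)

    for (epoch in seq_len(tcfg$epochs)) {
      ord <- tr[sample(length(tr))]
      epoch_loss <- 0
      epoch_n <- 0
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1) * tcfg$batch_size + 1):min(bi * tcfg$batch_size,
                                                        length(ord))]
        batch <- pad_batch(enc[idx])
        B <- length(idx)
        dm <- sample_dropout(cfg, B)
        headmask <- matrix(bern_mask(B * cfg$head_hidden, dm$out),
                           B, cfg$head_hidden)
        emb_eff <- params$emb * dm$emb_rows
        wh_eff <- params$Wh * dm$wmask
        res <- cpp_reg_step(batch$indices, batch$lengths, emb_eff, dm$inmask,
                            params$Wx, wh_eff, params$b, params$W1,
                            params$b1, params$W2, params$b2, headmask,
                            y[idx], br[idx], TRUE)
        grads <- res$grads
        grads$emb <- grads$emb * dm$emb_rows
        grads$Wh <- grads$Wh * dm$wmask
        step <- step + 1
        sched <- one_cycle_at(step, total_steps, tcfg)
        lr <- if (is.null(lr_override)) sched$lr else lr_override(step)
        upd <- sgd_update(params, vel, grads, lr, sched$mom,
                          group_mult, tcfg$grad_clip)
        params <- upd$params
        vel <- upd$vel
        epoch_loss <- epoch_loss + res$loss * B
        epoch_n <- epoch_n + B
      }
      hist_train[epoch] <- epoch_loss / epoch_n
      if (length(va) > 0) {
        vb <- pad_batch(enc[va])
        pv <- reg_forward_eval(params, cfg, vb)
        hist_valid[epoch] <- censored_mse(pv, y[va], tgt$bound[va])
      }
    }
    reg$params <- params
    structure(
      list(
        model = reg, allele = allele, cap_nm = cap_nm, tcfg = tcfg,
        pretrained = !is.null(pretrained),
        history = tibble::tibble(epoch = seq_len(tcfg$epochs),
                                 train_loss = hist_train,
                                 valid_loss = hist_valid),
        n_train = length(tr), n_valid = length(va)
      ),
      class = "pep_affinity_model"
    )
  })
}

#' Finetune an affinity regressor for one allele
#'
#' Trains the recurrent regression model on the affinity records of a single
#' MHC allele, minimising the censored mean-squared error
#' ([censored_mse()]) on log-transformed IC50 targets
#' ([ic50_to_target()]) under a 1-cycle learning-rate schedule. When a
#' pretrained language model is supplied its backbone initialises the
#' embedding and recurrent weights and discriminative learning rates are
#' applied per layer group (head at the scheduled rate, recurrent and
#' embedding at successively smaller rates).
#'
#' A ~`valid_frac` share of peptides (selected by a deterministic string
#' hash) is held out for the monitoring metrics in `history`; the fit is
#' fully reproducible from `(records, cfg, tcfg)`.
#'
#' @param records Affinity records of ONE allele (mixed alleles are an
#'   error).
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param pretrained Optional pretrained language model ([pretrain_lm()]
#'   fit, `pep_lm`, or backbone parameter list).
#' @param cap_nm IC50 cap of the target transform. Default 50000 nM.
#' @return An object of class `pep_affinity_model` with elements `model`,
#'   `allele`, `history`, `tcfg`, `cap_nm`.
#' @seealso [train_ensemble()], [predict.pep_affinity_model()]
#' @export
finetune_regressor <- function(records, cfg = model_config(),
                               tcfg = train_config(), pretrained = NULL,
                               cap_nm = 50000) {
  validate_affinity(records)
  if (!is.null(pretrained)) pretrained <- extract_backbone(pretrained)
  reg_train_loop(records, cfg, tcfg, pretrained, cap_nm)
}

#' Train an ensemble of affinity regressors
#'
#' Trains `tcfg$ensemble_size` regressors with identical architecture and
#' hyperparameters but distinct seeds derived deterministically from the
#' master seed, and averages their predictions (arithmetic mean on the
#' transformed-target scale, converted to nM afterwards). The first member's
#' seed equals the master seed, so an ensemble of one reproduces the single
#' model exactly.
#'
#' @inheritParams finetune_regressor
#' @return An object of class `pep_affinity_ensemble` with elements
#'   `members` (list of `pep_affinity_model`), `allele`, `tcfg`, `cap_nm`.
#' @export
train_ensemble <- function(records, cfg = model_config(),
                           tcfg = train_config(), pretrained = NULL,
                           cap_nm = 50000) {
  validate_affinity(records)
  if (!is.null(pretrained)) pretrained <- extract_backbone(pretrained)
  members <- lapply(seq_len(tcfg$ensemble_size), function(i) {
    tcfg_i <- tcfg
    tcfg_i$seed <- derive_seed(tcfg$seed, i)
    reg_train_loop(records, cfg, tcfg_i, pretrained, cap_nm)
  })
  structure(
    list(members = members, allele = members[[1]]$allele, tcfg = tcfg,
         cap_nm = cap_nm),
    class = "pep_affinity_ensemble"
  )
}

predict_y <- function(params, cfg, peptides, batch_size = 256L) {
  enc <- lapply(peptides, tokenize)
  out <- numeric(length(peptides))
  for (idx in split(seq_along(enc), ceiling(seq_along(enc) / batch_size))) {
    out[idx] <- reg_forward_eval(params, cfg, pad_batch(enc[idx]))
  }
  out
}

prediction_tbl <- function(peptides, y, cap_nm) {
  tibble::tibble(
    peptide = peptides,
    y_pred = y,
    ic50_pred_nm = cap_nm^(1 - pmin(pmax(y, 0), 1))
  )
}

#' Predict binding affinities
#'
#' Predicts the transformed affinity `y_pred` (raw, unconstrained model
#' output) and the corresponding IC50 in nM (via [target_to_ic50()] after
#' clipping to \[0, 1\]) for every input peptide; no peptide is ever
#' silently dropped. Ensemble predictions are the arithmetic mean of the
#' member outputs on the y scale.
#'
#' @param object A `pep_affinity_model` or `pep_affinity_ensemble`.
#' @param peptides Character vector of peptides.
#' @param ... Unused.
#' @return A tibble with one row per input peptide: `peptide`, `y_pred`,
#'   `ic50_pred_nm`.
#' @export
predict.pep_affinity_model <- function(object, peptides, ...) {
  y <- predict_y(object$model$params, object$model$cfg, peptides)
  prediction_tbl(peptides, y, object$cap_nm)
}

#' @rdname predict.pep_affinity_model
#' @export
predict.pep_affinity_ensemble <- function(object, peptides, ...) {
  ys <- vapply(
    object$members,
    function(m) predict_y(m$model$params, m$model$cfg, peptides),
    numeric(length(peptides))
  )
  if (length(peptides) == 1L) ys <- matrix(ys, nrow = 1)
  prediction_tbl(peptides, rowMeans(ys), object$cap_nm)
}

#' @export
print.pep_affinity_model <- function(x, ...) {
  cat("<pep_affinity_model>", x$allele,
      if (isTRUE(x$pretrained)) "(LM-pretrained)" else "(from scratch)", "\n")
  cat(sprintf("  trained on %d records (%d held out); final train loss %.4g\n",
              x$n_train, x$n_valid, utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' @export
print.pep_affinity_ensemble <- function(x, ...) {
  cat("<pep_affinity_ensemble>", x$allele, "-", length(x$members),
      "members\n")
  invisible(x)
}

# --- learning-rate range test ----------------------------------------------

#' Suggest a learning rate from a range-test curve
#'
#' Applies the range-test reading rule to a recorded loss-versus-rate curve:
#' find the divergence point (first rate at which the loss exceeds four
#' times the running minimum), take the rate with the smallest loss before
#' it, and suggest one order of magnitude below that rate.
#'
#' @param lrs Increasing vector of learning rates.
#' @param losses Loss recorded at each rate.
#' @return The suggested learning rate (scalar).
#' @seealso [lr_range_test()]
#' @export
suggest_lr_from_curve <- function(lrs, losses) {
  stopifnot(length(lrs) == length(losses), length(lrs) >= 3)
  finite <- is.finite(losses)
  losses[!finite] <- Inf
  run_min <- cummin(losses)
  diverged <- which(losses > 4 * run_min & seq_along(losses) > 1)
  last <- if (length(diverged) > 0) diverged[1] - 1L else length(lrs)
  best <- which.min(losses[seq_len(last)])
  lrs[best] / 10
}

#' Learning-rate range test
#'
#' Sweeps the learning rate exponentially between `lr_bounds` over training
#' steps (cycling through minibatches of the records), recording the
#' training loss after each step, and suggests a base learning rate one
#' order of magnitude below the loss minimum preceding divergence
#' ([suggest_lr_from_curve()]). Deterministic given `tcfg$seed`.
#'
#' @inheritParams finetune_regressor
#' @param lr_bounds Length-2 vector of sweep bounds. Default `c(1e-4, 3)`.
#' @param n_steps Number of sweep steps. Default 100.
#' @return An object of class `pep_lr_range`: list with `suggestion` and
#'   `curve` (tibble of `step`, `lr`, `loss`, `smooth`).
#' @export
lr_range_test <- function(records, cfg = model_config(),
                          tcfg = train_config(), lr_bounds = c(1e-4, 3),
                          n_steps = 100L, pretrained = NULL,
                          cap_nm = 50000) {
  validate_affinity(records)
  check_single_allele(records)
  if (!is.null(pretrained)) pretrained <- extract_backbone(pretrained)
  stopifnot(length(lr_bounds) == 2, lr_bounds[1] > 0,
            lr_bounds[2] > lr_bounds[1], n_steps >= 10)
  with_seed(tcfg$seed, {
    tgt <- records_to_targets(records, cap_nm)
    enc <- lapply(tgt$peptide, tokenize)
    br <- branch_code(tgt$bound)
    reg <- build_regressor(cfg, pretrained = pretrained)
    params <- reg$params
    vel <- init_velocity(params)
    group_mult <- list(head = 1, recurrent = 1, embedding = 1)
    lrs <- exp(seq(log(lr_bounds[1]), log(lr_bounds[2]),
                   length.out = n_steps))
    losses <- numeric(n_steps)
    ord <- sample(length(enc))
    pos <- 1
    for (s in seq_len(n_steps)) {
      idx <- ord[pos:min(pos + tcfg$batch_size - 1, length(ord))]
      pos <- pos + tcfg$batch_size
      if (pos > length(ord)) {
        ord <- sample(length(enc))
        pos <- 1
      }
      batch <- pad_batch(enc[idx])
      B <- length(idx)
      dm <- sample_dropout(cfg, B)
      headmask <- matrix(bern_mask(B * cfg$head_hidden, dm$out),
                         B, cfg$head_hidden)
      emb_eff <- params$emb * dm$emb_rows
      wh_eff <- params$Wh * dm$wmask
      res <- cpp_reg_step(batch$indices, batch$lengths, emb_eff, dm$inmask,
                          params$Wx, wh_eff, params$b, params$W1, params$b1,
                          params$W2, params$b2, headmask, tgt$y[idx],
                          br[idx], TRUE)
      losses[s] <- res$loss
      if (s == 1 && !is.finite(res$loss)) {
        stop("loss is not finite at the smallest learning rate; ",
             "check data and model configuration", call. = FALSE)
      }
      grads <- res$grads
      grads$emb <- grads$emb * dm$emb_rows
      grads$Wh <- grads$Wh * dm$wmask
      upd <- sgd_update(params, vel, grads, lrs[s], 0.9, group_mult,
                        tcfg$grad_clip)
      params <- upd$params
      vel <- upd$vel
      if (losses[s] > 100 * max(1e-8, min(losses[1:s]))) break
    }
    used <- seq_len(s)
    sm <- stats::filter(losses[used], rep(1 / 5, 5), sides = 1)
    sm[is.na(sm)] <- losses[used][is.na(sm)]
    structure(
      list(
        suggestion = suggest_lr_from_curve(lrs[used], as.numeric(sm)),
        curve = tibble::tibble(step = used, lr = lrs[used],
                               loss = losses[used],
                               smooth = as.numeric(sm))
      ),
      class = "pep_lr_range"
    )
  })
}

#' @export
print.pep_lr_range <- function(x, ...) {
  cat("<pep_lr_range>", nrow(x$curve), "steps; suggested base learning rate",
      signif(x$suggestion, 3), "\n")
  invisible(x)
}
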