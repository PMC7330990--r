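# Independent oracles used to derive expected values. Each is a deliberately
# naive implementation (brute force / closed form), kept separate from the
# package's code paths.

# O(n^2) pair-counting AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc_paircount <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# Mid-rank-then-Pearson Spearman, with the Pearson part written out by hand.
oracle_spearman_midrank <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# Scalar three-branch censored squared error, case by case.
oracle_censored_scalar <- function(y_pred, y, bound) {
  if (bound == "point") {
    (y_pred - y)^2
  } else if (bound == "at_least") {
    if (y_pred >= y) 0 else (y - y_pred)^2
  } else {
    if (y_pred <= y) 0 else (y_pred - y)^2
  }
}

# Naive loop concat pooling over a positions x units state matrix.
oracle_concat_pool <- function(hidden, len) {
  H <- ncol(hidden)
  last <- hidden[len, ]
  mx <- numeric(H)
  mn <- numeric(H)
  for (h in seq_len(H)) {
    mx[h] <- max(hidden[seq_len(len), h])
    mn[h] <- mean(hidden[seq_len(len), h])
  }
  c(last, mx, mn)
}

# Bayes-optimal next-token accuracy of a first-order residue chain for
# fixed-length peptides: the first residue is predicted from the stationary
# law, subsequent residues from their predecessor's transition row.
oracle_markov_bayes_accuracy <- function(P, len) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  pi_st <- v / sum(v)
  (max(pi_st) + (len - 1) * sum(pi_st * apply(P, 1, max))) / len
}

# Closed-form AUC of the binormal score model: positives ~ N(mu, 1),
# negatives ~ N(0, 1).
oracle_binormal_auc <- function(mu) stats::pnorm(mu / sqrt(2))

# Random valid peptides for property tests.
rand_peps <- function(n, min_len = 8, max_len = 15) {
  lens <- sample.int(max_len - min_len + 1L, n, replace = TRUE) + min_len - 1L
  vapply(lens, function(L) {
    paste(sample(amino_acids(), L, replace = TRUE), collapse = "")
  }, character(1))
}

# A tiny architecture for gradient checks and shape tests.
tiny_cfg <- function(drop = 0) {
  model_config(
    vocab_size = 8, embedding_dim = 3, hidden_units = 4,
    dropout = list(embedding = drop, input = drop, weight = drop,
                   output = drop),
    head_hidden = 5
  )
}

# Write a small affinity CSV and return its path.
write_toy_affinity <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("allele,peptide,ic50_nM,inequality,kind", lines), path)
  path
}
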