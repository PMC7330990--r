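#' Stochastic proteasome-cleavage model
#'
#' Specifies how proteins are sliced into peptide fragments: every
#' inter-residue site is cut independently with a probability that either
#' comes from a user-supplied per-site table (e.g. the output of an external
#' cleavage-site predictor) or from the internal residue-conditioned model,
#' where the cut probability depends on the residue N-terminal to the site.
#' The internal defaults give elevated probabilities after hydrophobic and
#' basic residues (the proteasome's broad preference) and a mean fragment
#' length of about 10 residues. Fragments outside `[min_len, max_len]`
#' (default 8-20) are discarded.
#'
#' @param site_probs Optional named list: for each protein, a numeric vector
#'   of cut probabilities, one per inter-residue site (length
#'   `nchar(protein) - 1`). Overrides the residue-conditioned model.
#' @param residue_probs Named numeric vector of cut probabilities per
#'   N-terminal residue, covering all 20 amino acids, values in \[0, 1\].
#' @param min_len,max_len Fragment length filter (inclusive). Defaults 8
#'   and 20.
#' @return A list of class `pep_cleavage_model`.
#' @export
cleavage_model <- function(site_probs = NULL,
                           residue_probs = default_residue_probs(),
                           min_len = 8L, max_len = 20L) {
  if (min_len > max_len) stop("min_len must not exceed max_len", call. = FALSE)
  if (is.null(site_probs)) {
    missing <- setdiff(amino_acids(), names(residue_probs))
    if (length(missing) > 0L) {
      stop("residue_probs must cover all 20 amino acids; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(residue_probs < 0 | residue_probs > 1)) {
      stop("cut probabilities must lie in [0, 1]", call. = FALSE)
    }
  } else {
    if (any(unlist(site_probs) < 0 | unlist(site_probs) > 1)) {
      stop("cut probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(site_probs = site_probs, residue_probs = residue_probs,
         min_len = as.integer(min_len), max_len = as.integer(max_len)),
    class = "pep_cleavage_model"
  )
}

#' @rdname cleavage_model
#' @export
default_residue_probs <- function() {
  p <- stats::setNames(rep(0.08, 20), amino_acids())
  p[c("L", "F")] <- 0.18
  p[c("Y", "W")] <- 0.14
  p[c("R", "K")] <- 0.12
  p
}

#' Simulate proteasome cleavage of proteins into a peptide corpus
#'
#' Cuts each protein at every inter-residue site independently with its cut
#' probability (see [cleavage_model()]), keeps fragments whose length lies
#' in the model's `[min_len, max_len]` window, and returns the resulting
#' peptide corpus for language-model pretraining. Deterministic given
#' `seed`. Corpus statistics (fragment count, length histogram, acceptance
#' rate) are attached as the `stats` attribute.
#'
#' @param proteins Named character vector of protein sequences over the
#'   amino-acid alphabet (or a `Biostrings::AAStringSet`).
#' @param model A [cleavage_model()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param repeats Number of independent stochastic slicings per protein.
#'   Default 1.
#' @return Character vector of peptides of class `pep_corpus` with
#'   attribute `stats` (list: `n_fragments`, `n_kept`, `length_table`).
#' @export
simulate_cleavage <- function(proteins, model = cleavage_model(),
                              seed = NULL, repeats = 1L) {
  if (inherits(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  for (pr in proteins) assert_valid_peptide(pr)
  run <- function() {
    pieces <- list()
    n_total <- 0L
    for (k in seq_along(proteins)) {
      prot <- proteins[[k]]
      n <- nchar(prot)
      if (n < 2L) next
      p <- if (!is.null(model$site_probs)) {
        sp <- model$site_probs[[names(proteins)[k] %||% k]]
        if (is.null(sp) || length(sp) != n - 1L) {
          stop("site_probs must provide one probability per inter-residue site",
               call. = FALSE)
        }
        sp
      } else {
        chars <- strsplit(substr(prot, 1L, n - 1L), "", fixed = TRUE)[[1]]
        unname(model$residue_probs[chars])
      }
      for (r in seq_len(repeats)) {
        cut_after <- which(stats::runif(n - 1L) < p)
        starts <- c(1L, cut_after + 1L)
        ends <- c(cut_after, n)
        len <- ends - starts + 1L
        n_total <- n_total + length(len)
        keep <- len >= model$min_len & len <= model$max_len
        if (any(keep)) {
          pieces[[length(pieces) + 1L]] <-
            substring(prot, starts[keep], ends[keep])
        }
      }
    }
    list(frags = unlist(pieces) %||% character(0), n_total = n_total)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    res$frags,
    stats = list(
      n_fragments = res$n_total,
      n_kept = length(res$frags),
      length_table = table(factor(nchar(res$frags),
                                  levels = model$min_len:model$max_len))
    ),
    class = "pep_corpus"
  )
}

#' @export
print.pep_corpus <- function(x, ...) {
  st <- attr(x, "stats")
  cat("<pep_corpus>", st$n_kept, "peptides kept of", st$n_fragments,
      "fragments\n")
  print(st$length_table)
  invisible(x)
}

#' Write a peptide corpus
#'
#' Plain peptide-per-line text, or FASTA when `format = "fasta"`.
#'
#' @param corpus Character vector of peptides.
#' @param path Output file.
#' @param format `"text"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("text", "fasta")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(as.character(corpus), path)
  } else {
    writeLines(
      as.vector(rbind(sprintf(">pep%06d", seq_along(corpus)),
                      as.character(corpus))),
      path
    )
  }
  invisible(path)
}

#' Generate a synthetic allele binding motif
#'
#' Builds an anchor-style position-specific score matrix used as ground
#' truth for synthetic affinity benchmarks: 2-3 anchor positions carry
#' high-contrast residue scores while the remaining positions are near
#' flat, mimicking the anchor-residue structure of real MHC binding
#' pockets. All scores scale with `sharpness` (as it tends to 0 every
#' peptide has near-equal energy). The energy-to-IC50 mapping
#' (see [simulate_affinity()]) is calibrated per motif so that about 25% of
#' uniform-random peptides fall below 500 nM, matching the binder share
#' typical of class I training sets.
#'
#' @param seed Integer seed; the motif is reproducible from it.
#' @param sharpness Positive scale of the score contrasts. Default 2.
#' @param core_length Length of the scored core window. Default 9.
#' @param noise_sd Standard deviation of the Gaussian energy noise added by
#'   [simulate_affinity()]. Default 0.05.
#' @param allele_id Allele identifier; default derived from the seed.
#' @param cap_nm IC50 cap / censoring ceiling. Default 50000 nM.
#' @return An object of class `pep_motif`: list with `allele_id`,
#'   `core_length`, `scores` (core x 20 matrix), `anchors`, `noise_sd`,
#'   calibration slope/offset `a`, `b`, and `cap_nm`.
#' @export
make_allele_motif <- function(seed, sharpness = 2, core_length = 9L,
                              noise_sd = 0.05, allele_id = NULL,
                              cap_nm = 50000) {
  if (sharpness <= 0) stop("sharpness must be positive", call. = FALSE)
  with_seed(seed, {
    aa <- amino_acids()
    scores <- matrix(stats::rnorm(core_length * 20, sd = 0.05 * sharpness),
                     core_length, 20, dimnames = list(NULL, aa))
    n_anchor <- sample(2:3, 1)
    anchors <- sort(sample(core_length, n_anchor))
    for (pos in anchors) {
      scores[pos, ] <- stats::rnorm(20, sd = sharpness)
    }
    motif <- list(
      allele_id = allele_id %||% sprintf("SYN-%04d", seed %% 10000),
      core_length = as.integer(core_length),
      scores = scores,
      anchors = anchors,
      noise_sd = noise_sd,
      cap_nm = cap_nm
    )
    # calibrate the logistic energy -> y map on random core-length peptides:
    # ~25% of random peptides should score below 500 nM
    probe <- random_peptides(2000, core_length, core_length)
    e <- motif_energy_impl(motif, probe)
    a <- 1.702 / max(stats::sd(e), 1e-12)
    y500 <- 1 - log(500) / log(cap_nm)
    b <- stats::quantile(e, 0.75, names = FALSE) -
      stats::qlogis(y500) / a
    motif$a <- a
    motif$b <- b
    structure(motif, class = "pep_motif")
  })
}

#' @export
print.pep_motif <- function(x, ...) {
  cat("<pep_motif>", x$allele_id, "- core", x$core_length, "anchors at",
      paste(x$anchors, collapse = ","), "\n")
  invisible(x)
}

#' Generate synthetic protein sequences
#'
#' Draws protein sequences either with independent uniform residues or, when
#' a `transition` matrix is given, from a first-order Markov chain over the
#' 20 amino acids (initial residue from the chain's stationary
#' distribution). Real proteomes carry residue-neighbour correlations;
#' Markov-structured proteins give a cleavage corpus the sequential
#' statistics a language model can actually learn.
#'
#' @param n Number of proteins.
#' @param length Protein length (recycled).
#' @param transition Optional 20 x 20 row-stochastic matrix (rows/cols in
#'   [amino_acids()] order): `transition[i, j]` is the probability that
#'   residue j follows residue i.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named character vector of protein sequences.
#' @seealso [markov_transition_matrix()], [simulate_cleavage()]
#' @export
random_proteins <- function(n, length = 500L, transition = NULL, seed = NULL) {
  length <- rep_len(as.integer(length), n)
  aa <- amino_acids()
  if (!is.null(transition)) {
    stopifnot(is.matrix(transition), dim(transition) == c(20, 20),
              all(transition >= 0),
              max(abs(rowSums(transition) - 1)) < 1e-8)
    init <- stationary_distribution(transition)
  }
  run <- function() {
    out <- vapply(seq_len(n), function(k) {
      L <- length[k]
      if (is.null(transition)) {
        paste(sample(aa, L, replace = TRUE), collapse = "")
      } else {
        idx <- integer(L)
        idx[1] <- sample.int(20, 1, prob = init)
        for (i in seq_len(L - 1)) {
          idx[i + 1] <- sample.int(20, 1, prob = transition[idx[i], ])
        }
        paste(aa[idx], collapse = "")
      }
    }, character(1))
    stats::setNames(out, sprintf("prot%04d", seq_len(n)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Random residue transition matrix
#'
#' A seeded row-stochastic 20 x 20 matrix for [random_proteins()]: each row
#' is a Dirichlet draw with one preferred successor residue, giving proteins
#' first-order structure of tunable strength.
#'
#' @param seed Integer seed.
#' @param dominance Probability mass placed on each row's preferred
#'   successor before renormalising with the Dirichlet remainder. Default
#'   0.4.
#' @return A 20 x 20 row-stochastic matrix with `dimnames` in
#'   [amino_acids()] order.
#' @export
markov_transition_matrix <- function(seed, dominance = 0.4) {
  stopifnot(dominance >= 0, dominance < 1)
  with_seed(seed, {
    aa <- amino_acids()
    P <- matrix(stats::rgamma(400, shape = 1), 20, 20,
                dimnames = list(aa, aa))
    P <- P / rowSums(P) * (1 - dominance)
    fav <- sample.int(20, 20, replace = FALSE)
    P[cbind(seq_len(20), fav)] <- P[cbind(seq_len(20), fav)] + dominance
    P
  })
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  v / sum(v)
}

# Uniform-random peptides with lengths uniform in [min_len, max_len].
random_peptides <- function(n, min_len, max_len) {
  lens <- sample.int(max_len - min_len + 1L, n, replace = TRUE) + min_len - 1L
  vapply(lens, function(L) {
    paste(sample(amino_acids(), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Best-scoring core window: max over sliding windows for peptides longer
# than the core.
motif_energy_impl <- function(motif, peptides) {
  core <- motif$core_length
  vapply(peptides, function(p) {
    L <- nchar(p)
    if (L < core) {
      stop(sprintf("peptide '%s' is shorter than the motif core (%d)", p, core),
           call. = FALSE)
    }
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    idx <- match(chars, colnames(motif$scores))
    best <- -Inf
    for (s in 0:(L - core)) {
      e <- sum(motif$scores[cbind(seq_len(core), idx[s + seq_len(core)])])
      if (e > best) best <- e
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}

#' Noiseless motif energy of peptides
#'
#' The ground-truth binding energy of each peptide under a synthetic motif:
#' the best (maximum) score over all sliding core windows. Monotonically
#' determines the expected IC50.
#'
#' @param motif A [make_allele_motif()] motif.
#' @param peptides Character vector, all at least `core_length` long.
#' @return Numeric energy vector.
#' @export
motif_energy <- function(motif, peptides) {
  stopifnot(inherits(motif, "pep_motif"))
  motif_energy_impl(motif, peptides)
}

#' Simulate affinity measurements under a synthetic motif
#'
#' Draws one affinity record per peptide: the noiseless motif energy plus
#' Gaussian noise (`motif$noise_sd`) is mapped through a per-motif
#' calibrated logistic onto the transformed-affinity scale and then to an
#' IC50 in `(1, cap_nm]`, strictly decreasing in energy. With probability
#' `qual_fraction` a record is emitted as qualitative instead, emulating a
#' thresholded assay censored at `qual_bound_nm`: the record reports only
#' `IC50 < bound` (inequality `LT`) or `IC50 > bound` (`GT`), carrying the
#' bound in its IC50 field, usable by the censored loss. Censoring at the
#' dataset's binder threshold keeps the binder label of a qualitative
#' record intact.
#'
#' @param motif A [make_allele_motif()] motif.
#' @param peptides Character vector of peptides (each at least
#'   `core_length` long).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param qual_fraction Probability that a record is emitted as qualitative.
#'   Default 0.
#' @param qual_bound_nm Censoring bound of qualitative records. Default 500
#'   (the class I binder threshold); use 100000 for assays censored at the
#'   higher ceiling.
#' @return An `affinity_tbl` with one row per peptide and attribute
#'   `energy` (the noiseless ground-truth energies).
#' @export
simulate_affinity <- function(motif, peptides, seed = NULL,
                              qual_fraction = 0,
                              qual_bound_nm = 500) {
  stopifnot(inherits(motif, "pep_motif"))
  energy <- motif_energy_impl(motif, peptides)
  run <- function() {
    e_obs <- energy + stats::rnorm(length(energy), sd = motif$noise_sd)
    y <- stats::plogis(motif$a * (e_obs - motif$b))
    ic50 <- pmin(pmax(motif$cap_nm^(1 - y), 1 + 1e-9), motif$cap_nm)
    qual <- stats::runif(length(energy)) < qual_fraction
    tibble::tibble(
      allele = motif$allele_id,
      peptide = peptides,
      ic50_nm = ifelse(qual, qual_bound_nm, ic50),
      inequality = ifelse(qual, ifelse(ic50 < qual_bound_nm, "LT", "GT"),
                          "EQ"),
      kind = ifelse(qual, "qualitative", "quantitative")
    )
  }
  rec <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- new_affinity_tbl(rec)
  attr(out, "energy") <- energy
  out
}

#' Build a synthetic affinity benchmark with known ground truth
#'
#' Generates, per allele: a synthetic binding motif, training and test
#' peptides of mixed lengths, and simulated affinity records. The test set
#' is decontaminated against the training set with
#' [similarity_overlap_audit()] at the given identity threshold (same
#' length, positional identity), so the emitted split always audits clean.
#' The returned truth table retains the noiseless energies for
#' parameter-recovery analyses.
#'
#' @param n_alleles Number of synthetic alleles. Default 1.
#' @param n_train,n_test Records per allele. Defaults 2000 and 500.
#' @param qual_fraction Probability of emitting a record as qualitative, in
#'   both splits. Default 0.
#' @param length_range Inclusive peptide length range, e.g. `c(8, 11)`. The
#'   motif core is `min(9, length_range[1])` so every peptide can be
#'   scored.
#' @param noise_sd Gaussian energy noise. Default 0.05.
#' @param sharpness Motif contrast scale. Default 2.
#' @param identity_threshold Decontamination threshold. Default 0.8.
#' @param seed Master seed; motifs, peptides and noise all derive from it.
#' @return An object of class `pep_benchmark`: list with `train` and `test`
#'   (`affinity_tbl`s over all alleles), `truth` (tibble `allele`,
#'   `peptide`, `energy`, `split`), and `motifs` (named list).
#' @export
make_benchmark <- function(n_alleles = 1L, n_train = 2000L, n_test = 500L,
                           qual_fraction = 0, length_range = c(8L, 11L),
                           noise_sd = 0.05, sharpness = 2,
                           identity_threshold = 0.8, seed = 1L) {
  stopifnot(n_alleles >= 1, n_train >= 1, n_test >= 1,
            length(length_range) == 2, length_range[1] <= length_range[2])
  core <- min(9L, as.integer(length_range[1]))
  train_list <- list()
  test_list <- list()
  truth_list <- list()
  motifs <- list()
  for (k in seq_len(n_alleles)) {
    motif <- make_allele_motif(
      seed = derive_seed(seed, 500 + k), sharpness = sharpness,
      core_length = core, noise_sd = noise_sd,
      allele_id = sprintf("SYN-%02d", k)
    )
    motifs[[motif$allele_id]] <- motif
    sim <- with_seed(derive_seed(seed, 700 + k), {
      train_pep <- unique(random_peptides(ceiling(n_train * 1.1),
                                          length_range[1], length_range[2]))
      train_pep <- train_pep[seq_len(min(n_train, length(train_pep)))]
      test_pep <- character(0)
      guard <- 0
      while (length(test_pep) < n_test && guard < 50) {
        guard <- guard + 1
        cand <- setdiff(
          unique(random_peptides(2 * (n_test - length(test_pep)) + 20,
                                 length_range[1], length_range[2])),
          c(train_pep, test_pep)
        )
        if (length(cand) == 0) next
        flagged <- similarity_overlap_audit(train_pep, cand,
                                            identity_threshold)
        cand <- setdiff(cand, flagged$peptide)
        test_pep <- c(test_pep, cand)
      }
      test_pep <- test_pep[seq_len(min(n_test, length(test_pep)))]
      list(train = train_pep, test = test_pep)
    })
    tr <- simulate_affinity(motif, sim$train,
                            seed = derive_seed(seed, 900 + k),
                            qual_fraction = qual_fraction)
    te <- simulate_affinity(motif, sim$test,
                            seed = derive_seed(seed, 1100 + k),
                            qual_fraction = qual_fraction)
    train_list[[k]] <- tr
    test_list[[k]] <- te
    truth_list[[k]] <- tibble::tibble(
      allele = motif$allele_id,
      peptide = c(sim$train, sim$test),
      energy = c(attr(tr, "energy"), attr(te, "energy")),
      split = rep(c("train", "test"), c(length(sim$train), length(sim$test)))
    )
  }
  structure(
    list(
      train = new_affinity_tbl(dplyr::bind_rows(train_list)),
      test = new_affinity_tbl(dplyr::bind_rows(test_list)),
      truth = dplyr::bind_rows(truth_list),
      motifs = motifs,
      params = list(n_alleles = n_alleles, n_train = n_train,
                    n_test = n_test, qual_fraction = qual_fraction,
                    length_range = length_range, noise_sd = noise_sd,
                    sharpness = sharpness,
                    identity_threshold = identity_threshold, seed = seed)
    ),
    class = "pep_benchmark"
  )
}

#' @export
print.pep_benchmark <- function(x, ...) {
  cat("<pep_benchmark>", length(x$motifs), "allele(s);",
      nrow(x$train), "train /", nrow(x$test), "test records\n")
  invisible(x)
}
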