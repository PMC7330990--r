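test_that("cleavage with p = 0 yields the whole protein when it fits the window", {
  cm <- cleavage_model(residue_probs = stats::setNames(rep(0, 20),
                                                       amino_acids()))
  prot <- c(p1 = "ACDEFGHIKLMN")  # length 12, inside [8, 20]
  out <- simulate_cleavage(prot, cm, seed = 1)
  expect_equal(as.character(out), "ACDEFGHIKLMN")
})

test_that("cleavage with p = 1 leaves only length-1 fragments, all filtered", {
  cm <- cleavage_model(residue_probs = stats::setNames(rep(1, 20),
                                                       amino_acids()))
  out <- simulate_cleavage(c(p1 = "ACDEFGHIKLMN"), cm, seed = 1)
  expect_length(out, 0L)
  expect_equal(attr(out, "stats")$n_fragments, 12L)
})

test_that("no kept fragment ever falls outside the length window", {
  prot <- random_proteins(30, 800, seed = 2)
  out <- simulate_cleavage(prot, cleavage_model(), seed = 3)
  expect_gt(length(out), 0L)
  expect_true(all(nchar(out) >= 8 & nchar(out) <= 20))
})

test_that("iid cutting yields truncated-geometric fragment lengths", {
  cm <- cleavage_model(residue_probs = stats::setNames(rep(0.1, 20),
                                                       amino_acids()))
  prot <- random_proteins(40, 5000, seed = 4)
  out <- simulate_cleavage(prot, cm, seed = 5)
  obs <- tabulate(nchar(out), 20)[8:20]
  p <- 0.1
  expp <- (1 - p)^(7:19)
  gof <- stats::chisq.test(obs, p = expp / sum(expp))
  expect_gt(gof$p.value, 0.01)
})

test_that("corpora are byte-identical under one seed and repeats multiply output", {
  prot <- random_proteins(5, 400, seed = 6)
  c1 <- simulate_cleavage(prot, seed = 7)
  c2 <- simulate_cleavage(prot, seed = 7)
  expect_identical(as.character(c1), as.character(c2))
  # with deterministic no-cut slicing, each repeat re-emits the protein
  cm0 <- cleavage_model(residue_probs = stats::setNames(rep(0, 20),
                                                        amino_acids()))
  c3 <- simulate_cleavage(c(p = "ACDEFGHIKLMN"), cm0, seed = 7, repeats = 3)
  expect_equal(as.character(c3), rep("ACDEFGHIKLMN", 3))
})

test_that("a supplied per-site probability table overrides the residue model", {
  prot <- c(p1 = "ACDEFGHIKLMN")
  sp <- list(p1 = c(rep(0, 7), 1, rep(0, 3)))  # deterministic cut after 8
  out <- simulate_cleavage(prot, cleavage_model(site_probs = sp), seed = 8)
  expect_equal(sort(as.character(out)), sort(c("ACDEFGHI")))  # tail is 4-mer
  expect_error(
    simulate_cleavage(prot, cleavage_model(site_probs = list(p1 = c(0.5)))),
    "per inter-residue site"
  )
  expect_error(cleavage_model(site_probs = list(p1 = c(0.5, 2))), "\\[0, 1\\]")
})

test_that("motifs are seed-reproducible, anchored, and scale with sharpness", {
  m1 <- make_allele_motif(101)
  m2 <- make_allele_motif(101)
  expect_identical(m1$scores, m2$scores)
  expect_false(identical(m1$scores, make_allele_motif(102)$scores))
  expect_true(all(m1$anchors %in% 1:9))
  expect_true(length(m1$anchors) %in% 2:3)
  # anchor columns carry far more contrast than flat positions
  sds <- apply(m1$scores, 1, stats::sd)
  expect_gt(min(sds[m1$anchors]), max(sds[-m1$anchors]))
  # flat limit: energies collapse as sharpness -> 0
  set.seed(9)
  peps <- rand_peps(50, 9, 9)
  tiny <- make_allele_motif(101, sharpness = 1e-6)
  expect_lt(diff(range(motif_energy(tiny, peps))), 1e-4)
  expect_error(make_allele_motif(1, sharpness = 0), "positive")
})

test_that("motif energy is the best window and is additive per position", {
  m <- make_allele_motif(103, core_length = 9)
  set.seed(10)
  p9 <- rand_peps(20, 9, 9)
  # single window: energy is the plain positional sum
  want <- vapply(p9, function(p) {
    idx <- match(strsplit(p, "")[[1]], colnames(m$scores))
    sum(m$scores[cbind(1:9, idx)])
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(motif_energy(m, p9), want)
  # longer peptides: max over sliding windows, checked by brute force
  p12 <- rand_peps(20, 12, 12)
  want12 <- vapply(p12, function(p) {
    idx <- match(strsplit(p, "")[[1]], colnames(m$scores))
    max(vapply(0:3, function(s) sum(m$scores[cbind(1:9, idx[s + 1:9])]),
               numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(motif_energy(m, p12), want12)
  expect_error(motif_energy(m, "ACDEFGHI"), "shorter than the motif core")
})

test_that("energy distribution matches the positional-marginal convolution", {
  # for uniform residues the 9-mer energy is a sum of independent draws,
  # one per position, from that position's score column
  m <- make_allele_motif(104, core_length = 9)
  set.seed(11)
  e <- motif_energy(m, rand_peps(1000, 9, 9))
  want_mean <- sum(rowMeans(m$scores))
  want_var <- sum(apply(m$scores, 1, function(s) mean(s^2) - mean(s)^2))
  expect_equal(mean(e), want_mean, tolerance = 5 * sqrt(want_var / 1000))
  expect_equal(stats::var(e), want_var, tolerance = 0.25 * want_var)
  # against a direct convolution sample drawn column-wise
  conv <- rowSums(vapply(1:9, function(pos) {
    sample(m$scores[pos, ], 1000, replace = TRUE)
  }, numeric(1000)))
  expect_gt(suppressWarnings(stats::ks.test(e, conv)$p.value), 0.01)
})

test_that("noiseless affinities follow the energy ordering exactly", {
  m <- make_allele_motif(105, noise_sd = 0)
  set.seed(12)
  peps <- rand_peps(100, 9, 11)
  rec <- simulate_affinity(m, peps, seed = 13)
  e <- attr(rec, "energy")
  expect_equal(spearman_r(e, rec$ic50_nm), -1)
  expect_true(all(rec$ic50_nm > 1 & rec$ic50_nm <= 50000))
  # peptides sharing their best window share their IC50
  twin <- simulate_affinity(m, c("ACDEFGHIK", "ACDEFGHIK"), seed = 14)
  expect_equal(twin$ic50_nm[1], twin$ic50_nm[2])
})

test_that("the calibrated map yields roughly a quarter binders at 500 nM", {
  m <- make_allele_motif(106, noise_sd = 0)
  set.seed(15)
  rec <- simulate_affinity(m, rand_peps(2000, 9, 9), seed = 16)
  share <- mean(binder_label(rec$ic50_nm, 500))
  expect_gt(share, 0.15)
  expect_lt(share, 0.35)
})

test_that("qualitative emission censors at the bound, preserving binder labels", {
  m <- make_allele_motif(107)
  set.seed(17)
  peps <- rand_peps(300, 9, 9)
  all_q <- simulate_affinity(m, peps, seed = 18, qual_fraction = 1,
                             qual_bound_nm = 500)
  expect_true(all(all_q$inequality %in% c("LT", "GT")))
  expect_true(all(all_q$kind == "qualitative"))
  expect_true(all(all_q$ic50_nm == 500))
  expect_gt(sum(all_q$inequality == "LT"), 0)  # both sides populated
  expect_gt(sum(all_q$inequality == "GT"), 0)
  # labels match the labels of the uncensored draws (same seed)
  none_q <- simulate_affinity(m, peps, seed = 18, qual_fraction = 0)
  expect_true(all(none_q$kind == "quantitative"))
  expect_equal(binder_label_records(all_q, 500),
               binder_label(none_q$ic50_nm, 500))
})

test_that("benchmarks emit decontaminated splits with retained ground truth", {
  bm <- make_benchmark(n_alleles = 2, n_train = 150, n_test = 40, seed = 19)
  expect_equal(nrow(bm$train), 300L)
  expect_equal(nrow(bm$test), 80L)
  for (al in names(bm$motifs)) {
    audit <- similarity_overlap_audit(
      bm$train$peptide[bm$train$allele == al],
      bm$test$peptide[bm$test$allele == al], 0.8
    )
    expect_equal(nrow(audit), 0L)
  }
  # truth table covers both splits with finite noiseless energies
  expect_equal(sort(unique(bm$truth$split)), c("test", "train"))
  expect_true(all(is.finite(bm$truth$energy)))
  # 8-11-mer benchmarks use a core of 8 so every peptide is scoreable
  expect_equal(bm$motifs[[1]]$core_length, 8L)
})

test_that("qualitative-only benchmarks leave Spearman undefined but AUC defined", {
  bm <- make_benchmark(n_train = 80, n_test = 60, qual_fraction = 1,
                       seed = 20)
  expect_true(all(bm$train$kind == "qualitative"))
  expect_true(all(bm$test$kind == "qualitative"))
  set.seed(23)
  pred <- dplyr::mutate(bm$test, y_pred = stats::rnorm(dplyr::n()))
  rep <- evaluate_predictions(pred, binder_threshold_nm = 500)
  expect_true(is.na(rep$per_allele$spearman))
  expect_false(is.na(rep$per_allele$auc))
})

test_that("markov proteins follow the requested transition structure", {
  P <- markov_transition_matrix(21, dominance = 0.5)
  expect_equal(rowSums(P), rep(1, 20), ignore_attr = TRUE)
  prot <- random_proteins(20, 400, transition = P, seed = 22)
  expect_identical(prot, random_proteins(20, 400, transition = P, seed = 22))
  # empirical transition frequencies agree with P for a frequent row
  chars <- strsplit(paste(prot, collapse = ""), "")[[1]]
  idx <- match(chars, amino_acids())
  from <- idx[-length(idx)]
  to <- idx[-1]
  row <- which.max(tabulate(from, 20))
  emp <- tabulate(to[from == row], 20) / sum(from == row)
  expect_lt(max(abs(emp - P[row, ])), 0.08)
})
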