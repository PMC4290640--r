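# The pair-feature extraction core and the baseline feature sets.

test_that("Q concatenates the evolutionary block then the structural block", {
  p1 <- rand_profile(1)
  expect_equal(dim(build_Q(p1)), c(1L, 23L))

  uni <- protein_profile("u", "AAAA",
                         P = matrix(1 / 20, 4, 20), S = matrix(1 / 3, 4, 3))
  Q <- build_Q(uni)
  expect_equal(unname(Q[2, ]), c(rep(1 / 20, 20), rep(1 / 3, 3)))

  withr::local_seed(11)
  for (rep in 1:100) {
    p <- rand_profile(sample(2:40, 1))
    Q <- build_Q(p)
    expect_identical(unname(Q[, 21]), unname(p$S[, 1]))
    expect_equal(rowSums(Q), rep(2, nrow(Q)), tolerance = 1e-6)
  }
})

test_that("pair features vanish when the separation exceeds the length", {
  p <- rand_profile(4)
  r <- kaap_single(build_Q(p), 4)
  expect_length(r$flat, 529L)
  expect_true(all(r$flat == 0))
  expect_error(kaap_single(build_Q(p), 0), "k must be", class = "kaapfold_input_error")
})

test_that("one-hot rows reduce pair features to pair counts", {
  # rows one-hot at columns 1, 2, 1 -> R(1,2) = R(2,1) = 1, all else 0
  Q <- matrix(0, 3, 23)
  Q[1, 1] <- 1; Q[2, 2] <- 1; Q[3, 1] <- 1
  R <- kaap_single(Q, 1)$R
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 1], 1)
  expect_equal(sum(R), 2)
})

test_that("pair features match an independent triple-loop accumulation", {
  withr::local_seed(7)
  for (rep in 1:20) {
    L <- sample(2:50, 1)
    p <- rand_profile(L)
    Q <- build_Q(p)
    k <- sample(1:6, 1)
    got <- kaap_single(Q, k)
    want <- oracle_pair_matrix(Q, k)
    expect_equal(unname(got$R), want, tolerance = 1e-12)
    expect_equal(unname(got$flat), oracle_flatten(want), tolerance = 1e-12)
  }
})

test_that("total pair mass obeys the row-sum conservation identity", {
  withr::local_seed(8)
  for (rep in 1:20) {
    L <- sample(2:40, 1)
    p <- rand_profile(L)
    Q <- build_Q(p)
    for (k in 1:6) {
      flat <- kaap_single(Q, k)$flat
      direct <- if (L > k) {
        sum(rowSums(Q)[seq_len(L - k)] * rowSums(Q)[seq_len(L - k) + k])
      } else 0
      expect_equal(sum(flat), direct, tolerance = 1e-9)
      expect_equal(sum(flat), 4 * max(L - k, 0), tolerance = 1e-6)
      expect_true(all(flat >= 0))
    }
  }
})

test_that("permuting Q columns permutes the pair matrix on both axes", {
  withr::local_seed(9)
  for (rep in 1:10) {
    p <- rand_profile(sample(5:30, 1))
    Q <- build_Q(p)
    perm <- sample(23)
    R <- kaap_single(Q, 2)$R
    Rp <- kaap_single(Q[, perm], 2)$R
    expect_equal(unname(Rp), unname(R[perm, perm]), tolerance = 1e-12)
  }
})

test_that("the full feature vector concatenates separations in ascending order", {
  p <- rand_profile(12)
  Q <- build_Q(p)
  F <- kaap_full(Q)
  expect_length(F, 2116L)
  expect_length(kaap_full(Q, k_max = 1), 529L)
  expect_equal(unname(F[530:1058]), unname(kaap_single(Q, 2)$flat))
  expect_equal(unname(F[1:529]), unname(kaap_single(Q, 1)$flat))
  # deterministic: identical input, bitwise-identical output
  expect_identical(F, kaap_full(build_Q(p)))
})

test_that("consensus takes the per-row argmax with ties to the lowest index", {
  P <- matrix(0, 2, 20)
  P[1, 1] <- 1            # one-hot at A
  P[2, ] <- 1 / 20        # uniform: tie breaks to A
  prof <- protein_profile("c", "KK", P = P, S = matrix(1 / 3, 2, 3))
  expect_equal(consensus_sequence(prof), "AA")

  withr::local_seed(10)
  for (rep in 1:100) {
    p <- rand_profile(sample(2:30, 1))
    got <- strsplit(consensus_sequence(p), "")[[1]]
    want <- character(nrow(p$P))
    for (i in seq_len(nrow(p$P))) {
      best <- 1
      for (j in 2:20) if (p$P[i, j] > p$P[i, best]) best <- j
      want[i] <- aa_order()[best]
    }
    expect_equal(got, want)
  }
})

test_that("composition counts and normalizes in canonical order", {
  occ <- composition("AAR", normalize = FALSE)
  expect_equal(unname(occ[c("A", "R")]), c(2, 1))
  expect_equal(sum(occ), 3)
  aac <- composition("AAR", normalize = TRUE)
  expect_equal(unname(aac[c("A", "R")]), c(2 / 3, 1 / 3))
  expect_equal(sum(aac), 1)
  # non-standard letters are skipped before counting
  expect_equal(composition("AXAR", normalize = FALSE), occ)
  expect_error(composition("XXB"), "no standard", class = "kaapfold_input_error")

  withr::local_seed(12)
  s <- paste(sample(aa_order(), 200, replace = TRUE), collapse = "")
  counts <- composition(s, normalize = FALSE)
  letters_s <- strsplit(s, "")[[1]]
  for (a in aa_order()) expect_equal(unname(counts[a]), sum(letters_s == a))
})

test_that("sequence pair features count ordered pairs at the declared gap", {
  pf2 <- sequence_pair_features("ARA", gap = 0)
  expect_length(pf2, 400L)
  expect_equal(unname(pf2[c("g0_A_R", "g0_R_A")]), c(1, 1))
  expect_equal(sum(pf2), 2)

  pf1 <- sequence_pair_features("ARA", gap = 1)
  expect_equal(unname(pf1["g1_A_A"]), 1)
  expect_equal(sum(pf1), 1)

  expect_error(sequence_pair_features("AR", gap = 1), "too short",
               class = "kaapfold_input_error")
  expect_length(sequence_pf("ARAK"), 800L)

  withr::local_seed(13)
  s <- sample(aa_order(), 300, replace = TRUE)
  for (gap in 0:1) {
    got <- sequence_pair_features(paste(s, collapse = ""), gap = gap)
    tally <- matrix(0, 20, 20, dimnames = list(aa_order(), aa_order()))
    for (i in seq_len(300 - gap - 1)) {
      tally[s[i], s[i + gap + 1]] <- tally[s[i], s[i + gap + 1]] + 1
    }
    expect_equal(unname(got), as.vector(t(tally)))
  }
})

test_that("profile n-grams reduce to sequence statistics for one-hot profiles", {
  withr::local_seed(14)
  s <- sample(aa_order(), 40, replace = TRUE)
  P <- matrix(0, 40, 20)
  P[cbind(1:40, match(s, aa_order()))] <- 1
  prof <- protein_profile("oh", paste(s, collapse = ""), P = P,
                          S = matrix(1 / 3, 40, 3))
  mono <- pssm_ngram(prof, 1)
  expect_equal(unname(mono), unname(composition(consensus_sequence(prof), normalize = FALSE)))
  bi <- pssm_ngram(prof, 2)
  expect_equal(unname(bi),
               unname(sequence_pair_features(consensus_sequence(prof), gap = 0)))
})

test_that("the profile bi-gram is the evolutionary 20x20 block of the k = 1 pair features", {
  withr::local_seed(15)
  for (rep in 1:10) {
    p <- rand_profile(sample(3:30, 1))
    bi <- matrix(pssm_ngram(p, 2), 20, 20, byrow = TRUE)
    R <- kaap_single(build_Q(p), 1)$R
    expect_equal(unname(R[1:20, 1:20]), unname(bi), tolerance = 1e-12)
  }
})

test_that("extractors declare and produce their documented dimensionalities", {
  reg <- list_extractors()
  expect_setequal(reg$extractor,
                  c("kaap", "monogram", "bigram", "aac", "occurrence",
                    "pf1", "pf2", "pf"))
  expect_equal(reg$dimension[match(c("kaap", "pf", "aac", "bigram"), reg$extractor)],
               c(2116L, 800L, 20L, 400L))

  withr::local_seed(16)
  profs <- lapply(1:3, function(i) rand_profile(20, sprintf("p%d", i), label = "f"))
  for (i in seq_len(nrow(reg))) {
    tbl <- extract_features(profs, reg$extractor[i])
    expect_equal(nrow(tbl), 3L)
    expect_equal(ncol(tbl) - 2L, reg$dimension[i])
    expect_true(all(as.matrix(tbl[, -(1:2)]) >= 0))
  }
  expect_error(extract_features(profs, "acc_hxpzv"), "unknown extractor",
               class = "kaapfold_input_error")
  # consensus-based variant runs sequence extractors on the profile argmax
  cons <- extract_features(profs, "aac", use_consensus = TRUE)
  expect_equal(unname(as.matrix(cons[1, -(1:2)]))[1, ],
               unname(composition(consensus_sequence(profs[[1]]))))
})
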