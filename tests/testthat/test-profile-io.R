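# Parsing of the PSSM / secondary-structure dialects and profile assembly.

test_that("a well-formed PSSM parses with canonical shapes and values", {
  path <- tmpfile(".pssm")
  truth <- write_tiny_pssm(path)
  raw <- read_pssm(path)
  expect_s3_class(raw, "raw_pssm")
  expect_equal(dim(raw$log_odds), c(3L, 20L))
  expect_equal(dim(raw$percentages), c(3L, 20L))
  expect_equal(raw$residues, c("A", "R", "V"))
  expect_equal(unname(raw$percentages[1, ]), as.numeric(truth$percentages[1, ]))
  expect_equal(unname(raw$log_odds[1, ]), as.numeric(truth$log_odds[1, ]))
  expect_equal(raw$column_order, aa_order())
})

test_that("permuted PSSM header columns are re-ordered to canonical order", {
  path <- tmpfile(".pssm")
  perm <- rev(seq_len(20))
  write_tiny_pssm(path, perm = perm)
  raw <- read_pssm(path)
  # row 1 had 100% in the first *file* column, which under rev() is V
  expect_equal(unname(raw$percentages[1, ]), c(rep(0, 19), 100))
  expect_equal(colnames(raw$percentages)[1], "A")
  # log-odds row 1 was -9..10 in file order; canonical A is the last file col
  expect_equal(unname(raw$log_odds[1, ]), rev(seq(-9, 10)))
})

test_that("malformed PSSM inputs raise format errors naming the problem", {
  path <- tmpfile(".pssm")
  writeLines(c("no header here", "1 A 1 2 3"), path)
  expect_error(read_pssm(path), "header", class = "kaapfold_format_error")

  path2 <- tmpfile(".pssm")
  write_tiny_pssm(path2)
  lines <- readLines(path2)
  row1 <- grep("^    1 ", lines)[1]
  lines[row1] <- "    1 A    1   2   3"  # too few score fields
  writeLines(lines, path2)
  expect_error(read_pssm(path2), "row 1", class = "kaapfold_format_error")

  path3 <- tmpfile(".pssm")
  writeLines(c(
    "matrix",
    paste0(strrep(" ", 11), paste(sprintf("%4s", c(aa_order(), aa_order())), collapse = ""))
  ), path3)
  expect_error(read_pssm(path3), "no residue rows", class = "kaapfold_format_error")
})

test_that("secondary-structure rows are stored helix/strand/coil and renormalized", {
  path <- tmpfile(".sspm")
  writeLines(c(
    "# index AA SS P(C) P(H) P(E)",
    "1 A C 0.2 0.3 0.5",
    "2 R H 1.0 0.0 0.0"
  ), path)
  raw <- read_sspm(path)
  expect_equal(dim(raw$probs), c(2L, 3L))
  # file order coil, helix, strand -> internal H, E, C
  expect_equal(unname(raw$probs[1, ]), c(0.3, 0.5, 0.2))
  expect_equal(unname(raw$probs[2, ]), c(0, 0, 1))
  expect_equal(raw$predicted_state, c("E", "C"))
  expect_equal(raw$residues, c("A", "R"))

  # a row off by less than 1e-3 is renormalized to sum exactly 1
  path2 <- tmpfile(".sspm")
  writeLines("1 A C 0.2001 0.3 0.5", path2)
  raw2 <- read_sspm(path2)
  expect_equal(sum(raw2$probs), 1)

  # larger deviations and out-of-range entries are format errors
  path3 <- tmpfile(".sspm")
  writeLines("1 A C 0.3 0.3 0.5", path3)
  expect_error(read_sspm(path3), "summing", class = "kaapfold_format_error")
  path4 <- tmpfile(".sspm")
  writeLines("1 A C -0.2 0.7 0.5", path4)
  expect_error(read_sspm(path4), "outside", class = "kaapfold_format_error")
})

test_that("assemble_profile converts percentages and log-odds as specified", {
  path <- tmpfile(".pssm")
  write_tiny_pssm(path)
  raw_p <- read_pssm(path)
  path2 <- tmpfile(".sspm")
  writeLines(c("1 A C 0.2 0.3 0.5", "2 R H 1 0 0", "3 V E 0 0 1"), path2)
  raw_s <- read_sspm(path2)

  prof <- assemble_profile(raw_p, raw_s, mode = "percentage")
  expect_s3_class(prof, "protein_profile")
  # one-hot percentage row stays one-hot
  expect_equal(unname(prof$P[1, ]), c(1, rep(0, 19)))
  expect_equal(rowSums(prof$P), rep(1, 3), tolerance = 1e-12)
  expect_equal(prof$S, raw_s$probs)

  # logistic mode: all-zero log-odds row becomes uniform
  prof2 <- assemble_profile(raw_p, raw_s, mode = "logistic")
  expect_equal(unname(prof2$P[2, ]), rep(1 / 20, 20))
  # arbitrary integer row equals a scalar sigmoid loop, renormalized
  row <- raw_p$log_odds[1, ]
  manual <- numeric(20)
  for (j in 1:20) manual[j] <- 1 / (1 + exp(-row[j]))
  manual <- manual / sum(manual)
  expect_equal(unname(prof2$P[1, ]), unname(manual), tolerance = 1e-12)
})

test_that("assemble_profile rejects mismatched pairs", {
  path <- tmpfile(".pssm")
  write_tiny_pssm(path)
  raw_p <- read_pssm(path)
  short <- tmpfile(".sspm")
  writeLines(c("1 A C 0.2 0.3 0.5"), short)
  expect_error(assemble_profile(raw_p, read_sspm(short)), "lengths differ",
               class = "kaapfold_input_error")

  wrong <- tmpfile(".sspm")
  writeLines(c("1 G C 0.2 0.3 0.5", "2 G H 1 0 0", "3 G E 0 0 1"), wrong)
  expect_error(assemble_profile(raw_p, read_sspm(wrong)), "agree",
               class = "kaapfold_input_error")
})

test_that("profile assembly is row-stochastic for every mode on random inputs", {
  withr::local_seed(42)
  for (rep in 1:25) {
    L <- sample(2:30, 1)
    pc <- matrix(sample(0:100, L * 20, replace = TRUE), L, 20)
    pc[1, ] <- 0  # all-zero percentage rows occur in real PSSMs
    raw_p <- structure(list(
      protein_id = "x", residues = sample(aa_order(), L, replace = TRUE),
      log_odds = matrix(sample(-12:13, L * 20, replace = TRUE), L, 20),
      percentages = pc, column_order = aa_order()
    ), class = "raw_pssm")
    s <- matrix(stats::runif(L * 3), L, 3)
    raw_s <- structure(list(protein_id = "x", residues = raw_p$residues,
                            probs = s / rowSums(s)), class = "raw_sspm")
    for (mode in c("percentage", "logistic")) {
      prof <- assemble_profile(raw_p, raw_s, mode = mode)
      expect_equal(rowSums(prof$P), rep(1, L), tolerance = 1e-9)
      expect_equal(rowSums(prof$S), rep(1, L), tolerance = 1e-9)
      expect_true(all(prof$P >= 0 & prof$P <= 1))
    }
  }
})

test_that("manifests and FASTA sequences load as tibbles", {
  man <- tmpfile(".tsv")
  writeLines(c("# comment", "p1\tfoldA", "p2\tfoldB", "", "p3\tfoldA"), man)
  tab <- read_label_manifest(man)
  expect_equal(tab$protein_id, c("p1", "p2", "p3"))
  expect_equal(tab$label, c("foldA", "foldB", "foldA"))

  dup <- tmpfile(".tsv")
  writeLines(c("p1 a", "p1 b"), dup)
  expect_error(read_label_manifest(dup), "duplicated", class = "kaapfold_input_error")

  fa <- tmpfile(".fasta")
  writeLines(c(">p1", "ARNDC", ">p2", "GHIL", "KMF"), fa)
  seqs <- read_fasta_sequences(fa)
  expect_equal(seqs$protein_id, c("p1", "p2"))
  expect_equal(seqs$sequence, c("ARNDC", "GHILKMF"))
})
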