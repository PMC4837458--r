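pssm <- build_repeat_pssm(default_scaffold())

test_that("repeat PSSM construction matches its definition", {
  sc <- default_scaffold()
  expect_equal(dim(pssm), c(35L, 20L))
  # code slots are free: all-zero score columns
  expect_true(all(pssm[c(5, 35), ] == 0))
  # consensus residue attains the column maximum at every non-slot column
  cons <- strsplit(sc$template, "")[[1]]
  for (j in setdiff(1:35, c(5, 35))) {
    expect_equal(unname(pssm[j, cons[j]]), max(pssm[j, ]))
  }
  # scoring the scaffold against itself attains the maximum score
  self_score <- sum(vapply(1:35, function(j) pssm[j, cons[j]], numeric(1)))
  expect_equal(self_score, attr(pssm, "max_score"))
})

test_that("window scores equal the brute-force 35-term sum", {
  d <- design_dppr("UCAGUC")
  arr <- scan_protein(d$full_sequence, pssm)[[1]]
  chars <- strsplit(d$full_sequence, "")[[1]]
  for (k in seq_len(nrow(arr$hits))) {
    s <- arr$hits$start[k]
    brute <- sum(vapply(0:34, function(j) pssm[j + 1, chars[s + j]],
                        numeric(1)))
    expect_equal(arr$hits$score[k], brute)
  }
})

test_that("designed proteins are recovered as a single exact array", {
  d <- design_dppr("UUUUCCUUUU")
  arrays <- scan_protein(d$full_sequence, pssm)
  expect_length(arrays, 1L)
  hits <- arrays[[1]]$hits
  expect_equal(nrow(hits), 10L)
  expect_equal(diff(hits$start), rep(35L, 9))
  expect_equal(hits$start, d$repeats$start)
})

test_that("short sequences and shuffled designs yield no arrays", {
  expect_length(scan_protein(strrep("A", 20), pssm), 0L)
  d <- design_dppr("UUUUGGUUUU")
  set.seed(11)
  shuffled <- paste(sample(strsplit(d$full_sequence, "")[[1]]), collapse = "")
  expect_length(scan_protein(shuffled, pssm), 0L)
})

test_that("predicted targets follow the code table row by row", {
  d <- design_dppr("UUUUGGUUUU")
  arr <- scan_protein(d$full_sequence, pssm)[[1]]
  ppm <- predict_target(arr)
  expect_equal(nrow(ppm), 10L)
  expect_true(all(abs(rowSums(unclass(ppm)) - 1) < 1e-9))
  expect_equal(ppm_consensus(ppm), "UUUUGGUUUU")
  # a degenerate NN repeat shows up as a U/C tie
  d2 <- design_dppr("UUUU", codes = c("2" = "NN"))
  ppm2 <- predict_target(scan_protein(d2$full_sequence, pssm)[[1]])
  expect_equal(ppm_consensus(ppm2), "U[C/U]UU")
  expect_equal(unname(ppm2[2, "U"]), unname(ppm2[2, "C"]))
})

test_that("design -> scan -> predict round-trips random targets", {
  set.seed(301)
  for (r in 1:25) {
    tg <- random_rna(sample(2:30, 1))
    d <- design_dppr(tg)
    arrays <- scan_protein(d$full_sequence, pssm)
    expect_length(arrays, 1L)
    expect_equal(ppm_consensus(predict_target(arrays[[1]])), tg)
  }
})

test_that("transcript scanning recovers a planted site at rank 1", {
  target <- "UUUUCCUUUU"
  d <- design_dppr(target)
  ppm <- predict_target(scan_protein(d$full_sequence, pssm)[[1]])
  set.seed(17)
  tx <- strsplit(random_rna(1000), "")[[1]]
  tx[401:410] <- strsplit(target, "")[[1]]
  hits <- scan_transcripts(ppm, c(tx1 = paste(tx, collapse = "")), top_k = 5)
  expect_equal(hits$start[1], 401L)
  expect_equal(hits$site[1], target)
  # closed-form score of the argmax site under a uniform background
  expected <- sum(log2(apply(unclass(ppm), 1, max) / 0.25))
  expect_equal(hits$score[1], expected)
})

test_that("site score degrades monotonically with planted mutations", {
  target <- "UUUUCCUUUU"
  d <- design_dppr(target)
  ppm <- predict_target(scan_protein(d$full_sequence, pssm)[[1]])
  site <- strsplit(target, "")[[1]]
  set.seed(23)
  scores <- vapply(0:4, function(nmut) {
    s <- site
    if (nmut > 0) {
      pos <- sample(10, nmut)
      s[pos] <- vapply(s[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "U"), b), 1)
      }, character(1))
    }
    scan_transcripts(ppm, c(x = paste(s, collapse = "")), top_k = 1)$score[1]
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("transcript scan edge cases behave", {
  d <- design_dppr("UUUUCCUUUU")
  ppm <- predict_target(scan_protein(d$full_sequence, pssm)[[1]])
  expect_equal(nrow(scan_transcripts(ppm, c(a = strrep("U", 50)), top_k = 0)), 0L)
  expect_warning(
    hits <- scan_transcripts(ppm, c(short = "UUU", ok = strrep("U", 40))),
    "shorter than")
  expect_true(all(hits$transcript_id == "ok"))
  # empirical p-values: planted site in random background is significant,
  # and identical seeds give identical results
  set.seed(5)
  tx <- strsplit(random_rna(300), "")[[1]]
  tx[101:110] <- strsplit("UUUUCCUUUU", "")[[1]]
  txs <- c(t1 = paste(tx, collapse = ""))
  h1 <- scan_transcripts(ppm, txs, top_k = 1, null_shuffles = 100, seed = 9)
  h2 <- scan_transcripts(ppm, txs, top_k = 1, null_shuffles = 100, seed = 9)
  expect_identical(h1, h2)
  expect_lt(h1$p_empirical[1], 0.05)
})
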