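# PSSM parsing, MSA profiles, window encoding.

test_that("parse_psiblast_pssm round-trips the fixture writer", {
  fx <- gen_pssm_text(201, L = 7)
  p <- parse_psiblast_pssm(fx$text)
  expect_equal(unname(p$scores), fx$scores + 0)
  expect_equal(p$sequence, fx$sequence)
  # the 40-column body is present; only the log-odds block is captured
  expect_equal(ncol(p$scores), 20)
  # residue cross-check
  expect_error(parse_psiblast_pssm(fx$text, sequence = strrep("A", 7)),
               "do not match")
  expect_silent(parse_psiblast_pssm(fx$text, sequence = fx$sequence))
})

test_that("parse_psiblast_pssm rejects empty or ragged input", {
  expect_error(parse_psiblast_pssm(""), "no profile rows")
  fx <- gen_pssm_text(202, L = 4)
  ragged <- fx$text
  body <- grep("^\\s+1 ", ragged)
  ragged[body + 1] <- substr(ragged[body + 1], 1, 40)
  expect_error(parse_psiblast_pssm(ragged),
               "column counts|no profile rows|consecutively numbered")
})

test_that("profile_from_alignment matches the closed-form score", {
  # unanimity: score -> log2(20) as the prior washes out
  msa <- setNames(rep("AAAA", 50), paste0("s", 1:50))
  p <- profile_from_alignment(msa, pseudocount = 0.01)
  expect_equal(unname(p$scores[1, "A"]), log2(20), tolerance = 1e-3)
  expect_true(all(p$scores[, setdiff(aa_columns(), "A")] < -5))

  # exact closed form at small N
  msa2 <- c(m = "AC", x = "AC", y = "GC")
  p2 <- profile_from_alignment(msa2, pseudocount = 1)
  bg <- 1 / 20
  expect_equal(unname(p2$scores[1, "A"]),
               log2((2 + 1 * bg) / ((3 + 1) * bg)), tolerance = 1e-12)
  expect_equal(unname(p2$scores[1, "G"]),
               log2((1 + 1 * bg) / ((3 + 1) * bg)), tolerance = 1e-12)

  # prior-dominated limit: all scores -> 0
  p3 <- profile_from_alignment(c(only = "MKV"), pseudocount = 1e7)
  expect_true(all(abs(p3$scores) < 1e-5))

  # exchangeability: half A, half G scores equal
  msa4 <- c(m = "A", b = "A", c = "G", d = "G")
  p4 <- profile_from_alignment(msa4)
  expect_equal(unname(p4$scores[1, "A"]), unname(p4$scores[1, "G"]))
})

test_that("profile_from_alignment is row-order invariant and master-indexed", {
  set.seed(3)
  base <- replicate(6, paste(sample(c("A", "C", "G", "W", "-"), 12,
                                    replace = TRUE), collapse = ""))
  base[1] <- gsub("-", "A", base[1]) # ungapped master
  msa <- setNames(base, paste0("s", 1:6))
  p1 <- profile_from_alignment(msa)
  p2 <- profile_from_alignment(msa[c(1, 6, 3, 5, 2, 4)])
  expect_equal(p1$scores, p2$scores)
  expect_equal(nrow(p1$scores), 12)
  expect_error(profile_from_alignment(c(a = "ACD", b = "AC")), "ragged")
})

test_that("window_encode lays out w slots of 20 scores plus a spacer", {
  fx <- gen_pssm_text(203, L = 10)
  p <- parse_psiblast_pssm(fx$text)

  # terminal residue of a 1-mer: both flanks are spacer slots
  p1 <- parse_psiblast_pssm(gen_pssm_text(204, L = 1)$text)
  v <- window_encode(p1, 1, 3)
  expect_length(v, 63)
  expect_equal(v[21], 1) # left spacer
  expect_equal(v[63], 1) # right spacer
  expect_equal(v[42], 0) # center in-sequence
  expect_true(all(v[1:20] == 0) && all(v[43:62] == 0))

  # interior residue at w = 9: 189 values, no spacers
  v9 <- window_encode(p, 5, 9)
  expect_length(v9, 9 * 21)
  expect_equal(v9[21 * (1:9)], rep(0, 9))

  # center = 1, w = 5 on L = 10: slots -1 and 0 flagged, rest real rows
  v5 <- window_encode(p, 1, 5)
  expect_equal(v5[c(21, 42)], c(1, 1))
  for (k in 3:5)
    expect_equal(v5[(k - 1) * 21 + 1:20], unname(p$scores[k - 2, ]))

  # w = 1 on an interior residue is the profile row plus a 0 spacer
  expect_equal(window_encode(p, 4, 1), c(unname(p$scores[4, ]), 0))

  expect_error(window_encode(p, 3, 4), "odd")
  expect_error(window_encode(p, 11, 3), "outside")
})

test_that("encoding respects the translation property", {
  set.seed(17)
  for (r in 1:5) {
    L <- 30
    scores <- matrix(rnorm(L * 20), L, 20)
    prof <- structure(list(seq_id = "p", scores = scores, sequence = NULL),
                      class = "pl_profile")
    k <- sample(1:5, 1)
    shifted <- structure(
      list(seq_id = "p", scores = scores[c((k + 1):L, 1:k), ],
           sequence = NULL), class = "pl_profile")
    pos <- sample(8:(L - 12), 1)
    expect_equal(window_encode(prof, pos + k, 7),
                 window_encode(shifted, pos, 7))
  }
})

test_that("vectorize_dataset emits one scaled example per labeled position", {
  fx <- gen_pssm_text(205, L = 20)
  prof <- parse_psiblast_pssm(fx$text, seq_id = "s1")
  ls <- list(structure(list(seq_id = "s1", positives = 10L,
                            negatives = c(3L, 16L)), class = "pl_labelset"))
  ds <- vectorize_dataset(ls, list(s1 = prof), w = 3, scale = 10)
  expect_s3_class(ds, "pl_dataset")
  expect_equal(dim(ds$X), c(3, 63))
  expect_equal(sum(ds$y), 1)
  # deterministic (seq_id, position) order
  expect_equal(ds$meta$position, c(3L, 10L, 16L))
  # score entries divided by 10, spacer flags untouched
  expect_equal(ds$X[2, 1:20], unname(prof$scores[9, ]) / 10)
  edge <- vectorize_dataset(
    list(structure(list(seq_id = "s1", positives = 1L, negatives = integer(0)),
                   class = "pl_labelset")),
    list(s1 = prof), w = 3, scale = 10)
  expect_equal(edge$X[1, 21], 1) # left spacer survives scaling

  expect_equal(length(vectorize_dataset(list(), list(), w = 3)$y), 0)
  expect_error(vectorize_dataset(ls, list(), w = 3), "no profile")
})

test_that("every window vector has exactly w binary spacer flags", {
  fx <- gen_pssm_text(206, L = 12)
  p <- parse_psiblast_pssm(fx$text)
  for (w in seq(1, 11, 2)) for (center in c(1, 6, 12)) {
    v <- window_encode(p, center, w)
    flags <- v[21 * seq_len(w)]
    expect_true(all(flags %in% c(0, 1)))
    half <- (w - 1) / 2
    expect_equal(sum(flags), sum((center - half):(center + half) < 1 |
                                   (center - half):(center + half) > 12))
    for (k in which(flags == 1))
      expect_true(all(v[(k - 1) * 21 + 1:20] == 0))
  }
})
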