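test_that("position extraction matches the worked example and handles ambiguity", {
  pos <- extract_positions("ACTGGCAAT")
  expect_identical(pos$A, c(1L, 7L, 8L))
  expect_identical(pos$C, c(2L, 6L))
  expect_identical(pos$G, c(4L, 5L))
  expect_identical(pos$T, c(3L, 9L))
  expect_identical(attr(pos, "N"), 9L)

  homo <- extract_positions("AAAA")
  expect_identical(homo$A, 1:4)
  expect_identical(homo$C, integer(0))

  # ambiguous base occupies its position but joins no list
  amb <- extract_positions("ANGT")
  expect_identical(amb$A, 1L)
  expect_identical(amb$G, 3L)
  expect_identical(amb$T, 4L)
  expect_identical(amb$C, integer(0))
  expect_identical(attr(amb, "N"), 4L)

  # lowercase and RNA handling
  expect_identical(extract_positions("actu")$T, c(3L, 4L))
})

test_that("invalid sequences are rejected with the offending character named", {
  expect_error(extract_positions(""), "empty sequence", class = "pcnv_input_error")
  err <- tryCatch(extract_positions("ACXGT"), error = identity)
  expect_s3_class(err, "pcnv_input_error")
  expect_match(conditionMessage(err), "'X'")
  expect_match(conditionMessage(err), "position 3")
  expect_error(extract_positions("ANGT", strict = TRUE),
               class = "pcnv_input_error")
})

test_that("positional distribution reproduces the printed step functions", {
  # U_C row: 0, then 2/4 x4, then 6/4 x4
  expect_equal(positional_distribution(c(2L, 6L), 9L),
               c(0, rep(1 / 2, 4), rep(3 / 2, 4)))
  # U_A row: 1/6 x6, then 7/1, then 8/2 x2
  expect_equal(positional_distribution(c(1L, 7L, 8L), 9L),
               c(rep(1 / 6, 6), 7, 4, 4))
  expect_equal(positional_distribution(integer(0), 5L), rep(0, 5))
  # adjacent occurrences: blocks of width 1 give p_j itself
  expect_equal(positional_distribution(1:4, 4L), c(1, 2, 3, 4))
  # single-base sequence: p1 / (1 - (p1 - 1)) = 1
  expect_equal(positional_distribution(1L, 1L), 1)
})

test_that("block-sum identity holds: sum of U equals sum of positions", {
  set.seed(11)
  for (rep in 1:200) {
    N <- sample(1:150, 1)
    s <- random_test_seq(N)
    pos <- extract_positions(s)
    for (b in c("A", "C", "G", "T")) {
      u <- positional_distribution(pos[[b]], N)
      expect_equal(sum(u), sum(pos[[b]]), tolerance = 1e-9)
    }
  }
})

test_that("positional mean equals the mean occurrence position", {
  pos <- extract_positions("ACTGGCAAT")
  uA <- positional_distribution(pos$A, 9L)
  expect_equal(positional_mean(uA, 3L), 16 / 3, tolerance = 1e-12)
  expect_identical(positional_mean(numeric(9), 0L), 0)
  uAAAA <- positional_distribution(1:4, 4L)
  expect_equal(positional_mean(uAAAA, 4L), 2.5)
})

test_that("positional covariance matches the printed worked value and is symmetric", {
  pos <- extract_positions("ACTGGCAAT")
  uA <- positional_distribution(pos$A, 9L)
  uC <- positional_distribution(pos$C, 9L)
  cAC <- positional_covariance(uA, uC, 3L, 2L)
  expect_equal(round(cAC, 4), 1.4769)
  expect_identical(cAC, positional_covariance(uC, uA, 2L, 3L))
  expect_equal(cAC, oracle_cov(uA, uC, 3, 2), tolerance = 1e-12)
  expect_identical(positional_covariance(uA, numeric(9), 3L, 0L), 0)
  expect_error(positional_covariance(uA, numeric(5), 3L, 2L),
               class = "pcnv_input_error")
})

test_that("positional variance is cov(alpha, alpha) and nonnegative", {
  pos <- extract_positions("ACTGGCAAT")
  uA <- positional_distribution(pos$A, 9L)
  expect_identical(positional_variance(uA, 3L),
                   positional_covariance(uA, uA, 3L, 3L))
  expect_equal(positional_variance(uA, 3L), 949 / 162, tolerance = 1e-12)
  expect_identical(positional_variance(numeric(4), 0L), 0)
})

test_that("the assembled 18-vector has the fixed layout and worked values", {
  v <- compute_pcnv("ACTGGCAAT", id = "s1")
  expect_length(v, 18L)
  expect_identical(names(v), pcnv_components())
  expect_identical(unname(v[1:4]), c(3, 2, 2, 2))
  expect_equal(unname(v["covAC"]), 1.4769, tolerance = 5e-5)
  expect_identical(attr(v, "source_id"), "s1")
  expect_identical(attr(v, "source_length"), 9L)

  vh <- compute_pcnv("AAAA")
  expect_equal(as.numeric(vh),
               c(4, 0, 0, 0, 2.5, 0, 0, 0, 0.3125, 0, 0, 0, rep(0, 6)))
})

test_that("pcnv agrees with the literal-transcription oracle on random sequences", {
  set.seed(97)
  for (rep in 1:150) {
    s <- random_test_seq(sample(1:200, 1))
    expect_equal(as.numeric(compute_pcnv(s)), oracle_pcnv(s), tolerance = 1e-9)
  }
  # sequences with ambiguity codes: present-base positions unchanged
  for (rep in 1:25) {
    s <- random_test_seq(sample(2:100, 1), ambiguous = TRUE)
    expect_equal(as.numeric(compute_pcnv(s)), oracle_pcnv(s), tolerance = 1e-9)
  }
})

test_that("counts are conserved and variances nonnegative on random input", {
  set.seed(31)
  for (rep in 1:100) {
    N <- sample(1:200, 1)
    v <- compute_pcnv(random_test_seq(N))
    expect_identical(sum(v[1:4]), as.numeric(N))
    expect_true(all(v[9:12] >= 0))
  }
})

test_that("pcnv matrices carry ids and one row per sequence", {
  seqs <- c(s1 = "ACTGGCAAT", s2 = "AAAA", s3 = "GGGTTTCCC")
  m <- compute_pcnv_matrix(seqs)
  expect_identical(dim(m), c(3L, 18L))
  expect_identical(rownames(m), names(seqs))
  expect_equal(m["s1", ], compute_pcnv("ACTGGCAAT"),
               ignore_attr = TRUE)
  expect_error(compute_pcnv_matrix(unname(seqs)), class = "pcnv_input_error")
})
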