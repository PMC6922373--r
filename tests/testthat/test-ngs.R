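test_that("alignment parameter invariants are enforced", {
  expect_s3_class(alignment_params(), "alignment_params")
  expect_error(alignment_params(gap_open = -1, gap_extend = -8))
  expect_error(alignment_params(gap_extend = 1))
  expect_error(alignment_params(match = -1))
})

test_that("identity and single-indel reads align as expected", {
  ref <- fix$ref
  rd <- substr(ref$sequence, 101, 250)
  a <- align_read(rd, ref)
  expect_equal(a$score, 2L * 150L)
  expect_equal(a$ref_start, 100L)
  expect_equal(unique(strsplit(a$ops, "")[[1]]), "M")

  # internal 4-base deletion merges into one contiguous affine gap
  del4 <- apply_indel(ref, -4L)
  a2 <- align_read(substr(del4$sequence, 201, 350), ref)
  r <- rle(strsplit(a2$ops, "")[[1]])
  expect_equal(sum(r$values == "D"), 1L)
  expect_equal(r$lengths[r$values == "D"], 4L)
  expect_equal(alignment_net_indel(a2, 240, 260), -4L)

  # single-base read lands on a best-scoring position
  a3 <- align_read("A", ref)
  expect_equal(a3$score, 2L)
  expect_equal(a3$ops, "M")
})

test_that("alignment matches exhaustive enumeration on short sequences", {
  set.seed(99)
  cases <- list(
    c("ACGT", "AACGTT"), c("TTTT", "TATATATA"), c("GATTACA", "GATCA"),
    c("CCGG", "CCAAGG"), c("ACACAC", "ACAC"))
  for (i in 1:10) {
    n <- sample(3:7, 1); m <- sample(n:12, 1)
    cases[[length(cases) + 1]] <-
      c(paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
        paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = ""))
  }
  for (cs in cases) {
    a <- align_read(cs[1], cs[2])
    expect_equal(a$score, enumerate_best_score(cs[1], cs[2]),
                 info = paste(cs, collapse = " vs "))
    expect_equal(score_alignment(cs[1], cs[2], a), a$score,
                 info = paste(cs, collapse = " vs "))
  }
})

test_that("alignment scores agree with Biostrings under the same affine scoring", {
  skip_if_not_installed("Biostrings")
  pars <- alignment_params()
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = pars$match,
                                                  mismatch = pars$mismatch)
  for (i in 1:8) {
    al <- fix$pool[[sample(length(fix$pool), 1)]]
    rd <- substr(al$sequence, 180, 330)
    if (i > 4) { # inject two mismatches
      v <- strsplit(rd, "")[[1]]
      v[c(30, 90)] <- c("A", "C")
      rd <- paste(v, collapse = "")
    }
    ours <- align_read(rd, fix$ref)
    # Biostrings gap of length L costs gapOpening + L * gapExtension
    bs <- Biostrings::pairwiseAlignment(
      rd, fix$ref$sequence, type = "global-local", substitutionMatrix = mat,
      gapOpening = -(pars$gap_open - pars$gap_extend),
      gapExtension = -pars$gap_extend)
    expect_equal(ours$score, Biostrings::score(bs))
  }
})

test_that("read quantification recovers single alleles and mixtures", {
  del7 <- allele_by_size(-7L)
  rs <- simulate_reads(mixture(list(del7), 1), fix$ref, n_reads = 400, seed = 3)
  q <- quantify_reads(rs, fix$ref)
  expect_equal(q$table$indel_size, -7L)
  expect_equal(q$table$frequency, 100)
  expect_equal(q$efficiency, 100)
  expect_equal(q$n_discarded, 0L)

  m <- mixture(list(allele_by_size(0L), allele_by_size(1L)), c(0.5, 0.5))
  rs <- simulate_reads(m, fix$ref, n_reads = 4000, seed = 5)
  q2 <- quantify_reads(rs, fix$ref)
  sd3pp <- 3 * sqrt(0.25 / 4000) * 100
  expect_equal(q2$table$frequency[q2$table$indel_size == 1L], 50,
               tolerance = sd3pp)
})

test_that("the mean-phred filter discards low-quality reads before counting", {
  m <- mixture(list(allele_by_size(-7L)), 1)
  rs <- simulate_reads(m, fix$ref, n_reads = 600, low_quality_fraction = 0.5,
                       seed = 11)
  n_low <- sum(vapply(rs$qualities, mean, 0) < 30)
  q <- quantify_reads(rs, fix$ref)
  expect_equal(q$n_discarded, n_low)
  expect_equal(q$n_used, 600L - n_low)
  expect_equal(q$table$frequency, 100)
  all_low <- read_set(rs$sequences, lapply(rs$qualities, function(x) rep(10L, length(x))))
  expect_error(quantify_reads(all_low, fix$ref), "no reads pass")
})

test_that("quantification is invariant to read order and duplication", {
  m <- mixture(list(allele_by_size(0L), allele_by_size(-2L)), c(0.3, 0.7))
  rs <- simulate_reads(m, fix$ref, n_reads = 500, seed = 13)
  q <- quantify_reads(rs, fix$ref)
  perm <- sample(length(rs))
  q_perm <- quantify_reads(read_set(rs$sequences[perm], rs$qualities[perm]),
                           fix$ref)
  expect_equal(q_perm$table, q$table)
  dup <- read_set(c(rs$sequences, rs$sequences), c(rs$qualities, rs$qualities))
  expect_equal(quantify_reads(dup, fix$ref)$table, q$table)
})

test_that("batch net-indel calls equal per-read alignment plus windowing", {
  m <- mixture(list(allele_by_size(0L), allele_by_size(-7L), allele_by_size(2L)),
               c(0.4, 0.3, 0.3))
  rs <- simulate_reads(m, fix$ref, n_reads = 60, error_rate = 0.01, seed = 17)
  cut <- fix$ref$cut_site
  per_read <- vapply(rs$sequences, function(r)
    alignment_net_indel(align_read(r, fix$ref), cut - 10, cut + 10), 0L)
  q <- quantify_reads(rs, fix$ref)
  tab <- table(factor(per_read, levels = sort(unique(per_read))))
  got <- setNames(q$table$frequency, q$table$indel_size)
  want <- 100 * as.numeric(tab) / sum(tab)
  expect_equal(unname(got[names(tab)]), want)
})

test_that("deviation report computes MAD, missed and spurious variants", {
  identical_t <- data.frame(indel_size = c(-7L, -2L), frequency = c(50, 50))
  cmp <- compare_to_decomposition(identical_t, identical_t)
  expect_equal(cmp$mad, 0)
  expect_length(cmp$missed, 0L)
  expect_length(cmp$spurious, 0L)

  ngs <- data.frame(indel_size = c(-7L, -2L), frequency = c(50, 50))
  dec <- data.frame(indel_size = c(-7L, -2L), frequency = c(55, 45))
  expect_equal(compare_to_decomposition(ngs, dec)$mad, 5)

  ngs2 <- data.frame(indel_size = -7L, frequency = 100)
  dec2 <- data.frame(indel_size = c(-7L, 0L), frequency = c(90, 10))
  out <- compare_to_decomposition(ngs2, dec2)
  expect_equal(out$spurious, 0L)     # spurious wild-type call flagged
  expect_length(out$missed, 0L)
})
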