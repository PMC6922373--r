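test_that("registration recovers identity and constructed shifts", {
  ctrl <- wt_trace(trace_noise_model(seed = 4))
  expect_equal(as.integer(align_control(ctrl, ctrl)), 0L)
  # control prepended with 3 baseline positions: sample p matches control p+3
  pre <- chromatogram(rbind(matrix(1, 3, 4), ctrl$channels))
  expect_equal(as.integer(align_control(ctrl, pre)), 3L)
  expect_gt(attr(align_control(ctrl, pre), "correlation"), 0.9)
})

test_that("registration fails on an unrelated trace", {
  ctrl <- wt_trace(trace_noise_model(seed = 4))
  set.seed(31)
  other <- chromatogram(ctrl$channels[sample(length(ctrl)), ])
  expect_error(align_control(ctrl, other), "registration failure")
})

test_that("components are the control shifted by the indel size, with insertion masks", {
  ctrl <- wt_trace()
  cut <- fix$ref$cut_site
  cmp <- build_components(ctrl, cut)
  sizes <- vapply(cmp$components, `[[`, 0L, "indel_size")
  expect_equal(range(sizes), c(-30L, 30L))
  expect_equal(cmp$positions, 250:499)
  d0 <- cmp$components[[match(0L, sizes)]]
  expect_identical(d0$profile, ctrl$channels[cmp$positions + 1L, ])
  d2 <- cmp$components[[match(-2L, sizes)]]
  expect_identical(d2$profile, ctrl$channels[cmp$positions + 3L, ])
  i3 <- cmp$components[[match(3L, sizes)]]
  expect_identical(i3$profile, ctrl$channels[cmp$positions - 3L + 1L, ])
  expect_identical(i3$masked_positions, cut + 0:2)
  expect_length(d2$masked_positions, 0L)
  short <- chromatogram(ctrl$channels[1:400, ])
  expect_error(build_components(short, cut), "past the shifted control")
})

test_that("a pure wild-type sample decomposes to 100% WT with perfect fit", {
  ctrl <- wt_trace()
  res <- decompose(ctrl, ctrl, fix$ref)
  expect_equal(res$status, "ok")
  expect_equal(res$r_squared, 1, tolerance = 1e-6)
  expect_equal(res$variants$indel_size, 0L)
  expect_equal(res$variants$frequency, 100)
  expect_equal(res$efficiency, 0)
  expect_equal(overall_efficiency(res), 0)
})

test_that("noiseless two-allele mixtures match the grid-search oracle", {
  ctrl <- wt_trace()
  for (case in list(c(-7, 0.5), c(-2, 0.25), c(1, 0.8))) {
    d <- as.integer(case[1]); p <- case[2]
    m <- mixture(list(allele_by_size(0L), allele_by_size(d)), c(1 - p, p))
    tr <- simulate_trace(m, fix$ref, noiseless())
    res <- decompose(tr, ctrl, fix$ref)
    oracle <- grid_oracle(tr, wt_trace(), c(0L, d))
    got <- setNames(res$variants$frequency, res$variants$indel_size)
    expect_equal(unname(got[as.character(d)]), unname(oracle[as.character(d)]),
                 tolerance = 0.5)
    expect_equal(unname(got[as.character(d)]), 100 * p, tolerance = 0.5)
  }
})

test_that("frequencies are non-negative and sum to 100 across noisy wells", {
  ctrl <- wt_trace(trace_noise_model(seed = 8))
  for (s in 1:10) {
    w <- simulate_well(sample(c("homozygous", "compound_het", "nonclonal"), 1),
                       fix$pool, fix$ref, seed = 400 + s)
    res <- decompose(w$trace, ctrl, fix$ref)
    expect_true(all(res$variants$frequency >= 0))
    expect_equal(sum(res$variants$frequency), 100, tolerance = 0.1)
  }
})

test_that("decomposition against a shuffled control is eliminated by the fit filter", {
  ctrl <- wt_trace(trace_noise_model(seed = 8))
  set.seed(77)
  shuf <- chromatogram(ctrl$channels[sample(length(ctrl)), ])
  w <- simulate_well("compound_het", fix$pool, fix$ref, seed = 21)
  res <- decompose(w$trace, shuf, fix$ref)
  expect_false(res$registration_ok)
  expect_equal(res$status, "eliminated_low_fit")
  expect_lt(res$r_squared, 0.95)
  expect_error(overall_efficiency(res), "unavailable|eliminated")
})

test_that("decomposition is equivariant to a known registration shift", {
  ctrl <- wt_trace(trace_noise_model(seed = 8))
  m <- mixture(list(allele_by_size(0L), allele_by_size(-7L)), c(0.4, 0.6))
  tr <- simulate_trace(m, fix$ref, trace_noise_model(seed = 12))
  base <- decompose(tr, ctrl, fix$ref)
  # prepend 4 baseline positions to the sample: offset -4 must be absorbed
  shifted <- chromatogram(rbind(matrix(1e-3, 4, 4), tr$channels))
  res <- decompose(shifted, ctrl, fix$ref)
  expect_equal(res$offset, -4L)
  got <- setNames(res$variants$frequency, res$variants$indel_size)
  want <- setNames(base$variants$frequency, base$variants$indel_size)
  shared <- intersect(names(got), names(want))
  expect_gte(length(shared), 2L)
  expect_equal(got[shared], want[shared], tolerance = 1.5)
})

test_that("degenerate inputs raise explicit errors", {
  ctrl <- wt_trace()
  zero <- chromatogram(matrix(0, 560, 4))
  expect_error(decompose(zero, ctrl, fix$ref), "degenerate|zero")
  expect_error(decompose(ctrl, zero, fix$ref), "degenerate|zero")
})

test_that("efficiency is 100 minus the wild-type frequency", {
  mk <- function(sizes, freqs) {
    structure(list(variants = data.frame(indel_size = sizes, frequency = freqs,
                                         p_value = 0),
                   r_squared = 0.99, status = "ok",
                   efficiency = 100 - ifelse(0 %in% sizes,
                                             freqs[sizes == 0], 0),
                   offset = 0L, registration_ok = TRUE,
                   settings = decomposition_settings()),
              class = "decomposition_result")
  }
  expect_equal(overall_efficiency(mk(0L, 100)), 0)
  expect_equal(overall_efficiency(mk(c(0L, -7L), c(25, 75))), 75)
  expect_equal(overall_efficiency(mk(-7L, 100)), 100)
})
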