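mk_result <- function(sizes, freqs, status = "ok", r2 = 0.99) {
  structure(list(variants = data.frame(indel_size = as.integer(sizes),
                                       frequency = freqs,
                                       p_value = rep(1e-9, length(sizes))),
                 r_squared = r2, status = status,
                 efficiency = 100 - ifelse(0 %in% sizes, freqs[sizes == 0], 0),
                 offset = 0L, registration_ok = TRUE,
                 settings = decomposition_settings()),
            class = "decomposition_result")
}

test_that("triage verdicts follow the screening flow chart rules", {
  expect_equal(classify_well(mk_result(-7, 100))$verdict, "retain_homozygous")
  expect_equal(classify_well(mk_result(c(0, -2), c(48, 52)))$verdict,
               "discard_wildtype")
  expect_equal(classify_well(mk_result(c(-1, -4, 1), c(30, 35, 35)))$verdict,
               "discard_nonclonal")
  expect_equal(classify_well(mk_result(c(-7, 1), c(80, 20)))$verdict,
               "discard_nonclonal")   # outside the 50 +/- 15 band
  expect_equal(classify_well(mk_result(c(-7, 1), c(55, 45)))$verdict,
               "retain_compound_het")
  expect_equal(classify_well(mk_result(c(-7, 1, -12), c(50, 46, 4)))$verdict,
               "retain_compound_het") # 4% variant ignored by min_variant_freq
  expect_equal(classify_well(mk_result(-7, 100, status = "eliminated_low_fit",
                                       r2 = 0.8))$verdict, "indeterminate")
  # single variant below the homozygous band
  expect_equal(classify_well(mk_result(-7, 100 - 20))$verdict,
               "discard_nonclonal")
})

test_that("triage is pure: variant order and duplicated wells never change verdicts", {
  res <- mk_result(c(-7, 1), c(55, 45))
  shuffled <- res
  shuffled$variants <- res$variants[2:1, ]
  expect_equal(classify_well(shuffled)$verdict, classify_well(res)$verdict)
  plate <- screen_plate(list(a1 = res, a2 = res))
  expect_equal(plate$wells$verdict[1], plate$wells$verdict[2])
})

test_that("triage settings move the decision boundaries", {
  res <- mk_result(c(-1, -4, 1), c(30, 35, 35))
  expect_equal(classify_well(res, triage_settings(max_variants = 3))$verdict,
               "discard_nonclonal")  # 3 variants allowed but not 33:33:33
  strict <- triage_settings(het_tolerance = 4)
  expect_equal(classify_well(mk_result(c(-7, 1), c(55, 45)), strict)$verdict,
               "discard_nonclonal")
})

test_that("a four-class noiseless plate is screened end to end", {
  nl <- noiseless()
  ctrl <- wt_trace()
  wells <- list(
    h1 = simulate_well("homozygous", fix$pool, fix$ref, nl, seed = 1),
    c1 = simulate_well("compound_het", fix$pool, fix$ref, nl, jitter_sd = 0, seed = 2),
    w1 = simulate_well("het_with_wt", fix$pool, fix$ref, nl, jitter_sd = 0, seed = 3),
    n1 = simulate_well("nonclonal", fix$pool, fix$ref, nl, seed = 4))
  out <- run_screen(lapply(wells, `[[`, "trace"), ctrl, fix$ref)
  verdicts <- setNames(out$plate$wells$verdict, out$plate$wells$well)
  expect_equal(unname(verdicts[c("h1", "c1", "w1", "n1")]),
               c("retain_homozygous", "retain_compound_het",
                 "discard_wildtype", "discard_nonclonal"))
  expect_true(all(out$plate$wells$confirm_by_imaging ==
                  grepl("^retain", out$plate$wells$verdict)))
  expect_error(screen_plate(list()), "empty")
  expect_error(screen_plate(setNames(list(mk_result(-7, 100)), "")), "named")
})

test_that("frameshift classification is modular arithmetic about zero", {
  expect_equal(frameshift_class(c(-3L, 1L, 0L, -7L, 6L, -1L)),
               c("in_frame", "frameshift", "wild_type", "frameshift",
                 "in_frame", "frameshift"))
})

test_that("spectrum aggregation pools mutant mass and renormalizes", {
  one <- data.frame(indel_size = -2L, frequency = 100)
  sp <- aggregate_spectrum(list(one))
  expect_equal(unname(sp$deletion_freq["2"]), 100)
  expect_equal(sp$frameshift_fraction, 100)

  two <- aggregate_spectrum(list(data.frame(indel_size = -2L, frequency = 100),
                                 data.frame(indel_size = 1L, frequency = 100)))
  expect_equal(unname(two$deletion_freq["2"]), 50)
  expect_equal(unname(two$insertion_freq["1"]), 50)

  with_wt <- aggregate_spectrum(list(data.frame(indel_size = c(0L, -2L),
                                                frequency = c(40, 60))))
  expect_equal(unname(with_wt$deletion_freq["2"]), 100)

  big <- aggregate_spectrum(list(data.frame(indel_size = c(-20L, -3L),
                                            frequency = c(25, 75))))
  expect_equal(big$other_freq, 25)
  expect_equal(big$frameshift_fraction, 25)  # -20 shifts frame, -3 does not

  # conservation across bins
  set.seed(3)
  tabs <- lapply(1:5, function(i) {
    s <- sample(c(-18:-1, 1:18), 4)
    f <- runif(4); data.frame(indel_size = s, frequency = 100 * f / sum(f))
  })
  spc <- aggregate_spectrum(tabs)
  expect_equal(sum(spc$deletion_freq) + sum(spc$insertion_freq) + spc$other_freq,
               100, tolerance = 0.1)
  expect_error(aggregate_spectrum(list(data.frame(indel_size = 0L, frequency = 100))),
               "wild type")
})

test_that("identical replicate groups yield no significant spectrum bins", {
  probs <- setNames(c(.4, .3, .2, .1), c(-2, -1, 1, -7))
  set.seed(21)
  a <- lapply(1:4, function(i) aggregate_spectrum(list(sim_replicate_table(probs))))
  cmpr <- compare_spectra(a, a)
  expect_true(all(cmpr$difference == 0))
  expect_true(all(!cmpr$significant))
  expect_error(compare_spectra(a[1], a), ">= 2 replicate")
})

test_that("spectra with displaced mass are detected where they differ", {
  # short-deletion-heavy profile vs long-deletion-heavy profile
  pa <- setNames(c(.5, .3, .2), c(-1, -2, -3))
  pb <- setNames(c(.5, .3, .2), c(-8, -10, -14))
  set.seed(8)
  reps_a <- lapply(1:4, function(i) aggregate_spectrum(list(sim_replicate_table(pa))))
  reps_b <- lapply(1:4, function(i) aggregate_spectrum(list(sim_replicate_table(pb))))
  out <- compare_spectra(reps_a, reps_b)
  hot <- out$bin[out$significant]
  expect_true(all(c("del1", "del8") %in% hot))
  cold <- out$bin[abs(out$difference) < 1]
  expect_false(any(cold %in% hot))
})

test_that("T7 densitometry converts cut fractions by the closed form", {
  expect_equal(t7_indel_fraction(1000, 0, 0), 0)
  expect_equal(t7_indel_fraction(640, 200, 160), 100 * (1 - sqrt(0.64)))
  expect_equal(t7_indel_fraction(0, 50, 50), 100)
  expect_error(t7_indel_fraction(0, 0, 0), "zero")
  # monotone in the cut fraction, bounded in [0, 100]
  f <- seq(0, 1, length.out = 101)
  est <- vapply(f, function(fc) t7_indel_fraction(1 - fc, fc / 2, fc / 2), 0)
  expect_true(all(diff(est) >= 0))
  expect_true(all(est >= 0 & est <= 100))
})
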