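#' Packaged synthetic reference amplicon
#'
#' A 560 bp synthetic amplicon embedding the glutamine-synthetase screening
#' primer pair and the guide `GCCATACCAACTTTAGCACC`, with the Cas9 cut at
#' inter-base coordinate 250. The flanking filler sequence is seeded random
#' (the real locus sequence is not redistributed); it stands in for the
#' wild-type amplicon in examples, tests and simulations.
#'
#' @return A [reference_amplicon()].
#' @export
synthetic_reference <- function() {
  fa <- system.file("extdata", "synthetic_gs_amplicon.fa",
                    package = "sangerscreen", mustWork = TRUE)
  read_reference(fa, guide = "GCCATACCAACTTTAGCACC")
}

#' Example allele pool for well simulation
#'
#' Wild type plus a panel of short deletions and insertions around the cut
#' site (the size range single-cut editing produces); insertion bases are
#' drawn at the given seed and recorded in each allele.
#'
#' @param reference A [reference_amplicon()].
#' @param seed Seed for the inserted bases.
#' @return List of alleles (first element wild type).
#' @export
example_allele_pool <- function(reference = synthetic_reference(), seed = 42L) {
  set.seed(seed)
  sizes <- c(0L, -1L, -2L, -4L, -5L, -7L, -9L, -12L, -14L, 1L, 2L, 3L, 5L)
  lapply(sizes, function(d) {
    ins <- if (d > 0L) paste(sample(BASES, d, replace = TRUE), collapse = "") else ""
    apply_indel(reference, d, ins)
  })
}

derive_seed <- function(seed, k, tag = 0L) {
  as.integer((as.numeric(seed) * 7919 + k * 104729 + tag * 31) %% 2147483629)
}

#' Decompose and triage a plate of sample traces
#'
#' End-to-end screening: every sample trace is decomposed against the
#' control and the resulting variant tables are triaged into
#' retain/discard verdicts. Deterministic given its inputs.
#'
#' @param samples Named list of sample [chromatogram()]s, or a named
#'   character vector of tabular trace file paths.
#' @param control Control (wild-type) [chromatogram()] or trace file path.
#' @param reference The [reference_amplicon()].
#' @param decomposition A [decomposition_settings()].
#' @param triage A [triage_settings()].
#' @param output_dir Optional directory: writes `plate_report.tsv` plus a
#'   per-well `<well>_variants.tsv`.
#' @return List: `plate` ([screen_plate()] report), `decompositions`
#'   (named list of [decompose()] results).
#' @export
run_screen <- function(samples, control, reference,
                       decomposition = decomposition_settings(),
                       triage = triage_settings(), output_dir = NULL) {
  if (is.character(samples)) {
    nm <- if (!is.null(names(samples))) names(samples)
          else sub("\\.tsv$", "", basename(samples))
    missing <- samples[!file.exists(samples)]
    if (length(missing)) stop("sample trace not found: ", missing[1L], call. = FALSE)
    samples <- setNames(lapply(samples, read_trace), nm)
  }
  if (is.character(control)) {
    if (!file.exists(control)) stop("control trace not found: ", control,
                                    call. = FALSE)
    control <- read_trace(control)
  }
  if (length(samples) == 0L) stop("empty plate", call. = FALSE)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be named by well id", call. = FALSE)
  decomps <- lapply(names(samples), function(id) {
    tryCatch(decompose(samples[[id]], control, reference, decomposition),
             error = function(e) stop("well '", id, "', stage decompose: ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(decomps) <- names(samples)
  plate <- screen_plate(decomps, triage)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(plate$wells, file.path(output_dir, "plate_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (id in names(decomps))
      utils::write.table(variant_table(decomps[[id]]),
                         file.path(output_dir, paste0(id, "_variants.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(plate = plate, decompositions = decomps)
}

#' Mixing-series sensitivity experiment
#'
#' Stepwise equal-parts mixtures Mix-1 .. Mix-n of homozygous clones are
#' rendered as noisy traces and decomposed; the report records, for every
#' constituent of every mix, whether it was detected (reported with
#' p below the significance cutoff) and the estimated vs expected
#' proportion.
#'
#' @param clones List of mutant alleles (default: five distinct deletions /
#'   insertions from [example_allele_pool()]).
#' @param reference The [reference_amplicon()].
#' @param noise A [trace_noise_model()].
#' @param settings A [decomposition_settings()].
#' @param seed Integer seed (noise substreams are derived from it).
#' @return List: `detection` (data.frame of `mix`, `indel_size`,
#'   `expected`, `estimated`, `p_value`, `detected`), `results` (list of
#'   decomposition results per mix).
#' @export
run_mixing_experiment <- function(clones = NULL, reference = synthetic_reference(),
                                  noise = trace_noise_model(),
                                  settings = decomposition_settings(),
                                  seed = 1L) {
  if (is.null(clones)) {
    pool <- example_allele_pool(reference)
    sizes <- vapply(pool, `[[`, 0L, "indel_size")
    clones <- pool[match(c(-7L, -2L, -1L, 1L, -14L), sizes)]
  }
  mixes <- mixing_series(clones)
  ctrl_noise <- noise; ctrl_noise$seed <- derive_seed(seed, 0L, 1L)
  control <- simulate_trace(mixture(list(apply_indel(reference, 0L)), 1),
                            reference, ctrl_noise)
  rows <- list(); results <- list()
  for (k in seq_along(mixes)) {
    nk <- noise; nk$seed <- derive_seed(seed, k, 2L)
    trace <- simulate_trace(mixes[[k]], reference, nk)
    res <- decompose(trace, control, reference, settings)
    results[[paste0("mix", k)]] <- res
    truth <- indel_sizes(mixes[[k]])
    for (i in seq_along(truth)) {
      hit <- res$variants[res$variants$indel_size == truth[i], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        mix = k, indel_size = truth[i], expected = 100 / k,
        estimated = if (nrow(hit)) hit$frequency else 0,
        p_value = if (nrow(hit)) hit$p_value else NA_real_,
        detected = nrow(hit) > 0L &&
          hit$p_value < settings$p_cutoff)
    }
  }
  list(detection = do.call(rbind, rows), results = results)
}

#' Decomposition-vs-read-oracle validation on compound heterozygous clones
#'
#' Simulates `n_clones` compound-heterozygous clones (two distinct mutant
#' alleles at 50:50, sizes drawn from 1--15 bp deletions and insertions),
#' renders each as a noisy trace plus a deep error-free read set, runs both
#' quantifications, and reports the absolute frequency deviation at each
#' clone's true mutant alleles along with the overall mean absolute
#' deviation (percentage points).
#'
#' @param n_clones Number of clones.
#' @param reference The [reference_amplicon()].
#' @param noise A [trace_noise_model()].
#' @param n_reads Reads per clone.
#' @param settings A [decomposition_settings()].
#' @param align A [alignment_params()].
#' @param seed Integer seed.
#' @return List: `per_clone` (data.frame of `clone`, `indel_size`,
#'   `true_percent`, `decomposition`, `reads`, `deviation`), `mad` (mean
#'   absolute deviation over all mutant alleles, pp).
#' @export
run_clone_validation <- function(n_clones = 13L, reference = synthetic_reference(),
                                 noise = trace_noise_model(), n_reads = 10000L,
                                 settings = decomposition_settings(),
                                 align = alignment_params(), seed = 1L) {
  stopifnot(n_clones >= 1L)
  sizes_pool <- c(-(1:15), 1:15)
  ctrl_noise <- noise; ctrl_noise$seed <- derive_seed(seed, 0L, 3L)
  control <- simulate_trace(mixture(list(apply_indel(reference, 0L)), 1),
                            reference, ctrl_noise)
  rows <- list()
  for (k in seq_len(n_clones)) {
    set.seed(derive_seed(seed, k, 4L))
    d <- sample(sizes_pool, 2L)
    alleles <- lapply(d, function(s) {
      ins <- if (s > 0L) paste(sample(BASES, s, replace = TRUE), collapse = "") else ""
      apply_indel(reference, s, ins)
    })
    mix <- mixture(alleles, c(0.5, 0.5))
    nk <- noise; nk$seed <- derive_seed(seed, k, 5L)
    trace <- simulate_trace(mix, reference, nk)
    res <- decompose(trace, control, reference, settings)
    reads <- simulate_reads(mix, reference, n_reads = n_reads, error_rate = 0,
                            seed = derive_seed(seed, k, 6L))
    ngs <- quantify_reads(reads, reference, align)
    for (i in 1:2) {
      s <- d[i]
      dv <- res$variants$frequency[res$variants$indel_size == s]
      nv <- ngs$table$frequency[ngs$table$indel_size == s]
      dv <- if (length(dv)) dv else 0
      nv <- if (length(nv)) nv else 0
      rows[[length(rows) + 1L]] <- data.frame(
        clone = k, indel_size = s, true_percent = 50,
        decomposition = dv, reads = nv, deviation = abs(dv - nv))
    }
  }
  per_clone <- do.call(rbind, rows)
  list(per_clone = per_clone, mad = mean(per_clone$deviation))
}
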