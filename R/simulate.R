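#' Sanger trace noise model
#'
#' Three-knob signal model for synthetic chromatograms: exponential amplitude
#' decay along the read (3'-end degradation), additive truncated Gaussian
#' channel noise (baseline), and linear cross-channel bleed (crosstalk). The
#' peak amplitude at position `i` (0-based) is
#' `base_amplitude * exp(-decay_rate * i)`.
#'
#' @param base_amplitude Peak height at position 0 (arbitrary units).
#' @param decay_rate Exponential decay per base.
#' @param noise_sd Additive Gaussian sigma per channel cell (truncated at 0).
#' @param crosstalk Fraction of each peak redistributed to each of the other
#'   three channels, in \[0, 0.25\].
#' @param seed Integer seed used when the model is rendered.
#' @return An object of class `trace_noise_model`.
#' @export
trace_noise_model <- function(base_amplitude = 1000, decay_rate = 0.002,
                              noise_sd = 30, crosstalk = 0.02, seed = 1L) {
  stopifnot(base_amplitude > 0, decay_rate >= 0, noise_sd >= 0,
            crosstalk >= 0, crosstalk <= 0.25)
  structure(list(base_amplitude = base_amplitude, decay_rate = decay_rate,
                 noise_sd = noise_sd, crosstalk = crosstalk,
                 seed = as.integer(seed)),
            class = "trace_noise_model")
}

#' Simulate a bulk Sanger chromatogram of an allele mixture
#'
#' Renders the superposition trace of a mixture: at each position the channel
#' of each allele's base receives `proportion * amplitude(i)`, redistributed
#' by crosstalk, summed over alleles, plus truncated Gaussian noise. Alleles
#' shorter than the longest allele (deletions) contribute nothing beyond
#' their own length, reproducing the ragged 3' end of real mixed traces.
#'
#' @param mix A [mixture()]; all allele sequences must agree with the
#'   reference up to the cut site.
#' @param reference The [reference_amplicon()].
#' @param noise A [trace_noise_model()].
#' @return A [chromatogram()] of length `max(allele lengths)`.
#' @export
simulate_trace <- function(mix, reference, noise = trace_noise_model()) {
  stopifnot(inherits(mix, "mixture"), inherits(reference, "reference_amplicon"),
            inherits(noise, "trace_noise_model"))
  if (length(mix$alleles) == 0L) stop("empty mixture", call. = FALSE)
  cut <- reference$cut_site
  pref <- substr(reference$sequence, 1L, cut)
  for (al in mix$alleles)
    if (substr(al$sequence, 1L, cut) != pref)
      stop("allele '", al$label, "' does not share the reference prefix up to the cut site",
           call. = FALSE)
  L <- max(vapply(mix$alleles, function(a) nchar(a$sequence), 0L))
  amp <- noise$base_amplitude * exp(-noise$decay_rate * (0:(L - 1L)))
  ch <- matrix(0, L, 4L, dimnames = list(NULL, BASES))
  k <- noise$crosstalk
  for (j in seq_along(mix$alleles)) {
    al <- mix$alleles[[j]]
    p <- mix$proportions[j]
    if (p == 0) next
    n <- nchar(al$sequence)
    idx <- match(seq_chars(al$sequence), BASES)
    h <- p * amp[seq_len(n)]
    # crosstalk: own channel keeps 1 - 3k, each other channel receives k
    bleed <- h * k
    for (c in 1:4) ch[seq_len(n), c] <- ch[seq_len(n), c] + bleed
    ch[cbind(seq_len(n), idx)] <- ch[cbind(seq_len(n), idx)] + h * (1 - 4 * k)
  }
  if (noise$noise_sd > 0) {
    set.seed(noise$seed)
    ch <- ch + matrix(rnorm(4L * L, 0, noise$noise_sd), L, 4L)
    ch[ch < 0] <- 0
  }
  chromatogram(ch)
}

#' Simulate a labelled clone well
#'
#' Draws a ground-truth mixture for a genotype class and renders its trace:
#' \describe{
#'   \item{homozygous}{one mutant allele at 100\%}
#'   \item{compound_het}{two distinct mutant alleles at 50:50 (Gaussian
#'     jitter of sd `jitter_sd`, renormalized)}
#'   \item{het_with_wt}{wild type plus one mutant at 50:50 (jittered)}
#'   \item{nonclonal}{3--5 distinct mutant alleles with proportions drawn
#'     from a symmetric Dirichlet (concentration 5)}
#' }
#'
#' @param label_class One of `"homozygous"`, `"compound_het"`,
#'   `"het_with_wt"`, `"nonclonal"`.
#' @param allele_pool List of alleles to draw from (must contain the
#'   wild-type allele when the class requires it).
#' @param reference The [reference_amplicon()].
#' @param noise A [trace_noise_model()]; its seed is re-derived from `seed`.
#' @param jitter_sd Sd of the proportion jitter around 50:50 (fraction).
#' @param seed Integer seed.
#' @return A list with elements `trace` (chromatogram), `label` (list with
#'   `class` and `truth` mixture) and `seed`.
#' @export
simulate_well <- function(label_class = c("homozygous", "compound_het",
                                          "het_with_wt", "nonclonal"),
                          allele_pool, reference, noise = trace_noise_model(),
                          jitter_sd = 0.05, seed = 1L) {
  label_class <- match.arg(label_class)
  stopifnot(is.list(allele_pool), length(allele_pool) > 0L)
  sizes <- vapply(allele_pool, `[[`, 0L, "indel_size")
  mut <- allele_pool[sizes != 0L]
  wt <- allele_pool[sizes == 0L]
  need <- switch(label_class, homozygous = 1L, compound_het = 2L,
                 het_with_wt = 1L, nonclonal = 3L)
  if (length(mut) < need)
    stop("allele_pool provides too few distinct mutant alleles for class '",
         label_class, "'", call. = FALSE)
  if (label_class == "het_with_wt" && length(wt) == 0L)
    stop("class 'het_with_wt' requires a wild-type allele in the pool", call. = FALSE)
  set.seed(seed)
  jitter2 <- function(a, b) {
    p <- 0.5 + rnorm(1L, 0, jitter_sd)
    p <- min(max(p, 0.05), 0.95)
    mixture(list(a, b), c(p, 1 - p))
  }
  truth <- switch(label_class,
    homozygous = mixture(mut[sample.int(length(mut), 1L)], 1),
    compound_het = {
      pick <- mut[sample.int(length(mut), 2L)]
      jitter2(pick[[1L]], pick[[2L]])
    },
    het_with_wt = jitter2(wt[[1L]], mut[[sample.int(length(mut), 1L)]]),
    nonclonal = {
      k <- sample(3:min(5L, length(mut)), 1L)
      pick <- mut[sample.int(length(mut), k)]
      g <- rgamma(k, shape = 5)     # symmetric Dirichlet(5)
      mixture(pick, g / sum(g))
    })
  noise$seed <- as.integer((seed * 1009L + 7L) %% .Machine$integer.max)
  trace <- simulate_trace(truth, reference, noise)
  list(trace = trace, label = list(class = label_class, truth = truth),
       seed = as.integer(seed))
}

#' Stepwise mixing series of homozygous clones
#'
#' Emulates the stepwise sensitivity design: `Mix-k` combines the first `k`
#' clones in equal parts (each at 1/k). The printed ratios of the original
#' wet-lab series are figure-internal, so the scheme is parameterizable and
#' `stepwise_equal` is the default.
#'
#' @param clones List of 2--5 alleles with pairwise-distinct indel sizes.
#' @param scheme Mixing scheme; only `"stepwise_equal"` is defined.
#' @return List of [mixture()] objects `Mix-1 .. Mix-n`.
#' @export
mixing_series <- function(clones, scheme = "stepwise_equal") {
  scheme <- match.arg(scheme)
  stopifnot(is.list(clones))
  if (length(clones) < 2L || length(clones) > 5L)
    stop("mixing series requires 2-5 clones", call. = FALSE)
  sizes <- vapply(clones, `[[`, 0L, "indel_size")
  if (anyDuplicated(sizes)) stop("clone indel sizes must be distinct", call. = FALSE)
  lapply(seq_along(clones), function(k)
    mixture(clones[seq_len(k)], rep(1 / k, k)))
}

#' Simulate amplicon reads over a mixture
#'
#' Single-end reads spanning the cut site: for each read an allele is sampled
#' by proportion, the start position uniformly among starts placing the cut
#' at least `span_margin` bases from either read end (the anchor an aligner
#' needs to place an indel; reads grazing the cut cannot support a call),
#' substitution errors injected i.i.d. at `error_rate`, and constant phred
#' 40 qualities assigned except for a `low_quality_fraction` of reads at
#' constant phred 20 (to exercise the quality filter).
#'
#' @param mix A [mixture()].
#' @param reference The [reference_amplicon()] (supplies the cut coordinate).
#' @param n_reads Number of reads (>= 0).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability, in \[0, 0.25).
#' @param low_quality_fraction Fraction of reads emitted at phred 20.
#' @param span_margin Minimum distance (bp) between the cut and either read
#'   end.
#' @param seed Integer seed.
#' @return A [read_set()].
#' @export
simulate_reads <- function(mix, reference, n_reads = 10000L, read_length = 150L,
                           error_rate = 0, low_quality_fraction = 0,
                           span_margin = 20L, seed = 1L) {
  stopifnot(inherits(mix, "mixture"), n_reads >= 0L,
            error_rate >= 0, error_rate < 0.25,
            low_quality_fraction >= 0, low_quality_fraction <= 1,
            span_margin >= 1L, 2L * span_margin < read_length)
  cut <- reference$cut_site
  lens <- vapply(mix$alleles, function(a) nchar(a$sequence), 0L)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest allele", call. = FALSE)
  n_reads <- as.integer(n_reads)
  if (n_reads == 0L) return(read_set(character(0), list()))
  set.seed(seed)
  which_allele <- sample.int(length(mix$alleles), n_reads, replace = TRUE,
                             prob = mix$proportions)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    al <- mix$alleles[[which_allele[i]]]
    n <- nchar(al$sequence)
    # 0-based starts leaving >= span_margin anchor on each side of the cut
    lo <- max(0L, cut + span_margin - read_length)
    hi <- min(cut - span_margin, n - read_length)
    if (hi < lo) stop("no valid start spans the cut site", call. = FALSE)
    s <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    seqs[i] <- substr(al$sequence, s + 1L, s + read_length)
  }
  if (error_rate > 0) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    for (i in seq_len(n_reads)) {
      hit <- which(runif(read_length) < error_rate)
      for (j in hit) {
        alt <- setdiff(BASES, chars[[i]][j])
        chars[[i]][j] <- alt[sample.int(3L, 1L)]
      }
    }
    seqs <- vapply(chars, paste, "", collapse = "")
  }
  lowq <- runif(n_reads) < low_quality_fraction
  quals <- lapply(lowq, function(lq) rep(if (lq) 20L else 40L, read_length))
  read_set(seqs, quals)
}
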