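#' Clone-well triage settings
#'
#' The triage rules encode the expectation that a clonal edited well is a
#' 100% (homozygous) or 50:50 (compound heterozygous) mix of mutant alleles:
#' wells showing wild type, more than `max_variants` variants, or
#' frequencies deviating from those ideals are discarded.
#'
#' @param max_variants Most non-wild-type variants a clonal well may show.
#' @param wt_min_freq Wild-type frequency (percent) at or above which the
#'   well is discarded as wild-type-containing.
#' @param hom_tolerance Homozygous band half-width: a single variant in
#'   `[100 - hom_tolerance, 100]` percent is retained as homozygous.
#' @param het_tolerance Heterozygous band half-width: two variants each in
#'   `50 +/- het_tolerance` percent are retained as compound heterozygous.
#' @param min_variant_freq Variants below this frequency (percent) are
#'   ignored by the rules.
#' @return An object of class `triage_settings`.
#' @export
triage_settings <- function(max_variants = 2L, wt_min_freq = 10,
                            hom_tolerance = 15, het_tolerance = 15,
                            min_variant_freq = 5) {
  stopifnot(max_variants >= 1L, hom_tolerance > 0, hom_tolerance < 50,
            het_tolerance > 0, het_tolerance < 50, wt_min_freq >= 0,
            min_variant_freq >= 0)
  structure(list(max_variants = as.integer(max_variants),
                 wt_min_freq = wt_min_freq, hom_tolerance = hom_tolerance,
                 het_tolerance = het_tolerance,
                 min_variant_freq = min_variant_freq),
            class = "triage_settings")
}

#' Triage a clone well from its decomposition result
#'
#' Pure decision function applying the screening rules in order:
#' eliminated fits are indeterminate; sub-threshold variants are dropped;
#' wells with wild type at or above `wt_min_freq` are discarded; wells with
#' more than `max_variants` variants are discarded as non-clonal; a single
#' variant in the homozygous band is retained, two variants each in the
#' 50:50 band are retained as compound heterozygous; anything else is
#' discarded as non-clonal (frequency deviation from the clonal ideals).
#' Retained wells still require imaging confirmation of single-cell origin,
#' which is outside this package's scope.
#'
#' @param result A [decompose()] result.
#' @param settings A [triage_settings()].
#' @return An object of class `triage_decision`: `verdict` (one of
#'   `retain_homozygous`, `retain_compound_het`, `discard_wildtype`,
#'   `discard_nonclonal`, `indeterminate`), `reason`, and
#'   `variants_considered`.
#' @export
classify_well <- function(result, settings = triage_settings()) {
  stopifnot(inherits(result, "decomposition_result"),
            inherits(settings, "triage_settings"))
  decision <- function(verdict, reason, v) {
    structure(list(verdict = verdict, reason = reason, variants_considered = v),
              class = "triage_decision")
  }
  if (result$status == "eliminated_low_fit")
    return(decision("indeterminate",
                    sprintf("fit R^2 %.3f below threshold", result$r_squared),
                    result$variants[0, c("indel_size", "frequency")]))
  v <- result$variants[result$variants$frequency >= settings$min_variant_freq,
                       c("indel_size", "frequency")]
  v <- v[order(v$indel_size), , drop = FALSE]
  wt <- v$frequency[v$indel_size == 0L]
  if (length(wt) && wt >= settings$wt_min_freq)
    return(decision("discard_wildtype",
                    sprintf("wild type at %.1f%%", wt), v))
  mut <- v[v$indel_size != 0L, , drop = FALSE]
  if (nrow(mut) > settings$max_variants)
    return(decision("discard_nonclonal",
                    sprintf("%d variants exceed the clonality cutoff of %d",
                            nrow(mut), settings$max_variants), v))
  if (nrow(mut) == 1L && mut$frequency >= 100 - settings$hom_tolerance)
    return(decision("retain_homozygous",
                    sprintf("single variant at %.1f%%", mut$frequency), v))
  if (nrow(mut) == 2L &&
      all(abs(mut$frequency - 50) <= settings$het_tolerance))
    return(decision("retain_compound_het",
                    sprintf("two variants at %.1f%% / %.1f%%",
                            mut$frequency[1L], mut$frequency[2L]), v))
  decision("discard_nonclonal",
           "frequencies deviate from the 100% / 50:50 clonal ideals", v)
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage_decision> %s (%s)\n", x$verdict, x$reason))
  invisible(x)
}

#' Triage every well of a plate
#'
#' @param results Named list of [decompose()] results (names are well ids)
#'   or a list of `list(well, result)` pairs.
#' @param settings A [triage_settings()].
#' @return An object of class `plate_report`: `wells` (data.frame of
#'   `well`, `verdict`, `reason`, `n_variants`, `confirm_by_imaging`) and
#'   `summary` (counts per verdict). Retained wells carry the
#'   confirm-by-imaging flag because frequency triage cannot exclude
#'   multi-cell wells with identical indels.
#' @export
screen_plate <- function(results, settings = triage_settings()) {
  if (length(results) == 0L) stop("empty plate", call. = FALSE)
  ids <- names(results)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("results must be a named list (well ids)", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate well ids", call. = FALSE)
  ord <- order(ids)
  decisions <- lapply(results[ord], classify_well, settings = settings)
  verdicts <- vapply(decisions, `[[`, "", "verdict")
  wells <- data.frame(
    well = ids[ord],
    verdict = verdicts,
    reason = vapply(decisions, `[[`, "", "reason"),
    n_variants = vapply(decisions, function(d) nrow(d$variants_considered), 0L),
    confirm_by_imaging = verdicts %in% c("retain_homozygous", "retain_compound_het"),
    row.names = NULL)
  lv <- c("retain_homozygous", "retain_compound_het", "discard_wildtype",
          "discard_nonclonal", "indeterminate")
  structure(list(wells = wells,
                 summary = table(factor(verdicts, levels = lv)),
                 settings = settings),
            class = "plate_report")
}

#' @export
print.plate_report <- function(x, ...) {
  cat("<plate_report>", nrow(x$wells), "wells\n")
  print(x$summary)
  invisible(x)
}

#' Reading-frame class of an indel
#'
#' @param indel_size Signed indel size(s) in bp.
#' @return Character vector: `"wild_type"` (0), `"in_frame"` (multiple of
#'   3), else `"frameshift"`.
#' @export
frameshift_class <- function(indel_size) {
  ifelse(indel_size == 0L, "wild_type",
         ifelse(indel_size %% 3L == 0L, "in_frame", "frameshift"))
}

#' Pool allele frequency tables into a mutant indel spectrum
#'
#' Wild-type entries are excluded; mutant frequencies are summed across
#' tables per indel size and renormalized so that the spectrum reads as the
#' percentage of each allele among all mutant alleles. Deletions and
#' insertions are binned at 1--15 bp; anything larger accumulates in
#' `other_freq`. The frameshift fraction is the mutant mass at sizes not
#' divisible by 3.
#'
#' @param tables List of allele frequency tables (decomposition results,
#'   read quantifications, or data.frames).
#' @return An object of class `indel_spectrum`: `deletion_freq` and
#'   `insertion_freq` (percent, sizes 1--15), `other_freq`,
#'   `frameshift_fraction`.
#' @export
aggregate_spectrum <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L) stop(">= 1 table required",
                                                     call. = FALSE)
  if (inherits(tables, "ngs_quantification") ||
      inherits(tables, "decomposition_result") || is.data.frame(tables))
    tables <- list(tables)
  acc <- numeric(0)
  for (tb in tables) {
    ft <- as_freq_table(tb)
    ft <- ft[ft$indel_size != 0L, , drop = FALSE]
    for (i in seq_len(nrow(ft))) {
      key <- as.character(ft$indel_size[i])
      acc[key] <- if (key %in% names(acc)) acc[key] + ft$frequency[i] else ft$frequency[i]
    }
  }
  if (length(acc) == 0L || sum(acc) <= 0)
    stop("all tables are pure wild type: empty mutant spectrum", call. = FALSE)
  sizes <- as.integer(names(acc))
  freq <- 100 * as.numeric(acc) / sum(acc)
  del <- setNames(numeric(15L), 1:15)
  ins <- setNames(numeric(15L), 1:15)
  other <- 0
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    if (s < 0L && s >= -15L) del[as.character(-s)] <- del[as.character(-s)] + freq[i]
    else if (s > 0L && s <= 15L) ins[as.character(s)] <- ins[as.character(s)] + freq[i]
    else other <- other + freq[i]
  }
  structure(list(deletion_freq = del, insertion_freq = ins, other_freq = other,
                 frameshift_fraction = sum(freq[sizes %% 3L != 0L])),
            class = "indel_spectrum")
}

#' @export
print.indel_spectrum <- function(x, ...) {
  cat("<indel_spectrum> frameshift fraction",
      sprintf("%.1f%%", x$frameshift_fraction), "\n")
  top <- sort(c(setNames(x$deletion_freq, paste0("del", 1:15)),
                setNames(x$insertion_freq, paste0("ins", 1:15))),
              decreasing = TRUE)
  top <- top[top > 0][seq_len(min(6L, sum(top > 0)))]
  for (nm in names(top)) cat(sprintf("  %-6s %5.1f%%\n", nm, top[[nm]]))
  if (x$other_freq > 0) cat(sprintf("  >15bp  %5.1f%%\n", x$other_freq))
  invisible(x)
}

spectrum_bins <- function(sp) {
  c(setNames(as.numeric(sp$deletion_freq), paste0("del", 1:15)),
    setNames(as.numeric(sp$insertion_freq), paste0("ins", 1:15)),
    other = sp$other_freq)
}

#' Compare two sets of replicate indel spectra bin by bin
#'
#' For each size bin the replicate frequencies of the two groups are
#' compared with a two-sample Welch t-test and Benjamini-Hochberg
#' adjustment across bins; this tests the same per-bin hypotheses as a
#' factorial ANOVA on the size-by-modality layout while needing no balanced
#' replicate structure.
#'
#' @param a,b Lists (>= 2 each) of [aggregate_spectrum()] objects
#'   (replicates of two editing modalities).
#' @param alpha Significance level applied to the adjusted p-values.
#' @return data.frame per bin: `bin`, `mean_a`, `mean_b`, `difference`
#'   (pp, a - b), `p_value`, `p_adjusted`, `significant`.
#' @export
compare_spectra <- function(a, b, alpha = 0.05) {
  ok <- function(x) is.list(x) && length(x) >= 2L &&
    all(vapply(x, inherits, TRUE, "indel_spectrum"))
  if (!ok(a) || !ok(b))
    stop(">= 2 replicate spectra required on each side", call. = FALSE)
  ma <- t(vapply(a, spectrum_bins, numeric(31L)))
  mb <- t(vapply(b, spectrum_bins, numeric(31L)))
  if (!identical(colnames(ma), colnames(mb)))
    stop("replicate spectra have mismatched bin domains", call. = FALSE)
  p <- vapply(seq_len(ncol(ma)), function(j) {
    x <- ma[, j]; y <- mb[, j]
    if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, 0)
  padj <- p.adjust(p, method = "BH")
  data.frame(bin = colnames(ma), mean_a = colMeans(ma), mean_b = colMeans(mb),
             difference = colMeans(ma) - colMeans(mb),
             p_value = p, p_adjusted = padj,
             significant = padj < alpha, row.names = NULL)
}

#' Indel fraction from T7 endonuclease band densitometry
#'
#' Closed-form estimate from mismatch-cleavage band intensities:
#' `fcut = (frag1 + frag2) / (parent + frag1 + frag2)` and
#' `indel% = 100 * (1 - sqrt(1 - fcut))`.
#'
#' @param parent Uncleaved parent band intensity (densitometry units).
#' @param frag1,frag2 Cleavage fragment band intensities.
#' @return Estimated indel percentage in \[0, 100\].
#' @export
t7_indel_fraction <- function(parent, frag1, frag2) {
  stopifnot(parent >= 0, frag1 >= 0, frag2 >= 0)
  tot <- parent + frag1 + frag2
  if (tot <= 0) stop("all-zero band intensities", call. = FALSE)
  fcut <- (frag1 + frag2) / tot
  100 * (1 - sqrt(1 - fcut))
}
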