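#' Alignment scoring parameters for the read oracle
#'
#' Defaults favour one contiguous indel over scattered gaps, matching the
#' biology of a single double-strand break: opening a gap costs far more
#' than extending one. `min_phred` is the per-read mean-quality floor below
#' which reads are discarded before quantification.
#'
#' @param match,mismatch Substitution scores (`match >= 0 >= mismatch`).
#' @param gap_open Score of a length-1 gap.
#' @param gap_extend Score of each additional gap base
#'   (`gap_open <= gap_extend <= 0`).
#' @param min_phred Minimum mean phred for a read to be used.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -3L, gap_open = -8L,
                             gap_extend = -1L, min_phred = 30L) {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0L, match >= 0L,
            mismatch <= 0L, min_phred >= 0L)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_phred = as.integer(min_phred)),
            class = "alignment_params")
}

#' Align a read to the reference amplicon
#'
#' Optimal semi-global alignment (the read aligned end to end, reference
#' overhangs free) under affine gap scoring; a gap of length L scores
#' `gap_open + (L - 1) * gap_extend`. Ties are broken deterministically:
#' aligned pairs over gaps, deletions over insertions, leftmost gap
#' placement.
#'
#' @param read Read sequence (string).
#' @param reference A [reference_amplicon()] or plain sequence string.
#' @param params An [alignment_params()].
#' @return An object of class `read_alignment`: `score`, `ref_start`
#'   (0-based), `ops` (per-column string of `M`/`D`/`I`: aligned pair,
#'   reference base deleted from the read, read base inserted).
#' @export
align_read <- function(read, reference, params = alignment_params()) {
  ref <- if (inherits(reference, "reference_amplicon")) reference$sequence
         else check_dna(reference, "reference")
  check_dna(read, "read")
  if (nchar(read) == 0L) stop("read must be non-empty", call. = FALSE)
  a <- align_read_cpp(read, ref, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(a, class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> score %d, ref_start %d, cigar %s\n",
              x$score, x$ref_start, cigar_string(x$ops)))
  invisible(x)
}

#' Net indel of a read alignment within a reference window
#'
#' Sums insertion lengths minus deletion lengths over the gap runs of an
#' alignment that overlap the half-open reference window `[lo, hi)` (a gap
#' run counts in full when it overlaps; insertions sit at an inter-base
#' coordinate).
#'
#' @param alignment An [align_read()] result.
#' @param lo,hi Half-open reference window bounds (0-based).
#' @return Signed net indel in bp.
#' @export
alignment_net_indel <- function(alignment, lo, hi) {
  stopifnot(inherits(alignment, "read_alignment"))
  r <- alignment$ref_start
  net <- 0L
  runs <- rle(seq_chars(alignment$ops))
  for (k in seq_along(runs$values)) {
    len <- runs$lengths[k]
    op <- runs$values[k]
    if (op == "M") r <- r + len
    else if (op == "D") {
      if (r < hi && r + len > lo) net <- net - len
      r <- r + len
    } else if (r >= lo && r <= hi) net <- net + len
  }
  net
}

cigar_string <- function(ops) {
  if (nchar(ops) == 0L) return("*")
  r <- rle(seq_chars(ops))
  paste0(r$lengths, r$values, collapse = "")
}

#' Quantify indel allele frequencies from amplicon reads
#'
#' The read-count ground truth used to validate trace decomposition. Reads
#' with mean phred below `params$min_phred` are discarded; the rest are
#' aligned semi-globally to the reference and the net indel (insertion minus
#' deletion lengths of gap runs overlapping `cut_site +/-
#' quant_halfwidth`) is tallied. Frequencies are percentages of passing
#' reads.
#'
#' @param reads A [read_set()].
#' @param reference The [reference_amplicon()].
#' @param params An [alignment_params()].
#' @param quant_halfwidth Half-width (bp) of the quantification window
#'   around the cut; insulates calls from read-end errors.
#' @return An object of class `ngs_quantification`: `table` (data.frame of
#'   `indel_size`, `frequency` percent), `efficiency` (percent mutant),
#'   `n_used`, `n_discarded`.
#' @export
quantify_reads <- function(reads, reference, params = alignment_params(),
                           quant_halfwidth = 10L) {
  stopifnot(inherits(reads, "read_set"), inherits(reference, "reference_amplicon"),
            quant_halfwidth >= 0L)
  mean_q <- vapply(reads$qualities, mean, 0)
  pass <- mean_q >= params$min_phred
  n_disc <- sum(!pass)
  if (!any(pass)) stop("no reads pass the quality filter", call. = FALSE)
  cut <- reference$cut_site
  net <- align_reads_net_cpp(reads$sequences[pass], reference$sequence,
                             params$match, params$mismatch, params$gap_open,
                             params$gap_extend,
                             cut - as.integer(quant_halfwidth),
                             cut + as.integer(quant_halfwidth))
  tab <- table(net)
  sizes <- as.integer(names(tab))
  freq <- 100 * as.numeric(tab) / sum(tab)
  ord <- order(sizes)
  ft <- data.frame(indel_size = sizes[ord], frequency = freq[ord])
  wt <- if (0L %in% ft$indel_size) ft$frequency[ft$indel_size == 0L] else 0
  structure(list(table = ft, efficiency = 100 - wt,
                 n_used = sum(pass), n_discarded = n_disc),
            class = "ngs_quantification")
}

#' @export
print.ngs_quantification <- function(x, ...) {
  cat(sprintf("<ngs_quantification> %d reads used (%d discarded), efficiency %.2f%%\n",
              x$n_used, x$n_discarded, x$efficiency))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  indel %+3d  %6.2f%%\n", x$table$indel_size[i],
                x$table$frequency[i]))
  invisible(x)
}

as_freq_table <- function(x) {
  if (inherits(x, "ngs_quantification")) return(x$table)
  if (inherits(x, "decomposition_result")) return(variant_table(x))
  if (is.data.frame(x) && all(c("indel_size", "frequency") %in% names(x)))
    return(x[, c("indel_size", "frequency")])
  stop("not an allele frequency table", call. = FALSE)
}

#' Compare decomposition frequencies against the read-count oracle
#'
#' Deviations are computed over the union of variant sizes (a size absent
#' from one table contributes 0% there). Variants at or above
#' `report_threshold` in one table but absent from the other are flagged
#' missed (present in reads, absent from decomposition) or spurious
#' (the converse).
#'
#' @param ngs_table An `ngs_quantification` or frequency data.frame.
#' @param decomp A [decompose()] result with status `"ok"`.
#' @param report_threshold Percent floor for missed/spurious flagging.
#' @return List: `by_variant` (data.frame of size, ngs, decomposition,
#'   deviation), `mad` (mean absolute deviation, pp), `max_deviation`,
#'   `missed`, `spurious`.
#' @export
compare_to_decomposition <- function(ngs_table, decomp, report_threshold = 5) {
  if (inherits(decomp, "decomposition_result") && decomp$status != "ok")
    stop("comparison unavailable: decomposition was eliminated (low fit)",
         call. = FALSE)
  a <- as_freq_table(ngs_table)
  b <- as_freq_table(decomp)
  sizes <- sort(union(a$indel_size, b$indel_size))
  fa <- setNames(rep(0, length(sizes)), sizes)
  fb <- fa
  fa[as.character(a$indel_size)] <- a$frequency
  fb[as.character(b$indel_size)] <- b$frequency
  dev <- fb - fa
  list(by_variant = data.frame(indel_size = sizes, ngs = as.numeric(fa),
                               decomposition = as.numeric(fb),
                               deviation = as.numeric(dev)),
       mad = mean(abs(dev)),
       max_deviation = max(abs(dev)),
       missed = sizes[fa >= report_threshold & fb == 0],
       spurious = sizes[fb >= report_threshold & fa == 0])
}
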