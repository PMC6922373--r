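#' Settings for Sanger trace decomposition
#'
#' Defaults follow standard decomposition practice for single-cut editing:
#' candidate indel sizes 1--30 bp in both directions, a decomposition window
#' of trace positions \[115, 500), a 100 bp upstream alignment window for
#' sample/control registration, a p < 1e-4 significance cutoff on
#' components, and elimination of fits with R-squared below 0.95.
#'
#' @param max_indel Largest indel size modelled (bp).
#' @param window Half-open decomposition window `c(start, end)` in 0-based
#'   trace positions (intersected with `[cut_site, end)` at fit time).
#' @param alignment_window Number of leading positions used for registration.
#' @param p_cutoff Per-component significance cutoff.
#' @param min_r2 Minimum fit R-squared; below it the result is eliminated.
#' @param min_report_freq Smallest reported component frequency (percent);
#'   suppresses numerical dust.
#' @param idealize_control Reconstruct the control's expected channel
#'   profile from its basecalls before building components (see
#'   [idealize_control()]). Removes control-side measurement noise from the
#'   design matrix; disable to regress on the raw control peaks.
#' @return An object of class `decomposition_settings`.
#' @export
decomposition_settings <- function(max_indel = 30L, window = c(115L, 500L),
                                   alignment_window = 100L, p_cutoff = 1e-4,
                                   min_r2 = 0.95, min_report_freq = 0.5,
                                   idealize_control = TRUE) {
  stopifnot(max_indel >= 1L, length(window) == 2L, window[1L] > 0L,
            window[2L] > window[1L], alignment_window >= 10L,
            p_cutoff > 0, p_cutoff < 1, min_r2 > 0, min_r2 <= 1,
            min_report_freq >= 0, is.logical(idealize_control))
  structure(list(max_indel = as.integer(max_indel),
                 window = as.integer(window),
                 alignment_window = as.integer(alignment_window),
                 p_cutoff = p_cutoff, min_r2 = min_r2,
                 min_report_freq = min_report_freq,
                 idealize_control = isTRUE(idealize_control)),
            class = "decomposition_settings")
}

#' Idealize a clonal control chromatogram
#'
#' A control trace is by definition a pure clonal wild-type sequence, so its
#' expected signal has exactly one peak per position (plus crosstalk bleed)
#' riding on a smooth amplitude envelope; any per-position deviation from
#' that ideal is measurement noise. This reconstructs the expected profile:
#' the envelope is a running mean of the per-position total intensity, the
#' crosstalk fraction a global median of off-peak signal, and the called
#' channel carries the remainder. Used on the control before component
#' construction so that control noise does not propagate into every
#' regression component. Real controls also carry sequence-context peak
#' height variation, which this flattens; the smoothing window is wide
#' relative to that variation but narrow relative to signal decay.
#'
#' @param trace A clonal [chromatogram()].
#' @param smooth_window Odd window (positions) for the envelope running mean.
#' @return An idealized [chromatogram()] with the same basecalls.
#' @export
idealize_control <- function(trace, smooth_window = 21L) {
  stopifnot(inherits(trace, "chromatogram"), smooth_window >= 1L)
  n <- length(trace)
  if (n == 0L) return(trace)
  tot <- rowSums(trace$channels)
  if (all(tot == 0)) return(trace)
  h <- (as.integer(smooth_window) - 1L) %/% 2L
  padded <- c(rep(tot[1L], h), tot, rep(tot[n], h))
  env <- vapply(seq_len(n), function(i) mean(padded[i:(i + 2L * h)]), 0)
  called <- match(trace$basecalls, BASES)
  pos_tot <- ifelse(tot > 0, tot, 1)
  off <- (pos_tot - trace$channels[cbind(seq_len(n), called)]) / (3 * pos_tot)
  k <- stats::median(off[tot > 0])
  k <- min(max(k, 0), 0.25)
  ch <- matrix(env * k, n, 4L)
  ch[cbind(seq_len(n), called)] <- env * (1 - 3 * k)
  ch[ch < 0] <- 0
  chromatogram(ch)
}

#' Register a sample trace against its wild-type control
#'
#' Finds the integer shift in \[-10, 10\] maximizing the summed channel-wise
#' Pearson correlation between sample and control over the first
#' `alignment_window` positions (upstream of the cut, where all alleles
#' agree). Sample position `p` corresponds to control position `p + offset`.
#'
#' @param sample,control [chromatogram()] objects.
#' @param settings A [decomposition_settings()].
#' @return Integer offset, with attribute `"correlation"` (mean per-channel
#'   correlation at the optimum).
#' @export
align_control <- function(sample, control, settings = decomposition_settings()) {
  W <- settings$alignment_window
  max_shift <- 10L
  if (length(sample) < W || length(control) < W + max_shift)
    stop("traces shorter than alignment_window + maximum shift", call. = FALSE)
  best <- -Inf; best_s <- 0L
  for (s in -max_shift:max_shift) {
    p <- 0:(W - 1L)
    keep <- p + s >= 0L & p + s < length(control)
    p <- p[keep]
    if (length(p) < W / 2L) next
    cc <- vapply(1:4, function(c) {
      x <- sample$channels[p + 1L, c]; y <- control$channels[p + s + 1L, c]
      if (sd(x) == 0 || sd(y) == 0) return(0)
      cor(x, y)
    }, 0)
    tot <- sum(cc)
    if (tot > best) { best <- tot; best_s <- s }
  }
  mean_cor <- best / 4
  if (mean_cor < 0.5)
    stop("registration failure: best sample/control correlation ",
         sprintf("%.2f", mean_cor), " < 0.5 (sample/control mismatch?)",
         call. = FALSE)
  structure(best_s, correlation = mean_cor)
}

#' Build indel-shifted component profiles from the control trace
#'
#' For each candidate indel size `d` in `-max_indel .. +max_indel` the
#' expected mixed-trace contribution over the decomposition window is the
#' control trace shifted by `d`: a deletion of `|d|` bp reads the control
#' `|d|` positions downstream; an insertion reads it `d` positions upstream,
#' with the `d` inserted (unknown-base) positions `[cut_site, cut_site + d)`
#' masked. The window is restricted to positions at or after the cut, where
#' alleles diverge.
#'
#' @param control Control [chromatogram()] (already in the sample frame).
#' @param cut_site 0-based inter-base cut coordinate.
#' @param settings A [decomposition_settings()].
#' @return List with `positions` (0-based window positions) and `components`,
#'   a list of `list(indel_size, profile, masked_positions)`.
#' @export
build_components <- function(control, cut_site, settings = decomposition_settings()) {
  win <- c(max(settings$window[1L], cut_site), settings$window[2L])
  if (win[2L] <= win[1L]) stop("empty decomposition window after cut-site restriction",
                               call. = FALSE)
  m <- settings$max_indel
  if (length(control) < win[2L] + m)
    stop("decomposition window extends past the shifted control trace", call. = FALSE)
  if (win[1L] - m < 0L)
    stop("decomposition window start too small for max_indel insertions", call. = FALSE)
  pos <- win[1L]:(win[2L] - 1L)
  comps <- lapply(-m:m, function(d) {
    src <- pos + abs(min(d, 0L)) - max(d, 0L)  # pos + |d| for del, pos - d for ins
    list(indel_size = d,
         profile = control$channels[src + 1L, , drop = FALSE],
         masked_positions = if (d > 0L) cut_site + 0:(d - 1L) else integer(0))
  })
  list(positions = pos, components = comps)
}

#' Decompose a mixed Sanger trace into an indel frequency spectrum
#'
#' Registers the sample against the wild-type control, rescales both to
#' equal total intensity over the alignment window, and solves the
#' non-negative least-squares problem
#' `min || sum_d w_d * profile_d - sample ||^2, w_d >= 0` over all
#' decomposition-window cells not masked by any insertion component.
#' Per-component two-sided p-values come from the unconstrained refit on the
#' active (non-zero) set; components failing `p_cutoff` or
#' `min_report_freq` are removed and the remaining weights renormalized to
#' 100%. Fits with R-squared below `min_r2` are flagged
#' `eliminated_low_fit`. If registration fails outright (unrelated or
#' shuffled control), the fit proceeds at offset 0 so that the R-squared
#' filter — rather than an error — eliminates the well.
#'
#' @param sample,control [chromatogram()] objects.
#' @param reference The [reference_amplicon()] (supplies `cut_site`).
#' @param settings A [decomposition_settings()].
#' @return An object of class `decomposition_result`: `variants`
#'   (data.frame of `indel_size`, `frequency` in percent, `p_value`),
#'   `r_squared`, `status` (`"ok"` or `"eliminated_low_fit"`), `efficiency`
#'   (percent mutant), `offset`, `registration_ok`, `settings`.
#' @export
decompose <- function(sample, control, reference,
                      settings = decomposition_settings()) {
  stopifnot(inherits(sample, "chromatogram"), inherits(control, "chromatogram"),
            inherits(reference, "reference_amplicon"))
  cut <- reference$cut_site
  offset <- tryCatch(align_control(sample, control, settings),
                     error = function(e) NA_integer_)
  registration_ok <- !is.na(offset)
  if (!registration_ok) offset <- 0L

  # shift control into the sample frame: control row for sample position p is
  # p + offset; out-of-bounds rows (|offset| leading/trailing) are zero-filled
  # and never intersect the decomposition window for |offset| <= 10
  n_need <- settings$window[2L] + settings$max_indel
  src <- (0:(n_need - 1L)) + offset
  ch <- matrix(0, n_need, 4L)
  ok_rows <- src >= 0L & src < length(control)
  if (!all(ok_rows[(settings$window[1L] + 1L):n_need]))
    stop("control trace does not cover the decomposition window at offset ",
         offset, call. = FALSE)
  ch[ok_rows, ] <- control$channels[src[ok_rows] + 1L, ]
  ctrl_shift <- chromatogram(ch)
  if (settings$idealize_control) ctrl_shift <- idealize_control(ctrl_shift)

  # rescale both to unit mean intensity over the alignment window
  W <- settings$alignment_window
  rescale <- function(tr) {
    s <- mean(tr$channels[seq_len(min(W, length(tr))), ])
    if (s <= 0) stop("degenerate trace: zero intensity over the alignment window",
                     call. = FALSE)
    chromatogram(tr$channels / s)
  }
  sam <- rescale(sample)
  ctl <- rescale(ctrl_shift)

  cmp <- build_components(ctl, cut, settings)
  if (length(sam) < max(cmp$positions) + 1L)
    stop("sample trace does not cover the decomposition window", call. = FALSE)

  m <- settings$max_indel
  masked <- cut + 0:(m - 1L)                    # union of all insertion masks
  use <- setdiff(cmp$positions, masked)
  if (length(use) == 0L) stop("decomposition window fully masked", call. = FALSE)
  ridx <- match(use, cmp$positions)

  y <- as.numeric(sam$channels[use + 1L, ])
  if (all(y == 0)) stop("degenerate input: all-zero sample over the decomposition window",
                        call. = FALSE)
  A <- vapply(cmp$components, function(co) as.numeric(co$profile[ridx, ]),
              numeric(length(y)))
  sizes <- vapply(cmp$components, `[[`, 0L, "indel_size")
  if (nrow(A) < ncol(A))
    stop("under-determined decomposition: window smaller than candidate set",
         call. = FALSE)

  w <- pracma::lsqnonneg(A, y)$x
  fit <- as.numeric(A %*% w)

  # R^2 is the paper's trace-quality gate, so it spans the whole
  # decomposition window: upstream of the cut every allele equals the
  # reference, the model prediction there is sum(w) * control, and a trace
  # too noisy (or mismatched) to reproduce even that region is eliminated.
  # Weights themselves are estimated from post-cut cells only (above),
  # because only those carry indel information.
  up <- settings$window[1L]:(cut - 1L)
  up <- up[up < cut & up >= settings$window[1L]]
  if (length(up) > 0L && settings$window[1L] < cut) {
    y_up <- as.numeric(sam$channels[up + 1L, ])
    fit_up <- sum(w) * as.numeric(ctl$channels[up + 1L, ])
    y_all <- c(y_up, y)
    fit_all <- c(fit_up, fit)
  } else {
    y_all <- y
    fit_all <- fit
  }
  rss <- sum((y_all - fit_all)^2)
  tss <- sum((y_all - mean(y_all))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  active <- which(w > 0)
  pvals <- rep(NA_real_, length(active))
  if (length(active) > 0L) {
    Aa <- A[, active, drop = FALSE]
    XtX <- crossprod(Aa)
    df <- nrow(Aa) - length(active)
    inv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
    if (is.null(inv)) {
      pvals <- rep(0, length(active))
    } else {
      beta <- inv %*% crossprod(Aa, y)
      res <- y - Aa %*% beta
      sigma2 <- sum(res^2) / df
      if (sigma2 < 1e-12 * mean(y^2)) {
        pvals <- rep(0, length(active))
      } else {
        se <- sqrt(pmax(diag(inv), 0) * sigma2)
        tval <- as.numeric(beta) / se
        pvals <- 2 * pt(-abs(tval), df)
      }
    }
  }

  keep <- pvals < settings$p_cutoff
  freq_all <- 100 * w[active] / sum(w[active])
  keep <- keep & freq_all >= settings$min_report_freq
  if (!any(keep)) {
    variants <- data.frame(indel_size = integer(0), frequency = numeric(0),
                           p_value = numeric(0))
  } else {
    ks <- active[keep]
    freq <- 100 * w[ks] / sum(w[ks])
    ord <- order(sizes[ks])
    variants <- data.frame(indel_size = sizes[ks][ord], frequency = freq[ord],
                           p_value = pvals[keep][ord])
  }
  wt_freq <- if (0L %in% variants$indel_size)
    variants$frequency[variants$indel_size == 0L] else 0
  status <- if (!is.na(r2) && r2 < settings$min_r2) "eliminated_low_fit" else "ok"
  structure(list(variants = variants, r_squared = r2, status = status,
                 efficiency = 100 - wt_freq, offset = as.integer(offset),
                 registration_ok = registration_ok, settings = settings),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> status %s, R^2 = %.4f, offset %d\n",
              x$status, x$r_squared, x$offset))
  if (nrow(x$variants)) {
    for (i in seq_len(nrow(x$variants)))
      cat(sprintf("  indel %+3d  %6.2f%%  p = %.3g\n", x$variants$indel_size[i],
                  x$variants$frequency[i], x$variants$p_value[i]))
    cat(sprintf("  editing efficiency: %.2f%%\n", x$efficiency))
  } else cat("  no significant components\n")
  invisible(x)
}

#' Overall editing efficiency of a decomposition
#'
#' The percentage of mutant alleles: 100 minus the wild-type (indel 0)
#' frequency, 100 when no wild-type component is reported.
#'
#' @param result A [decompose()] result with status `"ok"`.
#' @return Efficiency in percent.
#' @export
overall_efficiency <- function(result) {
  stopifnot(inherits(result, "decomposition_result"))
  if (result$status != "ok")
    stop("efficiency unavailable: decomposition was eliminated (low fit)",
         call. = FALSE)
  result$efficiency
}

#' Extract the allele frequency table of a decomposition
#'
#' @param result A [decompose()] result.
#' @return data.frame with `indel_size` and `frequency` (percent).
#' @export
variant_table <- function(result) {
  stopifnot(inherits(result, "decomposition_result"))
  result$variants[, c("indel_size", "frequency")]
}
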