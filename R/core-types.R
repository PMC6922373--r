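#' @useDynLib sangerscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt rnorm runif rgamma setNames sd p.adjust t.test
NULL

BASES <- c("A", "C", "G", "T")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

check_dna <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(s) > 0L && grepl("[^ACGT]", s))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Reference amplicon with cut-site coordinate
#'
#' Bundles the wild-type amplicon sequence with the coordinate frame used by
#' every downstream operation. All coordinates in this package are 0-based
#' and half-open; `cut_site` is an inter-base index, i.e. the nuclease cut
#' falls between positions `cut_site - 1` and `cut_site`.
#'
#' @param sequence Wild-type amplicon sequence (A/C/G/T string).
#' @param cut_site Integer inter-base cut coordinate, `0 < cut_site < nchar(sequence)`.
#' @param name Text label.
#' @param guide Optional guide (protospacer) sequence; must occur in the
#'   amplicon on either strand.
#' @param primer_fwd,primer_rev Optional primer sequences (annotation only).
#' @return An object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(sequence, cut_site, name = "amplicon",
                               guide = NULL, primer_fwd = NULL, primer_rev = NULL) {
  check_dna(sequence, "reference sequence")
  cut_site <- as.integer(cut_site)
  if (!(cut_site > 0L && cut_site < nchar(sequence)))
    stop("cut_site must satisfy 0 < cut_site < length(sequence)", call. = FALSE)
  if (!is.null(guide)) {
    check_dna(guide, "guide")
    if (!grepl(guide, sequence, fixed = TRUE) &&
        !grepl(revcomp(guide), sequence, fixed = TRUE))
      stop("guide (or its reverse complement) does not occur in the amplicon",
           call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, cut_site = cut_site,
                 guide = guide, primer_fwd = primer_fwd, primer_rev = primer_rev),
            class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("<reference_amplicon '%s'> %d bp, cut site at %d (0-based, inter-base)\n",
              x$name, nchar(x$sequence), x$cut_site))
  if (!is.null(x$guide)) cat("  guide:", x$guide, "\n")
  invisible(x)
}

#' Locate the Cas9 cut site implied by a guide sequence
#'
#' Finds the 20-nt protospacer on either strand of the amplicon and returns
#' the blunt-cut inter-base coordinate 3 bp from the PAM-proximal end of the
#' protospacer (between positions 17 and 18 of the guide match).
#'
#' @param sequence Amplicon sequence string.
#' @param guide Protospacer sequence (PAM not included).
#' @return 0-based inter-base cut coordinate.
#' @export
guide_cut_site <- function(sequence, guide) {
  check_dna(sequence, "sequence"); check_dna(guide, "guide")
  hit <- regexpr(guide, sequence, fixed = TRUE)
  if (hit > 0L) return(as.integer(hit) - 1L + nchar(guide) - 3L)
  hit <- regexpr(revcomp(guide), sequence, fixed = TRUE)
  if (hit > 0L) return(as.integer(hit) - 1L + 3L)
  stop("guide not found on either strand of the amplicon", call. = FALSE)
}

#' Apply an indel at the cut site of a reference amplicon
#'
#' Realizes a single allele: deletions remove bases `[cut_site,
#' cut_site + |size|)`; insertions place `inserted_bases` at `cut_site`;
#' size 0 returns the wild-type allele.
#'
#' @param reference A [reference_amplicon()].
#' @param indel_size Signed integer (negative = deletion, positive = insertion).
#' @param inserted_bases Bases to insert (length must equal `max(indel_size, 0)`).
#' @param label Optional text label; defaults to e.g. `"del7"`, `"ins2"`, `"WT"`.
#' @return An object of class `allele`.
#' @export
apply_indel <- function(reference, indel_size, inserted_bases = "", label = NULL) {
  stopifnot(inherits(reference, "reference_amplicon"))
  d <- as.integer(indel_size)
  ref <- reference$sequence
  cut <- reference$cut_site
  if (abs(d) > cut || abs(d) > nchar(ref) - cut)
    stop("indel of size ", d, " overruns the amplicon around cut site ", cut,
         call. = FALSE)
  if (nchar(inserted_bases) != max(d, 0L))
    stop("inserted_bases must have length max(indel_size, 0)", call. = FALSE)
  if (d > 0L) check_dna(inserted_bases, "inserted_bases")
  seq <- if (d == 0L) ref
  else if (d < 0L) paste0(substr(ref, 1L, cut), substr(ref, cut - d + 1L, nchar(ref)))
  else paste0(substr(ref, 1L, cut), inserted_bases, substr(ref, cut + 1L, nchar(ref)))
  if (is.null(label))
    label <- if (d == 0L) "WT" else if (d < 0L) paste0("del", -d) else paste0("ins", d)
  structure(list(indel_size = d, sequence = seq,
                 inserted_bases = if (d > 0L) inserted_bases else "",
                 label = label),
            class = "allele")
}

#' Allele mixture
#'
#' A set of alleles with pairwise-distinct indel sizes and proportions that
#' sum to one: the ground-truth composition of a bulk sample or clone well.
#'
#' @param alleles List of [apply_indel()] alleles.
#' @param proportions Numeric vector of the same length, non-negative,
#'   summing to 1 (tolerance 1e-9).
#' @return An object of class `mixture`.
#' @export
mixture <- function(alleles, proportions) {
  if (!is.list(alleles) || !all(vapply(alleles, inherits, TRUE, "allele")))
    stop("alleles must be a list of allele objects", call. = FALSE)
  proportions <- as.numeric(proportions)
  if (length(alleles) != length(proportions))
    stop("alleles and proportions differ in length", call. = FALSE)
  if (any(proportions < 0)) stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1", call. = FALSE)
  sizes <- vapply(alleles, `[[`, 0L, "indel_size")
  if (anyDuplicated(sizes)) stop("allele indel sizes must be pairwise distinct",
                                 call. = FALSE)
  structure(list(alleles = alleles, proportions = proportions), class = "mixture")
}

indel_sizes <- function(mix) vapply(mix$alleles, `[[`, 0L, "indel_size")

#' @export
print.mixture <- function(x, ...) {
  cat("<mixture>", length(x$alleles), "allele(s):\n")
  for (i in seq_along(x$alleles))
    cat(sprintf("  %-6s (indel %+d) %.1f%%\n", x$alleles[[i]]$label,
                x$alleles[[i]]$indel_size, 100 * x$proportions[i]))
  invisible(x)
}

basecall_channels <- function(channels) {
  if (nrow(channels) == 0L) return(character(0))
  # ties broken alphabetically: max.col with ties.method = "first" on A,C,G,T order
  BASES[max.col(channels, ties.method = "first")]
}

#' Per-base chromatogram
#'
#' A chromatogram reduced to one row per called base with the four channel
#' peak intensities (arbitrary units). Basecalls are the arg-max channel,
#' ties broken alphabetically (A < C < G < T); if `basecalls` is omitted they
#' are computed from the channels.
#'
#' @param channels Numeric matrix, one row per position, columns A, C, G, T;
#'   all intensities non-negative.
#' @param basecalls Optional character vector of per-position calls.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(channels, basecalls = NULL) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 4L) stop("channels must have 4 columns (A,C,G,T)", call. = FALSE)
  colnames(channels) <- BASES
  storage.mode(channels) <- "double"
  if (any(channels < 0)) stop("channel intensities must be non-negative", call. = FALSE)
  calls <- basecall_channels(channels)
  if (is.null(basecalls)) basecalls <- calls
  basecalls <- as.character(basecalls)
  if (length(basecalls) != nrow(channels))
    stop("basecalls length must equal the number of positions", call. = FALSE)
  if (nrow(channels) > 0L) {
    mx <- apply(channels, 1L, max)
    ok <- channels[cbind(seq_len(nrow(channels)), match(basecalls, BASES))] == mx
    if (!all(ok)) stop("each basecall must be a channel achieving the maximum intensity",
                       call. = FALSE)
  }
  structure(list(channels = channels, basecalls = basecalls), class = "chromatogram")
}

#' @export
length.chromatogram <- function(x) nrow(x$channels)

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d positions; calls: %s%s\n", length(x),
              paste(utils::head(x$basecalls, 30), collapse = ""),
              if (length(x) > 30) "..." else ""))
  invisible(x)
}

called_sequence <- function(trace) paste(trace$basecalls, collapse = "")

#' Read a chromatogram from the tabular trace dialect
#'
#' The dialect is UTF-8 TSV with header `pos  A  C  G  T  call`, `pos`
#' 0-based and ascending, non-negative decimal intensities, and calls in
#' {A,C,G,T}. Vendor chromatogram containers are expected to be converted to
#' this dialect upstream; it is the normative, version-controllable format.
#'
#' @param path File path.
#' @return A [chromatogram()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !identical(strsplit(lines[1L], "\t")[[1L]],
                                        c("pos", "A", "C", "G", "T", "call")))
    stop("not a tabular trace file (bad header): ", path, call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  ch <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
  calls <- character(n)
  pos_prev <- -1L
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 6L)
      stop("trace parse error at line ", i + 1L, ": expected 6 columns, got ",
           length(f), call. = FALSE)
    pos <- suppressWarnings(as.integer(f[1L]))
    vals <- suppressWarnings(as.numeric(f[2:5]))
    if (is.na(pos) || anyNA(vals))
      stop("trace parse error at line ", i + 1L, ": non-numeric field", call. = FALSE)
    if (any(vals < 0))
      stop("trace parse error at line ", i + 1L, ": negative intensity", call. = FALSE)
    if (pos != pos_prev + 1L)
      stop("trace parse error at line ", i + 1L, ": positions must be 0-based ascending",
           call. = FALSE)
    if (!f[6L] %in% BASES)
      stop("trace parse error at line ", i + 1L, ": call must be one of A,C,G,T",
           call. = FALSE)
    ch[i, ] <- vals
    calls[i] <- f[6L]
    pos_prev <- pos
  }
  chromatogram(ch, calls)
}

#' Write a chromatogram in the tabular trace dialect
#'
#' Intensities are written with full precision so that
#' `read_trace(write_trace(x))` reproduces the channels bit-exactly.
#'
#' @param trace A [chromatogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "chromatogram"))
  n <- length(trace)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("pos\tA\tC\tG\tT\tcall", con)
  if (n > 0L) {
    rows <- sprintf("%d\t%s\t%s\t%s\t%s\t%s", 0:(n - 1L),
                    sprintf("%.17g", trace$channels[, 1L]),
                    sprintf("%.17g", trace$channels[, 2L]),
                    sprintf("%.17g", trace$channels[, 3L]),
                    sprintf("%.17g", trace$channels[, 4L]),
                    trace$basecalls)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a reference amplicon from FASTA
#'
#' The cut site (and optional guide) are supplied alongside the FASTA, not
#' encoded in it. If `cut_site` is omitted but a guide is given, the cut
#' coordinate is derived with [guide_cut_site()].
#'
#' @param path FASTA file (first record used).
#' @param cut_site 0-based inter-base cut coordinate, or `NULL` to derive
#'   from `guide`.
#' @param guide Optional protospacer sequence.
#' @return A [reference_amplicon()].
#' @export
read_reference <- function(path, cut_site = NULL, guide = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seq <- as.character(ss[[1L]])
  if (is.null(cut_site)) {
    if (is.null(guide)) stop("supply cut_site or guide", call. = FALSE)
    cut_site <- guide_cut_site(seq, guide)
  }
  reference_amplicon(seq, cut_site, name = names(ss)[1L], guide = guide)
}

#' Amplicon read set
#'
#' @param sequences Character vector of read sequences.
#' @param qualities List of integer phred vectors (one per read, each the
#'   read's length, values in \[0, 60\]).
#' @return An object of class `read_set`.
#' @export
read_set <- function(sequences, qualities) {
  sequences <- as.character(sequences)
  if (!is.list(qualities) || length(qualities) != length(sequences))
    stop("qualities must be a list parallel to sequences", call. = FALSE)
  for (i in seq_along(sequences)) {
    q <- qualities[[i]]
    if (length(q) != nchar(sequences[i]))
      stop("read ", i, ": quality length != sequence length", call. = FALSE)
    if (any(q < 0L | q > 60L))
      stop("read ", i, ": phred scores must lie in [0, 60]", call. = FALSE)
  }
  structure(list(sequences = sequences, qualities = qualities), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$sequences)

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", length(x), "reads\n")
  invisible(x)
}

#' Write a read set as FASTQ (phred+33)
#' @param reads A [read_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  ss <- Biostrings::DNAStringSet(reads$sequences)
  names(ss) <- sprintf("read%06d", seq_along(reads$sequences))
  q <- Biostrings::BStringSet(vapply(reads$qualities,
                                     function(v) rawToChar(as.raw(v + 33L)), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ (phred+33) file into a read set
#' @param path FASTQ path.
#' @return A [read_set()].
#' @export
read_reads <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- lapply(as.character(S4Vectors::mcols(ss)$qualities),
                  function(s) as.integer(charToRaw(s)) - 33L)
  read_set(as.character(ss), quals)
}
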