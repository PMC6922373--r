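# Shared fixtures, built once per test run.

fix <- local({
  ref <- synthetic_reference()
  pool <- example_allele_pool(ref)
  list(ref = ref, pool = pool,
       sizes = vapply(pool, `[[`, 0L, "indel_size"))
})

allele_by_size <- function(d) fix$pool[[match(d, fix$sizes)]]

noiseless <- function() trace_noise_model(noise_sd = 0, crosstalk = 0,
                                          decay_rate = 0)

wt_trace <- function(noise = noiseless()) {
  simulate_trace(mixture(list(allele_by_size(0L)), 1), fix$ref, noise)
}

# Independent grid-search least-squares oracle for NNLS decomposition:
# search the simplex of proportions over the given candidate sizes (with the
# overall scale solved in closed form per direction) against the same design
# decompose() fits, and return the residual-minimizing frequencies.
grid_oracle <- function(sample, control, sizes,
                        settings = decomposition_settings(), step = 0.001) {
  cut <- fix$ref$cut_site
  rescale <- function(tr) {
    chromatogram(tr$channels / mean(tr$channels[seq_len(settings$alignment_window), ]))
  }
  sam <- rescale(sample)
  ctl <- rescale(control)
  if (settings$idealize_control) ctl <- idealize_control(ctl)
  cmp <- build_components(ctl, cut, settings)
  use <- setdiff(cmp$positions, cut + 0:(settings$max_indel - 1L))
  ridx <- match(use, cmp$positions)
  all_sizes <- vapply(cmp$components, `[[`, 0L, "indel_size")
  Tm <- vapply(cmp$components[match(sizes, all_sizes)],
               function(co) as.numeric(co$profile[ridx, ]),
               numeric(length(use) * 4L))
  y <- as.numeric(sam$channels[use + 1L, ])
  G <- crossprod(Tm)
  cc <- crossprod(Tm, y)
  k <- length(sizes)
  grid <- seq(0, 1, by = step)
  props <- if (k == 1L) matrix(1, 1, 1)
  else if (k == 2L) cbind(grid, 1 - grid)
  else {
    g <- expand.grid(a = grid, b = grid)
    g <- g[g$a + g$b <= 1, ]
    cbind(g$a, g$b, 1 - g$a - g$b)
  }
  obj <- apply(props, 1L, function(p) {
    uu <- as.numeric(t(p) %*% G %*% p)
    if (uu <= 0) return(Inf)
    -(sum(cc * p))^2 / uu       # minimizing residual = maximizing (y'u)^2/u'u
  })
  best <- props[which.min(obj), ]
  setNames(100 * best / sum(best), sizes)
}

# Exhaustive enumeration of semi-global affine-gap alignments (small inputs
# only): all monotone paths, read fully consumed, reference overhangs free.
# Branch-and-bound pruning keeps it tractable.
enumerate_best_score <- function(read, ref, params = alignment_params()) {
  n <- nchar(read); m <- nchar(ref)
  rc <- strsplit(read, "")[[1]]; fc <- strsplit(ref, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (score + (n - i) * params$match <= best) return()
    if (i == n) { best <<- max(best, score); return() }
    if (j < m) {
      s <- if (rc[i + 1] == fc[j + 1]) params$match else params$mismatch
      rec(i + 1L, j + 1L, score + s, "M")
      rec(i, j + 1L, score + if (prev == "D") params$gap_extend else params$gap_open, "D")
    }
    rec(i + 1L, j, score + if (prev == "I") params$gap_extend else params$gap_open, "I")
  }
  for (j0 in 0:m) rec(0L, j0, 0, "none")
  best
}

# Re-score an alignment object from its operations (independent check that
# the reported score is consistent with the reported alignment).
score_alignment <- function(read, ref, aln, params = alignment_params()) {
  rc <- strsplit(read, "")[[1]]; fc <- strsplit(ref, "")[[1]]
  i <- 0L; j <- aln$ref_start; score <- 0; prev <- ""
  for (op in strsplit(aln$ops, "")[[1]]) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      score <- score + if (rc[i] == fc[j]) params$match else params$mismatch
    } else if (op == "D") {
      j <- j + 1L
      score <- score + if (prev == "D") params$gap_extend else params$gap_open
    } else {
      i <- i + 1L
      score <- score + if (prev == "I") params$gap_extend else params$gap_open
    }
    prev <- op
  }
  stopifnot(i == nchar(read))
  score
}

# Multinomial replicate frequency table over a named indel-size distribution
sim_replicate_table <- function(probs, depth = 2000L) {
  counts <- as.numeric(stats::rmultinom(1L, depth, probs))
  data.frame(indel_size = as.integer(names(probs)),
             frequency = 100 * counts / depth)
}
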