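# Independent oracles used to cross-check the package implementation.
# These deliberately use naive brute-force algorithms, never the package's
# own code paths.

# Smith-Waterman local alignment score with linear gap penalty.
sw_local_score <- function(a, b, match = 1, mismatch = -2, gap = 2.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(
        0,
        H[i, j] + s,
        H[i, j + 1] - gap,
        H[i + 1, j] - gap
      )
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Best local alignment score of a read against a circular sequence, either
# strand, by scanning every rotation (brute force; tiny instances only).
oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

circular_best_score <- function(read, circ) {
  chars <- strsplit(circ, "")[[1]]
  L <- length(chars)
  best <- 0
  for (k in 0:(L - 1)) {
    rot <- paste(chars[((seq_len(L) - 1 + k) %% L) + 1], collapse = "")
    best <- max(
      best,
      sw_local_score(read, rot),
      sw_local_score(oracle_revcomp(read), rot)
    )
  }
  best
}

# Run-length chord oracle for one line of a binary mask: lengths of maximal
# TRUE runs not touching either end.
oracle_line_chords <- function(v) {
  out <- integer(0)
  len <- 0
  start <- NA
  for (i in seq_along(v)) {
    if (v[i]) {
      if (len == 0) start <- i
      len <- len + 1
    } else {
      if (len > 0 && start > 1) out <- c(out, len)
      len <- 0
    }
  }
  # run ending at the border is censored, so never appended
  out
}

# Exhaustive best-hit rule: dedup, then max identity, ties by longer
# aligned_length, lower ref_start, '+' before '-'.
oracle_best_hit <- function(hits) {
  hits <- unique(as.data.frame(hits))
  strand_rank <- ifelse(hits$strand == "+", 0, 1)
  o <- order(-hits$identity, -hits$aligned_length, hits$ref_start, strand_rank)
  hits[o[1], , drop = FALSE]
}

# Shortest prefix of `query` with no exact occurrence (either strand) in the
# genome texts, by exhaustive substring search.
oracle_unique_prefix <- function(query, genomes) {
  texts <- c(genomes, vapply(genomes, oracle_revcomp, ""))
  for (l in seq_len(nchar(query))) {
    pre <- substr(query, 1, l)
    found <- any(vapply(texts, function(t) {
      any(vapply(seq_len(max(nchar(t) - l + 1, 0)), function(i) {
        substr(t, i, i + l - 1) == pre
      }, TRUE))
    }, TRUE))
    if (!found) return(l)
  }
  0L
}

# Gaussian intensity profile sampled at unit steps.
gaussian_profile <- function(center, sigma, positions, height = 1, bg = 0) {
  bg + height * exp(-(positions - center)^2 / (2 * sigma^2))
}

# A multichannel image holding one isotropic Gaussian spot per channel.
spot_image <- function(size, centers, sigmas, heights = NULL) {
  nch <- length(sigmas)
  if (is.null(heights)) heights <- rep(1, nch)
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  img <- array(0, c(size, size, nch))
  for (k in seq_len(nch)) {
    img[, , k] <- heights[k] * exp(
      -((xs - centers[[k]][1])^2 + (ys - centers[[k]][2])^2) / (2 * sigmas[k]^2)
    )
  }
  img
}

# Random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
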