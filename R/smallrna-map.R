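# Small-RNA mapping against a circular mitochondrial reference region.
# Coordinates are 1-based inclusive on the heavy strand; descending pairs
# run in the light-strand direction and may wrap through the origin.
# Circularity is realised by doubling the target region and folding hit
# coordinates back onto the circle. The mapping chain is: local alignment of
# each read against both strands (BLASTN-like scoring: match +1, mismatch
# -2, gap -2.5), per-read best-hit selection (dedup, then highest identity
# with deterministic tie-breaks), orientation onto the plus strand, and
# tabulation of alignment lengths to find the dominant transcript length.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# heavy-strand substring ascending from `from` to `to`, wrapping the origin
circular_substr <- function(ref, from, to) {
  len <- nchar(ref)
  if (from <= to) {
    substr(ref, from, to)
  } else {
    paste0(substr(ref, from, len), substr(ref, 1, to))
  }
}

#' Length of a circular light-strand interval
#'
#' Intervals are measured in the light-strand (descending heavy-coordinate)
#' direction from `start` to `end`, wrapping through the origin when
#' `start < end`. A descending pair such as (16188, 16119) spans
#' `start - end + 1` nucleotides.
#'
#' @param start,end 1-based heavy-strand coordinates.
#' @param ref_length Circle length in nt.
#' @return Interval length in nt.
#' @export
interval_length <- function(start, end, ref_length) {
  check_number(ref_length, "ref_length", min = 1, integerish = TRUE)
  if (any(start < 1 | start > ref_length | end < 1 | end > ref_length)) {
    abort("coordinates out of range")
  }
  ((start - end) %% ref_length) + 1
}

#' Light-strand transcript sequence of a circular interval
#'
#' Returns the 5'->3' light-strand sequence covering the interval from
#' `start` down to `end` (heavy-strand coordinates, wrapping allowed), i.e.
#' the reverse complement of the underlying heavy-strand segment.
#'
#' @param reference Reference sequence (character scalar).
#' @param start,end 1-based heavy-strand coordinates, light-strand direction.
#' @return Transcript sequence.
#' @export
transcript_sequence <- function(reference, start, end) {
  revcomp(circular_substr(reference, end, start))
}

#' Align reads to a circular reference region
#'
#' Locally aligns each read against both strands of the doubled target
#' region (the region concatenated to itself, realising circularity), with
#' BLASTN-like scoring (match +1, mismatch -2, gap -2.5), and reports hits
#' passing the identity and score thresholds. The score threshold stands in
#' for an e-value cutoff at region scale. Reads containing characters other
#' than A/C/G/T are skipped with a warning naming them.
#'
#' @param reads A `read_set` (see [make_reads()]), a tibble with `read_id`
#'   and `seq`, or a named character vector.
#' @param reference Circular reference sequence (character scalar); taken
#'   from the `read_set` if not supplied.
#' @param region Length-2 ascending heavy-strand pair delimiting the target
#'   region (may wrap the origin). Default `c(16116, 16210)`.
#' @param min_identity Minimum percent identity of a reported hit.
#' @param min_score Minimum alignment score.
#' @return Tibble of `AlignmentHit`s: `read_id`, `ref`, `identity`,
#'   `aligned_length`, `ref_start`, `ref_end`, `strand`, `score`. Minus-strand
#'   hits have `ref_start > ref_end` (positions in heavy-strand coordinates).
#' @export
align_reads <- function(reads, reference = NULL, region = c(16116, 16210),
                        min_identity = 90, min_score = 15) {
  if (inherits(reads, "read_set")) {
    if (is.null(reference)) reference <- reads$reference
    reads <- reads$reads
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read_%05d", seq_along(reads))
    reads <- tibble(read_id = ids, seq = unname(reads))
  }
  if (is.null(reference)) abort("`reference` is required")
  check_number(min_identity, "min_identity", min = 0, max = 100)
  ref_name <- attr(reference, "name") %||% "reference"
  ref_len <- nchar(reference)

  empty <- tibble(
    read_id = character(), ref = character(), identity = numeric(),
    aligned_length = integer(), ref_start = integer(), ref_end = integer(),
    strand = character(), score = numeric()
  )
  if (nrow(reads) == 0) return(empty)

  seqs <- toupper(reads$seq)
  ok <- grepl("^[ACGT]+$", seqs)
  if (any(!ok)) {
    warn(sprintf(
      "skipping %d read(s) with non-ACGT characters: %s",
      sum(!ok), paste(utils::head(reads$read_id[!ok], 5), collapse = ", ")
    ))
  }
  reads <- reads[ok, ]
  seqs <- seqs[ok]
  if (nrow(reads) == 0) return(empty)

  region_seq <- toupper(circular_substr(reference, region[1], region[2]))
  l_region <- nchar(region_seq)
  doubled <- paste0(region_seq, region_seq)
  d_len <- 2L * l_region
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE
  )

  fold <- function(p) {
    ((region[1] - 1 + (p - 1) %% l_region) %% ref_len) + 1
  }

  align_strand <- function(subject, strand) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs), subject,
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2.5
    )
    s <- BiocGenerics::start(Biostrings::subject(aln))
    e <- BiocGenerics::end(Biostrings::subject(aln))
    # alignment length including gaps, computed from match/mismatch/indel
    # tallies (far cheaper than materialising the aligned strings)
    nid <- Biostrings::nindel(aln)
    alen <- unname(
      Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
        Biostrings::insertion(nid)[, "WidthSum"] +
        Biostrings::deletion(nid)[, "WidthSum"]
    )
    if (strand == "-") {
      # positions were on the reverse complement of the doubled region
      s2 <- d_len - e + 1
      e2 <- d_len - s + 1
      ref_start <- fold(e2) # 5' end of the hit on the read maps to the larger coord
      ref_end <- fold(s2)
    } else {
      ref_start <- fold(s)
      ref_end <- fold(e)
    }
    tibble(
      read_id = reads$read_id,
      ref = ref_name,
      identity = 100 * Biostrings::nmatch(aln) / alen,
      aligned_length = as.integer(alen),
      ref_start = as.integer(ref_start),
      ref_end = as.integer(ref_end),
      strand = strand,
      score = BiocGenerics::score(aln)
    )
  }

  hits <- bind_rows(
    align_strand(doubled, "+"),
    align_strand(revcomp(doubled), "-")
  ) %>%
    filter(.data$score >= min_score, .data$identity >= min_identity) %>%
    arrange(.data$read_id, desc(.data$score))
  hits
}

#' Best hit per read
#'
#' Applies the published filter: exact-duplicate hits are removed, then each
#' read keeps its single hit with the highest identity. Remaining ties are
#' broken deterministically by longer aligned length, lower `ref_start`,
#' then strand (`+` before `-`), so the survivor never depends on input
#' order.
#'
#' @param hits Alignment-hit tibble from [align_reads()] (one read or many).
#' @return One row per read; zero rows for empty input.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits %>%
    dplyr::distinct() %>%
    group_by(.data$read_id) %>%
    arrange(
      desc(.data$identity), desc(.data$aligned_length),
      .data$ref_start, .data$strand,
      .by_group = TRUE
    ) %>%
    slice(1) %>%
    ungroup()
}

#' Orient hits onto the plus strand
#'
#' Reverse-complements minus-strand hits onto the plus orientation (swapping
#' their coordinates) so all hits share one orientation; the original strand
#' is kept in `original_strand`. Applying the operation twice equals
#' applying it once.
#'
#' @param hits Alignment-hit tibble.
#' @return Hits with `strand` all `"+"` and an `original_strand` column.
#' @export
orient_hits <- function(hits) {
  if (!"original_strand" %in% names(hits)) hits$original_strand <- hits$strand
  flip <- hits$strand == "-"
  if (any(flip)) {
    tmp <- hits$ref_start[flip]
    hits$ref_start[flip] <- hits$ref_end[flip]
    hits$ref_end[flip] <- tmp
    hits$strand[flip] <- "+"
  }
  hits
}

#' Tabulate alignment lengths
#'
#' Histogram of the aligned lengths of a sample's best hits; the modal
#' length identifies the dominant transcript species.
#'
#' @param hits Best-hit tibble (see [best_hit()]).
#' @return A `length_tabulation` tibble `aligned_length`, `n`, with the
#'   modal length in the `modal_length` attribute (smallest on ties; `NA`
#'   for empty input).
#' @export
tabulate_lengths <- function(hits) {
  out <- hits %>%
    count(.data$aligned_length) %>%
    arrange(.data$aligned_length)
  modal <- if (nrow(out) == 0) NA_integer_ else {
    out$aligned_length[which.max(out$n)]
  }
  class(out) <- c("length_tabulation", class(out))
  attr(out, "modal_length") <- modal
  out
}

#' @export
autoplot.length_tabulation <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$aligned_length, y = .data$n)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "alignment length (nt)", y = "reads")
}

#' Shortest unique prefix of a query in a genome set
#'
#' Scans query prefixes of increasing length and returns the length of the
#' shortest prefix with no exact occurrence (on either strand) in any
#' provided genome -- the point from which the query is unique. Returns 0 if
#' the entire query occurs verbatim (no prefix is unique), and the full
#' query length, with a warning, for an empty genome set. Intended for toy
#' genomes, not genome-scale screens.
#'
#' @param query DNA string.
#' @param genomes Character vector of genome sequences.
#' @return Integer prefix length (0 if the whole query occurs).
#' @export
uniqueness_scan <- function(query, genomes) {
  if (!nzchar(query)) abort("`query` must be non-empty")
  query <- toupper(query)
  if (length(genomes) == 0) {
    warn("empty genome set: every prefix is trivially unique")
    return(nchar(query))
  }
  texts <- c(toupper(genomes), revcomp(toupper(genomes)))
  for (l in seq_len(nchar(query))) {
    prefix <- substr(query, 1, l)
    if (!any(vapply(texts, function(t) grepl(prefix, t, fixed = TRUE), TRUE))) {
      return(l)
    }
  }
  0L
}
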