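# Per-cell ISH dot counting and 4-tier semi-quantitative scoring. In each
# field the total nucleus count T and the surfactant-B-positive count S
# partition cells into AETII (S) and non-AETII (T - S). Dots are attributed
# to the nearest nucleus; the AETII mean is AETII dots / S and the non-AETII
# mean is the pooled remainder, (assigned dots - AETII dots) / (T - S).

#' Assign ISH dots to nuclei
#'
#' Each dot is assigned to the nearest nucleus within `max_radius`; ties are
#' broken by the lower nucleus index. Dots farther than `max_radius` from
#' every nucleus remain unassigned (`cell_id = NA`) and do not enter any
#' average. The default radius (10 um) is on the order of an alveolar cell
#' radius and stands in for manual attribution.
#'
#' @param field A `cell_field` (see [make_cell_field()]), or a list with
#'   tibbles `nuclei` (`cell_id`, `x`, `y`, `surfactant_positive`) and `dots`
#'   (`x`, `y`).
#' @param max_radius Maximum dot-to-nucleus distance, um (> 0).
#' @return The field with a `cell_id` column added to `dots`.
#' @export
assign_dots <- function(field, max_radius = 10) {
  check_number(max_radius, "max_radius", min = .Machine$double.eps)
  nuc <- field$nuclei
  dots <- field$dots
  if (nrow(dots) == 0) {
    field$dots$cell_id <- integer(0)
    return(field)
  }
  if (nrow(nuc) == 0) {
    field$dots$cell_id <- NA_integer_
    return(field)
  }
  # distance matrix dots x nuclei; nearest within radius, ties -> lower index
  d2 <- outer(dots$x, nuc$x, "-")^2 + outer(dots$y, nuc$y, "-")^2
  nearest <- apply(d2, 1, which.min) # which.min takes the first (lowest index) on ties
  dist <- sqrt(d2[cbind(seq_len(nrow(dots)), nearest)])
  field$dots$cell_id <- ifelse(dist <= max_radius, nuc$cell_id[nearest], NA_integer_)
  field
}

#' Mean dots per cell by cell type
#'
#' Computes the AETII mean as AETII dots / S and the non-AETII mean with the
#' pooled-remainder formula: (total assigned dots - AETII dots) / (T - S).
#' Degenerate partitions yield `NA` with a warning: S = 0 leaves the AETII
#' mean undefined, T = S the non-AETII mean.
#'
#' @param field A `cell_field` whose dots carry `cell_id` assignments (run
#'   [assign_dots()] first; fields with a `true_cell_id` and no `cell_id`
#'   are not accepted, so estimates stay separate from generator truth).
#' @return One-row tibble: `t_cells`, `s_cells`, `aetii_dots`,
#'   `assigned_dots`, `aetii_mean`, `non_aetii_mean`.
#' @export
type_averages <- function(field) {
  nuc <- field$nuclei
  dots <- field$dots
  if (nrow(nuc) == 0) abort("field has no nuclei (T = 0)")
  if (!"cell_id" %in% names(dots)) {
    abort("dots carry no assignments; run assign_dots() first")
  }
  t_cells <- nrow(nuc)
  s_cells <- sum(nuc$surfactant_positive)
  aetii_ids <- nuc$cell_id[nuc$surfactant_positive]
  assigned <- dots$cell_id[!is.na(dots$cell_id)]
  aetii_dots <- sum(assigned %in% aetii_ids)
  total_assigned <- length(assigned)

  aetii_mean <- if (s_cells == 0) {
    warn("S = 0: AETII mean undefined")
    NA_real_
  } else {
    aetii_dots / s_cells
  }
  non_mean <- if (t_cells == s_cells) {
    warn("T = S: non-AETII mean undefined")
    NA_real_
  } else {
    (total_assigned - aetii_dots) / (t_cells - s_cells)
  }

  tibble(
    t_cells = t_cells, s_cells = s_cells,
    aetii_dots = aetii_dots, assigned_dots = total_assigned,
    aetii_mean = aetii_mean, non_aetii_mean = non_mean
  )
}

#' 4-tier ISH expression score
#'
#' Assigns the semi-quantitative tier used for RNAScope-style evaluation:
#' 0 = no spots, 1 = few spots (up to `few_cutoff`), 2 = moderate (more than
#' `few_cutoff`, at most 10), 3 = high (more than 10 spots per cell). A mean
#' of exactly 10 is moderate, keeping tier 3 strictly "> 10". The boundary
#' between "few" and "moderate" is not fixed by the published rule;
#' `few_cutoff = 3` is this package's default and is configurable. Fractional
#' means are never rounded before scoring.
#'
#' @param mean_dots Mean spots per cell (vectorised, non-negative).
#' @param few_cutoff Upper bound of tier 1, exclusive lower bound of tier 2.
#' @return Integer tier(s) in 0--3.
#' @export
assign_tier <- function(mean_dots, few_cutoff = 3) {
  if (any(is.na(mean_dots)) || any(mean_dots < 0)) {
    abort("`mean_dots` must be non-negative")
  }
  check_number(few_cutoff, "few_cutoff", min = 0, max = 10)
  ifelse(mean_dots == 0, 0L,
    ifelse(mean_dots > 10, 3L,
      ifelse(mean_dots > few_cutoff, 2L, 1L)
    )
  )
}

#' Marker purity percentage
#'
#' Percentage of marker-positive cells among all counted nuclei, rounded to
#' the nearest integer percent, as used to report the purity of an isolated
#' cell preparation.
#'
#' @param positive Number of marker-positive cells.
#' @param total Total number of nuclei (> 0).
#' @return Integer percentage.
#' @export
purity_percent <- function(positive, total) {
  check_number(positive, "positive", min = 0, integerish = TRUE)
  check_number(total, "total", min = 1, integerish = TRUE)
  if (positive > total) abort("`positive` cannot exceed `total`")
  as.integer(round(100 * positive / total))
}

#' Fraction of AETII cells without any dot
#'
#' Share of surfactant-positive cells with zero assigned dots, the readout
#' that marks exhaustion of expression in chronically exposed lungs.
#'
#' @param field A `cell_field` with dot assignments.
#' @return Fraction in \[0, 1\].
#' @export
zero_dot_fraction <- function(field) {
  nuc <- field$nuclei
  if (!"cell_id" %in% names(field$dots)) {
    abort("dots carry no assignments; run assign_dots() first")
  }
  aetii_ids <- nuc$cell_id[nuc$surfactant_positive]
  if (length(aetii_ids) == 0) abort("S = 0: no AETII cells in field")
  with_dots <- unique(field$dots$cell_id)
  sum(!(aetii_ids %in% with_dots)) / length(aetii_ids)
}

#' Score a cell field
#'
#' Runs the full per-field pipeline: dot assignment, type averages, tier
#' assignment, zero-dot fraction, and the field's surfactant-marker
#' percentage.
#'
#' @inheritParams assign_dots
#' @inheritParams assign_tier
#' @return One-row `score_report` tibble: `field_id`, `t_cells`, `s_cells`,
#'   `aetii_mean_dots`, `non_aetii_mean_dots`, `aetii_tier`,
#'   `non_aetii_tier`, `fraction_zero_aetii`, `purity_percent`,
#'   `unassigned_dots`.
#' @export
score_field <- function(field, max_radius = 10, few_cutoff = 3) {
  field <- assign_dots(field, max_radius = max_radius)
  av <- type_averages(field)
  out <- tibble(
    field_id = field$field_id %||% "field",
    t_cells = av$t_cells,
    s_cells = av$s_cells,
    aetii_mean_dots = av$aetii_mean,
    non_aetii_mean_dots = av$non_aetii_mean,
    aetii_tier = if (is.na(av$aetii_mean)) NA_integer_ else assign_tier(av$aetii_mean, few_cutoff),
    non_aetii_tier = if (is.na(av$non_aetii_mean)) NA_integer_ else assign_tier(av$non_aetii_mean, few_cutoff),
    fraction_zero_aetii = if (av$s_cells > 0) zero_dot_fraction(field) else NA_real_,
    purity_percent = purity_percent(av$s_cells, av$t_cells),
    unassigned_dots = sum(is.na(field$dots$cell_id))
  )
  class(out) <- c("score_report", class(out))
  out
}
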