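# Mito stress test parameter derivation. A trace of oxygen consumption rate
# (OCR) readings spans four phases -- basal, post-oligomycin, post-FCCP and
# post-rotenone/antimycin A. Non-mitochondrial respiration (the mean of the
# last k post-rotenone/antimycin readings) is subtracted from every phase
# mean to give basal respiration, proton leak and maximal respiration; ATP
# production = basal - leak and spare capacity = maximal - basal follow by
# construction. Coupling efficiency is implemented exactly as the source
# formula states it, 100 * ATP production / non-mitochondrial respiration;
# the conventional definition (divide by basal respiration) is available via
# `coupling_definition = "conventional"`.

#' Phase mean of an OCR trace
#'
#' Arithmetic mean of the first or last `k` readings of one phase.
#'
#' @param trace An `ocr_trace` tibble (`time_min`, `ocr`, `phase`; see
#'   [make_ocr_trace()] for the layout).
#' @param phase One of `"basal"`, `"post_oligomycin"`, `"post_fccp"`,
#'   `"post_rotaa"`.
#' @param which Take the first or the last `k` readings of the phase.
#' @param k Number of readings to average (default 3).
#' @return Mean OCR, pmol O2/min.
#' @export
phase_mean <- function(trace, phase, which = c("first_k", "last_k"), k = 3) {
  which <- match.arg(which)
  phase <- match.arg(phase, ocr_phases())
  check_number(k, "k", min = 1, integerish = TRUE)
  v <- trace$ocr[trace$phase == phase][order(trace$time_min[trace$phase == phase])]
  if (length(v) < k) {
    abort(sprintf("phase '%s' has %d readings, fewer than k = %d", phase, length(v), k))
  }
  sel <- if (which == "first_k") utils::head(v, k) else utils::tail(v, k)
  mean(sel)
}

#' Derive mito stress test parameters from an OCR trace
#'
#' Applies the phase-average formulas: with `nm` the mean of the last `k`
#' post-rotenone/antimycin readings,
#' basal = mean(first k basal) - nm;
#' proton leak = mean(first k post-oligomycin) - nm;
#' ATP production = basal - leak;
#' maximal = mean(first k post-FCCP) - nm;
#' spare capacity = maximal - basal;
#' coupling efficiency = 100 * ATP / nm (source definition) or
#' 100 * ATP / basal (conventional).
#'
#' @param trace An `ocr_trace` tibble; multiple wells are processed per
#'   `well_id`.
#' @param k Readings averaged per phase.
#' @param normalize_protein Divide every rate parameter by the well's
#'   `protein_ug` (coupling efficiency, a percentage, is unaffected).
#' @param coupling_definition `"paper"` (ATP / non-mitochondrial, as the
#'   source formula prints) or `"conventional"` (ATP / basal).
#' @return A `bioenergetics_params` tibble, one row per well: `well_id`,
#'   `basal`, `proton_leak`, `atp_production`, `maximal`, `spare_capacity`,
#'   `non_mito`, `coupling_efficiency`. `tidy()` pivots to long form;
#'   `glance()` gives across-well means and standard errors.
#' @export
derive_params <- function(trace, k = 3, normalize_protein = FALSE,
                          coupling_definition = c("paper", "conventional")) {
  coupling_definition <- match.arg(coupling_definition)
  if (!"well_id" %in% names(trace)) trace$well_id <- "well"

  one_well <- function(tr) {
    nm <- phase_mean(tr, "post_rotaa", "last_k", k)
    basal <- phase_mean(tr, "basal", "first_k", k) - nm
    leak <- phase_mean(tr, "post_oligomycin", "first_k", k) - nm
    atp <- basal - leak
    maximal <- phase_mean(tr, "post_fccp", "first_k", k) - nm
    spare <- maximal - basal
    denom <- if (coupling_definition == "paper") nm else basal
    if (denom == 0) {
      abort("division by zero in coupling efficiency denominator")
    }
    coupling <- 100 * atp / denom
    protein <- tr$protein_ug[1] %||% 1
    scale <- if (normalize_protein) {
      if (is.null(protein) || protein <= 0) abort("protein must be positive to normalize")
      protein
    } else {
      1
    }
    tibble(
      well_id = tr$well_id[1],
      basal = basal / scale, proton_leak = leak / scale,
      atp_production = atp / scale, maximal = maximal / scale,
      spare_capacity = spare / scale, non_mito = nm / scale,
      coupling_efficiency = coupling
    )
  }

  out <- trace %>%
    as_tibble() %>%
    dplyr::group_split(.data$well_id) %>%
    map(one_well) %>%
    list_rbind()
  class(out) <- c("bioenergetics_params", class(out))
  attr(out, "coupling_definition") <- coupling_definition
  out
}

#' @rdname derive_params
#' @param x,object A `bioenergetics_params` table.
#' @param ... Unused.
#' @export
tidy.bioenergetics_params <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x),
    cols = -"well_id", names_to = "parameter", values_to = "value"
  )
}

#' @rdname derive_params
#' @export
glance.bioenergetics_params <- function(x, ...) {
  tidy(x) %>%
    group_by(.data$parameter) %>%
    summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(n()),
      n_wells = n(),
      .groups = "drop"
    )
}

#' @export
autoplot.ocr_trace <- function(object, ...) {
  inj <- attr(object, "injections")
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$time_min, y = .data$ocr, colour = .data$phase,
                 group = .data$well_id)
  ) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time (min)", y = "OCR (pmol O2/min)", colour = "phase")
  if (!is.null(inj)) {
    p <- p + ggplot2::geom_vline(
      xintercept = inj$after_time_min, linetype = "dashed", colour = "grey40"
    )
  }
  p
}
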