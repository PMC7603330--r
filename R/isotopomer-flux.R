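# 13C mass-isotopomer flux arithmetic. Molar percent enrichment (MPE) of a
# metabolite is the labeled share of its isotopomer intensities -- for
# glucose monitored as M0-M5, MPE = M5 / sum(M0..M5). Fractional metabolic
# flux is MPE_product / MPE_precursor, and absolute flux is fractional flux
# times the metabolite's pool size (relative concentration against an
# internal standard).

#' Isotopic enrichment of an intensity vector
#'
#' Ratio of the labeled isotopomer intensities to the total. For glucose the
#' labeled set is the M5 bin (`labeled_set = 5`); for multi-carbon TCA
#' metabolites the default counts every bin M1 and above as labeled.
#'
#' @param intensities Numeric vector of isotopomer intensities `M0..Mn`
#'   (non-negative, not all zero).
#' @param labeled_set Mass indices (1-based label count, i.e. `5` means M5)
#'   counted as labeled; default all of `1..n`.
#' @return Enrichment fraction in \[0, 1\].
#' @export
enrichment <- function(intensities, labeled_set = NULL) {
  if (any(intensities < 0)) abort("intensities must be non-negative")
  total <- sum(intensities)
  if (total <= 0) abort("no signal: all-zero intensity vector")
  n <- length(intensities) - 1
  if (is.null(labeled_set)) labeled_set <- seq_len(n)
  if (length(labeled_set) > 0 && (min(labeled_set) < 1 || max(labeled_set) > n)) {
    abort("`labeled_set` must be a subset of 1..n")
  }
  sum(intensities[labeled_set + 1]) / total
}

#' Fractional metabolic flux
#'
#' `MPE_product / MPE_precursor`. Values above 1 are physically suspicious
#' (a product cannot be more enriched than its precursor without another
#' labeled source) and raise a warning rather than an error, since
#' measurement noise can produce them.
#'
#' @param mpe_product,mpe_precursor Enrichment fractions; the precursor MPE
#'   must be positive.
#' @return Dimensionless fractional flux.
#' @export
fractional_flux <- function(mpe_product, mpe_precursor) {
  if (any(mpe_precursor == 0)) abort("unlabeled precursor: MPE_precursor = 0")
  out <- mpe_product / mpe_precursor
  if (any(out > 1)) warn("fractional flux > 1: product more enriched than precursor")
  out
}

#' Absolute metabolic flux
#'
#' Product of fractional flux and pool size; carries the pool-size units
#' (relative concentration).
#'
#' @param fractional Fractional flux (>= 0).
#' @param pool_size Relative concentration (>= 0).
#' @return Absolute flux.
#' @export
absolute_flux <- function(fractional, pool_size) {
  if (any(pool_size < 0)) abort("pool size must be non-negative")
  fractional * pool_size
}

#' Pool size from an internal standard
#'
#' Relative concentration of a metabolite as the ratio of its signal to the
#' co-injected internal standard's signal.
#'
#' @param metabolite_signal,internal_standard_signal Signals in arbitrary
#'   units; the standard must be positive.
#' @return Relative concentration.
#' @export
pool_size_from_standard <- function(metabolite_signal, internal_standard_signal) {
  if (any(internal_standard_signal <= 0)) abort("internal standard signal must be positive")
  metabolite_signal / internal_standard_signal
}

#' Pathway group of each monitored metabolite
#'
#' @return Tibble `metabolite`, `group` mapping the monitored metabolites to
#'   glycolysis, TCA-cycle, or amino-acid-turnover panels.
#' @export
metabolite_groups <- function() {
  tibble(
    metabolite = c(
      "pyruvate", "lactate", "serine",
      "citrate", "alpha_ketoglutarate", "succinate", "fumarate", "malate",
      "oxaloacetate",
      "alanine", "aspartate", "glutamate"
    ),
    group = rep(c("glycolysis", "tca", "amino_acid"), c(3, 6, 3))
  )
}

#' MPE, fractional and absolute flux for a whole isotopomer panel
#'
#' Computes each product metabolite's MPE (labeled set: all bins M1 and
#' above, unless supplied per metabolite), divides by the precursor MPE
#' (glucose by default, labeled set M5), and multiplies by the pool size to
#' give the absolute flux. Metabolites are tagged with their pathway group.
#'
#' @param panel Long-format `isotopomer_panel` tibble with columns
#'   `metabolite`, `mass_index`, `intensity`, `pool_size`, `role` (see
#'   [make_isotopomer_panel()]), or the same columns read from CSV.
#' @param precursor Precursor metabolite name (default `"glucose"`).
#' @param labeled_sets Optional named list of labeled-set vectors per
#'   metabolite; the precursor defaults to its top bin, products to all M>=1.
#' @param na_correct Apply natural-abundance 13C correction to each
#'   metabolite's intensity vector before computing MPE (off by default; the
#'   printed formulas operate on uncorrected intensities).
#' @return A `flux_result` tibble: `metabolite`, `group`, `mpe`,
#'   `fractional_flux`, `pool_size`, `absolute_flux`, plus the precursor MPE
#'   in the `precursor_mpe` attribute.
#' @export
run_flux_panel <- function(panel, precursor = "glucose", labeled_sets = NULL,
                           na_correct = FALSE) {
  need <- c("metabolite", "mass_index", "intensity", "pool_size")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("panel lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  mets <- unique(panel$metabolite)
  if (!precursor %in% mets) abort(sprintf("precursor '%s' not in panel", precursor))

  vec_of <- function(m) {
    p <- panel[panel$metabolite == m, ]
    p <- p[order(p$mass_index), ]
    v <- p$intensity
    if (na_correct) v <- correct_natural_abundance(v)
    v
  }
  set_of <- function(m, n) {
    if (!is.null(labeled_sets) && !is.null(labeled_sets[[m]])) {
      labeled_sets[[m]]
    } else if (m == precursor) {
      n # top bin only, e.g. M5 of glucose
    } else {
      seq_len(n)
    }
  }

  pre_v <- vec_of(precursor)
  mpe_pre <- enrichment(pre_v, set_of(precursor, length(pre_v) - 1))
  if (mpe_pre == 0) abort("unlabeled precursor: MPE_precursor = 0")

  products <- setdiff(mets, precursor)
  out <- map(products, function(m) {
    v <- vec_of(m)
    mpe <- enrichment(v, set_of(m, length(v) - 1))
    pool <- panel$pool_size[panel$metabolite == m][1]
    frac <- fractional_flux(mpe, mpe_pre)
    tibble(
      metabolite = m, mpe = mpe, fractional_flux = frac,
      pool_size = pool, absolute_flux = absolute_flux(frac, pool)
    )
  }) %>%
    list_rbind() %>%
    left_join(metabolite_groups(), by = "metabolite") %>%
    select("metabolite", "group", "mpe", "fractional_flux", "pool_size",
           "absolute_flux")
  class(out) <- c("flux_result", class(out))
  attr(out, "precursor_mpe") <- mpe_pre
  out
}

#' Natural-abundance 13C correction of an isotopomer vector
#'
#' Deconvolves the contribution of naturally occurring 13C (1.07% per carbon
#' of the metabolite skeleton) from an observed `M0..Mn` intensity vector by
#' inverting the binomial mixing matrix. Correction applies to the carbon
#' skeleton only (derivatization atoms are not modelled) and is an optional
#' pre-step, off by default in [run_flux_panel()].
#'
#' @param intensities Observed `M0..Mn` vector.
#' @param p13 Natural 13C abundance per carbon.
#' @return Corrected intensity vector (negative solutions clipped to zero).
#' @export
correct_natural_abundance <- function(intensities, p13 = 0.0107) {
  n <- length(intensities) - 1
  if (n < 1) return(intensities)
  cm <- matrix(0, n + 1, n + 1)
  for (t in 0:n) { # true label count t, observed o >= t
    for (o in t:n) {
      cm[o + 1, t + 1] <- dbinom(o - t, n - t, p13)
    }
  }
  out <- solve(cm, intensities)
  pmax(out, 0)
}

#' @export
autoplot.flux_result <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$metabolite, y = .data$absolute_flux,
                 fill = .data$group)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "absolute flux (pool-size units)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
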