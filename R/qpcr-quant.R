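# Relative quantification by the Livak 2^-ddCt method, mitochondrial DNA
# copy-number ratios, and symmetric fold-change filtering of expression
# arrays. Folds below 1 are reported as fractions, never negative folds;
# direction (up/down) is a separate annotation.

#' 2^-ddCt fold change
#'
#' Livak relative quantification: per sample, dCt = target Ct - reference
#' Ct; dCt values are averaged per group before differencing (ddCt =
#' mean dCt treated - mean dCt control), and the fold change is 2^-ddCt.
#'
#' @param ct_data Tibble with columns `group` (values `"control"` and
#'   `"treated"`), `target_ct`, `reference_ct`; e.g. from [make_ct_table()].
#' @param per_replicate Also return per-replicate folds (each treated
#'   replicate's dCt against the control-group mean dCt).
#' @return One-row tibble `dct_control`, `dct_treated`, `ddct`, `fold`,
#'   `direction`; with `per_replicate = TRUE`, a `replicates` attribute
#'   carries the per-replicate folds.
#' @export
ddct_fold <- function(ct_data, per_replicate = FALSE) {
  need <- c("group", "target_ct", "reference_ct")
  if (!all(need %in% names(ct_data))) {
    abort("ct_data needs columns group, target_ct, reference_ct")
  }
  if (anyNA(ct_data$target_ct) || anyNA(ct_data$reference_ct)) {
    abort("missing Ct value")
  }
  if (!all(c("control", "treated") %in% ct_data$group)) {
    abort("ct_data must contain both a control and a treated group")
  }
  dct <- ct_data$target_ct - ct_data$reference_ct
  dct_c <- mean(dct[ct_data$group == "control"])
  dct_t <- mean(dct[ct_data$group == "treated"])
  ddct <- dct_t - dct_c
  fold <- 2^(-ddct)
  out <- tibble(
    dct_control = dct_c, dct_treated = dct_t, ddct = ddct, fold = fold,
    direction = ifelse(fold >= 1, "up", "down")
  )
  if (per_replicate) {
    attr(out, "replicates") <- tibble(
      sample = ct_data$sample[ct_data$group == "treated"] %||%
        seq_len(sum(ct_data$group == "treated")),
      fold = 2^(-(dct[ct_data$group == "treated"] - dct_c))
    )
  }
  out
}

#' Relative mitochondrial DNA copy number
#'
#' Ratio of mitochondrial to nuclear DNA by qPCR, normalised so the control
#' ratio is 1: with dCt = Ct_mito - Ct_nuclear, the relative copy number of
#' a sample is 2^-(dCt_sample - dCt_control).
#'
#' @param ct_mito,ct_nuclear Sample Ct values (vectorised).
#' @param control_ct_mito,control_ct_nuclear Control Ct values.
#' @return Relative copy number (control = 1).
#' @export
copy_number_ratio <- function(ct_mito, ct_nuclear,
                              control_ct_mito, control_ct_nuclear) {
  vals <- list(ct_mito, ct_nuclear, control_ct_mito, control_ct_nuclear)
  if (any(vapply(vals, anyNA, TRUE)) || any(vapply(vals, length, 1L) == 0)) {
    abort("missing Ct value")
  }
  dct_s <- ct_mito - ct_nuclear
  dct_c <- mean(control_ct_mito - control_ct_nuclear)
  2^(-(dct_s - dct_c))
}

#' Filter genes by fold change
#'
#' Keeps genes whose fold change passes the threshold symmetrically in
#' log2 space: `|log2(fold)| >= log2(threshold)`, so a 1.7-fold increase and
#' a 1/1.7 decrease filter identically. Each kept gene is annotated with its
#' direction.
#'
#' @param fold_table Tibble with columns `gene` and `fold` (positive folds;
#'   decreases expressed as fractions), or a named numeric vector.
#' @param threshold Fold-change threshold (> 1), default 1.7.
#' @return Tibble `gene`, `fold`, `log2_fold`, `direction` of the genes
#'   passing the filter.
#' @export
fold_change_filter <- function(fold_table, threshold = 1.7) {
  if (is.numeric(fold_table) && !is.data.frame(fold_table)) {
    fold_table <- tibble(gene = names(fold_table), fold = unname(fold_table))
  }
  if (!all(c("gene", "fold") %in% names(fold_table))) {
    abort("fold_table needs columns gene and fold")
  }
  if (!(threshold > 1)) abort("`threshold` must be > 1")
  if (any(fold_table$fold <= 0)) abort("folds must be positive")
  fold_table %>%
    as_tibble() %>%
    mutate(log2_fold = log2(.data$fold)) %>%
    filter(abs(.data$log2_fold) >= log2(threshold)) %>%
    mutate(direction = ifelse(.data$log2_fold > 0, "up", "down"))
}
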