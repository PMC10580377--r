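# Per-variant binary-classification metrics and locus-level concordance.

#' Confusion counts for per-variant kataegis labels
#'
#' @param truth,predicted Logical vectors of equal length, aligned by
#'   variant: is the variant inside a (true / called) kataegis locus?
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  tibble(
    tp = sum(truth & predicted),
    fp = sum(!truth & predicted),
    tn = sum(!truth & !predicted),
    fn = sum(truth & !predicted)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, Matthews correlation coefficient (MCC), normalised MCC
#' (`(MCC + 1) / 2`), F1, true-positive rate and true-negative rate. When
#' any factor of the MCC denominator is zero, MCC is defined as 0 (nMCC
#' 0.5).
#'
#' @param cm A one-row tibble/data frame (or named list) with `tp`, `fp`,
#'   `tn`, `fn`.
#' @return A one-row tibble: `accuracy`, `mcc`, `nmcc`, `f1`, `tpr`, `tnr`.
#' @examples
#' classification_metrics(list(tp = 45, fp = 5, tn = 940, fn = 10))
#' @export
classification_metrics <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  total <- tp + fp + tn + fn
  if (any(total == 0)) abort("Empty confusion matrix.")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
  tibble(
    accuracy = (tp + tn) / total,
    mcc = mcc,
    nmcc = (mcc + 1) / 2,
    f1 = ifelse(tp + (fp + fn) / 2 == 0, 0, tp / (tp + (fp + fn) / 2)),
    tpr = ifelse(tp + fn == 0, NA_real_, tp / (tp + fn)),
    tnr = ifelse(tn + fp == 0, NA_real_, tn / (tn + fp))
  )
}

#' Evaluate a detection result against a labelled sample
#'
#' Variants are matched positionally (chromosome, start); the prediction for
#' a variant is whether it lies inside any called locus.
#'
#' @param sim A `kataegis_sim` (or any variant tibble with a logical
#'   `in_locus` truth column).
#' @param result A `katdetect` from [detect_kataegis()].
#' @return A one-row confusion tibble (see [confusion_counts()]).
#' @export
evaluate_sample <- function(sim, result) {
  truth_tbl <- if (inherits(sim, "kataegis_sim")) sim$variants else sim
  if (!"in_locus" %in% names(truth_tbl)) {
    abort("Truth table lacks the logical `in_locus` column.")
  }
  pred_tbl <- result$variants
  m <- dplyr::left_join(
    truth_tbl[, c("chromosome", "start", "in_locus")],
    pred_tbl[, c("chromosome", "start", "in_kataegis")],
    by = c("chromosome", "start")
  )
  m$in_kataegis[is.na(m$in_kataegis)] <- FALSE
  confusion_counts(m$in_locus, m$in_kataegis)
}

#' Pool per-sample confusion counts by TMB class
#'
#' Confusion matrices are summed elementwise within each TMB class and over
#' all samples, and metrics computed on the pooled counts.
#'
#' @param confusions A tibble with one row per sample holding `tmb`, `tp`,
#'   `fp`, `tn`, `fn`.
#' @return A tibble with one row per TMB class plus an `overall` row;
#'   columns `tmb` (character), pooled counts and the metric set.
#' @export
evaluate_by_tmb <- function(confusions) {
  pool <- function(x, label) {
    cm <- summarise(x, tp = sum(.data$tp), fp = sum(.data$fp),
                    tn = sum(.data$tn), fn = sum(.data$fn))
    bind_cols(tibble(tmb = label, n_samples = nrow(x)), cm,
              classification_metrics(cm))
  }
  per_class <- confusions |>
    group_by(.data$tmb) |>
    group_map(~ pool(.x, as.character(.y$tmb))) |>
    bind_rows()
  bind_rows(per_class, pool(confusions, "overall"))
}

#' Match loci between two call sets by 1-bp overlap
#'
#' A locus in `loci_a` is matched when some locus in `loci_b` on the same
#' chromosome overlaps it by at least one base pair; intervals that merely
#' abut (no shared base) do not match.
#'
#' @param loci_a,loci_b Loci tibbles with `chromosome`, `genomic_start`,
#'   `genomic_end`.
#' @return `loci_a` with a logical `matched` column.
#' @export
locus_concordance <- function(loci_a, loci_b) {
  matched <- vapply(seq_len(nrow(loci_a)), function(i) {
    any(loci_b$chromosome == loci_a$chromosome[i] &
          loci_b$genomic_start <= loci_a$genomic_end[i] &
          loci_b$genomic_end >= loci_a$genomic_start[i])
  }, logical(1))
  loci_a$matched <- matched
  loci_a
}
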