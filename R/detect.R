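# The end-to-end detector: variants -> IMD -> changepoints -> segments ->
# kataegis loci, per chromosome, for a single sample.

#' Detect kataegis loci in a sample
#'
#' Runs the full workflow on one sample's variant calls: per chromosome the
#' intermutation distances (plus the closing pseudo-IMD) are segmented by
#' penalized changepoint detection under an exponential model, segments are
#' annotated with genomic bounds, variant counts, mean IMD and mutation
#' rate, and maximal runs of qualifying segments are merged into kataegis
#' loci. Defaults follow the common operational definition of kataegis:
#' segments of at least 6 variants with mean IMD of at most 1,000 bp, found
#' with PELT, exponential cost, BIC penalty and minimal segment length 2.
#'
#' Chromosomes whose IMD sequence is shorter than `2 * min_seg_len` skip
#' changepoint analysis and form a single segment. A pseudo-IMD of 0 (last
#' variant on the chromosome's final base) is replaced by 1 during
#' segmentation so the exponential cost stays defined.
#'
#' @param variants Variant tibble (see [read_variants()]); a single sample.
#' @param chromosome_lengths Named numeric vector or tibble
#'   (`chromosome`, `length`).
#' @param imd_cutoff Maximal mean IMD (bp) of a qualifying segment (default
#'   1000), `"pcawg"` for the sample-adaptive cutoff, or a
#'   `function(segments, summary)` returning per-segment cutoffs.
#' @param min_size_kataegis Minimal variants per qualifying segment
#'   (default 6).
#' @param method Changepoint search algorithm (default `"pelt"`).
#' @param penalty `"bic"` or a positive number.
#' @param min_seg_len Minimal observations per segment (default 2).
#' @param max_segments Optional segment budget for `"binseg"`/`"segneigh"`.
#' @param preprocess If `TRUE` (default), sort and merge overlapping records
#'   first via [preprocess_variants()].
#' @return A `katdetect` object: list with tibbles `loci`, `segments`,
#'   `variants` (input plus `imd` and logical `in_kataegis`), the one-row
#'   `rates` summary, and `params`.
#' @examples
#' sim <- simulate_sample(tmb = 0, n_loci = 1, variants_per_locus = 10,
#'                        expected_imd = 100, chromosome_length = 1e6,
#'                        seed = 1)
#' kd <- detect_kataegis(sim$variants, c("1" = 1e6))
#' tidy(kd)
#' @export
detect_kataegis <- function(variants, chromosome_lengths,
                            imd_cutoff = 1000, min_size_kataegis = 6,
                            method = "pelt", penalty = "bic",
                            min_seg_len = 2L, max_segments = NULL,
                            preprocess = TRUE) {
  lens <- as_chromosome_lengths(chromosome_lengths)
  variants <- assert_variant_tbl(variants)
  if (length(unique(variants$sample_id[!is.na(variants$sample_id)])) > 1) {
    abort("`variants` holds multiple samples; detect one sample at a time.")
  }
  if (isTRUE(preprocess)) {
    variants <- preprocess_variants(variants, lens)
  } else {
    variants$chromosome <- normalize_chromosomes(variants$chromosome,
                                                 names(lens))
  }
  params <- list(
    imd_cutoff = imd_cutoff, min_size_kataegis = min_size_kataegis,
    method = method, penalty = penalty, min_seg_len = as.integer(min_seg_len),
    max_segments = max_segments
  )
  if (nrow(variants) == 0) {
    warn("No variants in sample; returning an empty result.")
    return(new_katdetect(empty_loci(), empty_segments(),
                         mutate(variants, imd = numeric(0),
                                in_kataegis = logical(0)),
                         sample_rate_summary(empty_segments(),
                                             sum(lens)), params))
  }
  chroms <- unique(variants$chromosome)
  imd_all <- vector("list", length(chroms))
  seg_all <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    pos <- variants$start[variants$chromosome == ch]
    imd <- compute_imd(pos, lens[[ch]])
    obs <- imd$imd
    obs[length(obs)] <- max(obs[length(obs)], 1)  # zero pseudo-IMD guard
    n_obs <- length(obs)
    if (n_obs < 2 * min_seg_len) {
      cps <- n_obs
    } else {
      cps <- cpt_exponential(obs, method = method, penalty = penalty,
                             min_seg_len = min_seg_len,
                             max_segments = max_segments)$changepoints
    }
    seg_all[[i]] <- annotate_segments(imd, cps, chromosome = ch,
                                      chromosome_length = lens[[ch]])
    imd_all[[i]] <- mutate(imd[!imd$pseudo, c("position", "imd")],
                           chromosome = ch)
  }
  segments <- bind_rows(seg_all)
  imd_tbl <- bind_rows(imd_all)
  summary <- sample_rate_summary(segments, sum(lens),
                                 median_imd = median(imd_tbl$imd))
  loci <- call_kataegis(segments, summary, imd_cutoff = imd_cutoff,
                        min_size_kataegis = min_size_kataegis)
  variants <- variants |>
    left_join(imd_tbl, by = c("chromosome", "start" = "position"))
  variants$in_kataegis <- flag_in_loci(variants, loci)
  new_katdetect(loci, segments, variants, summary, params)
}

flag_in_loci <- function(variants, loci) {
  flag <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(loci))) {
    flag <- flag | (variants$chromosome == loci$chromosome[i] &
                      variants$start >= loci$genomic_start[i] &
                      variants$start <= loci$genomic_end[i])
  }
  flag
}

empty_loci <- function() {
  tibble(chromosome = character(), locus = integer(),
         genomic_start = numeric(), genomic_end = numeric(),
         variant_count = integer(), mean_imd = numeric(),
         n_segments = integer())
}

empty_segments <- function() {
  tibble(chromosome = character(), segment = integer(),
         first_index = integer(), last_index = integer(),
         genomic_start = numeric(), genomic_end = numeric(),
         first_variant_pos = numeric(), last_variant_pos = numeric(),
         variant_count = integer(), length_bp = numeric(),
         imd_sum = numeric(), mean_imd = numeric(), rate = numeric())
}

new_katdetect <- function(loci, segments, variants, rates, params) {
  structure(
    list(loci = loci, segments = segments, variants = variants,
         rates = rates, params = params),
    class = "katdetect"
  )
}

#' @export
print.katdetect <- function(x, ...) {
  cat("<katdetect>\n")
  cat(sprintf("  variants: %d on %d chromosome(s)\n", nrow(x$variants),
              length(unique(x$variants$chromosome))))
  cat(sprintf("  segments: %d\n", nrow(x$segments)))
  cat(sprintf("  kataegis loci: %d (%d variants flagged)\n", nrow(x$loci),
              sum(x$variants$in_kataegis)))
  invisible(x)
}

#' @export
summary.katdetect <- function(object, ...) {
  print(object)
  if (nrow(object$loci) > 0) print(object$loci)
  invisible(object)
}

#' Tidy a kataegis detection result
#'
#' `tidy()` returns the called loci, one row per locus; `glance()` returns a
#' one-row summary of the whole sample.
#'
#' @param x A `katdetect` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy katdetect
#' @export
tidy.katdetect <- function(x, ...) {
  x$loci
}

#' @rdname tidy.katdetect
#' @method glance katdetect
#' @export
glance.katdetect <- function(x, ...) {
  tibble(
    n_variants = nrow(x$variants),
    n_segments = nrow(x$segments),
    n_loci = nrow(x$loci),
    n_in_kataegis = sum(x$variants$in_kataegis),
    sample_rate = x$rates$sample_rate,
    median_imd = x$rates$median_imd
  )
}

#' Write called loci as BED
#'
#' BED uses 0-based half-open coordinates; the conversion from the package's
#' 1-based inclusive bounds happens here only.
#'
#' @param loci Loci tibble (`tidy()` of a `katdetect`, or `x$loci`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- tibble(
    chrom = loci$chromosome,
    chromStart = format(loci$genomic_start - 1, scientific = FALSE,
                        trim = TRUE),
    chromEnd = format(loci$genomic_end, scientific = FALSE, trim = TRUE),
    name = sprintf("kataegis_%d", loci$locus),
    score = loci$variant_count
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write loci or segments as TSV
#'
#' @param x Loci or segment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
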