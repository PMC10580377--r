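# Segment annotation, mutation rates and kataegis calling.

#' Annotate changepoint-delimited segments of one chromosome
#'
#' Converts a segmentation of the IMD sequence (variant IMDs plus the
#' closing pseudo-IMD) into genomic segments. Segments tile the chromosome:
#' a segment starts one base after the previous segment's last variant (the
#' first at base 1) and ends at its own last variant (the last segment at
#' the chromosome end). The pseudo-IMD observation belongs to the final
#' segment but is not a variant: it contributes to the segment's genomic
#' length, never to its variant count or mean IMD.
#'
#' @param imd IMD tibble from [compute_imd()].
#' @param changepoints Integer vector of last observation indices per
#'   segment (a `cpt_result$changepoints`), ending at `nrow(imd)`.
#' @param chromosome Chromosome identifier carried into the output.
#' @param chromosome_length Chromosome length in base pairs.
#' @return A tibble with one row per segment: `chromosome`, `segment`,
#'   `genomic_start`, `genomic_end`, `first_variant_pos`, `last_variant_pos`,
#'   `variant_count`, `length_bp`, `imd_sum`, `mean_imd`, `rate`.
#' @export
annotate_segments <- function(imd, changepoints, chromosome = "1",
                              chromosome_length = NULL) {
  n_obs <- nrow(imd)
  stopifnot(length(changepoints) >= 1,
            changepoints[length(changepoints)] == n_obs,
            all(diff(c(0L, changepoints)) >= 1))
  k <- sum(!imd$pseudo)
  chromosome_length <- chromosome_length %||% sum(imd$imd)
  pos <- imd$position[seq_len(k)]
  ends <- as.integer(changepoints)
  starts_idx <- c(1L, head(ends, -1) + 1L)
  boundary_pos <- c(0, pos, chromosome_length)  # boundary_pos[i + 1] = pos of obs i
  seg <- tibble(
    chromosome = chromosome,
    segment = seq_along(ends),
    first_index = starts_idx,
    last_index = ends
  )
  last_var <- pmin(seg$last_index, k)     # last member variant (if any)
  has_var <- seg$first_index <= k
  n_var <- pmax(0L, last_var - seg$first_index + 1L)
  # boundary_pos[i] = position of observation i - 1 (0 for the start)
  genomic_start <- boundary_pos[seg$first_index] + 1
  genomic_end <- ifelse(seg$last_index > k, chromosome_length,
                        pos[pmax(seg$last_index, 1L)])
  imd_real <- imd$imd[seq_len(k)]
  cs <- cumsum(c(0, imd_real))
  imd_sum <- ifelse(has_var, cs[last_var + 1L] - cs[seg$first_index], 0)
  seg$genomic_start <- as.numeric(genomic_start)
  seg$genomic_end <- as.numeric(genomic_end)
  seg$first_variant_pos <- ifelse(has_var, pos[pmin(seg$first_index, k)],
                                  NA_real_)
  seg$last_variant_pos <- ifelse(has_var, pos[pmax(last_var, 1L)], NA_real_)
  seg$variant_count <- ifelse(has_var, n_var, 0L)
  seg$length_bp <- seg$genomic_end - seg$genomic_start + 1
  seg$imd_sum <- imd_sum
  seg$mean_imd <- ifelse(seg$variant_count > 0, imd_sum / seg$variant_count,
                         NA_real_)
  seg$rate <- seg$variant_count / seg$length_bp
  seg
}

#' Summarise a sample's mutation rate
#'
#' The sample-wide mutation rate is the total variant count over the genome
#' length, identically the length-weighted arithmetic mean of the per-segment
#' rates (both forms are computed; they agree exactly because segments tile
#' the genome).
#'
#' @param segments Segment tibble ([annotate_segments()]), possibly spanning
#'   several chromosomes.
#' @param genome_length Total genome length in base pairs.
#' @param median_imd Sample-wide median of the (non-pseudo) IMDs; optional,
#'   used by the adaptive cutoff.
#' @return A one-row tibble: `total_variants`, `genome_length`,
#'   `sample_rate`, `weighted_rate`, `segment_count`, `median_imd`,
#'   `lambda_med`.
#' @export
sample_rate_summary <- function(segments, genome_length, median_imd = NA_real_) {
  k_t <- sum(segments$variant_count)
  weighted <- sum(segments$rate * segments$length_bp) / genome_length
  tibble(
    total_variants = k_t,
    genome_length = genome_length,
    sample_rate = k_t / genome_length,
    weighted_rate = weighted,
    segment_count = nrow(segments),
    median_imd = median_imd,
    lambda_med = log(2) / median_imd
  )
}

#' Sample-adaptive IMD cutoff (PCAWG-style)
#'
#' Segment-specific IMD threshold under an exponential model of the sample's
#' IMDs: `-log(1 - (0.01 / L_s)^(1 / (k_s - 1))) / lambda_med`, with
#' `lambda_med = log(2) / median(IMD)`, capped at `cap` (1,000 bp by
#' default). Segments with fewer than two variants get cutoff 0 and can
#' never qualify.
#'
#' @param variant_count Number of variants in the segment(s); vectorised.
#' @param length_bp Segment length(s) in base pairs.
#' @param median_imd Sample-wide median IMD.
#' @param cap Upper bound on the cutoff (default 1000).
#' @return Numeric vector of per-segment cutoffs in base pairs.
#' @examples
#' pcawg_imd_cutoff(10, 1e4, 1e5)  # raw value ~3.5e4, capped at 1000
#' @export
pcawg_imd_cutoff <- function(variant_count, length_bp, median_imd,
                             cap = 1000) {
  lambda_med <- log(2) / median_imd
  raw <- -log(1 - (0.01 / length_bp)^(1 / (variant_count - 1))) / lambda_med
  out <- pmin(cap, raw)
  out[variant_count < 2] <- 0
  out
}

resolve_cutoff <- function(imd_cutoff, segments, summary) {
  if (is.function(imd_cutoff)) {
    as.numeric(imd_cutoff(segments, summary))
  } else if (identical(imd_cutoff, "pcawg")) {
    pcawg_imd_cutoff(segments$variant_count, segments$length_bp,
                     summary$median_imd)
  } else if (is.numeric(imd_cutoff) && length(imd_cutoff) == 1) {
    rep(imd_cutoff, nrow(segments))
  } else {
    abort('`imd_cutoff` must be a single number, "pcawg", or a function.')
  }
}

#' Call kataegis loci from annotated segments
#'
#' A segment qualifies when its mean IMD is at most the cutoff (static value,
#' `"pcawg"`, or a function of the segment table and sample summary) and it
#' holds at least `min_size_kataegis` variants. Maximal runs of adjacent
#' qualifying segments on a chromosome are merged into a single locus with
#' pooled variant count and pooled mean IMD; locus bounds run from the first
#' to the last member variant.
#'
#' @param segments Segment tibble ([annotate_segments()]).
#' @param summary Sample summary ([sample_rate_summary()]); only needed for
#'   function-valued/adaptive cutoffs.
#' @param imd_cutoff Maximal mean IMD (bp) of a qualifying segment
#'   (default 1000), `"pcawg"`, or `function(segments, summary)`.
#' @param min_size_kataegis Minimal variants per qualifying segment
#'   (default 6).
#' @return A tibble of loci: `chromosome`, `locus`, `genomic_start`,
#'   `genomic_end`, `variant_count`, `mean_imd`, `n_segments`.
#' @export
call_kataegis <- function(segments, summary = NULL, imd_cutoff = 1000,
                          min_size_kataegis = 6) {
  cutoff <- resolve_cutoff(imd_cutoff, segments, summary)
  qual <- !is.na(segments$mean_imd) & segments$mean_imd <= cutoff &
    segments$variant_count >= min_size_kataegis
  if (!any(qual)) {
    return(tibble(
      chromosome = character(), locus = integer(), genomic_start = numeric(),
      genomic_end = numeric(), variant_count = integer(),
      mean_imd = numeric(), n_segments = integer()
    ))
  }
  segments |>
    mutate(.qual = qual) |>
    group_by(.data$chromosome) |>
    mutate(.run = cumsum(.data$.qual != lag(.data$.qual, default = FALSE) &
                           .data$.qual)) |>
    ungroup() |>
    filter(.data$.qual) |>
    group_by(.data$chromosome, .data$.run) |>
    summarise(
      genomic_start = first(.data$first_variant_pos),
      genomic_end = last(.data$last_variant_pos),
      variant_count = sum(.data$variant_count),
      mean_imd = sum(.data$imd_sum) / sum(.data$variant_count),
      n_segments = n(),
      .groups = "drop"
    ) |>
    arrange(.data$chromosome, .data$genomic_start) |>
    mutate(locus = row_number()) |>
    select("chromosome", "locus", "genomic_start", "genomic_end",
           "variant_count", "mean_imd", "n_segments")
}
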