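# Benchmark harness: run the detector over (a subset of) the synthetic
# dataset design and score it per variant and per locus.

#' Select a balanced subset of the benchmark design
#'
#' Keeps, per TMB class, `samples_per_class / 2` kataegis samples (stratified
#' over the loci-count grid) and as many locus-free samples. Selection is
#' deterministic given `seed` and independent of the per-sample generation
#' seeds already fixed in the design.
#'
#' @param design Design tibble from [plan_dataset()].
#' @param samples_per_class Samples retained per TMB class (even number).
#' @param seed Integer seed for the subset draw.
#' @return The subset of `design` rows.
#' @export
select_benchmark_subset <- function(design, samples_per_class = 16,
                                    seed = 1L) {
  half <- samples_per_class %/% 2
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  out <- design |>
    group_by(.data$tmb, .data$kataegis, .data$n_loci) |>
    group_modify(function(g, key) {
      take <- if (key$kataegis) {
        max(1L, round(half / 4))  # stratified over the four loci counts
      } else {
        half
      }
      g[sample.int(nrow(g), min(take, nrow(g))), ]
    }) |>
    ungroup() |>
    arrange(.data$tmb, desc(.data$kataegis), .data$sample_name)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Run the detector over a benchmark design and score it
#'
#' For every design row, generates the sample from its fixed seed, runs
#' [detect_kataegis()] with the supplied parameters, and scores the result:
#' the per-variant confusion counts against the planted truth and the number
#' of planted loci recovered by at least one base pair of overlap.
#'
#' @param design Design tibble ([plan_dataset()] or
#'   [select_benchmark_subset()]).
#' @param chromosome_length Chromosome length in bp.
#' @param progress Print a dot per 16 samples.
#' @param ... Detection parameters passed to [detect_kataegis()].
#' @return The design with columns `n_variants`, `n_in_locus`, `tp`, `fp`,
#'   `tn`, `fn`, `n_called_loci`, `n_recovered_loci` appended.
#' @export
run_benchmark <- function(design, chromosome_length = 249250621,
                          progress = FALSE, ...) {
  lens <- setNames(chromosome_length, "1")
  score <- function(sim) {
    kd <- detect_kataegis(sim$variants, lens, preprocess = FALSE, ...)
    cm <- evaluate_sample(sim, kd)
    recovered <- if (nrow(sim$loci) > 0) {
      planted <- tibble(chromosome = "1", genomic_start = sim$loci$start,
                        genomic_end = sim$loci$end)
      sum(locus_concordance(planted, kd$loci)$matched)
    } else {
      0L
    }
    mutate(cm, n_called_loci = nrow(kd$loci),
           n_recovered_loci = as.integer(recovered))
  }
  manifest <- simulate_dataset(design, chromosome_length = chromosome_length,
                               alleles = FALSE, sample_fun = score,
                               progress = progress)
  bind_cols(
    manifest[, setdiff(names(manifest), "result")],
    bind_rows(manifest$result)
  )
}
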