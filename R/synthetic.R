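# Labelled synthetic mutation samples: uniform background mutations (a
# Bernoulli process conditioned on its count) plus planted kataegis loci.
#
# The benchmark design mirrors a published evaluation: 8 TMB classes
# (0.1-500 mutations/Mbp) on a single 249,250,621 bp chromosome, each class
# holding one sample for every combination of loci-count {1,2,3,5} x
# variants-per-locus {6,10,25,50} x expected intra-locus IMD
# {100,250,500,750} plus 64 locus-free samples.

#' Number of background mutations implied by a TMB
#'
#' Inverts `TMB = variants / genome_length * 1e6`, rounding half away from
#' zero so that e.g. TMB 10 on 249,250,621 bp gives 2,493.
#'
#' @param tmb Tumor mutational burden in mutations per megabase.
#' @param chromosome_length Genome/chromosome length in base pairs.
#' @return Integer count of background mutations.
#' @examples
#' n_background_mutations(0.5, 249250621)  # 125
#' @export
n_background_mutations <- function(tmb, chromosome_length) {
  if (any(tmb < 0)) abort("`tmb` must be nonnegative.")
  as.integer(floor(tmb * chromosome_length / 1e6 + 0.5))
}

#' Simulate one labelled mutation sample
#'
#' Background mutations are placed uniformly without replacement (the
#' Bernoulli mutation process conditioned on its count, under which the IMD
#' is geometric). Each planted kataegis locus draws a uniform start and ends
#' at `start + expected_imd * (variants_per_locus + 1) - 1`, so intra-locus
#' gaps average `expected_imd`; it receives `variants_per_locus` uniform
#' positions, and loci are resampled until pairwise disjoint and in bounds. All
#' positions in a sample are unique. A variant is labelled in-kataegis
#' (`in_locus`) when it falls inside any planted locus, background variants
#' included.
#'
#' @param tmb Background tumor mutational burden (mutations/Mbp).
#' @param n_loci Number of planted kataegis loci.
#' @param variants_per_locus Variants per planted locus.
#' @param expected_imd Expected intra-locus IMD in bp (integer).
#' @param chromosome_length Chromosome length in bp (default: length of the
#'   largest human chromosome, hg19 chr1).
#' @param chromosome Chromosome name used in the output (default `"1"`).
#' @param seed Optional integer seed; the sample is fully reproducible
#'   given it.
#' @param alleles If `TRUE` (default), draw SNV ref/alt alleles uniformly.
#' @param sample_name Sample identifier; defaults to
#'   `"<background>_<loci>_<variants>_<imd>"`.
#' @return A list of class `kataegis_sim`: `variants` (tibble with logical
#'   truth column `in_locus`), `loci` (planted loci), `params`.
#' @examples
#' sim <- simulate_sample(0, 1, 6, 100, chromosome_length = 1e6, seed = 7)
#' sim$loci
#' @export
simulate_sample <- function(tmb, n_loci, variants_per_locus, expected_imd,
                            chromosome_length = 249250621,
                            chromosome = "1", seed = NULL, alleles = TRUE,
                            sample_name = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bg <- n_background_mutations(tmb, chromosome_length)
  if (n_loci > 0) {
    stopifnot(variants_per_locus >= 1, expected_imd >= 1)
    locus_len <- expected_imd * (variants_per_locus + 1)
    if (n_loci * locus_len > chromosome_length) {
      abort("Planted loci do not fit within the chromosome.")
    }
  }
  bg <- if (n_bg > 0) sample.int(chromosome_length, n_bg) else integer(0)
  loci <- plant_loci(n_loci, if (n_loci > 0) locus_len else 0,
                     chromosome_length)
  taken <- bg
  locus_pos <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    avail <- setdiff(seq.int(loci$start[i], loci$end[i]), taken)
    if (length(avail) < variants_per_locus) {
      abort("Locus interval too dense to place the requested variants.")
    }
    p <- sort(avail[sample.int(length(avail), variants_per_locus)])
    locus_pos[[i]] <- p
    taken <- c(taken, p)
  }
  pos <- sort(c(bg, unlist(locus_pos)))
  in_locus <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(loci))) {
    in_locus <- in_locus | (pos >= loci$start[i] & pos <= loci$end[i])
  }
  name <- sample_name %||%
    paste(n_bg, n_loci, if (n_loci > 0) variants_per_locus else 0,
          if (n_loci > 0) expected_imd else 0, sep = "_")
  variants <- tibble(
    chromosome = chromosome,
    start = as.integer(pos),
    end = as.integer(pos),
    ref = NA_character_,
    alt = NA_character_,
    sample_id = name,
    in_locus = in_locus
  )
  if (isTRUE(alleles)) variants <- assign_alleles(variants)
  structure(
    list(
      variants = variants,
      loci = loci,
      params = list(tmb = tmb, n_background = n_bg, n_loci = n_loci,
                    variants_per_locus = variants_per_locus,
                    expected_imd = expected_imd,
                    chromosome_length = chromosome_length,
                    chromosome = chromosome, seed = seed,
                    sample_name = name)
    ),
    class = "kataegis_sim"
  )
}

#' @export
print.kataegis_sim <- function(x, ...) {
  cat(sprintf("<kataegis_sim> %s: %d variants, %d planted locus/loci\n",
              x$params$sample_name, nrow(x$variants), nrow(x$loci)))
  invisible(x)
}

plant_loci <- function(n_loci, locus_len, chromosome_length, max_tries = 1e4) {
  if (n_loci == 0) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  starts <- numeric(0)
  tries <- 0
  while (length(starts) < n_loci) {
    s <- sample.int(chromosome_length - locus_len + 1, 1)
    e <- s + locus_len - 1
    if (!any(s <= starts + locus_len - 1 & e >= starts)) {
      starts <- c(starts, s)
    }
    tries <- tries + 1
    if (tries > max_tries) abort("Could not place disjoint kataegis loci.")
  }
  tibble(start = sort(starts), end = sort(starts) + locus_len - 1)
}

#' Draw SNV alleles for simulated variants
#'
#' Reference bases uniform over A/C/G/T, alternate uniform over the other
#' three; existing non-`NA` alleles are overwritten.
#'
#' @param variants Variant tibble.
#' @param seed Optional integer seed.
#' @return The tibble with `ref` and `alt` filled in.
#' @export
assign_alleles <- function(variants, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(variants)
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4, n, replace = TRUE)]
  shift <- sample.int(3, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  variants$ref <- ref
  variants$alt <- alt
  variants
}

#' Lay out the full synthetic benchmark design
#'
#' Returns the deterministic per-sample design of the benchmark dataset
#' (before any random generation): for every TMB class, one sample per
#' combination of the loci grid plus `n_null` locus-free samples. Per-sample
#' seeds are derived from `seed` so any single sample can be regenerated in
#' isolation.
#'
#' @param tmb_classes TMB classes (mutations/Mbp).
#' @param n_loci,variants_per_locus,expected_imd Grid of planted-locus
#'   parameters.
#' @param n_null Locus-free samples per TMB class (default 64).
#' @param chromosome_length Chromosome length in bp.
#' @param seed Master seed for the per-sample seed stream.
#' @return A tibble with one row per planned sample: `sample_name`, `tmb`,
#'   `n_background`, `kataegis`, `n_loci`, `variants_per_locus`,
#'   `expected_imd`, `planned_variants`, `seed`.
#' @export
plan_dataset <- function(tmb_classes = c(0.1, 0.5, 1, 5, 10, 50, 100, 500),
                         n_loci = c(1, 2, 3, 5),
                         variants_per_locus = c(6, 10, 25, 50),
                         expected_imd = c(100, 250, 500, 750),
                         n_null = 64,
                         chromosome_length = 249250621,
                         seed = 1L) {
  grid <- tidyr::expand_grid(
    tmb = tmb_classes,
    n_loci = n_loci,
    variants_per_locus = variants_per_locus,
    expected_imd = expected_imd
  ) |>
    mutate(kataegis = TRUE)
  null <- tidyr::expand_grid(tmb = tmb_classes, replicate = seq_len(n_null)) |>
    mutate(n_loci = 0, variants_per_locus = 0, expected_imd = 0,
           kataegis = FALSE)
  design <- bind_rows(grid, null) |>
    arrange(.data$tmb, desc(.data$kataegis)) |>
    mutate(
      n_background = n_background_mutations(.data$tmb,
                                            .env$chromosome_length),
      planned_variants = .data$n_background +
        .data$n_loci * .data$variants_per_locus,
      sample_name = paste(.data$n_background, .data$n_loci,
                          .data$variants_per_locus, .data$expected_imd,
                          sep = "_"),
      sample_name = if_else(.data$kataegis, .data$sample_name,
                            paste0(.data$sample_name, "_",
                                   dplyr::coalesce(.data$replicate, 0L)))
    ) |>
    select("sample_name", "tmb", "n_background", "kataegis", "n_loci",
           "variants_per_locus", "expected_imd", "planned_variants")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  design$seed <- sample.int(.Machine$integer.max - 1L, nrow(design))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  design
}

#' Generate the synthetic benchmark dataset
#'
#' Materialises every sample of a benchmark design (see [plan_dataset()]),
#' optionally writing each to disk and/or applying a function to each
#' generated sample (e.g. a detector). Returns the manifest: the design
#' plus realised counts, and, when `sample_fun` is given, a list-column of
#' its results.
#'
#' @param design Design tibble from [plan_dataset()]; built from the
#'   defaults when `NULL`.
#' @param chromosome_length Chromosome length in bp.
#' @param seed Master seed (used only when `design` is `NULL`).
#' @param out_dir If non-`NULL`, write one VCF, one truth TSV and one
#'   planted-loci BED per sample here, plus a JSON manifest.
#' @param alleles Draw alleles (needed for VCF output; skip for speed when
#'   only positions matter).
#' @param sample_fun Optional `function(sim)` applied to each generated
#'   sample.
#' @param progress Print a dot every 64 samples.
#' @return The manifest tibble: design columns plus `n_variants` and
#'   `n_in_locus` (realised counts), and `result` (list) when `sample_fun`
#'   is supplied.
#' @export
simulate_dataset <- function(design = NULL, chromosome_length = 249250621,
                             seed = 1L, out_dir = NULL, alleles = FALSE,
                             sample_fun = NULL, progress = FALSE) {
  design <- design %||% plan_dataset(chromosome_length = chromosome_length,
                                     seed = seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  n <- nrow(design)
  n_variants <- integer(n)
  n_in_locus <- integer(n)
  results <- if (!is.null(sample_fun)) vector("list", n)
  for (i in seq_len(n)) {
    d <- design[i, ]
    sim <- simulate_sample(
      tmb = d$tmb, n_loci = d$n_loci,
      variants_per_locus = d$variants_per_locus,
      expected_imd = d$expected_imd,
      chromosome_length = chromosome_length,
      seed = d$seed, alleles = alleles, sample_name = d$sample_name
    )
    n_variants[i] <- nrow(sim$variants)
    n_in_locus[i] <- sum(sim$variants$in_locus)
    if (!is.null(out_dir)) write_sim_sample(sim, out_dir)
    if (!is.null(sample_fun)) results[[i]] <- sample_fun(sim)
    if (progress && i %% 64 == 0) cat(".")
  }
  if (progress) cat("\n")
  manifest <- design
  manifest$n_variants <- n_variants
  manifest$n_in_locus <- n_in_locus
  if (!is.null(sample_fun)) manifest$result <- results
  if (!is.null(out_dir)) {
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        manifest[, setdiff(names(manifest), "result")],
        file.path(out_dir, "manifest.json")
      )
    }
  }
  manifest
}

write_sim_sample <- function(sim, out_dir) {
  name <- sim$params$sample_name
  write_variants_vcf(
    sim$variants, file.path(out_dir, paste0(name, ".vcf")),
    chromosome_lengths =
      setNames(sim$params$chromosome_length, sim$params$chromosome)
  )
  readr::write_tsv(
    tibble(chromosome = sim$variants$chromosome,
           position = sim$variants$start,
           label = sim$variants$in_locus),
    file.path(out_dir, paste0(name, ".truth.tsv")), progress = FALSE
  )
  if (nrow(sim$loci) > 0) {
    readr::write_tsv(
      tibble(chrom = sim$params$chromosome,
             chromStart = format(sim$loci$start - 1, scientific = FALSE,
                                 trim = TRUE),
             chromEnd = format(sim$loci$end, scientific = FALSE,
                               trim = TRUE)),
      file.path(out_dir, paste0(name, ".loci.bed")),
      col_names = FALSE, progress = FALSE
    )
  }
  invisible(name)
}

#' Write variants as a minimal VCF v4.2
#'
#' @param variants Variant tibble; a logical `in_kataegis` column, when
#'   present, is emitted as an INFO flag `KATAEGIS`.
#' @param path Output path.
#' @param chromosome_lengths Optional named lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, chromosome_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kataegisr",
    '##INFO=<ID=KATAEGIS,Number=0,Type=Flag,Description="Variant lies in a called kataegis locus">'
  )
  if (!is.null(chromosome_lengths)) {
    lens <- as_chromosome_lengths(chromosome_lengths)
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>", names(lens),
                                as.integer(lens)))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- if ("in_kataegis" %in% names(variants)) {
    ifelse(variants$in_kataegis, "KATAEGIS", ".")
  } else {
    rep(".", nrow(variants))
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  variants$chromosome, variants$start,
                  dplyr::coalesce(variants$ref, "N"),
                  dplyr::coalesce(variants$alt, "N"), info)
  readr::write_lines(c(header, body), path)
  invisible(path)
}
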