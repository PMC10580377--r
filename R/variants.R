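# Variant import, validation and preprocessing.
#
# The canonical representation throughout the package is a plain tibble with
# one row per variant record and columns chromosome, start, end, ref, alt,
# sample_id (1-based inclusive coordinates, as in VCF and MAF). Optional
# columns (e.g. a logical truth label from the simulator) are carried along
# untouched.

variant_cols <- c("chromosome", "start", "end", "ref", "alt", "sample_id")

new_variant_tbl <- function(chromosome, start, end, ref, alt, sample_id) {
  tibble(
    chromosome = as.character(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    ref = as.character(ref),
    alt = as.character(alt),
    sample_id = as.character(sample_id)
  )
}

assert_variant_tbl <- function(x, arg = "variants") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of variant records.", arg))
  }
  missing <- setdiff(c("chromosome", "start"), names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` lacks required column(s): %s.", arg,
      paste(missing, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  if (!"end" %in% names(x)) x$end <- x$start
  if (!"ref" %in% names(x)) x$ref <- NA_character_
  if (!"alt" %in% names(x)) x$alt <- NA_character_
  if (!"sample_id" %in% names(x)) x$sample_id <- NA_character_
  if (any(x$start < 1L, na.rm = TRUE)) {
    abort(sprintf("`%s` contains start positions < 1.", arg))
  }
  if (any(x$end < x$start, na.rm = TRUE)) {
    abort(sprintf("`%s` contains records with end < start.", arg))
  }
  x
}

#' Read somatic variant calls into the canonical variant table
#'
#' Imports variant records from VCF (v4.x), MAF (GDC-style tab-separated) or
#' a generic TSV with columns `chromosome`, `start`, `end`, `ref`, `alt` and
#' optionally `sample`/`sample_id`. All rows are imported, including indels
#' and structural records; multi-allelic VCF rows are split into one record
#' per alternate allele. Coordinates are kept 1-based inclusive.
#'
#' @param path Path to the variant file.
#' @param format One of `"auto"` (by file extension), `"vcf"`, `"maf"`,
#'   `"tsv"`.
#' @param sample_id Restrict to (MAF) or assign (VCF/TSV without sample
#'   column) this sample identifier. Defaults to the file base name when the
#'   format carries no sample annotation.
#' @param filter_pass For VCF only: if `TRUE`, drop records whose FILTER is
#'   neither `PASS` nor `.`. Default `FALSE` (keep all records).
#' @return A tibble with columns `chromosome`, `start`, `end`, `ref`, `alt`,
#'   `sample_id`.
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(paste(
#'   c("Chromosome\tStart_Position\tEnd_Position\tReference_Allele\tTumor_Seq_Allele2\tTumor_Sample_Barcode",
#'     "1\t100\t100\tC\tT\tS1"), collapse = "\n"), maf)
#' read_variants(maf, format = "maf")
#' @export
read_variants <- function(path, format = c("auto", "vcf", "maf", "tsv"),
                          sample_id = NULL, filter_pass = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
      vcf = "vcf", maf = "maf", tsv = "tsv", txt = "tsv",
      abort(sprintf("Cannot guess variant format from extension of %s", path))
    )
  }
  switch(format,
    vcf = read_variants_vcf(path, sample_id, filter_pass),
    maf = read_variants_maf(path, sample_id),
    tsv = read_variants_tsv(path, sample_id)
  )
}

read_variants_vcf <- function(path, sample_id, filter_pass) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(sprintf("Failed to parse VCF %s: %s", path, conditionMessage(e)))
    }
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(new_variant_tbl(character(), integer(), integer(),
                           character(), character(), character()))
  }
  if (isTRUE(filter_pass)) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
  }
  sid <- sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  out <- tibble(
    chromosome = as.character(fix$CHROM),
    start = as.integer(fix$POS),
    ref = as.character(fix$REF),
    alt = as.character(fix$ALT),
    sample_id = sid
  )
  # one record per alternate allele
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  out$end <- out$start + pmax(nchar(out$ref), 1L) - 1L
  out[, variant_cols]
}

maf_required <- c("Chromosome", "Start_Position", "End_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2")

read_variants_maf <- function(path, sample_id) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  missing <- setdiff(maf_required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("MAF %s lacks required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  sid <- if ("Tumor_Sample_Barcode" %in% names(x)) {
    as.character(x$Tumor_Sample_Barcode)
  } else {
    sample_id %||% sub("\\.maf$", "", basename(path))
  }
  out <- new_variant_tbl(x$Chromosome, x$Start_Position, x$End_Position,
                         x$Reference_Allele, x$Tumor_Seq_Allele2, sid)
  if (!is.null(sample_id)) out <- out[out$sample_id == sample_id, ]
  out
}

read_variants_tsv <- function(path, sample_id) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if ("sample" %in% names(x) && !"sample_id" %in% names(x)) {
    x$sample_id <- x$sample
  }
  missing <- setdiff(c("chromosome", "start"), names(x))
  if (length(missing) > 0) {
    abort(sprintf("TSV %s lacks required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (!"end" %in% names(x)) x$end <- x$start
  if (!"sample_id" %in% names(x)) {
    x$sample_id <- sample_id %||% sub("\\.(tsv|txt)$", "", basename(path))
  }
  if (!"ref" %in% names(x)) x$ref <- NA_character_
  if (!"alt" %in% names(x)) x$alt <- NA_character_
  out <- new_variant_tbl(x$chromosome, x$start, x$end, x$ref, x$alt,
                         x$sample_id)
  if (!is.null(sample_id)) out <- out[out$sample_id == sample_id, ]
  out
}

#' Write the canonical variant table as TSV
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  variants <- assert_variant_tbl(variants)
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

# Match the chromosome-name dialect ("chr1" vs "1") of the lengths table.
normalize_chromosomes <- function(chromosome, target) {
  bare <- sub("^chr", "", chromosome)
  target_bare <- sub("^chr", "", target)
  uses_prefix <- any(startsWith(target, "chr"))
  mapped <- if (uses_prefix) paste0("chr", bare) else bare
  ifelse(chromosome %in% target, chromosome,
         ifelse(mapped %in% target | bare %in% target_bare, mapped,
                chromosome))
}

as_chromosome_lengths <- function(chromosome_lengths) {
  if (is.data.frame(chromosome_lengths)) {
    stopifnot(all(c("chromosome", "length") %in% names(chromosome_lengths)))
    setNames(as.numeric(chromosome_lengths$length),
             as.character(chromosome_lengths$chromosome))
  } else if (is.numeric(chromosome_lengths) &&
             !is.null(names(chromosome_lengths))) {
    chromosome_lengths
  } else {
    abort(paste0("`chromosome_lengths` must be a named numeric vector or a ",
                 "tibble with columns chromosome and length."))
  }
}

#' Sort variants and merge overlapping records
#'
#' Per chromosome (and sample), records are sorted by ascending genomic
#' position and any set of records whose `[start, end]` intervals overlap is
#' collapsed into a single record spanning their union; the alleles of the
#' earliest record are retained. After preprocessing, starts are strictly
#' increasing within each chromosome, which guarantees strictly positive
#' intermutation distances. Phasing and clonality are not considered.
#'
#' @param variants Variant tibble.
#' @param chromosome_lengths Named numeric vector (`c("chr1" = 249250621)`) or
#'   tibble with columns `chromosome`, `length`. When supplied, chromosome
#'   names are normalised to the dialect of this table and records beyond the
#'   chromosome end raise an error.
#' @return The preprocessed variant tibble.
#' @examples
#' v <- tibble::tibble(chromosome = "1", start = c(100L, 100L, 300L),
#'                     end = c(100L, 101L, 300L), ref = c("A", "C", "G"),
#'                     alt = c("T", "G", "A"), sample_id = "s")
#' preprocess_variants(v)
#' @export
preprocess_variants <- function(variants, chromosome_lengths = NULL) {
  variants <- assert_variant_tbl(variants)
  if (nrow(variants) == 0) {
    return(variants)
  }
  if (!is.null(chromosome_lengths)) {
    lens <- as_chromosome_lengths(chromosome_lengths)
    variants$chromosome <-
      normalize_chromosomes(variants$chromosome, names(lens))
    unknown <- setdiff(unique(variants$chromosome), names(lens))
    if (length(unknown) > 0) {
      abort(sprintf("Chromosome(s) absent from the length table: %s",
                    paste(unknown, collapse = ", ")))
    }
    over <- variants$end > lens[variants$chromosome]
    if (any(over)) {
      abort(sprintf(
        "%d record(s) extend beyond their chromosome length (first: %s:%d).",
        sum(over), variants$chromosome[which(over)[1]],
        variants$end[which(over)[1]]
      ))
    }
  }
  variants |>
    group_by(.data$sample_id, .data$chromosome) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(
      .reach = cummax(lag(.data$end, default = 0L)),
      .grp = cumsum(.data$start > .data$.reach)
    ) |>
    group_by(.data$sample_id, .data$chromosome, .data$.grp) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      ref = .data$ref[1],
      alt = .data$alt[1],
      across(!any_of(c(variant_cols, ".reach")), ~ .x[1]),
      .groups = "drop"
    ) |>
    select(!".grp") |>
    arrange(.data$sample_id, .data$chromosome, .data$start) |>
    select(any_of(variant_cols), everything())
}

#' Classify a substitution by its reference and alternate alleles
#'
#' Single-nucleotide substitutions are normalised to a pyrimidine reference
#' base, giving the six conventional classes (C>A, C>G, C>T, T>A, T>C, T>G).
#' Equal-length multi-base changes are `MNV`, length-changing ones `indel`,
#' anything with non-nucleotide characters `other`.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return A character vector of classes.
#' @examples
#' classify_substitution(c("G", "AT", "A"), c("T", "GC", "AT"))
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  out <- rep("other", n)
  ok <- !is.na(ref) & !is.na(alt) & grepl("^[ACGTN]+$", ref) &
    grepl("^[ACGTN]+$", alt)
  snv <- ok & nchar(ref) == 1L & nchar(alt) == 1L & ref != "N" & alt != "N" &
    ref != alt
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r <- ref[snv]
  a <- alt[snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  out[snv] <- paste0(r, ">", a)
  mnv <- ok & !snv & nchar(ref) == nchar(alt) & nchar(ref) >= 1L & ref != alt
  out[mnv & nchar(ref) > 1L] <- "MNV"
  out[ok & nchar(ref) != nchar(alt)] <- "indel"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
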