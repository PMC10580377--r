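chr <- function(len) stats::setNames(len, "1")

test_that("a planted locus is detected with default parameters", {
  sim <- simulate_sample(tmb = 2, n_loci = 1, variants_per_locus = 50,
                         expected_imd = 100, chromosome_length = 1e7,
                         seed = 42)
  kd <- detect_kataegis(sim$variants, chr(1e7))
  expect_equal(nrow(kd$loci), 1)
  conc <- locus_concordance(
    tibble::tibble(chromosome = "1", genomic_start = sim$loci$start,
                   genomic_end = sim$loci$end),
    kd$loci
  )
  expect_true(all(conc$matched))
  expect_gte(sum(kd$variants$in_kataegis), 40)
})

test_that("a locus below the minimum size is never called", {
  sim <- simulate_sample(tmb = 0, n_loci = 1, variants_per_locus = 5,
                         expected_imd = 100, chromosome_length = 1e7,
                         seed = 7)
  kd <- detect_kataegis(sim$variants, chr(1e7))
  expect_equal(nrow(kd$loci), 0)
  expect_false(any(kd$variants$in_kataegis))
})

test_that("relaxing either threshold never reduces the flagged variants", {
  sim <- simulate_sample(tmb = 5, n_loci = 2, variants_per_locus = 10,
                         expected_imd = 400, chromosome_length = 1e7,
                         seed = 99)
  base <- detect_kataegis(sim$variants, chr(1e7))
  wider <- detect_kataegis(sim$variants, chr(1e7), imd_cutoff = 2000)
  smaller <- detect_kataegis(sim$variants, chr(1e7), min_size_kataegis = 4)
  expect_gte(sum(wider$variants$in_kataegis),
             sum(base$variants$in_kataegis))
  expect_gte(sum(smaller$variants$in_kataegis),
             sum(base$variants$in_kataegis))
})

test_that("flags, segments and loci are mutually consistent", {
  set.seed(3)
  for (rep in 1:5) {
    sim <- simulate_sample(tmb = sample(c(1, 10), 1), n_loci = sample(0:3, 1),
                           variants_per_locus = 10, expected_imd = 250,
                           chromosome_length = 5e6, seed = rep * 11)
    kd <- detect_kataegis(sim$variants, chr(5e6))
    # every flagged variant lies inside exactly one locus
    for (i in which(kd$variants$in_kataegis)) {
      hits <- sum(kd$variants$start[i] >= kd$loci$genomic_start &
                    kd$variants$start[i] <= kd$loci$genomic_end)
      expect_equal(hits, 1)
    }
    # loci fall inside the chromosome and within variant range
    if (nrow(kd$loci) > 0) {
      expect_true(all(kd$loci$genomic_start >= 1))
      expect_true(all(kd$loci$genomic_end <= 5e6))
      expect_true(all(kd$loci$variant_count >= 6))
    }
    # the two rate forms agree on every run
    expect_equal(kd$rates$sample_rate, kd$rates$weighted_rate,
                 tolerance = 1e-9)
    # segments tile each chromosome
    expect_equal(sum(kd$segments$length_bp), 5e6)
  }
})

test_that("detection is invariant to the input row order", {
  sim <- simulate_sample(tmb = 5, n_loci = 1, variants_per_locus = 25,
                         expected_imd = 250, chromosome_length = 2e6,
                         seed = 5)
  kd1 <- detect_kataegis(sim$variants, chr(2e6))
  shuffled <- sim$variants[sample.int(nrow(sim$variants)), ]
  kd2 <- detect_kataegis(shuffled, chr(2e6))
  expect_equal(kd1$loci, kd2$loci)
  expect_equal(kd1$segments, kd2$segments)
})

test_that("chromosomes are segmented independently", {
  v1 <- simulate_sample(tmb = 2, n_loci = 1, variants_per_locus = 10,
                        expected_imd = 100, chromosome_length = 1e6,
                        chromosome = "1", seed = 1)$variants
  v2 <- simulate_sample(tmb = 2, n_loci = 0, variants_per_locus = 0,
                        expected_imd = 0, chromosome_length = 2e6,
                        chromosome = "2", seed = 2)$variants
  v2$sample_id <- v1$sample_id[1]
  both <- dplyr::bind_rows(v1, v2)
  lens <- c("1" = 1e6, "2" = 2e6)
  kd <- detect_kataegis(both, lens)
  kd1 <- detect_kataegis(v1, lens["1"])
  expect_equal(kd$loci$genomic_start, kd1$loci$genomic_start)
  expect_setequal(unique(kd$segments$chromosome), c("1", "2"))
  expect_equal(sum(kd$segments$length_bp), 3e6)
})

test_that("tiny chromosomes skip changepoint analysis and empty samples warn", {
  v <- make_variants(c(100L, 5000L))
  kd <- detect_kataegis(v, c("1" = 1e6))
  expect_equal(nrow(kd$segments), 1)
  expect_warning(
    empty <- detect_kataegis(make_variants(integer(0)), c("1" = 1e6)),
    "No variants"
  )
  expect_equal(nrow(empty$loci), 0)
})

test_that("locus-free low-burden genomes rarely yield false-positive samples", {
  # null condition: TMB 0.1 on a full-length chromosome, 20 seeds
  fp <- 0L
  for (s in 1:20) {
    sim <- simulate_sample(tmb = 0.1, n_loci = 0, variants_per_locus = 0,
                           expected_imd = 0, seed = 1000 + s, alleles = FALSE)
    kd <- detect_kataegis(sim$variants, chr(249250621))
    fp <- fp + (nrow(kd$loci) > 0)
  }
  expect_lte(fp, 1)  # <= 5% of 20 samples
})

test_that("the adaptive cutoff route works end to end", {
  sim <- simulate_sample(tmb = 5, n_loci = 1, variants_per_locus = 25,
                         expected_imd = 100, chromosome_length = 1e7,
                         seed = 123)
  kd <- detect_kataegis(sim$variants, chr(1e7), imd_cutoff = "pcawg")
  expect_s3_class(kd, "katdetect")
  expect_gte(nrow(kd$loci), 1)
})

test_that("tidy and glance summarise the result", {
  sim <- simulate_sample(tmb = 1, n_loci = 1, variants_per_locus = 10,
                         expected_imd = 100, chromosome_length = 1e6,
                         seed = 2)
  kd <- detect_kataegis(sim$variants, chr(1e6))
  expect_equal(tidy(kd), kd$loci)
  g <- glance(kd)
  expect_equal(g$n_variants, nrow(kd$variants))
  expect_equal(g$n_loci, nrow(kd$loci))
})

test_that("result writers emit BED with 0-based half-open intervals", {
  loci <- tibble::tibble(chromosome = "1", locus = 1L,
                         genomic_start = 1001, genomic_end = 2000,
                         variant_count = 10L, mean_imd = 100,
                         n_segments = 1L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_loci_bed(loci, path)
  bed <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(bed[2], "1000")
  expect_equal(bed[3], "2000")
})
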