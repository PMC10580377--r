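test_that("background counts reproduce the benchmark's TMB classes", {
  L <- 249250621
  expect_equal(n_background_mutations(0.1, L), 25L)
  expect_equal(n_background_mutations(0.5, L), 125L)
  expect_equal(n_background_mutations(1, L), 249L)
  expect_equal(n_background_mutations(5, L), 1246L)
  expect_equal(n_background_mutations(10, L), 2493L)  # 2492.5 rounds up
  expect_equal(n_background_mutations(50, L), 12463L)
  expect_equal(n_background_mutations(100, L), 24925L)
  expect_equal(n_background_mutations(500, L), 124625L)
  expect_error(n_background_mutations(-1, L), "nonnegative")
})

test_that("a pure-kataegis sample is fully labelled and sized by construction", {
  sim <- simulate_sample(tmb = 0, n_loci = 1, variants_per_locus = 6,
                         expected_imd = 100, chromosome_length = 1e6,
                         seed = 31)
  expect_equal(nrow(sim$variants), 6)
  expect_true(all(sim$variants$in_locus))
  # end = start + E(T) (k + 1) - 1, so the locus spans E(T) (k + 1) bases
  expect_equal(sim$loci$end - sim$loci$start, 100 * 7 - 1)
  expect_true(all(sim$variants$start >= sim$loci$start &
                    sim$variants$start <= sim$loci$end))
})

test_that("a locus-free sample has exactly the background count, all unlabelled", {
  sim <- simulate_sample(tmb = 0.1, n_loci = 0, variants_per_locus = 0,
                         expected_imd = 0, seed = 8, alleles = FALSE)
  expect_equal(nrow(sim$variants), 25)
  expect_false(any(sim$variants$in_locus))
  expect_true(all(diff(sim$variants$start) > 0))
})

test_that("intra-locus gaps average the requested expected IMD", {
  set.seed(71)
  gaps <- unlist(lapply(1:200, function(i) {
    sim <- simulate_sample(tmb = 0, n_loci = 1, variants_per_locus = 50,
                           expected_imd = 100, chromosome_length = 1e6)
    diff(sim$variants$start)
  }))
  expect_equal(mean(gaps), 100, tolerance = 0.1)
})

test_that("planted loci are pairwise disjoint and in bounds", {
  set.seed(15)
  for (rep in 1:10) {
    sim <- simulate_sample(tmb = 0, n_loci = 5, variants_per_locus = 10,
                           expected_imd = 750, chromosome_length = 2e5)
    loci <- sim$loci[order(sim$loci$start), ]
    expect_true(all(loci$start >= 1 & loci$end <= 2e5))
    if (nrow(loci) > 1) {
      expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
    }
    expect_equal(nrow(sim$variants), 50)
    expect_true(all(!duplicated(sim$variants$start)))
  }
  expect_error(
    simulate_sample(tmb = 0, n_loci = 2, variants_per_locus = 50,
                    expected_imd = 100, chromosome_length = 5000),
    "fit"
  )
})

test_that("background IMDs are approximately geometric", {
  L <- 249250621
  sim <- simulate_sample(tmb = 50, n_loci = 0, variants_per_locus = 0,
                         expected_imd = 0, seed = 4, alleles = FALSE)
  imds <- diff(sim$variants$start)
  p <- nrow(sim$variants) / L
  ks <- max(abs(stats::ecdf(imds)(sort(imds)) -
                  stats::pgeom(sort(imds) - 1, p)))
  expect_lt(ks, 0.05)
})

test_that("assigned alleles are valid SNVs with near-uniform class frequencies", {
  v <- assign_alleles(make_variants(seq_len(6000)), seed = 2)
  expect_true(all(v$ref %in% c("A", "C", "G", "T")))
  expect_true(all(v$alt %in% c("A", "C", "G", "T")))
  expect_true(all(v$ref != v$alt))
  classes <- classify_substitution(v$ref, v$alt)
  expect_setequal(unique(classes),
                  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  chi <- stats::chisq.test(table(classes))
  expect_gt(chi$p.value, 1e-4)
})

test_that("samples are reproducible from their seed", {
  a <- simulate_sample(tmb = 1, n_loci = 2, variants_per_locus = 10,
                       expected_imd = 250, chromosome_length = 1e6, seed = 77)
  b <- simulate_sample(tmb = 1, n_loci = 2, variants_per_locus = 10,
                       expected_imd = 250, chromosome_length = 1e6, seed = 77)
  expect_identical(a$variants, b$variants)
  expect_identical(a$loci, b$loci)
})

test_that("the dataset design matches the published grid exactly", {
  design <- plan_dataset(seed = 3)
  expect_equal(nrow(design), 1024)
  per_class <- dplyr::count(design, tmb)
  expect_true(all(per_class$n == 128))
  kataegis_per_class <- dplyr::count(design[design$kataegis, ], tmb)
  expect_true(all(kataegis_per_class$n == 64))
  loci_per_class <- design |>
    dplyr::group_by(tmb) |>
    dplyr::summarise(loci = sum(n_loci))
  expect_true(all(loci_per_class$loci == 176))
  planted_per_class <- design |>
    dplyr::group_by(tmb) |>
    dplyr::summarise(v = sum(n_loci * variants_per_locus))
  expect_true(all(planted_per_class$v == 4004))
  expect_equal(sum(design$planned_variants), 21299360)
  # per-sample seeds are distinct and reproducible
  expect_equal(design$seed, plan_dataset(seed = 3)$seed)
  expect_false(any(duplicated(design$seed)))
})

test_that("generated samples realise their planned counts (cheapest class)", {
  design <- plan_dataset(seed = 6)
  cheap <- design[design$tmb == 0.1, ]
  manifest <- simulate_dataset(cheap)
  expect_equal(manifest$n_variants, manifest$planned_variants)
  expect_gte(sum(manifest$n_in_locus), 4004)
  expect_equal(sum(manifest$n_loci), 176)
})

test_that("dataset files are written in standard plain-text formats", {
  design <- plan_dataset(seed = 2)[1:2, ]
  out <- withr::local_tempdir()
  manifest <- simulate_dataset(design, out_dir = out, alleles = TRUE)
  vcfs <- list.files(out, pattern = "\\.vcf$")
  expect_equal(length(vcfs), 2)
  reread <- read_variants(file.path(out, vcfs[1]), format = "vcf")
  expect_equal(nrow(reread),
               manifest$n_variants[manifest$sample_name ==
                                     sub("\\.vcf$", "", vcfs[1])])
  expect_true(file.exists(file.path(out, "manifest.json")))
})
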