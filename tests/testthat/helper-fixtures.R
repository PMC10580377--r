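# Shared fixtures, built in code.

# variant tibble shorthand
make_variants <- function(start, end = start, chromosome = "1",
                          ref = "C", alt = "T", sample_id = "s1", ...) {
  tibble::tibble(chromosome = chromosome, start = as.integer(start),
                 end = as.integer(end), ref = ref, alt = alt,
                 sample_id = sample_id, ...)
}

# positions whose IMD sequence is 10 slow gaps (1000 bp) then 10 fast (10 bp)
two_rate_positions <- function() {
  cumsum(c(rep(1000, 10), rep(10, 10)))
}

# a small single-sample VCF written to a temp file
write_test_vcf <- function(path, rows = NULL) {
  rows <- rows %||% c(
    "1\t100\t.\tC\tT\t.\tPASS\t.",
    "1\t250\t.\tG\tA\t.\tPASS\t.",
    "1\t900\t.\tT\tG\t.\tlowqual\t."
  )
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows
  ), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force interval union used as oracle for overlap merging
interval_union_oracle <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- ue <- numeric(0)
  for (i in seq_along(start)) {
    if (length(us) > 0 && start[i] <= ue[length(ue)]) {
      ue[length(ue)] <- max(ue[length(ue)], end[i])
    } else {
      us <- c(us, start[i]); ue <- c(ue, end[i])
    }
  }
  list(start = us, end = ue)
}
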