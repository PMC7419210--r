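test_that("read_bed parses coordinates, preserves order, validates input", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr4\t155451842\t155466390\tLCR16a-003",
               "chr1\t10\t20"), p)
  x <- read_bed(p)
  expect_equal(nrow(x), 2)
  expect_equal(x$end[1] - x$start[1], 14548)
  expect_equal(x$chrom, c("chr4", "chr1")) # input order kept
  expect_true(is.na(x$name[2]))

  # 1-based inclusive input shifts start down by one
  x1 <- read_bed(p, one_based = TRUE)
  expect_equal(x1$start[1], 155451841)
  expect_equal(x1$end[1], 155466390)

  writeLines(character(), p)
  expect_equal(nrow(read_bed(p)), 0)

  writeLines("chr1\t5\t5", p)
  expect_error(read_bed(p), "start >= end")
  writeLines("chr1\t5", p)
  expect_error(read_bed(p), "line 1")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "not found")
})

test_that("write_bed round-trips a region set", {
  p <- withr::local_tempfile(fileext = ".bed")
  x <- region_tbl(c("chr1", "chr2"), c(0, 100), c(50, 400), name = c("a", "b"))
  write_bed(x, p)
  y <- read_bed(p)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)
})

test_that("merge_intervals coalesces overlapping and abutting intervals", {
  m <- merge_intervals(region_tbl("chr1", c(10, 40), c(50, 80)))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(10, 80))

  # abutting intervals merge; disjoint stay apart
  m2 <- merge_intervals(region_tbl("chr1", c(10, 50, 200), c(50, 80, 300)))
  expect_equal(nrow(m2), 2)
  expect_equal(m2$end[1], 80)

  disj <- region_tbl(c("chr1", "chr2"), c(0, 0), c(10, 10))
  expect_equal(nrow(merge_intervals(disj)), 2)
})

test_that("merge is idempotent and conserves covered bases", {
  set.seed(42)
  for (i in 1:20) {
    x <- random_regions(15)
    m <- merge_intervals(x)
    expect_identical(merge_intervals(m), m)
    # base-set union oracle
    covered <- unique(unlist(lapply(seq_len(nrow(x)), function(k) {
      paste(x$chrom[k], seq(x$start[k], x$end[k] - 1))
    })))
    expect_equal(covered_bases(m), length(covered))
    # merged output has no overlapping or abutting neighbors
    by_chr <- split(m, m$chrom)
    for (b in by_chr) {
      if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    }
  }
})

test_that("allowed_space complements the exclusion mask exactly", {
  sizes <- tibble::tibble(chrom = c("chrA", "chrB"), size = c(1000, 500))
  gc <- tibble::tibble(chrom = "chrA", start = 0, end = 1000, gc = 0.4)
  land <- genome_landscape(sizes, gc)
  expect_equal(sum(allowed_space(land)$end - allowed_space(land)$start), 1500)

  land2 <- genome_landscape(sizes, gc,
                            exclusion = region_tbl(c("chrA", "chrB"), c(100, 0),
                                                   c(200, 500)))
  a <- allowed_space(land2)
  expect_false("chrB" %in% a$chrom) # fully masked chromosome absent
  expect_equal(a$start[a$chrom == "chrA"], c(0, 200))
  expect_equal(a$end[a$chrom == "chrA"], c(100, 1000))
  # partition: allowed + excluded bases sum to each chromosome length
  expect_equal(sum(a$end - a$start) + covered_bases(land2$exclusion), 1500)

  land3 <- genome_landscape(sizes, gc,
                            exclusion = region_tbl(c("chrA", "chrB"), c(0, 0),
                                                   c(1000, 500)))
  expect_error(allowed_space(land3), "entire genome")
})

test_that("flanking_unique walks outward over the unique mask", {
  sizes <- tibble::tibble(chrom = "chr1", size = 1e6)
  gc <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, gc = 0.4)
  block <- region_tbl("chr1", 50000, 60000, role = "block")

  # unobstructed: one clean 10-kbp interval each side
  land <- genome_landscape(sizes, gc)
  f <- flanking_unique(block, land)
  expect_equal(f$start, c(40000, 60000))
  expect_equal(f$end, c(50000, 70000))
  expect_false(any(f$truncated))

  # block at chromosome start: left side truncated (absent), right present
  f0 <- flanking_unique(region_tbl("chr1", 0, 10000), land)
  expect_equal(unique(f0$side), "right")
  expect_true(attr(f0, "truncated_sides")[["left"]])

  # an SD abutting the right edge: the walk skips it and collects unique
  # bases starting at its far end
  land_sd <- genome_landscape(sizes, gc,
                              sd_mask = region_tbl("chr1", 60000, 65000))
  fs <- flanking_unique(block, land_sd)
  right <- fs[fs$side == "right", ]
  expect_equal(right$start, 65000)
  expect_equal(right$end, 75000)

  # output never intersects the SD mask and sums to <= 2 * flank_len
  set.seed(7)
  sd_mask <- merge_intervals(random_regions(10, chroms = "chr1", max_pos = 2e5))
  land_r <- genome_landscape(sizes, gc, sd_mask = sd_mask)
  fr <- flanking_unique(region_tbl("chr1", 100000, 120000), land_r, flank_len = 5000)
  expect_lte(sum(fr$end - fr$start), 10000)
  expect_equal(oracle_overlap_elements(fr, sd_mask), 0)
})

test_that("overlap_elements counts distinct elements once", {
  reps <- tibble::tibble(chrom = "chr1", start = 100, end = 400,
                         repeat_class = "SINE", family = "AluS")
  expect_equal(overlap_elements(region_tbl("chr1", 0, 50), reps, "SINE"), 0)
  expect_equal(overlap_elements(region_tbl("chr1", 0, 200), reps, "SINE"), 1)

  # one LINE spanning two adjacent regions counts once at the set level
  line <- tibble::tibble(chrom = "chr1", start = 90, end = 210,
                         repeat_class = "LINE", family = "L1")
  two <- region_tbl("chr1", c(0, 100), c(100, 200))
  expect_equal(overlap_elements(two, line, "LINE"), 1)
  # ... but contributes to each region's own count
  expect_equal(overlap_counts_per_region(two, line, "LINE"), c(1L, 1L))
})

test_that("overlap_elements agrees with a brute-force scan", {
  set.seed(11)
  for (i in 1:15) {
    regions <- random_regions(8)
    elems <- random_regions(20)
    elems$repeat_class <- "SINE"
    elems$family <- "AluY"
    expect_equal(overlap_elements(regions, elems, "SINE"),
                 oracle_overlap_elements(regions, elems))
  }
})

test_that("repeat classes outside the enum map to other", {
  r <- tibble::tibble(chrom = "chr1", start = 0, end = 10,
                      repeat_class = c("SINE/Alu", "Simple_repeat", "LINE/L1"),
                      family = c("AluY", "(AT)n", "L1PA3"))
  sizes <- tibble::tibble(chrom = "chr1", size = 100)
  gc <- tibble::tibble(chrom = "chr1", start = 0, end = 100, gc = 0.4)
  land <- genome_landscape(sizes, gc, repeats = r)
  expect_setequal(land$repeats$repeat_class, c("LINE", "other", "SINE"))
})

test_that("read_repeatmasker tolerates headers and 1-based coordinates", {
  p <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query      position in query           matching repeat",
    "score   div. del. ins.  sequence    begin     end    (left)    repeat class/family",
    "",
    "  463   1.3  0.6  1.7  chr1        1001      1300  (1000) +  AluSx  SINE/Alu   1 297 (15) 1",
    "  240  25.1  5.0  2.0  chr1        5001     10000  (500)  C  L1PA4  LINE/L1    2 600 (0)  2"),
    p)
  r <- read_repeatmasker(p)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(1000, 5000))
  expect_equal(r$end, c(1300, 10000))
  expect_equal(r$repeat_class, c("SINE", "LINE"))
  expect_equal(r$family, c("AluSx", "L1PA4"))
})

test_that("gc_track_from_fasta windows GC correctly", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", paste0(strrep("GC", 10), strrep("AT", 10))), p)
  g <- gc_track_from_fasta(p, window = 20)
  expect_equal(nrow(g), 2)
  expect_equal(g$gc, c(1, 0))
})
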