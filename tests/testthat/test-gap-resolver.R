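# N-gap detection, read collection and overlap-consensus assembly.

test_that("find_gaps reports maximal N-runs in coordinate order", {
  g <- find_gaps("ACGTNNNNACGT", min_run = 2)
  expect_equal(g$start, 4L)
  expect_equal(g$end, 8L)
  expect_equal(nrow(find_gaps("ACGT", min_run = 1)), 0L)
  g2 <- find_gaps("NNACGTNN", min_run = 2)
  expect_equal(g2$start, c(0L, 6L))
  expect_equal(g2$end, c(2L, 8L))
  expect_equal(nrow(find_gaps("", min_run = 2)), 0L)
  expect_error(find_gaps("ACGT", min_run = 0), "min_run")
})

make_pair_records <- function(qname, pos1, seq1, pos2, seq2) {
  rl1 <- nchar(seq1)
  rl2 <- nchar(seq2)
  tibble::tibble(
    qname = qname, flag = c(99L, 147L), rname = "scaffold_1",
    pos = c(pos1, pos2), mapq = 60L, cigar = paste0(c(rl1, rl2), "M"),
    rnext = "=", pnext = c(pos2, pos1), tlen = c(pos2 - pos1 + rl2, -(pos2 - pos1 + rl2)),
    seq = c(seq1, seq2), qual = strrep("I", c(rl1, rl2))
  )
}

test_that("collect_flanking_reads applies the window and straddle rules", {
  gap <- tibble::tibble(scaffold = "scaffold_1", start = 1000L, end = 1200L,
                        width = 200L, flank_window = 500L)
  near <- make_pair_records("near", 1000L - 50L + 1L, strrep("A", 100),
                            1000L - 50L + 201L, strrep("C", 100))
  far <- make_pair_records("far", 11000L, strrep("G", 100), 11200L, strrep("T", 100))
  straddling <- make_pair_records("str", 851L, strrep("A", 100),
                                  1251L, strrep("C", 100))
  pairs <- collect_flanking_reads(dplyr::bind_rows(near, far, straddling), gap)
  expect_setequal(pairs$qname, c("near", "str"))
  expect_true(pairs$straddle[pairs$qname == "str"])
  expect_false(pairs$straddle[pairs$qname == "near"])
  expect_equal(nrow(collect_flanking_reads(near[0, ], gap)), 0L)
})

test_that("assemble_gap returns unfillable without flank-anchored reads", {
  gap <- tibble::tibble(start = 1000L, end = 1200L, flank_window = 500L)
  out <- assemble_gap(tibble::tibble(), gap)
  expect_equal(out$status, "unfillable")
  expect_true(is.na(out$fill))
})

test_that("a single spanning read bridges a short gap exactly", {
  scaffold <- withr::with_seed(11L, ignarkit:::random_dna(600))
  masked <- mask_gap(scaffold, c(280, 320))
  gap <- find_gaps(masked$scaffold, min_run = 10)[1, ]
  # one read spanning the gap plus a right-anchored mate
  span_seq <- substr(scaffold, 231, 380)
  right_seq <- substr(scaffold, 331, 480)
  rec <- make_pair_records("bridge", 231L, span_seq, 331L, right_seq)
  pairs <- collect_flanking_reads(rec, gap)
  fill <- assemble_gap(pairs, gap)
  expect_equal(fill$status, "filled")
  # the fill equals direct substring extraction from the spanning read
  expect_equal(fill$fill, substr(span_seq, 280 - 230 + 1, 320 - 230))
  expect_equal(fill$fill, masked$truth)
})

test_that("error-free pairs at deep coverage recover planted gaps exactly", {
  for (seed in c(101L, 202L, 303L)) {
    fx <- make_gap_fixture(seed)
    pairs <- collect_flanking_reads(fx$alignments, fx$gap)
    fill <- assemble_gap(pairs, fx$gap)
    expect_equal(fill$status, "filled")
    expect_equal(fill$fill, fx$truth)
    # support never exceeds the number of collected reads
    expect_true(all(fill$support <= 2L * nrow(pairs)))
    expect_true(all(fill$support >= 1L))
    patched <- patch_scaffold(fx$masked, fx$gap, fill$fill)
    expect_false(grepl("N", substr(patched$scaffold, fx$gap$start + 1,
                                   fx$gap$start + nchar(fill$fill)), fixed = TRUE))
    expect_equal(patched$scaffold, fx$scaffold)
  }
})

test_that("patch_scaffold replaces the N-run and reports coordinate shifts", {
  gap <- tibble::tibble(start = 2L, end = 4L)
  out <- patch_scaffold("ACNNGT", gap, "TT")
  expect_equal(out$scaffold, "ACTTGT")
  expect_equal(out$offsets$offset[out$offsets$segment == "downstream"], 0L)
  longer <- patch_scaffold("ACNNGT", gap, "TTTT")
  expect_equal(nchar(longer$scaffold), 6L + 2L)
  expect_equal(longer$offsets$offset[longer$offsets$segment == "downstream"], 2L)
  expect_error(patch_scaffold("ACNNGT", gap, "AANA"), "without N")
})
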