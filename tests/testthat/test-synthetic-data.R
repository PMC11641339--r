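# Synthetic locus, read and repertoire generators.

test_that("packaged architectures build loci with the expected exon structure", {
  l1 <- ignar1_locus()
  l2 <- ignar2_locus()
  expect_equal(nrow(l1$exons), 10L)
  expect_equal(nrow(l2$exons), 9L)
  expect_equal(which(l1$exons$domain == "VNAR"), 2L)
  expect_equal(which(l2$exons$domain == "VNAR"), 2L)
  expect_equal(which(l1$exons$domain %in% paste0("C", 1:5)), 4:8)
  expect_equal(which(l2$exons$domain %in% paste0("C", 1:5)), 3:7)
  for (l in list(l1, l2)) {
    expect_true(all(diff(l$exons$start) > 0))
    expect_true(all(utils::head(l$exons$end, -1) <= utils::tail(l$exons$start, -1)))
    # exon sequences on the scaffold encode the exon peptides
    for (i in seq_len(nrow(l$exons))) {
      dna <- substr(l$scaffold, l$exons$start[i] + 1, l$exons$end[i])
      aa <- ignarkit:::translate_dna(dna)
      expect_equal(sub("\\*$", "", aa), l$exon_peptides[[i]])
    }
  }
})

test_that("degenerate architectures are rejected", {
  expect_error(
    locus_architecture("bad", domains = c("leader", "VNAR", "C1"),
                       exon_aa = c(20, 113, 100), intron_len = c(0, 100)),
    "intron"
  )
  expect_error(
    locus_architecture("bad", domains = c("leader", "VNAR", "C1"),
                       exon_aa = c(20, 113, 100), intron_len = c(100, 100),
                       exon_bp = c(60, 339, 100)),
    "multiple of 3"
  )
})

test_that("every packaged isoform splices to an in-frame stop-free CDS", {
  for (fx in list(list(ignar1_locus(), ignar1_isoforms),
                  list(ignar2_locus(), ignar2_isoforms))) {
    locus <- fx[[1]]
    isoforms <- fx[[2]](locus)
    for (iso in isoforms) {
      cds <- ignarkit:::isoform_sequence(iso, locus)
      expect_equal(nchar(cds) %% 3, 0)
      aa <- ignarkit:::translate_dna(cds)
      expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    }
  }
  expect_equal(which(vapply(ignar1_isoforms(), `[[`, logical(1), "short_form")), 6L)
  expect_equal(which(vapply(ignar2_isoforms(), `[[`, logical(1), "short_form")), 3L)
})

test_that("mask_gap substitutes N and returns the hidden truth", {
  m <- mask_gap("ACGTACGT", c(2, 4))
  expect_equal(m$scaffold, "ACNNACGT")
  expect_equal(m$truth, "GT")
  m0 <- mask_gap("ACGTACGT", c(3, 3))
  expect_equal(m0$scaffold, "ACGTACGT")
  expect_equal(m0$truth, "")
  mall <- mask_gap("ACGT", c(0, 4))
  expect_equal(mall$scaffold, "NNNN")
  expect_error(mask_gap("ACGT", c(2, 9)), "bounds")
})

test_that("genomic read simulation matches the coverage formula and is deterministic", {
  scaffold <- withr::with_seed(1L, ignarkit:::random_dna(10000))
  sim <- simulate_genomic_reads(scaffold, coverage = 30, read_len = 100,
                                insert = 300, err = 0, seed = 7)
  expect_lt(abs(nrow(sim$pairs) - 1500) / 1500, 0.1)
  # error-free reads are exact substrings of the truth (mate 2 after revcomp)
  idx <- sample.int(nrow(sim$pairs), 50)
  for (i in idx) {
    expect_true(grepl(sim$pairs$read1[i], scaffold, fixed = TRUE))
    expect_true(grepl(revcomp(sim$pairs$read2[i]), scaffold, fixed = TRUE))
  }
  # mates on opposite strands in SAM emission
  rec <- sam_records(sim)
  expect_setequal(unique(rec$flag), c(99L, 147L))
  # same seed -> byte-identical FASTQ
  d1 <- withr::local_tempdir()
  sim2 <- simulate_genomic_reads(scaffold, coverage = 30, read_len = 100,
                                 insert = 300, err = 0, seed = 7)
  write_fastq(sim, file.path(d1, "a"))
  write_fastq(sim2, file.path(d1, "b"))
  expect_identical(readLines(file.path(d1, "a_1.fastq")),
                   readLines(file.path(d1, "b_1.fastq")))
  expect_identical(readLines(file.path(d1, "a_2.fastq")),
                   readLines(file.path(d1, "b_2.fastq")))
  expect_error(simulate_genomic_reads(scaffold, err = 1.5), "err")
  expect_error(simulate_genomic_reads(scaffold, read_len = 400, insert = 300),
               "insert")
})

test_that("spliced fragments stay inside their isoform's exons", {
  locus <- ignar1_locus()
  isoforms <- ignar1_isoforms(locus)
  sim <- simulate_spliced_reads(isoforms, locus, n_fragments = 500, seed = 3)
  exon_keys <- paste(locus$exons$start, locus$exons$end)
  expect_true(all(paste(sim$blocks$start, sim$blocks$end) %in% exon_keys))
  # single-isoform input: all junctions observed are that isoform's junctions
  one <- simulate_spliced_reads(isoforms[1], locus, n_fragments = 50, seed = 4)
  planted <- isoform_junctions(isoforms[[1]], locus)
  ch <- collapse_isoforms(one, min_support = 1)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$junctions[[1]], planted)
  # degenerate mixture: zero-abundance isoform yields no fragments
  iso2 <- list(isoforms[[1]], isoform_model(locus, 1:9, abundance = 0))
  mix <- simulate_spliced_reads(iso2, locus, n_fragments = 200, seed = 5)
  expect_false(any(mix$alignments$isoform == iso2[[2]]$name))
  # read_len mode: partial fragments, contract error when too long
  short <- simulate_spliced_reads(isoforms, locus, n_fragments = 100,
                                  read_len = 150, seed = 6)
  widths <- short$blocks |>
    dplyr::group_by(fragment_id) |>
    dplyr::summarise(w = sum(end - start))
  expect_true(all(widths$w == 150))
  expect_error(
    simulate_spliced_reads(isoforms, locus, n_fragments = 10, read_len = 1e6),
    "read_len"
  )
  expect_error(simulate_spliced_reads(list(), locus, 10), "at least one")
})

test_that("repertoire generation honours its configuration", {
  # zero mutation rate and a point-mass CDR3 -> all sequences identical
  cfg0 <- repertoire_config(n_sequences = 20, hv_mut_rate = 0,
                            cdr3_length_dist = c(`14` = 1),
                            cdr3_cys_dist = c(`2` = 1),
                            fr2_cys = TRUE, seed = 1)
  rep0 <- generate_repertoire(cfg0)
  expect_equal(length(unique(substr(rep0$sequences, 1, 88))), 1L)
  expect_true(all(rep0$truth$cdr3_cys == 2))
  # framework positions outside the hypervariable regions are never mutated
  cfg <- repertoire_config(n_sequences = 200, hv_mut_rate = 0.5, seed = 2)
  rep <- generate_repertoire(cfg)
  sch <- cfg$scheme
  tpl <- cfg$template
  fr1 <- substr(rep$sequences, 1, sch$lengths$FR1)
  expect_true(all(fr1 == tpl[["FR1"]]))
  fr3a_start <- sch$lengths$FR1 + sch$lengths$CDR1 + sch$lengths$FR2 + sch$lengths$HV2 + 1
  fr3a <- substr(rep$sequences, fr3a_start, fr3a_start + sch$lengths$FR3a - 1)
  expect_true(all(fr3a == tpl[["FR3a"]]))
  # canonical cysteines always present
  expect_true(all(substr(rep$sequences, 22, 22) == "C"))
  expect_true(all(substr(rep$sequences, 84, 84) == "C"))
  expect_error(repertoire_config(hv_mut_rate = 1.2), "hv_mut_rate")
  expect_error(repertoire_config(cdr3_cys_dist = c(`1` = 0.5, `2` = 0.4)),
               "sum to 1")
})

test_that("FASTA/FASTQ/SAM round-trips preserve sequences", {
  d <- withr::local_tempdir()
  seqs <- c(a = "ACGTACGT", b = "GGGNCCC")
  write_fasta(seqs, file.path(d, "x.fasta"))
  expect_equal(read_fasta(file.path(d, "x.fasta")), seqs)
  scaffold <- withr::with_seed(2L, ignarkit:::random_dna(3000))
  sim <- simulate_genomic_reads(scaffold, coverage = 5, seed = 9)
  write_fastq(sim, file.path(d, "r"))
  fq <- read_fastq(file.path(d, "r_1.fastq"))
  expect_equal(fq$seq, sim$pairs$read1)
  rec <- sam_records(sim)
  write_sam(rec, file.path(d, "x.sam"), c(scaffold_1 = nchar(scaffold)))
  back <- read_sam(file.path(d, "x.sam"))
  expect_equal(back$seq, rec$seq)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$cigar, rec$cigar)
})
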