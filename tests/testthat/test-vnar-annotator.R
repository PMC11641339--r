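# ORF extraction, positional VNAR annotation, typing, census, PCR.

test_that("longest_orf picks the longest ATG-initiated frame, leftmost on ties", {
  expect_equal(longest_orf("ATGAAATAG")$peptide, "MK")
  expect_equal(longest_orf("CCATGAAATAGATGGGGTAA")$peptide, "MK")
  orf <- longest_orf(strrep("C", 30))
  expect_equal(orf$status, "no-start")
  expect_equal(orf$peptide, "")
  # ORF without a downstream stop runs to the end of the frame
  expect_equal(longest_orf("ATGAAAGGG")$peptide, "MKG")
  expect_error(longest_orf("AT"), "at least 3")
})

test_that("annotation reproduces planted truth spans on a synthetic repertoire", {
  cfg <- repertoire_config(n_sequences = 60, fr2_cys = TRUE, seed = 31)
  rep <- generate_repertoire(cfg)
  ann <- annotate_repertoire(rep)
  truth <- tidy(rep)
  expect_equal(ann$cdr3_start, truth$cdr3_start)
  expect_equal(ann$cdr3_end, truth$cdr3_end)
  expect_equal(ann$cdr3_cys, truth$cdr3_cys)
  expect_true(all(ann$canonical_ok))
  expect_true(all(ann$fr4_found))
  # region spans tile the sequence over the annotated extent
  a1 <- ann$annotation[[1]]
  tiled <- paste(a1$regions$seq, collapse = "")
  expect_equal(tiled, a1$sequence)
})

test_that("annotation degrades with diagnostics on rule violations", {
  cfg <- repertoire_config(n_sequences = 1, fr2_cys = TRUE,
                           cdr3_cys_dist = c(`2` = 1), seed = 32)
  s <- unname(generate_repertoire(cfg)$sequences[1])
  # canonical cysteines mutated out -> unclassified with diagnostics
  broken <- s
  substr(broken, 22, 22) <- "A"
  ab <- annotate_vnar(broken)
  expect_equal(ab$type, "unclassified")
  expect_match(ab$diagnostics, "canonical")
  # no FR4 anchor -> CDR3 extends to the terminus, flagged
  no_anchor <- gsub("YGGG", "ASSS", s)
  aa <- annotate_vnar(no_anchor)
  expect_false(aa$fr4_found)
  cdr3 <- aa$regions[aa$regions$region == "CDR3", ]
  expect_equal(cdr3$end, nchar(no_anchor))
  expect_error(annotate_vnar("MKV"), "shorter")
})

test_that("type calls follow the cysteine-pattern rules with fixed bond counts", {
  mk_seq <- function(fr2_cys, cdr1_cys, cdr3_cys) {
    cfg <- repertoire_config(n_sequences = 1, hv_mut_rate = 0,
                             cdr3_length_dist = c(`14` = 1),
                             cdr3_cys_dist = setNames(1, cdr3_cys),
                             fr2_cys = fr2_cys, cdr1_cys = cdr1_cys, seed = 33)
    unname(generate_repertoire(cfg)$sequences[1])
  }
  type1 <- annotate_vnar(mk_seq(TRUE, FALSE, 2))
  expect_equal(type1$type, "I")
  expect_equal(nrow(type1$bonds), 3L)
  expect_setequal(paste(type1$bonds$from_region, type1$bonds$to_region),
                  c("FR1 FR3b", "FR2 CDR3", "CDR3 FR4"))
  type2 <- annotate_vnar(mk_seq(FALSE, TRUE, 1))
  expect_equal(type2$type, "II")
  expect_equal(nrow(type2$bonds), 2L)
  expect_setequal(paste(type2$bonds$from_region, type2$bonds$to_region),
                  c("FR1 FR3b", "CDR1 CDR3"))
  canon <- annotate_vnar(mk_seq(FALSE, FALSE, 0))
  expect_equal(canon$type, "canonical-only")
  expect_equal(nrow(canon$bonds), 1L)
  # ambiguous: cysteines in both FR2 and CDR1
  both <- mk_seq(TRUE, FALSE, 2)
  substr(both, 29, 29) <- "C"  # CDR1 position
  ambig <- annotate_vnar(both)
  expect_equal(ambig$type, "unclassified")
  expect_setequal(ambig$candidates, c("I", "II"))
})

test_that("type calls depend only on cysteine placement", {
  cfg <- repertoire_config(n_sequences = 10, fr2_cys = TRUE,
                           cdr3_cys_dist = c(`2` = 1), seed = 34)
  rep <- generate_repertoire(cfg)
  withr::with_seed(35L, {
    for (s in rep$sequences[1:5]) {
      ann <- annotate_vnar(s)
      chars <- strsplit(s, "")[[1]]
      # permute non-cysteine residues of the fixed FR1..FR3b block (region
      # boundaries there are positional, so spans are unaffected)
      non_cys <- which(chars[1:88] != "C")
      perm <- chars
      perm[non_cys] <- chars[sample(non_cys)]
      ann_p <- annotate_vnar(paste(perm, collapse = ""))
      expect_equal(ann_p$type, ann$type)
      expect_equal(nrow(ann_p$bonds), nrow(ann$bonds))
    }
  })
})

test_that("census histograms count CDR3 cysteines exactly", {
  cfg <- repertoire_config(n_sequences = 1, cdr3_cys_dist = c(`2` = 1),
                           fr2_cys = TRUE, seed = 36)
  ann <- annotate_repertoire(generate_repertoire(cfg))
  cen <- census(ann)
  expect_equal(tidy(cen)$cdr3_cys, 2L)
  expect_equal(tidy(cen)$n, 1L)
  # point mass over 100 sequences
  cfg100 <- repertoire_config(n_sequences = 100, cdr3_cys_dist = c(`2` = 1),
                              fr2_cys = TRUE, seed = 37)
  cen100 <- census(annotate_repertoire(generate_repertoire(cfg100)))
  expect_equal(tidy(cen100)$n, 100L)
  expect_equal(tidy(cen100)$frac, 1)
  # canonical-only repertoires have zero CDR3 cysteines
  cfg0 <- repertoire_config(n_sequences = 20, cdr3_cys_dist = c(`0` = 1),
                            fr2_cys = FALSE, cdr1_cys = FALSE, seed = 38)
  cen0 <- census(annotate_repertoire(generate_repertoire(cfg0)))
  expect_equal(tidy(cen0)$cdr3_cys, 0L)
  expect_equal(tidy(cen0)$n, 20L)
  empty <- census(annotate_repertoire(character(0)))
  expect_equal(empty$n, 0L)
})

test_that("constant-domain cysteine checks read planted locus truth", {
  locus <- ignar1_locus()
  isoforms <- ignar1_isoforms(locus)
  full_aa <- ignarkit:::translate_dna(ignarkit:::isoform_sequence(isoforms[[1]], locus))
  full_aa <- sub("\\*$", "", full_aa)
  cc <- check_constant_domains(full_aa, domain_protein_ranges(locus))
  expect_equal(cc$counts$domain, paste0("C", 1:5))
  expect_equal(cc$counts$n_cys, c(3L, 2L, 2L, 2L, 2L))
  expect_true(cc$linker_cys)
  # short form reports C1-C3 only
  iso6 <- isoforms[[6]]
  aa6 <- ignarkit:::translate_dna(ignarkit:::isoform_sequence(iso6, locus))
  cc6 <- check_constant_domains(aa6, domain_protein_ranges(locus, iso6$chain))
  expect_equal(cc6$counts$domain, paste0("C", 1:3))
  # no linker cysteine -> flag false
  clean <- gsub("C", "A", full_aa)
  ranges <- domain_protein_ranges(locus)
  cc_clean <- check_constant_domains(clean, ranges)
  expect_false(cc_clean$linker_cys)
  expect_error(check_constant_domains(full_aa, NULL), "missing")
})

test_that("in-silico PCR respects IUPAC codes and the 3' exactness rule", {
  insert <- withr::with_seed(41L, ignarkit:::random_dna(400))
  fwd_site <- "ATGCATGCATGCATGCATGC"
  rev_site <- "GGGGCCCCAAAATTTTGGCC"
  template <- paste0("AAAA", fwd_site, insert, rev_site, "TTTT")
  fwd <- primer_spec("F", fwd_site, "forward")
  rev <- primer_spec("R", revcomp(rev_site), "reverse")
  amp <- in_silico_pcr(template, fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 440L)
  expect_equal(amp$seq, paste0(fwd_site, insert, rev_site))
  # primer with internal N still hits
  fwd_n <- primer_spec("FN", sub("^(.{8}).", "\\1N", fwd_site), "forward")
  expect_equal(nrow(in_silico_pcr(template, fwd_n, rev)), 1L)
  # mismatch in the final 3' base kills the hit
  fwd_bad <- primer_spec("F3", sub(".$", "A", fwd_site), "forward")
  expect_equal(nrow(in_silico_pcr(template, fwd_bad, rev)), 0L)
  expect_error(primer_spec("bad", ""), "non-empty")
  expect_error(primer_spec("bad", "ACGU"), "IUPAC")
})
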