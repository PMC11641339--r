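# Synthetic IgNAR-like locus construction.
#
# The generator plants a complete locus (leader, VNAR, constant-domain and tail
# exons separated by introns) inside a random scaffold, with every feature the
# downstream modules look for: canonical FR1/FR3b cysteines, type-defining
# noncanonical cysteines, three cysteines in C1 versus two in C2-C5, an extra
# cysteine in the C3-C4 linker, and exon lengths that are whole codons so that
# any exon-skipping chain stays in frame.

# Default VNAR framework templates. Fixed lengths FR1 25 / CDR1 8 / FR2 10 /
# HV2 8 / FR3a 16 / HV4 6 / FR3b 15 give the constant FR1..FR3b total of 88 aa;
# canonical cysteines sit at FR1 offset 22 and FR3b offset 11.
VNAR_TEMPLATES <- list(
  FR1  = "ARVDQTPQTITKETGESLTINCVLR",
  CDR1 = "TYWYRKNP",
  FR2  = "PGRYVETVNS",
  HV2  = "SGSKSFSL",
  FR3a = "TIRDLTVADSATYYKA",
  HV4  = "NSGSKD",
  FR3b = "LTITNVQPEDCGTYY",
  FR4  = "YGGGTAVTVNA"
)
FR1_CYS_OFFSET <- 22L
FR3B_CYS_OFFSET <- 11L
FR2_CYS_OFFSET <- 5L
CDR1_CYS_OFFSET <- 4L
FR4_CYS_OFFSET <- 6L

set_char <- function(x, pos, ch) {
  substr(x, pos, pos) <- ch
  x
}

# Shared ancestral peptides for the packaged loci; a fixed master seed makes
# the packaged loci homologous (so one query finds them all) while each locus
# diverges from this base at its own rate.
base_domain_peptides <- function() {
  withr::with_seed(90411L, {
    list(
      leader = paste0("M", random_peptide(19L)),
      cdr1 = random_peptide(nchar(VNAR_TEMPLATES$CDR1)),
      hv2 = random_peptide(nchar(VNAR_TEMPLATES$HV2)),
      hv4 = random_peptide(nchar(VNAR_TEMPLATES$HV4)),
      cdr3 = random_peptide(14L, exclude = c("C", "G")),
      spacer = random_peptide(11L),
      C1 = local({
        p <- random_peptide(100L)
        p <- set_char(p, 25L, "C"); p <- set_char(p, 50L, "C"); set_char(p, 75L, "C")
      }),
      C2 = local({p <- random_peptide(100L); p <- set_char(p, 25L, "C"); set_char(p, 75L, "C")}),
      C3 = local({p <- random_peptide(100L); p <- set_char(p, 25L, "C"); set_char(p, 75L, "C")}),
      C4 = local({p <- random_peptide(100L); p <- set_char(p, 25L, "C"); set_char(p, 75L, "C")}),
      C5 = local({p <- random_peptide(100L); p <- set_char(p, 25L, "C"); set_char(p, 75L, "C")}),
      linker = set_char(random_peptide(6L), 4L, "C"),
      tail1 = random_peptide(30L),
      tail2 = random_peptide(12L)
    )
  })
}

# assemble the VNAR exon peptide for a locus from templates + hypervariable parts
vnar_exon_peptide <- function(cdr1, hv2, hv4, cdr3, fr2_cys, cdr1_cys, n_cdr3_cys) {
  fr2 <- VNAR_TEMPLATES$FR2
  fr4 <- VNAR_TEMPLATES$FR4
  if (fr2_cys) {
    fr2 <- set_char(fr2, FR2_CYS_OFFSET, "C")
    fr4 <- set_char(fr4, FR4_CYS_OFFSET, "C")
  }
  if (cdr1_cys) cdr1 <- set_char(cdr1, CDR1_CYS_OFFSET, "C")
  if (n_cdr3_cys > 0L) {
    len <- nchar(cdr3)
    pos <- unique(pmax(1L, pmin(len, round(seq(0.25, 0.75, length.out = n_cdr3_cys) * len))))
    for (p in pos) cdr3 <- set_char(cdr3, p, "C")
  }
  paste0(VNAR_TEMPLATES$FR1, cdr1, fr2, hv2, VNAR_TEMPLATES$FR3a, hv4,
         VNAR_TEMPLATES$FR3b, cdr3, fr4)
}

#' Describe the architecture of a synthetic IgNAR-like locus
#'
#' An architecture fixes everything `build_locus()` needs: exon order and
#' domain assignment, exon sizes (in codons or bp), intron sizes, the
#' type-defining cysteine placements of the VNAR exon, and the divergence of
#' this locus from the shared ancestral domain peptides.
#'
#' @param name Locus label.
#' @param domains Character vector, one entry per exon, over
#'   `{leader, VNAR, C1..C5, tail}` with `NA` for unassigned exons.
#' @param exon_aa Integer amino-acid length per exon (ignored for the VNAR exon,
#'   whose length follows the framework templates and `cdr3_len`).
#' @param intron_len Integer intron lengths (bp), one per inter-exon gap; all
#'   must be positive.
#' @param exon_bp Optional explicit exon lengths in bp overriding `exon_aa`;
#'   constant-domain entries must be whole codons.
#' @param flank Flanking sequence added on each side of the locus (bp).
#' @param linker_cys Plant an extra cysteine in the C3-C4 linker?
#' @param fr2_cys,cdr1_cys Noncanonical cysteine placement of the VNAR exon
#'   (type-I-like vs type-II-like).
#' @param cdr3_cys Number of cysteines planted in the VNAR exon's CDR3.
#' @param cdr3_len CDR3 length (aa) encoded in the VNAR exon.
#' @param divergence Per-position substitution rate applied to the shared base
#'   peptides when building this locus (cysteine placements protected).
#' @return A `locus_architecture` list.
#' @export
locus_architecture <- function(name, domains, exon_aa, intron_len,
                               exon_bp = NULL, flank = 500L,
                               linker_cys = TRUE, fr2_cys = FALSE,
                               cdr1_cys = FALSE, cdr3_cys = 0L,
                               cdr3_len = 14L, divergence = 0.08) {
  n <- length(domains)
  if (length(exon_aa) != n) abort("exon_aa must have one entry per exon")
  if (length(intron_len) != n - 1L) {
    abort("intron_len must have one entry per inter-exon gap (n_exons - 1)")
  }
  if (any(intron_len <= 0)) abort("all intron lengths must be > 0 (zero introns requested)")
  if (any(exon_aa <= 0)) abort("all exon lengths must be > 0")
  if (!is.null(exon_bp)) {
    if (length(exon_bp) != n) abort("exon_bp must have one entry per exon")
    const <- which(domains %in% paste0("C", 1:5))
    if (any(exon_bp[const] %% 3L != 0L)) {
      abort("constant-domain exon length must be a multiple of 3 (inconsistent architecture)")
    }
    exon_aa <- exon_bp %/% 3L
  }
  structure(
    list(name = name, domains = domains, exon_aa = as.integer(exon_aa),
         intron_len = as.integer(intron_len), flank = as.integer(flank),
         linker_cys = linker_cys, fr2_cys = fr2_cys, cdr1_cys = cdr1_cys,
         cdr3_cys = as.integer(cdr3_cys), cdr3_len = as.integer(cdr3_len),
         divergence = divergence, c3_linker_aa = if (linker_cys) 6L else 0L),
    class = "locus_architecture"
  )
}

#' @rdname locus_architecture
#' @details `ignar1_architecture()` is the packaged GcIgNAR1-like model:
#'   10 exons with the VNAR at exon 2, constant domains C1-C5 at exons 4-8,
#'   an unassigned short exon 3, two tail exons, a type-I-like VNAR (FR2
#'   cysteine, two CDR3 cysteines) and a cysteine-bearing C3-C4 linker.
#'   `ignar2_architecture()` is the GcIgNAR2-like model: 9 exons, VNAR at
#'   exon 2, constant domains at exons 3-7, and a type-II-like VNAR (CDR1
#'   cysteine, one CDR3 cysteine).
#' @export
ignar1_architecture <- function() {
  locus_architecture(
    name = "GcIgNAR1",
    domains = c("leader", "VNAR", NA, "C1", "C2", "C3", "C4", "C5", "tail", "tail"),
    exon_aa = c(20L, 113L, 11L, 100L, 100L, 106L, 100L, 100L, 30L, 12L),
    intron_len = c(420L, 380L, 350L, 460L, 330L, 520L, 390L, 440L, 310L),
    linker_cys = TRUE, fr2_cys = TRUE, cdr1_cys = FALSE, cdr3_cys = 2L
  )
}

#' @rdname locus_architecture
#' @export
ignar2_architecture <- function() {
  locus_architecture(
    name = "GcIgNAR2",
    domains = c("leader", "VNAR", "C1", "C2", "C3", "C4", "C5", "tail", "tail"),
    exon_aa = c(20L, 113L, 100L, 100L, 106L, 100L, 100L, 30L, 12L),
    intron_len = c(450L, 360L, 410L, 340L, 500L, 370L, 430L, 320L),
    linker_cys = TRUE, fr2_cys = FALSE, cdr1_cys = TRUE, cdr3_cys = 1L
  )
}

#' Build a synthetic IgNAR-like locus and its scaffold
#'
#' Generates the exon peptides from the shared ancestral set (diverged at the
#' architecture's rate with all planted cysteines protected), reverse-translates
#' them with random synonymous codons, and embeds the exons between random
#' introns and flanks. The concatenated coding exons translate without internal
#' stop codons in the designed frame, and every exon is a whole number of
#' codons, so exon-skipping isoforms remain in frame.
#'
#' @param arch A `locus_architecture` (see [ignar1_architecture()]).
#' @param seed Integer seed controlling all randomness of this build.
#' @return A `locus_model` whose `scaffold` field holds the scaffold sequence.
#' @export
build_locus <- function(arch = ignar1_architecture(), seed = 4201L) {
  stopifnot(inherits(arch, "locus_architecture"))
  base <- base_domain_peptides()
  with_seed_if(seed, {
    div <- arch$divergence
    dv <- function(p, protect = integer()) mutate_peptide(p, div, protect = protect)
    peptides <- vector("list", length(arch$domains))
    for (i in seq_along(arch$domains)) {
      d <- arch$domains[i]
      peptides[[i]] <-
        if (identical(d, "leader")) {
          dv(base$leader, protect = 1L)
        } else if (identical(d, "VNAR")) {
          cdr3 <- base$cdr3
          if (arch$cdr3_len != nchar(cdr3)) {
            cdr3 <- if (arch$cdr3_len < nchar(cdr3)) {
              substr(cdr3, 1L, arch$cdr3_len)
            } else {
              paste0(cdr3, random_peptide(arch$cdr3_len - nchar(cdr3), exclude = c("C", "G")))
            }
          }
          vnar_exon_peptide(dv(base$cdr1), dv(base$hv2), dv(base$hv4),
                            mutate_peptide(cdr3, div, forbid = c("C", "G")),
                            arch$fr2_cys, arch$cdr1_cys, arch$cdr3_cys)
        } else if (identical(d, "C3") && arch$linker_cys) {
          paste0(dv(base$C3, protect = c(25L, 75L)), dv(base$linker, protect = 4L))
        } else if (!is.na(d) && d %in% paste0("C", 1:5)) {
          prot <- if (identical(d, "C1")) c(25L, 50L, 75L) else c(25L, 75L)
          dv(base[[d]], protect = prot)
        } else if (identical(d, "tail")) {
          nth <- sum(arch$domains[seq_len(i)] %in% "tail")
          dv(base[[paste0("tail", nth)]])
        } else {
          dv(base$spacer)
        }
    }
    exon_dna <- vapply(peptides, reverse_translate, character(1))
    exon_dna[length(exon_dna)] <- paste0(exon_dna[length(exon_dna)], "TAA")
    introns <- vapply(arch$intron_len, random_dna, character(1))
    left <- random_dna(arch$flank)
    right <- random_dna(arch$flank)
    pieces <- character(0)
    starts <- integer(length(exon_dna))
    ends <- integer(length(exon_dna))
    pos <- nchar(left)
    pieces <- left
    for (i in seq_along(exon_dna)) {
      starts[i] <- pos
      ends[i] <- pos + nchar(exon_dna[i])
      pieces <- c(pieces, exon_dna[i])
      pos <- ends[i]
      if (i < length(exon_dna)) {
        pieces <- c(pieces, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    pieces <- c(pieces, right)
    scaffold <- paste(pieces, collapse = "")
    exons <- tibble(
      exon = seq_along(exon_dna), start = starts, end = ends,
      domain = arch$domains
    )
    new_locus_model(
      name = arch$name, scaffold_name = paste0(arch$name, "_scaffold"),
      strand = "+", exons = exons, linker_cys = arch$linker_cys,
      scaffold = scaffold, exon_peptides = peptides, arch = arch
    )
  })
}

#' Packaged GcIgNAR1-like and GcIgNAR2-like loci
#'
#' Deterministic builds of the two packaged architectures; repeated calls
#' return identical objects.
#'
#' @param seed Build seed (fixed defaults make the fixtures reproducible).
#' @return A `locus_model`.
#' @export
ignar1_locus <- function(seed = 4201L) build_locus(ignar1_architecture(), seed = seed)

#' @rdname ignar1_locus
#' @export
ignar2_locus <- function(seed = 4202L) build_locus(ignar2_architecture(), seed = seed)

#' Packaged isoform sets
#'
#' The GcIgNAR1-like locus carries 11 isoform models and the GcIgNAR2-like
#' locus 4, all at unit abundance. Exactly one isoform per locus is the short
#' form lacking C4 and C5 (the 6th and 3rd models respectively); every exon of
#' each locus is used by at least one isoform.
#'
#' @param locus The corresponding `locus_model` (defaults to the packaged one).
#' @return List of `isoform_model` objects.
#' @export
ignar1_isoforms <- function(locus = ignar1_locus()) {
  chains <- list(
    1:10,
    c(1L, 2L, 4:10),
    c(1:8, 10L),
    c(1L, 2L, 4:8, 10L),
    1:9,
    c(1:6, 9L, 10L),          # short form: skips C4 and C5
    c(1L, 2L, 4:9),
    c(1:6, 8:10),             # skips C4 only (atypical)
    c(1:7, 9L, 10L),          # skips C5 only (atypical)
    1:8,
    c(1L, 2L, 4:8)
  )
  purrr::imap(chains, function(ch, i) {
    isoform_model(locus, ch, abundance = 1, name = paste0(locus$name, "-", i))
  })
}

#' @rdname ignar1_isoforms
#' @export
ignar2_isoforms <- function(locus = ignar2_locus()) {
  chains <- list(
    1:9,
    c(1:7, 9L),
    c(1:5, 8L, 9L),           # short form: skips C4 and C5
    1:8
  )
  purrr::imap(chains, function(ch, i) {
    isoform_model(locus, ch, abundance = 1, name = paste0(locus$name, "-", i))
  })
}

#' Multi-locus scaffold fixture for translated search
#'
#' Concatenates several packaged-architecture loci (homologous through the
#' shared ancestral peptides) on one scaffold separated by random spacers, the
#' layout used to exercise locus calling and clustering.
#'
#' @param spacing Random spacer length (bp) between consecutive loci.
#' @param seed Integer seed.
#' @return List with `scaffold` (character), `loci` (tibble of planted locus
#'   names and their scaffold spans), and `models` (the per-locus
#'   `locus_model`s in their own coordinates).
#' @export
ignar_multilocus_scaffold <- function(spacing = 10000L, seed = 7701L) {
  archs <- list(ignar1_architecture(), ignar2_architecture(), {
    a <- ignar2_architecture(); a$name <- "GcIgNAR3"; a
  })
  with_seed_if(seed, {
    seeds <- sample.int(1e6, length(archs))
    models <- purrr::map2(archs, seeds, ~ build_locus(.x, seed = .y))
    pieces <- character(0)
    offs <- integer(length(models))
    pos <- 0L
    for (i in seq_along(models)) {
      offs[i] <- pos
      pieces <- c(pieces, models[[i]]$scaffold)
      pos <- pos + nchar(models[[i]]$scaffold)
      if (i < length(models)) {
        pieces <- c(pieces, random_dna(spacing))
        pos <- pos + spacing
      }
    }
    loci <- purrr::map2_dfr(models, offs, function(m, o) {
      tibble(name = m$name, start = o + min(m$exons$start), end = o + max(m$exons$end))
    })
    list(scaffold = paste(pieces, collapse = ""), loci = loci, models = models)
  })
}

#' Reference-style query protein for translated search
#'
#' The undiverged ancestral VNAR + C1 peptide, playing the role of a published
#' IgNAR protein used as a translated-search query against scaffolds carrying
#' the packaged loci.
#'
#' @return Single amino-acid string.
#' @export
ignar_query_protein <- function() {
  base <- base_domain_peptides()
  paste0(
    vnar_exon_peptide(base$cdr1, base$hv2, base$hv4, base$cdr3,
                      fr2_cys = FALSE, cdr1_cys = FALSE, n_cdr3_cys = 0L),
    base$C1
  )
}

#' Mask a scaffold span with N and keep the hidden truth
#'
#' Emulates an assembly gap: the bases in `span` are replaced by `N`; the
#' original bases are returned separately as the recovery target. Scaffold
#' length is unchanged.
#'
#' @param scaffold Character scalar DNA sequence.
#' @param span Integer length-2 vector, 0-based half-open `(start, end)`.
#' @return List with `scaffold` (gapped sequence) and `truth` (masked bases).
#' @export
mask_gap <- function(scaffold, span) {
  L <- nchar(scaffold)
  start <- as.integer(span[1]); end <- as.integer(span[2])
  if (start < 0L || end > L || end < start) {
    abort("span outside scaffold bounds")
  }
  if (end == start) return(list(scaffold = scaffold, truth = ""))
  truth <- substr(scaffold, start + 1L, end)
  gapped <- paste0(
    substr(scaffold, 1L, start),
    strrep("N", end - start),
    substr(scaffold, end + 1L, L)
  )
  list(scaffold = gapped, truth = truth)
}
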