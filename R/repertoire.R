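# Synthetic VNAR repertoire generation.
#
# Sequences share a fixed framework (constant total length from FR1 through
# FR3b), diversify only inside CDR1/HV2/HV4 (point substitutions) and CDR3
# (variable length, controlled cysteine count), emulating a repertoire whose
# framework diversification arises from deamination-like point changes and
# whose CDR3 diversity arises from splicing plus deamination.

#' Configuration for a synthetic VNAR repertoire
#'
#' @param n_sequences Number of sequences to generate.
#' @param hv_mut_rate Per-position substitution probability applied only inside
#'   CDR1, HV2 and HV4; must lie in `[0, 1]`.
#' @param cdr3_length_dist Named numeric vector: probability per CDR3 length.
#' @param cdr3_cys_dist Named numeric vector: probability per CDR3 cysteine
#'   count. Defaults emulate a type-I-like locus when `fr2_cys` is set
#'   (majority two cysteines), a type-II-like locus when `cdr1_cys` is set
#'   (majority one), else no CDR3 cysteines.
#' @param fr2_cys Plant the type-I-like noncanonical cysteine in FR2 (and a
#'   partner cysteine in FR4)?
#' @param cdr1_cys Plant the type-II-like noncanonical cysteine in CDR1?
#' @param scheme The [vnar_scheme()] the templates follow.
#' @param framework_template Named character vector of region templates
#'   (`FR1`, `CDR1`, `FR2`, `HV2`, `FR3a`, `HV4`, `FR3b`, `FR4`); lengths must
#'   match the scheme.
#' @param seed Integer seed.
#' @return A `repertoire_config`.
#' @export
repertoire_config <- function(n_sequences = 100L, hv_mut_rate = 0.2,
                              cdr3_length_dist = NULL, cdr3_cys_dist = NULL,
                              fr2_cys = TRUE, cdr1_cys = FALSE,
                              scheme = vnar_scheme(),
                              framework_template = NULL, seed = NULL) {
  if (hv_mut_rate < 0 || hv_mut_rate > 1) abort("hv_mut_rate must lie in [0, 1]")
  if (n_sequences < 1) abort("n_sequences must be >= 1")
  cdr3_length_dist <- cdr3_length_dist %||%
    setNames(rep(1 / 7, 7), as.character(12:18))
  cdr3_cys_dist <- cdr3_cys_dist %||% {
    if (fr2_cys) {
      c(`0` = 0.05, `1` = 0.15, `2` = 0.69, `3` = 0.08, `4` = 0.03)
    } else if (cdr1_cys) {
      c(`0` = 0.17, `1` = 0.75, `2` = 0.08)
    } else {
      c(`0` = 1)
    }
  }
  check_dist(cdr3_length_dist, "cdr3_length_dist")
  check_dist(cdr3_cys_dist, "cdr3_cys_dist")
  tpl <- framework_template %||% unlist(VNAR_TEMPLATES)
  need <- c("FR1", "CDR1", "FR2", "HV2", "FR3a", "HV4", "FR3b", "FR4")
  if (!all(need %in% names(tpl))) {
    abort(paste0("framework_template must name ", paste(need, collapse = ", ")))
  }
  for (r in c("FR1", "CDR1", "FR2", "HV2", "FR3a", "HV4", "FR3b")) {
    if (nchar(tpl[[r]]) != scheme$lengths[[r]]) {
      abort(paste0("template ", r, " length does not match the scheme"))
    }
  }
  structure(
    list(n_sequences = as.integer(n_sequences), hv_mut_rate = hv_mut_rate,
         cdr3_length_dist = cdr3_length_dist, cdr3_cys_dist = cdr3_cys_dist,
         fr2_cys = fr2_cys, cdr1_cys = cdr1_cys, scheme = scheme,
         template = tpl, seed = seed),
    class = "repertoire_config"
  )
}

#' Generate a synthetic VNAR repertoire with planted truth
#'
#' Framework positions outside CDR1/HV2/HV4/CDR3 are never mutated; the
#' canonical FR1 and FR3b cysteines are always present; CDR3 lengths and
#' cysteine counts are drawn from the configured distributions. Mutations draw
#' uniformly from the 19 non-identical amino acids excluding cysteine, so the
#' cysteine census stays under the control of the configuration. Sampled CDR3
#' residues exclude cysteine (planted separately) and glycine (so the FR4
#' anchor motif cannot arise by chance inside CDR3).
#'
#' @param config A [repertoire_config()].
#' @return A `vnar_repertoire`: list with `sequences` (named character vector)
#'   and `truth` (tibble of planted region spans, CDR3 length and cysteine
#'   count per sequence).
#' @export
generate_repertoire <- function(config = repertoire_config()) {
  stopifnot(inherits(config, "repertoire_config"))
  tpl <- config$template
  sch <- config$scheme
  fr2 <- tpl[["FR2"]]
  cdr1_tpl <- tpl[["CDR1"]]
  fr4 <- tpl[["FR4"]]
  cdr1_protect <- integer()
  if (config$fr2_cys) {
    fr2 <- set_char(fr2, FR2_CYS_OFFSET, "C")
    fr4 <- set_char(fr4, FR4_CYS_OFFSET, "C")
  }
  if (config$cdr1_cys) {
    cdr1_tpl <- set_char(cdr1_tpl, CDR1_CYS_OFFSET, "C")
    cdr1_protect <- CDR1_CYS_OFFSET
  }
  with_seed_if(config$seed, {
    n <- config$n_sequences
    cdr3_len <- sample_dist(config$cdr3_length_dist, n)
    cdr3_cys <- pmin(sample_dist(config$cdr3_cys_dist, n), cdr3_len)
    rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      cdr1 <- mutate_peptide(cdr1_tpl, config$hv_mut_rate, protect = cdr1_protect)
      hv2 <- mutate_peptide(tpl[["HV2"]], config$hv_mut_rate)
      hv4 <- mutate_peptide(tpl[["HV4"]], config$hv_mut_rate)
      cdr3 <- random_peptide(cdr3_len[i], exclude = c("C", "G"))
      if (cdr3_cys[i] > 0L) {
        pos <- sort(sample.int(cdr3_len[i], cdr3_cys[i]))
        for (p in pos) cdr3 <- set_char(cdr3, p, "C")
      }
      seqs[i] <- paste0(tpl[["FR1"]], cdr1, fr2, hv2, tpl[["FR3a"]], hv4,
                        tpl[["FR3b"]], cdr3, fr4)
      rows[[i]] <- tibble(cdr3_len = cdr3_len[i], cdr3_cys = cdr3_cys[i])
    }
    names(seqs) <- sprintf("vnar%05d", seq_len(n))
    lens <- sch$lengths
    fixed_ends <- unname(cumsum(unlist(lens[c("FR1", "CDR1", "FR2", "HV2", "FR3a", "HV4", "FR3b")])))
    fixed_starts <- c(1L, utils::head(fixed_ends, -1L) + 1L)
    truth <- bind_rows(rows)
    truth <- mutate(truth,
      id = names(seqs), sequence = unname(seqs),
      fr1_start = fixed_starts[1], fr1_end = fixed_ends[1],
      cdr1_start = fixed_starts[2], cdr1_end = fixed_ends[2],
      fr2_start = fixed_starts[3], fr2_end = fixed_ends[3],
      hv2_start = fixed_starts[4], hv2_end = fixed_ends[4],
      fr3a_start = fixed_starts[5], fr3a_end = fixed_ends[5],
      hv4_start = fixed_starts[6], hv4_end = fixed_ends[6],
      fr3b_start = fixed_starts[7], fr3b_end = fixed_ends[7],
      cdr3_start = fixed_ends[7] + 1L, cdr3_end = fixed_ends[7] + .data$cdr3_len,
      fr4_start = .data$cdr3_end + 1L,
      fr4_end = .data$cdr3_end + nchar(fr4),
      .before = 1
    )
    structure(
      list(sequences = seqs, truth = truth, config = config),
      class = "vnar_repertoire"
    )
  })
}

#' @export
print.vnar_repertoire <- function(x, ...) {
  cat("<vnar_repertoire> ", length(x$sequences), " sequences (",
      if (x$config$fr2_cys) "FR2-cys" else if (x$config$cdr1_cys) "CDR1-cys" else "canonical",
      " placement)\n", sep = "")
  invisible(x)
}

#' @export
tidy.vnar_repertoire <- function(x, ...) x$truth
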