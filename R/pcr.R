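# In-silico PCR with IUPAC-aware primer matching.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_compatible <- function(code, bases) {
  allowed <- IUPAC_DNA[[code]]
  if (is.null(allowed)) abort(paste0("invalid IUPAC code '", code, "'"))
  bases %in% allowed
}

#' Specify a PCR primer
#'
#' @param name Primer label.
#' @param sequence Primer sequence over IUPAC nucleotide codes, written 5'->3'.
#' @param orientation `"forward"` or `"reverse"`. Reverse primers are matched
#'   against the reverse complement of the template.
#' @param max_mismatch Maximum mismatches tolerated over the whole primer.
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly.
#' @return A `primer_spec`.
#' @export
primer_spec <- function(name, sequence, orientation = c("forward", "reverse"),
                        max_mismatch = 1L, three_prime_exact = 3L) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) abort("primer sequence must be non-empty")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_DNA))
  if (length(bad) > 0L) {
    abort(paste0("invalid IUPAC code(s) in primer: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         max_mismatch = as.integer(max_mismatch),
         three_prime_exact = as.integer(three_prime_exact)),
    class = "primer_spec"
  )
}

# 1-based start positions where the primer (given as its forward-strand
# representation) matches the template; `exact_idx` are primer positions
# (1-based on that representation) that must match with zero mismatches
match_primer_fwd <- function(template_chars, primer_chars, max_mismatch, exact_idx) {
  L <- length(template_chars)
  p <- length(primer_chars)
  if (L < p) return(integer())
  n_off <- L - p + 1L
  mism <- integer(n_off)
  exact_ok <- rep(TRUE, n_off)
  for (i in seq_len(p)) {
    ok <- iupac_compatible(primer_chars[i], template_chars[i:(i + n_off - 1L)])
    mism <- mism + !ok
    if (i %in% exact_idx) exact_ok <- exact_ok & ok
  }
  which(mism <= max_mismatch & exact_ok)
}

#' In-silico PCR over a template
#'
#' IUPAC-aware primer matching: a hit tolerates at most the primer's
#' `max_mismatch` mismatches overall and none within its
#' `three_prime_exact` 3'-terminal bases. An amplicon is the inclusive span
#' from the forward primer's 5' end to the reverse primer's 5' end on the
#' template; all products up to `max_len` are reported.
#'
#' @param template Character scalar DNA template.
#' @param fwd,rev [primer_spec()] objects (forward and reverse).
#' @param max_len Maximum product length reported.
#' @return Tibble of amplicons: `start`, `end` (1-based inclusive), `length`,
#'   `seq`.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_len = 5000L) {
  stopifnot(inherits(fwd, "primer_spec"), inherits(rev, "primer_spec"))
  if (fwd$orientation != "forward" || rev$orientation != "reverse") {
    abort("supply one forward and one reverse primer")
  }
  template <- toupper(template)
  tchars <- strsplit(template, "")[[1]]
  fchars <- strsplit(fwd$sequence, "")[[1]]
  pf <- length(fchars)
  f_exact <- seq(pf - min(fwd$three_prime_exact, pf) + 1L, pf)
  f_hits <- match_primer_fwd(tchars, fchars, fwd$max_mismatch, f_exact)
  # reverse primer: match its reverse complement on the forward strand; its
  # 3' end then corresponds to the match's leftmost bases
  rc <- strsplit(revcomp(rev$sequence), "")[[1]]
  pr <- length(rc)
  r_exact <- seq_len(min(rev$three_prime_exact, pr))
  r_hits <- match_primer_fwd(tchars, rc, rev$max_mismatch, r_exact)
  out <- tibble(start = integer(), end = integer(), length = integer(),
                seq = character())
  if (length(f_hits) == 0L || length(r_hits) == 0L) return(out)
  combos <- expand.grid(f = f_hits, r = r_hits)
  combos$end <- combos$r + pr - 1L
  combos$len <- combos$end - combos$f + 1L
  keep <- combos$len >= max(pf, pr) & combos$len <= max_len
  combos <- combos[keep, , drop = FALSE]
  if (nrow(combos) == 0L) return(out)
  combos <- combos[order(combos$f, combos$end), , drop = FALSE]
  tibble(
    start = as.integer(combos$f), end = as.integer(combos$end),
    length = as.integer(combos$len),
    seq = substring(template, combos$f, combos$end)
  )
}
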