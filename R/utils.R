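# Internal sequence utilities shared across modules.
# All genomic coordinates inside the package are 0-based half-open; conversion
# to/from 1-based inclusive happens only at SAM/GTF/PDB boundaries.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# one codon per amino acid, used for deterministic reverse translation fallback
CODON_BY_AA <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA", E = "GAA",
  G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA", M = "ATG", F = "TTT",
  P = "CCT", S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

CODONS_BY_AA <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG")
)

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n, exclude = "C") {
  alphabet <- setdiff(AA20, exclude)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; `N` maps to `N`.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# translate a DNA string in-frame; codons containing N become X, stops kept as *
translate_dna <- function(x) {
  n <- nchar(x)
  n <- n - n %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

# reverse-translate a peptide choosing random synonymous codons (uses current RNG)
reverse_translate <- function(peptide, random = TRUE) {
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(unique(aa), names(CODON_BY_AA))
  if (length(bad) > 0) {
    abort(paste0("cannot reverse-translate residue(s): ", paste(bad, collapse = ", ")))
  }
  codons <- if (random) {
    vapply(aa, function(a) {
      cs <- CODONS_BY_AA[[a]]
      if (length(cs) == 1L) cs else sample(cs, 1L)
    }, character(1))
  } else {
    CODON_BY_AA[aa]
  }
  paste(codons, collapse = "")
}

# mutate peptide positions in `at` with probability `rate`; never introduces the
# residues in `forbid` and never touches positions in `protect`
mutate_peptide <- function(peptide, rate, at = NULL, protect = integer(),
                           forbid = "C") {
  if (rate <= 0) return(peptide)
  aa <- strsplit(peptide, "")[[1]]
  at <- if (is.null(at)) seq_along(aa) else at
  at <- setdiff(at, protect)
  hit <- at[runif(length(at)) < rate]
  for (i in hit) {
    alphabet <- setdiff(AA20, c(forbid, aa[i]))
    aa[i] <- sample(alphabet, 1L)
  }
  paste(aa, collapse = "")
}

# validate a discrete distribution given as a named numeric vector
check_dist <- function(x, what) {
  if (length(x) == 0 || is.null(names(x))) {
    abort(paste0(what, " must be a named numeric vector of probabilities"))
  }
  if (any(x < 0 | x > 1)) abort(paste0(what, " probabilities must lie in [0, 1]"))
  if (abs(sum(x) - 1) > 1e-9) abort(paste0(what, " probabilities must sum to 1"))
  invisible(x)
}

sample_dist <- function(x, n) {
  vals <- as.integer(names(x))
  vals[sample.int(length(x), n, replace = TRUE, prob = x)]
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# positions (1-based) of a character within a string
char_positions <- function(x, ch = "C") {
  if (nchar(x) == 0) return(integer())
  which(strsplit(x, "")[[1]] == ch)
}
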