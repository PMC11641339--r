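# Translated search for IgNAR-like loci.
#
# A protein query (e.g. a published IgNAR sequence) is aligned locally against
# the six-frame translation of a scaffold; high-scoring hits are clustered by
# genomic proximity into candidate loci. Hits fragment across introns (stop
# codons break the translated segments); clustering, not spliced alignment,
# joins them into one locus call.

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

sanitize_protein <- function(x, alphabet) {
  x <- toupper(x)
  chars <- strsplit(x, "")[[1]]
  chars[!chars %in% alphabet] <- "X"
  paste(chars, collapse = "")
}

#' Six-frame translation with coordinate maps
#'
#' Translates a DNA sequence in all six frames under the standard genetic
#' code; codons containing `N` translate to `X`, and stop codons are emitted
#' as `*` and retained. Use [frame_genomic_span()] to map amino-acid positions
#' of a frame back to forward-strand genomic coordinates.
#'
#' @param dna Character scalar over `{A,C,G,T,N}`.
#' @return Tibble with `frame` (+1,+2,+3,-1,-2,-3), `offset` (0-based offset of
#'   the frame's first base on its strand), and `aa` (translated sequence).
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(dna)
  rc <- if (nchar(dna) > 0) revcomp(dna) else ""
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  aa <- vapply(frames, function(f) {
    src <- if (f > 0) dna else rc
    off <- abs(f) - 1L
    if (nchar(src) <= off) "" else translate_dna(substr(src, off + 1L, nchar(src)))
  }, character(1))
  tibble(frame = frames, offset = abs(frames) - 1L, aa = aa)
}

#' Map an amino-acid span of a translation frame to genomic coordinates
#'
#' @param frame One of +1,+2,+3,-1,-2,-3.
#' @param aa_start,aa_end 1-based inclusive amino-acid positions in the frame's
#'   translation.
#' @param dna_length Length of the translated DNA sequence.
#' @return Integer length-2 vector: 0-based half-open span on the forward
#'   strand.
#' @export
frame_genomic_span <- function(frame, aa_start, aa_end, dna_length) {
  off <- abs(frame) - 1L
  s <- off + 3L * (aa_start - 1L)
  e <- off + 3L * aa_end
  if (frame > 0) c(s, e) else c(dna_length - e, dna_length - s)
}

#' Optimal local protein alignment (affine gaps)
#'
#' Smith-Waterman-style local alignment under a substitution matrix with
#' affine gap penalties (a gap of length *k* costs `gap_open + k * gap_ext`).
#' Residues absent from the matrix are treated as `X`. Scores are clamped at
#' zero (the empty local alignment), so an empty target scores 0.
#'
#' @param query,target Amino-acid strings.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_ext Affine gap penalties (defaults 11 and 1, the
#'   customary translated-search settings).
#' @return One-row tibble: `score`, `query_start`, `query_end`,
#'   `target_start`, `target_end` (1-based inclusive; NA when the best local
#'   alignment is empty).
#' @export
local_align <- function(query, target, matrix = NULL, gap_open = 11, gap_ext = 1) {
  if (nchar(query) == 0L) abort("query must be non-empty")
  mat <- matrix %||% blosum62()
  if (nchar(target) == 0L) {
    return(tibble(score = 0, query_start = NA_integer_, query_end = NA_integer_,
                  target_start = NA_integer_, target_end = NA_integer_))
  }
  alphabet <- rownames(mat)
  q <- sanitize_protein(query, alphabet)
  t <- sanitize_protein(target, alphabet)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q), subject = Biostrings::AAString(t),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(tibble(score = 0, query_start = NA_integer_, query_end = NA_integer_,
                  target_start = NA_integer_, target_end = NA_integer_))
  }
  pr <- Biostrings::pattern(pa)
  sr <- Biostrings::subject(pa)
  tibble(
    score = sc,
    query_start = BiocGenerics::start(pr), query_end = BiocGenerics::end(pr),
    target_start = BiocGenerics::start(sr), target_end = BiocGenerics::end(sr)
  )
}

# translated hits of a query against one scaffold: stop-free segments of each
# frame are aligned separately (so hits fragment at intron stop codons)
translated_hits <- function(scaffold, query, min_score, matrix = NULL,
                            gap_open = 11, gap_ext = 1) {
  L <- nchar(scaffold)
  frames <- six_frame_translate(scaffold)
  min_seg <- max(3L, ceiling(min_score / 11))  # no shorter segment can reach min_score
  out <- list()
  for (i in seq_len(nrow(frames))) {
    aa <- frames$aa[i]
    if (nchar(aa) == 0L) next
    m <- gregexpr("[^*]+", aa)[[1]]
    if (m[1] == -1L) next
    seg_start <- as.integer(m)
    seg_len <- attr(m, "match.length")
    for (k in seq_along(seg_start)) {
      if (seg_len[k] < min_seg) next
      seg <- substr(aa, seg_start[k], seg_start[k] + seg_len[k] - 1L)
      al <- local_align(query, seg, matrix = matrix,
                        gap_open = gap_open, gap_ext = gap_ext)
      if (al$score < min_score) next
      aa_s <- seg_start[k] + al$target_start - 1L
      aa_e <- seg_start[k] + al$target_end - 1L
      g <- frame_genomic_span(frames$frame[i], aa_s, aa_e, L)
      out[[length(out) + 1L]] <- tibble(
        frame = frames$frame[i], start = g[1], end = g[2], score = al$score,
        query_start = al$query_start, query_end = al$query_end
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(frame = integer(), start = integer(), end = integer(),
                  score = numeric(), query_start = integer(), query_end = integer()))
  }
  arrange(bind_rows(out), .data$start)
}

#' Call candidate loci from a translated search
#'
#' Aligns the query against every stop-free segment of the six-frame
#' translation, keeps hits with score at least `min_score`, and single-linkage
#' clusters them along the genome: consecutive hits closer than
#' `max_cluster_gap` join one locus. Clusters are labelled left to right.
#'
#' @param scaffold Character scalar DNA sequence.
#' @param query Amino-acid query sequence.
#' @param min_score Minimum alignment score for a hit to be kept (> 0).
#' @param max_cluster_gap Maximum genomic distance (bp) between hits of one
#'   locus (> 0).
#' @param ... Passed on to [local_align()] (matrix, gap penalties).
#' @return Tibble with one row per locus call: `label`, `start`, `end`
#'   (envelope of member hits, 0-based half-open), `n_hits`, `best_score`, and
#'   a `hits` list-column of the member hit tables.
#' @export
call_loci <- function(scaffold, query, min_score = 60, max_cluster_gap = 50000L, ...) {
  if (min_score <= 0 || max_cluster_gap <= 0) abort("thresholds must be > 0")
  hits <- translated_hits(scaffold, query, min_score, ...)
  if (nrow(hits) == 0L) {
    return(tibble(label = character(), start = integer(), end = integer(),
                  n_hits = integer(), best_score = numeric(), hits = list()))
  }
  cluster <- integer(nrow(hits))
  cluster[1] <- 1L
  cur_end <- hits$end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$start[i] - cur_end <= max_cluster_gap) {
      cluster[i] <- cluster[i - 1L]
    } else {
      cluster[i] <- cluster[i - 1L] + 1L
    }
    cur_end <- max(cur_end, hits$end[i])
  }
  hits$cluster <- cluster
  summ <- hits |>
    group_by(.data$cluster) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_hits = n(), best_score = max(.data$score),
      .groups = "drop"
    )
  nested <- tidyr::nest(hits, hits = -"cluster")
  out <- arrange(left_join(summ, nested, by = "cluster"), .data$start)
  mutate(select(out, -"cluster"),
         label = sprintf("locus_%d", row_number()), .before = 1)
}

#' Write locus calls to BED
#'
#' @param calls Output of [call_loci()].
#' @param path Output BED file.
#' @param scaffold_name Reference name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path, scaffold_name = "scaffold_1") {
  lines <- paste(scaffold_name, calls$start, calls$end, calls$label,
                 round(calls$best_score), "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
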