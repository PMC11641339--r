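# Assembly-gap resolution from locally mapped read pairs.
#
# The workflow automates what is otherwise done by hand in a sequence viewer:
# locate N-runs, pull the read pairs mapped around them, seed a contig on the
# consensus of left-flank-anchored reads, extend greedily by prefix/suffix
# overlap, and stop when the right-flank consensus is reached.

#' Find N-gaps in a scaffold
#'
#' @param scaffold Character scalar DNA sequence.
#' @param min_run Minimum N-run length to report (>= 1).
#' @param scaffold_name Label carried into the output.
#' @param flank_window Flank size (bp) recorded with each gap and used
#'   downstream when collecting reads.
#' @return Tibble of maximal N-runs in coordinate order: `scaffold`, `start`,
#'   `end` (0-based half-open), `width`, `flank_window`.
#' @export
find_gaps <- function(scaffold, min_run = 10L, scaffold_name = "scaffold_1",
                      flank_window = 500L) {
  if (min_run < 1L) abort("min_run must be >= 1")
  empty <- tibble(scaffold = character(), start = integer(), end = integer(),
                  width = integer(), flank_window = integer())
  if (nchar(scaffold) == 0L) return(empty)
  m <- gregexpr(sprintf("N{%d,}", min_run), scaffold)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  width <- attr(m, "match.length")
  tibble(scaffold = scaffold_name, start = start, end = start + width,
         width = as.integer(width), flank_window = as.integer(flank_window))
}

# reference-consuming width of a CIGAR string (M/D/N/=/X consume)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Collect read pairs mapped around a gap
#'
#' Returns the pairs with at least one mate overlapping
#' `[start - flank_window, end + flank_window)`, including pairs whose mates
#' straddle the gap (one mate on each flank). Mate sequences from SAM are
#' already in reference orientation, so no further reverse-complementing is
#' needed before overlap comparison.
#'
#' @param alignments SAM records as a tibble (see [read_sam()]/[sam_records()])
#'   or a path to a SAM file.
#' @param gap One gap: a single row of [find_gaps()] output (or any list with
#'   `start`, `end`, and optionally `flank_window`).
#' @param flank_window Override for the gap's flank window (bp).
#' @return Tibble with one row per pair: positions/sequences of both mates
#'   (0-based `start1`/`end1` etc.), `straddle`, `proper_pair`.
#' @export
collect_flanking_reads <- function(alignments, gap, flank_window = NULL) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam(alignments)
  }
  fw <- as.integer(flank_window %||% gap$flank_window %||% 500L)
  aln <- filter(alignments, bitwAnd(.data$flag, 4L) == 0L, .data$rname != "*")
  empty <- tibble(qname = character(), seq1 = character(), start1 = integer(),
                  end1 = integer(), strand1 = character(), seq2 = character(),
                  start2 = integer(), end2 = integer(), strand2 = character(),
                  straddle = logical(), proper_pair = logical())
  if (nrow(aln) == 0L) return(empty)
  aln <- mutate(aln,
    start0 = .data$pos - 1L,
    end0 = .data$pos - 1L + cigar_ref_width(.data$cigar),
    strand = ifelse(bitwAnd(.data$flag, 16L) > 0L, "-", "+"),
    first = bitwAnd(.data$flag, 64L) > 0L
  )
  wstart <- gap$start - fw
  wend <- gap$end + fw
  aln <- mutate(aln, in_window = .data$start0 < wend & .data$end0 > wstart)
  keep <- unique(aln$qname[aln$in_window])
  if (length(keep) == 0L) return(empty)
  aln <- filter(aln, .data$qname %in% keep)
  out <- aln |>
    group_by(.data$qname) |>
    summarise(
      seq1 = .data$seq[order(!.data$first)][1],
      start1 = .data$start0[order(!.data$first)][1],
      end1 = .data$end0[order(!.data$first)][1],
      strand1 = .data$strand[order(!.data$first)][1],
      seq2 = if (n() > 1L) .data$seq[order(!.data$first)][2] else NA_character_,
      start2 = if (n() > 1L) .data$start0[order(!.data$first)][2] else NA_integer_,
      end2 = if (n() > 1L) .data$end0[order(!.data$first)][2] else NA_integer_,
      strand2 = if (n() > 1L) .data$strand[order(!.data$first)][2] else NA_character_,
      proper_pair = any(bitwAnd(.data$flag, 2L) > 0L),
      .groups = "drop"
    )
  mutate(out,
    straddle = !is.na(.data$start2) &
      ((.data$end1 <= gap$start & .data$start2 >= gap$end) |
       (.data$end2 <= gap$start & .data$start1 >= gap$end))
  )
}

# long-form read table from a pair table
pairs_to_reads <- function(pairs) {
  r1 <- tibble(name = paste0(pairs$qname, "/1"), seq = pairs$seq1,
               start = pairs$start1, end = pairs$end1)
  r2 <- tibble(name = paste0(pairs$qname, "/2"), seq = pairs$seq2,
               start = pairs$start2, end = pairs$end2)
  filter(bind_rows(r1, r2), !is.na(.data$seq))
}

# majority-vote consensus of reads laid out by mapped position, starting at
# the first covered column at or after `from` and running while coverage is
# contiguous; ties broken by alphabetical base. Returns the realised anchor.
layout_consensus <- function(reads, from) {
  reads <- filter(reads, .data$end > from)
  if (nrow(reads) == 0L) return(list(seq = "", cov = integer(), from = from))
  to <- max(reads$end)
  span <- to - from
  counts <- matrix(0L, nrow = 5L, ncol = span,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]; e <- reads$end[i]; sq <- reads$seq[i]
    lo <- max(s, from)
    ch <- strsplit(substr(sq, lo - s + 1L, e - s), "")[[1]]
    cols <- (lo - from + 1L):(e - from)
    for (k in seq_along(cols)) {
      counts[ch[k], cols[k]] <- counts[ch[k], cols[k]] + 1L
    }
  }
  cov <- colSums(counts)
  first <- which(cov > 0L)[1]
  rest <- cov[first:span]
  stop_at <- if (any(rest == 0L)) which(rest == 0L)[1] - 1L else length(rest)
  if (stop_at == 0L) return(list(seq = "", cov = integer(), from = from))
  cols <- seq(first, first + stop_at - 1L)
  cons <- rownames(counts)[apply(counts[, cols, drop = FALSE], 2L, which.max)]
  list(seq = paste(cons, collapse = ""), cov = as.integer(cov[cols]),
       from = from + first - 1L)
}

# mismatches between suffix of a (length ov) and prefix of b (length ov)
overlap_mismatches <- function(a_chars, b_chars, ov) {
  la <- length(a_chars)
  sum(a_chars[(la - ov + 1L):la] != b_chars[seq_len(ov)])
}

# best overlap (longest, <= max_mismatch) of read prefix against contig suffix;
# exact seed of min_overlap bases is tried first, then a full scan fallback
best_overlap <- function(contig, read_chars, read_seq, min_overlap, max_mismatch) {
  lc <- nchar(contig)
  lr <- length(read_chars)
  ovmax <- min(lc, lr - 1L)
  if (ovmax < min_overlap) return(0L)
  tail_len <- min(lc, lr + max_mismatch)
  tail_str <- substr(contig, lc - tail_len + 1L, lc)
  seed <- substr(read_seq, 1L, min_overlap)
  hits <- gregexpr(seed, tail_str, fixed = TRUE)[[1]]
  best <- 0L
  if (hits[1] != -1L) {
    tail_chars <- strsplit(tail_str, "")[[1]]
    for (j in as.integer(hits)) {
      ov <- tail_len - j + 1L
      if (ov > ovmax || ov < min_overlap || ov <= best) next
      # verify the part of the overlap beyond the seed
      mism <- sum(tail_chars[(j):(j + ov - 1L)] != read_chars[seq_len(ov)])
      if (mism <= max_mismatch) best <- max(best, ov)
    }
  }
  if (best == 0L && max_mismatch > 0L) {
    tail_chars <- strsplit(tail_str, "")[[1]]
    lt <- length(tail_chars)
    top <- min(ovmax, lt)
    if (top < min_overlap) return(0L)
    for (ov in seq(top, min_overlap, by = -1L)) {
      if (overlap_mismatches(tail_chars, read_chars, ov) <= max_mismatch) {
        best <- ov
        break
      }
    }
  }
  best
}

#' Assemble the sequence missing in a gap from flanking read pairs
#'
#' Seeds a contig on the positional consensus of reads anchored in the left
#' flank, then repeatedly extends with the read whose prefix overlaps the
#' contig suffix by at least `min_overlap` bases with at most `max_mismatch`
#' mismatches (ties broken by longer overlap, then lexicographically smaller
#' read name), until the right-flank consensus is reached or no extension
#' exists. Conflicting bases in the seed consensus are resolved by majority
#' vote (ties alphabetically).
#'
#' @param pairs Output of [collect_flanking_reads()] for the gap.
#' @param gap The gap record (row with `start`, `end`, `flank_window`).
#' @param min_overlap Minimum prefix/suffix overlap (bp).
#' @param max_mismatch Maximum mismatches tolerated inside an overlap.
#' @param flank_window Flank size used for anchoring (defaults to the gap's).
#' @param max_fill Abandon extension once the contig implies a fill longer
#'   than this (default `3 * gap width + 500`).
#' @return A `gap_fill` object with `status` (`"filled"`, `"unfillable"`, or
#'   `"unjoined"`), `fill` (inferred sequence, `NA` on failure), and `support`
#'   (per-base read depth over the fill).
#' @export
assemble_gap <- function(pairs, gap, min_overlap = 30L, max_mismatch = 1L,
                         flank_window = NULL, max_fill = NULL) {
  fw <- as.integer(flank_window %||% gap$flank_window %||% 500L)
  gstart <- as.integer(gap$start)
  gend <- as.integer(gap$end)
  max_fill <- as.integer(max_fill %||% (3L * (gend - gstart) + 500L))
  fail <- function(status) {
    structure(list(status = status, fill = NA_character_, support = integer(),
                   gap = gap, contig = NULL), class = "gap_fill")
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(fail("unfillable"))
  reads <- pairs_to_reads(pairs)
  left_anchor <- filter(reads, .data$start < gstart, .data$end > gstart - fw)
  right_anchor <- filter(reads, .data$start >= gend, .data$start < gend + fw)
  if (nrow(left_anchor) == 0L || nrow(right_anchor) == 0L) {
    return(fail("unfillable"))
  }
  from <- max(0L, gstart - fw)
  left <- layout_consensus(left_anchor, from)
  right <- layout_consensus(right_anchor, gend)
  if (nchar(left$seq) == 0L || nchar(right$seq) == 0L) return(fail("unfillable"))
  if (left$from >= gstart) return(fail("unfillable"))
  contig <- left$seq
  cov <- left$cov
  anchor <- left$from
  right_off <- right$from - gend   # uncovered bases between gap end and right anchor
  pool <- filter(reads, !(.data$name %in% c(left_anchor$name, right_anchor$name)))
  pool <- arrange(pool, .data$name)
  pool_chars <- lapply(pool$seq, function(s) strsplit(s, "")[[1]])
  used <- rep(FALSE, nrow(pool))
  right_chars <- strsplit(right$seq, "")[[1]]

  right_seed <- substr(right$seq, 1L, min_overlap)
  join_overlap <- function(contig) {
    lc <- nchar(contig)
    ovmax <- min(lc, length(right_chars))
    if (ovmax < min_overlap) return(0L)
    tail_str <- substr(contig, lc - ovmax + 1L, lc)
    tail_chars <- strsplit(tail_str, "")[[1]]
    lt <- length(tail_chars)
    hits <- gregexpr(right_seed, tail_str, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (j in as.integer(hits)) {
        ov <- lt - j + 1L
        if (ov < min_overlap) next
        mism <- sum(tail_chars[j:lt] != right_chars[seq_len(ov)])
        if (mism <= max_mismatch) return(ov)
      }
    }
    if (max_mismatch > 0L) {
      for (ov in seq(ovmax, min_overlap, by = -1L)) {
        mism <- sum(tail_chars[(lt - ov + 1L):lt] != right_chars[seq_len(ov)])
        if (mism <= max_mismatch) return(ov)
      }
    }
    0L
  }

  repeat {
    ov <- join_overlap(contig)
    if (ov > 0L) {
      # contig position p + 1 corresponds to the right anchor (gend + right_off)
      p <- nchar(contig) - ov - right_off
      fill_from <- gstart - anchor + 1L
      fill <- if (p >= fill_from) substr(contig, fill_from, p) else ""
      support <- if (p >= fill_from) cov[fill_from:p] else integer()
      return(structure(
        list(status = "filled", fill = fill, support = as.integer(support),
             gap = gap, contig = contig, anchor = anchor,
             reads_used = sum(used) + nrow(left_anchor) + nrow(right_anchor)),
        class = "gap_fill"
      ))
    }
    if (nchar(contig) - (gstart - anchor) > max_fill) return(fail("unjoined"))
    # greedy extension: longest admissible overlap, ties by read name (pool
    # is name-sorted, and strict '>' keeps the earlier name on ties)
    best_i <- 0L
    best_ov <- 0L
    for (i in which(!used)) {
      ovi <- best_overlap(contig, pool_chars[[i]], pool$seq[i],
                          min_overlap, max_mismatch)
      if (ovi > best_ov) {
        best_ov <- ovi
        best_i <- i
      }
    }
    if (best_i == 0L) return(fail("unjoined"))
    used[best_i] <- TRUE
    rd <- pool_chars[[best_i]]
    ext <- paste(rd[(best_ov + 1L):length(rd)], collapse = "")
    lc <- nchar(contig)
    contig <- paste0(contig, ext)
    cov_idx <- (lc - best_ov + 1L):(lc + length(rd) - best_ov)
    cov <- c(cov, rep(0L, nchar(contig) - length(cov)))
    cov[cov_idx] <- cov[cov_idx] + 1L
  }
}

#' @export
print.gap_fill <- function(x, ...) {
  cat("<gap_fill> status: ", x$status, sep = "")
  if (identical(x$status, "filled")) {
    cat(", fill ", nchar(x$fill), " bp, min support ",
        if (length(x$support)) min(x$support) else NA, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.gap_fill <- function(x, ...) {
  if (!identical(x$status, "filled")) {
    return(tibble(position = integer(), base = character(), support = integer()))
  }
  tibble(
    position = seq(x$gap$start, length.out = nchar(x$fill)),
    base = strsplit(x$fill, "")[[1]],
    support = x$support
  )
}

#' @export
glance.gap_fill <- function(x, ...) {
  tibble(
    status = x$status,
    fill_length = if (is.na(x$fill)) NA_integer_ else nchar(x$fill),
    min_support = if (length(x$support)) min(x$support) else NA_integer_,
    mean_support = if (length(x$support)) mean(x$support) else NA_real_
  )
}

#' Patch a scaffold gap with an assembled fill
#'
#' Replaces the N-run with the fill and reports how downstream coordinates
#' shift. The fill must not contain N.
#'
#' @param scaffold Character scalar (gapped) scaffold.
#' @param gap Gap record (`start`, `end`).
#' @param fill Replacement sequence (may differ in length from the gap).
#' @return List with `scaffold` (patched sequence) and `offsets`, a tibble
#'   mapping the old coordinate segments to new coordinates.
#' @export
patch_scaffold <- function(scaffold, gap, fill) {
  if (is.na(fill) || grepl("N", fill, fixed = TRUE)) {
    abort("fill must be a sequence without N")
  }
  gstart <- as.integer(gap$start)
  gend <- as.integer(gap$end)
  L <- nchar(scaffold)
  if (gstart < 0L || gend > L || gend < gstart) abort("gap outside scaffold")
  span <- substr(scaffold, gstart + 1L, gend)
  if (gend > gstart && gsub("N", "", span) != "") {
    abort("gap span does not contain only N")
  }
  patched <- paste0(substr(scaffold, 1L, gstart), fill, substr(scaffold, gend + 1L, L))
  shift <- nchar(fill) - (gend - gstart)
  offsets <- tibble(
    segment = c("upstream", "fill", "downstream"),
    old_start = c(0L, gstart, gend),
    old_end = c(gstart, gend, L),
    new_start = c(0L, gstart, gend + shift),
    new_end = c(gstart, gstart + nchar(fill), L + shift),
    offset = c(0L, NA_integer_, shift)
  )
  list(scaffold = patched, offsets = offsets)
}
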