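# Read simulators and sequence I/O.
#
# Genomic pairs are simulated against the ungapped truth scaffold, so pairs
# straddling a later-masked N-gap exist by construction. Spliced fragments are
# simulated from isoform models; by default each fragment is reported as one
# full-length spliced alignment carrying its isoform's complete junction chain
# (full-cDNA emulation), with an optional short-read mode.

#' Write named sequences to FASTA
#'
#' @param x Named character vector of sequences (DNA or protein).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(!is.null(names(x)))
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

apply_seq_errors <- function(seqs, err) {
  if (err <= 0) return(seqs)
  vapply(seqs, function(s) {
    aa <- strsplit(s, "")[[1]]
    hit <- which(runif(length(aa)) < err)
    for (i in hit) aa[i] <- sample(setdiff(c("A", "C", "G", "T"), aa[i]), 1L)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end genomic reads from a scaffold
#'
#' Draws `round(coverage * L / (2 * read_len))` fragments with normally
#' distributed insert sizes, sequencing `read_len` bases inward from each
#' fragment end (mates on opposite strands). Placements refer to the supplied
#' (ungapped) scaffold. Base qualities are constant maximum quality.
#'
#' @param scaffold Character scalar DNA sequence (the ungapped truth).
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length in bp.
#' @param insert Mean insert (fragment) size in bp; must be `>= read_len`.
#' @param err Per-base substitution error rate in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical output.
#' @param insert_sd Standard deviation of the insert size (default `insert/20`).
#' @param scaffold_name Reference name used in SAM emission.
#' @return A `read_sim` object; see [sam_records()] and [write_fastq()].
#' @export
simulate_genomic_reads <- function(scaffold, coverage = 30, read_len = 100L,
                                   insert = 300L, err = 0, seed = NULL,
                                   insert_sd = insert / 20,
                                   scaffold_name = "scaffold_1") {
  if (err < 0 || err > 1) abort("err must lie in [0, 1]")
  if (insert < read_len) abort("insert must be >= read_len")
  if (coverage <= 0) abort("coverage must be > 0")
  L <- nchar(scaffold)
  if (L < insert) abort("scaffold shorter than the insert size")
  n <- max(1L, round(coverage * L / (2 * read_len)))
  with_seed_if(seed, {
    ins <- as.integer(pmax(read_len, pmin(L, round(rnorm(n, insert, insert_sd)))))
    start <- as.integer(floor(runif(n, 0, L - ins + 1)))  # 0-based fragment start
    r1 <- substring(scaffold, start + 1L, start + read_len)
    r2f <- substring(scaffold, start + ins - read_len + 1L, start + ins)
    r1 <- apply_seq_errors(r1, err)
    r2f <- apply_seq_errors(r2f, err)
    pairs <- tibble(
      qname = sprintf("frag%06d", seq_len(n)),
      start = start, insert = ins,
      read1 = r1,                 # forward strand, as sequenced
      read2 = revcomp(r2f),       # reverse strand, as sequenced
      read2_forward = r2f         # mate 2 in scaffold orientation
    )
    structure(
      list(pairs = pairs, read_len = as.integer(read_len),
           scaffold_name = scaffold_name, scaffold_length = L),
      class = "read_sim"
    )
  })
}

#' @export
print.read_sim <- function(x, ...) {
  cat("<read_sim> ", nrow(x$pairs), " pairs x ", x$read_len, " bp on ",
      x$scaffold_name, " (", x$scaffold_length, " bp)\n", sep = "")
  invisible(x)
}

#' SAM records of a read simulation
#'
#' Emits one properly paired record per mate against the ungapped truth
#' scaffold (flags 99/147; mate 2 sequence stored in reference orientation per
#' the SAM convention). Positions are 1-based as required by SAM.
#'
#' @param x A `read_sim` or `spliced_sim` object.
#' @param ... Unused.
#' @return Tibble with the 11 mandatory SAM columns.
#' @export
sam_records <- function(x, ...) UseMethod("sam_records")

#' @export
sam_records.read_sim <- function(x, ...) {
  p <- x$pairs
  rl <- x$read_len
  qual <- strrep("I", rl)
  r1 <- tibble(
    qname = p$qname, flag = 99L, rname = x$scaffold_name, pos = p$start + 1L,
    mapq = 60L, cigar = paste0(rl, "M"), rnext = "=",
    pnext = p$start + p$insert - rl + 1L, tlen = p$insert,
    seq = p$read1, qual = qual
  )
  r2 <- tibble(
    qname = p$qname, flag = 147L, rname = x$scaffold_name,
    pos = p$start + p$insert - rl + 1L, mapq = 60L, cigar = paste0(rl, "M"),
    rnext = "=", pnext = p$start + 1L, tlen = -p$insert,
    seq = p$read2_forward, qual = qual
  )
  arrange(bind_rows(r1, r2), .data$pos, .data$qname)
}

#' Write paired FASTQ files for a read simulation
#'
#' @param x A `read_sim`.
#' @param prefix Output path prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq`
#'   are written.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(x, prefix) {
  stopifnot(inherits(x, "read_sim"))
  p <- x$pairs
  qual <- strrep("I", x$read_len)
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(paste0("@", p$qname, "/1"), p$read1, "+", qual)), f1)
  writeLines(as.vector(rbind(paste0("@", p$qname, "/2"), p$read2, "+", qual)), f2)
  invisible(c(f1, f2))
}

#' Read FASTQ into a tibble
#'
#' @param path FASTQ file.
#' @return Tibble with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  stopifnot(length(ln) %% 4L == 0L)
  idx <- seq(1L, length(ln), by = 4L)
  tibble(name = sub("^@", "", ln[idx]), seq = ln[idx + 1L], qual = ln[idx + 3L])
}

#' Write SAM records to a file
#'
#' @param records Tibble with the 11 mandatory SAM columns (as produced by
#'   [sam_records()]).
#' @param path Output SAM file.
#' @param seqlengths Named integer vector for the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, seqlengths) {
  stopifnot(!is.null(names(seqlengths)))
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", names(seqlengths), "\tLN:", as.integer(seqlengths))
  )
  body <- paste(records$qname, records$flag, records$rname, records$pos,
                records$mapq, records$cigar, records$rnext, records$pnext,
                records$tlen, records$seq, records$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into a tibble
#'
#' Parses the 11 mandatory columns of SAM text (header lines are skipped) and
#' adds convenience columns decoded from the flag.
#'
#' @param path SAM file.
#' @return Tibble with `qname`, `flag`, `rname`, `pos` (1-based), `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, plus `strand`,
#'   `proper_pair`, and `first_of_pair`.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L) {
    return(tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  rnext = character(), pnext = integer(), tlen = integer(),
                  seq = character(), qual = character(), strand = character(),
                  proper_pair = logical(), first_of_pair = logical()))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  out <- tibble(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    rnext = get(7), pnext = as.integer(get(8)), tlen = as.integer(get(9)),
    seq = get(10), qual = get(11)
  )
  mutate(out,
    strand = ifelse(bitwAnd(.data$flag, 16L) > 0L, "-", "+"),
    proper_pair = bitwAnd(.data$flag, 2L) > 0L,
    first_of_pair = bitwAnd(.data$flag, 64L) > 0L
  )
}

#' Simulate spliced transcriptome alignments from isoform models
#'
#' Fragment counts per isoform are multinomial in the abundances. By default
#' (`read_len = NULL`) each fragment is emitted as one full-length spliced
#' alignment whose blocks are exactly its isoform's exons, so every fragment
#' carries the complete junction chain of its isoform (full-length cDNA
#' emulation). With `read_len` set, each fragment instead yields one read of
#' that length starting uniformly along the transcript, producing partial
#' chains.
#'
#' @param isoforms List of `isoform_model`s (at least one; abundances must not
#'   all be zero).
#' @param locus The `locus_model` the isoforms refer to.
#' @param n_fragments Number of fragments to draw.
#' @param read_len `NULL` for full-length fragments, else a read length in bp
#'   (must not exceed the shortest isoform's transcript length).
#' @param seed Integer seed.
#' @return A `spliced_sim` with `alignments` (fragment_id, isoform, pos,
#'   cigar), `blocks` (fragment_id, start, end; 0-based half-open), and
#'   per-isoform `counts`.
#' @export
simulate_spliced_reads <- function(isoforms, locus, n_fragments,
                                   read_len = NULL, seed = NULL) {
  if (length(isoforms) < 1L) abort("at least one isoform is required")
  ab <- vapply(isoforms, function(i) i$abundance, numeric(1))
  if (all(ab == 0)) abort("abundances must not all be zero")
  iso_blocks <- purrr::map(isoforms, function(iso) locus$exons[iso$chain, c("start", "end")])
  tx_len <- vapply(iso_blocks, function(b) sum(b$end - b$start), integer(1))
  if (!is.null(read_len) && read_len > min(tx_len)) {
    abort("read_len longer than the shortest isoform transcript")
  }
  iso_names <- vapply(seq_along(isoforms), function(i) {
    isoforms[[i]]$name %||% paste0("iso", i)
  }, character(1))
  with_seed_if(seed, {
    idx <- sample.int(length(isoforms), n_fragments, replace = TRUE, prob = ab)
    ids <- sprintf("spl%06d", seq_len(n_fragments))
    if (is.null(read_len)) {
      frag_blocks <- iso_blocks[idx]
    } else {
      tstart <- as.integer(floor(runif(n_fragments, 0, tx_len[idx] - read_len + 1)))
      frag_blocks <- purrr::map2(idx, tstart, function(i, t0) {
        transcript_window_blocks(iso_blocks[[i]], t0, read_len)
      })
    }
    nb <- vapply(frag_blocks, nrow, integer(1))
    blocks <- tibble(
      fragment_id = rep(ids, nb),
      start = unlist(purrr::map(frag_blocks, "start"), use.names = FALSE),
      end = unlist(purrr::map(frag_blocks, "end"), use.names = FALSE)
    )
    alignments <- tibble(
      fragment_id = ids,
      isoform = iso_names[idx],
      pos = vapply(frag_blocks, function(b) b$start[1] + 1L, integer(1)),
      cigar = vapply(frag_blocks, blocks_to_cigar, character(1))
    )
    counts <- dplyr::count(tibble(isoform = iso_names[idx]), .data$isoform, name = "n")
    structure(
      list(alignments = alignments, blocks = blocks, counts = counts,
           locus_name = locus$name, scaffold_name = locus$scaffold_name),
      class = "spliced_sim"
    )
  })
}

# genomic blocks of transcript window [t0, t0 + len) over exon blocks
transcript_window_blocks <- function(exons, t0, len) {
  w <- exons$end - exons$start
  offs <- cumsum(c(0L, utils::head(w, -1L)))
  t1 <- t0 + len
  keep <- which(offs < t1 & offs + w > t0)
  tibble(
    start = as.integer(exons$start[keep] + pmax(0L, t0 - offs[keep])),
    end = as.integer(exons$start[keep] + pmin(w[keep], t1 - offs[keep]))
  )
}

blocks_to_cigar <- function(b) {
  w <- b$end - b$start
  if (nrow(b) == 1L) return(paste0(w, "M"))
  gaps <- b$start[-1] - b$end[-nrow(b)]
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""), w[length(w)], "M")
}

#' @export
print.spliced_sim <- function(x, ...) {
  cat("<spliced_sim> ", nrow(x$alignments), " fragments from ",
      nrow(x$counts), " isoforms of ", x$locus_name, "\n", sep = "")
  invisible(x)
}

#' @export
sam_records.spliced_sim <- function(x, locus = NULL, ...) {
  if (is.null(locus)) abort("supply the locus (for the scaffold sequence) to emit SAM")
  al <- x$alignments
  seqs <- vapply(seq_len(nrow(al)), function(i) {
    b <- filter(x$blocks, .data$fragment_id == al$fragment_id[i])
    paste(substring(locus$scaffold, b$start + 1L, b$end), collapse = "")
  }, character(1))
  tibble(
    qname = al$fragment_id, flag = 0L, rname = x$scaffold_name, pos = al$pos,
    mapq = 60L, cigar = al$cigar, rnext = "*", pnext = 0L, tlen = 0L,
    seq = seqs, qual = vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  )
}
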