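# Isoform reconstruction from spliced alignments.
#
# Fragments are reduced to their junction chains (the ordered splice junctions
# their alignment blocks imply); identical chains are collapsed into isoform
# candidates, matched to a locus model's exon boundaries, and translated into
# domain content with the short-form (C4+C5 skipped) rule.

# parse a CIGAR string into (len, op); errors name the offending token
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    abort(paste0("malformed CIGAR: '", cigar, "'"))
  }
  m <- gregexpr("\\d+[A-Za-z=]", cigar)[[1]]
  tokens <- regmatches(cigar, gregexpr("\\d+[A-Za-z=]", cigar))[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    bad <- substr(cigar, if (m[1] == -1L) 1L else sum(attr(m, "match.length")) + 1L, nchar(cigar))
    abort(paste0("malformed CIGAR token '", bad, "' in '", cigar, "'"))
  }
  op <- substr(tokens, nchar(tokens), nchar(tokens))
  len <- as.integer(substr(tokens, 1L, nchar(tokens) - 1L))
  list(len = len, op = op)
}

#' Genomic blocks of one spliced alignment
#'
#' Standard CIGAR arithmetic: `M` and `D` consume reference into the current
#' block, `N` closes a block and opens the next, `S` and `I` consume no
#' reference. Operations outside `M/N/S/I/D` raise an error naming the token.
#'
#' @param pos 1-based leftmost mapping position (SAM POS).
#' @param cigar CIGAR string.
#' @return Tibble of ordered blocks `start`, `end` in 0-based half-open
#'   genomic coordinates.
#' @export
blocks_from_alignment <- function(pos, cigar) {
  ops <- parse_cigar(cigar)
  bad <- setdiff(unique(ops$op), c("M", "N", "S", "I", "D"))
  if (length(bad) > 0L) {
    abort(paste0("unsupported CIGAR operation '", bad[1], "' in '", cigar, "'"))
  }
  cur <- as.integer(pos) - 1L
  bstart <- cur
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "D")) {
      cur <- cur + len
    } else if (op == "N") {
      starts <- c(starts, bstart)
      ends <- c(ends, cur)
      cur <- cur + len
      bstart <- cur
    }
    # S and I consume no reference
  }
  starts <- c(starts, bstart)
  ends <- c(ends, cur)
  keep <- ends > starts
  tibble(start = starts[keep], end = ends[keep])
}

# junction-chain key of a block table (empty string = unspliced)
junction_key <- function(donor_end, acceptor_start) {
  if (length(donor_end) == 0L) return("unspliced")
  paste(paste0(donor_end, ">", acceptor_start), collapse = ";")
}

#' Collapse spliced fragments into junction chains
#'
#' Fragments are grouped by identical junction chain; chains supported by
#' fewer than `min_support` fragments are dropped; junction-free fragments are
#' grouped as the unspliced class. Output is sorted by support (descending)
#' and then by leftmost junction coordinate.
#'
#' @param blocks Alignment blocks as a tibble with `fragment_id`, `start`,
#'   `end` (e.g. the `blocks` element of [simulate_spliced_reads()] output, or
#'   rows built with [blocks_from_alignment()]). A `spliced_sim` may be passed
#'   directly.
#' @param min_support Minimum fragment count per chain (>= 1).
#' @return Tibble with `chain_id`, `junctions` (list-column of tibbles with
#'   `donor_end`, `acceptor_start`), `n_junctions`, `support`, `leftmost`.
#' @export
collapse_isoforms <- function(blocks, min_support = 2L) {
  if (inherits(blocks, "spliced_sim")) blocks <- blocks$blocks
  if (min_support < 1L) abort("min_support must be >= 1")
  empty <- tibble(chain_id = character(), junctions = list(),
                  n_junctions = integer(), support = integer(),
                  leftmost = integer())
  if (is.null(blocks) || nrow(blocks) == 0L) return(empty)
  per_frag <- blocks |>
    group_by(.data$fragment_id) |>
    summarise(
      key = junction_key(utils::head(sort(.data$end), -1L),
                         utils::tail(sort(.data$start), -1L)),
      leftmost = min(.data$start),
      .groups = "drop"
    )
  chains <- per_frag |>
    group_by(.data$key) |>
    summarise(support = n(), leftmost = min(.data$leftmost), .groups = "drop") |>
    filter(.data$support >= min_support) |>
    arrange(desc(.data$support), .data$leftmost)
  if (nrow(chains) == 0L) return(empty)
  junctions <- purrr::map(chains$key, function(k) {
    if (k == "unspliced") {
      return(tibble(donor_end = integer(), acceptor_start = integer()))
    }
    parts <- strsplit(strsplit(k, ";", fixed = TRUE)[[1]], ">", fixed = TRUE)
    tibble(
      donor_end = as.integer(vapply(parts, `[[`, character(1), 1)),
      acceptor_start = as.integer(vapply(parts, `[[`, character(1), 2))
    )
  })
  tibble(
    chain_id = ifelse(chains$key == "unspliced", "unspliced",
                      sprintf("chain_%03d", seq_len(nrow(chains)))),
    junctions = junctions,
    n_junctions = vapply(junctions, nrow, integer(1)),
    support = chains$support,
    leftmost = chains$leftmost
  )
}

#' Assign exons and domains to a junction chain
#'
#' Matches each junction to the exon boundaries of a locus model (exact
#' matching, 0 bp tolerance by default), infers the exon chain, reads domain
#' content from the exon -> domain map, and sets the short-form flag when C4
#' and C5 are both absent while C1-C3 are present. Junctions not matching any
#' exon boundary set the `novel_junction` flag and domains are inferred
#' best-effort from the matching junctions.
#'
#' @param junctions Tibble with `donor_end`, `acceptor_start` (one chain), or
#'   a row of [collapse_isoforms()] output.
#' @param locus A `locus_model`.
#' @return One-row tibble: `exon_indices` (list), `domains` (list),
#'   `short_form`, `novel_junction`.
#' @export
assign_domains <- function(junctions, locus) {
  if (is.data.frame(junctions) && "junctions" %in% names(junctions)) {
    junctions <- junctions$junctions[[1]]
  }
  ex <- locus$exons
  novel <- FALSE
  if (nrow(junctions) == 0L) {
    idx <- integer(0)
  } else {
    idx <- integer(0)
    first <- match(junctions$donor_end[1], ex$end)
    if (is.na(first)) novel <- TRUE else idx <- first
    for (j in seq_len(nrow(junctions))) {
      nxt <- which(ex$start == junctions$acceptor_start[j])
      if (length(nxt) == 0L) {
        novel <- TRUE
        next
      }
      if (j < nrow(junctions)) {
        # the exon entered here must also donate the next junction
        if (ex$end[nxt[1]] != junctions$donor_end[j + 1L]) novel <- TRUE
      }
      idx <- c(idx, nxt[1])
    }
    idx <- sort(unique(idx))
  }
  doms <- ex$domain[idx]
  present <- doms[!is.na(doms)]
  short <- all(c("C1", "C2", "C3") %in% present) && !any(c("C4", "C5") %in% present)
  tibble(
    exon_indices = list(idx),
    domains = list(doms),
    short_form = short,
    novel_junction = novel
  )
}

#' Locus expression in FPKM
#'
#' Fragments per kilobase of exonic model per million mapped fragments:
#' `fpkm = fragments * 1e9 / (total_fragments * exonic_length)`.
#'
#' @param fragments Fragment count assigned to the locus.
#' @param exonic_length Exonic model length in bp (> 0).
#' @param total_fragments Total mapped fragments in the library (> 0).
#' @param locus Optional locus label.
#' @return One-row tibble: `locus`, `fragments`, `exonic_length`,
#'   `total_fragments`, `fpkm`.
#' @export
compute_fpkm <- function(fragments, exonic_length, total_fragments,
                         locus = NA_character_) {
  if (exonic_length <= 0) abort("exonic_length must be > 0")
  if (total_fragments <= 0) abort("total_fragments must be > 0")
  if (fragments < 0) abort("fragments must be >= 0")
  tibble(
    locus = locus, fragments = fragments, exonic_length = exonic_length,
    total_fragments = total_fragments,
    fpkm = fragments * 1e9 / (total_fragments * exonic_length)
  )
}

#' Write a locus model's exon structure as GTF
#'
#' @param locus A `locus_model`.
#' @param path Output GTF file.
#' @return `path`, invisibly.
#' @export
write_locus_gtf <- function(locus, path) {
  ex <- locus$exons
  attrs <- sprintf('gene_id "%s"; exon_number "%d"; domain "%s";',
                   locus$name, ex$exon,
                   ifelse(is.na(ex$domain), "NA", ex$domain))
  lines <- paste(locus$scaffold_name, "ignarkit", "exon",
                 ex$start + 1L, ex$end, ".", locus$strand, ".", attrs,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
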