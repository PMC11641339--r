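# VNAR domain annotation, cysteine census and type classification.
#
# Regions are delimited positionally: the fixed-length regions FR1, CDR1, FR2,
# HV2, FR3a, HV4, FR3b are laid down from the FR1 start (their total length is
# constant across a scheme), CDR3 runs from the FR3b end to the FR4 anchor
# motif, and FR4 from the anchor to the terminus. Type calls depend only on
# cysteine placement: a noncanonical FR2 cysteine with >= 2 CDR3 cysteines is
# type I (bonds FR1-FR3b, FR2-CDR3, CDR3-FR4); a CDR1 cysteine with >= 1 CDR3
# cysteine is type II (bonds FR1-FR3b, CDR1-CDR3); exactly the two canonical
# cysteines is canonical-only; everything else is unclassified.

#' Positional VNAR region scheme
#'
#' @param fr1,cdr1,fr2,hv2,fr3a,hv4,fr3b Fixed region lengths in amino acids.
#' @param fr1_cys,fr3b_cys 1-based offsets of the canonical cysteines inside
#'   FR1 and FR3b.
#' @param fr4_anchor Regular expression locating the FR4 anchor motif.
#' @return A `vnar_scheme`.
#' @export
vnar_scheme <- function(fr1 = 25L, cdr1 = 8L, fr2 = 10L, hv2 = 8L,
                        fr3a = 16L, hv4 = 6L, fr3b = 15L,
                        fr1_cys = 22L, fr3b_cys = 11L,
                        fr4_anchor = "[YW]G.G") {
  lengths <- list(FR1 = as.integer(fr1), CDR1 = as.integer(cdr1),
                  FR2 = as.integer(fr2), HV2 = as.integer(hv2),
                  FR3a = as.integer(fr3a), HV4 = as.integer(hv4),
                  FR3b = as.integer(fr3b))
  if (any(unlist(lengths) <= 0L)) abort("all fixed region lengths must be > 0")
  if (fr1_cys < 1L || fr1_cys > fr1) abort("fr1_cys offset outside FR1")
  if (fr3b_cys < 1L || fr3b_cys > fr3b) abort("fr3b_cys offset outside FR3b")
  structure(
    list(lengths = lengths, fixed_total = sum(unlist(lengths)),
         fr1_cys = as.integer(fr1_cys), fr3b_cys = as.integer(fr3b_cys),
         fr4_anchor = fr4_anchor),
    class = "vnar_scheme"
  )
}

#' @export
print.vnar_scheme <- function(x, ...) {
  cat("<vnar_scheme> fixed FR1..FR3b total ", x$fixed_total, " aa (",
      paste(names(x$lengths), unlist(x$lengths), sep = "=", collapse = ", "),
      "); FR4 anchor /", x$fr4_anchor, "/\n", sep = "")
  invisible(x)
}

#' Annotate one VNAR sequence against a scheme
#'
#' @param protein Amino-acid string, at least as long as the scheme's fixed
#'   FR1..FR3b total.
#' @param scheme A [vnar_scheme()].
#' @return A `vnar_annotation`: region spans, per-region cysteine positions,
#'   type call, predicted disulfide bonds, unpaired cysteines, and flags
#'   (`canonical_ok`, `fr4_found`).
#' @export
annotate_vnar <- function(protein, scheme = vnar_scheme()) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n < scheme$fixed_total) {
    abort("sequence shorter than the scheme's fixed-region total")
  }
  lens <- unlist(scheme$lengths)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  regions <- tibble(region = names(lens), start = starts, end = unname(ends))
  fr4_found <- FALSE
  fixed_end <- scheme$fixed_total
  if (n > fixed_end) {
    rest <- substr(protein, fixed_end + 1L, n)
    m <- regexpr(scheme$fr4_anchor, rest)
    if (m[1] != -1L) {
      fr4_found <- TRUE
      cdr3_end <- fixed_end + as.integer(m) - 1L
      regions <- bind_rows(
        regions,
        tibble(region = "CDR3", start = fixed_end + 1L, end = cdr3_end),
        tibble(region = "FR4", start = cdr3_end + 1L, end = n)
      )
    } else {
      regions <- bind_rows(
        regions,
        tibble(region = "CDR3", start = fixed_end + 1L, end = n)
      )
    }
  } else {
    regions <- bind_rows(regions,
                         tibble(region = "CDR3", start = n + 1L, end = n))
  }
  regions$seq <- substring(protein, regions$start, regions$end)
  regions$seq[regions$end < regions$start] <- ""
  cys <- regions |>
    dplyr::rowwise() |>
    dplyr::reframe(region = .data$region,
                   pos = .data$start - 1L + char_positions(.data$seq))
  canonical_ok <-
    substr(protein, scheme$fr1_cys, scheme$fr1_cys) == "C" &&
    substr(protein, fixed_end - lens[["FR3b"]] + scheme$fr3b_cys,
           fixed_end - lens[["FR3b"]] + scheme$fr3b_cys) == "C"
  ann <- structure(
    list(sequence = protein, scheme = scheme, regions = regions, cys = cys,
         canonical_ok = canonical_ok, fr4_found = fr4_found,
         canonical_pos = c(scheme$fr1_cys,
                           fixed_end - lens[["FR3b"]] + scheme$fr3b_cys)),
    class = "vnar_annotation"
  )
  cls <- classify_type(ann)
  ann$type <- cls$type
  ann$bonds <- cls$bonds
  ann$unpaired <- cls$unpaired
  ann$candidates <- cls$candidates
  ann$diagnostics <- cls$diagnostics
  ann
}

#' Classify a VNAR annotation by its cysteine pattern
#'
#' A pure function of cysteine placement. Type I requires a noncanonical FR2
#' cysteine and at least two CDR3 cysteines and predicts three bonds
#' (FR1-FR3b, FR2-CDR3, CDR3-FR4, pairing the first CDR3 cysteine with FR2 and
#' the last with FR4); type II requires a CDR1 cysteine and at least one CDR3
#' cysteine and predicts two bonds (FR1-FR3b, CDR1-CDR3); exactly the two
#' canonical cysteines predicts the single FR1-FR3b bond. Ambiguous patterns
#' (cysteines in both FR2 and CDR1) are unclassified with both candidate
#' calls listed; unpaired cysteines are reported.
#'
#' @param annotation A `vnar_annotation`.
#' @return List with `type` (`"I"`, `"II"`, `"canonical-only"`,
#'   `"unclassified"`), `bonds` (tibble), `unpaired` (tibble), `candidates`,
#'   `diagnostics`.
#' @export
classify_type <- function(annotation) {
  stopifnot(inherits(annotation, "vnar_annotation"))
  cys <- annotation$cys
  canon <- annotation$canonical_pos
  pos_in <- function(region) sort(cys$pos[cys$region == region])
  fr2 <- pos_in("FR2")
  cdr1 <- pos_in("CDR1")
  cdr3 <- pos_in("CDR3")
  fr4 <- pos_in("FR4")
  all_pos <- sort(cys$pos)
  noncanonical <- setdiff(all_pos, canon)
  bond <- function(fr, fp, tr, tp) {
    tibble(from_region = fr, from_pos = fp, to_region = tr, to_pos = tp)
  }
  canonical_bond <- bond("FR1", canon[1], "FR3b", canon[2])
  out <- list(type = "unclassified", bonds = canonical_bond[0, ],
              unpaired = tibble(region = character(), pos = integer()),
              candidates = character(), diagnostics = character())
  if (!annotation$canonical_ok) {
    out$diagnostics <- "canonical FR1/FR3b cysteine(s) absent"
    out$unpaired <- tibble(region = cys$region, pos = cys$pos)
    return(out)
  }
  paired <- canon
  if (length(fr2) > 0L && length(cdr1) > 0L) {
    out$type <- "unclassified"
    out$candidates <- c("I", "II")
    out$diagnostics <- "cysteines in both FR2 and CDR1"
    out$bonds <- canonical_bond
  } else if (length(fr2) > 0L && length(cdr3) >= 2L) {
    out$type <- "I"
    out$bonds <- bind_rows(
      canonical_bond,
      bond("FR2", fr2[1], "CDR3", cdr3[1]),
      bond("CDR3", cdr3[length(cdr3)], "FR4",
           if (length(fr4) > 0L) fr4[1] else NA_integer_)
    )
    paired <- c(paired, fr2[1], cdr3[1], cdr3[length(cdr3)],
                if (length(fr4) > 0L) fr4[1])
  } else if (length(cdr1) > 0L && length(cdr3) >= 1L) {
    out$type <- "II"
    out$bonds <- bind_rows(canonical_bond, bond("CDR1", cdr1[1], "CDR3", cdr3[1]))
    paired <- c(paired, cdr1[1], cdr3[1])
  } else if (length(noncanonical) == 0L) {
    out$type <- "canonical-only"
    out$bonds <- canonical_bond
  } else {
    out$diagnostics <- "cysteine pattern matches no defined type"
    out$bonds <- canonical_bond
  }
  un <- filter(cys, !.data$pos %in% paired)
  out$unpaired <- tibble(region = un$region, pos = un$pos)
  out
}

#' @export
print.vnar_annotation <- function(x, ...) {
  cat("<vnar_annotation> type ", x$type, "; CDR3 ",
      sum(x$cys$region == "CDR3"), " cys; ", nrow(x$bonds),
      " predicted bond(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.vnar_annotation <- function(x, ...) x$regions

#' Annotate a set of VNAR sequences
#'
#' @param seqs Named character vector of amino-acid sequences, or a
#'   `vnar_repertoire`.
#' @param scheme A [vnar_scheme()].
#' @return Tibble with one row per sequence: `id`, `type`, `cdr3_cys`,
#'   `n_bonds`, `canonical_ok`, `fr4_found`, `cdr3_start`, `cdr3_end`, and an
#'   `annotation` list-column.
#' @export
annotate_repertoire <- function(seqs, scheme = vnar_scheme()) {
  if (inherits(seqs, "vnar_repertoire")) seqs <- seqs$sequences
  if (length(seqs) == 0L) {
    return(tibble(id = character(), type = character(), cdr3_cys = integer(),
                  n_bonds = integer(), canonical_ok = logical(),
                  fr4_found = logical(), cdr3_start = integer(),
                  cdr3_end = integer(), annotation = list()))
  }
  ids <- names(seqs) %||% sprintf("seq%05d", seq_along(seqs))
  anns <- purrr::map(unname(seqs), annotate_vnar, scheme = scheme)
  tibble(
    id = ids,
    type = vapply(anns, `[[`, character(1), "type"),
    cdr3_cys = vapply(anns, function(a) sum(a$cys$region == "CDR3"), integer(1)),
    n_bonds = vapply(anns, function(a) nrow(a$bonds), integer(1)),
    canonical_ok = vapply(anns, `[[`, logical(1), "canonical_ok"),
    fr4_found = vapply(anns, `[[`, logical(1), "fr4_found"),
    cdr3_start = vapply(anns, function(a) {
      as.integer(a$regions$start[a$regions$region == "CDR3"])
    }, integer(1)),
    cdr3_end = vapply(anns, function(a) {
      as.integer(a$regions$end[a$regions$region == "CDR3"])
    }, integer(1)),
    annotation = anns
  )
}

#' CDR3 cysteine census of an annotated repertoire
#'
#' @param annotations Output of [annotate_repertoire()] (or a list of
#'   `vnar_annotation`s).
#' @return A `vnar_census`: histogram of CDR3 cysteine counts with exact-k
#'   fractions and cumulative at-least-k fractions.
#' @export
census <- function(annotations) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    counts <- vapply(annotations, function(a) {
      sum(a$cys$region == "CDR3")
    }, integer(1))
  } else {
    counts <- annotations$cdr3_cys
  }
  n <- length(counts)
  if (n == 0L) {
    hist <- tibble(cdr3_cys = integer(), n = integer(), frac = numeric(),
                   frac_at_least = numeric())
    return(structure(list(histogram = hist, n = 0L), class = "vnar_census"))
  }
  hist <- tibble(cdr3_cys = sort(unique(counts))) |>
    mutate(
      n = vapply(.data$cdr3_cys, function(k) sum(counts == k), integer(1)),
      frac = .data$n / !!n,
      frac_at_least = vapply(.data$cdr3_cys, function(k) mean(counts >= k), numeric(1))
    )
  structure(list(histogram = hist, n = n), class = "vnar_census")
}

#' @export
print.vnar_census <- function(x, ...) {
  cat("<vnar_census> ", x$n, " sequences\n", sep = "")
  print(x$histogram)
  invisible(x)
}

#' @export
tidy.vnar_census <- function(x, ...) x$histogram

#' @export
glance.vnar_census <- function(x, ...) {
  h <- x$histogram
  frac_at <- function(k) {
    if (any(h$cdr3_cys >= k)) sum(h$n[h$cdr3_cys >= k]) / x$n else 0
  }
  tibble(n = x$n, frac_ge1 = frac_at(1L), frac_ge2 = frac_at(2L),
         modal_count = if (x$n) h$cdr3_cys[which.max(h$n)] else NA_integer_)
}

#' Bar chart of a CDR3 cysteine census
#'
#' @param object A `vnar_census`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vnar_census <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = factor(.data$cdr3_cys), y = .data$frac)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "CDR3 cysteine count", y = "fraction of sequences") +
    ggplot2::theme_minimal()
}

#' Longest ATG-initiated open reading frame
#'
#' Scans the three forward frames for ATG-initiated ORFs (ending at the first
#' in-frame stop, or at the end of the frame when no stop follows) and returns
#' the longest peptide; ties are broken by leftmost start.
#'
#' @param transcript Nucleotide sequence (length >= 3).
#' @return List with `peptide` (without the stop), `frame` (1..3), `span`
#'   (0-based half-open nucleotide span including the stop codon if present),
#'   and `status` (`"ok"` or `"no-start"`).
#' @export
longest_orf <- function(transcript) {
  transcript <- toupper(transcript)
  n <- nchar(transcript)
  if (n < 3L) abort("sequence must be at least 3 nt")
  best <- NULL
  for (f in 1:3) {
    aa <- translate_dna(substr(transcript, f, n))
    if (nchar(aa) == 0L) next
    chars <- strsplit(aa, "")[[1]]
    starts <- which(chars == "M")
    stops <- which(chars == "*")
    for (s in starts) {
      stop_after <- stops[stops > s]
      e <- if (length(stop_after)) stop_after[1] - 1L else length(chars)
      len <- e - s + 1L
      nt_start <- (f - 1L) + 3L * (s - 1L)
      nt_end <- (f - 1L) + 3L * (if (length(stop_after)) e + 1L else e)
      if (is.null(best) || len > best$len ||
          (len == best$len && nt_start < best$span[1])) {
        best <- list(len = len,
                     peptide = paste(chars[s:e], collapse = ""),
                     frame = f, span = c(nt_start, nt_end))
      }
    }
  }
  if (is.null(best)) {
    return(list(peptide = "", frame = NA_integer_, span = c(NA_integer_, NA_integer_),
                status = "no-start"))
  }
  list(peptide = best$peptide, frame = best$frame, span = best$span, status = "ok")
}

#' Cysteine counts of constant domains along a chain
#'
#' @param protein Full-length (spliced, translated) chain.
#' @param domain_ranges Tibble with `region`, `start`, `end` (1-based
#'   inclusive amino-acid coordinates), e.g. from [domain_protein_ranges()];
#'   an optional `linker_C3_C4` row is used for the linker flag.
#' @return List with `counts` (tibble `domain`, `n_cys` for the constant
#'   domains present) and `linker_cys` (TRUE when the C3-C4 linker contains a
#'   cysteine; NA when no linker range was supplied).
#' @export
check_constant_domains <- function(protein, domain_ranges) {
  if (is.null(domain_ranges) || nrow(domain_ranges) == 0L) {
    abort("domain boundaries missing")
  }
  protein <- toupper(protein)
  count_in <- function(s, e) {
    if (e < s || s > nchar(protein)) return(0L)
    length(char_positions(substr(protein, s, min(e, nchar(protein)))))
  }
  const <- filter(domain_ranges, .data$region %in% paste0("C", 1:5))
  counts <- tibble(
    domain = const$region,
    n_cys = as.integer(mapply(count_in, const$start, const$end))
  )
  linker <- filter(domain_ranges, .data$region == "linker_C3_C4")
  linker_cys <- if (nrow(linker) == 0L) {
    NA
  } else {
    count_in(linker$start[1], linker$end[1]) > 0L
  }
  list(counts = counts, linker_cys = linker_cys)
}
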