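# Locus and isoform model classes.
#
# A locus_model describes the genomic architecture of one IgNAR-like locus:
# ordered exons on a scaffold (0-based half-open), an exon -> domain map over
# {leader, VNAR, C1..C5, tail} (NA for exons whose content is not fixed by the
# architecture), and a flag for the extra cysteine in the C3-C4 linker.

new_locus_model <- function(name, scaffold_name, strand, exons, linker_cys,
                            scaffold, exon_peptides, arch) {
  stopifnot(is.data.frame(exons), all(c("exon", "start", "end", "domain") %in% names(exons)))
  if (any(diff(exons$start) <= 0) || any(exons$end <= exons$start)) {
    abort("exons must be non-overlapping and strictly increasing")
  }
  if (any(utils::head(exons$end, -1) > utils::tail(exons$start, -1))) {
    abort("exons must be non-overlapping")
  }
  if (sum(exons$domain == "VNAR", na.rm = TRUE) != 1L) {
    abort("exactly one exon must carry the VNAR domain")
  }
  for (d in paste0("C", 1:5)) {
    if (sum(exons$domain == d, na.rm = TRUE) > 1L) {
      abort(paste0("domain ", d, " may map to at most one exon"))
    }
  }
  structure(
    list(name = name, scaffold_name = scaffold_name, strand = strand,
         exons = exons, linker_cys = linker_cys, scaffold = scaffold,
         exon_peptides = exon_peptides, arch = arch),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model> ", x$name, " (", nrow(x$exons), " exons, strand ",
      x$strand, ")\n", sep = "")
  cat("  scaffold: ", x$scaffold_name, " [", nchar(x$scaffold), " bp]\n", sep = "")
  cat("  domains:  ",
      paste(ifelse(is.na(x$exons$domain), "-", x$exons$domain), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a locus model into its exon table
#'
#' @param x A `locus_model`.
#' @param ... Unused.
#' @return A tibble with one row per exon: `exon`, `start`, `end` (0-based
#'   half-open scaffold coordinates), `width`, and `domain`.
#' @export
tidy.locus_model <- function(x, ...) {
  dplyr::mutate(x$exons, width = .data$end - .data$start, .after = "end")
}

#' @rdname tidy.locus_model
#' @export
glance.locus_model <- function(x, ...) {
  tibble(
    name = x$name, scaffold = x$scaffold_name, strand = x$strand,
    n_exons = nrow(x$exons), span_start = min(x$exons$start),
    span_end = max(x$exons$end), scaffold_length = nchar(x$scaffold),
    linker_cys = x$linker_cys
  )
}

#' Construct an isoform model over a locus
#'
#' An isoform is an ordered chain of exon indices of a locus, with a relative
#' abundance used by the spliced-read simulator. The short-form flag is set
#' when the chain lacks both C4 and C5 while retaining C1-C3, the hallmark of
#' the short IgNAR transcripts that skip the two membrane-proximal constant
#' domains.
#'
#' @param locus A `locus_model`.
#' @param chain Strictly increasing integer vector of exon indices (1-based).
#' @param abundance Non-negative relative weight (default 1).
#' @param name Optional isoform label.
#' @return An `isoform_model` object.
#' @export
isoform_model <- function(locus, chain, abundance = 1, name = NULL) {
  stopifnot(inherits(locus, "locus_model"))
  chain <- as.integer(chain)
  if (length(chain) < 1L || any(diff(chain) <= 0L)) {
    abort("chain must be a strictly increasing vector of exon indices")
  }
  if (any(chain < 1L | chain > nrow(locus$exons))) {
    abort("chain indices outside the locus exon range")
  }
  if (abundance < 0) abort("abundance must be >= 0")
  doms <- locus$exons$domain[chain]
  short <- all(c("C1", "C2", "C3") %in% doms) && !any(c("C4", "C5") %in% doms)
  structure(
    list(locus_name = locus$name, chain = chain, abundance = abundance,
         short_form = short,
         name = name %||% paste0(locus$name, "-chain", paste(chain, collapse = ""))),
    class = "isoform_model"
  )
}

#' @export
print.isoform_model <- function(x, ...) {
  cat("<isoform_model> ", x$name, ": exons ", paste(x$chain, collapse = "-"),
      if (x$short_form) "  [short form]" else "", "\n", sep = "")
  invisible(x)
}

#' Splice junctions implied by an isoform model
#'
#' @param iso An `isoform_model`.
#' @param locus The `locus_model` the isoform refers to.
#' @return Tibble with one row per junction: `donor_end` (exclusive end of the
#'   upstream exon) and `acceptor_start` (start of the downstream exon), both
#'   0-based.
#' @export
isoform_junctions <- function(iso, locus) {
  ex <- locus$exons[iso$chain, ]
  if (nrow(ex) < 2L) {
    return(tibble(donor_end = integer(), acceptor_start = integer()))
  }
  tibble(
    donor_end = utils::head(ex$end, -1),
    acceptor_start = utils::tail(ex$start, -1)
  )
}

# spliced transcript sequence of an isoform (scaffold orientation)
isoform_sequence <- function(iso, locus) {
  ex <- locus$exons[iso$chain, ]
  paste(substring(locus$scaffold, ex$start + 1L, ex$end), collapse = "")
}

#' Protein-coordinate ranges of domains along a spliced isoform
#'
#' Maps the exon -> domain assignment of a locus onto amino-acid coordinates of
#' the translated spliced product of a chain. When the locus carries the extra
#' C3-C4 linker cysteine, the terminal linker residues of the C3 exon are
#' reported as a separate `linker_C3_C4` range so that domain cysteine counts
#' and linker flags can be assessed independently.
#'
#' @param locus A `locus_model`.
#' @param chain Integer exon chain; default all exons (the full-length form).
#' @return Tibble with columns `region`, `start`, `end` (1-based inclusive
#'   amino-acid positions on the spliced protein).
#' @export
domain_protein_ranges <- function(locus, chain = NULL) {
  chain <- chain %||% seq_len(nrow(locus$exons))
  aa_len <- vapply(locus$exon_peptides[chain], nchar, integer(1))
  offs <- cumsum(c(0L, utils::head(aa_len, -1L)))
  doms <- locus$exons$domain[chain]
  linker_aa <- locus$arch$c3_linker_aa %||% 0L
  rows <- list()
  for (i in seq_along(chain)) {
    if (is.na(doms[i])) next
    start <- offs[i] + 1L
    end <- offs[i] + aa_len[i]
    if (identical(doms[i], "C3") && locus$linker_cys && linker_aa > 0L) {
      rows[[length(rows) + 1L]] <-
        tibble(region = "C3", start = start, end = end - linker_aa)
      rows[[length(rows) + 1L]] <-
        tibble(region = "linker_C3_C4", start = end - linker_aa + 1L, end = end)
    } else {
      rows[[length(rows) + 1L]] <- tibble(region = doms[i], start = start, end = end)
    }
  }
  bind_rows(rows)
}

#' Exon/domain diagram of a locus model
#'
#' @param object A `locus_model`.
#' @param ... Unused.
#' @return A ggplot showing exons as boxes coloured by domain along the
#'   scaffold coordinate.
#' @export
autoplot.locus_model <- function(object, ...) {
  ex <- tidy(object)
  ex$domain <- ifelse(is.na(ex$domain), "other", ex$domain)
  ggplot2::ggplot(ex) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
                   fill = .data$domain)
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = 1.25,
                   label = .data$exon), size = 3
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(-0.25, 1.5)) +
    ggplot2::labs(x = paste0(object$scaffold_name, " position (bp)"),
                  title = object$name, fill = "domain") +
    ggplot2::theme_minimal()
}
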