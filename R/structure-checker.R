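# Geometric disulfide-bond verification on coordinate files.
#
# Cysteine SG atoms are paired greedily by nearest distance under a threshold
# (typical S-S bond length is about 2.05 A; the default threshold 2.5 A
# accepts modelling noise), then classified against per-chain domain ranges:
# intra-domain, inter-domain, or inter-chain (the C3-C4 linker dimerisation
# bond is expected to be inter-chain).

#' Extract cysteine SG atoms from a structure
#'
#' @param structure Path to a PDB file, a `bio3d` `pdb` object, or a data
#'   frame of atoms with columns `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @return Tibble of SG atoms: `chain`, `resno`, `insert`, `reskey`
#'   (chain:resno with any insertion code), `x`, `y`, `z`.
#' @export
cysteine_sulfurs <- function(structure) {
  atoms <- if (is.character(structure) && length(structure) == 1L) {
    bio3d::read.pdb(structure)$atom
  } else if (inherits(structure, "pdb")) {
    structure$atom
  } else if (is.data.frame(structure)) {
    structure
  } else {
    abort("structure must be a PDB path, a bio3d pdb object, or an atom data frame")
  }
  if (!"insert" %in% names(atoms)) atoms$insert <- NA_character_
  if (!all(c("resid", "elety") %in% names(atoms))) {
    # already a sulfur table (e.g. cysteine_sulfurs() output)
    stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(atoms)))
    atoms$resid <- "CYS"
    atoms$elety <- "SG"
  }
  sg <- atoms[atoms$resid == "CYS" & atoms$elety == "SG", , drop = FALSE]
  if (nrow(sg) == 0L) {
    return(tibble(chain = character(), resno = integer(), insert = character(),
                  reskey = character(), x = numeric(), y = numeric(),
                  z = numeric()))
  }
  ins <- ifelse(is.na(sg$insert) | sg$insert == "", "", sg$insert)
  tibble(
    chain = as.character(sg$chain), resno = as.integer(sg$resno), insert = ins,
    reskey = paste0(sg$chain, ":", sg$resno, ins),
    x = sg$x, y = sg$y, z = sg$z
  )
}

#' Detect disulfide bonds geometrically
#'
#' All SG-SG pairs within `threshold` angstroms are candidates; sulfurs are
#' matched greedily by nearest pair (each sulfur in at most one bond; distance
#' ties broken by lower residue number). Distances are reported to 0.01 A.
#'
#' @param structure See [cysteine_sulfurs()].
#' @param threshold Maximum SG-SG distance in angstroms (default 2.5).
#' @return Tibble of bonds: `chain_a`, `resno_a`, `chain_b`, `resno_b`,
#'   `reskey_a`, `reskey_b`, `distance`.
#' @export
detect_disulfides <- function(structure, threshold = 2.5) {
  sg <- cysteine_sulfurs(structure)
  empty <- tibble(chain_a = character(), resno_a = integer(),
                  chain_b = character(), resno_b = integer(),
                  reskey_a = character(), reskey_b = character(),
                  distance = numeric())
  n <- nrow(sg)
  if (n < 2L) return(empty)
  # stable order so the bond list is invariant under atom-order permutations
  ord <- order(sg$chain, sg$resno, sg$insert)
  sg <- sg[ord, ]
  d <- as.matrix(stats::dist(cbind(sg$x, sg$y, sg$z)))
  diag(d) <- Inf
  used <- rep(FALSE, n)
  rows <- list()
  repeat {
    d[used, ] <- Inf
    d[, used] <- Inf
    mn <- min(d)
    if (!is.finite(mn) || mn > threshold) break
    hit <- which(d == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    rows[[length(rows) + 1L]] <- tibble(
      chain_a = sg$chain[i], resno_a = sg$resno[i],
      chain_b = sg$chain[j], resno_b = sg$resno[j],
      reskey_a = sg$reskey[i], reskey_b = sg$reskey[j],
      distance = round(mn, 2)
    )
    used[c(i, j)] <- TRUE
    if (all(used)) break
  }
  if (length(rows) == 0L) return(empty)
  arrange(bind_rows(rows), .data$chain_a, .data$resno_a)
}

lookup_domain <- function(chain, resno, ranges) {
  hit <- ranges[ranges$chain == chain & ranges$start <= resno & ranges$end >= resno, ]
  if (nrow(hit) == 0L) "linker/unassigned" else hit$domain[1]
}

#' Classify detected disulfide bonds against domain ranges
#'
#' Bonds are labelled intra-domain, inter-domain, or inter-chain (chain ids
#' differ). Flags are raised when a constant domain lacks an internal bond and
#' when a linker cysteine is bonded but not between chains.
#'
#' @param bonds Output of [detect_disulfides()].
#' @param domain_ranges Tibble with `chain`, `start`, `end` (1-based inclusive
#'   residue numbers), `domain`. Ranges must not overlap within a chain.
#' @return List with `bonds` (input plus `domain_a`, `domain_b`, `klass`),
#'   `summary` (counts per klass), and `flags` (tibble of raised flags).
#' @export
classify_bonds <- function(bonds, domain_ranges) {
  rngs <- domain_ranges
  stopifnot(all(c("chain", "start", "end", "domain") %in% names(rngs)))
  for (ch in unique(rngs$chain)) {
    r <- arrange(filter(rngs, .data$chain == ch), .data$start)
    if (nrow(r) > 1L && any(utils::head(r$end, -1L) >= utils::tail(r$start, -1L))) {
      abort("overlapping domain ranges")
    }
  }
  if (nrow(bonds) > 0L) {
    bonds <- mutate(bonds,
      domain_a = mapply(lookup_domain, .data$chain_a, .data$resno_a,
                        MoreArgs = list(ranges = rngs)),
      domain_b = mapply(lookup_domain, .data$chain_b, .data$resno_b,
                        MoreArgs = list(ranges = rngs)),
      klass = dplyr::case_when(
        .data$chain_a != .data$chain_b ~ "inter-chain",
        .data$domain_a == .data$domain_b ~ "intra-domain",
        TRUE ~ "inter-domain"
      )
    )
  } else {
    bonds <- mutate(bonds, domain_a = character(), domain_b = character(),
                    klass = character())
  }
  summary <- dplyr::count(bonds, .data$klass, name = "n")
  flags <- list()
  const <- filter(rngs, .data$domain %in% paste0("C", 1:5))
  for (i in seq_len(nrow(const))) {
    has_internal <- any(
      bonds$klass == "intra-domain" &
        bonds$chain_a == const$chain[i] & bonds$domain_a == const$domain[i]
    )
    if (!has_internal) {
      flags[[length(flags) + 1L]] <- tibble(
        flag = "constant-domain-without-internal-bond",
        chain = const$chain[i], domain = const$domain[i]
      )
    }
  }
  linker_bonded <- bonds[grepl("linker", bonds$domain_a) | grepl("linker", bonds$domain_b), ]
  bad_linker <- filter(linker_bonded, .data$klass != "inter-chain")
  for (i in seq_len(nrow(bad_linker))) {
    flags[[length(flags) + 1L]] <- tibble(
      flag = "linker-cysteine-not-inter-chain",
      chain = bad_linker$chain_a[i],
      domain = paste(bad_linker$domain_a[i], bad_linker$domain_b[i], sep = "/")
    )
  }
  list(
    bonds = bonds, summary = summary,
    flags = if (length(flags)) bind_rows(flags) else
      tibble(flag = character(), chain = character(), domain = character())
  )
}

#' Report unpaired cysteines of a structure
#'
#' @param structure See [cysteine_sulfurs()].
#' @param domain_ranges As in [classify_bonds()] (optional; labels fall back
#'   to `"linker/unassigned"`).
#' @param threshold Bond threshold passed to [detect_disulfides()].
#' @return Tibble of cysteines not in any detected bond: `chain`, `resno`,
#'   `reskey`, `domain`.
#' @export
unpaired_report <- function(structure, domain_ranges = NULL, threshold = 2.5) {
  sg <- cysteine_sulfurs(structure)
  if (nrow(sg) == 0L) {
    return(tibble(chain = character(), resno = integer(), reskey = character(),
                  domain = character()))
  }
  bonds <- detect_disulfides(sg, threshold = threshold)
  bonded <- c(bonds$reskey_a, bonds$reskey_b)
  un <- filter(sg, !.data$reskey %in% bonded)
  dom <- if (is.null(domain_ranges)) {
    rep("linker/unassigned", nrow(un))
  } else {
    mapply(lookup_domain, un$chain, un$resno, MoreArgs = list(ranges = domain_ranges))
  }
  tibble(chain = un$chain, resno = un$resno, reskey = un$reskey,
         domain = as.character(dom))
}

#' Write atoms as fixed-column PDB ATOM records
#'
#' Minimal writer used to materialise synthetic coordinate sets as PDB text
#' (e.g. planted cysteine geometries for testing bond detection).
#'
#' @param atoms Tibble with `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`
#'   (optional `insert`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  ins <- if ("insert" %in% names(atoms)) {
    ifelse(is.na(atoms$insert) | atoms$insert == "", " ", atoms$insert)
  } else {
    rep(" ", nrow(atoms))
  }
  elem <- substr(trimws(atoms$elety), 1L, 1L)
  name4 <- sprintf(" %-3s", atoms$elety)  # atom names of <4 chars start in col 14
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, atoms$resid, atoms$chain, atoms$resno, ins,
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, elem
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
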