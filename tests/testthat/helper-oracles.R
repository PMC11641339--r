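# Independent oracles, written before the tests that use them.

# Quadratic Gotoh dynamic program for local alignment with affine gaps
# (gap of length k costs open + k * ext). Score-only; clamped at 0.
gotoh_local_score <- function(query, target, mat, open = 11, ext = 1) {
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  n <- length(qc)
  m <- length(tc)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[qc[i - 1L], tc[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# All-pairs brute-force disulfide detection: greedy nearest pair under the
# threshold, recomputed from the full distance list at each step.
brute_force_disulfides <- function(sg, threshold = 2.5) {
  n <- nrow(sg)
  if (n < 2L) {
    return(data.frame(reskey_a = character(), reskey_b = character(),
                      distance = numeric()))
  }
  ord <- order(sg$chain, sg$resno, sg$insert)
  sg <- sg[ord, ]
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs$d <- sqrt((sg$x[pairs$i] - sg$x[pairs$j])^2 +
                  (sg$y[pairs$i] - sg$y[pairs$j])^2 +
                  (sg$z[pairs$i] - sg$z[pairs$j])^2)
  pairs <- pairs[pairs$d <= threshold, ]
  pairs <- pairs[order(pairs$d, pairs$i, pairs$j), ]
  used <- rep(FALSE, n)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used[i] || used[j]) next
    used[c(i, j)] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      reskey_a = sg$reskey[i], reskey_b = sg$reskey[j],
      distance = round(pairs$d[r], 2)
    )
  }
  if (length(out) == 0L) {
    return(data.frame(reskey_a = character(), reskey_b = character(),
                      distance = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$reskey_a), , drop = FALSE]
}

# random amino-acid string over the 20 standard residues
random_aa <- function(n) {
  paste(sample(rownames(blosum62_matrix)[1:20], n, replace = TRUE), collapse = "")
}

# random sulfur-coordinate table with clustered cysteines
random_sulfur_set <- function(n, box = 30) {
  tibble::tibble(
    chain = sample(c("A", "B"), n, replace = TRUE),
    resno = sample.int(500L, n),
    insert = "",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)
  ) |>
    dplyr::distinct(chain, resno, .keep_all = TRUE) |>
    dplyr::mutate(reskey = paste0(chain, ":", resno))
}

# small end-to-end gap fixture: scaffold, masked gap, simulated pairs
make_gap_fixture <- function(seed, scaffold_len = 2000L, gap_span = c(900L, 1100L),
                             coverage = 30, read_len = 100L, insert = 300L,
                             err = 0) {
  withr::with_seed(seed, {
    scaffold <- paste(sample(c("A", "C", "G", "T"), scaffold_len, replace = TRUE),
                      collapse = "")
    masked <- mask_gap(scaffold, gap_span)
    sim <- simulate_genomic_reads(scaffold, coverage = coverage,
                                  read_len = read_len, insert = insert,
                                  err = err, seed = seed + 1L)
    gaps <- find_gaps(masked$scaffold, min_run = 10L)
    list(truth = masked$truth, scaffold = scaffold, masked = masked$scaffold,
         gap = gaps[1, ], alignments = sam_records(sim))
  })
}
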