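# Geometric disulfide detection and classification on synthetic coordinates.

sg_tbl <- function(chain, resno, x, y, z) {
  tibble::tibble(chain = chain, resno = as.integer(resno), insert = "",
                 reskey = paste0(chain, ":", resno), x = x, y = y, z = z)
}

test_that("bond detection applies the distance threshold and greedy matching", {
  two <- sg_tbl("A", c(10, 20), c(0, 0), c(0, 0), c(0, 2.05))
  b <- detect_disulfides(two, threshold = 2.5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance, 2.05)
  far <- sg_tbl("A", c(10, 20), c(0, 0), c(0, 0), c(0, 5))
  expect_equal(nrow(detect_disulfides(far, threshold = 2.5)), 0L)
  # three sulfurs at mutual distances 2.0/2.0/3.9: one bond, third unpaired
  tri <- sg_tbl("A", c(1, 2, 3), c(0, 2.0, -1.95), c(0, 0, 0.44), c(0, 0, 0))
  bt <- detect_disulfides(tri, threshold = 2.5)
  expect_equal(nrow(bt), 1L)
  expect_true(all(table(c(bt$reskey_a, bt$reskey_b)) <= 1))
})

test_that("detection is invariant under atom order and matches brute force", {
  withr::with_seed(51L, {
    for (k in 1:10) {
      sg <- random_sulfur_set(sample(5:40, 1), box = 12)
      got <- detect_disulfides(sg, threshold = 2.5)
      oracle <- brute_force_disulfides(sg, threshold = 2.5)
      expect_equal(nrow(got), nrow(oracle))
      if (nrow(got) > 0) {
        key <- function(d) sort(paste(pmin(d$reskey_a, d$reskey_b),
                                      pmax(d$reskey_a, d$reskey_b)))
        expect_equal(key(got), key(oracle))
      }
      # permuting input rows changes nothing
      perm <- sg[sample(nrow(sg)), ]
      got_p <- detect_disulfides(perm, threshold = 2.5)
      expect_equal(got, got_p)
      # each sulfur appears in at most one bond
      expect_true(all(table(c(got$reskey_a, got$reskey_b)) <= 1))
    }
  })
})

test_that("bond classification distinguishes intra/inter-domain and inter-chain", {
  sg <- dplyr::bind_rows(
    sg_tbl("A", c(25, 75), c(0, 0), c(0, 0), c(0, 2.05)),        # intra C1
    sg_tbl("A", 150, 10, 0, 0), sg_tbl("B", 150, 10, 0, 2.05),   # inter-chain linker
    sg_tbl("A", c(210, 260), c(20, 20), c(0, 0), c(0, 2.05))     # spans C2/C3
  )
  ranges <- tibble::tibble(
    chain = c("A", "A", "A", "A", "B"),
    start = c(1, 140, 200, 250, 140),
    end = c(100, 160, 240, 300, 160),
    domain = c("C1", "linker_C3_C4", "C2", "C3", "linker_C3_C4")
  )
  bonds <- detect_disulfides(sg, threshold = 2.5)
  cls <- classify_bonds(bonds, ranges)
  kl <- setNames(cls$bonds$klass, paste(cls$bonds$reskey_a, cls$bonds$reskey_b))
  expect_equal(unname(kl[["A:25 A:75"]]), "intra-domain")
  expect_equal(unname(kl[["A:150 B:150"]]), "inter-chain")
  expect_equal(unname(kl[["A:210 A:260"]]), "inter-domain")
  # C2/C3 lack internal bonds -> flags raised
  expect_true(any(cls$flags$flag == "constant-domain-without-internal-bond"))
  expect_error(
    classify_bonds(bonds, dplyr::mutate(ranges, end = end + 200)),
    "overlapping"
  )
})

test_that("unpaired cysteines are reported with domain labels", {
  # C1 with three cysteines, two bonded: middle one stays unpaired
  sg <- sg_tbl("A", c(25, 50, 75), c(0, 8, 0), c(0, 0, 0.5), c(0, 0, 1.95))
  ranges <- tibble::tibble(chain = "A", start = 1, end = 100, domain = "C1")
  un <- unpaired_report(sg, ranges)
  expect_equal(un$reskey, "A:50")
  expect_equal(un$domain, "C1")
  # all paired -> empty; no cysteines -> empty
  paired <- sg_tbl("A", c(1, 2), c(0, 0), c(0, 0), c(0, 2))
  expect_equal(nrow(unpaired_report(paired, ranges)), 0L)
  none <- tibble::tibble(chain = character(), resno = integer(),
                         insert = character(), reskey = character(),
                         x = numeric(), y = numeric(), z = numeric())
  expect_equal(nrow(unpaired_report(none, ranges)), 0L)
})

test_that("PDB round-trip preserves planted sulfur geometry", {
  atoms <- tibble::tibble(
    chain = c("A", "A", "B"), resno = c(22L, 84L, 107L), resid = "CYS",
    elety = "SG", x = c(1.234, 1.234, 9.5), y = c(2.5, 2.5, -3.25),
    z = c(0, 2.05, 4.75)
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  sg <- cysteine_sulfurs(path)
  expect_equal(sg$chain, atoms$chain)
  expect_equal(sg$resno, atoms$resno)
  expect_equal(sg$x, atoms$x)
  expect_equal(sg$z, atoms$z)
  b <- detect_disulfides(path)
  expect_equal(nrow(b), 1L)
  expect_equal(b$reskey_a, "A:22")
  expect_equal(b$reskey_b, "A:84")
})
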