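# hydrogen-bond chemistry tables and detection

test_that("donor and acceptor tables match standard N/O chemistry", {
  expect_setequal(donor_atoms("GLY"), "N")
  expect_equal(donor_atoms("PRO"), character(0))  # ring N carries no H
  expect_setequal(donor_atoms("ARG"), c("N", "NE", "NH1", "NH2"))
  expect_setequal(donor_atoms("LYS"), c("N", "NZ"))
  expect_setequal(acceptor_atoms("ALA"), c("O", "OXT"))
  expect_setequal(acceptor_atoms("ASP"), c("O", "OXT", "OD1", "OD2"))
  expect_setequal(acceptor_atoms("LYS"), c("O", "OXT"))  # NZ donor-only
  # sulfur only on request
  expect_false("SG" %in% donor_atoms("CYS"))
  expect_true("SG" %in% donor_atoms("CYS", include_sulfur = TRUE))
  expect_true("SD" %in% acceptor_atoms("MET", include_sulfur = TRUE))
  expect_warning(out <- donor_atoms("XYZ"), "unknown residue")
  expect_equal(out, character(0))
})

two_res <- function(d) {
  toy_model(atomspec("N", "GLY", "A", 1, c(0, 0, 0)),
            atomspec("O", "GLY", "A", 5, c(d, 0, 0)))
}

test_that("detect_hbonds distance criterion is inclusive at 3.5", {
  expect_equal(nrow(detect_hbonds(two_res(3.40))), 1)
  expect_equal(nrow(detect_hbonds(two_res(3.60))), 0)
  expect_equal(nrow(detect_hbonds(two_res(3.50))), 1)  # boundary inclusive
})

test_that("intra-residue and peptide-bond pairs are excluded", {
  # same residue
  same <- toy_model(atomspec("N", "SER", "A", 1, c(0, 0, 0)),
                    atomspec("OG", "SER", "A", 1, c(2.8, 0, 0)))
  expect_equal(nrow(detect_hbonds(same)), 0)
  # consecutive residues: N(2)-O(1) is the covalent 1-3 pair
  pep <- toy_model(atomspec("O", "GLY", "A", 1, c(0, 0, 0)),
                   atomspec("N", "GLY", "A", 2, c(2.25, 0, 0)))
  expect_equal(nrow(detect_hbonds(pep)), 0)
  # but a numbering gap (chain break) is not a peptide bond
  gap <- toy_model(atomspec("O", "GLY", "A", 1, c(0, 0, 0)),
                   atomspec("N", "GLY", "A", 9, c(3.0, 0, 0)))
  expect_equal(nrow(detect_hbonds(gap)), 1)
  # and the reverse direction N(1)...O(2) is a real bond geometry-wise
  rev <- toy_model(atomspec("N", "GLY", "A", 1, c(0, 0, 0)),
                   atomspec("O", "GLY", "A", 2, c(3.0, 0, 0)))
  expect_equal(nrow(detect_hbonds(rev)), 1)
})

test_that("bifunctional atom pairs are reported once per unordered pair", {
  m <- toy_model(atomspec("ND1", "HIS", "A", 1, c(0, 0, 0)),
                 atomspec("NE2", "HIS", "A", 3, c(3.0, 0, 0)))
  expect_equal(nrow(detect_hbonds(m)), 1)
  # a donor with two acceptors yields two bonds (atom-pair counting)
  m2 <- toy_model(atomspec("NZ", "LYS", "A", 1, c(0, 0, 0)),
                  atomspec("OD1", "ASP", "A", 3, c(3.0, 0, 0)),
                  atomspec("OD2", "ASP", "A", 3, c(0, 3.0, 0)))
  expect_equal(nrow(detect_hbonds(m2)), 2)
})

test_that("ligand N/O atoms participate when include_ligand", {
  m <- toy_model(atomspec("N", "GLY", "A", 1, c(0, 0, 0)),
                 atomspec("O1", "LIG", "A", 90, c(3.0, 0, 0),
                          is_het = TRUE))
  expect_equal(nrow(detect_hbonds(m)), 1)
  expect_true(detect_hbonds(m)$involves_ligand)
  off <- hbond_params(include_ligand = FALSE)
  expect_equal(nrow(detect_hbonds(m, off)), 0)
})

test_that("explicit hydrogens gate bonds under auto/always/never policies", {
  base <- list(atomspec("N", "GLY", "A", 1, c(0, 0, 0)),
               atomspec("O", "GLY", "A", 5, c(3.4, 0, 0)))
  # H on the donor pointing at the acceptor: passes the 2.5 A criterion
  h_good <- c(base, list(atomspec("H", "GLY", "A", 1, c(1.0, 0, 0))))
  # H pointing away: hydrogen-acceptor distance 4.4 A fails
  h_bad <- c(base, list(atomspec("H", "GLY", "A", 1, c(-1.0, 0, 0))))
  m_good <- do.call(toy_model, h_good)
  m_bad <- do.call(toy_model, h_bad)
  expect_equal(nrow(detect_hbonds(m_good)), 1)
  expect_equal(nrow(detect_hbonds(m_bad)), 0)
  expect_equal(nrow(detect_hbonds(m_bad,
                                  hbond_params(use_explicit_hydrogens =
                                                 "never"))), 1)
  # no hydrogens in the file: auto applies the heavy-atom rule alone,
  # always finds nothing
  m_noh <- do.call(toy_model, base)
  expect_equal(nrow(detect_hbonds(m_noh)), 1)
  expect_equal(nrow(detect_hbonds(m_noh,
                                  hbond_params(use_explicit_hydrogens =
                                                 "always"))), 0)
})

test_that("parameter validation and degenerate inputs", {
  expect_error(hbond_params(max_hydrogen_acceptor = 4),
               "must be smaller")
  expect_error(hbond_params(max_donor_acceptor = -1))
  nanm <- two_res(3.0)
  nanm$atoms$x[1] <- NaN
  expect_error(detect_hbonds(nanm), "non-finite")
})

test_that("grid detection equals all-pairs brute force and the independent
           oracle on random structures", {
  for (seed in 1:12) {
    m <- rand_structure(seed, n_res = 35)
    grid <- detect_hbonds(m, method = "grid")
    brute <- detect_hbonds(m, method = "brute")
    expect_identical(grid, brute)
    expect_equal(nrow(grid), oracle_hbond_count(m))
  }
})

test_that("detection is invariant under rigid motion", {
  m <- rand_structure(101, n_res = 30)
  ref <- detect_hbonds(m)
  for (seed in 1:5) {
    moved <- apply_rigid_motion(m, seed)
    got <- detect_hbonds(moved)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$distance, ref$distance, tolerance = 1e-9)
  }
})

test_that("enlarging the cutoff never removes a bond (monotonicity)", {
  m <- rand_structure(55, n_res = 30)
  key <- function(ct) paste(ct$donor_chain, ct$donor_resseq, ct$donor_atom,
                            ct$acceptor_chain, ct$acceptor_resseq,
                            ct$acceptor_atom)
  prev <- character(0)
  for (cutoff in c(2.5, 3.0, 3.5, 4.0)) {
    ct <- detect_hbonds(m, hbond_params(max_donor_acceptor = cutoff,
                                        max_hydrogen_acceptor =
                                          cutoff - 1))
    k <- key(ct)
    expect_true(all(prev %in% k))
    prev <- k
  }
})

test_that("bond counts are additive for well-separated chains", {
  m <- rand_structure(7, n_res = 24)
  a <- m; a$atoms <- a$atoms[a$atoms$chain == "A", ]
  b <- m; b$atoms <- b$atoms[b$atoms$chain == "B", ]
  b$atoms[, c("x", "y", "z")] <- b$atoms[, c("x", "y", "z")] + 100  # >=10 A
  joint <- m
  joint$atoms <- rbind(a$atoms, b$atoms)
  expect_equal(nrow(detect_hbonds(joint)),
               nrow(detect_hbonds(a)) + nrow(detect_hbonds(b)))
})

test_that("ideal helices give exactly n - 4 backbone bonds", {
  for (n in c(5, 6, 10, 17)) {
    h <- make_ideal_helix(n)
    expect_equal(nrow(detect_hbonds(h)), n - 4)
  }
  # and every reported bond is the i -> i+4 amide-carbonyl pair
  ct <- detect_hbonds(make_ideal_helix(12))
  expect_true(all(ct$donor_atom == "N" & ct$acceptor_atom == "O"))
  expect_true(all(ct$donor_resseq - ct$acceptor_resseq == 4))
})
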