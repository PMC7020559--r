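# Synthetic test inputs: ideal helices and salt-bridge dimers with known
# contact counts (geometric oracles for the detectors), and two-species
# proteome ensembles with planted effects (oracles for the comparative
# statistics). Structures are built from internal coordinates (NeRF-style
# placement) so every geometric guarantee can be re-checked by brute force
# at generation time instead of shipping coordinate fixtures.

# Place atom D given positions of A, B, C, the C-D bond length, the B-C-D
# bond angle (degrees) and the A-B-C-D dihedral (degrees).
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang), bond * cos(dih) * sin(ang),
          bond * sin(dih) * sin(ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  as.vector(cbind(bc, m2, n) %*% d2) + c
}

# rotation matrix taking unit vector u onto unit vector v (Rodrigues)
.rot_align <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- c(u[2] * p[3] - u[3] * p[2],
           u[3] * p[1] - u[1] * p[3],
           u[1] * p[2] - u[2] * p[1])
    w <- w / sqrt(sum(w^2))
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# Ideal-helix backbone torsions. The textbook alpha-helix value (-57, -47)
# puts the i,i+2 and i,i+3 N-O separations at 3.2-3.4 A -- inside a 3.5 A
# distance-only criterion -- so a distance-only detector would report three
# bonds per residue. These values stay within the alpha-helical basin of
# the Ramachandran map while keeping i+4 N-O near 2.9 A and every other
# non-covalent backbone N-O pair above 3.55 A, giving the clean n-4 bond
# count the fixture guarantees.
.HELIX_PHI <- -70
.HELIX_PSI <- -41

.helix_backbone <- function(n, phi = .HELIX_PHI, psi = .HELIX_PSI,
                            omega = 180) {
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + c(1.525 * cos(pi - ang), 1.525 * sin(pi - ang), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          1.329, 116.2, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           1.458, 121.7, omega)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in seq_len(n)) {
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Generate an ideal alpha-helix model with a known hydrogen-bond count
#'
#' Builds an n-residue poly-alanine backbone (N/CA/C/O) from ideal internal
#' coordinates. The geometry guarantees that every i -> i+4 backbone N-O
#' distance falls in [2.8, 3.3] Angstrom while all other non-covalent
#' backbone N-O pairs exceed 3.5 Angstrom, so a 3.5 A distance-only
#' hydrogen-bond detector finds exactly n - 4 bonds. The guarantee is
#' re-verified by brute force on the generated coordinates; violation is a
#' hard (internal) error.
#'
#' @param n_res Number of residues, at least 5.
#' @param sequence Optional one-letter sequence of length `n_res` used only
#'   to label residues (side chains are not built); defaults to poly-Ala.
#' @param protein_id Model identifier.
#' @return A `structure_model` with one chain ("A").
#' @export
make_ideal_helix <- function(n_res, sequence = NULL, protein_id = "helix") {
  if (!is.numeric(n_res) || n_res < 5) {
    stop("n_res must be at least 5")
  }
  n_res <- as.integer(n_res)
  if (is.null(sequence)) {
    res3 <- rep("ALA", n_res)
  } else {
    sequence <- toupper(sequence)
    if (nchar(sequence) != n_res) {
      stop("sequence length must equal n_res")
    }
    letters1 <- strsplit(sequence, "")[[1]]
    if (!all(letters1 %in% .AA1)) {
      stop("sequence contains non-canonical letters")
    }
    res3 <- names(.AA1)[match(letters1, .AA1)]
  }

  bb <- .helix_backbone(n_res)
  atom_names <- c("N", "CA", "C", "O")
  rows <- lapply(seq_len(n_res), function(i) {
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    data.frame(name = atom_names, resname = res3[i], chain = "A",
               resseq = i, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$x <- round(atoms$x, 3)
  atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)

  # generation-time brute-force verification of the declared guarantee
  N <- as.matrix(atoms[atoms$name == "N", c("x", "y", "z")])
  O <- as.matrix(atoms[atoms$name == "O", c("x", "y", "z")])
  for (i in seq_len(n_res)) {
    for (j in seq_len(n_res)) {
      if (i == j || i - j == 1) next  # intra-residue / covalent exclusion
      dij <- sqrt(sum((N[i, ] - O[j, ])^2))
      if (i - j == 4) {
        if (dij < 2.8 || dij > 3.3) {
          stop("internal error: helix i,i+4 N-O distance ", round(dij, 3),
               " outside [2.8, 3.3]")
        }
      } else if (dij <= 3.5) {
        stop("internal error: helix N(", i, ")-O(", j, ") distance ",
             round(dij, 3), " violates the > 3.5 A guarantee")
      }
    }
  }
  structure_model(atoms, protein_id = protein_id,
                  source_path = "<synthetic helix>")
}

# Side-chain internal coordinates (bond A / angle deg / dihedral deg, built
# from the three previously placed reference atoms). Idealized geometry;
# only inter-residue distances matter for the fixtures.
.SIDECHAINS <- list(
  ASP = list(
    list("CG",  c("N", "CA", "CB"), 1.52, 113.0, -65),
    list("OD1", c("CA", "CB", "CG"), 1.25, 118.3, -30),
    list("OD2", c("CA", "CB", "CG"), 1.25, 118.3, 150)
  ),
  GLU = list(
    list("CG",  c("N", "CA", "CB"), 1.52, 113.0, -65),
    list("CD",  c("CA", "CB", "CG"), 1.52, 112.0, 180),
    list("OE1", c("CB", "CG", "CD"), 1.25, 118.3, -30),
    list("OE2", c("CB", "CG", "CD"), 1.25, 118.3, 150)
  ),
  LYS = list(
    list("CG", c("N", "CA", "CB"), 1.52, 111.0, -65),
    list("CD", c("CA", "CB", "CG"), 1.52, 111.0, 180),
    list("CE", c("CB", "CG", "CD"), 1.52, 111.0, 180),
    list("NZ", c("CG", "CD", "CE"), 1.49, 110.0, 180)
  ),
  ARG = list(
    list("CG",  c("N", "CA", "CB"), 1.52, 111.0, -65),
    list("CD",  c("CA", "CB", "CG"), 1.52, 111.0, 180),
    list("NE",  c("CB", "CG", "CD"), 1.46, 111.0, 180),
    list("CZ",  c("CG", "CD", "NE"), 1.33, 124.0, 180),
    list("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
    list("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180)
  ),
  HIS = list(
    list("CG",  c("N", "CA", "CB"), 1.50, 113.8, -65),
    list("ND1", c("CA", "CB", "CG"), 1.38, 122.7, 90),
    list("CD2", c("CA", "CB", "CG"), 1.36, 131.0, -90),
    list("CE1", c("CB", "CG", "ND1"), 1.32, 109.0, 180),
    list("NE2", c("CB", "CG", "CD2"), 1.37, 107.0, 180)
  )
)

# Build one residue (backbone + side chain) at the origin from internal
# coordinates; returns a named coordinate matrix.
.build_residue <- function(resname) {
  crd <- list(
    N = c(0, 0, 0),
    CA = c(1.458, 0, 0)
  )
  ang <- 111.2 * pi / 180
  crd$C <- crd$CA + c(1.525 * cos(pi - ang), 1.525 * sin(pi - ang), 0)
  crd$O <- .place_atom(crd$N, crd$CA, crd$C, 1.231, 120.8, 133)
  # CB via the standard improper about CA
  crd$CB <- .place_atom(crd$N, crd$C, crd$CA, 1.53, 110.1, -122.6)
  for (def in .SIDECHAINS[[resname]]) {
    refs <- def[[2]]
    crd[[def[[1]]]] <- .place_atom(crd[[refs[1]]], crd[[refs[2]]],
                                   crd[[refs[3]]], def[[3]], def[[4]],
                                   def[[5]])
  }
  do.call(rbind, crd)
}

# the atom aimed at the partner, and the bonded atom behind it that defines
# the pointing direction
.SB_TARGETS <- list(
  ASP = c(anchor = "CG", target = "OD1"),
  GLU = c(anchor = "CD", target = "OE1"),
  LYS = c(anchor = "CE", target = "NZ"),
  ARG = c(anchor = "CZ", target = "NH1"),
  HIS = c(anchor = "CE1", target = "NE2")
)

#' Generate a two-chain salt-bridge dimer at a prescribed distance
#'
#' Builds one acidic and one basic residue with idealized full side chains
#' on separate chains, oriented so that their charged groups point at each
#' other along a common axis. The minimum distance over all qualifying
#' carboxyl-O / basic-N atom pairs is exactly `distance` (to 1e-3 A, the
#' PDB coordinate precision) and is attained by a unique atom pair; all
#' other qualifying pairs are farther. Verified by brute force at
#' generation time.
#'
#' @param acid `"ASP"` or `"GLU"`.
#' @param base `"ARG"`, `"LYS"` or `"HIS"`.
#' @param distance Requested minimum O-N distance in Angstrom; must be at
#'   least 2 (a smaller request would clash van der Waals radii).
#' @param protein_id Model identifier.
#' @return A `structure_model` with chains "A" (acid) and "B" (base).
#' @export
make_salt_bridge_dimer <- function(acid = c("ASP", "GLU"),
                                   base = c("LYS", "ARG", "HIS"),
                                   distance,
                                   protein_id = "dimer") {
  acid <- match.arg(acid)
  base <- match.arg(base)
  if (!is.numeric(distance) || distance <= 0) {
    stop("distance must be positive")
  }
  if (distance < 2.0) {
    stop("distance ", distance, " A is below the 2.0 A van der Waals limit")
  }

  orient <- function(resname, direction) {
    m <- .build_residue(resname)
    tg <- .SB_TARGETS[[resname]]
    v <- m[tg["target"], ] - m[tg["anchor"], ]
    R <- .rot_align(v, direction)
    m <- m %*% t(R)
    sweep(m, 2, m[tg["target"], ])  # target atom at origin
  }
  ma <- orient(acid, c(1, 0, 0))
  mb <- orient(base, c(-1, 0, 0))
  mb <- sweep(mb, 2, c(distance, 0, 0), "+")

  to_atoms <- function(m, resname, chain, resseq) {
    data.frame(name = rownames(m), resname = resname, chain = chain,
               resseq = resseq, x = round(m[, 1], 3), y = round(m[, 2], 3),
               z = round(m[, 3], 3), stringsAsFactors = FALSE)
  }
  atoms <- rbind(to_atoms(ma, acid, "A", 1L), to_atoms(mb, base, "B", 1L))

  # brute-force verification: unique minimum at the requested distance
  o_names <- .ACIDIC_ATOMS[[acid]]
  n_names <- .BASIC_ATOMS[[base]]
  om <- atoms[atoms$chain == "A" & atoms$name %in% o_names, ]
  nm <- atoms[atoms$chain == "B" & atoms$name %in% n_names, ]
  dd <- outer(seq_len(nrow(om)), seq_len(nrow(nm)), Vectorize(function(i, j) {
    sqrt((om$x[i] - nm$x[j])^2 + (om$y[i] - nm$y[j])^2 +
         (om$z[i] - nm$z[j])^2)
  }))
  if (abs(min(dd) - distance) > 1e-3) {
    stop("internal error: realized minimum O-N distance ",
         round(min(dd), 4), " differs from requested ", distance)
  }
  if (sum(dd <= min(dd) + 1e-6) != 1) {
    stop("internal error: minimum O-N pair is not unique")
  }
  structure_model(atoms, protein_id = protein_id,
                  source_path = "<synthetic dimer>")
}

# Average amino-acid background frequencies (proteome-average composition,
# normalized), in alphabetical one-letter order.
.BASE_FREQS <- c(
  A = 0.0825, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0707, H = 0.0228, I = 0.0591, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)
.BASE_FREQS <- .BASE_FREQS / sum(.BASE_FREQS)

#' Specification of a synthetic two-species proteome ensemble
#'
#' The defaults describe a desk-scale stand-in for a pair of congeneric
#' proteomes: 300 proteins per species with uniformly distributed lengths,
#' proteome-average amino-acid frequencies, and per-protein hydrogen-bond
#' and salt-bridge rates drawn from log-normal distributions whose medians
#' and spreads place roughly 5% of proteins above 4.0 hydrogen bonds per
#' amino acid and roughly 6% above 0.14 salt bridges per amino acid --
#' matching the upper-tail behaviour that proteome-scale surveys report.
#' Planted effects: `top_fraction`/`top_multiplier` inflate both bond rates
#' in the top fraction (ranked by hydrogen-bond rate) of species A only;
#' `freq_shift_b` perturbs species B's residue frequencies (additive,
#' renormalized).
#'
#' @param n_proteins Proteins per species.
#' @param length_range Integer min/max of the uniform length distribution.
#' @param base_freqs Named 20-vector of amino-acid frequencies (summing to
#'   1) shared by both species before shifts.
#' @param freq_shift_b Named vector of additive frequency shifts applied to
#'   species B (e.g. `c(K = 0.02, D = -0.02)`); NULL for none.
#' @param top_fraction Fraction (0-1) of species-A proteins, ranked by
#'   hydrogen-bond rate, whose bond rates are inflated. 0 plants no effect.
#' @param top_multiplier Multiplier applied to both bond rates of the
#'   inflated proteins.
#' @param hbond_meanlog,hbond_sdlog Log-normal parameters of the per-protein
#'   hydrogen-bonds-per-amino-acid rate.
#' @param sb_meanlog,sb_sdlog Log-normal parameters of the salt-bridges-
#'   per-amino-acid rate.
#' @param qmean_mean,qmean_sd Normal parameters of the simulated QMEAN
#'   model-quality score.
#' @param sequences Generate amino-acid sequences (TRUE, default). FALSE
#'   skips sequence strings for speed in bond-rate-only simulations; the
#'   per-residue count columns are still generated.
#' @param seed Integer seed; the ensemble is a pure function of spec + seed.
#' @return A validated list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_proteins = 300,
                          length_range = c(80L, 500L),
                          base_freqs = .BASE_FREQS,
                          freq_shift_b = NULL,
                          top_fraction = 0,
                          top_multiplier = 1.5,
                          hbond_meanlog = log(2.5), hbond_sdlog = 0.29,
                          sb_meanlog = log(0.08), sb_sdlog = 0.37,
                          qmean_mean = -2, qmean_sd = 1.5,
                          sequences = TRUE,
                          seed = 1L) {
  stopifnot(n_proteins >= 2, length(length_range) == 2,
            length_range[1] >= 20, length_range[2] >= length_range[1],
            top_fraction >= 0, top_fraction <= 1, top_multiplier > 0,
            hbond_sdlog > 0, sb_sdlog > 0)
  if (length(base_freqs) != 20 ||
      !setequal(names(base_freqs), unname(.AA1_SORTED))) {
    stop("base_freqs must be a named 20-vector over the canonical residues")
  }
  base_freqs <- base_freqs[.AA1_SORTED]
  if (abs(sum(base_freqs) - 1) > 1e-9) {
    stop("base_freqs must sum to 1")
  }
  if (!is.null(freq_shift_b)) {
    if (!all(names(freq_shift_b) %in% .AA1_SORTED)) {
      stop("freq_shift_b names must be canonical one-letter codes")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 base_freqs = base_freqs, freq_shift_b = freq_shift_b,
                 top_fraction = top_fraction,
                 top_multiplier = top_multiplier,
                 hbond_meanlog = hbond_meanlog, hbond_sdlog = hbond_sdlog,
                 sb_meanlog = sb_meanlog, sb_sdlog = sb_sdlog,
                 qmean_mean = qmean_mean, qmean_sd = qmean_sd,
                 sequences = isTRUE(sequences),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

.gen_species <- function(spec, label, prefix, freqs) {
  n <- spec$n_proteins
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n,
                 replace = TRUE)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  ann <- sprintf("synthetic protein %04d", seq_len(n))

  counts <- matrix(0L, n, 20, dimnames = list(NULL, .AA1_SORTED))
  seqs <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    idx <- sample.int(20, lens[i], replace = TRUE, prob = freqs)
    counts[i, ] <- tabulate(idx, nbins = 20)
    if (spec$sequences) {
      seqs[i] <- paste(.AA1_SORTED[idx], collapse = "")
    }
  }

  hb_rate <- stats::rlnorm(n, spec$hbond_meanlog, spec$hbond_sdlog)
  sb_rate <- stats::rlnorm(n, spec$sb_meanlog, spec$sb_sdlog)
  qmean <- stats::rnorm(n, spec$qmean_mean, spec$qmean_sd)
  list(protein_id = ids, annotation = ann, length = lens, seqs = seqs,
       counts = counts, hb_rate = hb_rate, sb_rate = sb_rate, qmean = qmean,
       label = label)
}

.species_to_table <- function(g) {
  n_hb <- as.integer(round(g$hb_rate * g$length))
  n_sb <- as.integer(round(g$sb_rate * g$length))
  df <- data.frame(
    protein_id = g$protein_id, annotation = g$annotation,
    length = g$length, qmean = g$qmean,
    n_hbonds = n_hb, n_saltbridges = n_sb,
    hbonds_per_aa = n_hb / g$length,
    saltbridges_per_aa = n_sb / g$length,
    stringsAsFactors = FALSE
  )
  cc <- as.data.frame(g$counts)
  names(cc) <- paste0("aa_", .AA1_SORTED)
  df <- cbind(df, cc)
  feature_table(df, species_label = g$label)
}

#' Generate a two-species synthetic ensemble with an expected-truth record
#'
#' Produces sequence sets, per-protein synthetic bond counts and simulated
#' QMEAN scores for two species under an [ensemble_spec()], together with a
#' truth record stating which species-level comparisons a correct analysis
#' should find significant. Bond counts are planted integers (they bypass
#' the geometric detectors, which are validated on structure fixtures
#' instead). Generation is a pure function of the spec, including its seed.
#'
#' @param spec An `ensemble_spec`.
#' @param dir Optional directory; when given, FASTA files (if sequences
#'   were generated) and per-species metadata TSVs are written there.
#' @return A list with elements `a` and `b` (per-species `feature_table`s),
#'   `seqs_a`/`seqs_b` (data frames shaped like [read_fasta()] output, with
#'   NA sequences when `spec$sequences` is FALSE), and `truth` (list:
#'   planted effect description plus `expect_full_reject` and
#'   `expect_upper_reject` flags).
#' @export
make_ensemble <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  freqs_a <- spec$base_freqs
  freqs_b <- freqs_a
  if (!is.null(spec$freq_shift_b)) {
    freqs_b[names(spec$freq_shift_b)] <-
      freqs_b[names(spec$freq_shift_b)] + spec$freq_shift_b
    if (any(freqs_b < 0)) stop("freq_shift_b drives a frequency below 0")
    freqs_b <- freqs_b / sum(freqs_b)
  }

  ga <- .gen_species(spec, "species_a", "SPA", freqs_a)
  gb <- .gen_species(spec, "species_b", "SPB", freqs_b)

  planted <- spec$top_fraction > 0 && spec$top_multiplier != 1
  if (planted) {
    k <- ceiling(spec$top_fraction * spec$n_proteins)
    top <- order(-ga$hb_rate)[seq_len(k)]
    ga$hb_rate[top] <- ga$hb_rate[top] * spec$top_multiplier
    ga$sb_rate[top] <- ga$sb_rate[top] * spec$top_multiplier
  }

  ta <- .species_to_table(ga)
  tb <- .species_to_table(gb)
  seq_df <- function(g) {
    data.frame(protein_id = g$protein_id, annotation = g$annotation,
               sequence = g$seqs, length = g$length,
               flagged = FALSE, stringsAsFactors = FALSE)
  }
  out <- list(
    a = ta, b = tb, seqs_a = seq_df(ga), seqs_b = seq_df(gb),
    truth = list(
      planted_top_fraction = spec$top_fraction,
      top_multiplier = spec$top_multiplier,
      freq_shift_b = spec$freq_shift_b,
      expect_full_reject = FALSE,
      expect_upper_reject = planted,
      expect_usage_reject = !is.null(spec$freq_shift_b)
    )
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (spec$sequences) {
      for (sp in c("a", "b")) {
        s <- out[[paste0("seqs_", sp)]]
        set <- Biostrings::BStringSet(s$sequence)
        names(set) <- paste(s$protein_id, s$annotation)
        Biostrings::writeXStringSet(set,
                                    file.path(dir,
                                              paste0("species_", sp,
                                                     ".fasta")))
      }
    }
    write_tsv(as.data.frame(ta), file.path(dir, "species_a_features.tsv"))
    write_tsv(as.data.frame(tb), file.path(dir, "species_b_features.tsv"))
    truth_df <- data.frame(
      key = c("planted_top_fraction", "top_multiplier",
              "expect_upper_reject", "expect_full_reject"),
      value = c(spec$top_fraction, spec$top_multiplier,
                as.numeric(out$truth$expect_upper_reject),
                as.numeric(out$truth$expect_full_reject))
    )
    write_tsv(truth_df, file.path(dir, "truth.tsv"))
  }
  out
}
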