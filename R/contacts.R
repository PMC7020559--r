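# Geometric contact detection: hydrogen bonds and salt bridges under
# distance-only criteria. Two search routes are provided: a grid (cell
# list) spatial index, and the O(n^2) all-pairs route kept as an
# independent oracle; they must always agree.

# Comparisons against cutoffs are inclusive. A small epsilon absorbs
# floating-point noise so that pairs constructed at exactly the cutoff
# (3.50 / 4.00 A at PDB 3-decimal precision) are detected deterministically.
.DIST_EPS <- 1e-9

#' Hydrogen-bond detection parameters
#'
#' @param max_donor_acceptor Maximum donor-acceptor heavy-atom distance in
#'   Angstrom (inclusive). Default 3.5.
#' @param max_hydrogen_acceptor Maximum hydrogen-acceptor distance in
#'   Angstrom (inclusive), applied only when explicit hydrogens are present
#'   (see `use_explicit_hydrogens`). Default 2.5.
#' @param use_explicit_hydrogens `"auto"` (apply the hydrogen-acceptor
#'   criterion only when the model contains hydrogens, the normal case for
#'   crystallography-derived models being that it does not), `"always"`, or
#'   `"never"`.
#' @param include_sulfur Allow Cys SG / Met SD as donor/acceptor.
#' @param include_ligand Treat ligand (HETATM) N/O atoms as both donors and
#'   acceptors.
#' @return A validated list of class `hbond_params`.
#' @export
hbond_params <- function(max_donor_acceptor = 3.5,
                         max_hydrogen_acceptor = 2.5,
                         use_explicit_hydrogens = c("auto", "always", "never"),
                         include_sulfur = FALSE,
                         include_ligand = TRUE) {
  use_explicit_hydrogens <- match.arg(use_explicit_hydrogens)
  stopifnot(max_donor_acceptor > 0, max_hydrogen_acceptor > 0)
  if (max_hydrogen_acceptor >= max_donor_acceptor) {
    stop("max_hydrogen_acceptor must be smaller than max_donor_acceptor")
  }
  structure(list(max_donor_acceptor = max_donor_acceptor,
                 max_hydrogen_acceptor = max_hydrogen_acceptor,
                 use_explicit_hydrogens = use_explicit_hydrogens,
                 include_sulfur = include_sulfur,
                 include_ligand = include_ligand),
            class = "hbond_params")
}

#' Salt-bridge detection parameters
#'
#' @param max_distance Maximum acidic-O to basic-N distance in Angstrom
#'   (inclusive). Default 4.0.
#' @param counting_unit `"residue_pair"` (default; one bridge per acidic
#'   residue / basic residue pair with at least one qualifying atom pair,
#'   reporting the minimum-distance atoms) or `"atom_pair"` (one bridge per
#'   qualifying atom pair).
#' @param include_his Count histidine ND1/NE2 among the basic nitrogens.
#' @return A validated list of class `saltbridge_params`.
#' @export
saltbridge_params <- function(max_distance = 4.0,
                              counting_unit = c("residue_pair", "atom_pair"),
                              include_his = TRUE) {
  counting_unit <- match.arg(counting_unit)
  stopifnot(max_distance > 0)
  structure(list(max_distance = max_distance, counting_unit = counting_unit,
                 include_his = include_his),
            class = "saltbridge_params")
}

# All pairs (i from A, j from B) with euclidean distance <= cutoff.
# method "grid" bins B into cells of edge `cutoff` and visits the 27
# neighbouring cells of each occupied A cell; "brute" is the O(n^2) oracle.
.pair_dists <- function(ax, bx, cutoff, method = c("grid", "brute")) {
  method <- match.arg(method)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (nrow(ax) == 0 || nrow(bx) == 0) return(empty)
  lim <- cutoff + .DIST_EPS

  # the quadratic form is used only to gather candidates (with slack for
  # its floating-point error); exact distances are then recomputed from
  # coordinate differences so both routes yield bit-identical results
  exact <- function(i, j) {
    d <- sqrt((ax[i, 1] - bx[j, 1])^2 + (ax[i, 2] - bx[j, 2])^2 +
              (ax[i, 3] - bx[j, 3])^2)
    keep <- d <= lim
    data.frame(i = i[keep], j = j[keep], d = d[keep])
  }
  slack <- lim^2 * 1e-9 + 1e-9

  if (method == "brute") {
    d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
    hit <- which(d2 <= lim^2 + slack, arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty)
    return(exact(hit[, 1], hit[, 2]))
  }

  cell_of <- function(m) {
    cbind(floor(m[, 1] / cutoff), floor(m[, 2] / cutoff),
          floor(m[, 3] / cutoff))
  }
  ca <- cell_of(ax)
  cb <- cell_of(bx)
  bkey <- paste(cb[, 1], cb[, 2], cb[, 3], sep = ",")
  bmap <- split(seq_len(nrow(bx)), bkey)
  akey <- paste(ca[, 1], ca[, 2], ca[, 3], sep = ",")
  acells <- split(seq_len(nrow(ax)), akey)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  out_i <- out_j <- integer(0)
  out_d <- numeric(0)
  for (ck in names(acells)) {
    ai <- acells[[ck]]
    cc <- as.integer(strsplit(ck, ",", fixed = TRUE)[[1]])
    nb <- sweep(off, 2, cc, "+")
    nbk <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
    bj <- unlist(bmap[nbk], use.names = FALSE)
    if (is.null(bj) || length(bj) == 0) next
    sub <- ax[ai, , drop = FALSE]
    cand <- bx[bj, , drop = FALSE]
    d2 <- outer(rowSums(sub^2), rowSums(cand^2), "+") - 2 * sub %*% t(cand)
    hit <- which(d2 <= lim^2 + slack, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    got <- exact(ai[hit[, 1]], bj[hit[, 2]])
    out_i <- c(out_i, got$i)
    out_j <- c(out_j, got$j)
    out_d <- c(out_d, got$d)
  }
  out <- data.frame(i = out_i, j = out_j, d = out_d)
  out[order(out$i, out$j), , drop = FALSE]
}

.empty_contacts <- function() {
  data.frame(kind = character(0),
             donor_chain = character(0), donor_resseq = integer(0),
             donor_icode = character(0), donor_resname = character(0),
             donor_atom = character(0),
             acceptor_chain = character(0), acceptor_resseq = integer(0),
             acceptor_icode = character(0), acceptor_resname = character(0),
             acceptor_atom = character(0),
             distance = numeric(0), involves_ligand = logical(0),
             stringsAsFactors = FALSE)
}

.check_coords <- function(atoms) {
  if (nrow(atoms) > 0 &&
      !all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atomic coordinates in model")
  }
}

# residue ordinal within each chain by author numbering (resseq, then
# insertion code, empty first), used for the covalent backbone
# N(i) -> O(i-1) exclusion; independent of record order in the file
.residue_ordinals <- function(atoms) {
  ord <- integer(nrow(atoms))
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch
    res <- unique(data.frame(r = atoms$resseq[sel], i = atoms$icode[sel]))
    res <- res[order(res$r, res$i), , drop = FALSE]
    ord[sel] <- match(paste(atoms$resseq[sel], atoms$icode[sel]),
                      paste(res$r, res$i))
  }
  ord
}

.contacts_df <- function(kind, atoms, di, ai, d) {
  out <- data.frame(
    kind = rep(kind, length(di)),
    donor_chain = atoms$chain[di], donor_resseq = atoms$resseq[di],
    donor_icode = atoms$icode[di], donor_resname = atoms$resname[di],
    donor_atom = atoms$name[di],
    acceptor_chain = atoms$chain[ai], acceptor_resseq = atoms$resseq[ai],
    acceptor_icode = atoms$icode[ai], acceptor_resname = atoms$resname[ai],
    acceptor_atom = atoms$name[ai],
    distance = d,
    involves_ligand = atoms$is_het[di] | atoms$is_het[ai],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$donor_chain, out$donor_resseq, out$donor_icode,
                   out$donor_atom, out$acceptor_chain, out$acceptor_resseq,
                   out$acceptor_icode, out$acceptor_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect hydrogen bonds in a structure model
#'
#' Enumerates every unique donor/acceptor heavy-atom pair within the
#' donor-acceptor cutoff (inclusive), across all chains, with no angle
#' criterion. Intra-residue pairs and the covalent backbone pair
#' N(i)->O(i-1) (the only inter-residue donor-acceptor pair within two
#' covalent bonds of a polypeptide) are excluded. When the model contains
#' explicit hydrogens and the policy allows, a qualifying pair must
#' additionally have a hydrogen attached to the donor (within 1.2 A) at no
#' more than the hydrogen-acceptor cutoff from the acceptor. Ligand N/O
#' atoms act as both donors and acceptors when `include_ligand` is set.
#' Bifunctional atoms (e.g. His ND1) are never paired with themselves and
#' each unordered atom pair is reported once.
#'
#' @param model A `structure_model`.
#' @param params An `hbond_params` object.
#' @param method Spatial search route: `"grid"` (cell-list index, default)
#'   or `"brute"` (all pairs; retained as an independent oracle).
#' @return A data frame of contacts (class `contact_pairs`): one row per
#'   bond with donor/acceptor identities, distance and a ligand flag.
#' @export
detect_hbonds <- function(model, params = hbond_params(),
                          method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms
  if (nrow(atoms) == 0) return(.empty_contacts())
  .check_coords(atoms)

  key <- paste(atoms$resname, atoms$name, sep = "\r")
  donor_keys <- unlist(lapply(.AA3, function(r) {
    paste(r, donor_atoms(r, include_sulfur = params$include_sulfur),
          sep = "\r")
  }))
  acceptor_keys <- unlist(lapply(.AA3, function(r) {
    paste(r, acceptor_atoms(r, include_sulfur = params$include_sulfur),
          sep = "\r")
  }))

  is_don <- !atoms$is_het & key %in% donor_keys
  is_acc <- !atoms$is_het & key %in% acceptor_keys
  if (params$include_ligand) {
    lig_no <- atoms$is_het & atoms$element %in% c("N", "O")
    is_don <- is_don | lig_no
    is_acc <- is_acc | lig_no
  }
  di_all <- which(is_don)
  ai_all <- which(is_acc)
  if (length(di_all) == 0 || length(ai_all) == 0) return(.empty_contacts())

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pairs <- .pair_dists(xyz[di_all, , drop = FALSE],
                       xyz[ai_all, , drop = FALSE],
                       params$max_donor_acceptor, method)
  if (nrow(pairs) == 0) return(.empty_contacts())
  di <- di_all[pairs$i]
  ai <- ai_all[pairs$j]
  d <- pairs$d

  uid <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$is_het,
               sep = "\r")
  keep <- uid[di] != uid[ai]

  # covalent exclusion: backbone N of residue i vs backbone O of the
  # immediately preceding residue in the same chain
  ord <- .residue_ordinals(atoms)
  # adjacency requires both file order (ordinal) and author numbering to be
  # consecutive, so a numbering gap (chain break) is not treated as a
  # peptide bond
  dres <- atoms$resseq[di] - atoms$resseq[ai]
  cov <- atoms$name[di] == "N" & atoms$name[ai] == "O" &
    !atoms$is_het[di] & !atoms$is_het[ai] &
    atoms$chain[di] == atoms$chain[ai] &
    ord[di] - ord[ai] == 1L & (dres == 0L | dres == 1L)
  keep <- keep & !cov
  di <- di[keep]; ai <- ai[keep]; d <- d[keep]
  if (length(di) == 0) return(.empty_contacts())

  # one report per unordered atom pair (bifunctional atoms can appear in
  # both roles); canonical orientation = smaller donor index, so the
  # result is independent of the search route's pair ordering
  cano <- order(pmin(di, ai), pmax(di, ai), di)
  di <- di[cano]; ai <- ai[cano]; d <- d[cano]
  pk <- paste(pmin(di, ai), pmax(di, ai), sep = "\r")
  first <- !duplicated(pk)
  di <- di[first]; ai <- ai[first]; d <- d[first]

  # hydrogen-acceptor criterion when explicit hydrogens are in play
  policy <- params$use_explicit_hydrogens
  has_h <- any(atoms$element %in% c("H", "D"))
  if (policy == "always" || (policy == "auto" && has_h)) {
    h_idx <- which(atoms$element %in% c("H", "D"))
    ok <- vapply(seq_along(di), function(k) {
      hd <- h_idx[uid[h_idx] == uid[di[k]]]
      if (length(hd) == 0) return(FALSE)
      dh <- sqrt((atoms$x[hd] - atoms$x[di[k]])^2 +
                 (atoms$y[hd] - atoms$y[di[k]])^2 +
                 (atoms$z[hd] - atoms$z[di[k]])^2)
      hd <- hd[dh <= 1.2 + .DIST_EPS]
      if (length(hd) == 0) return(FALSE)
      ha <- sqrt((atoms$x[hd] - atoms$x[ai[k]])^2 +
                 (atoms$y[hd] - atoms$y[ai[k]])^2 +
                 (atoms$z[hd] - atoms$z[ai[k]])^2)
      any(ha <= params$max_hydrogen_acceptor + .DIST_EPS)
    }, logical(1))
    di <- di[ok]; ai <- ai[ok]; d <- d[ok]
  }

  out <- .contacts_df("hbond", atoms, di, ai, d)
  class(out) <- c("contact_pairs", class(out))
  out
}

#' Detect salt bridges in a structure model
#'
#' A salt bridge is recorded when at least one Asp/Glu side-chain carboxyl
#' oxygen (OD1/OD2, OE1/OE2) lies within the cutoff (inclusive) of a
#' side-chain nitrogen of Arg (NH1/NH2/NE), Lys (NZ) or His (ND1/NE2).
#' Inter-chain pairs are included; ligands are not (the criterion names
#' protein residues only). In `residue_pair` mode one contact is reported
#' per (acidic residue, basic residue) pair, carrying its minimum-distance
#' atom pair; in `atom_pair` mode every qualifying atom pair is reported.
#' The basic nitrogen is reported in the donor slot and the carboxyl oxygen
#' in the acceptor slot, consistent with the hydrogen bond such a contact
#' contains.
#'
#' @param model A `structure_model`.
#' @param params A `saltbridge_params` object.
#' @param method `"grid"` or `"brute"` as in [detect_hbonds()].
#' @return A `contact_pairs` data frame with kind `"saltbridge"`.
#' @export
detect_salt_bridges <- function(model, params = saltbridge_params(),
                                method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms
  if (nrow(atoms) == 0) return(.empty_contacts())
  .check_coords(atoms)

  key <- paste(atoms$resname, atoms$name, sep = "\r")
  acid_keys <- unlist(lapply(names(.ACIDIC_ATOMS), function(r) {
    paste(r, .ACIDIC_ATOMS[[r]], sep = "\r")
  }))
  basic <- .BASIC_ATOMS
  if (!params$include_his) basic$HIS <- NULL
  basic_keys <- unlist(lapply(names(basic), function(r) {
    paste(r, basic[[r]], sep = "\r")
  }))

  oi_all <- which(!atoms$is_het & key %in% acid_keys)
  ni_all <- which(!atoms$is_het & key %in% basic_keys)
  if (length(oi_all) == 0 || length(ni_all) == 0) return(.empty_contacts())

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pairs <- .pair_dists(xyz[ni_all, , drop = FALSE],
                       xyz[oi_all, , drop = FALSE],
                       params$max_distance, method)
  if (nrow(pairs) == 0) return(.empty_contacts())
  ni <- ni_all[pairs$i]
  oi <- oi_all[pairs$j]
  d <- pairs$d

  if (params$counting_unit == "residue_pair") {
    uid <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
    rp <- paste(uid[ni], uid[oi], sep = "\n")
    best <- tapply(seq_along(rp), rp, function(ix) ix[which.min(d[ix])])
    sel <- sort(unlist(best, use.names = FALSE))
    ni <- ni[sel]; oi <- oi[sel]; d <- d[sel]
  }

  out <- .contacts_df("saltbridge", atoms, ni, oi, d)
  class(out) <- c("contact_pairs", class(out))
  out
}
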