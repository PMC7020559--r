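# Test fixtures and independent oracles. Everything here is generated in
# code; nothing is read from disk.

# minimal model: a set of named atoms placed explicitly
toy_model <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r$name, resname = r$resname, chain = r$chain,
               resseq = r$resseq, x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               is_het = isTRUE(r$is_het), stringsAsFactors = FALSE)
  }))
  structure_model(atoms, protein_id = "toy")
}

atomspec <- function(name, resname, chain, resseq, xyz, is_het = FALSE) {
  list(name = name, resname = resname, chain = chain, resseq = resseq,
       xyz = xyz, is_het = is_het)
}

# random protein-like structure: residues with their donor/acceptor-bearing
# atoms jittered around random centres in a box, two chains
rand_structure <- function(seed, n_res = 40, box = 22) {
  set.seed(seed)
  pool <- c("ALA", "GLY", "SER", "THR", "ASP", "GLU", "LYS", "ARG", "HIS",
            "ASN", "GLN", "TYR", "TRP", "PRO", "CYS", "MET", "VAL", "LEU")
  side <- list(ASP = c("CB", "CG", "OD1", "OD2"), GLU = c("OE1", "OE2"),
               LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
               HIS = c("ND1", "NE2"), ASN = c("ND2", "OD1"),
               GLN = c("NE2", "OE1"), SER = "OG", THR = "OG1", TYR = "OH",
               TRP = "NE1", CYS = "SG", MET = "SD")
  resnames <- sample(pool, n_res, replace = TRUE)
  half <- ceiling(n_res / 2)
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    rn <- resnames[i]
    nms <- c("N", "CA", "C", "O", side[[rn]])
    centre <- runif(3, 0, box)
    xyz <- matrix(centre, length(nms), 3, byrow = TRUE) +
      matrix(runif(3 * length(nms), -1.5, 1.5), ncol = 3)
    rows[[i]] <- data.frame(
      name = nms, resname = rn,
      chain = if (i <= half) "A" else "B",
      resseq = if (i <= half) i else i - half,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), protein_id = paste0("rand", seed))
}

.oracle_dist <- function(atoms, i, j) {
  sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
       (atoms$z[i] - atoms$z[j])^2)
}

# residue ordinal by author numbering within each chain
.oracle_ordinals <- function(atoms) {
  ord <- integer(nrow(atoms))
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch
    key <- paste(atoms$resseq[sel], atoms$icode[sel])
    df <- unique(data.frame(r = atoms$resseq[sel], i = atoms$icode[sel]))
    df <- df[order(df$r, df$i), , drop = FALSE]
    ord[sel] <- match(key, paste(df$r, df$i))
  }
  ord
}

# strip bookkeeping attributes so record content can be compared
strip_ft <- function(tab) {
  df <- as.data.frame(tab)
  attr(df, "filter_log") <- NULL
  attr(df, "species_label") <- NULL
  df
}

# independent all-pairs hydrogen-bond count (no hydrogens assumed)
oracle_hbond_count <- function(model, params = hbond_params()) {
  atoms <- model$atoms
  n <- nrow(atoms)
  uid <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$is_het)
  ord <- .oracle_ordinals(atoms)
  don <- acc <- logical(n)
  for (k in seq_len(n)) {
    if (atoms$is_het[k]) {
      lig <- params$include_ligand && atoms$element[k] %in% c("N", "O")
      don[k] <- acc[k] <- lig
    } else {
      don[k] <- atoms$name[k] %in%
        suppressWarnings(donor_atoms(atoms$resname[k], params$include_sulfur))
      acc[k] <- atoms$name[k] %in%
        suppressWarnings(acceptor_atoms(atoms$resname[k],
                                        params$include_sulfur))
    }
  }
  seen <- new.env(hash = TRUE)
  count <- 0L
  for (iD in which(don)) {
    for (iA in which(acc)) {
      if (iD == iA || uid[iD] == uid[iA]) next
      if (.oracle_dist(atoms, iD, iA) > params$max_donor_acceptor + 1e-9) {
        next
      }
      dres <- atoms$resseq[iD] - atoms$resseq[iA]
      if (atoms$name[iD] == "N" && atoms$name[iA] == "O" &&
          !atoms$is_het[iD] && !atoms$is_het[iA] &&
          atoms$chain[iD] == atoms$chain[iA] &&
          ord[iD] - ord[iA] == 1L && dres %in% c(0L, 1L)) {
        next
      }
      key <- paste(min(iD, iA), max(iD, iA))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      count <- count + 1L
    }
  }
  count
}

# independent all-pairs salt-bridge count
oracle_saltbridge_count <- function(model, params = saltbridge_params()) {
  atoms <- model$atoms
  acid <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  basic <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
  if (params$include_his) basic$HIS <- c("ND1", "NE2")
  oi <- which(!atoms$is_het &
              mapply(function(r, a) a %in% (acid[[r]] %||% character(0)),
                     atoms$resname, atoms$name))
  ni <- which(!atoms$is_het &
              mapply(function(r, a) a %in% (basic[[r]] %||% character(0)),
                     atoms$resname, atoms$name))
  pairs <- character(0)
  count <- 0L
  for (i in oi) {
    for (j in ni) {
      if (.oracle_dist(atoms, i, j) > params$max_distance + 1e-9) next
      if (params$counting_unit == "atom_pair") {
        count <- count + 1L
      } else {
        key <- paste(atoms$chain[i], atoms$resseq[i], atoms$icode[i], "|",
                     atoms$chain[j], atoms$resseq[j], atoms$icode[j])
        if (!(key %in% pairs)) {
          pairs <- c(pairs, key)
          count <- count + 1L
        }
      }
    }
  }
  count
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rigid motion: random rotation + translation applied to all coordinates
apply_rigid_motion <- function(model, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, runif(3, -20, 20), "+")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# feature table with given rate vectors (planted counts, unit lengths)
ft_from_rates <- function(hb, sb = hb * 0.03, ids = NULL,
                          label = "species") {
  n <- length(hb)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  len <- rep(100L, n)
  df <- data.frame(protein_id = ids,
                   annotation = paste("protein", seq_len(n)),
                   length = len, qmean = 0,
                   n_hbonds = as.integer(round(hb * len)),
                   n_saltbridges = as.integer(round(sb * len)),
                   hbonds_per_aa = hb, saltbridges_per_aa = sb,
                   stringsAsFactors = FALSE)
  for (a in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
    df[[paste0("aa_", a)]] <- 5L
  }
  feature_table(df, species_label = label)
}
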