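# PDB / FASTA / TSV input-output.
#
# Models are consumed as single-structure PDB files (possibly multi-chain
# biounits, possibly with ligand HETATM records). Parsing is fixed-column
# per the PDB specification; waters are excluded at parse time because the
# bond criteria deliberately ignore protein-solvent interactions.

.WATER_NAMES <- c("HOH", "WAT", "H2O")
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
names(.AA1) <- .AA3
.AA1_SORTED <- sort(.AA1)  # alphabetical one-letter order used in tables

#' Read a PDB-format protein model
#'
#' Parses ATOM/HETATM records with fixed-column semantics into a
#' `structure_model`. Water residues (HOH/WAT/H2O) are dropped, only the
#' first coordinate model of a multi-model (NMR-style) file is kept, and
#' alternate locations are resolved by keeping the altloc with the highest
#' occupancy (ties broken by the lexicographically first altloc code).
#' Non-water HETATM records (ligands) are retained and flagged.
#'
#' @param path Path to a PDB file.
#' @param altloc_policy `"highest_occupancy"` (default) or `"first"`, which
#'   keeps the first altloc seen for each atom regardless of occupancy.
#' @param protein_id Identifier stored on the model; defaults to the file
#'   base name without extension.
#' @return An object of class `structure_model`: a list with elements
#'   `protein_id`, `atoms` (a data frame with one row per retained atom:
#'   serial, name, altloc, resname, chain, resseq, icode, x, y, z,
#'   occupancy, element, is_het), and `source_path`.
#' @export
read_pdb <- function(path, altloc_policy = c("highest_occupancy", "first"),
                     protein_id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    stop("PDB file does not exist: ", path)
  }
  lines <- readLines(path, warn = FALSE)

  # multi-model: keep the first MODEL...ENDMDL block only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    end <- grep("^ENDMDL", lines)
    end <- if (length(end) > 0) end[1] else length(lines)
    keep <- seq(model_starts[1], end)
    lines <- lines[keep]
    lineno <- keep
  } else {
    lineno <- seq_along(lines)
  }

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records found in ", path)
  }
  al <- lines[is_atom]
  ln <- lineno[is_atom]

  f <- function(from, to) trimws(substr(al, from, to))
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(s))
    if (length(bad) > 0) {
      stop("malformed ", what, " field in PDB record at line ", ln[bad[1]],
           ": '", s[bad[1]], "'")
    }
    v
  }

  serial <- num(f(7, 11), "serial")
  name <- f(13, 16)
  altloc <- substr(al, 17, 17)
  altloc[altloc == " "] <- ""
  resname <- f(18, 20)
  chain <- trimws(substr(al, 22, 22))
  resseq <- num(f(23, 26), "residue number")
  icode <- trimws(substr(al, 27, 27))
  x <- num(f(31, 38), "x coordinate")
  y <- num(f(39, 46), "y coordinate")
  z <- num(f(47, 54), "z coordinate")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("missing coordinate in PDB record at line ",
         ln[which(is.na(x) | is.na(y) | is.na(z))[1]])
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1.0
  element <- toupper(f(77, 78))
  is_het <- substr(al, 1, 6) == "HETATM"

  # element inference from the atom name when the element column is blank
  # (older PDB dialects): first non-digit character of the name.
  blank <- !nzchar(element)
  if (any(blank)) {
    inferred <- sub("^[0-9]*", "", name[blank])
    element[blank] <- toupper(substr(inferred, 1, 1))
  }
  if (any(!nzchar(element))) {
    stop("cannot infer element for atom at line ",
         ln[which(!nzchar(element))[1]])
  }

  atoms <- data.frame(
    serial = as.integer(serial), name = name, altloc = altloc,
    resname = resname, chain = chain, resseq = as.integer(resseq),
    icode = icode, x = x, y = y, z = z, occupancy = occ,
    element = element, is_het = is_het,
    stringsAsFactors = FALSE
  )

  atoms <- atoms[!(atoms$resname %in% .WATER_NAMES), , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("structure contains only water records: ", path)
  }

  # altloc resolution per (chain, resseq, icode, name)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    if (altloc_policy == "highest_occupancy") {
      ord <- order(key, -atoms$occupancy, atoms$altloc)
    } else {
      ord <- seq_len(nrow(atoms))
    }
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
    key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name,
                 sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate atom (same chain/residue/name, same altloc) in ", path)
    }
  }
  rownames(atoms) <- NULL

  if (is.null(protein_id)) {
    protein_id <- tools::file_path_sans_ext(basename(path))
  }
  structure(
    list(protein_id = protein_id, atoms = atoms, source_path = path),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  prot <- a[!a$is_het, , drop = FALSE]
  nres <- length(unique(paste(prot$chain, prot$resseq, prot$icode)))
  cat("structure_model '", x$protein_id, "': ",
      nrow(prot), " protein atoms, ", nres, " residues, ",
      length(unique(prot$chain)), " chain(s), ",
      sum(a$is_het), " ligand atoms\n", sep = "")
  invisible(x)
}

#' Construct a structure_model from an atom table
#'
#' Low-level constructor used by the synthetic-fixture generators and by
#' tests. Performs the same invariant checks as [read_pdb()] (no waters, no
#' duplicate atom identities).
#'
#' @param atoms Data frame with at least columns name, resname, chain,
#'   resseq, x, y, z. Missing optional columns (serial, altloc, icode,
#'   occupancy, element, is_het) are filled with defaults.
#' @param protein_id Model identifier.
#' @param source_path Provenance string.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, protein_id = "model",
                            source_path = "<in-memory>") {
  need <- c("name", "resname", "chain", "resseq", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  if (is.null(atoms$is_het)) atoms$is_het <- FALSE
  if (is.null(atoms$element)) {
    atoms$element <- toupper(substr(sub("^[0-9]*", "", atoms$name), 1, 1))
  }
  if (any(atoms$resname %in% .WATER_NAMES)) {
    stop("water residues are not allowed in a structure_model")
  }
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate atom identity in atom table")
  }
  rownames(atoms) <- NULL
  structure(
    list(protein_id = protein_id, atoms = atoms, source_path = source_path),
    class = "structure_model"
  )
}

#' Write a structure_model as a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (coordinates at the format's
#' 3-decimal precision) followed by END. Used by the synthetic fixture
#' generators; round-trips through [read_pdb()] to 1e-3 Angstrom.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return Invisibly, the character vector of lines written.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  rec <- ifelse(a$is_het, "HETATM", "ATOM  ")
  # atom name column convention: 1-3 character names start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf("%s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, nm,
                   ifelse(nzchar(a$altloc), a$altloc, " "),
                   a$resname, a$chain, a$resseq %% 10000L,
                   ifelse(nzchar(a$icode), a$icode, " "),
                   a$x, a$y, a$z, a$occupancy, 0, a$element)
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(lines)
}

#' Read a FASTA file of protein sequences
#'
#' One record per header. The protein ID is the first whitespace-delimited
#' token of the header; UniProt-style `db|ID|name` tokens are reduced to the
#' central accession. The remainder of the header is kept as the annotation
#' string. Sequences are upper-cased and validated against the 20 canonical
#' one-letter codes plus X; records containing X are flagged (they mirror
#' sequences for which structure modeling fails).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns protein_id, annotation, sequence,
#'   length, flagged.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("no sequences found in ", path)
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  first_tok <- sub("\\s.*$", "", headers)
  annotation <- trimws(sub("^\\S+\\s*", "", headers))
  id <- vapply(first_tok, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)

  if (anyDuplicated(id)) {
    stop("duplicate protein IDs in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for: ", paste(id[empty], collapse = ", "))
  }
  alphabet <- c(.AA1_SORTED, "X")
  bad_chars <- lapply(strsplit(seqs, ""), function(ch) setdiff(ch, alphabet))
  bad <- lengths(bad_chars) > 0
  if (any(bad)) {
    stop("invalid sequence characters: ",
         paste(sprintf("%s [%s]", id[bad],
                       vapply(bad_chars[bad], paste, "", collapse = "")),
               collapse = "; "))
  }
  data.frame(
    protein_id = id,
    annotation = annotation,
    sequence = seqs,
    length = nchar(seqs),
    flagged = grepl("X", seqs, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write a tabular result as TSV
#'
#' UTF-8, tab-separated, header row. Floating point columns are rendered
#' with 6 significant digits and rows are sorted on the table's natural key
#' (protein_id or term_id when present, otherwise the first column), so
#' re-writing the same records yields a byte-identical file.
#'
#' @param records Non-empty data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("refusing to write an empty table to ", path)
  }
  df <- as.data.frame(records)
  key <- intersect(c("protein_id", "term_id"), names(df))
  key <- if (length(key) > 0) key[1] else names(df)[1]
  df <- df[order(df[[key]]), , drop = FALSE]
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(signif(df[[j]], 6), format = "g", digits = 6)
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
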