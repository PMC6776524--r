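#' Topology: atoms, molecules and named selections
#'
#' A topology holds per-atom metadata (name, element, residue number and
#' name, chain/segment id), a grouping of atoms into molecules, and an
#' optional table of named atom selections. Atom indices are 0-based and
#' contiguous (the \code{index} column); R code addresses atoms by 1-based
#' row position throughout.
#'
#' @param atoms data.frame with columns \code{name}, \code{elem},
#'   \code{resno}, \code{resname}, \code{chain}; one row per atom.
#' @param molno integer vector, one molecule id per atom.
#' @param selections named list of integer vectors (1-based atom positions).
#' @return object of class \code{"topology"}.
#' @export
topology <- function(atoms, molno = rep(1L, nrow(atoms)), selections = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "elem", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (length(molno) != n) stop("molno length must equal atom count")
  atoms$index <- seq_len(n) - 1L
  atoms$molno <- as.integer(molno)
  for (lab in names(selections)) {
    idx <- selections[[lab]]
    if (any(idx < 1L | idx > n))
      stop("selection '", lab, "' references atoms outside 1..", n)
  }
  structure(list(atoms = atoms, n_atoms = n, selections = selections),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d molecules, %d residues\n",
              x$n_atoms, length(unique(x$atoms$molno)),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

# Residue names treated as protein for the "protein" selection keyword.
.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HID",
  "HIE", "HIP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL", "CYX", "ASH", "GLH", "LYN")

# Atom names forming the peptide backbone; configurable at the call sites
# that take a `backbone` argument.
.backbone_names <- c("N", "CA", "C", "O")

.elem_from_name <- function(name) {
  # PDB convention: element is the first alphabetic character(s); strip
  # leading digits (e.g. "1HB") then take the leading letter.
  nm <- sub("^[0-9]+", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE"), two, one)
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records via \code{bio3d::read.pdb}. Molecules are
#' inferred from chain identifiers and TER breaks. Duplicate atom serial
#' numbers are tolerated: atoms are re-indexed 0..N-1 with a warning.
#'
#' @param path PDB file path.
#' @return \code{"topology"} object.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  rec <- raw[startsWith(raw, "ATOM") | startsWith(raw, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  bad <- which(nchar(rec) < 54)
  if (length(bad))
    stop("malformed ATOM/HETATM record (too short) at record ", bad[1],
         ": ", rec[bad[1]])
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (anyDuplicated(at$eleno))
    warning("duplicate atom serial numbers in ", basename(path),
            "; atoms re-indexed 0..N-1")
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == ""))
    elem <- .elem_from_name(at$elety)
  elem <- ifelse(is.na(elem) | trimws(elem) == "",
                 .elem_from_name(at$elety), trimws(elem))
  atoms <- data.frame(
    name = trimws(at$elety), elem = toupper(elem),
    resno = at$resno, resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE)
  molno <- .infer_molecules(raw, nrow(atoms), atoms)
  topology(atoms, molno = molno)
}

# Molecules from chain id changes and TER records, in file order.
.infer_molecules <- function(lines, n_atoms, atoms) {
  is_at <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_ter <- startsWith(lines, "TER")
  keep <- is_at | is_ter
  kind <- ifelse(is_at[keep], "A", "T")
  mol <- integer(n_atoms)
  cur <- 1L
  ai <- 0L
  prev_chain <- NULL
  for (k in seq_along(kind)) {
    if (kind[k] == "T") {
      if (ai > 0L && ai < n_atoms) cur <- cur + 1L
      prev_chain <- NULL
    } else {
      ai <- ai + 1L
      if (ai > n_atoms) break
      ch <- atoms$chain[ai]
      if (!is.null(prev_chain) && !identical(ch, prev_chain)) cur <- cur + 1L
      mol[ai] <- cur
      prev_chain <- ch
    }
  }
  # renumber contiguously
  as.integer(factor(mol, levels = unique(mol)))
}
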