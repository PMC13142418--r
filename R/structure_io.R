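# Reading and writing molecular structures (PDB via bio3d, XYZ natively) and
# ligand selection by residue identity.

.atom_cols <- c("element", "x", "y", "z", "serial", "resname", "resseq",
                "chain", "altloc", "is_cap")

.as_atom_frame <- function(df) {
  if (!all(c("element", "x", "y", "z") %in% names(df))) {
    stop("atom table needs at least element, x, y, z columns")
  }
  n <- nrow(df)
  if (is.null(df$serial)) df$serial <- seq_len(n)
  if (is.null(df$resname)) df$resname <- ""
  if (is.null(df$resseq)) df$resseq <- NA_integer_
  if (is.null(df$chain)) df$chain <- ""
  if (is.null(df$altloc)) df$altloc <- ""
  if (is.null(df$is_cap)) df$is_cap <- FALSE
  df$chain[is.na(df$chain)] <- ""
  df$resname[is.na(df$resname)] <- ""
  df$altloc[is.na(df$altloc)] <- ""
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite atom coordinates")
  }
  atomic_number(df$element)  # errors on unknown symbols
  rownames(df) <- NULL
  df[, .atom_cols]
}

#' Construct a molecular system
#'
#' A molecular system bundles an ordered atom table with its total charge.
#' The electron count follows from `sum(Z) - total_charge`.
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` (Angstrom)
#'   and optionally `serial`, `resname`, `resseq`, `chain`, `altloc`,
#'   `is_cap`.
#' @param total_charge integer total charge in elementary charges, or `NA`
#'   if not yet assigned (e.g. straight after carving).
#' @param label free-text label carried through to outputs.
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, total_charge = 0L, label = "") {
  atoms <- .as_atom_frame(atoms)
  n_el <- if (is.na(total_charge)) NA_integer_ else {
    as.integer(sum(atomic_number(atoms$element)) - total_charge)
  }
  if (!is.na(n_el) && n_el < 0) stop("negative electron count")
  structure(list(atoms = atoms, total_charge = total_charge,
                 n_electrons = n_el, label = label),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system '%s': %d atoms, charge %s, %s electrons\n",
              x$label, nrow(x$atoms),
              ifelse(is.na(x$total_charge), "unset", x$total_charge),
              ifelse(is.na(x$n_electrons), "?", x$n_electrons)))
  invisible(x)
}

# altLoc policy: within each (chain, resseq, resname, atom-name) group keep
# the highest-occupancy conformer; ties resolved in favour of blank/'A', then
# alphabetically.
.resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(rep(TRUE, nrow(at)))
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) == 1) next
    rank <- order(-occ[idx], alt[idx] != "", alt[idx])
    keep[idx[-rank[1]]] <- FALSE
  }
  keep
}

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records (CONECT records are ignored; bonds are inferred
#' geometrically downstream).  Elements are taken from the element column
#' when present and otherwise inferred from the atom name, checking two-letter
#' symbols (FE, CL, ...) before one-letter ones.  For alternate locations only
#' the highest-occupancy conformer is kept (ties: blank/'A' first).
#'
#' @param path path to a PDB file containing ATOM/HETATM records.
#' @return atom data frame (one row per accepted record) with columns
#'   `element`, `x`, `y`, `z`, `serial`, `resname`, `resseq`, `chain`,
#'   `altloc`, `is_cap`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  at <- at[.resolve_altloc(at), , drop = FALSE]
  el <- .normalize_element(at$elesy)
  fallback <- is.na(el)
  if (any(fallback)) {
    # atom-name heuristic: strip digits/primes, try the two-letter symbol first
    nm <- gsub("[^A-Za-z]", "", at$elety[fallback])
    two <- .normalize_element(substr(nm, 1, 2))
    one <- .normalize_element(substr(nm, 1, 1))
    el[fallback] <- ifelse(!is.na(two), two, one)
  }
  if (anyNA(el)) {
    bad <- unique(at$elety[is.na(el)])
    stop("cannot infer element for atom name(s): ", paste(bad, collapse = ", "))
  }
  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      serial = at$eleno, resname = at$resid,
                      resseq = at$resno, chain = at$chain,
                      altloc = ifelse(is.na(at$alt), "", at$alt),
                      is_cap = !is.na(at$resid) & at$resid == "CAP",
                      stringsAsFactors = FALSE)
  atoms <- .as_atom_frame(atoms)
  if (!any(atoms$element == "H")) {
    warning("no hydrogen atoms in '", path,
            "': expected a protonated structure (hydrogens are added externally)")
  }
  atoms
}

#' Write a system (or atom table) to a PDB file
#'
#' Cap hydrogens introduced by carving are written with residue name `CAP`
#' so that they remain identifiable after a round trip.
#'
#' @param system a [molecular_system()] or atom data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  atoms <- if (inherits(system, "molecular_system")) system$atoms else
    .as_atom_frame(system)
  resname <- ifelse(atoms$is_cap, "CAP", atoms$resname)
  resname[resname == ""] <- "UNK"
  resseq <- atoms$resseq
  resseq[is.na(resseq)] <- 0L
  chain <- atoms$chain
  chain[chain == ""] <- " "
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(atoms)),
                   eleno = atoms$serial, elety = atoms$element,
                   resid = resname, resno = resseq, chain = chain,
                   elesy = atoms$element,
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))
  invisible(path)
}

#' Read an XYZ geometry file
#'
#' @param path path to an XYZ file (atom count, comment line, then
#'   `element x y z` in Angstrom).
#' @return atom data frame as in [read_pdb()].
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 1) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(ln[1])))
  if (is.na(n)) stop("malformed XYZ header (atom count) in ", path)
  body <- ln[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop("XYZ declares ", n, " atoms but lists ", length(body))
  }
  body <- body[seq_len(n)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  if (any(vapply(parts, length, integer(1)) < 4)) {
    stop("malformed XYZ coordinate line in ", path)
  }
  el <- .normalize_element(vapply(parts, `[[`, character(1), 1))
  if (anyNA(el)) stop("unrecognized element symbol in ", path)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  .as_atom_frame(data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE))
}

#' Write atoms to an XYZ geometry file
#'
#' @param atoms a [molecular_system()] or atom data frame.
#' @param path output file path.
#' @param comment comment for the second line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  at <- if (inherits(atoms, "molecular_system")) atoms$atoms else
    .as_atom_frame(atoms)
  lines <- c(nrow(at), comment,
             sprintf("%-2s %14.6f %14.6f %14.6f", at$element, at$x, at$y, at$z))
  writeLines(lines, path)
  invisible(path)
}

#' Select ligand atoms by residue name
#'
#' Returns the indices of all atoms whose residue name is in `residue_names`
#' (optionally restricted to given chains), plus any hydrogens bonded to
#' them.
#'
#' @param atoms atom data frame.
#' @param residue_names character vector of residue codes, e.g. `"FAD"`.
#' @param chain optional chain identifier(s) to disambiguate multiple copies.
#' @param spec an [environment_spec()] providing the bond-detection scale
#'   used for attaching hydrogens.
#' @return sorted integer vector of atom indices.
#' @export
select_ligand <- function(atoms, residue_names, chain = NULL,
                          spec = environment_spec(cutoff = 0)) {
  atoms <- if (inherits(atoms, "molecular_system")) atoms$atoms else
    .as_atom_frame(atoms)
  sel <- atoms$resname %in% residue_names
  if (!is.null(chain)) sel <- sel & atoms$chain %in% chain
  idx <- which(sel)
  if (length(idx) == 0) {
    stop("no atoms with residue name(s) ",
         paste(residue_names, collapse = ", "),
         if (!is.null(chain)) paste0(" in chain(s) ", paste(chain, collapse = ", ")))
  }
  if (length(idx) < nrow(atoms)) {
    bonds <- detect_bonds(atoms, spec = spec)
    hyd <- atoms$element == "H"
    h_in <- c(bonds$i[hyd[bonds$i] & bonds$j %in% idx],
              bonds$j[hyd[bonds$j] & bonds$i %in% idx])
    idx <- union(idx, h_in)
  }
  sort(unique(idx))
}
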