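# Quantum-region construction: ligand plus all atoms within a distance
# cutoff, grown over the inferred bond graph until only carbon-carbon single
# bonds cross the boundary, then capped with hydrogens.

#' Parameters controlling carving and bond detection
#'
#' @param cutoff environment radius in Angstrom around the ligand; `0` keeps
#'   the ligand only.
#' @param cap_bond_length C-H bond length (Angstrom) used for cap hydrogens.
#' @param bond_detect_scale dimensionless factor applied to the sum of
#'   covalent radii; pairs closer than the scaled sum are bonded.
#' @param cc_single_min minimum length (Angstrom) for a C-C bond to count as
#'   a single bond; shorter C-C contacts (aromatic/double, ~1.34-1.40) are
#'   never cut.
#' @return a list of class `environment_spec`.
#' @export
environment_spec <- function(cutoff = 0, cap_bond_length = 1.09,
                             bond_detect_scale = 1.3, cc_single_min = 1.45) {
  stopifnot(cutoff >= 0, bond_detect_scale > 0, cc_single_min > 0)
  if (cap_bond_length <= 0.8 || cap_bond_length >= 1.3) {
    stop("cap_bond_length must lie in (0.8, 1.3) Angstrom")
  }
  structure(list(cutoff = cutoff, cap_bond_length = cap_bond_length,
                 bond_detect_scale = bond_detect_scale,
                 cc_single_min = cc_single_min),
            class = "environment_spec")
}

#' Detect bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' `bond_detect_scale * (r_cov(i) + r_cov(j))`.  A bond is classified
#' `single_CC` when both atoms are carbon and its length is at least
#' `cc_single_min`; all other bonds are `other` and are never cut.
#'
#' @param atoms atom data frame or [molecular_system()] (at least 2 atoms).
#' @param spec an [environment_spec()].
#' @return data frame with columns `i`, `j` (`i < j`), `length` (Angstrom)
#'   and `character` (`"single_CC"` or `"other"`).
#' @export
detect_bonds <- function(atoms, spec = environment_spec()) {
  atoms <- if (inherits(atoms, "molecular_system")) atoms$atoms else
    .as_atom_frame(atoms)
  n <- nrow(atoms)
  if (n < 2) {
    return(data.frame(i = integer(0), j = integer(0), length = numeric(0),
                      character = character(0), stringsAsFactors = FALSE))
  }
  d <- as.matrix(dist(as.matrix(atoms[, c("x", "y", "z")])))
  ut <- upper.tri(d)
  if (any(d[ut] < 0.4)) {
    w <- which(ut & d < 0.4, arr.ind = TRUE)[1, ]
    stop(sprintf("atoms %d and %d are %.3f Angstrom apart (clash)",
                 w[1], w[2], d[w[1], w[2]]))
  }
  rc <- covalent_radius(atoms$element)
  thr <- spec$bond_detect_scale * outer(rc, rc, `+`)
  hit <- which(ut & d <= thr, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(i = integer(0), j = integer(0), length = numeric(0),
                      character = character(0), stringsAsFactors = FALSE))
  }
  i <- pmin(hit[, 1], hit[, 2]); j <- pmax(hit[, 1], hit[, 2])
  len <- d[hit]
  cc <- atoms$element[i] == "C" & atoms$element[j] == "C"
  chr <- ifelse(cc & len >= spec$cc_single_min, "single_CC", "other")
  out <- data.frame(i = i, j = j, length = len, character = chr,
                    stringsAsFactors = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Carve a quantum region around a ligand
#'
#' The seed region is the ligand plus every atom within `spec$cutoff` of any
#' ligand atom (hydrogens included).  The region is then grown over the bond
#' graph: as long as any bond crossing the boundary is not a carbon-carbon
#' single bond, the outside atom is pulled in.  Each remaining boundary C-C
#' single bond is cut and the outside carbon replaced by a hydrogen placed on
#' the original bond vector at `spec$cap_bond_length`.
#'
#' The returned system has its total charge unset; charge assignment is a
#' separate step (see [select_charge()]).
#'
#' @param atoms atom data frame or [molecular_system()] of the full structure.
#' @param ligand_indices indices of the ligand atoms (see [select_ligand()]).
#' @param spec an [environment_spec()].
#' @return a [molecular_system()] with `total_charge = NA`; cap hydrogens are
#'   flagged `is_cap` and carry residue name `CAP`.
#' @export
carve <- function(atoms, ligand_indices, spec = environment_spec()) {
  atoms <- if (inherits(atoms, "molecular_system")) atoms$atoms else
    .as_atom_frame(atoms)
  n <- nrow(atoms)
  if (length(ligand_indices) == 0) stop("empty ligand selection")
  if (any(ligand_indices < 1 | ligand_indices > n)) {
    stop("ligand atom index outside the structure")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  inside <- rep(FALSE, n)
  inside[ligand_indices] <- TRUE
  if (spec$cutoff > 0) {
    lig <- xyz[ligand_indices, , drop = FALSE]
    for (a in which(!inside)) {
      d2 <- min(colSums((t(lig) - xyz[a, ])^2))
      if (d2 <= spec$cutoff^2) inside[a] <- TRUE
    }
  }
  bonds <- detect_bonds(atoms, spec = spec)
  repeat {
    boundary <- xor(inside[bonds$i], inside[bonds$j])
    bad <- boundary & bonds$character != "single_CC"
    if (!any(bad)) break
    out_end <- ifelse(inside[bonds$i[bad]], bonds$j[bad], bonds$i[bad])
    inside[out_end] <- TRUE
  }
  if (all(inside)) {
    if (n > length(ligand_indices)) {
      warning("environment growth consumed the entire structure; ",
              "returning it uncut")
    }
    kept <- atoms
    return(molecular_system(kept, total_charge = NA, label = "carved"))
  }
  boundary <- which(xor(inside[bonds$i], inside[bonds$j]))
  caps <- NULL
  if (length(boundary) > 0) {
    b_in <- ifelse(inside[bonds$i[boundary]], bonds$i[boundary],
                   bonds$j[boundary])
    b_out <- ifelse(inside[bonds$i[boundary]], bonds$j[boundary],
                    bonds$i[boundary])
    # canonical cap order, independent of input atom ordering
    ord <- order(xyz[b_in, 1], xyz[b_in, 2], xyz[b_in, 3],
                 xyz[b_out, 1], xyz[b_out, 2], xyz[b_out, 3])
    b_in <- b_in[ord]; b_out <- b_out[ord]
    vec <- xyz[b_out, , drop = FALSE] - xyz[b_in, , drop = FALSE]
    vec <- vec / sqrt(rowSums(vec^2))
    pos <- xyz[b_in, , drop = FALSE] + spec$cap_bond_length * vec
    caps <- data.frame(element = "H", x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       serial = max(atoms$serial) + seq_along(b_in),
                       resname = "CAP", resseq = NA_integer_, chain = "",
                       altloc = "", is_cap = TRUE, stringsAsFactors = FALSE)
  }
  kept <- atoms[inside, , drop = FALSE]
  out <- rbind(kept, caps)
  molecular_system(out, total_charge = NA, label = "carved")
}
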