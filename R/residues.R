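# Residue classification: acidic carboxylates, basic nitrogens, aromatic
# rings.  Defaults follow standard PDB naming; overrides let callers
# register non-protein rings (imidazolium cations, the NAD+ nicotinamide)
# or adjust protonation-dependent membership.

.ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_N  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"), HIE = c("ND1", "NE2"),
                  HID = c("ND1", "NE2"), HIP = c("ND1", "NE2"))
.RINGS <- list(
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIE = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HID = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIP = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))

.class_entries <- function(atoms, name_map) {
  uid <- .res_uid(atoms)
  out <- list()
  for (u in unique(uid)) {
    rows <- which(uid == u)
    rname <- atoms$residue_name[rows[1]]
    if (!rname %in% names(name_map)) next
    idx <- rows[atoms$atom_name[rows] %in% name_map[[rname]]]
    if (!length(idx)) next
    out[[u]] <- list(uid = u, residue_id = atoms$residue_id[rows[1]],
                     residue_name = rname, chain_id = atoms$chain_id[rows[1]],
                     atom_idx = idx)
  }
  out
}

.ring_entries <- function(atoms, ring_map) {
  uid <- .res_uid(atoms)
  out <- list()
  for (u in unique(uid)) {
    rows <- which(uid == u)
    rname <- atoms$residue_name[rows[1]]
    if (!rname %in% names(ring_map)) next
    want <- ring_map[[rname]]
    idx <- rows[match(want, atoms$atom_name[rows])]
    if (anyNA(idx)) next  # incomplete ring: skip rather than guess
    out[[u]] <- list(uid = u, residue_id = atoms$residue_id[rows[1]],
                     residue_name = rname, chain_id = atoms$chain_id[rows[1]],
                     atom_idx = idx)
  }
  out
}

#' Classify residues into acidic / basic / aromatic sets
#'
#' Acidic residues are Asp and Glu, represented by their carboxylate
#' oxygens (OD1/OD2, OE1/OE2); basic residues are Lys (NZ), Arg
#' (NE/NH1/NH2) and His (ND1/NE2; the simulated systems were protonated at
#' pH 10 via an external tool whose per-residue tautomer assignment is not
#' recorded, so His membership is overridable).  Aromatic rings are
#' registered with ordered atom lists: the Trp indole (9 atoms), His
#' imidazole (5), Phe/Tyr phenyl (6).
#'
#' @param topology a [new_topology()] object.
#' @param overrides optional data.frame with columns `residue_name`, `role`
#'   (`"acidic"`, `"basic"`, `"aromatic"`) and `atom_names` (comma-separated);
#'   entries extend or replace the defaults for that residue name, e.g.
#'   registering a 5-atom imidazolium ring for an ionic-liquid cation.
#' @param his_basic logical: count His as basic (default TRUE).
#' @return object of class `ResidueClasses` with `acidic`, `basic`,
#'   `aromatic` entry lists (each entry: uid, residue_id, residue_name,
#'   chain_id, atom_idx).
#' @export
classify_residues <- function(topology, overrides = NULL, his_basic = TRUE) {
  atoms <- topology$atoms
  acid_map <- .ACIDIC_O
  base_map <- .BASIC_N
  ring_map <- .RINGS
  if (!his_basic)
    base_map <- base_map[!names(base_map) %in% c("HIS", "HIE", "HID", "HIP")]
  if (!is.null(overrides)) {
    stopifnot(all(c("residue_name", "role", "atom_names") %in%
                  names(overrides)))
    for (i in seq_len(nrow(overrides))) {
      rn <- overrides$residue_name[i]
      anames <- trimws(strsplit(overrides$atom_names[i], ",")[[1]])
      present <- atoms$atom_name[atoms$residue_name == rn]
      if (!length(present))
        stop("override names residue '", rn, "' absent from topology")
      unknown <- setdiff(anames, present)
      if (length(unknown))
        stop("override for ", rn, " names unknown atom(s): ",
             paste(unknown, collapse = ", "))
      switch(overrides$role[i],
        acidic   = acid_map[[rn]] <- anames,
        basic    = base_map[[rn]] <- anames,
        aromatic = {
          if (length(anames) < 5L)
            stop("aromatic ring for ", rn, " must have >= 5 atoms")
          ring_map[[rn]] <- anames
        },
        stop("unknown override role: ", overrides$role[i]))
    }
  }
  structure(list(acidic = .class_entries(atoms, acid_map),
                 basic = .class_entries(atoms, base_map),
                 aromatic = .ring_entries(atoms, ring_map)),
            class = "ResidueClasses")
}

#' @export
print.ResidueClasses <- function(x, ...) {
  cat("ResidueClasses:", length(x$acidic), "acidic,", length(x$basic),
      "basic,", length(x$aromatic), "aromatic ring(s)\n")
  invisible(x)
}
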