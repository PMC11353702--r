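# Topology container and PDB structure input.

#' Construct a Topology
#'
#' @param atoms data.frame with columns `atom_id` (0-based, contiguous),
#'   `atom_name`, `element`, `residue_id` (author-visible residue number),
#'   `residue_name`, `chain_id`.
#' @param box_hint optional length-3 orthorhombic box lengths (Angstrom),
#'   e.g. from a CRYST1 record.
#' @return object of class `Topology`.
#' @export
new_topology <- function(atoms, box_hint = NULL) {
  req <- c("atom_id", "atom_name", "element", "residue_id", "residue_name",
           "chain_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("Topology atoms table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms[, req], stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0L) stop("Topology must contain at least one atom")
  if (anyDuplicated(atoms$atom_id) || !identical(sort(atoms$atom_id),
                                                 0:(n - 1L)))
    stop("atom_id must be unique and contiguous from 0")
  if (!is.null(box_hint)) {
    box_hint <- as.numeric(box_hint)
    stopifnot(length(box_hint) == 3L, all(box_hint > 0))
  }
  structure(list(atoms = atoms, box_hint = box_hint, n_atoms = n),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_id))),
      "residues,", length(unique(x$atoms$chain_id)), "chain(s)\n")
  if (!is.null(x$box_hint))
    cat("  box hint:", paste(format(x$box_hint), collapse = " x "), "A\n")
  invisible(x)
}

# CRYST1 is not surfaced by bio3d; one fixed-width record, parsed directly.
.parse_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  f <- cl[1]
  lens <- suppressWarnings(as.numeric(c(substr(f, 7, 15), substr(f, 16, 24),
                                        substr(f, 25, 33))))
  angs <- suppressWarnings(as.numeric(c(substr(f, 34, 40), substr(f, 41, 47),
                                        substr(f, 48, 54))))
  if (any(is.na(lens))) stop("malformed CRYST1 record: ", f)
  if (!all(is.na(angs)) && any(abs(angs - 90) > 1e-3))
    stop("triclinic boxes are not supported (CRYST1 angles must be 90)")
  lens
}

#' Read a PDB structure into a Topology
#'
#' ATOM/HETATM records are parsed (via bio3d) into the atoms table; the
#' author-visible residue numbering is preserved as `residue_id` while
#' atom indices are re-based to a contiguous 0-based `atom_id`.  A CRYST1
#' record, when present, populates `box_hint`; only orthorhombic cells are
#' accepted.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is supported here.
#' @return a [new_topology()] object.
#' @export
read_topology <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (anyDuplicated(paste(at$eleno, ifelse(is.na(at$chain), "", at$chain))))
    stop("duplicate atom serial number in ", path)
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) |
                                                           elem == ""]), 1, 1)
  atoms <- data.frame(
    atom_id      = seq_len(nrow(at)) - 1L,
    atom_name    = trimws(at$elety),
    element      = trimws(elem),
    residue_id   = as.integer(at$resno),
    residue_name = trimws(at$resid),
    chain_id     = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE)
  new_topology(atoms, box_hint = .parse_cryst1(path))
}

# residue uid used as a stable key: chain + author residue number
.res_uid <- function(atoms) paste0(atoms$chain_id, ":", atoms$residue_id)
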