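# Residue-name dictionaries used to classify molecule type. Docked poses and
# crystal structures are heavy-atom PDB files; hydrogens are dropped on read.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.RNA3 <- c("A", "U", "G", "C", "RA", "RU", "RG", "RC", "ADE", "URA", "GUA",
           "CYT")
.SOLVENT <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN", "MN",
              "SO4", "PO4", "GOL", "EDO")

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records of a (fixed-column) PDB file into an atom
#' table. Waters and common ions/cryoprotectants are dropped; alternate
#' locations are resolved to the highest-occupancy copy; hydrogens are
#' excluded (all downstream distance rules are heavy-atom rules).
#'
#' @param path Path to a PDB file.
#' @param drop_hydrogens Drop H/D atoms (default TRUE).
#' @return `data.frame` with columns `atom_name`, `element`,
#'   `residue_index`, `residue_name`, `chain_id`, `x`, `y`, `z`,
#'   `molecule_class` (`"protein"`, `"rna"`, or `"other"`).
#' @export
read_structure <- function(path, drop_hydrogens = TRUE) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0L) stop("no ATOM/HETATM records in ", path)
  ln <- lines[sel]
  fw <- function(a, b) trimws(substr(ln, a, b))
  xyz <- suppressWarnings(cbind(as.numeric(substr(ln, 31, 38)),
                                as.numeric(substr(ln, 39, 46)),
                                as.numeric(substr(ln, 47, 54))))
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad) > 0L)
    stop("unparseable coordinates at line ", sel[bad[1L]], " of ", path)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    atom_name = fw(13, 16),
    altloc = fw(17, 17),
    residue_name = fw(18, 20),
    chain_id = fw(22, 22),
    residue_index = suppressWarnings(as.integer(fw(23, 26))),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    element = fw(77, 78),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$residue_index))
    stop("unparseable residue number at line ",
         sel[which(is.na(atoms$residue_index))[1L]], " of ", path)
  no_el <- atoms$element == ""
  atoms$element[no_el] <- substr(gsub("[0-9']", "", atoms$atom_name[no_el]), 1, 1)
  atoms <- atoms[!(atoms$residue_name %in% .SOLVENT), , drop = FALSE]
  if (drop_hydrogens)
    atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  # altloc: keep the highest-occupancy copy of each (chain, residue, atom)
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i)
      i[which.max(atoms$occupancy[i])]), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$molecule_class <- ifelse(atoms$residue_name %in% .AA3, "protein",
                          ifelse(atoms$residue_name %in% .RNA3, "rna", "other"))
  atoms$altloc <- NULL
  atoms$occupancy <- NULL
  rownames(atoms) <- NULL
  atoms
}

#' Write an atom table to a PDB file
#'
#' Inverse of [read_structure()] to PDB numeric precision (coordinates
#' rounded to 0.001 Angstrom). An optional per-atom `bfactor` vector is
#' written to the B-factor column, the conventional channel for painting
#' per-residue scores (e.g. contact frequencies) onto a structure.
#'
#' @param atoms Atom `data.frame` as returned by [read_structure()].
#' @param path Output file path.
#' @param bfactor Optional numeric vector (length 1 or `nrow(atoms)`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path, bfactor = 0) {
  bfactor <- rep_len(bfactor, nrow(atoms))
  name4 <- ifelse(nchar(atoms$atom_name) < 4L,
                  sprintf(" %-3s", atoms$atom_name),
                  substr(atoms$atom_name, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000L, name4, atoms$residue_name,
    atoms$chain_id, atoms$residue_index, atoms$x, atoms$y, atoms$z,
    1, bfactor, toupper(atoms$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
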