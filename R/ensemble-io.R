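#' Construct a ligand selection
#'
#' @param residueNames character vector of 3-letter residue codes naming the
#'   ligand (e.g. `"ADP"`, or a docking code such as `"LIG"`).
#' @param chain restrict the selection to one chain (default: any).
#' @param residueNumbers restrict to specific residue numbers (default: any).
#' @return a [LigandSpec-class]
#' @examples
#' ligandSpec("ADP")
#' @export
ligandSpec <- function(residueNames, chain = NA_character_,
                       residueNumbers = integer(0)) {
  new("LigandSpec",
      residueNames = toupper(as.character(residueNames)),
      chain = as.character(chain),
      residueNumbers = as.integer(residueNumbers))
}

#' Construct contact-counting parameters
#'
#' @param cutoff distance cutoff in Angstrom (default 4.5). Pairs strictly
#'   closer than the cutoff count as contacts; a pair at exactly the cutoff
#'   does not.
#' @param heavyOnly exclude hydrogen/deuterium atoms from counting.
#' @return a [ContactParams-class]
#' @export
contactParams <- function(cutoff = 4.5, heavyOnly = FALSE) {
  new("ContactParams", cutoff = as.numeric(cutoff),
      heavyOnly = isTRUE(heavyOnly), strictLessThan = TRUE)
}

#' Backbone classification of protein atom names
#'
#' Main-chain atoms are N, CA, C, O, the terminal OXT, and the hydrogens
#' attached to them (H, H1-H3 amine hydrogens, HA; HA2/HA3 for glycine,
#' which has two alpha hydrogens). Contacts through these atoms cannot be
#' removed by a side-chain substitution, which is why backbone-mediated
#' residues are excluded from mutation-site triage.
#'
#' @param atomName character vector of PDB atom names.
#' @param residueName character vector of 3-letter residue codes (recycled).
#' @return logical vector; unknown names are `FALSE`.
#' @examples
#' classifyBackbone(c("CA", "CB", "OXT"), "LEU")
#' @export
classifyBackbone <- function(atomName, residueName) {
  atomName <- toupper(trimws(atomName))
  residueName <- toupper(trimws(residueName))
  core <- atomName %in% c("N", "CA", "C", "O", "OXT",
                          "H", "H1", "H2", "H3", "HA")
  glyHA <- atomName %in% c("HA2", "HA3") &
    rep_len(residueName, length(atomName)) == "GLY"
  core | glyHA
}

# canonical residue key "chain:resno[insert]:resname"
residueKey <- function(chain, resno, insert, resname) {
  insert <- ifelse(is.na(insert) | insert == "", "", insert)
  sprintf("%s:%d%s:%s", chain, as.integer(resno), insert, toupper(resname))
}

# "Leu593"-style label from a 3-letter code and number
residueLabel <- function(resname, resno) {
  code <- toupper(resname)
  paste0(substr(code, 1, 1), tolower(substr(code, 2, 3)), resno)
}

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

# element from the PDB element column, falling back to the atom name
.atomElement <- function(elesy, elety) {
  el <- toupper(trimws(as.character(elesy)))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- gsub("[0-9']", "", toupper(elety[miss]))
    el[miss] <- substr(nm, 1L, 1L)
  }
  el
}

# bio3d atom data.frame (+ xyz) -> resolved topology + frame list
.buildEnsemble <- function(atom, xyz, ligand, heavyOnly, source) {
  stopifnot(is(ligand, "LigandSpec"))
  n <- nrow(atom)
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  insert <- ifelse(is.na(atom$insert), "", atom$insert)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  element <- .atomElement(atom$elesy, atom$elety)

  # alternate locations: keep highest occupancy, ties -> altLoc 'A'
  dupKey <- paste(atom$chain, atom$resno, insert, atom$resid, atom$elety,
                  sep = "\r")
  keep <- rep(TRUE, n)
  if (anyDuplicated(dupKey)) {
    pref <- order(dupKey, -occ, alt != "A", seq_len(n))
    first <- !duplicated(dupKey[pref])
    keep[pref] <- first
  }

  isLig <- toupper(atom$resid) %in% ligand@residueNames
  if (!is.na(ligand@chain))
    isLig <- isLig & atom$chain == ligand@chain
  if (length(ligand@residueNumbers))
    isLig <- isLig & atom$resno %in% ligand@residueNumbers
  if (!any(isLig & keep))
    stop("ligand selection matches no atoms in the topology")

  partition <- ifelse(isLig, "ligand",
                      ifelse(toupper(atom$resid) %in% .STANDARD_AA,
                             "protein", "other"))
  if (!any(partition == "protein" & keep))
    stop("topology contains no protein atoms")

  if (heavyOnly)
    keep <- keep & !(element %in% c("H", "D"))

  idx <- which(keep)
  topo <- data.frame(
    serial = as.integer(atom$eleno[idx]),
    name = atom$elety[idx],
    element = element[idx],
    altLoc = alt[idx],
    resname = toupper(atom$resid[idx]),
    chain = atom$chain[idx],
    resno = as.integer(atom$resno[idx]),
    insert = insert[idx],
    partition = partition[idx],
    stringsAsFactors = FALSE
  )
  topo$isBackbone <- topo$partition == "protein" &
    classifyBackbone(topo$name, topo$resname)

  xyz <- as.matrix(xyz)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  frames <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, cols], ncol = 3L, byrow = TRUE))
  new("StructureEnsemble", topology = topo, frames = frames, source = source)
}

#' Read a conformational ensemble from PDB
#'
#' Reads either a multi-model PDB file (MODEL/ENDMDL records) or a
#' directory of single-model PDB files (frame order = lexicographic file
#' order) into a [StructureEnsemble-class]. Atoms are partitioned into
#' protein (standard amino acids), ligand (atoms matching `ligand`) and
#' other (waters, ions, remaining heteroatoms). Alternate locations are
#' resolved to the highest-occupancy record, ties to altLoc `"A"`.
#' Ensembles are assumed imaged/whole: no periodic-boundary handling is
#' performed.
#'
#' @param path PDB file or directory of `.pdb` files with identical
#'   topology.
#' @param ligand a [LigandSpec-class]; must select at least one atom.
#' @param heavyOnly drop hydrogens (element H/D) from the topology. The
#'   default keeps every atom present in the file, so that all
#'   ligand-residue atom pairs participate in contact counting.
#' @return a [StructureEnsemble-class]
#' @export
readEnsemble <- function(path, ligand, heavyOnly = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files))
      stop("no .pdb files found in directory: ", path)
    pdbs <- lapply(files, function(f)
      bio3d::read.pdb(f, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
    ref <- pdbs[[1L]]$atom
    xyzs <- lapply(seq_along(pdbs), function(i) {
      a <- pdbs[[i]]$atom
      if (nrow(a) != nrow(ref) ||
          !identical(a$elety, ref$elety) || !identical(a$resno, ref$resno))
        stop("inconsistent topology across models: ", files[i])
      as.matrix(pdbs[[i]]$xyz)
    })
    atom <- ref
    xyz <- do.call(rbind, xyzs)
  } else if (file.exists(path)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    atom <- pdb$atom
    xyz <- as.matrix(pdb$xyz)
    if (ncol(xyz) != 3L * nrow(atom))
      stop("inconsistent atom count across models in ", path)
  } else {
    stop("no such file or directory: ", path)
  }
  .buildEnsemble(atom, xyz, ligand, heavyOnly, source = normalizePath(path))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at the standard PDB precision (3 decimals,
#' Angstrom); a written ensemble re-read with [readEnsemble()] reproduces
#' topology and coordinates exactly at that precision. Protein atoms are
#' written as ATOM records, everything else as HETATM.
#'
#' @param ensemble a [StructureEnsemble-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  top <- ensemble@topology
  recname <- ifelse(top$partition == "protein", "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(top$name) >= 4L, substr(top$name, 1L, 4L),
                  sprintf(" %-3s", top$name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(ensemble@frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble@frames[[f]]
    writeLines(sprintf(
      "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      recname, top$serial %% 100000L, name4,
      ifelse(top$altLoc == "", " ", top$altLoc),
      top$resname, top$chain, top$resno %% 10000L,
      ifelse(top$insert == "", " ", top$insert),
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
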