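# In-code fixtures and independent brute-force oracles. The oracles use
# plain double loops and no package internals, so they stay independent
# of the implementation paths they check.

# build a StructureEnsemble directly from coordinates
makeEnsemble <- function(frames, names, resnames, resnos, partitions,
                         chain = "A", elements = NULL) {
  n <- length(names)
  if (is.null(elements))
    elements <- substr(gsub("[0-9]", "", names), 1, 1)
  topo <- data.frame(
    serial = seq_len(n), name = names, element = elements, altLoc = "",
    resname = resnames, chain = chain, resno = as.integer(resnos),
    insert = "", partition = partitions, stringsAsFactors = FALSE)
  topo$isBackbone <- topo$partition == "protein" &
    classifyBackbone(topo$name, topo$resname)
  new("StructureEnsemble", topology = topo, frames = frames,
      source = "test")
}

# a one-residue + one-ligand-atom ensemble with given protein coordinates
miniEnsemble <- function(protXyz, ligXyz = c(0, 0, 0), nframes = 1,
                         protNames = NULL) {
  protXyz <- rbind(protXyz)
  np <- nrow(protXyz)
  if (is.null(protNames))
    protNames <- c("CB", "CG", "CD1", "CD2", "CE", "CZ")[seq_len(np)]
  xyz <- rbind(matrix(ligXyz, ncol = 3), protXyz)
  makeEnsemble(rep(list(xyz), nframes),
               names = c("C1", protNames),
               resnames = c("LIG", rep("LEU", np)),
               resnos = c(900L, rep(1L, np)),
               partitions = c("ligand", rep("protein", np)))
}

# exhaustive double-loop contact oracle over one frame
bruteContacts <- function(xyz, ligIdx, protIdx, cutoff) {
  hits <- NULL
  for (i in ligIdx) {
    for (j in protIdx) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < cutoff) hits <- rbind(hits, c(i, j, d))
    }
  }
  if (is.null(hits)) hits <- matrix(numeric(0), ncol = 3)
  colnames(hits) <- c("lig", "prot", "d")
  hits
}

# per-residue total/backbone counts over all frames via the brute oracle
bruteProfile <- function(ensemble, cutoff) {
  top <- topology(ensemble)
  ligIdx <- which(top$partition == "ligand")
  protIdx <- which(top$partition == "protein")
  key <- paste(top$chain, top$resno, top$insert, top$resname)
  out <- list()
  for (f in seq_len(nFrames(ensemble))) {
    hits <- bruteContacts(frameCoords(ensemble, f), ligIdx, protIdx, cutoff)
    seen <- character(0)
    if (nrow(hits)) {
      for (r in seq_len(nrow(hits))) {
        k <- key[hits[r, "prot"]]
        if (is.null(out[[k]]))
          out[[k]] <- c(total = 0, backbone = 0, frames = 0)
        out[[k]]["total"] <- out[[k]]["total"] + 1
        if (top$isBackbone[hits[r, "prot"]])
          out[[k]]["backbone"] <- out[[k]]["backbone"] + 1
        if (!k %in% seen) {
          out[[k]]["frames"] <- out[[k]]["frames"] + 1
          seen <- c(seen, k)
        }
      }
    }
  }
  out
}

# random frame of ligand + protein atoms uniform in a box
randomFrameEnsemble <- function(nLig, nProt, nframes = 1, box = 25,
                                seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(nframes), function(f)
    matrix(runif((nLig + nProt) * 3, 0, box), ncol = 3))
  protRes <- rep(seq_len(ceiling(nProt / 3)), each = 3)[seq_len(nProt)]
  makeEnsemble(frames,
               names = c(paste0("C", seq_len(nLig)),
                         rep(c("CA", "CB", "CG"), length.out = nProt)),
               resnames = c(rep("LIG", nLig), rep("VAL", nProt)),
               resnos = c(rep(900L, nLig), protRes),
               partitions = c(rep("ligand", nLig), rep("protein", nProt)))
}

profRow <- function(profile, resno) {
  tab <- contactTable(profile)
  tab[tab$resno == resno, , drop = FALSE]
}

extdataPaths <- function() {
  dir <- system.file("extdata", package = "gatekeepR")
  c(fixture = file.path(dir, "mertk_worked_example.tsv"),
    msa = file.path(dir, "tam_family_synthetic.fasta"),
    numbering = file.path(dir, "tam_family_numbering.tsv"),
    annotations = file.path(dir, "mertk_critical_residues.tsv"))
}
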