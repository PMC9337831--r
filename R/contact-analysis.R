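# ligand/protein atom index pairs strictly closer than cutoff, in
# (ligand index, protein index) ascending order
.contactPairs <- function(xyz, ligIdx, protIdx, cutoff) {
  cut2 <- cutoff^2
  prot <- xyz[protIdx, , drop = FALSE]
  out <- vector("list", length(ligIdx))
  for (k in seq_along(ligIdx)) {
    d2 <- (prot[, 1L] - xyz[ligIdx[k], 1L])^2 +
          (prot[, 2L] - xyz[ligIdx[k], 2L])^2 +
          (prot[, 3L] - xyz[ligIdx[k], 3L])^2
    hit <- which(d2 < cut2)
    if (length(hit))
      out[[k]] <- cbind(lig = rep.int(ligIdx[k], length(hit)),
                        prot = protIdx[hit], d2 = d2[hit])
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- cbind(lig = integer(0), prot = integer(0), d2 = numeric(0))
  pairs
}

# atom indices eligible for contact counting under the params
.countingIndices <- function(topology, params) {
  elig <- rep(TRUE, nrow(topology))
  if (params@heavyOnly)
    elig <- !(topology$element %in% c("H", "D"))
  list(lig = which(topology$partition == "ligand" & elig),
       prot = which(topology$partition == "protein" & elig))
}

#' Enumerate ligand-protein close contacts in one frame
#'
#' A close contact is a ligand-atom/protein-atom pair with Euclidean
#' distance strictly below `cutoff`: a pair at exactly the cutoff is not
#' counted. Pairs are returned in deterministic order (ligand atom index,
#' then protein atom index, ascending).
#'
#' @param ensemble a [StructureEnsemble-class] with at least one ligand and
#'   one protein atom.
#' @param frame frame index (default 1).
#' @param params a [ContactParams-class].
#' @return data.frame with columns `ligandAtom`, `proteinAtom` (topology
#'   row indices) and `distance` (Angstrom).
#' @export
enumerateContacts <- function(ensemble, frame = 1L, params = contactParams()) {
  stopifnot(is(ensemble, "StructureEnsemble"), is(params, "ContactParams"))
  idx <- .countingIndices(ensemble@topology, params)
  if (!length(idx$lig) || !length(idx$prot))
    stop("frame must contain at least one ligand and one protein atom ",
         "after applying the counting parameters")
  pairs <- .contactPairs(frameCoords(ensemble, frame), idx$lig, idx$prot,
                         params@cutoff)
  data.frame(ligandAtom = as.integer(pairs[, "lig"]),
             proteinAtom = as.integer(pairs[, "prot"]),
             distance = sqrt(pairs[, "d2"]))
}

#' Per-residue contact profile of an ensemble
#'
#' Counts all ligand-residue atom pairs closer than the cutoff in every
#' frame and aggregates them by protein residue. The contact unit is the
#' atom-pair-per-frame: a pair present in k frames contributes k. The
#' backbone/side-chain split follows [classifyBackbone()]. Residues with
#' zero contacts over the whole ensemble are omitted.
#'
#' @param ensemble a [StructureEnsemble-class]
#' @param params a [ContactParams-class]; the default carries the 4.5 A
#'   cutoff into the profile metadata.
#' @return a [ResidueContactProfile-class]
#' @export
residueContactProfile <- function(ensemble, params = contactParams()) {
  stopifnot(is(ensemble, "StructureEnsemble"), is(params, "ContactParams"))
  top <- ensemble@topology
  idx <- .countingIndices(top, params)
  if (!length(idx$lig) || !length(idx$prot))
    stop("ensemble must contain at least one ligand and one protein atom ",
         "after applying the counting parameters")

  key <- residueKey(top$chain, top$resno, top$insert, top$resname)
  protKeys <- unique(key[top$partition == "protein"])
  resOfAtom <- match(key, protKeys)            # NA for non-protein atoms
  nRes <- length(protKeys)
  nF <- length(ensemble@frames)

  total <- backbone <- numeric(nRes)
  framesWith <- integer(nRes)
  cut <- params@cutoff
  for (f in seq_len(nF)) {
    pairs <- .contactPairs(ensemble@frames[[f]], idx$lig, idx$prot, cut)
    if (!nrow(pairs)) next
    r <- resOfAtom[pairs[, "prot"]]
    total <- total + tabulate(r, nRes)
    bb <- top$isBackbone[pairs[, "prot"]]
    if (any(bb)) backbone <- backbone + tabulate(r[bb], nRes)
    framesWith <- framesWith + (tabulate(r, nRes) > 0L)
  }

  hit <- which(total > 0)
  firstAtom <- match(protKeys[hit], key)
  tab <- data.frame(
    chain = top$chain[firstAtom],
    resno = top$resno[firstAtom],
    insert = top$insert[firstAtom],
    resname = top$resname[firstAtom],
    total = as.integer(total[hit]),
    backbone = as.integer(backbone[hit]),
    sidechain = as.integer(total[hit] - backbone[hit]),
    framesWithContact = framesWith[hit],
    meanPerFrame = total[hit] / nF,
    stringsAsFactors = FALSE
  )
  new("ResidueContactProfile", table = tab, nFrames = as.integer(nF),
      params = params, source = ensemble@source)
}

.sameParams <- function(a, b) {
  isTRUE(all.equal(a@cutoff, b@cutoff)) &&
    identical(a@heavyOnly, b@heavyOnly) &&
    identical(a@strictLessThan, b@strictLessThan)
}

#' Inhibitor-versus-natural-ligand differential contact table
#'
#' Compares two per-residue profiles on the per-frame scale (mean contacts
#' per frame), which normalizes unequal frame counts between ensembles.
#' The residue set is the union of both profiles; a residue absent from one
#' side contributes 0 for that side. The backbone fraction is taken from
#' the inhibitor profile (backbone / total contacts; 0 when the residue
#' never contacts the inhibitor).
#'
#' @param inhibitor profile of the inhibitor-bound ensemble.
#' @param natural profile of the nucleotide-bound ensemble. Both profiles
#'   must have been computed with identical [ContactParams-class].
#' @return a [DifferentialContactTable-class]
#' @export
differentialProfile <- function(inhibitor, natural) {
  stopifnot(is(inhibitor, "ResidueContactProfile"),
            is(natural, "ResidueContactProfile"))
  if (!.sameParams(inhibitor@params, natural@params))
    stop("profiles were computed with different contact parameters")

  ti <- inhibitor@table
  tn <- natural@table
  ki <- residueKey(ti$chain, ti$resno, ti$insert, ti$resname)
  kn <- residueKey(tn$chain, tn$resno, tn$insert, tn$resname)
  keys <- unique(c(ki, kn))
  ii <- match(keys, ki)
  ni <- match(keys, kn)

  pick <- function(tab, idx, col, default = 0) {
    v <- rep(default, length(idx))
    ok <- !is.na(idx)
    v[ok] <- tab[[col]][idx[ok]]
    v
  }
  chain <- ifelse(is.na(ii), pick(tn, ni, "chain", NA), pick(ti, ii, "chain", NA))
  resno <- ifelse(is.na(ii), pick(tn, ni, "resno", NA), pick(ti, ii, "resno", NA))
  insert <- ifelse(is.na(ii), pick(tn, ni, "insert", NA), pick(ti, ii, "insert", NA))
  resname <- ifelse(is.na(ii), pick(tn, ni, "resname", NA), pick(ti, ii, "resname", NA))

  inhMean <- pick(ti, ii, "meanPerFrame")
  natMean <- pick(tn, ni, "meanPerFrame")
  inhTot <- pick(ti, ii, "total")
  inhBb <- pick(ti, ii, "backbone")
  bf <- ifelse(inhTot > 0, inhBb / inhTot, 0)

  tab <- data.frame(chain = chain, resno = as.integer(resno),
                    insert = insert, resname = resname,
                    inhibitorMean = inhMean, naturalMean = natMean,
                    delta = inhMean - natMean,
                    inhibitorBackboneFraction = bf,
                    stringsAsFactors = FALSE)
  new("DifferentialContactTable", table = tab, params = inhibitor@params)
}

#' Write a per-residue profile or differential table as TSV
#'
#' @param x a [ResidueContactProfile-class] or
#'   [DifferentialContactTable-class]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeContactTSV <- function(x, path) {
  tab <- contactTable(x)
  if (is(x, "ResidueContactProfile")) {
    out <- data.frame(chain = tab$chain, resnum = tab$resno,
                      icode = tab$insert, resname = tab$resname,
                      total = tab$total, backbone = tab$backbone,
                      sidechain = tab$sidechain,
                      frames_with_contact = tab$framesWithContact,
                      n_frames = x@nFrames,
                      mean_per_frame = tab$meanPerFrame)
  } else {
    out <- data.frame(chain = tab$chain, resnum = tab$resno,
                      icode = tab$insert, resname = tab$resname,
                      inhibitor_mean = tab$inhibitorMean,
                      natural_mean = tab$naturalMean, delta = tab$delta,
                      inhibitor_backbone_fraction =
                        tab$inhibitorBackboneFraction)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
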