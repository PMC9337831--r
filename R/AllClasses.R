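#' @import methods
NULL

.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common protonation/termination variants seen in MD-derived PDBs
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "ASH", "GLH", "LYN"
)

.TOPOLOGY_COLS <- c(
  "serial", "name", "element", "altLoc", "resname", "chain",
  "resno", "insert", "partition", "isBackbone"
)

#' Ligand selection specification
#'
#' Selects the ligand atoms of a topology by residue name, optionally
#' restricted to a chain and/or specific residue numbers. Selection is by
#' residue, never by atom name, so that the full ligand is captured.
#'
#' @slot residueNames character vector of 3-letter residue codes.
#' @slot chain optional chain identifier (`NA_character_` = any chain).
#' @slot residueNumbers optional integer vector of residue numbers
#'   (length 0 = any number).
#' @export
setClass("LigandSpec",
  representation(
    residueNames = "character",
    chain = "character",
    residueNumbers = "integer"
  ),
  prototype(chain = NA_character_, residueNumbers = integer(0))
)

setValidity("LigandSpec", function(object) {
  if (length(object@residueNames) < 1L || any(!nzchar(object@residueNames)))
    return("residueNames must contain at least one non-empty code")
  if (length(object@chain) != 1L)
    return("chain must be a single value (possibly NA)")
  TRUE
})

#' Conformational ensemble of a ligand-protein complex
#'
#' An ordered set of structure snapshots (frames) sharing one topology.
#' The topology is a data.frame with one row per atom (serial, name,
#' element, altLoc, resname, chain, resno, insert, partition, isBackbone);
#' coordinates live in `frames`, a list of n_atoms x 3 matrices in Angstrom.
#'
#' @slot topology data.frame of per-atom records; `partition` is one of
#'   `"protein"`, `"ligand"`, `"other"`; `isBackbone` is `TRUE` only for
#'   protein main-chain atoms.
#' @slot frames list of numeric matrices (n_atoms x 3, Angstrom), one per
#'   frame, identical atom order throughout.
#' @slot source provenance string (file or directory the ensemble came
#'   from, or a generator tag).
#' @export
setClass("StructureEnsemble",
  representation(
    topology = "data.frame",
    frames = "list",
    source = "character"
  )
)

setValidity("StructureEnsemble", function(object) {
  top <- object@topology
  if (!all(.TOPOLOGY_COLS %in% names(top)))
    return(paste0("topology must contain columns: ",
                  paste(.TOPOLOGY_COLS, collapse = ", ")))
  if (length(object@frames) < 1L)
    return("ensemble must contain at least one frame")
  n <- nrow(top)
  for (f in object@frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      return("every frame must be an n_atoms x 3 coordinate matrix")
    if (!all(is.finite(f)))
      return("frame coordinates must be finite")
  }
  if (!all(top$partition %in% c("protein", "ligand", "other")))
    return("partition must be protein/ligand/other")
  if (any(top$isBackbone & top$partition != "protein"))
    return("isBackbone may be TRUE only for protein atoms")
  TRUE
})

#' Close-contact counting parameters
#'
#' @slot cutoff distance cutoff in Angstrom; atom pairs strictly closer
#'   than this count as contacts (default 4.5).
#' @slot heavyOnly if `TRUE`, hydrogens are excluded from counting.
#' @slot strictLessThan boundary semantics; fixed `TRUE` (a pair at exactly
#'   the cutoff is not a contact).
#' @export
setClass("ContactParams",
  representation(
    cutoff = "numeric",
    heavyOnly = "logical",
    strictLessThan = "logical"
  ),
  prototype(cutoff = 4.5, heavyOnly = FALSE, strictLessThan = TRUE)
)

setValidity("ContactParams", function(object) {
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
      object@cutoff <= 0)
    return("cutoff must be a single positive number")
  if (!isTRUE(object@strictLessThan))
    return("strictLessThan is fixed TRUE")
  TRUE
})

#' Per-residue contact profile of one ensemble
#'
#' Aggregated ligand contacts per protein residue over all frames of one
#' ensemble. `table` holds one row per residue with at least one contact:
#' chain, resno, insert, resname, total, backbone, sidechain,
#' framesWithContact, meanPerFrame.
#'
#' @slot table data.frame, one row per contacting residue.
#' @slot nFrames number of frames the profile was computed over.
#' @slot params the [ContactParams-class] used.
#' @slot source provenance string.
#' @export
setClass("ResidueContactProfile",
  representation(
    table = "data.frame",
    nFrames = "integer",
    params = "ContactParams",
    source = "character"
  )
)

setValidity("ResidueContactProfile", function(object) {
  tab <- object@table
  need <- c("chain", "resno", "insert", "resname", "total", "backbone",
            "sidechain", "framesWithContact", "meanPerFrame")
  if (!all(need %in% names(tab)))
    return(paste0("profile table must contain: ", paste(need, collapse = ", ")))
  if (object@nFrames < 1L)
    return("nFrames must be >= 1")
  if (nrow(tab)) {
    if (any(tab$total != tab$backbone + tab$sidechain))
      return("total must equal backbone + sidechain")
    if (any(tab$framesWithContact < 0L | tab$framesWithContact > object@nFrames))
      return("framesWithContact out of [0, nFrames]")
    if (any(abs(tab$meanPerFrame - tab$total / object@nFrames) > 1e-9))
      return("meanPerFrame must equal total / nFrames")
  }
  TRUE
})

#' Inhibitor-versus-natural-ligand differential contact table
#'
#' Per-residue comparison of mean contacts per frame between the
#' inhibitor-bound and nucleotide-bound ensembles. The residue set is the
#' union of the two profiles; a residue absent from one side contributes 0
#' on that side.
#'
#' @slot table data.frame with columns chain, resno, insert, resname,
#'   inhibitorMean, naturalMean, delta (= inhibitorMean - naturalMean) and
#'   inhibitorBackboneFraction (backbone share of the residue's inhibitor
#'   contacts, 0 if none).
#' @slot params shared [ContactParams-class].
#' @export
setClass("DifferentialContactTable",
  representation(
    table = "data.frame",
    params = "ContactParams"
  )
)

setValidity("DifferentialContactTable", function(object) {
  tab <- object@table
  need <- c("chain", "resno", "insert", "resname", "inhibitorMean",
            "naturalMean", "delta", "inhibitorBackboneFraction")
  if (!all(need %in% names(tab)))
    return(paste0("differential table must contain: ",
                  paste(need, collapse = ", ")))
  if (nrow(tab)) {
    if (any(abs(tab$delta - (tab$inhibitorMean - tab$naturalMean)) > 1e-12))
      return("delta must equal inhibitorMean - naturalMean")
    bf <- tab$inhibitorBackboneFraction
    if (any(bf < 0 | bf > 1))
      return("inhibitorBackboneFraction must lie in [0, 1]")
  }
  TRUE
})

#' Triage thresholds
#'
#' Tunable thresholds for the five-stage gatekeeper-site selection.
#'
#' @slot minOccupancy minimum fraction of frames with at least one contact
#'   for a residue to count as proximal (default 0.05).
#' @slot backboneFractionThreshold inhibitor backbone-contact fraction at or
#'   above which a residue counts as backbone-mediated (default 0.75).
#' @slot minMeanContacts mean inhibitor contacts per frame below which a
#'   residue has too few contacts overall (default 1.0).
#' @slot substitutionTarget 3-letter code of the suggested substitution
#'   (default `"GLY"`, which removes the whole side chain).
#' @export
setClass("TriageConfig",
  representation(
    minOccupancy = "numeric",
    backboneFractionThreshold = "numeric",
    minMeanContacts = "numeric",
    substitutionTarget = "character"
  ),
  prototype(minOccupancy = 0.05, backboneFractionThreshold = 0.75,
            minMeanContacts = 1.0, substitutionTarget = "GLY")
)

setValidity("TriageConfig", function(object) {
  if (object@minOccupancy < 0 || object@minOccupancy > 1)
    return("minOccupancy must be in [0, 1]")
  if (object@backboneFractionThreshold < 0 ||
      object@backboneFractionThreshold > 1)
    return("backboneFractionThreshold must be in [0, 1]")
  if (object@minMeanContacts < 0)
    return("minMeanContacts must be >= 0")
  if (length(object@substitutionTarget) != 1L ||
      nchar(object@substitutionTarget) != 3L)
    return("substitutionTarget must be one 3-letter residue code")
  TRUE
})

#' Result of the gatekeeper-site triage
#'
#' @slot stageSets named list of character vectors of residue keys, in
#'   stage order: proximal, structural_ok, differential_positive,
#'   sufficient_contact, family_invariant. Each set is a subset of the
#'   previous one.
#' @slot candidates data.frame of final ranked candidates (residue fields,
#'   delta, suggestion such as `"L593G"`, rationale), sorted by delta
#'   descending.
#' @slot config the [TriageConfig-class] used.
#' @slot provenance list of input descriptors/digests.
#' @export
setClass("TriageResult",
  representation(
    stageSets = "list",
    candidates = "data.frame",
    config = "TriageConfig",
    provenance = "list"
  )
)

.TRIAGE_STAGES <- c("proximal", "structural_ok", "differential_positive",
                    "sufficient_contact", "family_invariant")

setValidity("TriageResult", function(object) {
  if (!identical(names(object@stageSets), .TRIAGE_STAGES))
    return(paste0("stageSets must be named, in order: ",
                  paste(.TRIAGE_STAGES, collapse = ", ")))
  sets <- object@stageSets
  for (i in seq_along(sets)[-1L]) {
    if (!all(sets[[i]] %in% sets[[i - 1L]]))
      return(sprintf("stage '%s' is not a subset of stage '%s'",
                     names(sets)[i], names(sets)[i - 1L]))
  }
  TRUE
})

#' Family multiple sequence alignment with residue numbering
#'
#' A gapped protein family alignment plus, per sequence, the author residue
#' number of its first (ungapped) residue, so that author numbering (for
#' example MERTK Leu593) can be mapped to alignment columns.
#'
#' @slot sequences named character vector of equal-length gapped sequences
#'   (uppercase letters and `-`).
#' @slot numberingStart named integer vector: first-residue number per
#'   sequence identifier (default 1).
#' @export
setClass("FamilyAlignment",
  representation(
    sequences = "character",
    numberingStart = "integer"
  )
)

setValidity("FamilyAlignment", function(object) {
  seqs <- object@sequences
  if (length(seqs) < 2L)
    return("alignment must contain at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    return("sequences must have unique identifiers")
  if (length(unique(nchar(seqs))) != 1L)
    return("all gapped sequences must have equal length")
  if (!all(names(object@numberingStart) %in% names(seqs)))
    return("numberingStart refers to unknown sequence identifiers")
  TRUE
})

#' Synthetic-ensemble generator configuration
#'
#' Describes a toy binding pocket: `nResidues` pseudo-residues on a ring of
#' radius `pocketRadius` around a central single-atom ligand, sampled over
#' `nFrames` frames. Per residue, `contactPlan` plants expected contacting
#' atoms per frame for the inhibitor and the natural ligand, routes
#' contacts through backbone or side-chain atoms, and flags critical
#' residues; one residue is the designated gatekeeper ground truth.
#'
#' @slot nResidues number of pseudo-residues.
#' @slot nFrames frames per ensemble.
#' @slot seed RNG seed (single stream per generator call).
#' @slot jitterSd per-coordinate Gaussian noise, Angstrom.
#' @slot pocketRadius ring radius, Angstrom.
#' @slot contactPlan data.frame with one row per residue: resno,
#'   inhibitorPropensity, naturalPropensity, backboneRoute, critical.
#' @slot gatekeeperIndex row index of the planted gatekeeper.
#' @export
setClass("GeneratorConfig",
  representation(
    nResidues = "integer",
    nFrames = "integer",
    seed = "integer",
    jitterSd = "numeric",
    pocketRadius = "numeric",
    contactPlan = "data.frame",
    gatekeeperIndex = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  if (object@nResidues < 2L) return("need at least 2 residues")
  if (object@nFrames < 1L) return("need at least 1 frame")
  if (object@jitterSd < 0) return("jitterSd must be >= 0")
  plan <- object@contactPlan
  need <- c("resno", "inhibitorPropensity", "naturalPropensity",
            "backboneRoute", "critical")
  if (!all(need %in% names(plan)))
    return(paste0("contactPlan must contain: ", paste(need, collapse = ", ")))
  if (nrow(plan) != object@nResidues)
    return("contactPlan must have one row per residue")
  if (any(plan$inhibitorPropensity < 0) || any(plan$naturalPropensity < 0))
    return("propensities must be >= 0")
  gi <- object@gatekeeperIndex
  if (gi < 1L || gi > nrow(plan))
    return("gatekeeperIndex out of range")
  gk <- plan[gi, ]
  if (gk$inhibitorPropensity <= gk$naturalPropensity)
    return("gatekeeper must have inhibitorPropensity > naturalPropensity")
  if (gk$backboneRoute || gk$critical)
    return("gatekeeper must be side-chain routed and non-critical")
  TRUE
})
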