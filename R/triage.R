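#' Construct triage thresholds
#'
#' @param minOccupancy proximity threshold: minimum fraction of frames in
#'   which a residue contacts the inhibitor (default 0.05, robust to
#'   single-frame noise while retaining any persistently contacting
#'   residue).
#' @param backboneFractionThreshold backbone-contact fraction at or above
#'   which a residue counts as backbone-mediated (default 0.75).
#' @param minMeanContacts mean inhibitor contacts/frame below which a
#'   residue has too few contacts to anchor the inhibitor (default 1.0).
#' @param substitutionTarget suggested substitution (default `"GLY"`:
#'   removing the side chain switches off its van der Waals contacts).
#' @return a [TriageConfig-class]
#' @export
triageConfig <- function(minOccupancy = 0.05,
                         backboneFractionThreshold = 0.75,
                         minMeanContacts = 1.0,
                         substitutionTarget = "GLY") {
  new("TriageConfig", minOccupancy = as.numeric(minOccupancy),
      backboneFractionThreshold = as.numeric(backboneFractionThreshold),
      minMeanContacts = as.numeric(minMeanContacts),
      substitutionTarget = toupper(substitutionTarget))
}

# residue keys of a profile/differential table data.frame
.tableKeys <- function(tab) {
  residueKey(tab$chain, tab$resno, tab$insert, tab$resname)
}

# parse "chain:resno[insert]:resname" keys back into fields
.keyParts <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1L)
  mid <- vapply(parts, `[`, "", 2L)
  resname <- vapply(parts, `[`, "", 3L)
  resno <- as.integer(sub("^(-?[0-9]+).*$", "\\1", mid))
  insert <- sub("^-?[0-9]+", "", mid)
  data.frame(chain = chain, resno = resno, insert = insert,
             resname = resname, stringsAsFactors = FALSE)
}

# normalize a profile / fixture data.frame to per-residue stats with keys
.residueStats <- function(x) {
  if (is(x, "ResidueContactProfile")) {
    tab <- x@table
    tab$occupancy <- tab$framesWithContact / x@nFrames
    tab$backboneFraction <- ifelse(tab$total > 0, tab$backbone / tab$total, 0)
  } else if (is(x, "DifferentialContactTable")) {
    tab <- x@table
  } else if (is.data.frame(x)) {
    tab <- x
  } else {
    stop("expected a profile, differential table or stats data.frame")
  }
  tab$key <- .tableKeys(tab)
  tab
}

#' Proximity filter
#'
#' Stage 1: residues in close proximity to the inhibitor, defined as a
#' frame occupancy (fraction of frames with at least one close contact) of
#' at least `minOccupancy`.
#'
#' @param inhibitorProfile [ResidueContactProfile-class] of the
#'   inhibitor-bound ensemble, or a fixture stats data.frame (all rows of a
#'   fixture are taken as proximal, the fixture being a transcribed
#'   proximal set).
#' @param config a [TriageConfig-class]
#' @return character vector of residue keys
#' @export
proximityFilter <- function(inhibitorProfile, config = triageConfig()) {
  tab <- .residueStats(inhibitorProfile)
  if (!nrow(tab)) stop("profile is empty")
  if (!is.null(tab$occupancy))
    tab <- tab[tab$occupancy >= config@minOccupancy, , drop = FALSE]
  tab$key
}

#' Structural filter
#'
#' Stage 2: removes residues that contact the inhibitor mainly through
#' their backbone atoms (a side-chain substitution cannot remove those
#' contacts) and residues annotated as critical for the structural or
#' catalytic integrity of the enzyme. When the profile carries an explicit
#' per-residue `backboneMediated` flag (fixture mode) the flag takes
#' precedence over the backbone-fraction threshold; likewise an explicit
#' `critical` column supplements the annotation table.
#'
#' @param proximal character vector of residue keys from
#'   [proximityFilter()].
#' @param inhibitorProfile profile or fixture stats (see
#'   [proximityFilter()]).
#' @param annotations optional data.frame with columns `chain`, `resnum`,
#'   `icode`, `critical` (0/1) and `note` (see [readAnnotations()]).
#'   Annotations naming residues absent from the profile are ignored with
#'   a warning.
#' @param config a [TriageConfig-class]
#' @return character vector of surviving residue keys
#' @export
structuralFilter <- function(proximal, inhibitorProfile, annotations = NULL,
                             config = triageConfig()) {
  tab <- .residueStats(inhibitorProfile)
  tab <- tab[tab$key %in% proximal, , drop = FALSE]

  if (!is.null(tab$backboneMediated)) {
    bbOut <- as.logical(tab$backboneMediated)
  } else if (!is.null(tab$backboneFraction)) {
    bbOut <- tab$backboneFraction >= config@backboneFractionThreshold
  } else {
    bbOut <- rep(FALSE, nrow(tab))
  }

  criticalKeys <- character(0)
  if (!is.null(tab$critical))
    criticalKeys <- tab$key[as.logical(tab$critical)]
  if (!is.null(annotations) && nrow(annotations)) {
    parts <- .keyParts(tab$key)
    annPos <- match(paste(annotations$chain, annotations$resnum,
                          annotations$icode),
                    paste(parts$chain, parts$resno, parts$insert))
    unknown <- is.na(annPos)
    if (any(unknown))
      warning(sum(unknown), " annotation(s) reference residues absent ",
              "from the profile; ignored")
    criticalKeys <- c(criticalKeys,
                      tab$key[annPos[!unknown]][
                        annotations$critical[!unknown] != 0])
  }
  tab$key[!bbOut & !(tab$key %in% criticalKeys)]
}

#' Differential contact filter
#'
#' Stage 3 and 4: keeps residues with strictly more close contacts with
#' the inhibitor than with the natural ligand (`positive`; ties are not
#' "larger"), then removes residues whose inhibitor contacts are too few
#' overall to matter (`sufficient`). An explicit `lowContact` flag in a
#' fixture table takes precedence over the `minMeanContacts` threshold.
#' Residues absent from the table contribute zero on both sides.
#'
#' @param surviving character vector of residue keys from
#'   [structuralFilter()].
#' @param table a [DifferentialContactTable-class] or fixture stats
#'   data.frame with `inhibitorMean` and `naturalMean` columns.
#' @param config a [TriageConfig-class]
#' @return list with character vectors `positive` and `sufficient`
#' @export
differentialFilter <- function(surviving, table, config = triageConfig()) {
  tab <- .residueStats(table)
  idx <- match(surviving, tab$key)
  inh <- ifelse(is.na(idx), 0, tab$inhibitorMean[idx])
  nat <- ifelse(is.na(idx), 0, tab$naturalMean[idx])
  positive <- surviving[inh > nat]

  if (!is.null(tab$lowContact)) {
    low <- tab$key[as.logical(tab$lowContact)]
    sufficient <- positive[!(positive %in% low)]
  } else {
    inhPos <- inh[inh > nat]
    sufficient <- positive[inhPos >= config@minMeanContacts]
  }
  list(positive = positive, sufficient = sufficient)
}

#' Family-conservation filter
#'
#' Stage 5: removes candidate sites whose alignment column varies across
#' the kinase family (any homolog differing from the target, gaps
#' included). Such positions are natural "mutation" sites within the
#' family and therefore poor choices for a selective gatekeeper.
#'
#' @param sufficient character vector of residue keys.
#' @param family a [FamilyAlignment-class]
#' @param targetId identifier of the target sequence in the alignment.
#' @return character vector of family-invariant residue keys
#' @export
conservationFilter <- function(sufficient, family, targetId) {
  stopifnot(is(family, "FamilyAlignment"))
  if (!length(sufficient)) return(character(0))
  parts <- .keyParts(sufficient)
  keep <- vapply(seq_along(sufficient), function(i) {
    col <- mapPosition(family, targetId, parts$resno[i])
    !columnVaries(family, col, targetId)
  }, logical(1))
  sufficient[keep]
}

#' Rank candidates and suggest substitutions
#'
#' Orders the final candidates by differential contact (delta, descending;
#' ties broken by residue number ascending) and attaches a substitution
#' suggestion in the `L593G` style. A candidate that is already the
#' substitution target (glycine by default) has no side chain to remove
#' and is flagged instead of suggested.
#'
#' @param candidateKeys character vector of residue keys.
#' @param table a [DifferentialContactTable-class] or fixture stats
#'   data.frame covering the candidates.
#' @param config a [TriageConfig-class]
#' @return data.frame: chain, resno, insert, resname, delta, suggestion,
#'   rationale — sorted by delta descending.
#' @export
rankAndSuggest <- function(candidateKeys, table, config = triageConfig()) {
  tab <- .residueStats(table)
  parts <- .keyParts(candidateKeys)
  idx <- match(candidateKeys, tab$key)
  delta <- ifelse(is.na(idx), 0, tab$delta[idx])
  ord <- order(-delta, parts$resno)

  parts <- parts[ord, , drop = FALSE]
  delta <- delta[ord]
  tgt1 <- unname(.AA1[config@substitutionTarget])
  if (is.na(tgt1)) tgt1 <- "?"

  suggestion <- character(nrow(parts))
  rationale <- character(nrow(parts))
  for (i in seq_len(nrow(parts))) {
    res1 <- unname(.AA1[parts$resname[i]])
    if (is.na(res1)) res1 <- "X"
    lbl <- residueLabel(parts$resname[i], parts$resno[i])
    if (parts$resname[i] == config@substitutionTarget) {
      suggestion[i] <- NA_character_
      rationale[i] <- paste0(lbl, ": no side chain to remove")
    } else {
      suggestion[i] <- paste0(res1, parts$resno[i], tgt1)
      rationale[i] <- sprintf(
        paste0("%s: %.2f more close contacts/frame with the inhibitor than ",
               "with the natural ligand; substituting %s removes the ",
               "side-chain contacts"),
        lbl, delta[i], config@substitutionTarget)
    }
  }
  data.frame(chain = parts$chain, resno = parts$resno,
             insert = parts$insert, resname = parts$resname,
             delta = delta, suggestion = suggestion,
             rationale = rationale, stringsAsFactors = FALSE,
             row.names = NULL)
}

.triageFromStats <- function(inhibitorStats, diffStats, annotations, family,
                             targetId, config, provenance) {
  proximal <- proximityFilter(inhibitorStats, config)
  structuralOk <- structuralFilter(proximal, inhibitorStats, annotations,
                                   config)
  diffRes <- differentialFilter(structuralOk, diffStats, config)
  if (!is.null(family)) {
    familyInv <- conservationFilter(diffRes$sufficient, family, targetId)
  } else {
    familyInv <- diffRes$sufficient
  }
  cand <- rankAndSuggest(familyInv, diffStats, config)
  new("TriageResult",
      stageSets = list(proximal = proximal,
                       structural_ok = structuralOk,
                       differential_positive = diffRes$positive,
                       sufficient_contact = diffRes$sufficient,
                       family_invariant = familyInv),
      candidates = cand, config = config, provenance = provenance)
}

#' Run the full gatekeeper-site triage on two ensembles
#'
#' End-to-end composition of the five selection stages: per-residue
#' inhibitor contact profiling and proximity filtering, exclusion of
#' backbone-mediated and critical residues, differential
#' inhibitor-versus-nucleotide comparison, low-contact exclusion, and the
#' family-conservation filter, followed by ranking with substitution
#' suggestions.
#'
#' @param inhibitor [StructureEnsemble-class] of the inhibitor complex.
#' @param natural [StructureEnsemble-class] of the nucleotide complex.
#' @param annotations optional critical-residue annotations (see
#'   [readAnnotations()]).
#' @param family optional [FamilyAlignment-class]; when omitted the
#'   conservation stage passes every sufficient-contact residue through.
#' @param targetId target sequence identifier in `family`.
#' @param params a [ContactParams-class]
#' @param config a [TriageConfig-class]
#' @return a [TriageResult-class]
#' @export
runTriage <- function(inhibitor, natural, annotations = NULL, family = NULL,
                      targetId = NULL, params = contactParams(),
                      config = triageConfig()) {
  inhProf <- residueContactProfile(inhibitor, params)
  natProf <- residueContactProfile(natural, params)
  diff <- differentialProfile(inhProf, natProf)
  prov <- list(mode = "ensemble",
               inhibitor_source = inhibitor@source,
               natural_source = natural@source,
               n_frames = c(inhibitor = nFrames(inhibitor),
                            natural = nFrames(natural)),
               cutoff = params@cutoff, heavy_only = params@heavyOnly)
  .triageFromStats(inhProf, diff, annotations, family, targetId, config,
                   prov)
}

#' Run the triage from a transcribed per-residue fixture table
#'
#' Fixture mode executes the selection from a per-residue table of flags
#' and mean contact counts instead of raw ensembles, so that a published
#' worked example can be reproduced exactly without trajectories. The
#' fixture's rows define the proximal set; `critical` and
#' `backbone_mediated` flags drive the structural stage, the mean columns
#' the differential stage, and `low_contact` the sufficiency stage.
#'
#' @param fixture path to a fixture TSV (see [readFixtureTable()]) or the
#'   data.frame it parses to.
#' @param family optional [FamilyAlignment-class]
#' @param targetId target sequence identifier in `family`.
#' @param config a [TriageConfig-class]
#' @return a [TriageResult-class]
#' @export
runTriageFixture <- function(fixture, family = NULL, targetId = NULL,
                             config = triageConfig()) {
  src <- if (is.character(fixture)) fixture else "in-memory fixture"
  if (is.character(fixture)) fixture <- readFixtureTable(fixture)
  prov <- list(mode = "fixture", fixture_source = src)
  if (is.character(src) && file.exists(src))
    prov$fixture_md5 <- unname(tools::md5sum(src))
  .triageFromStats(fixture, fixture, annotations = NULL, family = family,
                   targetId = targetId, config = config, provenance = prov)
}

#' Read a critical-residue annotation table
#'
#' TSV with columns `chain`, `resnum`, `icode`, `critical` (0/1), `note`.
#'
#' @param path TSV path
#' @return data.frame
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(chain = "character",
                                          icode = "character",
                                          note = "character"))
  ann$icode[is.na(ann$icode)] <- ""
  ann
}

#' Read a worked-example fixture table
#'
#' TSV with per-residue columns `chain`, `resnum`, `icode`, `resname`,
#' `critical` (0/1), `backbone_mediated` (0/1), `inhibitor_mean`,
#' `natural_mean`, `low_contact` (0/1), `note`. Returns a stats data.frame
#' consumable by the triage filters.
#'
#' @param path TSV path
#' @return data.frame with triage-ready column names
#' @export
readFixtureTable <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(chain = "character",
                                          icode = "character"))
  raw$icode[is.na(raw$icode)] <- ""
  data.frame(chain = raw$chain, resno = as.integer(raw$resnum),
             insert = raw$icode, resname = toupper(raw$resname),
             critical = raw$critical != 0,
             backboneMediated = raw$backbone_mediated != 0,
             inhibitorMean = raw$inhibitor_mean,
             naturalMean = raw$natural_mean,
             delta = raw$inhibitor_mean - raw$natural_mean,
             lowContact = raw$low_contact != 0,
             stringsAsFactors = FALSE)
}
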