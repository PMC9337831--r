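# side-chain-bearing residue codes used for pseudo-residues (no GLY: the
# scaffold gives every residue CB/CG side-chain atoms)
.PSEUDO_AA <- setdiff(c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
                        "SER", "THR", "TRP", "TYR", "VAL"), "GLY")

#' Construct a synthetic-ensemble generator configuration
#'
#' When `contactPlan` is omitted a default plan is drawn from `seed`:
#' per-residue inhibitor and natural-ligand propensities uniform on
#' [0, 1.5] expected contacting atoms/frame, about 20% of residues routed
#' through their backbone atoms, two residues flagged critical, and one
#' randomly chosen side-chain residue planted as the gatekeeper
#' (inhibitor propensity 1.8, natural 0.2) so that its differential
#' contact exceeds every unplanted residue's by construction.
#'
#' @param nResidues number of pseudo-residues (default 50).
#' @param nFrames frames per ensemble (default 200).
#' @param seed RNG seed (mandatory; single stream per generator call).
#' @param jitterSd per-coordinate Gaussian jitter in Angstrom
#'   (default 0.3, small relative to the 1.5 A margin between planted
#'   contact positions and the 4.5 A shell).
#' @param pocketRadius scaffold ring radius in Angstrom (default 12).
#' @param contactPlan optional data.frame (resno, inhibitorPropensity,
#'   naturalPropensity, backboneRoute, critical), one row per residue.
#' @param gatekeeperIndex row of the planted gatekeeper (default: chosen
#'   by the default plan).
#' @return a [GeneratorConfig-class]
#' @export
generatorConfig <- function(nResidues = 50L, nFrames = 200L, seed,
                            jitterSd = 0.3, pocketRadius = 12,
                            contactPlan = NULL, gatekeeperIndex = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  nResidues <- as.integer(nResidues)
  if (is.null(contactPlan)) {
    rs <- .withSeed(seed, {
      plan <- data.frame(
        resno = seq_len(nResidues),
        inhibitorPropensity = stats::runif(nResidues, 0, 1.5),
        naturalPropensity = stats::runif(nResidues, 0, 1.5),
        backboneRoute = stats::runif(nResidues) < 0.2,
        critical = FALSE
      )
      plan$critical[sample.int(nResidues, min(2L, nResidues - 1L))] <- TRUE
      gi <- if (is.null(gatekeeperIndex)) {
        ok <- which(!plan$backboneRoute & !plan$critical)
        ok[sample.int(length(ok), 1L)]
      } else as.integer(gatekeeperIndex)
      plan$inhibitorPropensity[gi] <- 1.8
      plan$naturalPropensity[gi] <- 0.2
      plan$backboneRoute[gi] <- FALSE
      plan$critical[gi] <- FALSE
      list(plan = plan, gi = gi)
    })
    contactPlan <- rs$plan
    gatekeeperIndex <- rs$gi
  } else if (is.null(gatekeeperIndex)) {
    stop("gatekeeperIndex must be given with an explicit contactPlan")
  }
  new("GeneratorConfig", nResidues = nResidues,
      nFrames = as.integer(nFrames), seed = as.integer(seed),
      jitterSd = as.numeric(jitterSd),
      pocketRadius = as.numeric(pocketRadius),
      contactPlan = contactPlan,
      gatekeeperIndex = as.integer(gatekeeperIndex))
}

# evaluate expr under set.seed(seed), restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# scaffold topology + base geometry for a generator config
.scaffold <- function(config) {
  n <- config@nResidues
  R <- config@pocketRadius
  if (R < 9)
    stop("pocket too small for the scaffold: pocketRadius must be >= 9 A ",
         "so home positions stay outside the contact shell")
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  u <- cbind(cos(theta), sin(theta))

  atomNames <- c("N", "CA", "C", "O", "CB", "CG")
  radii <- c(N = R + 0.8, CA = R, C = R + 0.4, O = R + 1.2,
             CB = R - 1.5, CG = R - 2.8)
  zoff <- c(N = 0.8, CA = 0, C = -0.8, O = -1.4, CB = 0.4, CG = 0.8)

  nAtoms <- n * 6L + 1L
  base <- matrix(0, nAtoms, 3L)
  for (a in seq_len(6L)) {
    rows <- (seq_len(n) - 1L) * 6L + a
    base[rows, 1L] <- radii[a] * u[, 1L]
    base[rows, 2L] <- radii[a] * u[, 2L]
    base[rows, 3L] <- zoff[a]
  }
  # ligand: single heavy atom at the pocket center
  base[nAtoms, ] <- c(0, 0, 0)

  # contact slots: up to 4 positions per residue at ~3 A from the ligand
  slotZ <- c(-0.6, -0.2, 0.2, 0.6)
  contactPos <- array(0, dim = c(n, 4L, 3L))
  for (s in seq_len(4L)) {
    contactPos[, s, 1L] <- 3.0 * u[, 1L]
    contactPos[, s, 2L] <- 3.0 * u[, 2L]
    contactPos[, s, 3L] <- slotZ[s]
  }

  resnames <- rep_len(.PSEUDO_AA, n)
  topo <- data.frame(
    serial = seq_len(nAtoms),
    name = c(rep(atomNames, n), "C1"),
    element = c(rep(c("N", "C", "C", "O", "C", "C"), n), "C"),
    altLoc = "",
    resname = c(rep(resnames, each = 6L), "LIG"),
    chain = "A",
    resno = c(rep(config@contactPlan$resno, each = 6L), 9000L),
    insert = "",
    partition = c(rep("protein", n * 6L), "ligand"),
    stringsAsFactors = FALSE
  )
  topo$isBackbone <- topo$partition == "protein" &
    classifyBackbone(topo$name, topo$resname)
  list(base = base, contactPos = contactPos, topo = topo)
}

# draw frames for one ligand ensemble from planted propensities
.drawFrames <- function(scaffold, propensity, backboneRoute, nFrames,
                        jitterSd) {
  n <- length(propensity)
  nRouted <- ifelse(backboneRoute, 4L, 2L)
  if (any(propensity > nRouted))
    stop("propensity exceeds the number of routed atoms ",
         "(max 2 side-chain, 4 backbone)")
  kBase <- floor(propensity)
  kFrac <- propensity - kBase
  routeOffset <- ifelse(backboneRoute, 0L, 4L)  # atoms 1..4 bb, 5..6 sc
  nAtoms <- nrow(scaffold$base)

  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    k <- kBase + (stats::runif(n) < kFrac)
    xyz <- scaffold$base
    moved <- which(k > 0)
    if (length(moved)) {
      slots <- sequence(k[moved])
      resIdx <- rep.int(moved, k[moved])
      rows <- (resIdx - 1L) * 6L + routeOffset[resIdx] + slots
      for (d in 1:3)
        xyz[rows, d] <- scaffold$contactPos[cbind(resIdx, slots, d)]
    }
    if (jitterSd > 0)
      xyz <- xyz + matrix(stats::rnorm(nAtoms * 3L, 0, jitterSd), nAtoms, 3L)
    frames[[f]] <- xyz
  }
  frames
}

#' Generate a pair of synthetic ensembles with planted contact structure
#'
#' Builds inhibitor-bound and nucleotide-bound toy ensembles over a shared
#' scaffold: pseudo-residues (4 backbone + 2 side-chain atoms with legal
#' PDB names) on a ring around a central single-atom ligand. Per frame,
#' each residue's routed atoms (side chain, or backbone for
#' backbone-routed residues) are placed inside the 4.5 A shell of the
#' ligand with expected count equal to the planted propensity
#' (`floor(p)` atoms always, one more with probability `p - floor(p)`),
#' then all coordinates receive Gaussian jitter. The expected mean
#' contacts/frame of a residue therefore equals its propensity exactly in
#' the noise-free limit and up to boundary-crossing noise otherwise.
#' Identical seeds yield identical ensembles (and identical bytes when
#' written).
#'
#' @param config a [GeneratorConfig-class]
#' @param outdir optional directory; when given, writes
#'   `inhibitor.pdb`, `natural.pdb` (multi-model) and
#'   `ground_truth.json`.
#' @return list with elements `inhibitor` and `natural`
#'   ([StructureEnsemble-class]), and `groundTruth`: planted expected
#'   means per residue key, the gatekeeper residue, and the file manifest
#'   (when written).
#' @export
generateEnsembles <- function(config, outdir = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  sc <- .scaffold(config)
  plan <- config@contactPlan

  frames <- .withSeed(config@seed, list(
    inhibitor = .drawFrames(sc, plan$inhibitorPropensity, plan$backboneRoute,
                            config@nFrames, config@jitterSd),
    natural = .drawFrames(sc, plan$naturalPropensity, plan$backboneRoute,
                          config@nFrames, config@jitterSd)
  ))
  tag <- sprintf("synthetic(seed=%d)", config@seed)
  inh <- new("StructureEnsemble", topology = sc$topo,
             frames = frames$inhibitor, source = paste0(tag, ":inhibitor"))
  nat <- new("StructureEnsemble", topology = sc$topo,
             frames = frames$natural, source = paste0(tag, ":natural"))

  prot <- sc$topo[sc$topo$partition == "protein", ]
  first <- !duplicated(prot$resno)
  keys <- residueKey(prot$chain[first], prot$resno[first],
                     prot$insert[first], prot$resname[first])
  gt <- list(
    expectedInhibitorMean = stats::setNames(plan$inhibitorPropensity, keys),
    expectedNaturalMean = stats::setNames(plan$naturalPropensity, keys),
    gatekeeper = keys[config@gatekeeperIndex],
    gatekeeperResno = plan$resno[config@gatekeeperIndex],
    manifest = character(0)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    pI <- file.path(outdir, "inhibitor.pdb")
    pN <- file.path(outdir, "natural.pdb")
    pG <- file.path(outdir, "ground_truth.json")
    writeEnsemble(inh, pI)
    writeEnsemble(nat, pN)
    jsonlite::write_json(
      list(seed = config@seed, n_residues = config@nResidues,
           n_frames = config@nFrames, gatekeeper = gt$gatekeeper,
           expected_inhibitor_mean = as.list(gt$expectedInhibitorMean),
           expected_natural_mean = as.list(gt$expectedNaturalMean)),
      pG, auto_unbox = TRUE, digits = NA)
    gt$manifest <- c(pI, pN, pG)
  }
  list(inhibitor = inh, natural = nat, groundTruth = gt)
}

# the published MERTK/MRX-2843 worked example, transcribed as flags;
# numeric means are synthetic illustrative values consistent with the
# qualitative statements (which residues are inhibitor-enriched, which
# have too few contacts)
.mertkExampleTable <- function() {
  data.frame(
    chain = "A",
    resnum = c(591L, 593L, 594L, 596L, 597L, 601L, 617L, 619L, 637L, 650L,
               669L, 671L, 672L, 673L, 674L, 677L, 681L, 730L, 741L),
    icode = "",
    resname = c("LYS", "LEU", "GLY", "GLY", "GLU", "VAL", "ALA", "LYS",
                "GLU", "ILE", "VAL", "LEU", "PRO", "PHE", "MET", "GLY",
                "THR", "MET", "ASP"),
    critical = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L,
                 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    backbone_mediated = c(1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L,
                          0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L),
    inhibitor_mean = c(2.5, 5.8, 1.5, 1.2, 1.0, 2.0, 1.1, 3.0, 0.4, 6.2,
                       0.6, 4.9, 2.1, 3.3, 2.8, 1.4, 1.0, 2.2, 2.0),
    natural_mean = c(1.0, 2.1, 1.2, 1.5, 0.8, 2.5, 1.8, 3.5, 0.1, 4.0,
                     0.2, 3.0, 1.1, 2.2, 2.0, 0.9, 0.6, 2.2, 2.6),
    low_contact = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L,
                    1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    note = "",
    stringsAsFactors = FALSE
  )
}

# synthetic TAM-family (MERTK/TYRO3/AXL) kinase-domain fragment covering
# MERTK 585-745; identical everywhere except the Ile650 column, which
# holds Ala in TYRO3 and Met in AXL -- a test fixture encoding the
# published positional correspondence, not the true full-length alignment
.tamAlignment <- function() {
  span <- 585:745
  bg <- rep_len(strsplit("ACDEFHIKLMNPQRSTVWY", "")[[1L]], length(span))
  fix <- .mertkExampleTable()
  mertk <- bg
  mertk[fix$resnum - 584L] <- unname(.AA1[fix$resname])
  tyro3 <- axl <- mertk
  tyro3[650L - 584L] <- "A"
  axl[650L - 584L] <- "M"
  seqs <- c(MERTK = paste(mertk, collapse = ""),
            TYRO3 = paste(tyro3, collapse = ""),
            AXL = paste(axl, collapse = ""))
  new("FamilyAlignment", sequences = seqs,
      numberingStart = c(MERTK = 585L, TYRO3 = 516L, AXL = 534L))
}

#' Write the bundled MERTK worked-example fixture
#'
#' Emits the transcribed 19-residue MERTK/MRX-2843 worked example as a
#' fixture TSV (critical flags on Lys619/Asp741; backbone-mediated flags
#' on the nine main-chain-interacting residues; inhibitor-versus-ADP
#' differential flags, with Glu637/Val669 marked low-contact), the
#' synthetic TAM-family fragment alignment in which the Ile650 column
#' varies (Ala in TYRO3, Met in AXL), its numbering sidecar, and a
#' critical-residue annotation TSV. Running the triage in fixture mode on
#' these files reproduces the published selection exactly:
#' 19 proximal residues, 8 after the structural filter, 5
#' inhibitor-enriched, 3 promising sites, and the final candidates
#' Leu593 and Leu671 with glycine substitutions.
#'
#' @param outdir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
writeMertkExample <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fixture = file.path(outdir, "mertk_worked_example.tsv"),
    msa = file.path(outdir, "tam_family_synthetic.fasta"),
    numbering = file.path(outdir, "tam_family_numbering.tsv"),
    annotations = file.path(outdir, "mertk_critical_residues.tsv")
  )
  utils::write.table(.mertkExampleTable(), paths[["fixture"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeMsa(.tamAlignment(), paths[["msa"]], paths[["numbering"]])
  ann <- data.frame(chain = "A", resnum = c(619L, 741L), icode = "",
                    critical = 1L,
                    note = c("catalytic lysine", "DFG aspartate"))
  utils::write.table(ann, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
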