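#' @rdname StructureEnsemble-class
#' @param x a `StructureEnsemble`
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname StructureEnsemble-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname StructureEnsemble-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname StructureEnsemble-class
#' @param i frame index
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' Tabular view of a profile or differential table
#' @param x a `ResidueContactProfile` or `DifferentialContactTable`
#' @export
setGeneric("contactTable", function(x) standardGeneric("contactTable"))

#' @rdname TriageResult-class
#' @param x a `TriageResult`
#' @export
setGeneric("stageSets", function(x) standardGeneric("stageSets"))

#' @rdname TriageResult-class
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname FamilyAlignment-class
#' @param x a `FamilyAlignment`
#' @export
setGeneric("alignedSequences", function(x) standardGeneric("alignedSequences"))

#' @describeIn StructureEnsemble-class number of frames
setMethod("nFrames", "StructureEnsemble", function(x) length(x@frames))

#' @describeIn ResidueContactProfile-class number of frames aggregated
setMethod("nFrames", "ResidueContactProfile", function(x) x@nFrames)

#' @describeIn StructureEnsemble-class number of topology atoms
setMethod("nAtoms", "StructureEnsemble", function(x) nrow(x@topology))

#' @describeIn StructureEnsemble-class per-atom topology data.frame
setMethod("topology", "StructureEnsemble", function(x) x@topology)

#' @describeIn StructureEnsemble-class coordinates of frame `i`
setMethod("frameCoords", "StructureEnsemble", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@frames))
  x@frames[[i]]
})

#' @describeIn ResidueContactProfile-class per-residue statistics
setMethod("contactTable", "ResidueContactProfile", function(x) x@table)

#' @describeIn DifferentialContactTable-class per-residue comparison
setMethod("contactTable", "DifferentialContactTable", function(x) x@table)

#' @describeIn TriageResult-class surviving residue keys per stage
setMethod("stageSets", "TriageResult", function(x) x@stageSets)

#' @describeIn TriageResult-class ranked final candidates
setMethod("candidates", "TriageResult", function(x) x@candidates)

#' @describeIn FamilyAlignment-class named gapped sequences
setMethod("alignedSequences", "FamilyAlignment", function(x) x@sequences)

setMethod("show", "StructureEnsemble", function(object) {
  part <- table(object@topology$partition)
  cat("StructureEnsemble:", length(object@frames), "frame(s),",
      nrow(object@topology), "atoms\n")
  cat("  partition:", paste(names(part), unname(part), sep = "=",
                            collapse = ", "), "\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "ResidueContactProfile", function(object) {
  cat("ResidueContactProfile:", nrow(object@table),
      "contacting residue(s) over", object@nFrames, "frame(s)\n")
  cat(sprintf("  cutoff %.2f A, heavyOnly=%s\n",
              object@params@cutoff, object@params@heavyOnly))
  if (nrow(object@table))
    print(utils::head(object@table, 5L), row.names = FALSE)
})

setMethod("show", "DifferentialContactTable", function(object) {
  cat("DifferentialContactTable:", nrow(object@table), "residue(s)\n")
  if (nrow(object@table)) {
    ord <- order(-object@table$delta)
    print(utils::head(object@table[ord, ], 5L), row.names = FALSE)
  }
})

setMethod("show", "TriageResult", function(object) {
  cat("TriageResult\n")
  for (s in names(object@stageSets))
    cat(sprintf("  %-22s %d residue(s)\n", s, length(object@stageSets[[s]])))
  if (nrow(object@candidates)) {
    cat("  candidates:\n")
    print(object@candidates[, c("suggestion", "delta", "rationale")],
          row.names = FALSE)
  } else {
    cat("  candidates: none\n")
  }
})

setMethod("show", "FamilyAlignment", function(object) {
  cat("FamilyAlignment:", length(object@sequences), "sequences x",
      nchar(object@sequences[[1L]]), "columns\n")
  cat("  ids:", paste(names(object@sequences), collapse = ", "), "\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nResidues, "residues,",
      object@nFrames, "frames, seed", object@seed, "\n")
  cat(sprintf("  jitterSd %.2f A, pocketRadius %.1f A, gatekeeper row %d\n",
              object@jitterSd, object@pocketRadius, object@gatekeeperIndex))
})
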