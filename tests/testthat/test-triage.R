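# stats data.frame shorthand for filter tests (fixture-style input)
statsDF <- function(resno, resname = "LEU", inh = 2, nat = 1,
                    backboneMediated = NULL, critical = NULL,
                    lowContact = NULL) {
  df <- data.frame(chain = "A", resno = as.integer(resno), insert = "",
                   resname = resname, inhibitorMean = inh,
                   naturalMean = nat, delta = inh - nat,
                   stringsAsFactors = FALSE)
  if (!is.null(backboneMediated)) df$backboneMediated <- backboneMediated
  if (!is.null(critical)) df$critical <- critical
  if (!is.null(lowContact)) df$lowContact <- lowContact
  df
}

keyOf <- function(resno, resname = "LEU") {
  sprintf("A:%d:%s", resno, resname)
}

test_that("proximity filter applies the occupancy threshold", {
  tab <- data.frame(chain = "A", resno = c(1L, 2L), insert = "",
                    resname = "LEU", total = c(100L, 1L),
                    backbone = 0L, sidechain = c(100L, 1L),
                    framesWithContact = c(100L, 1L),
                    meanPerFrame = c(1, 0.01), stringsAsFactors = FALSE)
  prof <- new("ResidueContactProfile", table = tab, nFrames = 100L,
              params = contactParams(), source = "t")
  kept <- proximityFilter(prof, triageConfig(minOccupancy = 0.05))
  expect_equal(kept, keyOf(1))
  # retained set equals a recomputation from the raw occupancies
  expect_equal(kept, tab$resno[tab$framesWithContact / 100 >= 0.05] |>
                 keyOf())
})

test_that("structural filter removes backbone-mediated and critical residues", {
  df <- statsDF(1:4, backboneMediated = c(FALSE, TRUE, FALSE, FALSE),
                critical = c(FALSE, FALSE, TRUE, FALSE))
  out <- structuralFilter(keyOf(1:4), df)
  expect_equal(out, keyOf(c(1, 4)))
  # no flags, no annotations -> identity
  expect_equal(structuralFilter(keyOf(1:3), statsDF(1:3)), keyOf(1:3))
  # everything critical -> empty
  expect_equal(structuralFilter(keyOf(1:2),
                                statsDF(1:2, critical = c(TRUE, TRUE))),
               character(0))
})

test_that("structural filter uses the backbone-fraction threshold on profiles", {
  tab <- data.frame(chain = "A", resno = 1:2, insert = "", resname = "LEU",
                    total = c(10L, 10L), backbone = c(8L, 2L),
                    sidechain = c(2L, 8L), framesWithContact = 5L,
                    meanPerFrame = 2, stringsAsFactors = FALSE)
  prof <- new("ResidueContactProfile", table = tab, nFrames = 5L,
              params = contactParams(), source = "t")
  out <- structuralFilter(proximityFilter(prof), prof,
                          config = triageConfig(backboneFractionThreshold = 0.75))
  expect_equal(out, keyOf(2))  # residue 1 is 80% backbone-mediated
})

test_that("annotations flag critical residues; unknown residues warn and are ignored", {
  df <- statsDF(1:3)
  ann <- data.frame(chain = "A", resnum = c(2L, 99L), icode = "",
                    critical = 1L, note = "", stringsAsFactors = FALSE)
  expect_warning(out <- structuralFilter(keyOf(1:3), df, annotations = ann),
                 "absent")
  expect_equal(out, keyOf(c(1, 3)))
})

test_that("differential filter uses strict inequality and the low-contact bar", {
  df <- statsDF(1:4, inh = c(3, 1, 0.5, 2), nat = c(1, 1, 0.1, 2.5))
  out <- differentialFilter(keyOf(1:4), df, triageConfig(minMeanContacts = 1))
  expect_equal(out$positive, keyOf(c(1, 3)))   # ties and deficits excluded
  expect_equal(out$sufficient, keyOf(1))       # 0.5 contacts/frame too few
  # residues absent from the table count as zero on both sides
  out2 <- differentialFilter(keyOf(c(1, 9)), df)
  expect_equal(out2$positive, keyOf(1))
})

test_that("differential filter matches an exhaustive scan on a random table", {
  set.seed(41)
  df <- statsDF(1:50, inh = round(runif(50, 0, 4), 2),
                nat = round(runif(50, 0, 4), 2))
  cfg <- triageConfig(minMeanContacts = 1)
  out <- differentialFilter(keyOf(1:50), df, cfg)
  wantPos <- wantSuf <- character(0)
  for (i in 1:50) {           # independent double-check, residue by residue
    if (df$inhibitorMean[i] > df$naturalMean[i]) {
      wantPos <- c(wantPos, keyOf(i))
      if (df$inhibitorMean[i] >= 1) wantSuf <- c(wantSuf, keyOf(i))
    }
  }
  expect_equal(sort(out$positive), sort(wantPos))
  expect_equal(sort(out$sufficient), sort(wantSuf))
})

test_that("conservation filter drops residues at family-variable columns", {
  p <- extdataPaths()
  fam <- readMsa(p[["msa"]], p[["numbering"]])
  keys <- c("A:671:LEU", "A:593:LEU", "A:650:ILE")
  out <- conservationFilter(keys, fam, "MERTK")
  expect_setequal(out, c("A:593:LEU", "A:671:LEU"))
  # identical sequences -> identity
  same <- new("FamilyAlignment",
              sequences = c(X = "LLLL", Y = "LLLL"),
              numberingStart = c(X = 1L, Y = 1L))
  expect_equal(conservationFilter("A:2:LEU", same, "X"), "A:2:LEU")
  # homolog gap at the column -> excluded
  gap <- new("FamilyAlignment",
             sequences = c(X = "LLLL", Y = "L-LL"),
             numberingStart = c(X = 1L, Y = 1L))
  expect_equal(conservationFilter("A:2:LEU", gap, "X"), character(0))
})

test_that("ranking orders by delta then residue number, suggesting glycine", {
  df <- statsDF(c(671, 593), inh = c(4.1, 6.2), nat = c(3, 3))
  out <- rankAndSuggest(keyOf(c(671, 593)), df)
  expect_equal(out$suggestion, c("L593G", "L671G"))
  expect_equal(out$delta, c(3.2, 1.1))
  # tie broken by ascending residue number
  dfTie <- statsDF(c(20, 10), inh = 2, nat = 1)
  expect_equal(rankAndSuggest(keyOf(c(20, 10)), dfTie)$resno, c(10L, 20L))
  # glycine candidate gets a flag, no substitution
  dfGly <- statsDF(5, resname = "GLY")
  outGly <- rankAndSuggest("A:5:GLY", dfGly)
  expect_true(is.na(outGly$suggestion))
  expect_match(outGly$rationale, "no side chain")
})

test_that("stage sets are nested and the pipeline agrees with a naive reimplementation", {
  for (seed in c(5, 6)) {
    cfg <- generatorConfig(nResidues = 15, nFrames = 25, seed = seed)
    res <- generateEnsembles(cfg)
    tr <- runTriage(res$inhibitor, res$natural)
    ss <- stageSets(tr)
    for (i in seq_along(ss)[-1])
      expect_true(all(ss[[i]] %in% ss[[i - 1]]))

    # naive reimplementation: brute-force counts, explicit filters
    tcfg <- triageConfig()
    wi <- bruteProfile(res$inhibitor, 4.5)
    wn <- bruteProfile(res$natural, 4.5)
    nF <- nFrames(res$inhibitor)
    top <- topology(res$inhibitor)
    prot <- top[top$partition == "protein", ]
    naiveKeys <- character(0)
    for (k in names(wi)) {
      parts <- strsplit(k, " ")[[1]]
      if (wi[[k]]["frames"] / nF < tcfg@minOccupancy) next
      bbFrac <- wi[[k]]["backbone"] / wi[[k]]["total"]
      if (bbFrac >= tcfg@backboneFractionThreshold) next
      mi <- wi[[k]]["total"] / nF
      mn <- if (!is.null(wn[[k]])) wn[[k]]["total"] / nF else 0
      if (!(mi > mn)) next
      if (mi < tcfg@minMeanContacts) next
      naiveKeys <- c(naiveKeys,
                     sprintf("%s:%s:%s", parts[1], parts[2], parts[4]))
    }
    expect_setequal(ss$family_invariant, naiveKeys)
  }
})

test_that("an empty natural baseline keeps sufficiently contacting survivors", {
  df <- statsDF(1:3, inh = c(2, 0.5, 3), nat = 0)
  out <- differentialFilter(keyOf(1:3), df)
  expect_equal(out$positive, keyOf(1:3))
  expect_equal(out$sufficient, keyOf(c(1, 3)))
})

test_that("identical inputs give byte-identical serialized reports", {
  p <- extdataPaths()
  fam <- readMsa(p[["msa"]], p[["numbering"]])
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeTriageReport(runTriageFixture(p[["fixture"]], fam, "MERTK"), f1)
  writeTriageReport(runTriageFixture(p[["fixture"]], fam, "MERTK"), f2)
  expect_identical(readLines(f1), readLines(f2))
})
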