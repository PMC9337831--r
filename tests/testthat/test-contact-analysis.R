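test_that("contacts use strict less-than semantics at the cutoff", {
  ens <- miniEnsemble(rbind(c(0, 0, 4.6)))
  expect_equal(nrow(enumerateContacts(ens)), 0L)

  ens2 <- miniEnsemble(rbind(c(0, 0, 4.4), c(0, 0, 4.5)))
  hits <- enumerateContacts(ens2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 4.4)
})

test_that("enumeration matches the exhaustive double-loop oracle", {
  for (seed in c(1, 2, 3)) {
    ens <- randomFrameEnsemble(nLig = 10, nProt = 60, seed = seed)
    got <- enumerateContacts(ens, 1, contactParams(cutoff = 4.5))
    want <- bruteContacts(frameCoords(ens, 1),
                          which(topology(ens)$partition == "ligand"),
                          which(topology(ens)$partition == "protein"), 4.5)
    ord <- order(want[, "lig"], want[, "prot"])
    expect_equal(got$ligandAtom, as.integer(want[ord, "lig"]))
    expect_equal(got$proteinAtom, as.integer(want[ord, "prot"]))
    expect_equal(got$distance, unname(want[ord, "d"]))
  }
})

test_that("empty partitions are a precondition error", {
  ens <- miniEnsemble(rbind(c(0, 0, 2)))
  params <- contactParams(heavyOnly = TRUE)
  top <- topology(ens)
  top$element[top$partition == "protein"] <- "H"
  bad <- new("StructureEnsemble", topology = top, frames = ens@frames,
             source = "t")
  expect_error(enumerateContacts(bad, 1, params), "at least one")
})

test_that("profile replication is linear in identical frames", {
  # one residue, two side-chain atoms in contact, three identical frames
  ens <- miniEnsemble(rbind(c(0, 0, 2), c(0, 2, 0)), nframes = 3,
                      protNames = c("CB", "CG"))
  tab <- contactTable(residueContactProfile(ens))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$total, 6L)
  expect_equal(tab$sidechain, 6L)
  expect_equal(tab$backbone, 0L)
  expect_equal(tab$framesWithContact, 3L)
  expect_equal(tab$meanPerFrame, 2.0)
})

test_that("profiles equal the brute-force per-frame oracle on synthetic ensembles", {
  cfg <- generatorConfig(nResidues = 12, nFrames = 20, seed = 7)
  ens <- generateEnsembles(cfg)$inhibitor
  prof <- residueContactProfile(ens)
  tab <- contactTable(prof)
  want <- bruteProfile(ens, 4.5)
  expect_equal(nrow(tab), length(want))
  for (i in seq_len(nrow(tab))) {
    k <- paste(tab$chain[i], tab$resno[i], tab$insert[i], tab$resname[i])
    expect_equal(tab$total[i], unname(want[[k]]["total"]))
    expect_equal(tab$backbone[i], unname(want[[k]]["backbone"]))
    expect_equal(tab$framesWithContact[i], unname(want[[k]]["frames"]))
  }
})

test_that("default parameters carry the 4.5 A cutoff into profile metadata", {
  ens <- miniEnsemble(rbind(c(0, 0, 2)))
  prof <- residueContactProfile(ens)
  expect_equal(prof@params@cutoff, 4.5)
  expect_true(prof@params@strictLessThan)
})

test_that("total contacts are non-decreasing in the cutoff", {
  ens <- randomFrameEnsemble(nLig = 5, nProt = 45, nframes = 4, seed = 9)
  cutoffs <- c(3, 4.5, 6, 8)
  totals <- lapply(cutoffs, function(cut) {
    tab <- contactTable(residueContactProfile(ens, contactParams(cut)))
    setNames(tab$total, paste(tab$resno, tab$resname))
  })
  for (i in seq_along(cutoffs)[-1]) {
    shared <- names(totals[[i - 1]])
    expect_true(all(shared %in% names(totals[[i]])))
    expect_true(all(totals[[i]][shared] >= totals[[i - 1]][shared]))
  }
})

test_that("profiles are invariant to atom order within the topology", {
  ens <- randomFrameEnsemble(nLig = 4, nProt = 30, nframes = 3, seed = 5)
  set.seed(99)
  perm <- sample(nAtoms(ens))
  top <- topology(ens)[perm, ]
  shuffled <- new("StructureEnsemble", topology = top,
                  frames = lapply(ens@frames, function(f) f[perm, ]),
                  source = "t")
  a <- contactTable(residueContactProfile(ens))
  b <- contactTable(residueContactProfile(shuffled))
  a <- a[order(a$resno), ]
  b <- b[order(b$resno), ]
  expect_equal(a$total, b$total)
  expect_equal(a$backbone, b$backbone)
  expect_equal(a$framesWithContact, b$framesWithContact)
})

test_that("profiles add over concatenated ensembles", {
  e1 <- randomFrameEnsemble(nLig = 4, nProt = 30, nframes = 3, seed = 21)
  set.seed(22)
  e2 <- new("StructureEnsemble", topology = topology(e1),
            frames = lapply(1:2, function(i)
              matrix(runif(nAtoms(e1) * 3, 0, 25), ncol = 3)),
            source = "t")
  cat12 <- new("StructureEnsemble", topology = topology(e1),
               frames = c(e1@frames, e2@frames), source = "t")
  key <- function(tab) paste(tab$resno, tab$resname)
  t1 <- contactTable(residueContactProfile(e1))
  t2 <- contactTable(residueContactProfile(e2))
  t12 <- contactTable(residueContactProfile(cat12))
  for (i in seq_len(nrow(t12))) {
    k <- key(t12)[i]
    expect_equal(t12$total[i],
                 sum(t1$total[key(t1) == k], t2$total[key(t2) == k]))
    expect_equal(t12$framesWithContact[i],
                 sum(t1$framesWithContact[key(t1) == k],
                     t2$framesWithContact[key(t2) == k]))
    expect_equal(t12$meanPerFrame[i], t12$total[i] / 5)
  }
})

test_that("residue totals conserve the frame-wise pair count", {
  ens <- randomFrameEnsemble(nLig = 6, nProt = 36, nframes = 5, seed = 13)
  tab <- contactTable(residueContactProfile(ens))
  pairCount <- sum(vapply(seq_len(5), function(f)
    nrow(enumerateContacts(ens, f)), integer(1)))
  expect_equal(sum(tab$total), pairCount)
  expect_equal(tab$total, tab$backbone + tab$sidechain)
})

test_that("differential table compares per-frame means with zero fill", {
  mk <- function(resno, total, nframes, resname = "LEU") {
    tab <- data.frame(chain = "A", resno = resno, insert = "",
                      resname = resname, total = total, backbone = 0L,
                      sidechain = total, framesWithContact = nframes,
                      meanPerFrame = total / nframes,
                      stringsAsFactors = FALSE)
    new("ResidueContactProfile", table = tab, nFrames = as.integer(nframes),
        params = contactParams(), source = "t")
  }
  inh <- mk(c(10L, 11L), c(30L, 12L), 10)   # means 3.0, 1.2
  nat <- mk(c(10L, 12L), c(5L, 8L), 5)      # means 1.0, 1.6
  d <- contactTable(differentialProfile(inh, nat))
  expect_equal(d$delta[d$resno == 10], 2.0)
  expect_equal(d$inhibitorMean[d$resno == 12], 0)   # only in natural
  expect_equal(d$delta[d$resno == 12], -1.6)
  expect_equal(d$naturalMean[d$resno == 11], 0)
})

test_that("differential on a seeded synthetic pair equals the count-map oracle", {
  cfg <- generatorConfig(nResidues = 10, nFrames = 15, seed = 31)
  res <- generateEnsembles(cfg)
  pi_ <- residueContactProfile(res$inhibitor)
  pn <- residueContactProfile(res$natural)
  d <- contactTable(differentialProfile(pi_, pn))
  wi <- bruteProfile(res$inhibitor, 4.5)
  wn <- bruteProfile(res$natural, 4.5)
  for (i in seq_len(nrow(d))) {
    k <- paste(d$chain[i], d$resno[i], d$insert[i], d$resname[i])
    mi <- if (!is.null(wi[[k]])) wi[[k]]["total"] / 15 else 0
    mn <- if (!is.null(wn[[k]])) wn[[k]]["total"] / 15 else 0
    expect_equal(d$inhibitorMean[i], unname(mi))
    expect_equal(d$delta[i], unname(mi - mn))
  }
})

test_that("mismatched contact parameters are a configuration error", {
  ens <- miniEnsemble(rbind(c(0, 0, 2)))
  a <- residueContactProfile(ens, contactParams(4.5))
  b <- residueContactProfile(ens, contactParams(6.0))
  expect_error(differentialProfile(a, b), "different contact parameters")
})

test_that("profile TSV export round-trips totals", {
  cfg <- generatorConfig(nResidues = 8, nFrames = 10, seed = 17)
  prof <- residueContactProfile(generateEnsembles(cfg)$inhibitor)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeContactTSV(prof, f)
  back <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(back$total, contactTable(prof)$total)
  expect_equal(back$mean_per_frame, contactTable(prof)$meanPerFrame)
  expect_true(all(back$n_frames == nFrames(prof)))
})
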