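test_that("sequence extraction is the identity for untouched founder haplotypes", {
  panel <- tinyPanel(divergence = 0.5)
  m0 <- parseModel(c("pop A founder size=4", "pop B founder size=4"))
  g <- hotGenome()
  sim <- runSimulation(panel, m0, g, seed = 1)
  ex <- extractSequences(populations(sim)[["g0.B"]], panel, g)
  expect_identical(unname(ex$haplotypes),
                   unname(haplotypeMatrix(panel)[9:16, ]))
  expect_identical(ex$snv$pos, snvTable(panel)$pos)
})

test_that("a single breakpoint splits alleles by the half-open convention", {
  panel <- tinyPanel(divergence = 1)  # diagnostic sites
  snv <- snvTable(panel)
  cut <- snv$pos[6] - 1  # 0-based position of the 6th SNV: sites >= cut flip
  hap <- list(starts = c(0, cut), labels = c(0L, 8L),
              breakpoints = c(cut), mutations = numeric(0), sel = integer(0))
  ind <- list(sex = 0L, haps = list(list(hap)))
  st <- new("PopulationState", pop = "ADM", generation = 1L,
            individuals = list(ind))
  ex <- extractSequences(st, panel, hotGenome())
  H <- haplotypeMatrix(panel)
  expect_identical(unname(ex$haplotypes[1, ]),
                   unname(c(H[1, 1:5], H[9, 6:12])))
})

test_that("mutations flip matched SNVs and surface as sorted derived-singleton columns", {
  panel <- tinyPanel()
  snv <- snvTable(panel)
  hap <- list(starts = 0, labels = 0L, breakpoints = numeric(0),
              mutations = sort(c(snv$pos[4] - 1, 123456.0)), sel = integer(0))
  st <- new("PopulationState", pop = "ADM", generation = 2L,
            individuals = list(list(sex = 0L, haps = list(list(hap)))))
  ex <- extractSequences(st, panel, hotGenome())
  expect_identical(nrow(ex$snv), nrow(snv) + 1L)
  expect_false(is.unsorted(ex$snv$pos))
  newRow <- ex$snv[ex$snv$pos == 123457, ]
  expect_identical(newRow$ancestral, "0")
  expect_identical(newRow$derived, "1")
  expect_identical(ex$haplotypes[1, which(ex$snv$pos == 123457)], 1L)
  flipCol <- which(ex$snv$pos == snv$pos[4])
  expect_identical(ex$haplotypes[1, flipCol],
                   1L - haplotypeMatrix(panel)[1, 4])
})

test_that("tracks merge same-ancestry neighbours, tile the chromosome, and keep proportions invariant", {
  panel <- tinyPanel()
  m <- tinyModel(adm = 10L, gens = 4L)
  g <- hotGenome(recRate = 5e-6)
  sim <- runSimulation(panel, m, g, seed = 4)
  trk <- ancestryTracks(sim, which = "g4.ADM")
  seg <- ancestryTracks(sim, which = "g4.ADM", merge = FALSE)
  expect_true(all(trk$ancestry %in% c("A", "B")))
  for (id in unique(trk$hap)) {
    tt <- trk[trk$hap == id, ]
    expect_equal(sum(tt$end - (tt$start - 1)), 1e6)
    expect_false(any(tt$ancestry[-1] == tt$ancestry[-nrow(tt)]))
    ss <- seg[seg$hap == id, ]
    expect_gte(nrow(ss), nrow(tt))
  }
  expect_equal(segmentLengthProportions(trk), segmentLengthProportions(seg))
  # founder haplotype: a single track over [0, L)
  m0 <- parseModel(c("pop A founder size=4", "pop B founder size=4"))
  sim0 <- runSimulation(panel, m0, g, seed = 1)
  trk0 <- ancestryTracks(sim0, which = "g0.A")
  expect_identical(nrow(trk0[trk0$hap == trk0$hap[1], ]), 1L)
  expect_equal(unname(segmentLengthProportions(trk0)["A"]), 1.0)
})

test_that("selected-allele frequencies are exact haplotype-count fractions, X-aware", {
  panel <- tinyPanel(sexed = TRUE, chrom = "X")
  snv <- snvTable(panel)
  selp <- snv$pos[6]
  m <- parseModel(c(tinyModelLines(adm = 10L, gens = 2L),
                    sprintf("sel ADM chrom=X pos=%d allele=1 s=0.2", selp)))
  g <- hotGenome(chrom = "X", type = "X")
  sim <- runSimulation(panel, m, g, seed = 6)
  fr <- alleleFrequencies(sim)
  fr <- fr[fr$pop == "ADM", ]
  st2 <- populations(sim)[["g2.ADM"]]
  nm <- sum(vapply(st2@individuals, function(i) i$sex, 0L) == 1L)
  nf <- nIndividuals(st2) - nm
  row <- fr[fr$gen == 2L, ]
  expect_identical(row$nhap, 2L * nf + nm)
  expect_equal(row$freq * row$nhap, round(row$freq * row$nhap))
  expect_true(all(fr$freq >= 0 & fr$freq <= 1))
  # founder frequency is exact by construction (males: one X row counts)
  sexA <- individualTable(panel)$sex[1:4]
  rows <- unlist(lapply(1:4, function(i)
    if (sexA[i] == 1L) 2L * i - 1L else c(2L * i - 1L, 2L * i)))
  f0 <- alleleFrequencies(sim)
  f0 <- f0[f0$gen == 0L & f0$pop == "A", ]
  expect_equal(f0$freq, mean(haplotypeMatrix(panel)[rows, 6]))
})
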