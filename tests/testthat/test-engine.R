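test_that("founder labels are consecutive per population, 0..2N-1 overall", {
  panel <- tinyPanel(sizes = c(A = 2L, B = 3L))
  r <- founderLabelRanges(panel)
  expect_identical(r$first, c(0L, 4L))
  expect_identical(r$last, c(3L, 9L))
  # one individual -> labels {0, 1}
  r1 <- founderLabelRanges(tinyPanel(sizes = c(Z = 1L)))
  expect_identical(c(r1$first, r1$last), c(0L, 1L))
  # the engine seeds every founder chromosome as one full-length segment
  m <- parseModel(c("pop A founder size=2", "pop B founder size=3"))
  sim <- runSimulation(panel, m, hotGenome(), seed = 1)
  labs <- unlist(lapply(names(populations(sim)), function(nm)
    vapply(haplotypeList(populations(sim)[[nm]]), function(h) h$labels, 0L)))
  expect_setequal(sort(unique(labs)), 0:9)
})

test_that("source sampling follows the cumulative-threshold rule with right-cell ties", {
  p <- c(0.2, 0.1, 0.7)
  expect_identical(sampleSourcePopulation(p, 0.15), 1L)
  expect_identical(sampleSourcePopulation(p, 0.25), 2L)
  expect_identical(sampleSourcePopulation(p, 0.95), 3L)
  q <- c(0.25, 0.25, 0.5)   # exactly representable thresholds
  expect_identical(sampleSourcePopulation(q, 0.25), 2L)  # tie -> right cell
  expect_identical(sampleSourcePopulation(q, 0.5), 3L)
  expect_error(sampleSourcePopulation(numeric(0), 0.5), "empty")
  expect_error(sampleSourcePopulation(c(0.5, 0.4), 0.5), "sum to 1")
})

test_that("additive fitness is 1 + s per satisfying haplotype, floored at zero", {
  rule <- function(s) list(chrom = 0L, posIdx = 0L, allele = 1L, pop = -1L,
                           sex = 0L, g1 = 1L, g2 = 10L, s = s)
  both <- list(sex = 0L, haps = list(list(list(sel = 1L), list(sel = 1L))))
  one <- list(sex = 0L, haps = list(list(list(sel = 1L), list(sel = 0L))))
  none <- list(sex = 0L, haps = list(list(list(sel = 0L), list(sel = 0L))))
  expect_equal(computeFitness(both, list(rule(0.1)), 1), 1.2)
  expect_equal(computeFitness(one, list(rule(0.1)), 1), 1.1)
  expect_equal(computeFitness(none, list(rule(0.1)), 1), 1.0)
  expect_equal(computeFitness(both, list(), 1), 1.0)
  expect_equal(computeFitness(both, list(rule(-0.75)), 1), 0.0)  # rescaled
  # out-of-window and wrong-sex rules contribute nothing
  expect_equal(computeFitness(both, list(rule(0.1)), 11), 1.0)
  r2 <- rule(0.1); r2$sex <- 2L
  expect_equal(computeFitness(both, list(r2), 1), 1.0)
  # a multi-locus rule requires every position on the same haplotype
  rml <- list(chrom = 0L, posIdx = c(0L, 1L), allele = c(1L, 1L), pop = -1L,
              sex = 0L, g1 = 1L, g2 = 10L, s = 0.1)
  mixed <- list(sex = 0L, haps = list(list(list(sel = c(1L, 0L)),
                                           list(sel = c(0L, 1L)))))
  expect_equal(computeFitness(mixed, list(rml), 1), 1.0)
})

test_that("a gamete over zero genetic length is an exact copy of one parental haplotype", {
  hapA <- list(starts = 0, labels = 0L, breakpoints = numeric(0),
               mutations = c(5), sel = integer(0))
  hapB <- list(starts = c(0, 300), labels = c(2L, 3L), breakpoints = c(300),
               mutations = numeric(0), sel = integer(0))
  g0 <- GenomeSpec("1", lengths = 1000, recRate = 0, mutRate = 0)
  set.seed(1)
  for (i in 1:10) {
    gam <- makeGamete(hapA, hapB, g0)
    expect_true(identical(gam[1:4], hapA[1:4]) || identical(gam[1:4], hapB[1:4]))
  }
})

test_that("mutation draws follow the documented order, toggle on double hits, and vanish at mu = 0", {
  hap <- list(starts = 0, labels = 0L, breakpoints = numeric(0),
              mutations = 0, sel = integer(0))
  gOne <- GenomeSpec("1", lengths = 1, recRate = 0, mutRate = 1)
  for (sd in 1:6) {  # L = 1 forces every hit onto position 0
    set.seed(sd); m <- rpois(1, 1)
    set.seed(sd); out <- applyMutations(hap, gOne)
    expect_identical(length(out$mutations), as.integer((1 + m) %% 2))
  }
  gZero <- GenomeSpec("1", lengths = 1000, recRate = 0, mutRate = 0)
  set.seed(9)
  expect_identical(applyMutations(hap, gZero)$mutations, hap$mutations)
  # expected new mutations in one meiosis is mu * L
  gMu <- GenomeSpec("1", lengths = 1e6, recRate = 0, mutRate = 1e-4)
  set.seed(42)
  n <- replicate(400, length(applyMutations(list(starts = 0, labels = 0L,
    breakpoints = numeric(0), mutations = numeric(0), sel = integer(0)),
    gMu)$mutations))
  expect_lt(abs(mean(n) - 100) / (sd(n) / sqrt(length(n))), 4)
})

test_that("segments always tile [0, L) and junctions appear in the breakpoint list", {
  panel <- tinyPanel()
  m <- tinyModel(adm = 10L, gens = 4L)
  g <- hotGenome(recRate = 5e-6)  # ~5 crossovers per meiosis
  for (sd in 1:3) {
    sim <- runSimulation(panel, m, g, seed = sd)
    for (st in populations(sim)) {
      for (h in haplotypeList(st)) {
        expect_identical(h$starts[1], 0)
        expect_identical(length(h$starts), length(h$labels))
        if (length(h$starts) > 1) {
          expect_true(all(diff(h$starts) > 0))
          expect_true(all(h$starts[-1] %in% h$breakpoints))
        }
        expect_true(all(h$starts >= 0 & h$starts < 1e6))
        expect_false(is.unsorted(h$breakpoints))
      }
    }
  }
})

test_that("labels of a never-contributing population never appear downstream", {
  panel <- tinyPanel(sizes = c(A = 3L, B = 3L, C = 3L))
  m <- parseModel(c("pop A founder size=3", "pop B founder size=3",
                    "pop C founder size=3",
                    "gen 1: ADM size=12 from A:0.5,B:0.5",
                    "out gen=4 pop=ADM n=6"))
  ranges <- founderLabelRanges(panel)
  cRange <- ranges$first[3]:ranges$last[3]
  for (sd in 1:3) {
    sim <- runSimulation(panel, m, hotGenome(recRate = 5e-6), seed = sd)
    labs <- unlist(lapply(haplotypeList(populations(sim)[["g4.ADM"]]),
                          function(h) h$labels))
    expect_length(intersect(labs, cRange), 0)
  }
})

test_that("offspring counts match the model and monoecious parents are distinct", {
  panel <- tinyPanel()
  m <- tinyModel(adm = 9L, gens = 2L)
  sim <- runSimulation(panel, m, hotGenome(), seed = 5)
  expect_identical(nIndividuals(populations(sim)[["g2.ADM"]]), 9L)
  cen <- sim@census
  expect_identical(cen$size[cen$pop == "ADM"], c(9L, 9L))
  # a single-individual monoecious population cannot mate with itself
  p1 <- tinyPanel(sizes = c(A = 1L))
  m1 <- parseModel(c("pop A founder size=1", "gen 1: A size=1 from A:1"))
  expect_error(runSimulation(p1, m1, hotGenome(), seed = 1),
               "at least two individuals")
  # size-2 population: offspring exist, so the two parents were distinct
  p2 <- tinyPanel(sizes = c(A = 2L))
  m2 <- parseModel(c("pop A founder size=2", "gen 1: A size=6 from A:1"))
  expect_identical(nIndividuals(populations(
    runSimulation(p2, m2, hotGenome(), seed = 1))[["g1.A"]]), 6L)
})

test_that("runs are deterministic given a seed and trivial with zero generations", {
  panel <- tinyPanel()
  m <- tinyModel(adm = 8L, gens = 3L)
  g <- hotGenome()
  s1 <- runSimulation(panel, m, g, seed = 77)
  s2 <- runSimulation(panel, m, g, seed = 77)
  expect_identical(populations(s1), populations(s2))
  expect_identical(alleleFrequencies(s1), alleleFrequencies(s2))
  s3 <- runSimulation(panel, m, g, seed = 78)
  expect_false(identical(populations(s1), populations(s3)))
  # zero generations: founders pass through unchanged
  m0 <- parseModel(c("pop A founder size=4", "pop B founder size=4"))
  sim0 <- runSimulation(panel, m0, g, seed = 1)
  ex <- extractSequences(populations(sim0)[["g0.A"]], panel, g)
  expect_identical(unname(ex$haplotypes),
                   unname(haplotypeMatrix(panel)[1:8, ]))
})

test_that("X transmission: sons carry one maternal X, daughters get the paternal X intact", {
  panel <- tinyPanel(sexed = TRUE, chrom = "X")
  m <- tinyModel(adm = 12L, gens = 1L)
  g <- hotGenome(chrom = "X", type = "X", recRate = 5e-6, mutRate = 0)
  sim <- runSimulation(panel, m, g, seed = 3)
  st <- populations(sim)[["g1.ADM"]]
  ranges <- founderLabelRanges(panel)
  maleLabels <- unlist(lapply(which(individualTable(panel)$sex == 1L),
                              function(i) 2L * i - 2L))  # males' single X label
  for (ind in st@individuals) {
    nh <- length(ind$haps[[1]])
    if (ind$sex == 1L) {
      expect_identical(nh, 1L)
    } else {
      expect_identical(nh, 2L)
      # paternal X (second gamete) is copied without new recombination:
      # a single full-length segment with a male founder label
      pat <- ind$haps[[1]][[2]]
      expect_identical(length(pat$starts), 1L)
      expect_true(pat$labels %in% maleLabels)
    }
  }
})

test_that("reproduceGeneration steps one generation with the engine's sampling rules", {
  panel <- tinyPanel()
  m <- tinyModel(adm = 7L, gens = 1L)
  sim0 <- runSimulation(panel, parseModel(c("pop A founder size=4",
                                            "pop B founder size=4")),
                        hotGenome(), seed = 2)
  prev <- list(A = populations(sim0)[["g0.A"]], B = populations(sim0)[["g0.B"]])
  set.seed(10)
  nxt <- reproduceGeneration(prev, m, 1L, hotGenome(), snv = snvTable(panel))
  expect_identical(nIndividuals(nxt$ADM), 7L)
  # matches a full run at the same seed (the run draws identically)
  simFull <- runSimulation(panel, m, hotGenome(), seed = 10)
  expect_identical(nxt$ADM@individuals[[1]],
                   populations(simFull)[["g1.ADM"]]@individuals[[1]])
})
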