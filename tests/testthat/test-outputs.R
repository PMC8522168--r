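test_that("a no-event run writes outputs that re-ingest to the founder panel", {
  panel <- tinyPanel(divergence = 0.5)
  m0 <- parseModel(c("pop A founder size=4", "pop B founder size=4"))
  g <- hotGenome(mutRate = 0, recRate = 0)
  sim <- runSimulation(panel, m0, g, seed = 1)
  prefix <- tempfile()
  paths <- writeSimOutputs(sim, panel, prefix)
  expect_true(all(file.exists(paths[c("hap", "ind", "snv", "freq", "trk",
                                      "log")])))
  back <- readFounderPanel(paths["hap"], paths["ind"], paths["snv"])
  expect_identical(haplotypeMatrix(back), haplotypeMatrix(panel))
  expect_identical(snvTable(back)$pos, snvTable(panel)$pos)
  # chaining: outputs seed a subsequent simulation under a new model
  m2 <- parseModel(c("pop A founder size=4", "pop B founder size=4",
                     "gen 1: ADM size=6 from A:0.5,B:0.5"))
  sim2 <- runSimulation(back, m2, hotGenome(), seed = 2)
  expect_identical(nIndividuals(populations(sim2)[["g1.ADM"]]), 6L)
})

test_that("updated SNV files gain de novo sites and track lengths tile the chromosome", {
  panel <- tinyPanel()
  m <- tinyModel(adm = 10L, gens = 3L)
  g <- hotGenome(mutRate = 5e-6)    # ~5 de novo per meiosis
  sim <- runSimulation(panel, m, g, seed = 8)
  prefix <- tempfile()
  paths <- writeSimOutputs(sim, panel, prefix)
  upd <- read.table(paths["snv"], sep = "\t")
  expect_gt(nrow(upd), nrow(snvTable(panel)))
  expect_false(is.unsorted(upd[[2]], strictly = TRUE))
  hapLines <- readLines(paths["hap"])
  expect_true(all(nchar(hapLines) == nrow(upd)))
  trk <- read.table(paths["trk"], sep = "\t",
                    col.names = c("hap", "chrom", "start", "end", "ancestry"))
  tot <- tapply(trk$end - (trk$start - 1), trk$hap, sum)
  expect_true(all(tot == 1e6))
  # log carries the seed and the census
  log <- readLines(paths["log"])
  expect_true(any(grepl("seed: 8", log)))
  expect_true(any(grepl("ADM", log)))
})

test_that("output directives sample without replacement and reject oversampling", {
  panel <- tinyPanel()
  m <- parseModel(c("pop A founder size=4", "pop B founder size=4",
                    "gen 1: ADM size=10 from A:0.5,B:0.5",
                    "out gen=1 pop=ADM n=4"))
  sim <- runSimulation(panel, m, hotGenome(), seed = 3)
  prefix <- tempfile()
  set.seed(1)
  writeSimOutputs(sim, panel, prefix)
  ind <- read.table(paste0(prefix, ".ind"), sep = "\t")
  expect_identical(nrow(ind), 4L)
  expect_identical(length(unique(ind[[1]])), 4L)
  mBad <- m
  mBad@directives$n <- 99L
  simBad <- sim
  simBad@model <- mBad
  expect_error(writeSimOutputs(simBad, panel, tempfile()),
               "exceeds population size")
})

test_that("X-chromosome outputs are hemizygous for males and re-ingest cleanly", {
  panel <- tinyPanel(sexed = TRUE, chrom = "X")
  m <- parseModel(c("pop A founder size=4", "pop B founder size=4",
                    "gen 1: ADM size=8 from A:0.5,B:0.5",
                    "gen 1: A size=2,2 from A:1", "gen 1: B size=2,2 from B:1",
                    "gen 2: ADM size=8 from ADM:1",
                    "gen 2: A size=2,2 from A:1", "gen 2: B size=2,2 from B:1",
                    "out gen=2 pop=ADM n=4"))
  g <- hotGenome(chrom = "X", type = "X")
  sim <- runSimulation(panel, m, g, seed = 4)
  prefix <- tempfile()
  paths <- writeSimOutputs(sim, panel, prefix)
  ind <- read.table(paths["ind"], sep = "\t",
                    col.names = c("id", "pop", "sex"))
  nM <- sum(ind$sex == 1L)
  hapLines <- readLines(paths["hap"])
  expect_identical(length(hapLines), 2L * nrow(ind) - nM)
  back <- readFounderPanel(paths["hap"], paths["ind"], paths["snv"],
                           xHemizygous = TRUE)
  expect_identical(nrow(haplotypeMatrix(back)), 2L * nrow(ind))
})
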