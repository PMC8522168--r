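test_that("a hybrid-isolation block normalizes to one admixture event plus self-continuation", {
  m <- parseModel(c("pop ANC1 founder size=100", "pop ANC2 founder size=100",
                    "gen 1: ADM size=5000 from ANC1:0.8,ANC2:0.2",
                    "out gen=50 pop=ADM n=500"))
  expect_s4_class(m, "DemographicModel")
  expect_identical(m@endGen, 50L)
  adm <- match("ADM", m@registry) - 1L
  row1 <- Filter(function(r) r$pop == adm, m@events[[1]])[[1]]
  expect_equal(m@registry[row1$src + 1L], c("ANC1", "ANC2"))
  expect_equal(row1$prop, c(0.8, 0.2))
  expect_equal(cumsum(row1$prop), c(0.8, 1.0))
  for (g in 2:50) {
    row <- Filter(function(r) r$pop == adm, m@events[[g]])[[1]]
    expect_identical(m@registry[row$src + 1L], "ADM")
    expect_equal(row$prop, 1)
    expect_identical(row$size, 5000L)
  }
  # founder populations persist with 100% self-contribution
  a1 <- Filter(function(r) r$pop == 0L, m@events[[25]])[[1]]
  expect_identical(a1$src, 0L)
  expect_equal(a1$prop, 1)
})

test_that("three-way proportions yield the cumulative thresholds 0.2, 0.3, 1.0", {
  m <- parseModel(c("pop P1 founder size=2", "pop P2 founder size=2",
                    "pop P3 founder size=2",
                    "gen 1: ADM size=10 from P1:0.2,P2:0.1,P3:0.7"))
  row <- Filter(function(r) r$pop == 3L, m@events[[1]])[[1]]
  expect_equal(cumsum(row$prop), c(0.2, 0.3, 1.0))
})

test_that("an empty selection section leaves zero rules and unit fitness", {
  m <- tinyModel()
  expect_length(m@rules, 0)
  ind <- list(sex = 0L, haps = list(list(list(sel = integer(0)))))
  expect_equal(computeFitness(ind, list(), 1), 1)
})

test_that("model validation errors name the offending line", {
  bad <- c("pop A founder size=2", "gen 1: ADM size=4 from A:0.9")
  expect_error(parseModel(bad), "line 2.*sum to 0\\.9")
  expect_error(parseModel(c("pop A founder size=2",
                            "gen 1: ADM size=4 from GHOST:1")),
               "undeclared or extinct source population 'GHOST'")
  expect_error(parseModel(c("pop A founder size=2",
                            "gen 3: ADM size=4 from A:1",
                            "gen 2: ADM size=4 from ADM:1")),
               "non-monotone generation numbers")
  expect_error(parseModel(c("pop A founder size=2",
                            "gen 1: ADM size=4 from A:1",
                            "sel NOPE chrom=1 pos=5 allele=1 s=0.1")),
               "not a known population")
})

test_that("model normalization is idempotent and proportions always sum to 1", {
  lines <- c("pop A founder size=3", "pop B founder size=5",
             "gen 1: ADM size=20 from A:0.25,B:0.75",
             "gen 5: ADM size=40 from ADM:0.9,A:0.1",
             "gen 8: B size=0 from B:1",
             "out gen=10 pop=ADM n=10")
  m1 <- parseModel(lines)
  tmp <- tempfile(fileext = ".mod")
  writeModel(m1, tmp)
  m2 <- readModel(tmp)
  expect_identical(m2@events, m1@events)
  expect_identical(m2@registry, m1@registry)
  expect_identical(m2@directives, m1@directives)
  for (g in seq_along(m1@events))
    for (row in m1@events[[g]])
      expect_lt(abs(sum(row$prop) - 1), 1e-9)
  # B is gone after its size drops to zero
  popsAt10 <- vapply(m1@events[[10]], function(r) m1@registry[r$pop + 1L], "")
  expect_false("B" %in% popsAt10)
})

test_that("selection rules round-trip with scope, range and schedule intact", {
  lines <- c("pop A founder size=3",
             "gen 1: ADM size=10 from A:1",
             "sel ADM chrom=1 pos=100-200 allele=1 s=0.05@2-6 sex=F",
             "sel * chrom=1 pos=10,40 allele=1,0 s=-0.25",
             "out gen=6 pop=ADM n=5")
  m1 <- parseModel(lines)
  expect_length(m1@rules, 2)
  expect_identical(m1@rules[[1]]$sex, 2L)
  expect_identical(m1@rules[[1]]$g1, 2L)
  expect_identical(m1@rules[[1]]$g2, 6L)
  expect_equal(m1@rules[[2]]$allele, c(1L, 0L))
  tmp <- tempfile(fileext = ".mod")
  writeModel(m1, tmp)
  m2 <- readModel(tmp)
  expect_identical(m2@rules, m1@rules)
})

test_that("founder files round-trip and malformed input is rejected with coordinates", {
  panel <- tinyPanel(divergence = 0.5)
  prefix <- tempfile()
  writeFounderPanel(panel, prefix)
  back <- readFounderPanel(paste0(prefix, ".hap"), paste0(prefix, ".ind"),
                           paste0(prefix, ".snv"))
  expect_identical(haplotypeMatrix(back), haplotypeMatrix(panel))
  expect_identical(individualTable(back), individualTable(panel))
  expect_equal(snvTable(back)$pos, snvTable(panel)$pos)

  # 2 individuals x 3 SNVs -> 4 x 3 matrix
  h <- tempfile(); i <- tempfile(); s <- tempfile()
  writeLines(c("010", "110", "001", "000"), h)
  writeLines(c("i1\tP\t0", "i2\tP\t0"), i)
  writeLines(c("1\t10\tA\tG", "1\t20\tA\tG", "1\t30\tA\tG"), s)
  p <- readFounderPanel(h, i, s)
  expect_identical(dim(haplotypeMatrix(p)), c(4L, 3L))

  writeLines(c("010", "1x0", "001", "000"), h)
  expect_error(readFounderPanel(h, i, s), "row 2 column 2")
  writeLines(c("010", "110", "001"), h)
  expect_error(readFounderPanel(h, i, s), "odd number of rows")
  writeLines(c("010", "110", "001", "000", "011", "100"), h)
  expect_error(readFounderPanel(h, i, s), "6 rows")
})

test_that("sex codes switch on dioecious mode and a mapless SNV table gets a uniform map", {
  h <- tempfile(); i <- tempfile(); s <- tempfile()
  writeLines(c("01", "11", "00", "10"), h)
  writeLines(c("i1\tP\t1", "i2\tP\t2"), i)
  writeLines(c("1\t100\tA\tG", "1\t900\tC\tT"), s)
  p <- readFounderPanel(h, i, s)
  expect_true(any(individualTable(p)$sex != 0L))
  g <- GenomeSpec(snv = p, lengths = 1000, recRate = 1e-3)
  expect_equal(geneticLength(g, snv = snvTable(p)), 1e-3 * 1000)
  # with a gpos column the map follows the SNV table instead
  writeLines(c("1\t100\tA\tG\t0.01", "1\t900\tC\tT\t0.05"), s)
  p2 <- readFounderPanel(h, i, s)
  g2 <- GenomeSpec(snv = p2, lengths = 1000, recRate = 1e-3)
  expect_gt(geneticLength(g2, snv = snvTable(p2)), 0.05)
})
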