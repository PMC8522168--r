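test_that("synthetic founder panels have the contracted shape and are seed-stable", {
  p <- simulateFounderPanel(c(P1 = 100L, P2 = 100L), nSnv = 200,
                            length = 3e8, seed = 2)
  expect_identical(dim(haplotypeMatrix(p)), c(400L, 200L))
  expect_identical(nrow(individualTable(p)), 200L)
  expect_false(is.unsorted(snvTable(p)$pos, strictly = TRUE))
  prefix1 <- tempfile(); prefix2 <- tempfile()
  writeFounderPanel(simulateFounderPanel(c(A = 5L, B = 5L), 30, 1e6, seed = 9),
                    prefix1)
  writeFounderPanel(simulateFounderPanel(c(A = 5L, B = 5L), 30, 1e6, seed = 9),
                    prefix2)
  for (ext in c(".hap", ".ind", ".snv"))
    expect_identical(readLines(paste0(prefix1, ext)),
                     readLines(paste0(prefix2, ext)))
})

test_that("full divergence makes every site diagnostic of its owner population", {
  p <- simulateFounderPanel(c(A = 10L, B = 10L), nSnv = 20, length = 1e6,
                            divergence = 1, seed = 4)
  H <- haplotypeMatrix(p)
  own <- (seq_len(20) - 1L) %% 2L + 1L   # site owner alternates A, B
  for (j in seq_len(20)) {
    expect_true(all(H[1:20, j] == as.integer(own[j] == 1L)))
    expect_true(all(H[21:40, j] == as.integer(own[j] == 2L)))
  }
})

test_that("every scenario bundle validates and runs end-to-end at desk scale", {
  for (nm in c("hi_4to1_50g", "x_vs_autosome", "afram_11g", "mexican_18g",
               "uyghur_150g", "selection_grid")) {
    sc <- buildScenario(nm, size = 60L, nSnv = 30L, generations = 3L,
                        founderSize = 20L, seed = 2)
    expect_identical(sc$name, nm)
    expect_true(validObject(sc$panel))
    expect_true(validObject(sc$model))
    sim <- runSimulation(sc$panel, sc$model, sc$genome, seed = 2)
    st <- populations(sim)[["g3.ADM"]]
    expect_identical(nIndividuals(st), 60L)
  }
  expect_error(buildScenario("nope"), "hi_4to1_50g")
})

test_that("scenario parameters encode the stated study conditions", {
  hi <- buildScenario("hi_4to1_50g")
  expect_equal(unname(hi$params$proportions), c(0.8, 0.2))
  expect_identical(hi$params$generations, 50L)
  expect_equal(hi$params$L, 3e8)
  expect_equal(geneticLength(hi$genome), 3)       # 3 Morgan at 1e-8/bp
  af <- buildScenario("afram_11g")
  expect_equal(unname(af$params$proportions), c(0.246, 0.754))
  expect_identical(af$params$generations, 11L)
  mx <- buildScenario("mexican_18g")
  expect_equal(unname(mx$params$proportions), c(0.512, 0.052, 0.436))
  x <- buildScenario("x_vs_autosome")
  expect_identical(chromTable(x$genome)$type, "X")
  expect_true(any(individualTable(x$panel)$sex != 0L))
  # selection grid: exact initial frequency at the selected site
  sg <- buildScenario("selection_grid", x0 = 0.1, s = 0.03)
  snv <- snvTable(sg$panel)
  col <- which(snv$pos == sg$params$selPos)
  expect_equal(mean(haplotypeMatrix(sg$panel)[, col]), 0.1)
  expect_length(sg$model@rules, 1)
  expect_equal(sg$model@rules[[1]]$s, 0.03)
})
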