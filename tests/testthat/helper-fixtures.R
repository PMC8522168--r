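# Shared toy fixtures, built in code.

tinyPanel <- function(sizes = c(A = 4L, B = 4L), nSnv = 12L, length = 1e6,
                      divergence = 1, sexed = FALSE, chrom = "1", seed = 3L) {
  simulateFounderPanel(sizes, nSnv = nSnv, length = length,
                       divergence = divergence, sexed = sexed, chrom = chrom,
                       seed = seed)
}

tinyModelLines <- function(adm = 6L, gens = 3L, props = c(A = 0.5, B = 0.5),
                           extra = character(0)) {
  c("pop A founder size=4", "pop B founder size=4",
    sprintf("gen 1: ADM size=%d from %s", adm,
            paste(sprintf("%s:%g", names(props), props), collapse = ",")),
    extra,
    sprintf("out gen=%d pop=ADM n=%d", gens, min(adm, 4L)))
}

tinyModel <- function(...) parseModel(tinyModelLines(...))

hotGenome <- function(length = 1e6, recRate = 2e-6, mutRate = 2e-6,
                      chrom = "1", type = "autosome") {
  GenomeSpec(chrom, lengths = length, types = type, recRate = recRate,
             mutRate = mutRate)
}

# engine output vs per-site oracle: compare SNV alleles and non-SNV de novo
# position sets for one retained state
expectOracleMatch <- function(panel, model, genome, seed, state = NULL) {
  sim <- runSimulation(panel, model, genome, seed = seed)
  orc <- perSiteSimulate(panel, model, genome, seed = seed)
  nm <- if (is.null(state)) names(orc)[grepl("ADM", names(orc))][1] else state
  st <- populations(sim)[[nm]]
  ex <- extractSequences(st, panel, genome)
  snv <- snvTable(panel)
  key <- paste(ex$snv$chrom, ex$snv$pos)
  eng <- ex$haplotypes[, match(paste(snv$chrom, snv$pos), key), drop = FALSE]
  expect_identical(unname(eng), unname(orc[[nm]]$alleles))
  hl <- haplotypeList(st)
  engExtra <- lapply(hl, function(h)
    as.numeric(sort(setdiff(h$mutations, snv$pos - 1))))
  expect_identical(unname(engExtra),
                   lapply(orc[[nm]]$extra, as.numeric))
  expect_identical(vapply(st@individuals, function(i) i$sex, 0L),
                   orc[[nm]]$sexes)
  invisible(sim)
}
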