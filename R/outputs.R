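#' @include AllClasses.R ancestry.R
NULL

#' Write the six simulation output files
#'
#' Writes, under `prefix`: the haplotype (`.hap`), individual (`.ind`) and
#' updated SNV (`.snv`) files in the same dialect as the inputs, so a run's
#' output can seed a subsequent simulation with a new demographic model; a
#' selected-allele frequency table (`.freq.tsv`: generation, population,
#' chromosome, position, allele, frequency of the derived allele); ancestry
#' tracks (`.trk.tsv`, same-ancestry segments merged; the raw segment view
#' goes to a seventh file `.seg.tsv`); and a log (`.log`) recording seed,
#' rates and the per-generation census.
#'
#' Which individuals are written follows the model's output directives: for
#' each `out gen=<g> pop=<p> n=<k>` row, `k` individuals are sampled without
#' replacement from the retained state (an error if `k` exceeds the
#' population size).  Without directives, every individual of the final
#' generation is written.  Sampling draws from R's RNG.  On an X-chromosome
#' run, males contribute a single haplotype line (re-ingest with
#' `readFounderPanel(..., xHemizygous = TRUE)`).
#'
#' @param sim an [AdmixRun] result.
#' @param panel the [FounderPanel] the run started from.
#' @param prefix output path prefix.
#' @return Named character vector of the file paths, invisibly.
#' @export
writeSimOutputs <- function(sim, panel, prefix) {
  model <- sim@model
  genome <- sim@genome
  d <- model@directives
  states <- list()
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      nm <- sprintf("g%d.%s", d$gen[i], d$pop[i])
      st <- sim@populations[[nm]]
      if (is.null(st))
        stop("directive asks for ", nm, " but it was not retained")
      if (d$n[i] > length(st@individuals))
        stop(sprintf("sample size %d exceeds population size %d for %s",
                     d$n[i], length(st@individuals), nm))
      pick <- sort(sample.int(length(st@individuals), d$n[i]))
      states[[nm]] <- new("PopulationState", pop = st@pop,
                          generation = st@generation,
                          individuals = st@individuals[pick])
    }
  } else {
    G <- model@endGen
    states <- sim@populations[vapply(sim@populations,
                                     function(s) s@generation == G, TRUE)]
  }
  if (!length(states)) stop("nothing to write: no retained states")

  # union of de novo sites across written states, then one aligned pass
  updSnv <- panel@snv
  for (nm in names(states))
    updSnv <- .mergeSnv(updSnv, extractSequences(states[[nm]], panel, genome)$snv)
  full <- if (nrow(updSnv) > nrow(panel@snv)) .alignPanel(panel, updSnv)
          else panel

  hapLines <- character(0); indTab <- NULL; trk <- NULL; seg <- NULL
  for (nm in names(states)) {
    st <- states[[nm]]
    ex <- extractSequences(st, full, genome)
    hapLines <- c(hapLines, apply(ex$haplotypes, 1, paste, collapse = ""))
    indTab <- rbind(indTab, ex$individuals)
    for (ci in seq_len(nrow(genome@chroms))) {
      tpart <- ancestryTracks(st, chrom = ci, ranges = sim@labelRanges,
                              L = genome@chroms$length[ci])
      spart <- ancestryTracks(st, chrom = ci, merge = FALSE,
                              ranges = sim@labelRanges,
                              L = genome@chroms$length[ci])
      tpart$chrom <- genome@chroms$name[ci]
      spart$chrom <- genome@chroms$name[ci]
      trk <- rbind(trk, tpart); seg <- rbind(seg, spart)
    }
  }

  paths <- c(hap = paste0(prefix, ".hap"), ind = paste0(prefix, ".ind"),
             snv = paste0(prefix, ".snv"), freq = paste0(prefix, ".freq.tsv"),
             trk = paste0(prefix, ".trk.tsv"), log = paste0(prefix, ".log"),
             seg = paste0(prefix, ".seg.tsv"))
  writeLines(hapLines, paths["hap"])
  write.table(indTab, paths["ind"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  .writeSnvTable(updSnv, paths["snv"])
  fr <- sim@frequencies
  freqOut <- data.frame(gen = fr$gen, pop = fr$pop, chrom = fr$chrom,
                        pos = fr$pos, allele = rep(1L, nrow(fr)),
                        freq = fr$freq)
  write.table(freqOut, paths["freq"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(trk, paths["trk"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(seg, paths["seg"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  census <- sim@census
  log <- c(sprintf("AdmixWF %s", as.character(utils::packageVersion("AdmixWF"))),
           sprintf("seed: %d", sim@seed),
           sprintf("recRate: %g Morgan/bp", genome@recRate),
           sprintf("mutRate: %g /site/generation", genome@mutRate),
           sprintf("chromosome: %s %s length %g bp", genome@chroms$name,
                   genome@chroms$type, genome@chroms$length),
           sprintf("generations: %d", model@endGen),
           "census (gen pop size):",
           sprintf("  %d %s %d", census$gen, census$pop, census$size))
  writeLines(log, paths["log"])
  invisible(paths)
}

.writeSnvTable <- function(snv, path) {
  cols <- list(snv$chrom, format(snv$pos, scientific = FALSE, trim = TRUE),
               snv$ancestral, snv$derived)
  if (!is.null(snv$gpos)) cols <- c(cols, list(snv$gpos))
  if (!is.null(snv$mut_rate)) {
    if (is.null(snv$gpos)) cols <- c(cols, list(rep(NA, nrow(snv))))
    cols <- c(cols, list(snv$mut_rate))
  }
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# union of two updated SNV tables (same input panel, different de novo sets)
.mergeSnv <- function(a, b) {
  key <- function(x) paste(x$chrom, x$pos)
  add <- b[!(key(b) %in% key(a)), , drop = FALSE]
  out <- rbind(a, add)
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# widen the founder matrix with all-zero columns at de novo sites so that
# extraction against the union SNV table lines up column-wise
.alignPanel <- function(panel, updSnv) {
  key <- paste(updSnv$chrom, updSnv$pos)
  old <- paste(panel@snv$chrom, panel@snv$pos)
  H <- matrix(0L, nrow(panel@haplotypes), nrow(updSnv))
  H[, match(old, key)] <- panel@haplotypes
  new("FounderPanel", haplotypes = H, snv = updSnv,
      individuals = panel@individuals)
}
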