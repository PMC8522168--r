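#' @include AllClasses.R
NULL

#' Accessors for AdmixWF objects
#'
#' Small accessor generics: `snvTable()` and `individualTable()` return the
#' metadata tables of a [FounderPanel] (or the panel embedded in other
#' objects), `haplotypeMatrix()` the founder allele matrix, `populations()`
#' the retained [PopulationState]s of an [AdmixRun], `alleleFrequencies()`
#' the per-generation selected-allele frequency table, `nIndividuals()` the
#' number of individuals in a state, and `haplotypeList()` the flat list of
#' haplotypes of one chromosome with stable IDs.
#'
#' @param x an AdmixWF object.
#' @param ... passed on to methods.
#' @return The corresponding table, matrix or list; see details above.
#' @name accessors
#' @examples
#' panel <- simulateFounderPanel(sizes = c(A = 3, B = 2), nSnv = 5,
#'                               length = 1e6, seed = 1)
#' dim(haplotypeMatrix(panel))
#' head(snvTable(panel))
NULL

#' @rdname accessors
#' @export
setGeneric("snvTable", function(x) standardGeneric("snvTable"))
#' @rdname accessors
#' @export
setGeneric("individualTable", function(x) standardGeneric("individualTable"))
#' @rdname accessors
#' @export
setGeneric("haplotypeMatrix", function(x) standardGeneric("haplotypeMatrix"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("alleleFrequencies", function(x, ...) standardGeneric("alleleFrequencies"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("haplotypeList", function(x, ...) standardGeneric("haplotypeList"))
#' @rdname accessors
#' @export
setGeneric("labelRanges", function(x) standardGeneric("labelRanges"))

#' @rdname accessors
setMethod("snvTable", "FounderPanel", function(x) x@snv)
#' @rdname accessors
setMethod("individualTable", "FounderPanel", function(x) x@individuals)
#' @rdname accessors
setMethod("haplotypeMatrix", "FounderPanel", function(x) x@haplotypes)
#' @rdname accessors
setMethod("populations", "AdmixRun", function(x) x@populations)
#' @rdname accessors
setMethod("alleleFrequencies", "AdmixRun", function(x, ...) x@frequencies)
#' @rdname accessors
setMethod("nIndividuals", "PopulationState", function(x) length(x@individuals))
#' @rdname accessors
setMethod("labelRanges", "AdmixRun", function(x) x@labelRanges)

#' @rdname accessors
#' @param chrom chromosome index (1-based) within the simulated genome.
setMethod("haplotypeList", "PopulationState", function(x, chrom = 1L) {
  out <- list()
  for (i in seq_along(x@individuals)) {
    ind <- x@individuals[[i]]
    hv <- ind$haps[[chrom]]
    for (k in seq_along(hv))
      out[[sprintf("%s_g%d_i%d_h%d", x@pop, x@generation, i, k)]] <- hv[[k]]
  }
  out
})

#' Per-haplotype breakpoint and mutation counts
#'
#' Tabulates, for every haplotype of one chromosome in a
#' [PopulationState], the number of accumulated recombination breakpoints
#' and de novo mutation positions.  Under a hybrid-isolation model the
#' breakpoint mean approaches (genetic length in Morgan) x (generations) on
#' autosomes and two-thirds of that on the X; the mutation mean is
#' (mutation rate) x (bp length) x (generations).
#'
#' @param state a [PopulationState].
#' @param chrom chromosome index (1-based).
#' @return data.frame with columns `hap`, `nBreakpoints`, `nMutations`.
#' @export
simStats <- function(state, chrom = 1L) {
  hl <- haplotypeList(state, chrom = chrom)
  data.frame(hap = names(hl),
             nBreakpoints = vapply(hl, function(h) length(h$breakpoints), 0L),
             nMutations = vapply(hl, function(h) length(h$mutations), 0L),
             row.names = NULL)
}

setMethod("show", "GenomeSpec", function(object) {
  ch <- object@chroms
  cat(sprintf("GenomeSpec: %d chromosome(s)\n", nrow(ch)))
  for (i in seq_len(nrow(ch)))
    cat(sprintf("  %s  %s  %.4g bp\n", ch$name[i], ch$type[i], ch$length[i]))
  cat(sprintf("  recRate %.3g Morgan/bp, mutRate %.3g /site/gen\n",
              object@recRate, object@mutRate))
})

setMethod("show", "FounderPanel", function(object) {
  ind <- object@individuals
  cat(sprintf("FounderPanel: %d individuals (%d haplotype rows), %d SNVs\n",
              nrow(ind), nrow(object@haplotypes), nrow(object@snv)))
  tab <- table(ind$pop)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (any(ind$sex != 0L)) cat("  dioecious (sexes specified)\n")
})

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel: %d generations, %d population(s)\n",
              object@endGen, length(object@registry)))
  cat("  founders:",
      paste(sprintf("%s (%d)", object@founders, object@founderSizes),
            collapse = ", "), "\n")
  cat(sprintf("  %d selection rule(s), %d output directive(s)\n",
              length(object@rules), nrow(object@directives)))
})

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState: '%s' at generation %d, %d individuals\n",
              object@pop, object@generation, length(object@individuals)))
})

setMethod("show", "AdmixRun", function(object) {
  cat(sprintf("AdmixRun result (seed %d): %d retained population state(s)\n",
              object@seed, length(object@populations)))
  for (nm in names(object@populations)) {
    st <- object@populations[[nm]]
    cat(sprintf("  %s: %d individuals\n", nm, length(st@individuals)))
  }
  if (nrow(object@frequencies))
    cat(sprintf("  %d selected-allele frequency records\n",
                nrow(object@frequencies)))
})
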