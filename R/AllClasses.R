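#' Chromosome layout, genetic map and mutation model for a simulation
#'
#' A `GenomeSpec` describes the chromosomes a simulation runs over: physical
#' length in bp, type (`"autosome"` or `"X"`), the recombination map and the
#' mutation model.  By default the genetic map is uniform at `recRate`
#' Morgan/bp and mutation is uniform at `mutRate` per site per generation;
#' when the founder SNV table carries a `gpos` (Morgan) or `mut_rate` column
#' and `useSnvMap`/`useSnvRates` is `TRUE`, those locus-specific values
#' override the uniform defaults.
#'
#' An X chromosome recombines in female meioses only and may not be mixed
#' with autosomes in the same `GenomeSpec`; simulate the X separately.
#'
#' @slot chroms data.frame with columns `name`, `length` (bp), `type`.
#' @slot recRate uniform recombination rate, Morgan per bp.
#' @slot mutRate uniform mutation rate, per site per generation.
#' @slot useSnvMap use the SNV table's genetic-position column if present.
#' @slot useSnvRates use the SNV table's mutation-rate column if present.
#' @aliases GenomeSpec-class
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(chroms = "data.frame", recRate = "numeric",
                 mutRate = "numeric", useSnvMap = "logical",
                 useSnvRates = "logical"),
  validity = function(object) {
    ch <- object@chroms
    if (!all(c("name", "length", "type") %in% names(ch)))
      return("chroms must have columns name, length, type")
    if (any(duplicated(ch$name))) return("duplicated chromosome names")
    if (any(ch$length <= 0)) return("chromosome lengths must be positive")
    if (!all(ch$type %in% c("autosome", "X")))
      return("chromosome type must be 'autosome' or 'X'")
    if (any(ch$type == "X") && nrow(ch) > 1)
      return("an X chromosome must be simulated on its own GenomeSpec")
    if (object@recRate < 0 || object@mutRate < 0 || object@mutRate > 1)
      return("recRate must be >= 0 and mutRate in [0, 1]")
    TRUE
  })

#' Founder haplotype panel
#'
#' Phased founder haplotypes plus their SNV and individual metadata.  The
#' allele matrix has two consecutive rows per founder individual (in
#' `individuals` order) and one column per SNV record; entries are 0
#' (ancestral) or 1 (derived).  For an X-chromosome simulation, the second
#' row of a male founder is ignored.  Sex codes are 0 = unspecified,
#' 1 = male, 2 = female; any specified sex switches the simulation into
#' dioecious mode.
#'
#' @slot haplotypes integer matrix of 0/1 alleles, `2 * nrow(individuals)`
#'   rows.
#' @slot snv data.frame with columns `chrom`, `pos` (bp, 1-based),
#'   `ancestral`, `derived` and optional `gpos` (Morgan), `mut_rate`.
#' @slot individuals data.frame with columns `id`, `pop`, `sex`.
#' @aliases FounderPanel-class
#' @exportClass FounderPanel
setClass("FounderPanel",
  representation(haplotypes = "matrix", snv = "data.frame",
                 individuals = "data.frame"),
  validity = function(object) {
    H <- object@haplotypes; snv <- object@snv; ind <- object@individuals
    if (nrow(H) != 2L * nrow(ind))
      return("haplotype row count must equal 2 x number of individuals")
    if (ncol(H) != nrow(snv))
      return("haplotype column count must equal number of SNVs")
    if (length(H) && !all(H %in% c(0L, 1L)))
      return("haplotype entries must be 0 or 1")
    if (anyDuplicated(ind$id)) return("individual IDs must be unique")
    if (!all(ind$sex %in% 0:2)) return("sex codes must be 0, 1 or 2")
    for (cc in unique(snv$chrom)) {
      p <- snv$pos[snv$chrom == cc]
      if (any(diff(p) <= 0))
        return(sprintf("SNV positions not strictly increasing on chromosome %s", cc))
      if (!is.null(snv$gpos)) {
        gp <- snv$gpos[snv$chrom == cc]
        if (!anyNA(gp) && any(diff(gp) < 0))
          return(sprintf("genetic positions decreasing on chromosome %s", cc))
      }
    }
    if (!is.null(snv$mut_rate) && !anyNA(snv$mut_rate) &&
        (any(snv$mut_rate < 0) || any(snv$mut_rate > 1)))
      return("mutation rates must lie in [0, 1]")
    if (length(snv$ancestral) && any(snv$ancestral == snv$derived))
      return("ancestral and derived alleles must differ")
    TRUE
  })

#' Demographic model: per-generation sizes, admixture and selection
#'
#' A normalized demographic model: for every generation `1..endGen` and every
#' living population, the resolved size and admixture-proportion vector
#' (optionally sex-specific), plus selection rules and output directives.
#' Populations not mentioned in a generation persist unchanged (same size,
#' 100\% self-contribution).  Built by [readModel()]/[parseModel()].
#'
#' @slot registry character; all population names, founders first, in order
#'   of appearance.
#' @slot founders character; founder population names.
#' @slot founderSizes integer; founder sizes (individuals), parallel to
#'   `founders`.
#' @slot endGen integer; last simulated generation.
#' @slot events list of length `endGen`; element `g` is a list of resolved
#'   rows `list(pop, size, sizeM, sizeF, src, prop, srcF, propF, srcM,
#'   propM)` with 0-based registry indices, ordered by registry index.
#' @slot rules list of selection rules `list(pop, chrom, pos, allele, s,
#'   g1, g2, sex)`; `pos` is a vector of 1-based bp positions.
#' @slot directives data.frame with columns `gen`, `pop`, `n`; populations
#'   to retain (and sample) on output.
#' @aliases DemographicModel-class
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(registry = "character", founders = "character",
                 founderSizes = "integer", endGen = "integer",
                 events = "list", rules = "list", directives = "data.frame"),
  validity = function(object) {
    if (length(object@founders) != length(object@founderSizes))
      return("founders and founderSizes lengths differ")
    if (length(object@events) != object@endGen)
      return("events list must have one element per generation")
    for (g in seq_along(object@events))
      for (row in object@events[[g]]) {
        pr <- row$prop
        if (abs(sum(pr) - 1) > 1e-9)
          return(sprintf("proportions for '%s' at generation %d sum to %.12g, not 1",
                         object@registry[row$pop + 1L], g, sum(pr)))
      }
    TRUE
  })

#' One simulated population at one generation
#'
#' Individuals are lists with elements `sex` and `haps` (per chromosome, a
#' list of one or two haplotypes, each `list(starts, labels, breakpoints,
#' mutations, sel)` in 0-based bp).  Prefer the accessors
#' ([nIndividuals()], [haplotypeList()], [simStats()]) over direct access.
#'
#' @slot pop population name.
#' @slot generation generation index (0 = founders).
#' @slot individuals list of individuals.
#' @aliases PopulationState-class
#' @exportClass PopulationState
setClass("PopulationState",
  representation(pop = "character", generation = "integer",
                 individuals = "list"))

#' Result of a forward simulation
#'
#' Holds the retained [PopulationState]s (all populations of the final
#' generation, plus any (generation, population) pairs named in the model's
#' output directives), per-generation selected-allele frequencies, the
#' census, and enough founder metadata (label ranges) to resolve any founder
#' label to its ancestral population.
#'
#' @slot populations named list of [PopulationState] (`"g<gen>.<pop>"`).
#' @slot frequencies data.frame: `gen`, `pop`, `chrom`, `pos` (1-based bp),
#'   `freq` (derived-allele frequency), `nhap`.
#' @slot census data.frame: `gen`, `pop`, `size`.
#' @slot labelRanges data.frame: `pop`, `first`, `last` founder label.
#' @slot model the [DemographicModel] that was run.
#' @slot genome the [GenomeSpec] that was run.
#' @slot seed integer seed used for the run.
#' @aliases AdmixRun-class
#' @exportClass AdmixRun
setClass("AdmixRun",
  representation(populations = "list", frequencies = "data.frame",
                 census = "data.frame", labelRanges = "data.frame",
                 model = "DemographicModel", genome = "GenomeSpec",
                 seed = "integer"))
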