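#' @include AllClasses.R GenomeSpec.R
NULL

# Resolve model selection rules against the SNV table: positions become
# 0-based, range specs expand to every SNV in the interval, and each
# chromosome gets the sorted union of tracked positions (selPos).
.resolveRules <- function(model, genome, snv) {
  chromNames <- genome@chroms$name
  selPos <- lapply(chromNames, function(x) numeric(0))
  names(selPos) <- chromNames
  rulesPre <- list()
  for (r in model@rules) {
    ci <- match(r$chrom, chromNames)
    if (is.na(ci)) stop("selection rule on unknown chromosome: ", r$chrom)
    onChrom <- snv$pos[snv$chrom == r$chrom]
    if (r$posSpec$type == "range") {
      pos <- onChrom[onChrom >= r$posSpec$from & onChrom <= r$posSpec$to]
      if (!length(pos))
        stop(sprintf("selection interval %g-%g on chromosome %s contains no SNV",
                     r$posSpec$from, r$posSpec$to, r$chrom))
    } else {
      pos <- r$posSpec$pos
      miss <- setdiff(pos, onChrom)
      if (length(miss))
        stop(sprintf("selected position %g on chromosome %s is not in the SNV table",
                     miss[1], r$chrom))
    }
    allele <- r$allele
    if (length(allele) == 1L) allele <- rep(allele, length(pos))
    if (length(allele) != length(pos))
      stop("selection rule allele list length does not match its positions")
    selPos[[ci]] <- sort(unique(c(selPos[[ci]], pos - 1)))
    rulesPre[[length(rulesPre) + 1]] <-
      list(ci = ci, pos0 = pos - 1, allele = allele, pop = r$pop,
           sex = r$sex, g1 = r$g1, g2 = r$g2, s = r$s)
  }
  rulesR <- lapply(rulesPre, function(r) {
    list(chrom = r$ci - 1L,
         posIdx = match(r$pos0, selPos[[r$ci]]) - 1L,
         allele = as.integer(r$allele),
         pop = if (r$pop == "*") -1L else match(r$pop, model@registry) - 1L,
         sex = as.integer(r$sex), g1 = as.integer(r$g1), g2 = as.integer(r$g2),
         s = r$s)
  })
  list(selPos = selPos, rulesR = rulesR)
}

# founder descriptor list handed to C++: per founder population, its size,
# sexes and per-chromosome selected-site allele matrix
.founderDef <- function(panel, model, selPos) {
  ind <- panel@individuals
  ranges <- founderLabelRanges(panel)
  if (!identical(ranges$pop, model@founders))
    stop("founder populations in the individual table (",
         paste(ranges$pop, collapse = ", "),
         ") must match the model's founders (",
         paste(model@founders, collapse = ", "), ") in order")
  counts <- vapply(model@founders, function(p) sum(ind$pop == p), 0L)
  if (!all(counts == model@founderSizes))
    stop("founder sizes in the model do not match the individual table")
  snv <- panel@snv
  chromNames <- names(selPos)
  out <- list()
  for (i in seq_along(model@founders)) {
    rows <- (ranges$first[i] + 1L):(ranges$last[i] + 1L)
    sel <- lapply(seq_along(chromNames), function(ci) {
      sp <- selPos[[ci]]
      if (!length(sp)) return(matrix(0L, length(rows), 0L))
      col <- match(paste(chromNames[ci], sp + 1), paste(snv$chrom, snv$pos))
      m <- panel@haplotypes[rows, col, drop = FALSE]
      storage.mode(m) <- "integer"
      m
    })
    out[[i]] <- list(n = as.integer(counts[i]),
                     sexes = as.integer(ind$sex[ind$pop == model@founders[i]]),
                     sel = sel)
  }
  out
}

#' Run a forward Wright-Fisher admixture simulation
#'
#' Evolves the founder panel under the demographic model: for every
#' generation and population, each offspring draws a source population per
#' parent from the admixture-proportion vector (cumulative-threshold rule),
#' draws parents fitness-proportionally within the source (one female and
#' one male in dioecious mode; two distinct individuals otherwise), and
#' receives one gamete from each parent with Poisson crossovers on the
#' genetic map and Poisson de novo mutations.  On an X chromosome only
#' female meioses recombine: sons receive the maternal recombinant X,
#' daughters additionally the paternal X copied intact.  Only the current
#' and previous generation are held in memory; populations named in the
#' model's output directives (and all populations of the final generation)
#' are retained in the result.
#'
#' The run is deterministic given `seed`: all draws come from R's RNG in a
#' fixed documented order (see the package vignette).
#'
#' @param panel a [FounderPanel].
#' @param model a [DemographicModel].
#' @param genome a [GenomeSpec]; defaults to one uniform autosome spanning
#'   the SNV table.
#' @param seed integer seed.
#' @param recordFrequencies record per-generation derived-allele frequencies
#'   at every selected position (default `TRUE`).
#' @param retainFinal retain the final generation's populations (default
#'   `TRUE`); set `FALSE` for replicate runs where only the frequency
#'   trajectory or census is needed.
#' @param stopOnFixation stop as soon as every tracked selected position is
#'   fixed (frequency 0 or 1) in every population, e.g. for fixation-time
#'   replicates (requires `recordFrequencies`).  Leave `FALSE` for models
#'   where later gene flow could re-polymorphise a fixed population.
#' @return An [AdmixRun-class] result.
#' @examples
#' sc <- buildScenario("hi_4to1_50g", size = 200, nSnv = 50,
#'                     generations = 5, seed = 7)
#' sim <- runSimulation(sc$panel, sc$model, sc$genome, seed = 7)
#' sim
#' @export
runSimulation <- function(panel, model, genome = NULL, seed = 1L,
                          recordFrequencies = TRUE, retainFinal = TRUE,
                          stopOnFixation = FALSE) {
  stopifnot(is(panel, "FounderPanel"), is(model, "DemographicModel"))
  if (is.null(genome)) genome <- GenomeSpec(snv = panel)
  validObject(panel); validObject(model); validObject(genome)
  ind <- panel@individuals
  dioecious <- any(ind$sex != 0L)
  if (dioecious && any(ind$sex == 0L))
    stop("mixed sexed and unsexed founders: specify sex for all individuals or none")
  if (any(genome@chroms$type == "X") && !dioecious)
    stop("an X chromosome requires dioecious founders (sexes 1/2)")
  res <- .resolveRules(model, genome, panel@snv)
  chromsR <- .chromList(genome, snv = panel@snv, selPos = res$selPos)
  foundersR <- .founderDef(panel, model, res$selPos)

  d <- model@directives
  retain <- cbind(d$gen, match(d$pop, model@registry) - 1L)
  if (is.null(retain) || !nrow(d)) retain <- matrix(0L, 0, 2)
  storage.mode(retain) <- "integer"

  seed <- as.integer(seed)
  set.seed(seed)
  raw <- cpp_simulate(foundersR, model@events, chromsR, res$rulesR, retain,
                      dioecious, model@registry, recordFrequencies,
                      isTRUE(retainFinal), isTRUE(stopOnFixation))

  chromNames <- genome@chroms$name
  pops <- list()
  for (k in raw$kept) {
    nm <- sprintf("g%d.%s", k$gen, model@registry[k$pop + 1L])
    pops[[nm]] <- new("PopulationState", pop = model@registry[k$pop + 1L],
                      generation = as.integer(k$gen),
                      individuals = k$individuals)
  }
  fr <- raw$freq
  freqs <- data.frame(gen = fr$gen, pop = model@registry[fr$pop + 1L],
                      chrom = chromNames[fr$chrom + 1L], pos = fr$pos + 1,
                      freq = fr$freq, nhap = fr$nhap, stringsAsFactors = FALSE)
  census <- data.frame(gen = raw$census$gen,
                       pop = model@registry[raw$census$pop + 1L],
                       size = raw$census$size, stringsAsFactors = FALSE)
  new("AdmixRun", populations = pops, frequencies = freqs, census = census,
      labelRanges = founderLabelRanges(panel), model = model, genome = genome,
      seed = seed)
}

#' Cumulative-threshold source sampling
#'
#' Maps a uniform(0,1) draw to a source index through the cumulative sums of
#' an admixture-proportion vector: with proportions (0.2, 0.1, 0.7) a draw
#' below 0.2 selects source 1, between 0.2 and 0.3 source 2, otherwise
#' source 3.  A draw exactly equal to a threshold falls in the cell to its
#' right (a measure-zero tie, fixed for reproducibility).
#'
#' @param prop proportion vector summing to 1.
#' @param u uniform(0,1) draw.
#' @return 1-based source index.
#' @examples
#' sampleSourcePopulation(c(0.2, 0.1, 0.7), 0.25)  # 2
#' @export
sampleSourcePopulation <- function(prop, u) {
  if (!length(prop)) stop("empty proportion vector")
  if (abs(sum(prop) - 1) > 1e-9) stop("proportions must sum to 1")
  min(sum(cumsum(prop) <= u) + 1L, length(prop))
}

#' Additive fitness of one individual
#'
#' Fitness is one plus the sum, over the active selection rules and over the
#' individual's haplotypes, of the rule's coefficient for every haplotype
#' that carries the required allele at every rule position; negative totals
#' are rescaled to zero.  Carrying the selected allele on 0, 1 or 2
#' haplotypes under a single rule gives fitness 1, 1+s and 1+2s.
#'
#' @param individual internal individual (`list(sex, haps)`, e.g. from a
#'   [PopulationState]).
#' @param rules resolved rules in engine form (see [runSimulation()]
#'   internals); typically from an [AdmixRun] run or built in tests.
#' @param generation generation being produced (rules outside their active
#'   range contribute nothing).
#' @param popIndex 0-based registry index of the individual's population.
#' @return Non-negative fitness.
#' @export
computeFitness <- function(individual, rules, generation, popIndex = 0L) {
  f <- 1
  for (r in rules) {
    if (r$pop >= 0L && r$pop != popIndex) next
    if (generation < r$g1 || generation > r$g2) next
    if (r$sex != 0L && r$sex != individual$sex) next
    for (h in individual$haps[[r$chrom + 1L]]) {
      if (all(h$sel[r$posIdx + 1L] == r$allele)) f <- f + r$s
    }
  }
  max(0, f)
}

#' One meiosis: recombinant gamete from a pair of haplotypes
#'
#' Draws a Poisson(genetic length) number of crossovers, places them
#' uniformly on the genetic scale, maps them to physical positions through
#' the genetic map (ties at identical positions collapse to one crossover),
#' picks the starting haplotype by fair coin and splices segments,
#' accumulated breakpoints, mutation positions and selected-site states
#' accordingly.  Advances R's RNG; seed beforehand for reproducibility.
#'
#' @param hapA,hapB the two parental haplotypes (internal form).
#' @param genome a [GenomeSpec].
#' @param chrom chromosome index (1-based).
#' @param snv optional SNV table for map/rate columns.
#' @param selPos 0-based physical positions of the haplotypes' tracked
#'   selected states (`hap$sel`), if any.
#' @return A new haplotype (internal form) whose segments tile `[0, L)`.
#' @export
makeGamete <- function(hapA, hapB, genome, chrom = 1L, snv = NULL,
                       selPos = numeric(0)) {
  if (length(selPos) != length(hapA$sel))
    stop("selPos must give a position for every tracked selected state")
  cl <- .chromList(genome, snv = snv)
  cl[[chrom]]$selPos <- as.numeric(selPos)
  cpp_make_gamete(hapA, hapB, cl[[chrom]])
}

#' Poisson de novo mutation on one gamete
#'
#' Adds Poisson(total mutation rate) new mutation positions (uniform, or
#' proportional to per-site rates); a repeat hit at an occupied position
#' reverts it (two-allele model).  De novo mutations never enter fitness.
#'
#' @inheritParams makeGamete
#' @param hap the gamete to mutate (internal form).
#' @return The mutated haplotype.
#' @export
applyMutations <- function(hap, genome, chrom = 1L, snv = NULL) {
  cl <- .chromList(genome, snv = snv)
  cpp_apply_mutations(hap, cl[[chrom]])
}

#' Produce one generation from existing population states
#'
#' Runs a single generation of the Wright-Fisher loop for every population
#' row of `model@events[[generation]]`, drawing parents from `prev` (the
#' states at `generation - 1`).  Mainly a building block for tests and
#' step-wise experiments; [runSimulation()] is the production path.
#'
#' @param prev named list of [PopulationState]s at the previous generation
#'   (names = population names).
#' @param model a [DemographicModel].
#' @param generation generation to produce (1-based).
#' @param genome a [GenomeSpec].
#' @param snv optional SNV table (selection rules require it).
#' @return Named list of new [PopulationState]s.
#' @export
reproduceGeneration <- function(prev, model, generation, genome, snv = NULL) {
  if (is.null(snv)) snv <- data.frame(chrom = character(0), pos = numeric(0))
  res <- .resolveRules(model, genome, snv)
  chromsR <- .chromList(genome, snv = snv, selPos = res$selPos)
  dioecious <- any(vapply(prev, function(st)
    any(vapply(st@individuals, function(i) i$sex != 0L, TRUE)), TRUE))
  prevR <- lapply(prev, function(st) st@individuals)
  names(prevR) <- as.character(match(names(prev), model@registry) - 1L)
  out <- list()
  for (row in model@events[[generation]]) {
    nm <- model@registry[row$pop + 1L]
    inds <- cpp_step(prevR, row, chromsR, res$rulesR, as.integer(generation),
                     dioecious, model@registry)
    out[[nm]] <- new("PopulationState", pop = nm,
                     generation = as.integer(generation), individuals = inds)
  }
  out
}
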