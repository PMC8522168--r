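#' @include AllClasses.R FounderPanel.R DemographicModel.R GenomeSpec.R
NULL

#' Generate a synthetic founder panel
#'
#' Founder alleles are drawn per site from population-specific derived-allele
#' frequencies: a shared base frequency per site (uniform on 0.1-0.9) is
#' pushed towards a population-private pole by `divergence`, so
#' `divergence = 0` gives panmictic founders and `divergence = 1` gives
#' fully diagnostic sites (each site fixed derived in exactly one
#' population), from which ancestry is recoverable per site.
#'
#' @param sizes named integer vector: individuals per founder population
#'   (names become population labels).
#' @param nSnv number of SNVs.
#' @param length chromosome length in bp.
#' @param chrom chromosome name.
#' @param divergence between-population allele-frequency divergence in
#'   `[0, 1]`.
#' @param sexed assign alternating sexes (male/female) within each
#'   population, enabling dioecious mode.
#' @param seed integer seed (the panel is byte-identical given a seed).
#' @return A [FounderPanel-class].
#' @examples
#' p <- simulateFounderPanel(c(A = 2, B = 2), nSnv = 6, length = 1e6, seed = 1)
#' haplotypeMatrix(p)
#' @export
simulateFounderPanel <- function(sizes, nSnv, length, chrom = "1",
                                 divergence = 0.5, sexed = FALSE, seed = 1L) {
  stopifnot(all(sizes >= 1), nSnv >= 1, length >= nSnv)
  if (is.null(names(sizes)))
    names(sizes) <- paste0("ANC", seq_along(sizes))
  set.seed(as.integer(seed))
  pos <- sort(sample.int(length, nSnv))
  k <- base::length(sizes)
  baseFreq <- runif(nSnv, 0.1, 0.9)
  pole <- (seq_len(nSnv) - 1L) %% k + 1L  # which population owns the site
  rows <- list()
  for (i in seq_len(k)) {
    f <- (1 - divergence) * baseFreq + divergence * as.numeric(pole == i)
    ni <- 2L * sizes[i]
    rows[[i]] <- matrix(as.integer(runif(ni * nSnv) < rep(f, each = ni)),
                        nrow = ni, ncol = nSnv)
  }
  H <- do.call(rbind, rows)
  ind <- data.frame(
    id = unlist(lapply(seq_len(k), function(i)
      sprintf("%s_%d", names(sizes)[i], seq_len(sizes[i])))),
    pop = rep(names(sizes), sizes),
    sex = if (sexed) unlist(lapply(sizes, function(n)
      rep_len(c(1L, 2L), n))) else 0L,
    stringsAsFactors = FALSE)
  snv <- data.frame(chrom = chrom, pos = pos, ancestral = "A", derived = "G",
                    stringsAsFactors = FALSE)
  FounderPanel(H, snv, ind)
}

#' Ready-made simulation scenarios
#'
#' Self-contained bundles (founder panel + demographic model + genome) for
#' the validation scenarios used throughout the package:
#' \describe{
#'   \item{`hi_4to1_50g`}{hybrid isolation, two ancestries contributing
#'     4:1 (0.8/0.2), admixed size 5000, 3e8 bp autosome (3 Morgan at
#'     1e-8), 50 generations.}
#'   \item{`x_vs_autosome`}{the same model on an X chromosome with
#'     dioecious founders; recombination in female meioses only.}
#'   \item{`afram_11g`}{two-way African-American-like pulse, contributions
#'     0.246 (European) / 0.754 (African), 11 generations, 2.49e8 bp.}
#'   \item{`mexican_18g`}{three-way pulse 0.512/0.052/0.436
#'     (European/African/Native American), 18 generations, 2.48e8 bp.}
#'   \item{`uyghur_150g`}{four-way pulse 0.35/0.15/0.35/0.15 (East
#'     Asian/Siberian/West Eurasian/South Asian), 150 generations,
#'     2.48e8 bp.}
#'   \item{`selection_grid`}{hybrid isolation 1:1, founders 100 + 100,
#'     admixed size 5000, 1e6 bp (1 cM), additive selection at a single
#'     diagnostic site with initial frequency `x0` and coefficient `s`
#'     (defaults 0.05 and 0.1); the founder panel carries the selected
#'     allele at exactly `x0` in each founder population.}
#' }
#' Admixed-population sizes are 5000 unless overridden; founder populations
#' hold 100 individuals each.  Multi-way scenarios are built as single
#' admixture pulses with the stated total contributions.
#'
#' @param name scenario name (see above).
#' @param size admixed population size override.
#' @param nSnv SNV count of the synthetic panel (default 60).
#' @param generations generation-count override.
#' @param founderSize individuals per founder population (default 100).
#' @param recRate,mutRate uniform rates (default 1e-8 each).
#' @param x0,s selection-grid initial frequency and coefficient.
#' @param sampleSize `n` of the output directive (default
#'   `min(1000, size)`).
#' @param seed seed for the synthetic founder panel.
#' @return list with elements `name`, `panel`, `model`, `genome`, `params`.
#' @export
buildScenario <- function(name, size = NULL, nSnv = 60L, generations = NULL,
                          founderSize = 100L, recRate = 1e-8, mutRate = 1e-8,
                          x0 = 0.05, s = 0.1, sampleSize = NULL, seed = 1L) {
  known <- c("hi_4to1_50g", "x_vs_autosome", "afram_11g", "mexican_18g",
             "uyghur_150g", "selection_grid")
  if (!name %in% known)
    stop("unknown scenario '", name, "'; available: ",
         paste(known, collapse = ", "))
  cfg <- switch(name,
    hi_4to1_50g = list(pops = c(ANC1 = 0.8, ANC2 = 0.2), G = 50L, L = 3e8,
                       type = "autosome", sexed = FALSE),
    x_vs_autosome = list(pops = c(ANC1 = 0.8, ANC2 = 0.2), G = 50L, L = 3e8,
                         type = "X", sexed = TRUE),
    afram_11g = list(pops = c(EUR = 0.246, AFR = 0.754), G = 11L, L = 2.49e8,
                     type = "autosome", sexed = FALSE),
    mexican_18g = list(pops = c(EUR = 0.512, AFR = 0.052, NAM = 0.436),
                       G = 18L, L = 2.48e8, type = "autosome", sexed = FALSE),
    uyghur_150g = list(pops = c(EAS = 0.35, SIB = 0.15, WEU = 0.35,
                                SAS = 0.15), G = 150L, L = 2.48e8,
                       type = "autosome", sexed = FALSE),
    selection_grid = list(pops = c(ANC1 = 0.5, ANC2 = 0.5), G = 300L, L = 1e6,
                          type = "autosome", sexed = FALSE))
  if (!is.null(generations)) cfg$G <- as.integer(generations)
  if (is.null(size)) size <- 5000L
  if (is.null(sampleSize)) sampleSize <- min(1000L, size)
  chromName <- if (cfg$type == "X") "X" else "1"
  sizes <- setNames(rep(as.integer(founderSize), length(cfg$pops)),
                    names(cfg$pops))
  panel <- simulateFounderPanel(sizes, nSnv = nSnv, length = cfg$L,
                                chrom = chromName, sexed = cfg$sexed,
                                seed = seed)
  lines <- c(sprintf("pop %s founder size=%d", names(sizes), sizes),
             sprintf("gen 1: ADM size=%d from %s", as.integer(size),
                     paste(sprintf("%s:%g", names(cfg$pops), cfg$pops),
                           collapse = ",")))
  selPos <- NULL
  if (name == "selection_grid") {
    snv <- snvTable(panel)
    selPos <- snv$pos[which.min(abs(snv$pos - cfg$L / 2))]
    H <- haplotypeMatrix(panel)
    H[, snv$pos == selPos] <- 0L
    for (i in seq_along(sizes)) {
      # exact initial frequency per founder population; carriers land on
      # random haplotype slots so founder genotypes are Hardy-Weinberg-like
      # rather than artificially homozygous
      first <- 2L * c(0L, cumsum(sizes))[i]
      k <- round(x0 * 2L * sizes[i])
      if (k > 0) H[first + sample.int(2L * sizes[i], k),
                   snv$pos == selPos] <- 1L
    }
    panel <- FounderPanel(H, snv, individualTable(panel))
    lines <- c(lines, sprintf("sel * chrom=%s pos=%d allele=1 s=%g",
                              chromName, selPos, s))
  }
  lines <- c(lines, sprintf("out gen=%d pop=ADM n=%d", cfg$G,
                            as.integer(sampleSize)))
  model <- parseModel(lines)
  genome <- GenomeSpec(chromName, lengths = cfg$L, types = cfg$type,
                       recRate = recRate, mutRate = mutRate)
  list(name = name, panel = panel, model = model, genome = genome,
       params = list(proportions = cfg$pops, generations = cfg$G, L = cfg$L,
                     size = as.integer(size), x0 = x0, s = s,
                     selPos = selPos, recRate = recRate, mutRate = mutRate))
}
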