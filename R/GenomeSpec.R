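#' @include AllClasses.R
NULL

#' Construct a GenomeSpec
#'
#' @param names chromosome names, in simulation order.
#' @param lengths physical lengths in bp.  Defaults to the last SNV position
#'   per chromosome when `snv` is given.
#' @param types `"autosome"` or `"X"` per chromosome.  Chromosomes named
#'   `"X"` or `"chrX"` default to type `"X"`.  An X chromosome cannot share
#'   a `GenomeSpec` with autosomes; simulate it in its own run.
#' @param recRate uniform recombination rate in Morgan per bp (default
#'   `1e-8`, i.e. 1 cM/Mb).
#' @param mutRate uniform mutation rate per site per generation (default
#'   `1e-8`).
#' @param snv optional SNV table (or [FounderPanel]) used to default `names`
#'   and `lengths`.
#' @param useSnvMap if `TRUE` and the SNV table has a complete `gpos`
#'   column, the genetic map is the piecewise-linear interpolation of
#'   (position, gpos), anchored at (0, 0) and extended to the chromosome
#'   end at `recRate`.
#' @param useSnvRates if `TRUE` and the SNV table has a `mut_rate` column,
#'   de novo mutations arise only at the listed sites, Poisson with total
#'   rate `sum(mut_rate)` and positions sampled proportional to the
#'   per-site rates (`NA` entries fall back to `mutRate`).
#' @return A [GenomeSpec-class] object.
#' @examples
#' GenomeSpec("1", lengths = 3e8)                 # 3-Morgan autosome at 1e-8
#' GenomeSpec("X", lengths = 3e8, types = "X")    # X: female-only recombination
#' @export
GenomeSpec <- function(names, lengths = NULL, types = NULL, recRate = 1e-8,
                       mutRate = 1e-8, snv = NULL, useSnvMap = TRUE,
                       useSnvRates = TRUE) {
  if (is(snv, "FounderPanel")) snv <- snvTable(snv)
  if (missing(names) && !is.null(snv)) names <- unique(snv$chrom)
  names <- as.character(names)
  if (is.null(lengths)) {
    if (is.null(snv)) stop("either 'lengths' or 'snv' must be given")
    lengths <- vapply(names, function(cc) max(snv$pos[snv$chrom == cc]), 0)
  }
  if (is.null(types))
    types <- ifelse(names %in% c("X", "chrX", "x"), "X", "autosome")
  ch <- data.frame(name = names, length = as.numeric(lengths),
                   type = as.character(types), stringsAsFactors = FALSE)
  new("GenomeSpec", chroms = ch, recRate = recRate, mutRate = mutRate,
      useSnvMap = isTRUE(useSnvMap), useSnvRates = isTRUE(useSnvRates))
}

#' @rdname accessors
#' @export
chromTable <- function(x) {
  stopifnot(is(x, "GenomeSpec"))
  x@chroms
}

#' Total genetic length of a chromosome in Morgan
#'
#' @param genome a [GenomeSpec].
#' @param snv optional SNV table supplying a `gpos` map column.
#' @param chrom chromosome name (default: first).
#' @return Genetic length in Morgan (`map(L)`).
#' @export
geneticLength <- function(genome, snv = NULL, chrom = NULL) {
  if (is.null(chrom)) chrom <- genome@chroms$name[1]
  cl <- .chromList(genome, snv = snv)
  i <- match(chrom, genome@chroms$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  tail(cl[[i]]$mapGen, 1)
}

# Build the per-chromosome list handed to the C++ engine (and to the per-site
# oracle).  selPos is a list of 0-based selected positions per chromosome.
.chromList <- function(genome, snv = NULL, selPos = NULL) {
  ch <- genome@chroms
  out <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    nm <- ch$name[i]; L <- ch$length[i]
    s <- if (!is.null(snv)) snv[snv$chrom == nm, , drop = FALSE] else NULL
    mapPhys <- c(0, L); mapGen <- c(0, genome@recRate * L)
    if (genome@useSnvMap && !is.null(s) && !is.null(s$gpos) &&
        nrow(s) > 0 && !anyNA(s$gpos)) {
      p0 <- s$pos - 1
      mapPhys <- c(0, p0, L)
      mapGen <- c(0, s$gpos, s$gpos[length(s$gpos)] +
                    (L - p0[length(p0)]) * genome@recRate)
      keep <- !duplicated(mapPhys)
      mapPhys <- mapPhys[keep]; mapGen <- mapGen[keep]
      if (any(diff(mapGen) < 0))
        stop("genetic map on chromosome ", nm, " is decreasing")
    }
    uniformMut <- TRUE; muTotal <- genome@mutRate * L
    mutPos <- numeric(0); mutRates <- numeric(0)
    if (genome@useSnvRates && !is.null(s) && !is.null(s$mut_rate) &&
        nrow(s) > 0 && any(!is.na(s$mut_rate))) {
      uniformMut <- FALSE
      mutPos <- s$pos - 1
      mutRates <- ifelse(is.na(s$mut_rate), genome@mutRate, s$mut_rate)
      muTotal <- sum(mutRates)
    }
    sp <- if (!is.null(selPos)) selPos[[i]] else numeric(0)
    out[[i]] <- list(name = nm, length = L, isX = ch$type[i] == "X",
                     mapPhys = mapPhys, mapGen = mapGen,
                     uniformMut = uniformMut, muTotal = muTotal,
                     mutPos = mutPos, mutRates = mutRates,
                     selPos = as.numeric(sp))
  }
  out
}

# piecewise-linear inverse of the genetic map; arithmetic mirrored exactly in
# the per-site oracle
.gen2phys <- function(cl, g) {
  gp <- cl$mapGen; pp <- cl$mapPhys
  i <- sum(gp <= g)
  if (i == 0) return(pp[1])
  if (i >= length(gp)) return(pp[length(pp)])
  g0 <- gp[i]; g1 <- gp[i + 1]; p0 <- pp[i]; p1 <- pp[i + 1]
  if (g1 <= g0) return(p0)
  p0 + (g - g0) / (g1 - g0) * (p1 - p0)
}
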