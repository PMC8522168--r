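#' @include AllClasses.R
NULL

#' Materialise sequences from segments and the founder panel
#'
#' Founder haplotype data are consulted only here, after the simulation: for
#' every SNV the output allele is the founder allele of the segment covering
#' it (looked up by founder label), flipped once if the exact position was
#' hit by a de novo mutation.  De novo positions that match no SNV become
#' new derived-singleton columns in the updated SNV table (ancestral allele
#' coded "0", derived "1", map columns `NA`).
#'
#' @param state a [PopulationState].
#' @param panel the [FounderPanel] the simulation started from.
#' @param genome the [GenomeSpec] used (defaults to the SNV-derived one, as
#'   in [runSimulation()]).
#' @return list with `haplotypes` (0/1 matrix, one row per haplotype; on an
#'   X chromosome males contribute one row), `snv` (updated SNV table
#'   including de novo columns), `hapIDs`, and `individuals` (id/pop/sex
#'   table for the state).
#' @export
extractSequences <- function(state, panel, genome = NULL) {
  if (is.null(genome)) genome <- GenomeSpec(snv = panel)
  snv <- panel@snv
  H <- panel@haplotypes
  chromNames <- genome@chroms$name
  nLab <- nrow(H)
  hapIDs <- character(0)
  perChrom <- list()
  for (ci in seq_along(chromNames)) {
    cc <- chromNames[ci]
    colIdx <- which(snv$chrom == cc)
    pos0 <- snv$pos[colIdx] - 1
    hl <- haplotypeList(state, chrom = ci)
    if (ci == 1L) hapIDs <- names(hl)
    out <- matrix(0L, length(hl), length(colIdx))
    extras <- vector("list", length(hl))
    for (i in seq_along(hl)) {
      h <- hl[[i]]
      if (any(h$labels < 0L | h$labels >= nLab))
        stop("corrupt haplotype: founder label out of range")
      a <- integer(length(colIdx))
      if (length(colIdx)) {
        seg <- findInterval(pos0, h$starts)
        a <- H[cbind(h$labels[seg] + 1L, colIdx)]
      }
      m <- h$mutations
      if (length(m)) {
        mi <- match(m, pos0)
        hit <- !is.na(mi)
        a[mi[hit]] <- 1L - a[mi[hit]]
        extras[[i]] <- m[!hit]
      } else extras[[i]] <- numeric(0)
      out[i, ] <- a
    }
    newPos <- sort(unique(unlist(extras)))
    if (length(newPos)) {
      add <- matrix(0L, length(hl), length(newPos))
      for (i in seq_along(hl))
        add[i, match(extras[[i]], newPos)] <- 1L
      allPos0 <- c(pos0, newPos)
      ord <- order(allPos0)
      mat <- cbind(out, add)[, ord, drop = FALSE]
      tab <- data.frame(chrom = cc, pos = allPos0[ord] + 1,
                        ancestral = c(snv$ancestral[colIdx],
                                      rep("0", length(newPos)))[ord],
                        derived = c(snv$derived[colIdx],
                                    rep("1", length(newPos)))[ord],
                        stringsAsFactors = FALSE)
      if (!is.null(snv$gpos))
        tab$gpos <- c(snv$gpos[colIdx], rep(NA_real_, length(newPos)))[ord]
      if (!is.null(snv$mut_rate))
        tab$mut_rate <- c(snv$mut_rate[colIdx], rep(NA_real_, length(newPos)))[ord]
    } else {
      mat <- out
      tab <- snv[colIdx, , drop = FALSE]
    }
    perChrom[[ci]] <- list(mat = mat, tab = tab)
  }
  hap <- do.call(cbind, lapply(perChrom, `[[`, "mat"))
  upd <- do.call(rbind, lapply(perChrom, `[[`, "tab"))
  rownames(upd) <- NULL
  inds <- data.frame(
    id = sprintf("%s_g%d_i%d", state@pop, state@generation,
                 seq_along(state@individuals)),
    pop = state@pop,
    sex = vapply(state@individuals, function(i) i$sex, 0L),
    stringsAsFactors = FALSE)
  list(haplotypes = hap, snv = upd, hapIDs = hapIDs, individuals = inds)
}

#' Local-ancestry tracks
#'
#' Converts each haplotype's founder-label segments into ancestry tracks by
#' resolving labels through the founder populations' consecutive label
#' ranges; adjacent segments of the same ancestry (possibly different
#' founder labels) are merged unless `merge = FALSE`.  Tracks tile the
#' chromosome exactly.
#'
#' @param x an [AdmixRun] result or a [PopulationState].
#' @param which name of the retained state to use when `x` is an
#'   [AdmixRun] (default: the last one).
#' @param chrom chromosome index (1-based).
#' @param merge merge adjacent same-ancestry segments (the track view);
#'   `FALSE` returns the raw segment view.
#' @param ranges,L label-range table ([founderLabelRanges()]) and
#'   chromosome length in bp; required when `x` is a bare
#'   [PopulationState].
#' @return data.frame `hap`, `chrom`, `start`, `end` (1-based inclusive
#'   bp; fractional crossover boundaries are reported as-is), `ancestry`.
#' @export
ancestryTracks <- function(x, which = NULL, chrom = 1L, merge = TRUE,
                           ranges = NULL, L = NULL) {
  if (is(x, "AdmixRun")) {
    ranges <- x@labelRanges
    L <- x@genome@chroms$length[chrom]
    cname <- x@genome@chroms$name[chrom]
    if (is.null(which)) which <- names(x@populations)[length(x@populations)]
    state <- x@populations[[which]]
    if (is.null(state)) stop("no retained state named '", which, "'")
  } else if (is(x, "PopulationState")) {
    if (is.null(ranges) || is.null(L))
      stop("ranges and L are required for a bare PopulationState")
    state <- x
    cname <- as.character(chrom)
  } else stop("x must be an AdmixRun or a PopulationState")
  hl <- haplotypeList(state, chrom = chrom)
  res <- vector("list", length(hl))
  for (i in seq_along(hl)) {
    h <- hl[[i]]
    anc <- ranges$pop[findInterval(h$labels, ranges$first)]
    starts <- h$starts
    ends <- c(starts[-1], L)
    if (merge && length(anc) > 1) {
      r <- rle(anc)
      last <- cumsum(r$lengths)
      first <- c(1L, head(last, -1) + 1L)
      starts <- starts[first]; ends <- ends[last]; anc <- r$values
    }
    res[[i]] <- data.frame(hap = names(hl)[i], chrom = cname,
                           start = starts + 1, end = ends,
                           ancestry = anc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ancestry proportions from segment lengths
#'
#' The realized analogue of the model's admixture proportions: each
#' ancestry's total track length divided by the total length covered.
#' Invariant to merging of same-ancestry tracks.
#'
#' @param tracks a track table from [ancestryTracks()] (merged or raw).
#' @param ancestries optional ancestry names to report (defaults to those
#'   present); absent ancestries report 0.
#' @return Named numeric vector of proportions summing to 1.
#' @export
segmentLengthProportions <- function(tracks, ancestries = NULL) {
  len <- tracks$end - (tracks$start - 1)
  tot <- tapply(len, tracks$ancestry, sum)
  if (is.null(ancestries)) ancestries <- names(tot)
  out <- setNames(numeric(length(ancestries)), ancestries)
  out[names(tot)] <- tot / sum(tot)
  out
}

#' Fixation generation of a selected allele
#'
#' First generation at which the derived-allele frequency at a selected
#' position reaches 1 in a population.
#'
#' @param sim an [AdmixRun] with recorded frequencies.
#' @param pop population name.
#' @param pos selected position (1-based bp; default: the only tracked one).
#' @return Generation index, or `NA` if the allele never fixed.
#' @export
fixationTime <- function(sim, pop, pos = NULL) {
  fr <- sim@frequencies
  fr <- fr[fr$pop == pop, , drop = FALSE]
  if (is.null(pos)) {
    pos <- unique(fr$pos)
    if (length(pos) != 1) stop("several tracked positions; give 'pos'")
  }
  fr <- fr[fr$pos == pos, , drop = FALSE]
  fixed <- fr$gen[fr$freq >= 1]
  if (!length(fixed)) NA_integer_ else min(fixed)
}
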