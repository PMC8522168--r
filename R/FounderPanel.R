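#' @include AllClasses.R
NULL

#' Construct a founder panel from in-memory pieces
#'
#' @param haplotypes 0/1 matrix, two consecutive rows per individual.
#' @param snv SNV table: `chrom`, `pos` (1-based bp), `ancestral`,
#'   `derived`, optional `gpos` (Morgan) and `mut_rate`.
#' @param individuals individual table: `id`, `pop`, `sex` (0 unspecified,
#'   1 male, 2 female).
#' @return A [FounderPanel-class].
#' @export
FounderPanel <- function(haplotypes, snv, individuals) {
  storage.mode(haplotypes) <- "integer"
  snv$chrom <- as.character(snv$chrom)
  snv$pos <- as.numeric(snv$pos)
  individuals$id <- as.character(individuals$id)
  individuals$pop <- as.character(individuals$pop)
  individuals$sex <- as.integer(individuals$sex)
  new("FounderPanel", haplotypes = haplotypes, snv = snv,
      individuals = individuals)
}

#' Read the three founder input files
#'
#' File dialects (all plain text):
#' \itemize{
#'   \item haplotype file: one haplotype per line, SNV columns as contiguous
#'     `0`/`1` characters, two consecutive lines per individual (for an
#'     X-only panel, one line per male when `xHemizygous = TRUE`);
#'   \item individual file: headerless TSV `id  pop  sex` with sex coded
#'     0/1/2 (unspecified/male/female);
#'   \item SNV file: headerless TSV `chrom  pos  ancestral  derived
#'     [gpos] [mut_rate]`, positions 1-based and strictly increasing per
#'     chromosome; column 5 is the genetic position in Morgan, column 6 a
#'     per-site per-generation mutation rate (`NA` allowed).
#' }
#'
#' @param hapPath,indPath,snvPath paths to the three files.
#' @param xHemizygous if `TRUE`, male individuals contribute a single
#'   haplotype line (used when re-ingesting an X-chromosome output); their
#'   line is duplicated internally so the matrix keeps two rows per
#'   individual.
#' @return A [FounderPanel-class].
#' @export
readFounderPanel <- function(hapPath, indPath, snvPath, xHemizygous = FALSE) {
  for (p in c(hapPath, indPath, snvPath))
    if (!file.exists(p)) stop("input file not found: ", p)
  ind <- read.table(indPath, sep = "\t", header = FALSE,
                    col.names = c("id", "pop", "sex"),
                    colClasses = c("character", "character", "integer"))
  snvRaw <- read.table(snvPath, sep = "\t", header = FALSE,
                       colClasses = "character")
  if (ncol(snvRaw) < 4) stop("SNV file needs at least 4 columns")
  snv <- data.frame(chrom = snvRaw[[1]], pos = as.numeric(snvRaw[[2]]),
                    ancestral = snvRaw[[3]], derived = snvRaw[[4]],
                    stringsAsFactors = FALSE)
  if (ncol(snvRaw) >= 5) snv$gpos <- suppressWarnings(as.numeric(snvRaw[[5]]))
  if (ncol(snvRaw) >= 6) snv$mut_rate <- suppressWarnings(as.numeric(snvRaw[[6]]))
  lines <- readLines(hapPath, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (xHemizygous) {
    expanded <- character(2L * nrow(ind)); li <- 1L
    for (i in seq_len(nrow(ind))) {
      expanded[2L * i - 1L] <- lines[li]
      if (ind$sex[i] == 1L) {             # male: single X line, duplicated
        expanded[2L * i] <- lines[li]; li <- li + 1L
      } else {
        expanded[2L * i] <- lines[li + 1L]; li <- li + 2L
      }
    }
    if (li - 1L != length(lines))
      stop("haplotype line count does not match individual sexes")
    lines <- expanded
  }
  if (length(lines) %% 2L != 0L)
    stop("haplotype file has an odd number of rows (two per individual expected)")
  if (length(lines) != 2L * nrow(ind))
    stop(sprintf("haplotype file has %d rows but individual table implies %d",
                 length(lines), 2L * nrow(ind)))
  nc <- nchar(lines)
  if (any(nc != nrow(snv)))
    stop(sprintf("haplotype row %d has %d columns; SNV table has %d",
                 which(nc != nrow(snv))[1], nc[nc != nrow(snv)][1], nrow(snv)))
  H <- matrix(0L, length(lines), nrow(snv))
  for (i in seq_along(lines)) {
    v <- utf8ToInt(lines[i]) - 48L
    bad <- which(v != 0L & v != 1L)
    if (length(bad))
      stop(sprintf("haplotype row %d column %d: allele character not 0/1",
                   i, bad[1]))
    H[i, ] <- v
  }
  FounderPanel(H, snv, ind)
}

#' Write a founder panel in the native three-file dialect
#'
#' @param panel a [FounderPanel].
#' @param prefix output prefix; writes `<prefix>.hap`, `<prefix>.ind`,
#'   `<prefix>.snv`.
#' @param xHemizygous write a single haplotype line for male individuals
#'   (X-chromosome panels).
#' @return The three paths, invisibly.
#' @export
writeFounderPanel <- function(panel, prefix, xHemizygous = FALSE) {
  H <- panel@haplotypes; ind <- panel@individuals; snv <- panel@snv
  rows <- seq_len(nrow(H))
  if (xHemizygous) {
    drop <- 2L * which(ind$sex == 1L)  # males: second row is a duplicate
    rows <- setdiff(rows, drop)
  }
  hapLines <- vapply(rows, function(i) paste(H[i, ], collapse = ""), "")
  writeLines(hapLines, paste0(prefix, ".hap"))
  write.table(ind, paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cols <- list(snv$chrom, format(snv$pos, scientific = FALSE, trim = TRUE),
               snv$ancestral, snv$derived)
  if (!is.null(snv$gpos)) cols <- c(cols, list(snv$gpos))
  if (!is.null(snv$mut_rate)) {
    if (is.null(snv$gpos)) cols <- c(cols, list(rep(NA, nrow(snv))))
    cols <- c(cols, list(snv$mut_rate))
  }
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)),
              paste0(prefix, ".snv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".hap", ".ind", ".snv")))
}

#' Founder label ranges per population
#'
#' Founder haplotypes are labelled 0..2N-1 in individual-table order, so
#' each population owns a consecutive label range; every segment of every
#' descendant haplotype carries one of these labels, which is how ancestry
#' is resolved without storing it per segment.
#'
#' @param panel a [FounderPanel] (or the individual table of one).
#' @return data.frame `pop`, `first`, `last` (inclusive label range).
#' @export
founderLabelRanges <- function(panel) {
  ind <- if (is(panel, "FounderPanel")) panel@individuals else panel
  pops <- unique(ind$pop)
  n <- vapply(pops, function(p) sum(ind$pop == p), 0L)
  if (!all(ind$pop == rep(pops, n)))
    stop("individuals of one population must be contiguous in the table")
  last <- cumsum(2L * n) - 1L
  first <- c(0L, head(last, -1) + 1L)
  data.frame(pop = pops, first = first, last = last, row.names = NULL,
             stringsAsFactors = FALSE)
}
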