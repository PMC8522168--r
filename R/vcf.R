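#' @include AllClasses.R FounderPanel.R
NULL

#' Import a phased VCF as a founder panel
#'
#' Reads a phased, biallelic VCF (via \pkg{vcfR}) into a [FounderPanel]:
#' each sample contributes two consecutive haplotype rows, REF maps to the
#' ancestral allele (0) and ALT to the derived allele (1).  Site order is
#' preserved.  Unphased genotypes are an error naming the offending record;
#' multiallelic sites are an error unless `skipMultiallelic = TRUE`, in
#' which case they are dropped with a message.
#'
#' @param path VCF file (plain or gzipped).
#' @param popMap named character vector mapping sample IDs to population
#'   labels; unmapped samples get population `"POP1"`.
#' @param sexMap named integer vector mapping sample IDs to sex codes
#'   (0/1/2); default all 0.
#' @param skipMultiallelic drop multiallelic records instead of failing.
#' @return A [FounderPanel-class].
#' @export
importVCF <- function(path, popMap = NULL, sexMap = NULL,
                      skipMultiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  gt <- v@gt
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    if (!skipMultiallelic)
      stop(sprintf("multiallelic (or ALT-less) record at %s:%s; use skipMultiallelic = TRUE to drop",
                   fix$CHROM[multi][1], fix$POS[multi][1]))
    message(sum(multi), " multiallelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  samples <- colnames(gt)[-1]
  nS <- nrow(fix); nI <- length(samples)
  calls <- matrix(sub(":.*$", "", gt[, -1, drop = FALSE]), nS, nI)
  bad <- which(matrix(!grepl("^[01]\\|[01]$", calls), nS, nI), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unphased or non-diploid genotype '%s' at %s:%s (sample %s)",
                 calls[bad[1, 1], bad[1, 2]], fix$CHROM[bad[1, 1]],
                 fix$POS[bad[1, 1]], samples[bad[1, 2]]))
  H <- matrix(0L, 2L * nI, nS)
  a1 <- matrix(as.integer(substr(calls, 1, 1)), nS, nI)
  a2 <- matrix(as.integer(substr(calls, 3, 3)), nS, nI)
  H[seq(1, 2 * nI, 2), ] <- t(a1)
  H[seq(2, 2 * nI, 2), ] <- t(a2)
  pops <- if (is.null(popMap)) rep("POP1", nI)
          else ifelse(samples %in% names(popMap), popMap[samples], "POP1")
  sexes <- if (is.null(sexMap)) rep(0L, nI)
           else ifelse(samples %in% names(sexMap),
                       as.integer(sexMap[samples]), 0L)
  snv <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    ancestral = fix$REF, derived = fix$ALT,
                    stringsAsFactors = FALSE)
  ind <- data.frame(id = samples, pop = pops, sex = sexes,
                    stringsAsFactors = FALSE)
  FounderPanel(H, snv, ind)
}

#' Export a founder panel (or extracted sequences) as a phased VCF
#'
#' Writes a minimal phased VCFv4.2 with GT-only genotypes; a round trip
#' through [importVCF()] reproduces the allele matrix.
#'
#' @param panel a [FounderPanel].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportVCF <- function(panel, path) {
  snv <- panel@snv; H <- panel@haplotypes; ind <- panel@individuals
  hdr <- c("##fileformat=VCFv4.2",
           "##source=AdmixWF",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ind$id), collapse = "\t"))
  n <- nrow(ind)
  gtCols <- vapply(seq_len(n), function(i)
    paste(H[2L * i - 1L, ], H[2L * i, ], sep = "|"), character(nrow(snv)))
  if (nrow(snv) == 1L) gtCols <- matrix(gtCols, nrow = 1L)
  body <- paste(snv$chrom, format(snv$pos, scientific = FALSE, trim = TRUE),
                ".", snv$ancestral, snv$derived, ".", "PASS", ".", "GT",
                apply(gtCols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
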