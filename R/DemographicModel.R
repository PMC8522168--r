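#' @include AllClasses.R
NULL

#' Parse a demographic model description
#'
#' The model file is line-oriented; `#` starts a comment.  Four record types
#' are recognised:
#' \preformatted{
#' pop <name> founder size=<n>
#' gen <g>: <name> size=<n>[,<n_female>] from <src>:<p>[,<src>:<p>...]
#'                [from_f <src>:<p>,...] [from_m <src>:<p>,...]
#' sel <name|*> chrom=<c> pos=<p>[-<p2>|,<p2>,...] allele=<0|1>[,...]
#'                s=<val>[@g1-g2] [sex=F|M]
#' out gen=<g> pop=<name> n=<k>
#' }
#' `pop` declares a founder population and its size (must match the
#' individual table).  `gen` gives a population's size and admixture
#' proportions at generation `g`; a two-value size is
#' `<n_male>,<n_female>`, and `from_f`/`from_m` give separate source
#' vectors for the mother and father draws (sex-biased admixture).  A
#' population not mentioned at a generation persists unchanged (same size,
#' 100\% self-contribution); a size of 0 removes it.  `sel` declares an
#' additive selection rule: a single position, a comma list (multi-locus,
#' discrete) or a range `p1-p2` (multi-locus, continuous: every SNV in the
#' interval); a haplotype satisfies the rule only if it carries the
#' required allele at every rule position, and each satisfying haplotype
#' adds `s` to its carrier's fitness (fitness = max(0, 1 + sum)).  `@g1-g2`
#' restricts the generations in which the rule is active (coefficients that
#' change over time are expressed as several rules with disjoint ranges);
#' `sex=F`/`M` restricts it to one sex.  `out` asks for population `<name>`
#' to be retained at generation `<g>` and sampled to `<k>` individuals on
#' output.
#'
#' The final generation is the largest generation mentioned; all living
#' populations are always retained there.
#'
#' @param text character vector of model lines (or a single string with
#'   embedded newlines).
#' @param path for `readModel`, path to a model file.
#' @return A [DemographicModel-class] object with every (generation,
#'   population) cell resolved.
#' @examples
#' m <- parseModel(c(
#'   "pop ANC1 founder size=100",
#'   "pop ANC2 founder size=100",
#'   "gen 1: ADM size=5000 from ANC1:0.8,ANC2:0.2",
#'   "out gen=50 pop=ADM n=500"))
#' m
#' @export
parseModel <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  founders <- character(0); founderSizes <- integer(0)
  genLines <- list()   # list of (lineNo, g, pop, sizeM/F/total, sources...)
  rules <- list(); directives <- list()
  lastGen <- -Inf

  kv <- function(tok, key, lineNo, required = TRUE) {
    hit <- grep(paste0("^", key, "="), tok, value = TRUE)
    if (!length(hit)) {
      if (required) stop(sprintf("line %d: missing %s=", lineNo, key))
      return(NA_character_)
    }
    sub(paste0("^", key, "="), "", hit[1])
  }
  parseSources <- function(s, lineNo) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([^:]+):([0-9.eE+-]+)$", parts))
    if (any(vapply(m, length, 0L) != 3))
      stop(sprintf("line %d: malformed source list '%s'", lineNo, s))
    list(src = vapply(m, `[`, "", 2),
         prop = as.numeric(vapply(m, `[`, "", 3)))
  }

  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(l)) next
    tok <- strsplit(l, "[[:space:]]+")[[1]]
    if (tok[1] == "pop") {
      if (length(tok) < 4 || tok[3] != "founder")
        stop(sprintf("line %d: expected 'pop <name> founder size=<n>'", ln))
      founders <- c(founders, tok[2])
      founderSizes <- c(founderSizes, as.integer(kv(tok, "size", ln)))
    } else if (tok[1] == "gen") {
      g <- suppressWarnings(as.integer(sub(":$", "", tok[2])))
      if (is.na(g) || g < 1)
        stop(sprintf("line %d: bad generation number", ln))
      if (g < lastGen)
        stop(sprintf("line %d: non-monotone generation numbers (%d after %g)",
                     ln, g, lastGen))
      lastGen <- g
      pop <- tok[3]
      sz <- strsplit(kv(tok, "size", ln), ",", fixed = TRUE)[[1]]
      sizeM <- sizeF <- -1L
      if (length(sz) == 2) {
        sizeM <- as.integer(sz[1]); sizeF <- as.integer(sz[2])
        size <- sizeM + sizeF
      } else size <- as.integer(sz[1])
      grab <- function(word) {
        i <- which(tok == word)
        if (!length(i)) return(NULL)
        if (i[1] + 1 > length(tok))
          stop(sprintf("line %d: '%s' without a source list", ln, word))
        parseSources(tok[i[1] + 1], ln)
      }
      fr <- grab("from"); frF <- grab("from_f"); frM <- grab("from_m")
      if (is.null(fr) && (is.null(frF) || is.null(frM)))
        stop(sprintf("line %d: population '%s' needs 'from' (or both from_f and from_m)",
                     ln, pop))
      if (is.null(fr)) fr <- frF  # general vector defaults to the maternal one
      genLines[[length(genLines) + 1]] <-
        list(lineNo = ln, g = g, pop = pop, size = size,
             sizeM = sizeM, sizeF = sizeF, fr = fr, frF = frF, frM = frM)
    } else if (tok[1] == "sel") {
      popScope <- tok[2]
      chrom <- kv(tok, "chrom", ln)
      posS <- kv(tok, "pos", ln)
      if (grepl("-", posS, fixed = TRUE)) {
        pr <- as.numeric(strsplit(posS, "-", fixed = TRUE)[[1]])
        posSpec <- list(type = "range", from = pr[1], to = pr[2])
      } else {
        posSpec <- list(type = "set",
                        pos = as.numeric(strsplit(posS, ",", fixed = TRUE)[[1]]))
      }
      sS <- kv(tok, "s", ln)
      g1 <- NA_integer_; g2 <- NA_integer_
      if (grepl("@", sS, fixed = TRUE)) {
        pp <- strsplit(sS, "@", fixed = TRUE)[[1]]
        sS <- pp[1]
        gr <- as.integer(strsplit(pp[2], "-", fixed = TRUE)[[1]])
        g1 <- gr[1]; g2 <- if (length(gr) > 1) gr[2] else gr[1]
        if (is.na(g1) || is.na(g2) || g1 > g2)
          stop(sprintf("line %d: bad generation range in s=...@g1-g2", ln))
      }
      sexS <- kv(tok, "sex", ln, required = FALSE)
      sex <- if (is.na(sexS)) 0L else if (toupper(sexS) == "M") 1L
             else if (toupper(sexS) == "F") 2L
             else stop(sprintf("line %d: sex must be F or M", ln))
      allele <- as.integer(strsplit(kv(tok, "allele", ln), ",", fixed = TRUE)[[1]])
      if (!all(allele %in% 0:1))
        stop(sprintf("line %d: alleles must be 0 or 1", ln))
      s <- as.numeric(sS)
      if (!is.finite(s)) stop(sprintf("line %d: selection coefficient not finite", ln))
      rules[[length(rules) + 1]] <-
        list(pop = popScope, chrom = chrom, posSpec = posSpec,
             allele = allele, s = s, g1 = g1, g2 = g2, sex = sex, lineNo = ln)
    } else if (tok[1] == "out") {
      directives[[length(directives) + 1]] <-
        list(gen = as.integer(kv(tok, "gen", ln)), pop = kv(tok, "pop", ln),
             n = as.integer(kv(tok, "n", ln)), lineNo = ln)
    } else {
      stop(sprintf("line %d: unknown record '%s'", ln, tok[1]))
    }
  }
  if (!length(founders)) stop("model declares no founder populations")
  if (anyDuplicated(founders)) stop("duplicated founder population names")

  gensMentioned <- c(vapply(genLines, function(x) x$g, 0L),
                     vapply(directives, function(x) x$gen, 0L))
  G <- if (length(gensMentioned)) max(gensMentioned) else 0L

  registry <- founders
  curSize <- setNames(as.integer(founderSizes), founders)
  events <- vector("list", G)
  byGen <- split(genLines, vapply(genLines, function(x) x$g, 0L))
  for (g in seq_len(G)) {
    rows <- list()
    mentioned <- character(0)
    for (glr in if (as.character(g) %in% names(byGen)) byGen[[as.character(g)]] else list()) {
      pop <- glr$pop
      if (pop %in% mentioned)
        stop(sprintf("line %d: population '%s' appears twice at generation %d",
                     glr$lineNo, pop, g))
      mentioned <- c(mentioned, pop)
      if (!(pop %in% registry)) registry <- c(registry, pop)
      resolveSrc <- function(fr, isNew) {
        if (is.null(fr)) return(NULL)
        if (abs(sum(fr$prop) - 1) > 1e-9)
          stop(sprintf("line %d: proportions for '%s' sum to %.12g, not 1",
                       glr$lineNo, pop, sum(fr$prop)))
        bad <- setdiff(fr$src, names(curSize))
        if (length(bad))
          stop(sprintf("line %d: undeclared or extinct source population '%s'",
                       glr$lineNo, bad[1]))
        if (isNew && pop %in% fr$src)
          stop(sprintf("line %d: new population '%s' cannot source itself",
                       glr$lineNo, pop))
        list(src = match(fr$src, registry) - 1L, prop = fr$prop)
      }
      isNew <- !(pop %in% names(curSize))
      rows[[pop]] <- list(pop = match(pop, registry) - 1L,
                          size = glr$size, sizeM = glr$sizeM, sizeF = glr$sizeF,
                          src = NULL, fr = resolveSrc(glr$fr, isNew),
                          frF = resolveSrc(glr$frF, isNew),
                          frM = resolveSrc(glr$frM, isNew))
    }
    for (pop in setdiff(names(curSize), mentioned)) {
      rows[[pop]] <- list(pop = match(pop, registry) - 1L,
                          size = unname(curSize[pop]), sizeM = -1L, sizeF = -1L,
                          src = NULL,
                          fr = list(src = match(pop, registry) - 1L, prop = 1),
                          frF = NULL, frM = NULL)
    }
    rows <- rows[order(vapply(rows, function(r) r$pop, 0L))]
    events[[g]] <- lapply(rows, function(r) {
      list(pop = r$pop, size = r$size, sizeM = r$sizeM, sizeF = r$sizeF,
           src = r$fr$src, prop = r$fr$prop,
           srcF = r$frF$src, propF = r$frF$prop,
           srcM = r$frM$src, propM = r$frM$prop)
    })
    newSize <- setNames(vapply(rows, function(r) r$size, 0L),
                        registry[vapply(rows, function(r) r$pop, 0L) + 1L])
    curSize <- newSize[newSize > 0L]
  }

  rules <- lapply(rules, function(r) {
    if (r$pop != "*" && !(r$pop %in% registry))
      stop(sprintf("line %d: selection scope '%s' is not a known population",
                   r$lineNo, r$pop))
    r$g1 <- if (is.na(r$g1)) 1L else r$g1
    r$g2 <- if (is.na(r$g2)) G else min(r$g2, G)
    r
  })
  dir <- if (length(directives)) {
    data.frame(gen = vapply(directives, function(x) x$gen, 0L),
               pop = vapply(directives, function(x) x$pop, ""),
               n = vapply(directives, function(x) x$n, 0L),
               stringsAsFactors = FALSE)
  } else data.frame(gen = integer(0), pop = character(0), n = integer(0))
  if (nrow(dir) && !all(dir$pop %in% registry))
    stop("output directive names unknown population: ",
         paste(setdiff(dir$pop, registry), collapse = ", "))

  new("DemographicModel", registry = registry, founders = founders,
      founderSizes = as.integer(founderSizes), endGen = as.integer(G),
      events = events, rules = rules, directives = dir)
}

#' @rdname parseModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  parseModel(readLines(path, warn = FALSE))
}

#' Write a model back to its file dialect
#'
#' Serialises a [DemographicModel] (best effort: persist rows that
#' normalization added are omitted again).  Mainly used for scenario
#' bundles and chained simulations.
#'
#' @param model a [DemographicModel].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  out <- sprintf("pop %s founder size=%d", model@founders, model@founderSizes)
  prevSize <- setNames(rep(-1L, length(model@registry)), model@registry)
  prevSize[model@founders] <- model@founderSizes
  fmtSrc <- function(src, prop)
    paste(sprintf("%s:%g", model@registry[src + 1L], prop), collapse = ",")
  for (g in seq_len(model@endGen)) {
    for (row in model@events[[g]]) {
      nm <- model@registry[row$pop + 1L]
      selfOnly <- length(row$src) == 1 && model@registry[row$src + 1L] == nm &&
        is.null(row$srcF) && is.null(row$srcM)
      if (selfOnly && prevSize[nm] == row$size) next
      sz <- if (row$sizeM >= 0) sprintf("%d,%d", row$sizeM, row$sizeF)
            else sprintf("%d", row$size)
      l <- sprintf("gen %d: %s size=%s from %s", g, nm, sz,
                   fmtSrc(row$src, row$prop))
      if (!is.null(row$srcF))
        l <- paste(l, "from_f", fmtSrc(row$srcF, row$propF))
      if (!is.null(row$srcM))
        l <- paste(l, "from_m", fmtSrc(row$srcM, row$propM))
      out <- c(out, l)
      prevSize[nm] <- row$size
    }
  }
  for (r in model@rules) {
    posS <- if (r$posSpec$type == "range")
      sprintf("%g-%g", r$posSpec$from, r$posSpec$to)
    else paste(format(r$posSpec$pos, scientific = FALSE, trim = TRUE), collapse = ",")
    l <- sprintf("sel %s chrom=%s pos=%s allele=%s s=%g@%d-%d", r$pop, r$chrom,
                 posS, paste(r$allele, collapse = ","), r$s, r$g1, r$g2)
    if (r$sex == 1L) l <- paste0(l, " sex=M")
    if (r$sex == 2L) l <- paste0(l, " sex=F")
    out <- c(out, l)
  }
  d <- model@directives
  if (nrow(d))
    out <- c(out, sprintf("out gen=%d pop=%s n=%d", d$gen, d$pop, d$n))
  writeLines(out, path)
  invisible(path)
}
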