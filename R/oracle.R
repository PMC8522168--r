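#' @include AllClasses.R GenomeSpec.R engine.R
NULL

# The brute-force per-site simulator.
#
# Haplotypes are explicit allele vectors over every SNV (plus a set of
# non-SNV de novo positions); crossovers are applied site by site instead
# of by segment splicing.  The simulator consumes R's RNG stream in exactly
# the order documented in src/engine.cpp, so with the same seed it makes
# the same random decisions as the segment engine and must produce
# identical output sequences.  It shares no simulation code with the
# engine and exists purely as an independent correctness oracle; it is
# O(sites x individuals x generations) and only sensible at toy scale.

.oraclePickCell <- function(cum, u) min(sum(cum <= u) + 1L, length(cum))

.oracleGamete <- function(hapA, hapB, cl, pos0) {
  k <- if (cl$mapGen[length(cl$mapGen)] > 0)
    rpois(1, cl$mapGen[length(cl$mapGen)]) else 0L
  cx <- numeric(0)
  if (k > 0) {
    glen <- cl$mapGen[length(cl$mapGen)]
    cx <- vapply(seq_len(k), function(i) .gen2phys(cl, runif(1) * glen), 0)
    cx <- unique(sort(cx))
  }
  cur <- if (runif(1) < 0.5) 1L else 2L
  pick <- function(q) {  # 1 -> from hapA, 2 -> from hapB
    if ((cur - 1L + sum(cx <= q)) %% 2L == 0L) 1L else 2L
  }
  src <- vapply(pos0, pick, 0L)
  alleles <- ifelse(src == 1L, hapA$alleles, hapB$alleles)
  extra <- sort(c(hapA$extra[vapply(hapA$extra, pick, 0L) == 1L],
                  hapB$extra[vapply(hapB$extra, pick, 0L) == 2L]))
  list(alleles = as.integer(alleles), extra = as.numeric(extra))
}

.oracleMutate <- function(hap, cl, pos0) {
  if (cl$muTotal <= 0) return(hap)
  m <- rpois(1, cl$muTotal)
  for (i in seq_len(m)) {
    if (cl$uniformMut) {
      q <- floor(runif(1) * cl$length)
    } else {
      cum <- cumsum(cl$mutRates)
      u <- runif(1) * cum[length(cum)]
      q <- cl$mutPos[min(sum(cum <= u) + 1L, length(cum))]
    }
    j <- match(q, pos0)
    if (!is.na(j)) {
      hap$alleles[j] <- 1L - hap$alleles[j]
    } else if (q %in% hap$extra) {
      hap$extra <- setdiff(hap$extra, q)
    } else {
      hap$extra <- sort(c(hap$extra, q))
    }
  }
  hap
}

.oracleFitness <- function(ind, popIdx, g, rules, selSiteIdx) {
  f <- 1
  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    if (r$pop >= 0L && r$pop != popIdx) next
    if (g < r$g1 || g > r$g2) next
    if (r$sex != 0L && r$sex != ind$sex) next
    sites <- selSiteIdx[[r$chrom + 1L]][r$posIdx + 1L]
    for (h in ind$chroms[[r$chrom + 1L]])
      if (all(h$alleles[sites] == r$allele)) f <- f + r$s
  }
  max(0, f)
}

#' Brute-force per-site forward simulation (validation oracle)
#'
#' Runs the same extended Wright-Fisher model as [runSimulation()] but on
#' explicit per-site allele vectors, applying every crossover site by site
#' rather than through segment arithmetic, and sharing no code with the
#' segment engine.  Both consume R's RNG in the same documented order, so
#' given the same seed the two must produce identical output sequences;
#' [runSimulation()] plus [extractSequences()] is checked against this
#' function in the test suite.  Complexity scales with SNV count, so use
#' at toy scale only.
#'
#' @inheritParams runSimulation
#' @return Named list (`"g<gen>.<pop>"`) of retained states; each has
#'   `sexes`, `alleles` (0/1 matrix, one row per haplotype, SNV columns in
#'   panel order) and `extra` (per haplotype, sorted non-SNV de novo
#'   positions, 0-based bp).
#' @export
perSiteSimulate <- function(panel, model, genome = NULL, seed = 1L) {
  if (is.null(genome)) genome <- GenomeSpec(snv = panel)
  snv <- panel@snv
  ind <- panel@individuals
  dioecious <- any(ind$sex != 0L)
  res <- .resolveRules(model, genome, snv)
  cls <- .chromList(genome, snv = snv, selPos = res$selPos)
  chromNames <- genome@chroms$name
  pos0 <- lapply(chromNames, function(cc) snv$pos[snv$chrom == cc] - 1)
  colIdx <- lapply(chromNames, function(cc) which(snv$chrom == cc))
  selSiteIdx <- lapply(seq_along(chromNames), function(ci)
    match(res$selPos[[ci]], pos0[[ci]]))
  rules <- res$rulesR

  # founders: explicit allele vectors straight from the panel
  ranges <- founderLabelRanges(panel)
  state <- list()
  for (i in seq_along(model@founders)) {
    pop <- model@founders[i]
    rows <- which(ind$pop == pop)
    inds <- list()
    for (j in seq_along(rows)) {
      sx <- ind$sex[rows[j]]
      chroms <- list()
      for (ci in seq_along(chromNames)) {
        nh <- if (cls[[ci]]$isX && sx == 1L) 1L else 2L
        chroms[[ci]] <- lapply(seq_len(nh), function(k) {
          list(alleles = unname(panel@haplotypes[2L * rows[j] - 2L + k,
                                                 colIdx[[ci]]]),
               extra = numeric(0))
        })
      }
      inds[[j]] <- list(sex = sx, chroms = chroms)
    }
    state[[as.character(match(pop, model@registry) - 1L)]] <- inds
  }

  d <- model@directives
  retain <- cbind(d$gen, match(d$pop, model@registry) - 1L)
  kept <- list()
  keep <- function(g, pi) {
    inds <- state[[as.character(pi)]]
    nm <- sprintf("g%d.%s", g, model@registry[pi + 1L])
    rowsA <- list(); sexes <- integer(0); extras <- list(); ids <- character(0)
    for (j in seq_along(inds)) {
      sexes <- c(sexes, inds[[j]]$sex)
      nh <- length(inds[[j]]$chroms[[1]])
      for (k in seq_len(nh)) {
        rowsA[[length(rowsA) + 1L]] <-
          unlist(lapply(seq_along(chromNames), function(ci)
            inds[[j]]$chroms[[ci]][[k]]$alleles))
        extras[[length(extras) + 1L]] <-
          unlist(lapply(seq_along(chromNames), function(ci)
            inds[[j]]$chroms[[ci]][[k]]$extra))
        ids <- c(ids, sprintf("%s_g%d_i%d_h%d", model@registry[pi + 1L],
                              g, j, k))
      }
    }
    kept[[nm]] <<- list(pop = model@registry[pi + 1L], gen = g,
                        sexes = sexes, hapIDs = ids,
                        alleles = do.call(rbind, rowsA), extra = extras)
  }

  set.seed(as.integer(seed))
  G <- model@endGen
  for (g in 0) if (nrow(retain)) for (r in which(retain[, 1] == 0))
    keep(0L, retain[r, 2])
  for (g in seq_len(G)) {
    nxt <- list()
    for (row in model@events[[g]]) {
      if (row$size == 0) next
      n <- row$size
      sexSized <- row$sizeM >= 0 && row$sizeF >= 0
      sexes <- integer(n)
      if (sexSized) {
        sexes <- c(rep(1L, row$sizeM), rep(2L, row$sizeF))
        if (n >= 2) for (i in n:2) {  # Fisher-Yates, parity with engine
          j <- floor(runif(1) * i) + 1L
          tmp <- sexes[i]; sexes[i] <- sexes[j]; sexes[j] <- tmp
        }
      }
      cumAll <- cumsum(row$prop)
      cumF <- if (is.null(row$srcF)) cumAll else cumsum(row$propF)
      cumM <- if (is.null(row$srcM)) cumAll else cumsum(row$propM)
      sF <- if (is.null(row$srcF)) row$src else row$srcF
      sM <- if (is.null(row$srcM)) row$src else row$srcM
      pools <- list()
      getPool <- function(src, cls2) {
        key <- paste(src, cls2)
        if (is.null(pools[[key]])) {
          inds <- state[[as.character(src)]]
          if (is.null(inds))
            stop("source population missing at generation ", g - 1)
          sel <- if (cls2 == 0L) seq_along(inds)
                 else which(vapply(inds, function(x) x$sex, 0L) == cls2)
          if (!length(sel)) stop("empty parent pool at generation ", g - 1)
          w <- vapply(sel, function(ii)
            .oracleFitness(inds[[ii]], src, g, rules, selSiteIdx), 0)
          pools[[key]] <<- list(idx = sel, cum = cumsum(w))
        }
        pools[[key]]
      }
      kids <- vector("list", n)
      for (o in seq_len(n)) {
        sex <- 0L
        if (dioecious)
          sex <- if (sexSized) sexes[o] else if (runif(1) < 0.5) 1L else 2L
        cls1 <- if (dioecious) 2L else 0L
        cls2 <- if (dioecious) 1L else 0L
        src1 <- sF[.oraclePickCell(cumF, runif(1))]
        P1 <- getPool(src1, cls1)
        p1 <- P1$idx[.oraclePickCell(P1$cum, runif(1) * P1$cum[length(P1$cum)])]
        src2 <- sM[.oraclePickCell(cumM, runif(1))]
        P2 <- getPool(src2, cls2)
        p2 <- P2$idx[.oraclePickCell(P2$cum, runif(1) * P2$cum[length(P2$cum)])]
        if (!dioecious && src2 == src1) {
          if (length(state[[as.character(src1)]]) < 2)
            stop("monoecious population needs at least two individuals")
          while (p2 == p1)
            p2 <- P2$idx[.oraclePickCell(P2$cum,
                                         runif(1) * P2$cum[length(P2$cum)])]
        }
        mother <- state[[as.character(src1)]][[p1]]
        father <- state[[as.character(src2)]][[p2]]
        chroms <- list()
        for (ci in seq_along(chromNames)) {
          cl <- cls[[ci]]
          mh <- mother$chroms[[ci]]
          g1 <- if (length(mh) == 2) .oracleGamete(mh[[1]], mh[[2]], cl, pos0[[ci]])
                else .oracleGamete(mh[[1]], mh[[1]], cl, pos0[[ci]])
          g1 <- .oracleMutate(g1, cl, pos0[[ci]])
          if (cl$isX && sex == 1L) { chroms[[ci]] <- list(g1); next }
          fh <- father$chroms[[ci]]
          g2 <- if (cl$isX && dioecious) fh[[1]]
                else if (length(fh) == 2) .oracleGamete(fh[[1]], fh[[2]], cl, pos0[[ci]])
                else .oracleGamete(fh[[1]], fh[[1]], cl, pos0[[ci]])
          g2 <- .oracleMutate(g2, cl, pos0[[ci]])
          chroms[[ci]] <- list(g1, g2)
        }
        kids[[o]] <- list(sex = sex, chroms = chroms)
      }
      nxt[[as.character(row$pop)]] <- kids
    }
    state <- nxt
    if (nrow(retain)) for (r in which(retain[, 1] == g)) keep(g, retain[r, 2])
  }
  for (pi in as.integer(names(state))) {
    nm <- sprintf("g%d.%s", G, model@registry[pi + 1L])
    if (is.null(kept[[nm]])) keep(G, pi)
  }
  kept
}
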