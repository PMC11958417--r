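#' Microsatellite genotype tables
#'
#' Genotypes are held long-format: one row per individual x locus with two
#' integer allele sizes (unordered; `NA` for missing). Helpers below convert
#' to an internal per-individual list for likelihood computations.
#'
#' @param df data.frame with columns `individual_id`, `locus`, `allele1`,
#'   `allele2`.
#' @return data.frame of class `microsat_genotypes`.
#' @export
microsat_genotypes <- function(df) {
  need <- c("individual_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  bad <- !is.na(df$allele1) & df$allele1 <= 0 |
         !is.na(df$allele2) & df$allele2 <= 0
  if (any(bad)) stop("allele sizes must be positive")
  if (anyDuplicated(df[, c("individual_id", "locus")]))
    stop("duplicate individual x locus rows")
  class(df) <- c("microsat_genotypes", "data.frame")
  df
}

ms_pair <- function(ms, id, locus) {
  r <- ms[ms$individual_id == id & ms$locus == locus, ]
  if (nrow(r) == 0 || is.na(r$allele1[1]) || is.na(r$allele2[1]))
    return(NULL)
  sort(c(r$allele1[1], r$allele2[1]))
}

ms_loci <- function(ms) unique(ms$locus)

#' Per-locus allele frequencies by direct counting
#'
#' @param ms A [microsat_genotypes()] table.
#' @return Named list (per locus) of named numeric frequency vectors summing
#'   to 1. A locus with no non-missing genotype is an error.
#' @export
allele_frequencies <- function(ms) {
  out <- list()
  for (loc in ms_loci(ms)) {
    r <- ms[ms$locus == loc & !is.na(ms$allele1) & !is.na(ms$allele2), ]
    if (nrow(r) == 0) stop("locus ", loc, " has no non-missing genotypes")
    tab <- table(c(r$allele1, r$allele2))
    out[[as.character(loc)]] <- stats::setNames(as.numeric(tab) / sum(tab),
                                                names(tab))
  }
  out
}

freq_of <- function(f, allele) {
  x <- unname(f[as.character(allele)])
  ifelse(is.na(x), 0, x)
}

hw_prob <- function(pair, f) {
  p <- freq_of(f, pair[1]); q <- freq_of(f, pair[2])
  if (pair[1] == pair[2]) p * p else 2 * p * q
}

# probability that a parent with genotype g transmits allele a
transmit <- function(g, a) mean(g == a)

#' Single-parent LOD score (Kalinowski-style likelihood ratio)
#'
#' Sums, over loci typed in both individuals, the natural log of
#' P(offspring genotype | candidate is a parent, population frequencies) over
#' P(offspring genotype | frequencies alone). With `error_rate > 0` the
#' observed offspring genotype is, with that probability, a random
#' Hardy-Weinberg draw, so Mendelian-incompatible loci contribute finite
#' penalties instead of `-Inf`. Missing loci contribute 0.
#'
#' @param offspring,candidate Individual ids.
#' @param ms A [microsat_genotypes()] table.
#' @param freqs Output of [allele_frequencies()] (computed if `NULL`).
#' @param error_rate Per-locus genotype replacement probability in `[0, 1)`.
#' @return Natural-log LOD (scalar; `-Inf` possible at `error_rate = 0`).
#' @export
lod_single_parent <- function(offspring, candidate, ms,
                              freqs = NULL, error_rate = 0) {
  if (is.null(freqs)) freqs <- allele_frequencies(ms)
  lod <- 0
  for (loc in names(freqs)) {
    o <- ms_pair(ms, offspring, loc); p <- ms_pair(ms, candidate, loc)
    if (is.null(o) || is.null(p)) next
    f <- freqs[[loc]]
    hw <- hw_prob(o, f)
    num <- if (o[1] == o[2]) transmit(p, o[1]) * freq_of(f, o[1]) else
      transmit(p, o[1]) * freq_of(f, o[2]) +
      transmit(p, o[2]) * freq_of(f, o[1])
    l1 <- (1 - error_rate) * num + error_rate * hw
    lod <- lod + log(l1 / hw)
  }
  lod
}

#' Parent-pair LOD score
#'
#' As [lod_single_parent()] but conditioning on both candidate parents, each
#' transmitting one allele.
#'
#' @inheritParams lod_single_parent
#' @param mother,father Candidate parent ids.
#' @return Natural-log LOD.
#' @export
lod_parent_pair <- function(offspring, mother, father, ms,
                            freqs = NULL, error_rate = 0) {
  if (is.null(freqs)) freqs <- allele_frequencies(ms)
  lod <- 0
  for (loc in names(freqs)) {
    o <- ms_pair(ms, offspring, loc)
    m <- ms_pair(ms, mother, loc); fa <- ms_pair(ms, father, loc)
    if (is.null(o) || is.null(m) || is.null(fa)) next
    f <- freqs[[loc]]
    hw <- hw_prob(o, f)
    num <- if (o[1] == o[2]) transmit(m, o[1]) * transmit(fa, o[1]) else
      transmit(m, o[1]) * transmit(fa, o[2]) +
      transmit(m, o[2]) * transmit(fa, o[1])
    l1 <- (1 - error_rate) * num + error_rate * hw
    lod <- lod + log(l1 / hw)
  }
  lod
}

#' Mendelian compatibility of an offspring-mother-father trio
#'
#' A locus is compatible when the offspring pair can be formed by one allele
#' from each parent. Missing loci are skipped.
#'
#' @inheritParams lod_parent_pair
#' @return List with per-locus logical `compatible` (named) and integer
#'   `n_mismatch`.
#' @export
mendelian_compatible <- function(offspring, mother, father, ms) {
  comp <- logical(0)
  for (loc in ms_loci(ms)) {
    o <- ms_pair(ms, offspring, loc)
    m <- ms_pair(ms, mother, loc); fa <- ms_pair(ms, father, loc)
    if (is.null(o) || is.null(m) || is.null(fa)) next
    ok <- (o[1] %in% m && o[2] %in% fa) || (o[2] %in% m && o[1] %in% fa)
    comp[as.character(loc)] <- ok
  }
  list(compatible = comp, n_mismatch = sum(!comp))
}

#' Minimum number of unsampled fathers for a mother-defined family
#'
#' For each locus, counts the distinct offspring alleles not carried by the
#' mother; each father contributes at most two distinct alleles, so the
#' minimum father count is the ceiling of half the maximum such count over
#' loci.
#'
#' @param mother Mother id.
#' @param offspring Character vector of offspring ids.
#' @param ms A [microsat_genotypes()] table.
#' @return Integer (at least 1 when any offspring is typed).
#' @export
min_unsampled_fathers <- function(mother, offspring, ms) {
  mx <- 0
  for (loc in ms_loci(ms)) {
    m <- ms_pair(ms, mother, loc)
    if (is.null(m)) next
    pat <- unlist(lapply(offspring, function(o) {
      g <- ms_pair(ms, o, loc)
      if (is.null(g)) return(NULL)
      setdiff(g, m)
    }))
    mx <- max(mx, length(unique(pat)))
  }
  max(1L, as.integer(ceiling(mx / 2)))
}

#' Assign offspring to parents and build mother-defined families
#'
#' For each offspring, single-mother, single-father and parent-pair LOD
#' analyses are run; an offspring is `assigned` when the best mother, best
#' father and best pair are positive-LOD and mutually consistent. Two
#' same-sex candidates with positive LODs within `lod_margin` of each other
#' make the offspring `ambiguous`. Assigned offspring are grouped into
#' families by mother; each family reports the minimum number of unsampled
#' fathers inferred from non-maternal allele counts.
#'
#' @param offspring Character vector of offspring ids.
#' @param mothers,fathers Character vectors of candidate parent ids (disjoint
#'   from `offspring`).
#' @param ms A [microsat_genotypes()] table.
#' @param error_rate Passed to the LOD functions.
#' @param lod_margin Ambiguity margin on the LOD scale (default 0.1).
#' @return List with `results` (one row per offspring: best parents, LODs,
#'   status) and `families` (one row per mother with her assigned offspring
#'   and the minimum unsampled-father count).
#' @export
assign_families <- function(offspring, mothers, fathers, ms,
                            error_rate = 0, lod_margin = 0.1) {
  if (length(intersect(offspring, c(mothers, fathers))))
    stop("candidate parents must be disjoint from offspring")
  freqs <- allele_frequencies(ms)
  best_of <- function(o, cands) {
    if (length(cands) == 0) return(list(id = NA, lod = -Inf, amb = FALSE))
    lods <- vapply(cands, function(p)
      lod_single_parent(o, p, ms, freqs, error_rate), numeric(1))
    ord <- order(-lods)
    amb <- length(cands) > 1 && lods[ord[1]] > 0 && lods[ord[2]] > 0 &&
      (lods[ord[1]] - lods[ord[2]]) < lod_margin
    list(id = cands[ord[1]], lod = lods[ord[1]], amb = amb)
  }
  rows <- lapply(offspring, function(o) {
    bm <- best_of(o, mothers); bf <- best_of(o, fathers)
    pair_lod <- if (!is.na(bm$id) && !is.na(bf$id))
      lod_parent_pair(o, bm$id, bf$id, ms, freqs, error_rate) else -Inf
    status <- if (bm$amb || bf$amb) "ambiguous" else
      if (!is.na(bm$id) && bm$lod > 0 && !is.na(bf$id) && bf$lod > 0 &&
          pair_lod > 0) "assigned" else "unassigned"
    data.frame(offspring = o,
               mother = bm$id, mother_lod = bm$lod,
               father = bf$id, father_lod = bf$lod,
               pair_lod = pair_lod, status = status,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  fam_rows <- lapply(mothers, function(m) {
    kids <- results$offspring[results$status == "assigned" &
                              results$mother == m]
    if (length(kids) == 0) return(NULL)
    data.frame(mother = m,
               fathers = paste(sort(unique(
                 results$father[results$offspring %in% kids])),
                 collapse = ","),
               offspring = paste(kids, collapse = ","),
               n_offspring = length(kids),
               min_unsampled_fathers = min_unsampled_fathers(m, kids, ms),
               stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, fam_rows)
  list(results = results, families = families)
}
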