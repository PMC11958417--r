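#' Simulation configuration
#'
#' Defaults mirror the study system: an allele pool of 5 A, 20 B and 4 C
#' lineage alleles, haplotypes of one or two A/B alleles with an optional C
#' allele that is absent from a substantial fraction of haplotypes
#' (hemizygosity), mother-defined families with Dirichlet-weighted multiple
#' paternity, amplicon read tables with chimera / single-substitution /
#' bleed-through artifacts and C-amplicon dropout, and 11 co-dominant
#' microsatellite loci.
#'
#' @param seed Integer seed fixing all downstream randomness.
#' @param pool_sizes Named integer vector `c(A=, B=, C=)`.
#' @param seq_length Allele length in bp (multiple of 3; coding frame 0).
#' @param within_divergence,between_divergence Expected pairwise nucleotide
#'   p-distance within a lineage and between lineage ancestors
#'   (substitutions per site); within must be below between.
#' @param n_haplotypes Size of the founding haplotype pool.
#' @param c_absent_fraction Fraction of pool haplotypes with no C allele.
#' @param p_ab_mixed Probability a haplotype carries one A plus one B allele
#'   (otherwise one or two B alleles).
#' @param n_mothers,n_fathers,offspring_per_mother Pedigree dimensions.
#' @param paternity_concentration Dirichlet concentration for per-mother
#'   father weights: large values approach single paternity, small values
#'   spread offspring over many fathers.
#' @param read_depth Reads per amplicon.
#' @param chimera_rate,onebp_rate,bleed_rate Per-amplicon artifact injection
#'   probabilities.
#' @param c_dropout Probability that a sample's C amplicon fails (status
#'   `"missing"`).
#' @param allele_dropout Per-allele probability that an A/B allele is missed
#'   in an observed genotype (used for phasing-robustness checks).
#' @param replicate_fraction Fraction of samples with a replicate amplicon.
#' @param n_microsat_loci,microsat_alleles,microsat_error Microsatellite
#'   panel shape and genotyping error rate.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       pool_sizes = c(A = 5, B = 20, C = 4),
                       seq_length = 240,
                       within_divergence = 0.10,
                       between_divergence = 0.35,
                       n_haplotypes = 14,
                       c_absent_fraction = 0.6,
                       p_ab_mixed = 0.35,
                       n_mothers = 5, n_fathers = 3,
                       offspring_per_mother = 10,
                       paternity_concentration = 1,
                       read_depth = 3000,
                       chimera_rate = 0, onebp_rate = 0, bleed_rate = 0,
                       c_dropout = 0, allele_dropout = 0,
                       replicate_fraction = 0.2,
                       n_microsat_loci = 11, microsat_alleles = 6,
                       microsat_error = 0) {
  rates <- c(chimera_rate, onebp_rate, bleed_rate, c_dropout,
             allele_dropout, c_absent_fraction, p_ab_mixed,
             replicate_fraction, microsat_error)
  stopifnot(all(rates >= 0 & rates <= 1), all(pool_sizes >= 1),
            seq_length %% 3 == 0)
  structure(as.list(environment()), class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

has_stop <- function(s) {
  codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  any(codons %in% STOP_CODONS)
}

random_coding_seq <- function(len) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!has_stop(s)) return(s)
  }
}

# exactly round(rate * len) substitutions at distinct positions, stop-free
mutate_seq <- function(s, rate, max_tries = 200) {
  len <- nchar(s)
  k <- round(rate * len)
  if (k == 0) return(s)
  for (try in seq_len(max_tries)) {
    pos <- sample(len, k)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    out <- paste(ch, collapse = "")
    if (!has_stop(out)) return(out)
  }
  stop("could not place mutations without creating a stop codon")
}

#' Simulate a three-lineage allele pool
#'
#' Lineage ancestors diverge from a common root at the between-lineage rate;
#' alleles diverge from their lineage ancestor at half the within-lineage
#' rate, so pairwise within-lineage p-distances concentrate around
#' `within_divergence`. All sequences are unique and stop-free in frame 0.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return List with `sequences` (named), `lineages` (named), `frame` (0)
#'   and the off-target `paralog` sequence used for failed C amplicons.
#' @export
simulate_allele_pool <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$within_divergence >= cfg$between_divergence)
    stop("within-lineage divergence must be below between-lineage divergence")
  root <- random_coding_seq(cfg$seq_length)
  seqs <- character(0); lins <- character(0)
  for (lin in names(cfg$pool_sizes)) {
    anc <- mutate_seq(root, cfg$between_divergence / 2)
    n <- cfg$pool_sizes[[lin]]
    for (i in seq_len(n)) {
      repeat {
        s <- mutate_seq(anc, cfg$within_divergence / 2)
        if (!s %in% seqs) break
      }
      id <- sprintf("%s%02d", lin, i)
      seqs[id] <- s
      lins[id] <- lin
    }
  }
  paralog <- mutate_seq(root, 0.45)
  list(sequences = seqs, lineages = lins, frame = 0, paralog = paralog)
}

#' Simulate a founding haplotype pool
#'
#' @param cfg A [sim_config()].
#' @param pool Output of [simulate_allele_pool()].
#' @param seed Optional seed.
#' @return List of haplotypes (each `list(ab, c)`), all distinct.
#' @export
simulate_haplotype_pool <- function(cfg = sim_config(), pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a_ids <- names(pool$lineages)[pool$lineages == "A"]
  b_ids <- names(pool$lineages)[pool$lineages == "B"]
  c_ids <- names(pool$lineages)[pool$lineages == "C"]
  out <- list(); seen <- character(0)
  while (length(out) < cfg$n_haplotypes) {
    ab <- if (stats::runif(1) < cfg$p_ab_mixed)
      c(sample(a_ids, 1), sample(b_ids, 1)) else
      sample(b_ids, sample(1:2, 1))
    cc <- if (stats::runif(1) < cfg$c_absent_fraction) character(0) else
      sample(c_ids, 1)
    h <- hap(ab, cc)
    k <- hap_key(h)
    if (!k %in% seen) { seen <- c(seen, k); out <- c(out, list(h)) }
  }
  out
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate a multi-family pedigree with multiple paternity
#'
#' Each parent carries two haplotypes drawn from the pool; each mother's
#' offspring are sired by fathers drawn with Dirichlet-weighted
#' probabilities; each offspring inherits one haplotype from each parent.
#'
#' @param cfg A [sim_config()].
#' @param hap_pool Output of [simulate_haplotype_pool()].
#' @param seed Optional seed.
#' @return List with `individuals` (data.frame: id, role, mother, father,
#'   hap1, hap2 as pool indices), `haplotypes` (the pool) and `families`
#'   (list of [phase_family()]-ready family definitions).
#' @export
simulate_pedigree <- function(cfg = sim_config(), hap_pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npool <- length(hap_pool)
  draw2 <- function() sample(npool, 2, replace = TRUE)
  rows <- list()
  mothers <- sprintf("M%02d", seq_len(cfg$n_mothers))
  fathers <- sprintf("F%02d", seq_len(cfg$n_fathers))
  for (id in c(mothers, fathers)) {
    hp <- draw2()
    rows[[id]] <- data.frame(id = id,
                             role = if (startsWith(id, "M")) "mother" else
                               "father",
                             mother = NA_character_, father = NA_character_,
                             hap1 = hp[1], hap2 = hp[2],
                             stringsAsFactors = FALSE)
  }
  families <- list()
  for (m in mothers) {
    w <- rdirichlet1(rep(cfg$paternity_concentration, cfg$n_fathers))
    kids <- character(0); sires <- character(0)
    for (j in seq_len(cfg$offspring_per_mother)) {
      f <- fathers[sample(cfg$n_fathers, 1, prob = w)]
      id <- sprintf("%s-O%02d", m, j)
      mh <- rows[[m]][, sample(c("hap1", "hap2"), 1)]
      fh <- rows[[f]][, sample(c("hap1", "hap2"), 1)]
      rows[[id]] <- data.frame(id = id, role = "offspring",
                               mother = m, father = f,
                               hap1 = mh, hap2 = fh,
                               stringsAsFactors = FALSE)
      kids <- c(kids, id); sires <- c(sires, f)
    }
    families[[m]] <- list(family_id = m, mother = m,
                          offspring = data.frame(offspring_id = kids,
                                                 father_id = sires,
                                                 stringsAsFactors = FALSE))
  }
  list(individuals = do.call(rbind, rows), haplotypes = hap_pool,
       families = families)
}

diplotype_geno <- function(h1, h2, c_status_missing = FALSE) {
  ab <- sort(unique(c(h1$ab, h2$ab)))
  cc <- sort(unique(c(h1$c, h2$c)))
  if (c_status_missing)
    mhc_genotype(NA_character_, ab, character(0), "missing") else
    mhc_genotype(NA_character_, ab, cc)
}

#' Observed MHC genotypes from a simulated pedigree
#'
#' Applies genotype-level noise: per-allele A/B dropout and C-amplicon
#' dropout (status `"missing"`).
#'
#' @param ped Output of [simulate_pedigree()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return `mhc_genotypes` data.frame covering all individuals.
#' @export
simulated_genotypes <- function(ped, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- ped$individuals
  rows <- lapply(seq_len(nrow(ind)), function(i) {
    h1 <- ped$haplotypes[[ind$hap1[i]]]
    h2 <- ped$haplotypes[[ind$hap2[i]]]
    ab <- sort(unique(c(h1$ab, h2$ab)))
    cc <- sort(unique(c(h1$c, h2$c)))
    if (cfg$allele_dropout > 0 && length(ab))
      ab <- ab[stats::runif(length(ab)) >= cfg$allele_dropout]
    if (cfg$c_dropout > 0 && stats::runif(1) < cfg$c_dropout)
      return(mhc_genotype(ind$id[i], ab, character(0), "missing"))
    mhc_genotype(ind$id[i], ab, cc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mhc_genotypes", "data.frame")
  out
}

#' Simulate an amplicon read table with injected artifacts
#'
#' Per individual, an `NF2-NR2` amplicon carries its A/B alleles and a
#' `DF2-DR2` amplicon its C alleles (an off-target paralog when the
#' individual has none; the amplicon is skipped entirely — logged `missing`
#' — with probability `c_dropout`). Reads are multinomial at `read_depth`.
#' Injected artifacts: single-breakpoint chimeras of two carried alleles,
#' single-substitution variants of a carried allele, and bleed-through of an
#' allele from another individual, all at within-amplicon frequencies of
#' 1.5-4% (above the frequency filter, below any parent allele).
#'
#' @param ped Output of [simulate_pedigree()].
#' @param pool Output of [simulate_allele_pool()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return List with `table` (an [asv_table()]), `log` (artifact injection
#'   log) and `c_missing` (sample ids whose C amplicon was dropped).
#' @export
simulate_asv_table <- function(ped, pool, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- ped$individuals
  seqs <- pool$sequences
  var_seqs <- c(seqs, paralog = pool$paralog)
  counts <- list(); meta <- list(); log <- list(); c_missing <- character(0)
  art_n <- 0
  carried <- function(i, lin_c) {
    h1 <- ped$haplotypes[[ind$hap1[i]]]; h2 <- ped$haplotypes[[ind$hap2[i]]]
    if (lin_c) sort(unique(c(h1$c, h2$c))) else
      sort(unique(c(h1$ab, h2$ab)))
  }
  all_ab <- sort(unique(unlist(lapply(seq_len(nrow(ind)), carried,
                                      lin_c = FALSE))))
  all_c <- sort(unique(unlist(lapply(seq_len(nrow(ind)), carried,
                                     lin_c = TRUE))))
  add_amplicon <- function(amp_id, sample_id, primer, alleles, replicate) {
    w <- stats::setNames(rep(1, length(alleles)), alleles)
    arts <- list()
    if (length(alleles) >= 2 && stats::runif(1) < cfg$chimera_rate) {
      par <- sample(alleles, 2)
      bp <- sample(seq_len(nchar(var_seqs[[par[1]]]) - 1), 1)
      sq <- paste0(substr(var_seqs[[par[1]]], 1, bp),
                   substr(var_seqs[[par[2]]], bp + 1,
                          nchar(var_seqs[[par[2]]])))
      if (!sq %in% var_seqs) {
        art_n <<- art_n + 1
        id <- sprintf("chi%03d", art_n)
        var_seqs[[id]] <<- sq
        arts[[id]] <- list(type = "chimera", parents = par)
      }
    }
    if (length(alleles) >= 1 && stats::runif(1) < cfg$onebp_rate) {
      par <- sample(alleles, 1)
      sq <- mutate_seq(var_seqs[[par]], 1 / nchar(var_seqs[[par]]))
      if (!sq %in% var_seqs) {
        art_n <<- art_n + 1
        id <- sprintf("err%03d", art_n)
        var_seqs[[id]] <<- sq
        arts[[id]] <- list(type = "onebp", parents = par)
      }
    }
    # bleed-through comes from co-sequenced samples, so only alleles
    # carried by some other individual in the run can leak in
    circulating <- if (primer == "DF2-DR2") all_c else all_ab
    foreign <- setdiff(circulating, alleles)
    if (length(foreign) && stats::runif(1) < cfg$bleed_rate) {
      id <- sample(foreign, 1)
      arts[[id]] <- list(type = "bleed", parents = id)
    }
    for (id in names(arts)) {
      w[id] <- stats::runif(1, 0.015, 0.04) * length(alleles)
      log[[length(log) + 1]] <<- data.frame(
        amplicon = amp_id, variant = id, type = arts[[id]]$type,
        parents = paste(arts[[id]]$parents, collapse = "+"),
        stringsAsFactors = FALSE)
    }
    cnt <- stats::rmultinom(1, cfg$read_depth, w / sum(w))[, 1]
    counts[[amp_id]] <<- stats::setNames(cnt, names(w))
    meta[[amp_id]] <<- data.frame(amplicon_id = amp_id, sample_id = sample_id,
                                  primer_set = primer, replicate = replicate,
                                  stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    replicate_me <- stats::runif(1) < cfg$replicate_fraction
    ab <- carried(i, FALSE)
    add_amplicon(paste0(id, ".NF"), id, "NF2-NR2", ab, "")
    if (replicate_me)
      add_amplicon(paste0(id, ".NF.r"), id, "NF2-NR2", ab, "rep1")
    if (stats::runif(1) < cfg$c_dropout) {
      c_missing <- c(c_missing, id)
    } else {
      cc <- carried(i, TRUE)
      if (length(cc) == 0) cc <- "paralog"
      add_amplicon(paste0(id, ".DF"), id, "DF2-DR2", cc, "")
      if (replicate_me)
        add_amplicon(paste0(id, ".DF.r"), id, "DF2-DR2", cc, "rep1")
    }
  }
  vids <- sort(unique(unlist(lapply(counts, names))))
  mat <- matrix(0L, length(vids), length(counts),
                dimnames = list(vids, names(counts)))
  for (a in names(counts)) mat[names(counts[[a]]), a] <- counts[[a]]
  tab <- asv_table(mat, var_seqs[vids], do.call(rbind, meta))
  list(table = tab,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(amplicon = character(0), variant = character(0),
                    type = character(0), parents = character(0)),
       c_missing = c_missing)
}

#' Simulate co-dominant microsatellite genotypes over a pedigree
#'
#' Founder genotypes are Hardy-Weinberg draws from Dirichlet-distributed
#' per-locus frequencies; offspring inherit one parental allele per locus.
#' With probability `microsat_error` a genotype is replaced by a fresh
#' Hardy-Weinberg draw.
#'
#' @param ped Output of [simulate_pedigree()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return List with `genotypes` (a [microsat_genotypes()] table) and the
#'   true per-locus `frequencies`.
#' @export
simulate_microsats <- function(ped, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- ped$individuals
  loci <- sprintf("L%02d", seq_len(cfg$n_microsat_loci))
  freqs <- lapply(loci, function(l) {
    f <- rdirichlet1(rep(2, cfg$microsat_alleles))
    stats::setNames(f, 100 + 2 * seq_len(cfg$microsat_alleles))
  })
  names(freqs) <- loci
  draw_hw <- function(l) as.integer(sample(names(freqs[[l]]), 2,
                                           replace = TRUE,
                                           prob = freqs[[l]]))
  gt <- list()  # gt[[id]][[locus]] = c(a, b)
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    gt[[id]] <- list()
    for (l in loci) {
      if (ind$role[i] != "offspring") {
        gt[[id]][[l]] <- draw_hw(l)
      } else {
        m <- gt[[ind$mother[i]]][[l]]; f <- gt[[ind$father[i]]][[l]]
        gt[[id]][[l]] <- c(sample(m, 1), sample(f, 1))
      }
      if (cfg$microsat_error > 0 && stats::runif(1) < cfg$microsat_error)
        gt[[id]][[l]] <- draw_hw(l)
    }
  }
  rows <- list()
  for (id in names(gt)) for (l in loci) {
    g <- sort(gt[[id]][[l]])
    rows[[paste(id, l)]] <- data.frame(individual_id = id, locus = l,
                                       allele1 = g[1], allele2 = g[2],
                                       stringsAsFactors = FALSE)
  }
  list(genotypes = microsat_genotypes(do.call(rbind, rows)),
       frequencies = freqs)
}

#' Simulate a full study dataset with ground truth
#'
#' Orchestrates the allele pool, haplotype pool, pedigree, observed
#' genotypes, amplicon table and microsatellites under one seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `pool`, `pedigree`, `genotypes`, `asv`, `microsats`
#'   and the `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  pool <- simulate_allele_pool(cfg)
  hpool <- simulate_haplotype_pool(cfg, pool)
  ped <- simulate_pedigree(cfg, hpool)
  genos <- simulated_genotypes(ped, cfg)
  asv <- simulate_asv_table(ped, pool, cfg)
  ms <- simulate_microsats(ped, cfg)
  list(pool = pool, pedigree = ped, genotypes = genos, asv = asv,
       microsats = ms, config = cfg)
}
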