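#' The published haplotype catalog (worked-example data)
#'
#' The 14 haplotypes inferred from allele segregation in the five catshark
#' families, as printed: per haplotype the sampling group, family, parent of
#' origin, offspring count, allele ids with lineages, composition class and
#' the three within-haplotype diversity metrics (NA for the single-allele
#' haplotype H8).
#'
#' @return data.frame with one row per haplotype.
#' @export
study_haplotypes <- function() {
  path <- system.file("extdata", "study_haplotypes.csv", package = "mhcseg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Allele-to-lineage map for the worked-example families
#'
#' Covers the published alleles plus the private alleles (all lineage B)
#' used to pad parents that fall below the five-offspring reporting
#' threshold.
#'
#' @return Named character vector: allele id -> lineage.
#' @export
study_lineage_map <- function() {
  tab <- study_haplotypes()
  m <- character(0)
  for (i in seq_len(nrow(tab))) {
    al <- split_csv(tab$alleles[i]); li <- split_csv(tab$lineages[i])
    m[al] <- li
  }
  # private alleles of parents excluded from the catalog
  m[c("90", "91", "92", "93", "95", "96", "99")] <- "B"
  m
}

hap_row <- function(tab, hid) {
  r <- tab[tab$hap_id == hid, ]
  al <- split_csv(r$alleles); li <- split_csv(r$lineages)
  hap(al[li != "C"], al[li == "C"])
}

# offspring genotype = union of one maternal and one paternal haplotype
union_geno <- function(id, hm, hf) {
  mhc_genotype(id, c(hm$ab, hf$ab), c(hm$c, hf$c))
}

#' Reconstruct the five worked-example families
#'
#' Builds parent genotypes and offspring allele sets implied by the
#' published haplotype catalog: each listed parent carries its two listed
#' haplotypes and each offspring is the union of one haplotype per parent,
#' with per-haplotype offspring counts as printed. Group-1 fathers are
#' unsampled (offspring `father_id` empty); their haplotypes must be
#' recovered as set-difference remainders. Parents below the five-offspring
#' threshold (mother 2, father 2, three minor group-1 fathers) carry private
#' haplotypes that must not enter the catalog.
#'
#' @return List with `genotypes` (`mhc_genotypes` for all individuals),
#'   `families` (list of [phase_family()] inputs), `lineage_map`, and
#'   `truth` (named list of each parent's true haplotype pair keys).
#' @export
study_families <- function() {
  tab <- study_haplotypes()
  H <- lapply(tab$hap_id, function(h) hap_row(tab, h))
  names(H) <- tab$hap_id
  X1 <- hap("90"); X2 <- hap(c("91", "92")); X3 <- hap("93")
  M2a <- hap("95"); M2b <- hap("96"); F2x <- hap("99")

  genos <- list(); families <- list(); truth <- list()
  parent_geno <- function(id, h1, h2)
    mhc_genotype(id, c(h1$ab, h2$ab), unique(c(h1$c, h2$c)))
  add_kids <- function(fam, mhaps, phaps, fathers) {
    kids <- lapply(seq_along(mhaps), function(j) {
      id <- sprintf("%s-O%02d", fam, j)
      genos[[id]] <<- union_geno(id, mhaps[[j]], phaps[[j]])
      id
    })
    data.frame(offspring_id = unlist(kids), father_id = fathers,
               stringsAsFactors = FALSE)
  }
  rep_haps <- function(...) {
    args <- list(...)
    out <- list()
    for (i in seq(1, length(args), 2))
      out <- c(out, rep(args[i], args[[i + 1]]))
    out
  }

  # family F1 (group 1): mother with H1/H2, all fathers unsampled
  genos[["G1M"]] <- parent_geno("G1M", H$H1, H$H2)
  truth[["G1M"]] <- pair_key(H$H1, H$H2)
  off1 <- add_kids("F1",
    rep_haps(H$H1, 12, H$H2, 7),
    rep_haps(H$H3, 5, H$H4, 6, X1, 1, X1, 3, X2, 2, X3, 2),
    rep("", 19))
  families[["F1"]] <- list(family_id = "F1", mother = "G1M",
                           offspring = off1)

  # shared group-2 fathers
  genos[["Fa1"]] <- parent_geno("Fa1", H$H11, H$H12)
  genos[["Fa3"]] <- parent_geno("Fa3", H$H13, H$H14)
  truth[["Fa1"]] <- pair_key(H$H11, H$H12)
  truth[["Fa3"]] <- pair_key(H$H13, H$H14)

  # family F2: mother 1 (H5/H6) x fathers 1 and 3
  genos[["Mo1"]] <- parent_geno("Mo1", H$H5, H$H6)
  truth[["Mo1"]] <- pair_key(H$H5, H$H6)
  off2 <- add_kids("F2",
    rep_haps(H$H5, 5, H$H6, 6),
    rep_haps(H$H11, 5, H$H11, 2, H$H12, 2, H$H13, 2),
    c(rep("Fa1", 5), rep("Fa1", 4), rep("Fa3", 2)))
  families[["F2"]] <- list(family_id = "F2", mother = "Mo1",
                           offspring = off2)

  # family F3: mother 2 (below reporting threshold) x father 1
  genos[["Mo2"]] <- parent_geno("Mo2", M2a, M2b)
  truth[["Mo2"]] <- pair_key(M2a, M2b)
  off3 <- add_kids("F3", list(M2a, M2b), rep_haps(H$H12, 2),
                   rep("Fa1", 2))
  families[["F3"]] <- list(family_id = "F3", mother = "Mo2",
                           offspring = off3)

  # family F4: mother 3 (H7/H8, single-allele haplotype) x fathers 1, 2
  genos[["Mo3"]] <- parent_geno("Mo3", H$H7, H$H8)
  truth[["Mo3"]] <- pair_key(H$H7, H$H8)
  off4 <- add_kids("F4",
    rep_haps(H$H7, 1, H$H8, 5),
    rep_haps(H$H12, 1, H$H11, 2, H$H12, 3),
    rep("Fa1", 6))
  families[["F4"]] <- list(family_id = "F4", mother = "Mo3",
                           offspring = off4)

  # family F5: mother 4 (H9/H10) x fathers 1, 3 and ungenotyped father 2
  genos[["Mo4"]] <- parent_geno("Mo4", H$H9, H$H10)
  truth[["Mo4"]] <- pair_key(H$H9, H$H10)
  off5 <- add_kids("F5",
    rep_haps(H$H9, 3, H$H9, 1, H$H10, 2, H$H10, 1, H$H10, 2, H$H10, 3,
             H$H10, 1),
    rep_haps(H$H11, 3, H$H13, 1, H$H11, 2, H$H12, 1, H$H13, 2, H$H14, 3,
             F2x, 1),
    c(rep("Fa1", 3), "Fa3", rep("Fa1", 2), "Fa1", rep("Fa3", 5), "Fa2"))
  families[["F5"]] <- list(family_id = "F5", mother = "Mo4",
                           offspring = off5)

  g <- do.call(rbind, genos)
  rownames(g) <- NULL
  class(g) <- c("mhc_genotypes", "data.frame")
  list(genotypes = g, families = families,
       lineage_map = study_lineage_map(), truth = truth)
}

#' The family #5 worked example
#'
#' Mother 4 and fathers 1 and 3 with the twelve offspring attributable to
#' them (father 2's single offspring excluded, as in the published
#' reconstruction).
#'
#' @return List with `genotypes`, `family` (a [phase_family()] input),
#'   `lineage_map` and `truth` pair keys.
#' @export
family5_fixture <- function() {
  all <- study_families()
  fam <- all$families[["F5"]]
  keep <- fam$offspring$father_id %in% c("Fa1", "Fa3")
  fam$offspring <- fam$offspring[keep, ]
  ids <- c("Mo4", "Fa1", "Fa3", fam$offspring$offspring_id)
  g <- all$genotypes[all$genotypes$sample_id %in% ids, ]
  rownames(g) <- NULL
  class(g) <- c("mhc_genotypes", "data.frame")
  list(genotypes = g, family = fam, lineage_map = all$lineage_map,
       truth = all$truth[c("Mo4", "Fa1", "Fa3")])
}
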