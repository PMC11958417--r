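#' Composition class of a haplotype
#'
#' Classes follow the lineage content: `AB` (A and B alleles, no C), `AC`,
#' `BC`, `B-only`, or `other` (anything else, e.g. A-only or three-lineage).
#'
#' @param h Haplotype (list with `ab`, `c`).
#' @param lineage_map Named character vector: allele id -> lineage.
#' @return Character scalar.
#' @export
composition_class <- function(h, lineage_map) {
  lins <- unname(lineage_map[h$ab])
  if (any(is.na(lins))) stop("allele(s) without lineage label: ",
                             paste(h$ab[is.na(lins)], collapse = ", "))
  has_a <- "A" %in% lins; has_b <- "B" %in% lins; has_c <- length(h$c) > 0
  if (has_c) {
    if (has_a && !has_b) return("AC")
    if (has_b && !has_a) return("BC")
    return("other")
  }
  if (has_a && has_b) return("AB")
  if (has_b && !has_a) return("B-only")
  "other"
}

#' Build the unique-haplotype catalog from phased families
#'
#' Haplotypes are collected from every parent with at least `min_offspring`
#' assigned offspring (both haplotypes of such a parent are included, summed
#' across families for parents shared between families) and from external
#' (unsampled-father) haplotypes individually observed in at least
#' `min_offspring` offspring. Identical allele contents merge into one
#' catalog entry listing all sources.
#'
#' @param solutions List of [phase_family()] results (or a single one).
#' @param lineage_map Named character vector: allele id -> lineage.
#' @param min_offspring Inclusion threshold (default 5).
#' @return data.frame of class `haplotype_catalog`: `hap_id`, `alleles`,
#'   `lineages`, `class`, `sources`, `n_offspring`.
#' @export
build_catalog <- function(solutions, lineage_map, min_offspring = 5) {
  if (inherits(solutions, "phasing_solution")) solutions <- list(solutions)
  # per-parent totals across families
  parent_rows <- list()
  for (s in solutions) {
    a <- s$assignments[s$assignments$explained, , drop = FALSE]
    add <- function(id, role, h1, h2, n1, n2) {
      parent_rows[[length(parent_rows) + 1]] <<- list(
        family = s$family_id, parent = id, role = role,
        h = list(h1, h2), n = c(n1, n2))
    }
    add(s$mother$id, "mother", s$mother$h1, s$mother$h2,
        sum(a$maternal_hap == "1"), sum(a$maternal_hap == "2"))
    for (f in names(s$fathers)) {
      af <- a[a$father_id == f, , drop = FALSE]
      add(f, "father", s$fathers[[f]]$h1, s$fathers[[f]]$h2,
          sum(af$paternal_hap == "1"), sum(af$paternal_hap == "2"))
    }
  }
  totals <- list()
  for (r in parent_rows)
    totals[[r$parent]] <- (if (is.null(totals[[r$parent]])) 0 else
      totals[[r$parent]]) + sum(r$n)
  entries <- list()  # key -> list(h, sources, n)
  note <- function(h, src, n) {
    key <- hap_key(h)
    if (is.null(entries[[key]]))
      entries[[key]] <<- list(h = h, sources = character(0), n = 0)
    entries[[key]]$sources <<- union(entries[[key]]$sources, src)
    entries[[key]]$n <<- entries[[key]]$n + n
  }
  for (r in parent_rows) {
    if (totals[[r$parent]] < min_offspring) next
    for (i in 1:2)
      note(r$h[[i]], paste0(r$family, ":", r$parent), r$n[i])
  }
  for (s in solutions)

    if (nrow(s$external)) {
      for (i in seq_len(nrow(s$external))) {
        if (s$external$n_offspring[i] < min_offspring) next
        note(hap_from_key(s$external$hap[i]),
             paste0(s$family_id, ":father*"), s$external$n_offspring[i])
      }
    }
  if (length(entries) == 0)
    return(structure(data.frame(hap_id = character(0), alleles = character(0),
                                lineages = character(0), class = character(0),
                                sources = character(0),
                                n_offspring = integer(0)),
                     class = c("haplotype_catalog", "data.frame")))
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    alle <- c(e$h$ab, e$h$c)
    data.frame(hap_id = paste0("H", i),
               alleles = paste(alle, collapse = ","),
               lineages = paste(c(unname(lineage_map[e$h$ab]),
                                  rep("C", length(e$h$c))), collapse = ","),
               class = composition_class(e$h, lineage_map),
               sources = paste(sort(e$sources), collapse = ";"),
               n_offspring = e$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("haplotype_catalog", "data.frame")
  out
}

#' Genetic-architecture checks on population MHC genotypes
#'
#' Computes per-individual allele counts per lineage, flags violations of the
#' two-locus A/B + one-locus C model (more than 2 A, more than 2 C, or more
#' than 4 combined A+B alleles per individual), and reports Spearman rank
#' correlations between the per-individual counts of each lineage pair.
#'
#' @param genos `mhc_genotypes` data.frame.
#' @param lineage_map Named character vector: allele id -> lineage.
#' @return List with `counts` (per individual), `max_per_lineage`,
#'   `violations` data.frame and `correlations` data.frame.
#' @export
architecture_checks <- function(genos, lineage_map) {
  if (nrow(genos) == 0)
    return(list(counts = data.frame(), max_per_lineage = c(A = 0, B = 0, C = 0),
                violations = data.frame(), correlations = data.frame()))
  counts <- do.call(rbind, lapply(seq_len(nrow(genos)), function(i) {
    ab <- split_csv(genos$ab[i]); cc <- split_csv(genos$c[i])
    lins <- lineage_map[ab]
    data.frame(sample_id = genos$sample_id[i],
               A = sum(lins == "A", na.rm = TRUE),
               B = sum(lins == "B", na.rm = TRUE),
               C = length(cc), stringsAsFactors = FALSE)
  }))
  viol <- list()
  chk <- function(cond, rule) {
    if (any(cond)) viol[[rule]] <<- data.frame(
      sample_id = counts$sample_id[cond], rule = rule,
      stringsAsFactors = FALSE)
  }
  chk(counts$A > 2, "A > 2")
  chk(counts$C > 2, "C > 2")
  chk(counts$A + counts$B > 4, "A + B > 4")
  pairs <- list(c("C", "A"), c("C", "B"), c("A", "B"))
  cors <- do.call(rbind, lapply(pairs, function(p) {
    x <- counts[[p[1]]]; y <- counts[[p[2]]]
    rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      suppressWarnings(stats::cor(x, y, method = "spearman"))
    data.frame(lineage1 = p[1], lineage2 = p[2], spearman_rho = rho,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts,
       max_per_lineage = c(A = max(counts$A), B = max(counts$B),
                           C = max(counts$C)),
       violations = if (length(viol)) do.call(rbind, viol) else
         data.frame(sample_id = character(0), rule = character(0)),
       correlations = cors)
}

haps_of <- function(geno, ab_cap = 2, c_cap = 1) {
  bp <- enumerate_bipartitions(geno, ab_cap, c_cap)
  seen <- character(0); out <- list()
  for (p in bp) for (h in list(p$h1, p$h2)) {
    k <- hap_key(h)
    if (!k %in% seen) { seen <- c(seen, k); out <- c(out, list(h)) }
  }
  out
}

#' Congruence between offspring MHC alleles and their assigned parents
#'
#' An offspring is congruent when its allele set is the union of one
#' capacity-valid haplotype from each assigned parent. Incongruent offspring
#' are reported with the alleles carried by neither parent and with any
#' alternative father (from the supplied candidates) that would restore
#' congruence — supporting mislabelling/reassignment review.
#'
#' @param trios data.frame with columns `offspring_id`, `mother_id`,
#'   `father_id`.
#' @param genos `mhc_genotypes` data.frame.
#' @param candidate_fathers Optional character vector of alternative father
#'   ids to test for incongruent offspring.
#' @return List with `fraction_congruent` and per-offspring `results`.
#' @export
check_family_congruence <- function(trios, genos,
                                    candidate_fathers = NULL) {
  congruent_with <- function(o, m, f) {
    any(vapply(haps_of(m), function(hm)
      any(vapply(haps_of(f), function(hf) explains(hm, hf, o),
                 logical(1))), logical(1)))
  }
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    o <- geno_get(genos, trios$offspring_id[i])
    m <- geno_get(genos, trios$mother_id[i])
    f <- geno_get(genos, trios$father_id[i])
    if (is.null(o) || is.null(m) || is.null(f))
      stop("missing genotype in trio ", trios$offspring_id[i])
    ok <- congruent_with(o, m, f)
    off_alle <- c(o$ab, o$c)
    par_alle <- c(m$ab, m$c, f$ab, f$c)
    orphan <- setdiff(off_alle, par_alle)
    alt <- character(0)
    if (!ok && !is.null(candidate_fathers)) {
      for (cf in setdiff(candidate_fathers, trios$father_id[i])) {
        g <- geno_get(genos, cf)
        if (!is.null(g) && congruent_with(o, m, g)) alt <- c(alt, cf)
      }
    }
    data.frame(offspring_id = o$id, mother_id = m$id, father_id = f$id,
               congruent = ok,
               orphan_alleles = paste(orphan, collapse = ","),
               alternative_fathers = paste(alt, collapse = ","),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(fraction_congruent = mean(results$congruent), results = results)
}
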