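#' MHC genotype rows and haplotype objects
#'
#' An MHC genotype records, per individual, the observed allele set of the
#' co-amplified A/B lineages (`ab`), the lineage-C allele set (`c`) and the C
#' observation status: `"present"`, `"absent"` (the C amplicon worked but no
#' allele was found) or `"missing"` (no C amplicon — never evidence of
#' absence). A haplotype holds up to `ab_cap` (2) A/B alleles and up to
#' `c_cap` (1) C allele.
#'
#' @param sample_id Individual id.
#' @param ab Character vector of A/B-lineage allele ids (0-4).
#' @param c Character vector of C-lineage allele ids (0-2).
#' @param c_status One of `"present"`, `"absent"`, `"missing"`; defaults to
#'   `"present"` when `c` is non-empty, `"absent"` otherwise.
#' @return One-row data.frame (rbind-able into an `mhc_genotypes` table).
#' @export
mhc_genotype <- function(sample_id, ab = character(0), c = character(0),
                         c_status = NULL) {
  if (is.null(c_status)) c_status <- if (length(c)) "present" else "absent"
  stopifnot(c_status %in% c("present", "absent", "missing"))
  if (c_status == "present" && length(c) == 0)
    stop("c_status 'present' needs at least one C allele")
  if (c_status != "present" && length(c) > 0)
    stop("C alleles given but c_status is ", c_status)
  data.frame(sample_id = sample_id,
             ab = paste(sort(unique(ab)), collapse = ","),
             c = paste(sort(unique(c)), collapse = ","),
             c_status = c_status, stringsAsFactors = FALSE)
}

split_csv <- function(x) if (is.na(x) || !nzchar(x)) character(0) else
  strsplit(x, ",", fixed = TRUE)[[1]]

geno_get <- function(genos, id) {
  r <- genos[genos$sample_id == id, , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  list(id = id, ab = split_csv(r$ab[1]), c = split_csv(r$c[1]),
       c_status = r$c_status[1])
}

hap <- function(ab = character(0), c = character(0)) {
  list(ab = sort(unique(as.character(ab))), c = sort(as.character(c)))
}

#' Canonical string key of a haplotype
#'
#' Format `ab1+ab2|c` with `-` for an empty C slot, e.g. `"11+17|-"`.
#'
#' @param h Haplotype (list with `ab` and `c`).
#' @return Character scalar.
#' @export
hap_key <- function(h) {
  paste0(paste(h$ab, collapse = "+"), "|",
         if (length(h$c)) h$c else "-")
}

hap_from_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  ab <- if (nzchar(parts[1])) strsplit(parts[1], "+", fixed = TRUE)[[1]] else
    character(0)
  c <- if (length(parts) > 1 && parts[2] != "-" && parts[2] != "?")
    parts[2] else character(0)
  hap(ab, c)
}

pair_key <- function(h1, h2) {
  k <- sort(c(hap_key(h1), hap_key(h2)))
  paste(k, collapse = " / ")
}

#' Enumerate the candidate haplotype bipartitions of a parent genotype
#'
#' All unordered haplotype pairs whose union is the parent's observed allele
#' set, respecting per-haplotype capacities (at most `ab_cap` A/B alleles and
#' `c_cap` C alleles per haplotype). Because only allele presence is
#' observed, an allele may sit on both haplotypes (homozygosity), and a
#' single C allele generates homozygous and hemizygous placements.
#'
#' @param geno A genotype as returned by `geno_get`/[mhc_genotype()] row, or
#'   a one-row `mhc_genotypes` data.frame.
#' @param ab_cap,c_cap Per-haplotype capacities (defaults 2 and 1).
#' @return List of `list(h1, h2)` pairs (canonical order, no duplicates).
#' @export
enumerate_bipartitions <- function(geno, ab_cap = 2, c_cap = 1) {
  if (is.data.frame(geno)) geno <- geno_get(geno, geno$sample_id[1])
  ab <- sort(unique(geno$ab)); cc <- sort(unique(geno$c))
  if (length(ab) > 2 * ab_cap)
    stop("parent has ", length(ab), " A/B alleles; capacity is ",
         2 * ab_cap, " (architecture violation)")
  if (length(cc) > 2 * c_cap)
    stop("parent has ", length(cc), " C alleles; capacity is ", 2 * c_cap)
  subsets <- list(character(0))
  if (length(ab)) {
    for (k in seq_len(min(ab_cap, length(ab))))
      subsets <- c(subsets, utils::combn(ab, k, simplify = FALSE))
  }
  ab_pairs <- list()
  for (x in subsets) for (y in subsets) {
    if (setequal(union(x, y), ab)) ab_pairs <- c(ab_pairs, list(list(x, y)))
  }
  c_pairs <- switch(as.character(length(cc)),
    "0" = list(list(character(0), character(0))),
    "1" = list(list(cc, character(0)), list(character(0), cc),
               list(cc, cc)),
    "2" = list(list(cc[1], cc[2]), list(cc[2], cc[1])))
  seen <- character(0); out <- list()
  for (ap in ab_pairs) for (cp in c_pairs) {
    h1 <- hap(ap[[1]], cp[[1]]); h2 <- hap(ap[[2]], cp[[2]])
    key <- pair_key(h1, h2)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out <- c(out, list(list(h1 = h1, h2 = h2)))
    }
  }
  ord <- order(vapply(out, function(p) pair_key(p$h1, p$h2), character(1)))
  out[ord]
}

# does maternal hap m + paternal hap f explain offspring o?
explains <- function(m, f, o) {
  if (!setequal(union(m$ab, f$ab), o$ab)) return(FALSE)
  if (o$c_status == "missing") return(TRUE)
  if (o$c_status == "absent") return(length(m$c) == 0 && length(f$c) == 0)
  setequal(union(m$c, f$c), o$c)
}

pair_copies <- function(p)
  length(p$h1$ab) + length(p$h2$ab) + length(p$h1$c) + length(p$h2$c)

# C-boundary recombinants of a haplotype pair (exchange of the C slot)
recombinants_of <- function(pair) {
  r1 <- hap(pair$h1$ab, pair$h2$c)
  r2 <- hap(pair$h2$ab, pair$h1$c)
  keys <- c(hap_key(pair$h1), hap_key(pair$h2))
  out <- list()
  if (!hap_key(r1) %in% keys) out <- c(out, list(r1))
  if (!hap_key(r2) %in% keys) out <- c(out, list(r2))
  out
}

# candidate (hap, cost, label) list for one parent's bipartition
hap_candidates <- function(pair) {
  cands <- list(list(h = pair$h1, cost = 0, lab = "1"),
                list(h = pair$h2, cost = 0, lab = "2"))
  for (r in recombinants_of(pair))
    cands <- c(cands, list(list(h = r, cost = 1, lab = "R")))
  cands
}

# best explanation of offspring o from maternal pair mp and paternal pair fp;
# m_opts/f_opts collect every haplotype label usable at the minimal cost
explain_known <- function(o, mp, fp) {
  best <- NULL
  for (mc in hap_candidates(mp)) for (fc in hap_candidates(fp)) {
    if (!explains(mc$h, fc$h, o)) next
    cost <- mc$cost + fc$cost
    if (is.null(best) || cost < best$cost) {
      best <- list(cost = cost, maternal = mc$lab, paternal = fc$lab,
                   m_opts = mc$lab, f_opts = fc$lab)
    } else if (cost == best$cost) {
      best$m_opts <- union(best$m_opts, mc$lab)
      best$f_opts <- union(best$f_opts, fc$lab)
    }
  }
  best
}

# valid remainder after removing maternal hap m from offspring o, or NULL
remainder_of <- function(m, o, ab_cap = 2, c_cap = 1) {
  if (!all(m$ab %in% o$ab)) return(NULL)
  r_ab <- setdiff(o$ab, m$ab)
  if (length(r_ab) > ab_cap) return(NULL)
  if (o$c_status == "absent") {
    if (length(m$c)) return(NULL)
    return(list(hap = hap(r_ab), c_known = TRUE))
  }
  if (o$c_status == "missing")
    return(list(hap = hap(r_ab), c_known = FALSE))
  if (!all(m$c %in% o$c)) return(NULL)
  r_c <- setdiff(o$c, m$c)
  if (length(r_c) > c_cap) return(NULL)
  list(hap = hap(r_ab, r_c), c_known = TRUE)
}

explain_unknown <- function(o, mp, ab_cap = 2, c_cap = 1) {
  best <- NULL
  for (mc in hap_candidates(mp)) {
    r <- remainder_of(mc$h, o, ab_cap, c_cap)
    if (is.null(r)) next
    if (is.null(best) || mc$cost < best$cost) {
      best <- list(cost = mc$cost, maternal = mc$lab,
                   remainder = r$hap, c_known = r$c_known,
                   m_opts = mc$lab)
    } else if (mc$cost == best$cost) {
      best$m_opts <- union(best$m_opts, mc$lab)
    }
  }
  best
}

#' Phase one mother-defined family by exhaustive bipartition search
#'
#' Enumerates all candidate haplotype bipartitions of the mother and of each
#' genotyped father and scores every combination: an offspring is explained
#' when its observed allele set is exactly the union of one maternal and one
#' paternal haplotype (for offspring whose father is unsampled, the remainder
#' after removing a maternal haplotype must itself be a capacity-valid
#' haplotype). Offspring explainable only through a C-boundary exchange
#' between a parent's two haplotypes count as recombinant. Solutions
#' maximise explained offspring and then minimise recombination events;
#' `multiplicity` counts the optima at that level. Among equal optima the
#' reported representative prefers pairs whose two distinct haplotypes both
#' reach some offspring, then minimal total allele copies (an allele is
#' placed on both haplotypes only when the data force it), then
#' lexicographic order of haplotype keys.
#'
#' @param family List with `family_id`, `mother` (id), and `offspring`: a
#'   data.frame with columns `offspring_id` and `father_id` (`NA` or `""`
#'   when the father is unsampled).
#' @param genos `mhc_genotypes` data.frame holding the mother, any genotyped
#'   fathers, and all offspring.
#' @param ab_cap,c_cap Haplotype capacities.
#' @return Object of class `phasing_solution`; see Details.
#' @details The returned list carries `mother` / `fathers` haplotype pairs,
#'   per-offspring `assignments` (maternal hap `1`/`2`/`R`, paternal hap or
#'   external-remainder key, recombination cost, explained flag),
#'   `external` haplotype counts for unsampled fathers,
#'   `min_external_fathers`, `unexplained`, `n_explained`,
#'   `n_recombination_events`, `multiplicity` and `alt_solutions`.
#' @export
phase_family <- function(family, genos, ab_cap = 2, c_cap = 1) {
  stopifnot(!is.null(family$mother), nrow(family$offspring) >= 1)
  mg <- geno_get(genos, family$mother)
  if (is.null(mg)) stop("mother ", family$mother, " has no genotype")
  off <- family$offspring
  off$father_id[is.na(off$father_id)] <- ""
  olist <- lapply(off$offspring_id, function(i) {
    g <- geno_get(genos, i)
    if (is.null(g)) stop("offspring ", i, " has no genotype")
    g
  })
  names(olist) <- off$offspring_id
  father_ids <- unique(off$father_id[nzchar(off$father_id)])
  fg <- lapply(father_ids, function(f) geno_get(genos, f))
  names(fg) <- father_ids
  known_fathers <- father_ids[!vapply(fg, is.null, logical(1))]
  mb <- enumerate_bipartitions(mg, ab_cap, c_cap)
  fb <- lapply(known_fathers, function(f)
    enumerate_bipartitions(fg[[f]], ab_cap, c_cap))
  names(fb) <- known_fathers
  # offspring grouped by father; unknown group = unsampled or ungenotyped
  grp <- split(off$offspring_id,
               ifelse(off$father_id %in% known_fathers, off$father_id,
                      ".unknown"))

  used_labels <- function(ex, field) {
    u <- character(0)
    for (e in ex) if (!is.null(e)) u <- union(u, intersect(e[[field]],
                                                           c("1", "2")))
    u
  }
  # distinct haplotypes of a pair that no offspring can have received
  dead_haps <- function(pair, used) {
    if (hap_key(pair$h1) == hap_key(pair$h2)) return(0L)
    2L - length(used)
  }
  score_known <- function(kids, mp, fp) {
    ex <- lapply(kids, function(k) explain_known(olist[[k]], mp, fp))
    names(ex) <- kids
    n <- sum(!vapply(ex, is.null, logical(1)))
    cost <- sum(vapply(ex, function(e) if (is.null(e)) 0 else e$cost,
                       numeric(1)))
    list(n = n, cost = cost, ex = ex,
         used_m = used_labels(ex, "m_opts"),
         used_f = used_labels(ex, "f_opts"))
  }
  score_unknown <- function(kids, mp) {
    ex <- lapply(kids, function(k) explain_unknown(olist[[k]], mp,
                                                   ab_cap, c_cap))
    names(ex) <- kids
    n <- sum(!vapply(ex, is.null, logical(1)))
    cost <- sum(vapply(ex, function(e) if (is.null(e)) 0 else e$cost,
                       numeric(1)))
    list(n = n, cost = cost, ex = ex, used_m = used_labels(ex, "m_opts"))
  }

  # optimality is judged on (explained offspring, recombination events);
  # ties are then broken in favour of pairs where both distinct haplotypes
  # reach some offspring, then minimal total allele copies (homozygous
  # placements only when the data force them), then lexicographic key order.
  # multiplicity counts the (explained, recombination)-level optima.
  loose_best <- function(n, cost) {
    keep <- n == max(n)
    keep[keep] <- cost[keep] == min(cost[keep])
    which(keep)
  }
  evals <- list()
  for (mi in seq_along(mb)) {
    total_n <- 0; total_cost <- 0
    total_dead <- 0; total_copies <- pair_copies(mb[[mi]])
    used_m <- character(0)
    fchoice_loose <- list(); fchoice <- list()
    for (f in known_fathers) {
      scores <- lapply(fb[[f]], function(fp)
        score_known(grp[[f]], mb[[mi]], fp))
      ns <- vapply(scores, `[[`, numeric(1), "n")
      cs <- vapply(scores, `[[`, numeric(1), "cost")
      loose <- loose_best(ns, cs)
      dead <- vapply(loose, function(i)
        dead_haps(fb[[f]][[i]], scores[[i]]$used_f), integer(1))
      copies <- vapply(loose, function(i) pair_copies(fb[[f]][[i]]),
                       numeric(1))
      keep <- dead == min(dead)
      keep[keep] <- copies[keep] == min(copies[keep])
      pick <- loose[which(keep)[1]]
      fchoice_loose[[f]] <- loose
      fchoice[[f]] <- pick
      total_n <- total_n + ns[pick]
      total_cost <- total_cost + cs[pick]
      total_dead <- total_dead + min(dead)
      total_copies <- total_copies + pair_copies(fb[[f]][[pick]])
      used_m <- union(used_m, scores[[pick]]$used_m)
    }
    un <- if (".unknown" %in% names(grp))
      score_unknown(grp[[".unknown"]], mb[[mi]]) else
      list(n = 0, cost = 0, used_m = character(0))
    total_n <- total_n + un$n; total_cost <- total_cost + un$cost
    used_m <- union(used_m, un$used_m)
    total_dead <- total_dead + dead_haps(mb[[mi]], used_m)
    evals[[mi]] <- list(n = total_n, cost = total_cost,
                        dead = total_dead, copies = total_copies,
                        fchoice = fchoice, fchoice_loose = fchoice_loose)
  }
  ns <- vapply(evals, `[[`, numeric(1), "n")
  cs <- vapply(evals, `[[`, numeric(1), "cost")
  if (max(ns) == 0)
    stop("no bipartition explains any offspring of ", family$mother,
         "; conflicting alleles: ",
         paste(unique(unlist(lapply(olist, function(o)
       setdiff(o$ab, mg$ab)))), collapse = ", "))
  opt <- loose_best(ns, cs)
  multiplicity <- sum(vapply(opt, function(i)
    prod(c(1, vapply(evals[[i]]$fchoice_loose, length, numeric(1)))),
    numeric(1)))
  deads <- vapply(opt, function(i) evals[[i]]$dead, numeric(1))
  copies <- vapply(opt, function(i) evals[[i]]$copies, numeric(1))
  keep <- deads == min(deads)
  keep[keep] <- copies[keep] == min(copies[keep])
  best_mi <- opt[which(keep)[1]]  # enumeration is in lexicographic order
  mp <- mb[[best_mi]]
  fsel <- lapply(known_fathers, function(f)
    fb[[f]][[evals[[best_mi]]$fchoice[[f]]]])
  names(fsel) <- known_fathers

  rows <- list(); ext <- list()
  for (f in names(grp)) {
    kids <- grp[[f]]
    if (f != ".unknown") {
      sc <- score_known(kids, mp, fsel[[f]])
      for (k in kids) {
        e <- sc$ex[[k]]
        rows[[k]] <- data.frame(
          offspring_id = k, father_id = f,
          maternal_hap = if (is.null(e)) NA else e$maternal,
          paternal_hap = if (is.null(e)) NA else e$paternal,
          ext_hap = NA_character_,
          recomb_cost = if (is.null(e)) NA else e$cost,
          explained = !is.null(e), stringsAsFactors = FALSE)
      }
    } else {
      sc <- score_unknown(kids, mp)
      for (k in kids) {
        e <- sc$ex[[k]]
        key <- if (is.null(e)) NA_character_ else {
          kk <- hap_key(e$remainder)
          if (!e$c_known && length(e$remainder$c) == 0)
            kk <- sub("\\|-$", "|?", kk)
          kk
        }
        fid <- off$father_id[off$offspring_id == k]
        rows[[k]] <- data.frame(
          offspring_id = k, father_id = fid,
          maternal_hap = if (is.null(e)) NA else e$maternal,
          paternal_hap = if (is.null(e)) NA else "ext",
          ext_hap = key,
          recomb_cost = if (is.null(e)) NA else e$cost,
          explained = !is.null(e), stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- do.call(rbind, rows[off$offspring_id])
  rownames(assignments) <- NULL

  # cluster external remainders: fold C-unknown keys into a matching AB entry
  ek <- assignments$ext_hap[!is.na(assignments$ext_hap)]
  ext_tab <- data.frame()
  if (length(ek)) {
    known <- ek[!grepl("\\|\\?$", ek)]
    unk <- ek[grepl("\\|\\?$", ek)]
    cnt <- table(known)
    for (u in unk) {
      abpart <- sub("\\|\\?$", "", u)
      match_known <- names(cnt)[sub("\\|.*$", "", names(cnt)) == abpart]
      tgt <- if (length(match_known)) match_known[1] else u
      cnt[tgt] <- ifelse(is.na(cnt[tgt]), 1, cnt[tgt] + 1)
    }
    ext_tab <- data.frame(hap = names(cnt), n_offspring = as.integer(cnt),
                          stringsAsFactors = FALSE)
    ext_tab <- ext_tab[order(-ext_tab$n_offspring, ext_tab$hap), ]
    rownames(ext_tab) <- NULL
  }
  alt <- lapply(setdiff(opt, best_mi), function(i)
    pair_key(mb[[i]]$h1, mb[[i]]$h2))
  structure(list(
    family_id = family$family_id,
    mother = list(id = family$mother, h1 = mp$h1, h2 = mp$h2),
    fathers = lapply(fsel, function(p) list(h1 = p$h1, h2 = p$h2)),
    assignments = assignments,
    external = ext_tab,
    min_external_fathers = if (nrow(ext_tab)) ceiling(nrow(ext_tab) / 2)
      else 0,
    unexplained = assignments$offspring_id[!assignments$explained],
    n_explained = sum(assignments$explained),
    n_recombination_events = sum(assignments$recomb_cost, na.rm = TRUE),
    multiplicity = multiplicity,
    alt_solutions = unlist(alt)),
    class = "phasing_solution")
}

#' @export
print.phasing_solution <- function(x, ...) {
  cat("phasing_solution (family", x$family_id, ")\n")
  cat("  mother", x$mother$id, ":", hap_key(x$mother$h1), "/",
      hap_key(x$mother$h2), "\n")
  for (f in names(x$fathers))
    cat("  father", f, ":", hap_key(x$fathers[[f]]$h1), "/",
        hap_key(x$fathers[[f]]$h2), "\n")
  cat("  explained", x$n_explained, "of", nrow(x$assignments),
      "offspring;", x$n_recombination_events, "recombination event(s);",
      "multiplicity", x$multiplicity, "\n")
  invisible(x)
}

#' Count recombinant offspring across phased families
#'
#' A parent enters the denominator only when it is informative: at least
#' `min_offspring` assigned offspring and two haplotypes that differ in their
#' C slot (a parent whose haplotypes carry the same C content cannot reveal a
#' C-boundary exchange). Unsampled external fathers are never eligible.
#'
#' @param solutions A [phase_family()] result or list of them.
#' @param min_offspring Minimum offspring per eligible parent (default 5).
#' @return List with `n_recombinant`, `frequency`, and the per-parent
#'   eligibility table `parents`.
#' @export
count_recombinants <- function(solutions, min_offspring = 5) {
  if (inherits(solutions, "phasing_solution")) solutions <- list(solutions)
  rows <- list()
  for (s in solutions) {
    a <- s$assignments[s$assignments$explained, , drop = FALSE]
    parents <- c(list(mother = s$mother),
                 stats::setNames(lapply(names(s$fathers), function(f)
                   c(list(id = f), s$fathers[[f]])), names(s$fathers)))
    for (p in parents) {
      is_mother <- identical(p$id, s$mother$id)
      kids <- if (is_mother) a else a[a$father_id == p$id, , drop = FALSE]
      n <- nrow(kids)
      rec <- if (is_mother) sum(kids$maternal_hap == "R") else
        sum(kids$paternal_hap == "R")
      c_differs <- !identical(p$h1$c, p$h2$c)
      key <- paste(s$family_id, p$id)
      if (!key %in% names(rows)) {
        rows[[key]] <- data.frame(
          family = s$family_id, parent = p$id, n_offspring = n,
          n_recombinant = rec, c_slots_differ = c_differs,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # aggregate multi-family parents before applying the offspring threshold
  agg <- stats::aggregate(cbind(n_offspring, n_recombinant) ~ parent,
                          data = tab, FUN = sum)
  agg$c_slots_differ <- vapply(agg$parent, function(p)
    any(tab$c_slots_differ[tab$parent == p]), logical(1))
  agg$eligible <- agg$n_offspring >= min_offspring & agg$c_slots_differ
  el <- agg[agg$eligible, , drop = FALSE]
  n_rec <- sum(el$n_recombinant)
  denom <- sum(el$n_offspring)
  list(n_recombinant = n_rec,
       frequency = if (denom > 0) n_rec / denom else NA_real_,
       parents = agg)
}

#' Resolve the C slot of C-less parental haplotypes
#'
#' A parental haplotype with no C allele is marked `ABSENT` (the chromosome
#' truly lacks the C-locus copy) when at least one offspring assigned that
#' haplotype has C observation status `"absent"` — possible only when the
#' other parental contribution also carries no C. Otherwise the slot is
#' `UNKNOWN` (compatible with an untransmitted homozygous allele or a
#' methodological miss). Offspring with status `"missing"` are never
#' evidence. Haplotypes carrying a C allele report that allele.
#'
#' @param solution A [phase_family()] result.
#' @param genos The `mhc_genotypes` table used for phasing.
#' @return data.frame: `parent`, `hap` (1/2), `key`, `c_slot`.
#' @export
infer_hemizygosity <- function(solution, genos) {
  a <- solution$assignments[solution$assignments$explained, , drop = FALSE]
  out <- list()
  consider <- c(list(list(id = solution$mother$id, role = "maternal",
                          h1 = solution$mother$h1, h2 = solution$mother$h2)),
                lapply(names(solution$fathers), function(f)
                  list(id = f, role = "paternal",
                       h1 = solution$fathers[[f]]$h1,
                       h2 = solution$fathers[[f]]$h2)))
  for (p in consider) {
    for (i in 1:2) {
      h <- if (i == 1) p$h1 else p$h2
      slot <- if (length(h$c)) h$c else {
        kids <- if (p$role == "maternal")
          a$offspring_id[a$maternal_hap == as.character(i)] else
          a$offspring_id[a$father_id == p$id &
                         a$paternal_hap == as.character(i)]
        st <- vapply(kids, function(k)
          geno_get(genos, k)$c_status, character(1))
        if (any(st == "absent")) "ABSENT" else "UNKNOWN"
      }
      out[[paste(p$id, i)]] <- data.frame(
        parent = p$id, hap = i, key = hap_key(h), c_slot = slot,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected number of distinct offspring diplotypes under a linkage model
#'
#' Each parent is given as a loci-by-2 matrix of phased alleles (columns =
#' the parent's two haplotypes). Under independent assortment a parent's
#' gametes are all per-locus combinations; under complete linkage only the
#' two parental haplotypes are transmitted. Returns the number of distinct
#' unordered gamete pairings — e.g. 16 for two doubly-heterozygous parents at
#' two freely assorting loci, but 4 when the loci are tightly linked.
#'
#' @param mother,father Matrices (loci x 2) of allele labels.
#' @param linkage `"independent"` or `"complete"`.
#' @return Integer count of distinct offspring diplotypes.
#' @export
expected_diplotype_count <- function(mother, father,
                                     linkage = c("independent", "complete")) {
  linkage <- match.arg(linkage)
  gametes <- function(m) {
    m <- as.matrix(m)
    if (linkage == "complete") {
      gs <- apply(m, 2, paste, collapse = "|")
    } else {
      gr <- expand.grid(lapply(seq_len(nrow(m)), function(i) unique(m[i, ])),
                        stringsAsFactors = FALSE)
      gs <- apply(gr, 1, paste, collapse = "|")
    }
    unique(gs)
  }
  gm <- gametes(mother); gf <- gametes(father)
  combos <- character(0)
  for (x in gm) for (y in gf) {
    combos <- c(combos, paste(sort(c(x, y)), collapse = " + "))
  }
  length(unique(combos))
}
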