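ms_from_list <- function(lst) {
  rows <- list()
  for (id in names(lst)) for (loc in names(lst[[id]])) {
    g <- lst[[id]][[loc]]
    rows[[paste(id, loc)]] <- data.frame(individual_id = id, locus = loc,
                                         allele1 = g[1], allele2 = g[2])
  }
  microsat_genotypes(do.call(rbind, rows))
}

test_that("allele frequencies come from direct counting", {
  ms <- ms_from_list(list(i1 = list(L1 = c(100, 100)),
                          i2 = list(L1 = c(100, 102))))
  f <- allele_frequencies(ms)
  expect_equal(unname(f$L1["100"]), 0.75)
  expect_equal(unname(f$L1["102"]), 0.25)

  # missing genotypes are excluded; four balanced alleles are equifrequent
  ms2 <- ms_from_list(list(i1 = list(L1 = c(100, 102)),
                           i2 = list(L1 = c(104, 106)),
                           i3 = list(L1 = c(NA, NA))))
  f2 <- allele_frequencies(ms2)
  expect_equal(unname(f2$L1), rep(0.25, 4))
  ms3 <- ms_from_list(list(i1 = list(L1 = c(NA, NA))))
  expect_error(allele_frequencies(ms3), "L1")
})

test_that("single-parent LOD matches hand-computed likelihood ratios", {
  # offspring (a,a), candidate (a,b), p_a = 0.25 -> ln 2; pad the frequency
  # spectrum with a second dummy individual so p_a is exactly 0.25
  ms <- ms_from_list(list(off = list(L1 = c(100, 100)),
                          cand = list(L1 = c(100, 102)),
                          pad = list(L1 = c(104, 102))))
  f <- list(L1 = c("100" = 0.25, "102" = 0.5, "104" = 0.25))
  expect_equal(lod_single_parent("off", "cand", ms, f), log(2))

  # no shared allele at a locus -> exclusion at error rate 0
  ms2 <- ms_from_list(list(off = list(L1 = c(100, 100)),
                           cand = list(L1 = c(102, 104))))
  expect_identical(lod_single_parent("off", "cand", ms2,
                                     list(L1 = c("100" = 0.5, "102" = 0.25,
                                                 "104" = 0.25))), -Inf)

  # offspring (a,b), candidate (a,b), p_a = p_b = 0.5 -> LOD 0
  ms3 <- ms_from_list(list(off = list(L1 = c(100, 102)),
                           cand = list(L1 = c(100, 102))))
  expect_equal(lod_single_parent("off", "cand", ms3,
                                 list(L1 = c("100" = 0.5, "102" = 0.5))), 0)
})

test_that("Mendelian trio compatibility is per-locus and counted", {
  ms <- ms_from_list(list(
    off = list(L1 = c(100, 102), L2 = c(100, 102)),
    mom = list(L1 = c(100, 104), L2 = c(100, 104)),
    dad = list(L1 = c(102, 106), L2 = c(104, 106))))
  r <- mendelian_compatible("off", "mom", "dad", ms)
  expect_true(r$compatible[["L1"]])   # (a,b) from (a,c) x (b,d)
  expect_false(r$compatible[["L2"]])  # (a,b) from (a,c) x (c,d)
  expect_equal(r$n_mismatch, 1)
})

test_that("LOD exclusion coincides exactly with Mendelian incompatibility", {
  sim <- simulate_dataset(sim_config(seed = 41, n_mothers = 3, n_fathers = 3,
                                     offspring_per_mother = 5))
  ms <- sim$microsats$genotypes
  freqs <- allele_frequencies(ms)
  ids <- unique(ms$individual_id)
  offs <- grep("-O", ids, value = TRUE)
  adults <- setdiff(ids, offs)
  for (o in head(offs, 8)) for (a in adults) {
    lod <- lod_single_parent(o, a, ms, freqs, error_rate = 0)
    excl <- any(vapply(names(freqs), function(loc) {
      og <- mhcseg:::ms_pair(ms, o, loc); ag <- mhcseg:::ms_pair(ms, a, loc)
      !is.null(og) && !is.null(ag) && !any(og %in% ag)
    }, logical(1)))
    expect_equal(is.infinite(lod), excl)
  }
})

test_that("consistent allele relabelling leaves LOD unchanged", {
  ms <- ms_from_list(list(off = list(L1 = c(100, 102), L2 = c(110, 110)),
                          cand = list(L1 = c(100, 104), L2 = c(110, 112)),
                          pad = list(L1 = c(102, 104), L2 = c(112, 114))))
  shift <- as.data.frame(ms)
  shift$allele1 <- shift$allele1 + 1000
  shift$allele2 <- shift$allele2 + 1000
  expect_equal(lod_single_parent("off", "cand", ms),
               lod_single_parent("off", "cand", microsat_genotypes(shift)))
})

test_that("true parents outscore non-relatives in nearly all trials", {
  set.seed(97)
  n_trials <- 200
  wins <- 0
  for (t in seq_len(n_trials)) {
    # 8 informative loci, 6 alleles each; trio + unrelated candidate
    loci <- paste0("L", 1:8)
    fr <- lapply(loci, function(l) {
      p <- rgamma(6, 2); p <- p / sum(p)
      stats::setNames(p, 100 + 2 * (1:6))
    })
    names(fr) <- loci
    draw <- function() lapply(fr, function(f)
      as.integer(sample(names(f), 2, TRUE, prob = f)))
    mom <- draw(); unrel <- draw()
    kid <- lapply(loci, function(l)
      c(sample(mom[[l]], 1), as.integer(sample(names(fr[[l]]), 1,
                                               prob = fr[[l]]))))
    names(kid) <- loci
    ms <- ms_from_list(list(off = kid, mom = mom, unrel = unrel))
    l_true <- lod_single_parent("off", "mom", ms, fr, error_rate = 0.01)
    l_un <- lod_single_parent("off", "unrel", ms, fr, error_rate = 0.01)
    if (l_true > l_un) wins <- wins + 1
  }
  expect_gte(wins / n_trials, 0.95)
})

test_that("family assignment groups offspring and bounds father counts", {
  sim <- simulate_dataset(sim_config(seed = 43, n_mothers = 3, n_fathers = 3,
                                     offspring_per_mother = 8,
                                     microsat_alleles = 8))
  ms <- sim$microsats$genotypes
  ind <- sim$pedigree$individuals
  offs <- ind$id[ind$role == "offspring"]
  moms <- ind$id[ind$role == "mother"]
  dads <- ind$id[ind$role == "father"]
  res <- assign_families(offs, moms, dads, ms, error_rate = 0.01)
  assigned <- res$results[res$results$status == "assigned", ]
  expect_gt(nrow(assigned), 0.5 * length(offs))
  for (i in seq_len(nrow(assigned))) {
    o <- assigned$offspring[i]
    expect_equal(assigned$mother[i], ind$mother[ind$id == o])
    expect_equal(assigned$father[i], ind$father[ind$id == o])
  }
  expect_error(assign_families(c(offs, moms[1]), moms, dads, ms), "disjoint")
})

test_that("minimum unsampled fathers follows the allele-count bound", {
  # one locus where offspring carry 5 distinct non-maternal alleles
  kids <- lapply(1:5, function(i) list(L1 = c(100, 110 + 2 * i)))
  names(kids) <- paste0("o", 1:5)
  ms <- ms_from_list(c(list(mom = list(L1 = c(100, 102))), kids))
  # brute-force oracle over loci
  pat <- unique(unlist(lapply(paste0("o", 1:5), function(o)
    setdiff(mhcseg:::ms_pair(ms, o, "L1"), c(100, 102)))))
  expect_equal(length(pat), 5)
  expect_equal(min_unsampled_fathers("mom", paste0("o", 1:5), ms),
               ceiling(5 / 2))
})
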