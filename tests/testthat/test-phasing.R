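test_that("bipartition enumeration matches the brute-force oracle", {
  cases <- list(
    list(ab = c("a1", "b1", "b2"), c = "c1"),
    list(ab = c("a1", "a2", "b1", "b2"), c = c("c1", "c2")),
    list(ab = c("b1"), c = character(0)),
    list(ab = character(0), c = "c1"),
    list(ab = c("b1", "b2"), c = character(0)))
  for (cs in cases) {
    got <- enumerate_bipartitions(list(ab = cs$ab, c = cs$c))
    keys <- sort(vapply(got, function(p) mhcseg:::pair_key(p$h1, p$h2),
                        character(1)))
    expect_equal(keys, oracle_bipartitions(cs$ab, cs$c))
  }
  # 4 distinct A/B alleles x 2 C alleles -> 3 x 2 = 6 unordered pairs
  got6 <- enumerate_bipartitions(list(ab = c("a1", "a2", "b1", "b2"),
                                      c = c("c1", "c2")))
  expect_length(got6, 6)
  # single-allele parent: homozygote and hemizygote splits both present
  got1 <- enumerate_bipartitions(list(ab = "x", c = character(0)))
  keys1 <- vapply(got1, function(p) mhcseg:::pair_key(p$h1, p$h2),
                  character(1))
  expect_true("x|- / x|-" %in% keys1)
  expect_true("x|- / |-" %in% keys1)
  expect_error(enumerate_bipartitions(list(ab = letters[1:5],
                                           c = character(0))),
               "capacity")
})

test_that("the family #5 worked example is reconstructed exactly", {
  fx <- family5_fixture()
  s <- phase_family(fx$family, fx$genotypes)
  expect_equal(mhcseg:::pair_key(s$mother$h1, s$mother$h2),
               fx$truth[["Mo4"]])
  expect_equal(mhcseg:::pair_key(s$fathers$Fa1$h1, s$fathers$Fa1$h2),
               fx$truth[["Fa1"]])
  expect_equal(mhcseg:::pair_key(s$fathers$Fa3$h1, s$fathers$Fa3$h2),
               fx$truth[["Fa3"]])
  expect_equal(s$n_explained, 12)
  expect_equal(s$n_recombination_events, 0)
  # union property over every explained offspring
  for (i in seq_len(nrow(s$assignments))) {
    a <- s$assignments[i, ]
    o <- mhcseg:::geno_get(fx$genotypes, a$offspring_id)
    mh <- if (a$maternal_hap == "1") s$mother$h1 else s$mother$h2
    fh <- if (a$paternal_hap == "1") s$fathers[[a$father_id]]$h1 else
      s$fathers[[a$father_id]]$h2
    expect_setequal(union(mh$ab, fh$ab), o$ab)
    expect_setequal(union(mh$c, fh$c), o$c)
  }
})

test_that("an offspring equal to the mother's full allele set is ambiguous", {
  genos <- rbind(mhc_genotype("M", ab = c("a", "b", "x", "y")),
                 mhc_genotype("O", ab = c("a", "b", "x", "y")))
  fam <- list(family_id = "T", mother = "M",
              offspring = data.frame(offspring_id = "O", father_id = "",
                                     stringsAsFactors = FALSE))
  s <- phase_family(fam, genos)
  expect_gt(s$multiplicity, 1)
  expect_gt(length(s$alt_solutions), 0)
})

test_that("phasing recovers simulated truth across many seeded families", {
  set.seed(1000)
  n_fam <- 0; n_identifiable <- 0; n_recovered <- 0
  for (seed in 1:34) {
    cfg <- sim_config(seed = seed, n_mothers = 3, n_fathers = 3,
                      offspring_per_mother = sample(5:12, 1))
    sim <- simulate_dataset(cfg)
    truthpairs <- lapply(seq_len(nrow(sim$pedigree$individuals)),
                         function(i) {
      ind <- sim$pedigree$individuals[i, ]
      mhcseg:::pair_key(sim$pedigree$haplotypes[[ind$hap1]],
                        sim$pedigree$haplotypes[[ind$hap2]])
    })
    names(truthpairs) <- sim$pedigree$individuals$id
    for (fam in sim$pedigree$families) {
      n_fam <- n_fam + 1
      s <- phase_family(fam, sim$genotypes)
      expect_equal(s$n_explained, nrow(fam$offspring))
      expect_equal(s$n_recombination_events, 0)
      if (s$multiplicity == 1) {
        n_identifiable <- n_identifiable + 1
        if (mhcseg:::pair_key(s$mother$h1, s$mother$h2) ==
            truthpairs[[fam$mother]])
          n_recovered <- n_recovered + 1
      }
    }
  }
  expect_gte(n_fam, 100)
  expect_gt(n_identifiable, 30)
  # whenever the optimum is unique it is the simulated truth
  expect_equal(n_recovered, n_identifiable)
})

test_that("phasing stays accurate under 5% allele dropout", {
  n_id <- 0; n_rec <- 0
  for (seed in 101:130) {
    cfg <- sim_config(seed = seed, n_mothers = 2, n_fathers = 2,
                      offspring_per_mother = 10, allele_dropout = 0.05)
    sim <- simulate_dataset(cfg)
    clean <- simulated_genotypes(sim$pedigree, sim_config(seed = seed))
    for (fam in sim$pedigree$families) {
      # genotype parents cleanly, noise confined to offspring observations
      g <- sim$genotypes
      for (p in c(fam$mother, unique(fam$offspring$father_id))) {
        g[g$sample_id == p, ] <- clean[clean$sample_id == p, ]
      }
      s <- try(phase_family(fam, g), silent = TRUE)
      if (inherits(s, "try-error")) next
      if (s$multiplicity == 1) {
        n_id <- n_id + 1
        truth <- mhcseg:::pair_key(
          sim$pedigree$haplotypes[[sim$pedigree$individuals$hap1[
            sim$pedigree$individuals$id == fam$mother]]],
          sim$pedigree$haplotypes[[sim$pedigree$individuals$hap2[
            sim$pedigree$individuals$id == fam$mother]]])
        if (mhcseg:::pair_key(s$mother$h1, s$mother$h2) == truth)
          n_rec <- n_rec + 1
      }
    }
  }
  expect_gt(n_id, 20)
  expect_gte(n_rec / n_id, 0.90)
})

test_that("recombinant counting is parsimonious and eligibility-gated", {
  # mother {a1,c1}/{a2,c2}; offspring carrying maternal a1 + c2 is the
  # constructed C-boundary recombinant; father contributes neither
  genos <- rbind(
    mhc_genotype("M", ab = c("a1", "a2"), c = c("c1", "c2")),
    mhc_genotype("F", ab = c("b1", "b2")),
    mhc_genotype("O1", ab = c("a1", "b1"), c = "c1"),
    mhc_genotype("O2", ab = c("a2", "b1"), c = "c2"),
    mhc_genotype("O3", ab = c("a1", "b2"), c = "c1"),
    mhc_genotype("O4", ab = c("a2", "b2"), c = "c2"),
    mhc_genotype("O5", ab = c("a1", "b1"), c = "c2"))  # recombinant
  fam <- list(family_id = "R", mother = "M",
              offspring = data.frame(offspring_id = paste0("O", 1:5),
                                     father_id = rep("F", 5),
                                     stringsAsFactors = FALSE))
  s <- phase_family(fam, genos)
  expect_equal(s$n_explained, 5)
  expect_equal(s$n_recombination_events, 1)
  expect_equal(s$assignments$recomb_cost[s$assignments$offspring_id ==
                                           "O5"], 1)
  rec <- count_recombinants(s, min_offspring = 5)
  expect_equal(rec$n_recombinant, 1)
  expect_equal(rec$frequency, 1 / 5)

  # a parent with only 4 offspring is excluded from the denominator
  fam4 <- fam
  fam4$offspring <- fam$offspring[1:4, ]
  s4 <- phase_family(fam4, genos)
  rec4 <- count_recombinants(s4, min_offspring = 5)
  expect_equal(sum(rec4$parents$eligible), 0)
  expect_true(is.na(rec4$frequency))

  # brute-force parsimony check: no bipartition pair explains all five
  # offspring with fewer than one exchange
  mb <- enumerate_bipartitions(list(ab = c("a1", "a2"), c = c("c1", "c2")))
  fb <- enumerate_bipartitions(list(ab = c("b1", "b2"), c = character(0)))
  zero_cost_possible <- FALSE
  for (mp in mb) for (fp in fb) {
    ok <- all(vapply(paste0("O", 1:5), function(k) {
      o <- mhcseg:::geno_get(genos, k)
      any(vapply(list(mp$h1, mp$h2), function(mh)
        any(vapply(list(fp$h1, fp$h2), function(fh)
          mhcseg:::explains(mh, fh, o), logical(1))), logical(1)))
    }, logical(1)))
    if (ok) zero_cost_possible <- TRUE
  }
  expect_false(zero_cost_possible)
})

test_that("zero recombinants on the five study families", {
  all <- study_families()
  sols <- lapply(all$families, function(f) phase_family(f, all$genotypes))
  rec <- count_recombinants(sols, min_offspring = 5)
  expect_equal(rec$n_recombinant, 0)
  expect_equal(rec$frequency, 0)
  expect_gt(sum(rec$parents$eligible), 0)
})

test_that("hemizygosity calls distinguish ABSENT from UNKNOWN", {
  fx <- family5_fixture()
  s <- phase_family(fx$family, fx$genotypes)
  hz <- infer_hemizygosity(s, fx$genotypes)
  # father 3 carries a single C allele (45); his C-less haplotype {68,69}
  # fathered offspring with confirmed C absence -> ABSENT
  f3 <- hz[hz$parent == "Fa3" & hz$key == "68+69|-", ]
  expect_equal(f3$c_slot, "ABSENT")
  expect_equal(hz$c_slot[hz$parent == "Fa3" & hz$key == "67|45"], "45")

  # a parent whose single C allele reaches every offspring stays UNKNOWN
  genos <- rbind(
    mhc_genotype("M", ab = c("a1", "a2"), c = "c1"),
    mhc_genotype("F", ab = c("b1", "b2")),
    mhc_genotype("O1", ab = c("a1", "b1"), c = "c1"),
    mhc_genotype("O2", ab = c("a2", "b1"), c = "c1"),
    mhc_genotype("O3", ab = c("a1", "b2"), c = "c1"),
    mhc_genotype("O4", ab = c("a2", "b2"), c = "c1"),
    mhc_genotype("O5", ab = c("a1", "b1"), c = "c1"))
  fam <- list(family_id = "U", mother = "M",
              offspring = data.frame(offspring_id = paste0("O", 1:5),
                                     father_id = rep("F", 5),
                                     stringsAsFactors = FALSE))
  s2 <- phase_family(fam, genos)
  hz2 <- infer_hemizygosity(s2, genos)
  cless <- hz2[hz2$parent == "M" & !hz2$c_slot %in% c("c1"), ]
  if (nrow(cless)) expect_true(all(cless$c_slot == "UNKNOWN"))
  # father F (no C at all): both haplotype slots rest on offspring status
  expect_true(all(hz2$c_slot[hz2$parent == "F"] %in%
                  c("ABSENT", "UNKNOWN")))

  # two distinct C alleles -> both haplotypes carry C, nothing to resolve
  genos3 <- rbind(
    mhc_genotype("M", ab = c("a1", "a2"), c = c("c1", "c2")),
    mhc_genotype("F", ab = c("b1", "b2")),
    mhc_genotype("O1", ab = c("a1", "b1"), c = "c1"),
    mhc_genotype("O2", ab = c("a2", "b1"), c = "c2"),
    mhc_genotype("O3", ab = c("a1", "b2"), c = "c1"),
    mhc_genotype("O4", ab = c("a2", "b2"), c = "c2"),
    mhc_genotype("O5", ab = c("a2", "b1"), c = "c2"))
  s3 <- phase_family(list(family_id = "V", mother = "M",
                          offspring = data.frame(
                            offspring_id = paste0("O", 1:5),
                            father_id = rep("F", 5),
                            stringsAsFactors = FALSE)), genos3)
  hz3 <- infer_hemizygosity(s3, genos3)
  expect_setequal(hz3$c_slot[hz3$parent == "M"], c("c1", "c2"))
})

test_that("a deliberate recombinant transmission is counted exactly once", {
  cfg <- sim_config(seed = 78, n_mothers = 1, n_fathers = 1,
                    offspring_per_mother = 8)
  sim <- simulate_dataset(cfg)
  fam <- sim$pedigree$families[[1]]
  g <- sim$genotypes
  ind <- sim$pedigree$individuals
  mom <- ind[ind$id == fam$mother, ]
  h1 <- sim$pedigree$haplotypes[[mom$hap1]]
  h2 <- sim$pedigree$haplotypes[[mom$hap2]]
  # this seed gives a mother whose haplotypes differ in the C slot
  expect_false(identical(h1$c, h2$c))
  rec_hap <- list(ab = h1$ab, c = h2$c)
  kid <- fam$offspring$offspring_id[1]
  dad <- ind[ind$id == fam$offspring$father_id[1], ]
  fh <- sim$pedigree$haplotypes[[dad$hap1]]
  g[g$sample_id == kid, ] <- mhc_genotype(
    kid, c(rec_hap$ab, fh$ab), unique(c(rec_hap$c, fh$c)),
    if (length(c(rec_hap$c, fh$c))) "present" else "absent")
  s <- phase_family(fam, g)
  expect_equal(s$n_recombination_events, 1)
})

test_that("expected diplotype counts follow the linkage model", {
  mo <- rbind(L1 = c("a1", "a2"), L2 = c("b1", "b2"))
  fa <- rbind(L1 = c("a3", "a4"), L2 = c("b3", "b4"))
  expect_equal(expected_diplotype_count(mo, fa, "independent"), 16)
  expect_equal(expected_diplotype_count(mo, fa, "complete"), 4)
  one <- rbind(L1 = c("a1", "a2"))
  one2 <- rbind(L1 = c("a3", "a4"))
  expect_equal(expected_diplotype_count(one, one2, "independent"), 4)

  # brute-force enumeration oracle for small random inputs
  set.seed(5)
  for (rep in 1:10) {
    nl <- sample(1:3, 1)
    mo <- matrix(sample(paste0("m", 1:4), nl * 2, TRUE), nl, 2)
    fa <- matrix(sample(paste0("f", 1:4), nl * 2, TRUE), nl, 2)
    brute <- function(m, f) {
      gam <- function(x) unique(apply(
        as.matrix(expand.grid(lapply(seq_len(nrow(x)), function(i)
          unique(x[i, ])))), 1, paste, collapse = "|"))
      length(unique(c(outer(gam(m), gam(f), function(a, b)
        paste(pmin(a, b), pmax(a, b), sep = " + ")))))
    }
    expect_equal(expected_diplotype_count(mo, fa, "independent"),
                 brute(mo, fa))
  }
})
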