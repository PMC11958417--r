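base_seq <- rand_seq(240, seed = 42)
v1 <- base_seq
v2 <- substitute_k(base_seq, 24, seed = 2)
v3 <- substitute_k(base_seq, 30, seed = 3)

test_that("coverage filtering removes thin amplicons and variants", {
  counts <- cbind(a1 = c(v1 = 60, v2 = 39), a2 = c(500, 400),
                  a3 = c(9, 950))
  rownames(counts) <- c("v1", "v2")
  tab <- tiny_asv(counts, c(v1 = v1, v2 = v2))
  res <- filter_by_coverage(tab)  # a1 has 99 reads total
  expect_false("a1" %in% colnames(res$table$counts))
  expect_true(all(c("a2", "a3") %in% colnames(res$table$counts)))
  expect_true(any(res$status$amplicon == "a1" &
                  res$status$state == "low_coverage"))

  # variant with counts (9, 7, 3): max 9 < 10 -> dropped
  counts2 <- cbind(b1 = c(x = 9, y = 200), b2 = c(7, 150), b3 = c(3, 120))
  tab2 <- tiny_asv(counts2, c(x = v1, y = v2))
  res2 <- filter_by_coverage(tab2)
  expect_false("x" %in% rownames(res2$table$counts))
  expect_true("y" %in% rownames(res2$table$counts))

  # identity case: everything above both thresholds passes untouched
  counts3 <- cbind(c1 = c(p = 80, q = 40), c2 = c(10, 90))
  tab3 <- tiny_asv(counts3, c(p = v1, q = v2))
  res3 <- filter_by_coverage(tab3)
  expect_identical(res3$table$counts, tab3$counts)
  expect_equal(nrow(res3$status), 0)
})

test_that("off-target variants are dropped by alignment identity", {
  refs <- c(ref1 = v1, ref2 = v2)
  junk <- rand_seq(240, seed = 99)
  near <- substitute_k(v1, 12, seed = 4)  # 95% identity to ref1
  counts <- cbind(a1 = c(exact = 500, near = 400, junk = 300))
  tab <- tiny_asv(counts, c(exact = v1, near = near, junk = junk))
  # independent identity oracle for the equal-length, gap-free pairs
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  expect_lt(max(ident(junk, v1), ident(junk, v2)), 0.60)
  expect_equal(ident(near, v1), 0.95)
  res <- filter_offtarget(tab, refs)
  expect_true(all(c("exact", "near") %in% rownames(res$table$counts)))
  expect_false("junk" %in% rownames(res$table$counts))
  expect_equal(res$status$state, "offtarget")
  expect_error(filter_offtarget(tab, character(0)), "empty")
})

test_that("per-amplicon frequency rule is strict and per-amplicon", {
  # a1: v_lo at 0.9% -> flagged there; a2: v_lo at exactly 1% -> kept
  counts <- cbind(a1 = c(hi = 991, lo = 9), a2 = c(990, 10))
  tab <- tiny_asv(counts, c(hi = v1, lo = v2))
  res <- filter_low_frequency(tab)
  expect_true(any(res$status$variant == "lo" & res$status$amplicon == "a1"))
  expect_false(any(res$status$amplicon == "a2"))
  expect_equal(res$table$counts["lo", "a1"], 0)
  expect_equal(res$table$counts["lo", "a2"], 10)

  # a single variant at 100% of its amplicon is retained
  solo <- tiny_asv(cbind(a1 = c(only = 500)), c(only = v1))
  res2 <- filter_low_frequency(solo)
  expect_equal(nrow(res2$status), 0)
  expect_equal(res2$table$counts["only", "a1"], 500)
})

test_that("artifact classification finds 1-bp, chimera and bleed variants", {
  parent1 <- v1
  parent2 <- v2
  onebp <- mutate_at(parent1, 7, setdiff(c("A", "C", "G", "T"),
                                         substr(parent1, 7, 7))[1])
  chim <- paste0(substr(parent1, 1, 120), substr(parent2, 121, 240))
  counts <- cbind(a1 = c(p1 = 600, p2 = 300, e1 = 20, ch = 30),
                  a2 = c(500, 450, 0, 0))
  tab <- tiny_asv(counts, c(p1 = parent1, p2 = parent2, e1 = onebp,
                            ch = chim))
  st <- classify_artifacts(tab)
  get <- function(v, a) st$state[st$variant == v & st$amplicon == a]
  expect_equal(get("p1", "a1"), "true_allele")
  expect_equal(get("e1", "a1"), "artifact_1bp")
  expect_equal(get("ch", "a1"), "artifact_chimera")

  # variant at 2% in one amplicon but a true allele at ~40% elsewhere
  counts2 <- cbind(P = c(x = 20, y = 980, z = 0),
                   Q = c(400, 0, 600), R = c(380, 0, 620))
  tab2 <- tiny_asv(counts2, c(x = v1, y = v2, z = v3))
  st2 <- classify_artifacts(tab2)
  g2 <- function(v, a) st2$state[st2$variant == v & st2$amplicon == a]
  expect_equal(g2("x", "P"), "artifact_cross_amplicon")
  expect_equal(g2("x", "Q"), "true_allele")
  expect_equal(g2("x", "R"), "true_allele")
})

test_that("filter chain is idempotent and keeps true calls above thresholds", {
  sim <- simulate_dataset(sim_config(seed = 7, n_mothers = 2, n_fathers = 2,
                                     offspring_per_mother = 4,
                                     chimera_rate = 0.4, onebp_rate = 0.4,
                                     read_depth = 2000))
  refs <- sim$pool$sequences
  r1 <- filter_asv(sim$asv$table, refs)
  r2 <- filter_asv(r1$table, refs)
  expect_identical(r1$table$counts, r2$table$counts)
  expect_identical(sort(rownames(r1$table$counts)),
                   sort(rownames(r2$table$counts)))
  true <- r1$status[r1$status$state == "true_allele", ]
  f <- sweep(r1$table$counts, 2, pmax(colSums(r1$table$counts), 1), "/")
  for (i in seq_len(nrow(true))) {
    expect_gte(f[true$variant[i], true$amplicon[i]], 0.01)
    expect_gte(max(r1$table$counts[true$variant[i], ]), 10)
  }
})

test_that("noise-free simulated tables round-trip to the exact genotypes", {
  sim <- simulate_dataset(sim_config(seed = 11, n_mothers = 2, n_fathers = 2,
                                     offspring_per_mother = 5,
                                     read_depth = 2000))
  res <- filter_asv(sim$asv$table, sim$pool$sequences)
  genos <- call_genotypes(res$table, res$status, sim$pool$lineages)
  truth <- sim$genotypes
  expect_setequal(genos$sample_id, truth$sample_id)
  for (id in truth$sample_id) {
    g <- genos[genos$sample_id == id, ]
    t <- truth[truth$sample_id == id, ]
    expect_identical(g$ab, t$ab)
    expect_identical(g$c, t$c)
    expect_identical(g$c_status, t$c_status)
  }
})

test_that("injected sub-parent-frequency artifacts are always flagged", {
  sim <- simulate_dataset(sim_config(seed = 13, n_mothers = 3, n_fathers = 2,
                                     offspring_per_mother = 6,
                                     chimera_rate = 0.5, onebp_rate = 0.5,
                                     read_depth = 3000))
  log <- sim$asv$log
  expect_gt(nrow(log), 5)
  res <- filter_asv(sim$asv$table, sim$pool$sequences)
  st <- res$status
  for (i in seq_len(nrow(log))) {
    cell <- st[st$variant == log$variant[i] &
               st$amplicon == log$amplicon[i], ]
    if (nrow(cell) > 0)
      expect_false(any(cell$state == "true_allele"),
                   label = paste("artifact", log$variant[i], "called true"))
  }
  # and no simulated true allele is lost
  genos <- call_genotypes(res$table, res$status, sim$pool$lineages)
  truth <- sim$genotypes
  for (id in truth$sample_id) {
    expect_identical(genos$ab[genos$sample_id == id],
                     truth$ab[truth$sample_id == id])
  }
})

test_that("chimera injections are single-breakpoint joins of carried parents", {
  sim <- simulate_dataset(sim_config(seed = 17, n_mothers = 2, n_fathers = 2,
                                     offspring_per_mother = 5,
                                     chimera_rate = 0.6, read_depth = 2000))
  log <- sim$asv$log[sim$asv$log$type == "chimera", ]
  expect_gt(nrow(log), 0)
  seqs <- sim$asv$table$sequences
  for (i in seq_len(nrow(log))) {
    par <- strsplit(log$parents[i], "+", fixed = TRUE)[[1]]
    x <- seqs[[log$variant[i]]]
    joins <- vapply(seq_len(nchar(x) - 1), function(k)
      paste0(substr(seqs[[par[1]]], 1, k),
             substr(seqs[[par[2]]], k + 1, nchar(x))) == x, logical(1))
    expect_true(any(joins))
  }
})

test_that("replicate congruence reports identical and discordant pairs", {
  counts <- cbind(s1 = c(x = 500, y = 400, z = 0),
                  s1r = c(480, 420, 0),
                  s2 = c(300, 0, 700),
                  s2r = c(310, 300, 655))
  tab <- tiny_asv(counts, c(x = v1, y = v2, z = v3),
                  samples = c("s1", "s1", "s2", "s2"),
                  replicates = c("", "r1", "", "r1"))
  st <- classify_artifacts(tab)
  rc <- replicate_congruence(tab, st)
  expect_equal(rc$n_pairs, 2)
  expect_equal(rc$fraction_congruent, 0.5)
  expect_equal(rc$discordant$sample_id, "s2")
  expect_equal(rc$discordant$alleles, "y")

  # 20 all-identical pairs -> 100% congruent
  sim <- simulate_dataset(sim_config(seed = 23, n_mothers = 3, n_fathers = 3,
                                     offspring_per_mother = 8,
                                     replicate_fraction = 1,
                                     read_depth = 2000))
  res <- filter_asv(sim$asv$table, sim$pool$sequences)
  rc2 <- replicate_congruence(res$table, res$status)
  expect_gte(rc2$n_pairs, 20)
  expect_equal(rc2$fraction_congruent, 1)
})
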