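# tiny deterministic sequences and tables shared across tests

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(s, pos, base) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

# substitute k positions, never reusing the original base
substitute_k <- function(s, k, seed = 1) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

tiny_asv <- function(counts, seqs, samples = NULL, primers = NULL,
                     replicates = NULL) {
  n <- ncol(counts)
  meta <- data.frame(
    amplicon_id = colnames(counts),
    sample_id = if (is.null(samples)) paste0("s", seq_len(n)) else samples,
    primer_set = if (is.null(primers)) rep("NF2-NR2", n) else primers,
    replicate = if (is.null(replicates)) rep("", n) else replicates,
    stringsAsFactors = FALSE)
  asv_table(counts, seqs, meta)
}

# brute-force oracle: all unordered haplotype pairs covering the allele set
oracle_bipartitions <- function(ab, cc, ab_cap = 2, c_cap = 1) {
  subs <- list(character(0))
  if (length(ab))
    for (k in seq_len(min(ab_cap, length(ab))))
      subs <- c(subs, utils::combn(ab, k, simplify = FALSE))
  csubs <- list(character(0))
  if (length(cc))
    for (k in seq_len(min(c_cap, length(cc))))
      csubs <- c(csubs, utils::combn(cc, k, simplify = FALSE))
  keys <- character(0)
  for (a1 in subs) for (a2 in subs) for (c1 in csubs) for (c2 in csubs) {
    if (!setequal(union(a1, a2), ab)) next
    if (!setequal(union(c1, c2), cc)) next
    h1 <- paste0(paste(sort(a1), collapse = "+"), "|",
                 if (length(c1)) c1 else "-")
    h2 <- paste0(paste(sort(a2), collapse = "+"), "|",
                 if (length(c2)) c2 else "-")
    keys <- c(keys, paste(sort(c(h1, h2)), collapse = " / "))
  }
  sort(unique(keys))
}
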