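#' Amplicon sequence variant (ASV) table
#'
#' Container for a variant-by-amplicon read-count matrix plus amplicon
#' metadata. Amplicons are one sample x primer-set sequencing unit; the
#' `NF2-NR2` primer set co-amplifies lineage A/B alleles and `DF2-DR2`
#' amplifies lineage C.
#'
#' @param counts Non-negative integer matrix, variants in rows (rownames =
#'   variant ids), amplicons in columns (colnames = amplicon ids).
#' @param sequences Named character vector of variant nucleotide sequences
#'   (names matching rownames of `counts`); sequences must be unique.
#' @param meta data.frame with columns `amplicon_id`, `sample_id`,
#'   `primer_set` (one of `"NF2-NR2"`, `"DF2-DR2"`), `replicate` (tag,
#'   `""`/`NA` for the primary run); one row per column of `counts`.
#' @return Object of class `asv_table`.
#' @export
asv_table <- function(counts, sequences, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs variant rownames and amplicon colnames")
  if (!setequal(names(sequences), rownames(counts)))
    stop("sequence names must match count rownames")
  sequences <- toupper(sequences[rownames(counts)])
  if (any(!nzchar(sequences))) stop("empty variant sequence")
  if (anyDuplicated(sequences)) stop("variant sequences must be unique")
  need <- c("amplicon_id", "sample_id", "primer_set", "replicate")
  if (!all(need %in% names(meta)))
    stop("meta must have columns: ", paste(need, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  if (!setequal(meta$amplicon_id, colnames(counts)))
    stop("meta amplicon_id must match count colnames")
  meta <- meta[match(colnames(counts), meta$amplicon_id), ]
  rownames(meta) <- NULL
  if (any(is.na(meta$sample_id) | !nzchar(meta$sample_id)))
    stop("every amplicon needs a sample_id")
  meta$replicate[is.na(meta$replicate)] <- ""
  structure(list(counts = counts, sequences = sequences, meta = meta),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("asv_table:", nrow(x$counts), "variants x", ncol(x$counts),
      "amplicons (", length(unique(x$meta$sample_id)), "samples )\n")
  invisible(x)
}

#' Filtering thresholds for ASV post-processing
#'
#' Defaults follow the study protocol: amplicons with fewer than 100 reads
#' and variants whose maximum per-amplicon count is below 10 are removed, and
#' per-amplicon variant frequencies below 1% are artifacts. All comparisons
#' are strict (`<`), so boundary values are retained.
#'
#' @param min_sample_coverage Minimum total reads per amplicon (default 100).
#' @param min_variant_max_coverage Minimum of a variant's maximum per-amplicon
#'   count (default 10).
#' @param min_frequency Minimum within-amplicon frequency (default 0.01).
#' @param offtarget_identity_floor Minimum best global-alignment identity to a
#'   reference allele (default 0.80).
#' @param minor_fraction Cross-amplicon rule: a variant is an artifact in an
#'   amplicon where its frequency is below this fraction of its median
#'   frequency in amplicons where it is a true allele (default 0.25).
#' @param minor_absolute Absolute frequency cap for the cross-amplicon rule:
#'   only calls below this in-amplicon frequency can be demoted (default
#'   0.10), so legitimate co-amplified alleles (frequency about 1/k for k
#'   alleles) are never flagged merely because the variant dominates
#'   single-allele amplicons elsewhere.
#' @param check_chimeras,check_onebp Toggle the two within-amplicon artifact
#'   classes.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_sample_coverage = 100,
                          min_variant_max_coverage = 10,
                          min_frequency = 0.01,
                          offtarget_identity_floor = 0.80,
                          minor_fraction = 0.25,
                          minor_absolute = 0.10,
                          check_chimeras = TRUE,
                          check_onebp = TRUE) {
  stopifnot(min_sample_coverage >= 0, min_variant_max_coverage >= 0,
            min_frequency >= 0, min_frequency <= 1,
            offtarget_identity_floor >= 0, offtarget_identity_floor <= 1,
            minor_fraction >= 0, minor_fraction <= 1,
            minor_absolute >= 0, minor_absolute <= 1)
  structure(list(min_sample_coverage = min_sample_coverage,
                 min_variant_max_coverage = min_variant_max_coverage,
                 min_frequency = min_frequency,
                 offtarget_identity_floor = offtarget_identity_floor,
                 minor_fraction = minor_fraction,
                 minor_absolute = minor_absolute,
                 check_chimeras = check_chimeras,
                 check_onebp = check_onebp),
            class = "filter_config")
}

status_record <- function(variant, amplicon, state, reason) {
  data.frame(variant = as.character(variant),
             amplicon = as.character(amplicon),
             state = as.character(state), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

empty_status <- function() status_record(character(0), character(0),
                                         character(0), character(0))

drop_variants <- function(tab, keep) {
  tab$counts <- tab$counts[keep, , drop = FALSE]
  tab$sequences <- tab$sequences[rownames(tab$counts)]
  tab
}

#' Coverage filtering of an ASV table
#'
#' Removes amplicons whose total read count is below
#' `min_sample_coverage`, then variants whose maximum per-amplicon count
#' (after the amplicon drop) is below `min_variant_max_coverage`.
#'
#' @param tab An [asv_table()].
#' @param cfg A [filter_config()].
#' @return List with the filtered `table` and a `status` data.frame of removed
#'   (variant, amplicon) records (state `low_coverage`, amplicon `"*"` for
#'   whole-variant drops).
#' @export
filter_by_coverage <- function(tab, cfg = filter_config()) {
  stopifnot(inherits(tab, "asv_table"))
  status <- empty_status()
  tot <- colSums(tab$counts)
  # all-zero amplicons are kept: they arise when every variant of an
  # amplicon was already removed for cause (e.g. off-target-only columns)
  # and still attest that the amplification itself worked
  drop_amp <- tot < cfg$min_sample_coverage & tot > 0
  if (any(drop_amp)) {
    status <- rbind(status, status_record(
      "*", colnames(tab$counts)[drop_amp], "low_coverage",
      sprintf("amplicon total %g < %g", tot[drop_amp],
              cfg$min_sample_coverage)))
    tab$counts <- tab$counts[, !drop_amp, drop = FALSE]
    tab$meta <- tab$meta[!drop_amp, ]
  }
  if (ncol(tab$counts) == 0) {
    tab <- drop_variants(tab, logical(nrow(tab$counts)))
    return(list(table = tab, status = status))
  }
  vmax <- apply(tab$counts, 1, max)
  drop_var <- vmax < cfg$min_variant_max_coverage
  if (any(drop_var)) {
    status <- rbind(status, status_record(
      rownames(tab$counts)[drop_var], "*", "low_coverage",
      sprintf("max coverage %g < %g", vmax[drop_var],
              cfg$min_variant_max_coverage)))
    tab <- drop_variants(tab, !drop_var)
  }
  list(table = tab, status = status)
}

#' Off-target filtering against a reference allele panel
#'
#' Discards variants whose best global-alignment identity to any reference is
#' below `offtarget_identity_floor`.
#'
#' @param tab An [asv_table()].
#' @param references Named character vector of reference allele sequences.
#' @param cfg A [filter_config()].
#' @return List with filtered `table`, `status` records (state `offtarget`)
#'   and the per-variant `identity` vector.
#' @export
filter_offtarget <- function(tab, references, cfg = filter_config()) {
  stopifnot(inherits(tab, "asv_table"))
  if (length(references) == 0) stop("reference set is empty")
  ids <- rownames(tab$counts)
  best <- vapply(tab$sequences, function(s) {
    if (s %in% toupper(references)) return(1)
    max(vapply(references, function(r) alignment_identity(s, r), numeric(1)))
  }, numeric(1))
  drop <- best < cfg$offtarget_identity_floor
  status <- if (any(drop)) {
    status_record(ids[drop], "*", "offtarget",
                  sprintf("best identity %.3f < %.2f", best[drop],
                          cfg$offtarget_identity_floor))
  } else empty_status()
  list(table = drop_variants(tab, !drop), status = status,
       identity = best)
}

amplicon_freqs <- function(counts) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, "/")
}

#' Per-amplicon low-frequency filtering
#'
#' Within each amplicon, variants whose frequency is strictly below
#' `min_frequency` are artifacts in that amplicon (the count cell is zeroed);
#' the same variant may survive in other amplicons. Variants left with no
#' reads anywhere are dropped.
#'
#' @param tab An [asv_table()].
#' @param cfg A [filter_config()].
#' @return List with filtered `table` and `status` records
#'   (state `low_frequency`, one per flagged cell).
#' @export
filter_low_frequency <- function(tab, cfg = filter_config()) {
  stopifnot(inherits(tab, "asv_table"))
  f <- amplicon_freqs(tab$counts)
  flag <- f < cfg$min_frequency & tab$counts > 0
  status <- empty_status()
  if (any(flag)) {
    idx <- which(flag, arr.ind = TRUE)
    status <- status_record(rownames(tab$counts)[idx[, 1]],
                            colnames(tab$counts)[idx[, 2]],
                            "low_frequency",
                            sprintf("frequency %.4f < %.4f",
                                    f[flag], cfg$min_frequency))
    tab$counts[flag] <- 0L
  }
  tab <- drop_variants(tab, rowSums(tab$counts) > 0 | nrow(tab$counts) == 0)
  list(table = tab, status = status)
}

hamming1 <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1
}

is_chimera_of <- function(x, p1, p2) {
  # single internal breakpoint k: x == prefix(p1, k) + suffix(p2, k+1..)
  n <- nchar(x)
  if (nchar(p2) != n) return(FALSE)
  xs <- strsplit(x, "")[[1]]
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  np <- min(n, length(a))
  pre <- which(xs[seq_len(np)] != a[seq_len(np)])
  lcp <- if (length(pre)) pre[1] - 1 else np
  suf <- which(rev(xs) != rev(b))
  lcs <- if (length(suf)) suf[1] - 1 else n
  lcp + lcs >= n && lcp < n && lcs < n
}

#' Classify remaining variants as true alleles or artifacts
#'
#' Run after coverage, off-target and frequency filtering. Within each
#' amplicon, variants are visited in decreasing frequency; a variant is
#' `artifact_1bp` if it differs by exactly one substitution from an
#' already-accepted higher-frequency variant of the same amplicon, and
#' `artifact_chimera` if it is a single-breakpoint concatenation of two
#' distinct accepted higher-frequency variants. A final cross-amplicon pass
#' demotes a variant to `artifact_cross_amplicon` in amplicons where its
#' frequency is below `minor_fraction` of its median frequency in the
#' amplicons where it is a true allele. Everything else is `true_allele`.
#'
#' @param tab An [asv_table()] (already coverage/frequency filtered).
#' @param cfg A [filter_config()].
#' @return `status` data.frame with one row per (variant, amplicon) cell with
#'   non-zero reads.
#' @export
classify_artifacts <- function(tab, cfg = filter_config()) {
  stopifnot(inherits(tab, "asv_table"))
  f <- amplicon_freqs(tab$counts)
  out <- list()
  state <- matrix(NA_character_, nrow(tab$counts), ncol(tab$counts),
                  dimnames = dimnames(tab$counts))
  reason <- state
  for (j in seq_len(ncol(tab$counts))) {
    present <- which(tab$counts[, j] > 0)
    ord <- present[order(-f[present, j])]
    accepted <- character(0)
    for (i in ord) {
      v <- rownames(tab$counts)[i]
      sq <- tab$sequences[[v]]
      st <- "true_allele"; rs <- "passes all artifact checks"
      if (cfg$check_onebp && length(accepted)) {
        hits <- accepted[vapply(accepted, function(p)
          hamming1(sq, tab$sequences[[p]]), logical(1))]
        if (length(hits)) {
          st <- "artifact_1bp"
          rs <- paste("1 substitution from co-occurring", hits[1])
        }
      }
      if (st == "true_allele" && cfg$check_chimeras && length(accepted) >= 2) {
        pairs <- expand.grid(p1 = accepted, p2 = accepted,
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$p1 != pairs$p2, ]
        for (k in seq_len(nrow(pairs))) {
          if (is_chimera_of(sq, tab$sequences[[pairs$p1[k]]],
                            tab$sequences[[pairs$p2[k]]])) {
            st <- "artifact_chimera"
            rs <- sprintf("chimera of %s + %s", pairs$p1[k], pairs$p2[k])
            break
          }
        }
      }
      if (st == "true_allele") accepted <- c(accepted, v)
      state[i, j] <- st; reason[i, j] <- rs
    }
  }
  # cross-amplicon pass: compare each provisional true call against the
  # variant's typical frequency where it is true
  for (v in rownames(tab$counts)) {
    true_j <- which(state[v, ] == "true_allele")
    if (length(true_j) < 2) next
    med <- stats::median(f[v, true_j])
    low <- true_j[f[v, true_j] < cfg$minor_fraction * med &
                  f[v, true_j] < cfg$minor_absolute]
    if (length(low)) {
      state[v, low] <- "artifact_cross_amplicon"
      reason[v, low] <- sprintf(
        "frequency below %.0f%% of median true frequency %.3f",
        100 * cfg$minor_fraction, med)
    }
  }
  idx <- which(!is.na(state), arr.ind = TRUE)
  status_record(rownames(state)[idx[, 1]], colnames(state)[idx[, 2]],
                state[idx], reason[idx])
}

#' Run the full post-denoising filter chain
#'
#' Order is fixed: amplicon coverage, variant maximum coverage, off-target,
#' per-amplicon frequency, artifact classification. Applying the chain to its
#' own output is a no-op (idempotence).
#'
#' @param tab An [asv_table()].
#' @param references Named character vector of reference sequences, or `NULL`
#'   to skip the off-target step.
#' @param cfg A [filter_config()].
#' @return List with the final `table`, the combined `status` data.frame and
#'   `empty` (TRUE when nothing survived filtering).
#' @export
filter_asv <- function(tab, references = NULL, cfg = filter_config()) {
  s1 <- filter_by_coverage(tab, cfg)
  status <- s1$status
  tab <- s1$table
  if (!is.null(references) && nrow(tab$counts) > 0) {
    s2 <- filter_offtarget(tab, references, cfg)
    status <- rbind(status, s2$status)
    tab <- s2$table
  }
  if (nrow(tab$counts) > 0) {
    s3 <- filter_low_frequency(tab, cfg)
    status <- rbind(status, s3$status)
    tab <- s3$table
  }
  cls <- if (nrow(tab$counts) > 0) classify_artifacts(tab, cfg) else
    empty_status()
  status <- rbind(status, cls)
  list(table = tab, status = status,
       empty = nrow(tab$counts) == 0 || ncol(tab$counts) == 0)
}

#' Aggregate true-allele calls into per-individual MHC genotypes
#'
#' Per sample, the allele set is the union of `true_allele` variants across
#' its amplicons (replicates and primer sets merged). The lineage-C
#' observation status is `"missing"` when the sample retains no `DF2-DR2`
#' amplicon, `"absent"` when that amplicon survived filtering but yielded no
#' lineage-C allele, otherwise `"present"`.
#'
#' @param tab Filtered [asv_table()].
#' @param status Status data.frame from [classify_artifacts()]/[filter_asv()].
#' @param lineage_map Named character vector: variant id -> lineage
#'   (`"A"`, `"B"`, `"C"`).
#' @param samples Optional character vector of sample ids to report even if
#'   all their amplicons were filtered out (status all-missing).
#' @return data.frame of class `mhc_genotypes`: one row per sample with
#'   columns `sample_id`, `ab` and `c` (comma-separated allele ids) and
#'   `c_status`.
#' @export
call_genotypes <- function(tab, status, lineage_map, samples = NULL) {
  stopifnot(inherits(tab, "asv_table"))
  true <- status[status$state == "true_allele", , drop = FALSE]
  ids <- unique(c(samples, tab$meta$sample_id))
  rows <- lapply(ids, function(s) {
    amps <- tab$meta$amplicon_id[tab$meta$sample_id == s]
    alle <- unique(true$variant[true$amplicon %in% amps])
    lin <- lineage_map[alle]
    ab <- sort(alle[!is.na(lin) & lin %in% c("A", "B")])
    cc <- sort(alle[!is.na(lin) & lin == "C"])
    c_amp <- tab$meta$amplicon_id[tab$meta$sample_id == s &
                                  tab$meta$primer_set == "DF2-DR2"]
    c_status <- if (length(cc)) "present" else
      if (length(c_amp) == 0) "missing" else "absent"
    data.frame(sample_id = s, ab = paste(ab, collapse = ","),
               c = paste(cc, collapse = ","), c_status = c_status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mhc_genotypes", "data.frame")
  out
}

#' Congruence of allele calls between replicate amplicons
#'
#' Replicate pairs are amplicons sharing sample and primer set but carrying
#' different replicate tags. Each pair is congruent when the two amplicons
#' yield identical true-allele sets.
#'
#' @param tab Filtered [asv_table()].
#' @param status Status data.frame with `true_allele` states.
#' @return List with `fraction_congruent`, `n_pairs`, and a `discordant`
#'   data.frame listing each discordant pair with the symmetric-difference
#'   alleles.
#' @export
replicate_congruence <- function(tab, status) {
  stopifnot(inherits(tab, "asv_table"))
  m <- tab$meta
  rep_rows <- m[nzchar(m$replicate), , drop = FALSE]
  if (nrow(rep_rows) == 0) stop("no replicate pairs in metadata")
  true <- status[status$state == "true_allele", , drop = FALSE]
  aset <- function(amp) sort(unique(true$variant[true$amplicon == amp]))
  pairs <- list(); disc <- list()
  for (i in seq_len(nrow(rep_rows))) {
    s <- rep_rows$sample_id[i]; p <- rep_rows$primer_set[i]
    primary <- m$amplicon_id[m$sample_id == s & m$primer_set == p &
                             !nzchar(m$replicate)]
    if (length(primary) == 0)
      stop("replicate amplicon ", rep_rows$amplicon_id[i],
           " has no matching primary amplicon")
    a1 <- aset(primary[1]); a2 <- aset(rep_rows$amplicon_id[i])
    key <- paste(s, p)
    pairs[[key]] <- setequal(a1, a2)
    if (!setequal(a1, a2))
      disc[[key]] <- data.frame(
        sample_id = s, primer_set = p,
        alleles = paste(union(setdiff(a1, a2), setdiff(a2, a1)),
                        collapse = ","),
        stringsAsFactors = FALSE)
  }
  list(fraction_congruent = mean(unlist(pairs)),
       n_pairs = length(pairs),
       discordant = if (length(disc)) do.call(rbind, disc) else
         data.frame(sample_id = character(0), primer_set = character(0),
                    alleles = character(0)))
}
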