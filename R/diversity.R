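#' Within-haplotype diversity record
#'
#' For a haplotype with two or more alleles, computes the mean over allele
#' pairs of (i) nucleotide p-distance, (ii) amino-acid p-distance of the
#' translations and (iii) mean per-site Grantham functional distance. A
#' single-allele haplotype is undefined (`defined = FALSE`, metrics `NA`).
#'
#' @param alleles Character vector of allele ids in the haplotype.
#' @param seqs Named character vector of allele nucleotide sequences.
#' @param frame Reading-frame offset (0-2) for translation.
#' @param model A [grantham_model()].
#' @return One-row data.frame: `alleles`, `n_alleles`, `nucl_p`, `aa_p`,
#'   `func_dist`, `defined`.
#' @export
haplotype_diversity <- function(alleles, seqs, frame = 0,
                                model = default_grantham()) {
  missing <- setdiff(alleles, names(seqs))
  if (length(missing))
    stop("no sequence for allele(s): ", paste(missing, collapse = ", "))
  rec <- data.frame(alleles = paste(alleles, collapse = ","),
                    n_alleles = length(alleles),
                    nucl_p = NA_real_, aa_p = NA_real_,
                    func_dist = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  if (length(alleles) < 2) return(rec)
  prs <- utils::combn(alleles, 2, simplify = FALSE)
  np <- ap <- fd <- numeric(0)
  for (p in prs) {
    s1 <- seqs[[p[1]]]; s2 <- seqs[[p[2]]]
    np <- c(np, p_distance(s1, s2, "nt"))
    a1 <- translate_seq(s1, frame); a2 <- translate_seq(s2, frame)
    if (nchar(a1) != nchar(a2))
      stop("translations of ", p[1], " and ", p[2], " differ in length")
    ap <- c(ap, p_distance(a1, a2, "aa"))
    fd <- c(fd, functional_distance(a1, a2, model))
  }
  rec$nucl_p <- mean(np); rec$aa_p <- mean(ap); rec$func_dist <- mean(fd)
  rec$defined <- TRUE
  rec
}

#' Diversity table for a haplotype catalog
#'
#' @param catalog A [build_catalog()] result (or any data.frame with
#'   `hap_id` and comma-separated `alleles`).
#' @param seqs Named character vector of allele sequences.
#' @param frame Reading-frame offset.
#' @param model A [grantham_model()].
#' @return data.frame: one row per haplotype with the three metrics.
#' @export
catalog_diversity <- function(catalog, seqs, frame = 0,
                              model = default_grantham()) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    al <- split_csv(catalog$alleles[i])
    cbind(hap_id = catalog$hap_id[i],
          haplotype_diversity(al, seqs, frame, model))
  })
  do.call(rbind, rows)
}

#' Pearson correlations among the three diversity metrics
#'
#' Computed over records where all three metrics are defined.
#'
#' @param records data.frame with columns `nucl_p`, `aa_p`, `func_dist`
#'   (e.g. from [catalog_diversity()] or [study_haplotypes()]).
#' @return List with matrices `r` and `r2` (3x3) and `n_records`.
#' @export
metric_correlation <- function(records) {
  d <- records[, c("nucl_p", "aa_p", "func_dist")]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 defined records, got ", nrow(d))
  if (any(vapply(d, stats::sd, numeric(1)) == 0))
    stop("a metric is constant across records; correlation undefined")
  r <- stats::cor(d, method = "pearson")
  list(r = r, r2 = r^2, n_records = nrow(d))
}

#' Pairwise alignment identity matrix (e.g. for UTR comparisons)
#'
#' Globally aligns every sequence pair; identity is identical columns over
#' aligned columns, gaps counting as mismatches.
#'
#' @param seqs Named character vector (length >= 2).
#' @return Symmetric matrix of identity proportions (diagonal 1).
#' @export
utr_pairwise_identity <- function(seqs) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(seqs))) stop("empty sequence")
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- alignment_identity(seqs[[i]], seqs[[j]])
  }
  m
}
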