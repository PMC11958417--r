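#' Read a FASTA file of allele or reference sequences
#'
#' @param path FASTA path.
#' @return Named character vector (ids = first word of each header);
#'   duplicate ids are an error. The full headers are kept in the
#'   `"description"` attribute.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  ids <- vapply(strsplit(desc, "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- stats::setNames(as.character(x), ids)
  attr(out, "description") <- stats::setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference panel with lineage-annotated headers
#'
#' Headers carry `lineage=<L>` tokens (e.g. `>Scca-DBB*17 lineage=B`).
#'
#' @param path FASTA path.
#' @return List with `sequences` (named) and `lineages` (named).
#' @export
read_reference_panel <- function(path) {
  seqs <- read_fasta(path)
  desc <- attr(seqs, "description")
  lin <- vapply(desc, function(d) {
    m <- regmatches(d, regexpr("lineage=[A-Za-z]+", d))
    if (length(m) == 0) NA_character_ else sub("lineage=", "", m)
  }, character(1))
  if (any(is.na(lin)))
    stop("reference(s) without lineage= tag: ",
         paste(names(seqs)[is.na(lin)], collapse = ", "))
  attr(seqs, "description") <- NULL
  list(sequences = seqs, lineages = stats::setNames(lin, names(seqs)))
}

#' Read an ASV count table (TSV) plus amplicon metadata (CSV)
#'
#' The TSV has columns `variant_id`, `sequence`, then one integer column per
#' amplicon; the CSV has columns `amplicon_id`, `sample_id`, `primer_set`,
#' `replicate`.
#'
#' @param counts_path,meta_path File paths.
#' @return An [asv_table()].
#' @export
read_asv_tsv <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("variant_id", "sequence") %in% names(df)))
    stop(counts_path, ": needs variant_id and sequence columns")
  if (anyDuplicated(df$variant_id))
    stop(counts_path, ": duplicate variant_id ",
         df$variant_id[duplicated(df$variant_id)][1])
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  cnt <- as.matrix(df[, setdiff(names(df), c("variant_id", "sequence")),
                      drop = FALSE])
  rownames(cnt) <- df$variant_id
  missing_meta <- setdiff(colnames(cnt), meta$amplicon_id)
  if (length(missing_meta))
    stop(meta_path, ": no metadata row for amplicon ",
         paste(missing_meta, collapse = ", "))
  asv_table(cnt, stats::setNames(df$sequence, df$variant_id),
            meta[meta$amplicon_id %in% colnames(cnt), ])
}

#' Write an ASV table to TSV + CSV
#'
#' @param tab An [asv_table()].
#' @param counts_path,meta_path Output paths.
#' @export
write_asv_tsv <- function(tab, counts_path, meta_path) {
  df <- data.frame(variant_id = rownames(tab$counts),
                   sequence = unname(tab$sequences),
                   tab$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(tab$meta, meta_path, row.names = FALSE)
  invisible(counts_path)
}

#' Read/write MHC genotype tables (CSV)
#'
#' Columns `sample_id`, `ab`, `c` (comma-separated allele ids) and
#' `c_status`.
#'
#' @param path CSV path.
#' @return `mhc_genotypes` data.frame.
#' @export
read_mhc_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample_id", "ab", "c", "c_status")
  if (!all(need %in% names(df)))
    stop(path, ": needs columns ", paste(need, collapse = ", "))
  df$ab[is.na(df$ab)] <- ""; df$c[is.na(df$c)] <- ""
  class(df) <- c("mhc_genotypes", "data.frame")
  df
}

#' @rdname read_mhc_genotypes_csv
#' @param genos `mhc_genotypes` data.frame.
#' @export
write_mhc_genotypes_csv <- function(genos, path) {
  utils::write.csv(as.data.frame(genos), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read/write microsatellite genotypes (CSV)
#'
#' Columns `individual_id`, `locus`, `allele1`, `allele2` (blank = missing).
#'
#' @param path CSV path.
#' @return A [microsat_genotypes()] table.
#' @export
read_microsats_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  microsat_genotypes(df)
}

#' @rdname read_microsats_csv
#' @param ms A [microsat_genotypes()] table.
#' @export
write_microsats_csv <- function(ms, path) {
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}

#' Read family definitions (CSV)
#'
#' Columns `family_id`, `mother`, `offspring_id`, `father_id` (blank when
#' the father is unsampled); one row per offspring.
#'
#' @param path CSV path.
#' @return List of [phase_family()]-ready family definitions.
#' @export
read_families_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("family_id", "mother", "offspring_id", "father_id")
  if (!all(need %in% names(df)))
    stop(path, ": needs columns ", paste(need, collapse = ", "))
  df$father_id[is.na(df$father_id)] <- ""
  lapply(split(df, df$family_id), function(d) {
    if (length(unique(d$mother)) != 1)
      stop("family ", d$family_id[1], " has multiple mothers")
    list(family_id = d$family_id[1], mother = d$mother[1],
         offspring = data.frame(offspring_id = d$offspring_id,
                                father_id = d$father_id,
                                stringsAsFactors = FALSE))
  })
}

#' @rdname read_families_csv
#' @param families List of family definitions.
#' @export
write_families_csv <- function(families, path) {
  rows <- lapply(families, function(f)
    data.frame(family_id = f$family_id, mother = f$mother,
               offspring_id = f$offspring$offspring_id,
               father_id = f$offspring$father_id,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
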