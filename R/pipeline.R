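#' Pipeline configuration
#'
#' @param asv_counts,asv_meta,references,microsats,families Input paths
#'   (any may be `NULL` to skip the stage needing it; `genotypes` may be
#'   given directly instead of ASV inputs).
#' @param genotypes Optional path to an MHC genotype CSV (skips filtering).
#' @param out_dir Output directory (created if needed).
#' @param filter A [filter_config()].
#' @param error_rate Parentage genotyping error rate.
#' @param min_offspring Phasing/reporting threshold (default 5).
#' @param frame Reading-frame offset for translations (`NULL` = auto).
#' @param seed Seed recorded in the summary.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(asv_counts = NULL, asv_meta = NULL,
                            references = NULL, microsats = NULL,
                            families = NULL, genotypes = NULL,
                            out_dir = "mhcseg-out",
                            filter = filter_config(), error_rate = 0.01,
                            min_offspring = 5, frame = NULL, seed = 1) {
  stopifnot(min_offspring >= 1)
  for (p in c(asv_counts, asv_meta, references, microsats, families,
              genotypes))
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ASV filtering and genotype calling (when ASV inputs are
#' given), lineage assignment against the reference panel, LOD parentage
#' (when microsatellites are given), per-family haplotype phasing, haplotype
#' catalog and architecture checks, and within-haplotype diversity. Each
#' stage writes its table under `out_dir`; a `summary.json` collects the
#' headline numbers.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()
  refs <- NULL
  if (!is.null(config$references)) {
    panel <- read_reference_panel(config$references)
    refs <- panel$sequences
    lineage_map <- panel$lineages
  } else lineage_map <- NULL

  if (!is.null(config$asv_counts)) {
    tab <- read_asv_tsv(config$asv_counts, config$asv_meta)
    filt <- filter_asv(tab, refs, config$filter)
    write_tsv(filt$status, out("variant_status.tsv"))
    if (filt$empty) stop("no data left after filtering")
    true_ids <- unique(filt$status$variant[filt$status$state ==
                                             "true_allele"])
    if (is.null(lineage_map)) stop("lineage assignment needs references")
    la <- assign_lineages(filt$table$sequences[true_ids], refs,
                          lineage_map)
    vmap <- stats::setNames(la$lineage, la$allele)
    utils::write.csv(la, out("lineage_assignment.csv"), row.names = FALSE)
    genos <- call_genotypes(filt$table, filt$status, vmap)
    res$filter <- filt
    res$lineages <- la
    allele_lineage <- vmap
  } else if (!is.null(config$genotypes)) {
    genos <- read_mhc_genotypes_csv(config$genotypes)
    allele_lineage <- if (!is.null(lineage_map)) lineage_map else
      stop("genotype input needs a reference panel for lineage labels")
  } else stop("either ASV inputs or a genotype CSV is required")
  write_mhc_genotypes_csv(genos, out("mhc_genotypes.csv"))
  res$genotypes <- genos

  families <- NULL
  if (!is.null(config$families)) families <- read_families_csv(config$families)
  if (!is.null(config$microsats) && is.null(families)) {
    ms <- read_microsats_csv(config$microsats)
    ids <- unique(ms$individual_id)
    offspring <- grep("-O", ids, value = TRUE)
    mothers <- setdiff(grep("^M", ids, value = TRUE), offspring)
    fathers <- setdiff(grep("^F", ids, value = TRUE), offspring)
    pa <- assign_families(offspring, mothers, fathers, ms,
                          error_rate = config$error_rate)
    utils::write.csv(pa$results, out("parentage.csv"), row.names = FALSE)
    families <- lapply(split(pa$results[pa$results$status == "assigned", ],
                             pa$results$mother[pa$results$status ==
                                                 "assigned"]),
                       function(d) list(family_id = d$mother[1],
                                        mother = d$mother[1],
                                        offspring = data.frame(
                                          offspring_id = d$offspring,
                                          father_id = d$father,
                                          stringsAsFactors = FALSE)))
    res$parentage <- pa
  }
  if (is.null(families)) stop("no families: give a family CSV or microsats")

  solutions <- lapply(families, function(f) phase_family(f, genos))
  catalog <- build_catalog(solutions, allele_lineage,
                           min_offspring = config$min_offspring)
  write_tsv(as.data.frame(catalog), out("haplotype_catalog.tsv"))
  rec <- count_recombinants(solutions, min_offspring = config$min_offspring)
  write_tsv(rec$parents, out("recombination.tsv"))
  arch <- architecture_checks(genos, allele_lineage)
  res$solutions <- solutions
  res$catalog <- catalog
  res$recombination <- rec
  res$architecture <- arch

  div <- NULL
  if (!is.null(refs)) {
    seqs <- refs
    frame <- if (is.null(config$frame)) auto_frame(seqs) else config$frame
    div <- catalog_diversity(catalog, seqs, frame = frame)
    write_tsv(div, out("haplotype_diversity.tsv"))
    res$diversity <- div
  }
  summary <- list(
    n_samples = nrow(genos),
    n_families = length(families),
    n_haplotypes = nrow(catalog),
    composition_classes = as.list(table(catalog$class)),
    n_recombinant = rec$n_recombinant,
    recombinant_frequency = rec$frequency,
    architecture_violations = nrow(arch$violations),
    metric_r2 = if (!is.null(div) && sum(stats::complete.cases(
      div[, c("nucl_p", "aa_p", "func_dist")])) >= 3)
      as.list(metric_correlation(div)$r2) else NULL,
    seed = config$seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$summary <- summary
  invisible(res)
}
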