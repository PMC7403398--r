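#' Configuration for an end-to-end scan run
#'
#' Bundles inputs and per-stage settings for \code{\link{run_pipeline}}. Input
#' genotypes come either from files (PED/MAP pairs and/or VCFs) or from
#' in-memory \code{genotype_matrix} objects; multiple datasets are merged on
#' their shared variants before scanning. The effective configuration is
#' serialised beside the outputs so a run is reproducible from its report
#' directory alone.
#'
#' @param matrices optional list of \code{genotype_matrix} objects.
#' @param ped,map optional equal-length character vectors of PED/MAP paths.
#' @param vcf optional character vector of VCF paths.
#' @param vcf_filter optional \code{\link{variant_quality_filter}} applied to
#'   VCF inputs.
#' @param population_file optional sample -> population label TSV.
#' @param scan a \code{\link{scan_config}}.
#' @param ld an \code{\link{ld_config}}.
#' @param intensity_files optional named character vector of per-variant
#'   intensity TSVs, names "chrom:pos"; flagged variants with intensities are
#'   re-called and re-tested.
#' @param call_threshold posterior threshold for re-calling.
#' @param out_dir optional output directory; when given, all report tables
#'   are written there.
#' @param seed integer master seed.
#' @export
pipeline_config <- function(matrices = NULL, ped = NULL, map = NULL,
                            vcf = NULL, vcf_filter = NULL,
                            population_file = NULL,
                            scan = scan_config(), ld = ld_config(),
                            intensity_files = NULL, call_threshold = 0.95,
                            out_dir = NULL, seed = 1) {
  if (is.null(matrices) && is.null(ped) && is.null(vcf))
    stop("pipeline validation error: no input datasets configured")
  if (!is.null(ped) && (is.null(map) || length(ped) != length(map)))
    stop("ped and map path vectors must have equal length")
  structure(list(matrices = matrices, ped = ped, map = map, vcf = vcf,
                 vcf_filter = vcf_filter, population_file = population_file,
                 scan = scan, ld = ld, intensity_files = intensity_files,
                 call_threshold = call_threshold, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full candidate-lethal-variant workflow
#'
#' Stages, in order: load and merge the input genotype datasets on their
#' shared variants; scan every variant for a Hardy-Weinberg deficit with
#' absent minor homozygotes; cluster flagged variants into candidate blocks
#' (flagged singletons are reported separately as possible calling errors);
#' re-call any flagged variant for which raw intensities are available and
#' re-test it; shortlist variants linked (r2 / D-prime) to each block's most
#' significant member within the LD window; and summarise the block variants
#' per population. Identical configuration and seed reproduce identical
#' reports; when \code{out_dir} is set, all tables are written there along
#' with the serialised configuration.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return List of class \code{scan_report}: matrix, scan (per-variant
#'   table), blocks, singletons, recall_changes, ld_shortlists (one per
#'   block), population_summary, provenance.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mats <- config$matrices %||% list()
  if (!is.null(config$ped))
    for (k in seq_along(config$ped))
      mats <- c(mats, list(read_plink_text(config$ped[k], config$map[k])))
  if (!is.null(config$vcf))
    for (f in config$vcf)
      mats <- c(mats, list(read_vcf(f, config$vcf_filter)))
  if (length(mats) == 0) stop("no input datasets could be loaded")
  mat <- if (length(mats) > 1) merge_on_common_variants(mats) else mats[[1]]
  if (!is.null(config$population_file)) {
    labs <- read_population_labels(config$population_file)
    mat$population <- labs[intersect(names(labs), mat$samples)]
  }

  scan_res <- scan_deficit(mat, config$scan)
  recall_changes <- data.frame()
  if (!is.null(config$intensity_files)) {
    for (key in names(config$intensity_files)) {
      j <- tryCatch(variant_index(mat, key), error = function(e) NULL)
      if (is.null(j) || !scan_res$flagged[j]) next
      panel <- read_intensity_panel(config$intensity_files[[key]],
                                    mat$variants[j, ])
      rec <- recall_variant(mat, panel, seed = config$seed,
                            call_threshold = config$call_threshold)
      mat <- rec$matrix
      if (nrow(rec$changes)) {
        rec$changes$variant <- key
        recall_changes <- rbind(recall_changes, rec$changes)
      }
    }
    # re-test after re-calling so cleared artifacts drop out
    scan_res <- scan_deficit(mat, config$scan)
  }

  blocks <- cluster_adjacent(scan_res, config$scan)
  in_block <- unique(unlist(lapply(strsplit(blocks$member_idx, ","),
                                   as.integer)))
  singletons <- scan_res[scan_res$flagged &
                           !(seq_len(nrow(scan_res)) %in% in_block), ]

  ld_shortlists <- list()
  pop_summary <- data.frame()
  if (nrow(blocks) > 0) {
    for (b in seq_len(nrow(blocks))) {
      idx <- as.integer(strsplit(blocks$member_idx[b], ",")[[1]])
      anchor <- idx[which.min(scan_res$q_value[idx])]
      ld_shortlists[[as.character(blocks$block_id[b])]] <-
        shortlist_linked(mat, anchor, config$ld)
    }
    all_idx <- sort(unique(unlist(lapply(strsplit(blocks$member_idx, ","),
                                         as.integer))))
    pop_summary <- population_summary(mat, all_idx)
  }

  report <- structure(list(
    matrix = mat, scan = scan_res, blocks = blocks, singletons = singletons,
    recall_changes = recall_changes, ld_shortlists = ld_shortlists,
    population_summary = pop_summary,
    provenance = list(seed = config$seed,
                      n_samples = length(mat$samples),
                      n_variants = nrow(mat$variants),
                      scan = unclass(config$scan),
                      ld = unclass(config$ld),
                      package_version = as.character(
                        utils::packageVersion("lethscan")))),
    class = "scan_report")

  if (!is.null(config$out_dir)) write_scan_report(report, config$out_dir)
  report
}

# write every report table under out_dir (deterministic contents)
write_scan_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(report$scan, file.path(out_dir, "scan.tsv"), "tsv")
  write_report(report$blocks, file.path(out_dir, "blocks.tsv"), "tsv",
               allow_empty = TRUE)
  write_report(report$singletons, file.path(out_dir, "singletons.tsv"),
               "tsv", allow_empty = TRUE)
  if (nrow(report$population_summary))
    write_report(report$population_summary,
                 file.path(out_dir, "table1.tsv"), "tsv")
  if (nrow(report$recall_changes))
    write_report(report$recall_changes,
                 file.path(out_dir, "recall_changes.tsv"), "tsv")
  for (b in names(report$ld_shortlists))
    write_report(report$ld_shortlists[[b]],
                 file.path(out_dir, paste0("linked_block", b, ".tsv")),
                 "tsv", allow_empty = TRUE)
  jsonlite::write_json(report$provenance, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("scan_report:", nrow(x$scan), "variants scanned,",
      sum(x$scan$flagged), "flagged,", nrow(x$blocks),
      "candidate block(s)\n")
  invisible(x)
}

#' Published-table layout of a scan report's candidate blocks
#'
#' One row per population: sample size, then per block SNP the rounded
#' expected minor-homozygote count, the observed genotype class counts and a
#' significance star (raw exact p < 0.05) -- the layout of the published
#' breed-frequency table for the two-SNP candidate haplotype.
#'
#' @param report a \code{scan_report} with at least one block and population
#'   labels, or a data.frame already shaped like
#'   \code{\link{population_summary}} output.
#' @return Wide data.frame keyed by population.
#' @export
format_table1 <- function(report) {
  summ <- if (is.data.frame(report)) report else report$population_summary
  if (is.null(summ) || nrow(summ) == 0) {
    warning("no candidate blocks: empty table")
    return(data.frame(population = character()))
  }
  pops <- unique(summ$population)
  keys <- unique(paste0(summ$chrom, ":", summ$pos))
  out <- data.frame(population = pops, stringsAsFactors = FALSE)
  for (k in keys) {
    sub <- summ[paste0(summ$chrom, ":", summ$pos) == k, ]
    sub <- sub[match(pops, sub$population), ]
    safe <- gsub("[^0-9A-Za-z]", "_", k)
    out[[paste0("n_", safe)]] <- sub$n
    out[[paste0("expected_", safe)]] <- ifelse(
      sub$significant & !is.na(sub$significant),
      paste0(sub$expected_minor_hom_rounded, "*"),
      as.character(sub$expected_minor_hom_rounded))
    out[[paste0("minor_hom_", safe)]] <- sub$n_minor_hom
    out[[paste0("het_", safe)]] <- sub$n_het
    out[[paste0("major_hom_", safe)]] <- sub$n_major_hom
    out[[paste0("het_pct_", safe)]] <- sub$het_pct
  }
  out
}
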