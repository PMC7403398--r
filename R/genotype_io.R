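#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Parses whitespace-delimited PED/MAP files into a \code{\link{genotype_matrix}}.
#' Allele labels per variant are assigned from the alleles observed across
#' samples in stable lexicographic order (\code{allele_A} sorts first);
#' genotype codes count copies of \code{allele_B}. A variant observed with a
#' single allele gets \code{allele_B = NA} and all-zero codes. The PLINK
#' missing-allele code "0" (either allele) yields a missing call.
#'
#' Because PED files carry no reference/alternate orientation, a write/read
#' round trip reproduces a matrix exactly only when its allele labels are
#' already lexicographically oriented.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A \code{genotype_matrix}. The PED family id column is kept as the
#'   population label when it is not constant.
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4) stop("MAP file must have 4 columns (chrom id cM pos)")
  n_var <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6 + 2 * n_var
  bad <- which(vapply(toks, length, 1L) != expected)
  if (length(bad))
    stop("PED/MAP column mismatch: line ", bad[1], " of ", ped_path,
         " has ", length(toks[[bad[1]]]), " fields, expected ", expected)

  fam <- vapply(toks, `[`, "", 1L)
  ids <- vapply(toks, `[`, "", 2L)
  allele_mat <- t(vapply(toks, function(x) x[-(1:6)], character(expected - 6)))
  a1 <- allele_mat[, seq(1, ncol(allele_mat), by = 2), drop = FALSE]
  a2 <- allele_mat[, seq(2, ncol(allele_mat), by = 2), drop = FALSE]

  calls <- matrix(NA_integer_, nrow = length(ids), ncol = n_var)
  allele_A <- allele_B <- rep(NA_character_, n_var)
  for (j in seq_len(n_var)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2)
      stop("triallelic variant ", map[j, 2], ": alleles ",
           paste(obs, collapse = "/"))
    if (length(obs) >= 1) allele_A[j] <- obs[1]
    if (length(obs) == 2) allele_B[j] <- obs[2]
    cj <- (x1 == allele_B[j]) + (x2 == allele_B[j])
    cj[miss] <- NA_integer_
    if (is.na(allele_B[j])) cj[!miss] <- 0L
    calls[, j] <- cj
  }

  variants <- data.frame(chrom = map[, 1], pos = as.integer(map[, 4]),
                         id = map[, 2], allele_A = allele_A,
                         allele_B = allele_B, stringsAsFactors = FALSE)
  population <- NULL
  if (length(unique(fam)) > 1) population <- structure(fam, names = ids)
  genotype_matrix(variants, ids, calls, population)
}

#' Write a genotype matrix to PLINK text files (PED/MAP)
#'
#' @param matrix a \code{genotype_matrix}.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the PED path.
#' @export
write_plink_text <- function(matrix, ped_path, map_path) {
  v <- matrix$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  fam <- if (!is.null(matrix$population))
    unname(matrix$population[matrix$samples]) else matrix$samples
  fam[is.na(fam)] <- "unassigned"
  n <- length(matrix$samples)
  geno_txt <- matrix("0 0", nrow = n, ncol = nrow(v))
  for (j in seq_len(nrow(v))) {
    aa <- paste(v$allele_A[j], v$allele_A[j])
    ab <- paste(v$allele_A[j], v$allele_B[j])
    bb <- paste(v$allele_B[j], v$allele_B[j])
    g <- matrix$calls[, j]
    geno_txt[, j] <- ifelse(is.na(g), "0 0",
                            c(aa, ab, bb)[g + 1L])
  }
  lines <- paste(fam, matrix$samples, 0, 0, 0, -9,
                 apply(geno_txt, 1, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(ped_path)
}

#' Variant quality filter for sequencing-derived VCF records
#'
#' Thresholds are strict: a record is kept only when its mean per-sample
#' filtered depth is strictly greater than \code{min_depth} and its site
#' quality strictly greater than \code{min_qual}.
#'
#' @param min_depth mean FORMAT/DP threshold (default 10).
#' @param min_qual Phred-scaled site QUAL threshold (default 20).
#' @export
variant_quality_filter <- function(min_depth = 10, min_qual = 20) {
  stopifnot(min_depth >= 0, min_qual >= 0)
  structure(list(min_depth = min_depth, min_qual = min_qual),
            class = "variant_quality_filter")
}

#' Read genotypes from a VCF file
#'
#' Loads biallelic records from a VCF (GT field required) into a
#' \code{\link{genotype_matrix}}. Multi-allelic records are skipped with a
#' message. Half calls and "./." become missing. When a
#' \code{\link{variant_quality_filter}} is supplied, records failing either
#' strict threshold are dropped; mean depth is the mean of per-sample
#' FORMAT/DP over samples with a DP value, and records lacking QUAL or DP are
#' dropped under the filter since their quality cannot be verified.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param filter optional \code{variant_quality_filter}.
#' @return A \code{genotype_matrix}; zero surviving records yields an empty
#'   matrix with a warning, not an error.
#' @export
read_vcf <- function(vcf_path, filter = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("unreadable VCF: ",
                                           conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    warning("no records in VCF")
    return(empty_matrix(colnames(vcf@gt)[-1]))
  }
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    message("skipping ", sum(multi), " multi-allelic record(s)")
  keep <- !multi

  if (!is.null(filter)) {
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    dp <- tryCatch(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
      error = function(e) NULL)
    mean_dp <- if (is.null(dp)) rep(NA_real_, nrow(fix))
               else colMeans(t(dp), na.rm = TRUE)  # dp is variants x samples
    pass <- !is.na(qual) & qual > filter$min_qual &
            !is.na(mean_dp) & mean_dp > filter$min_depth
    keep <- keep & pass
  }
  if (!any(keep)) {
    warning("no records survive the quality filter")
    return(empty_matrix(colnames(vcf@gt)[-1]))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  g <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g))
  code[g == "0/0"] <- 0L
  code[g == "0/1" | g == "1/0"] <- 1L
  code[g == "1/1"] <- 2L

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  variants <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         id = ids, allele_A = fix[, "REF"],
                         allele_B = fix[, "ALT"], stringsAsFactors = FALSE)
  genotype_matrix(variants, colnames(gt), t(code))
}

empty_matrix <- function(samples) {
  genotype_matrix(
    data.frame(chrom = character(), pos = integer(), id = character(),
               allele_A = character(), allele_B = character()),
    samples %||% character(),
    matrix(integer(), nrow = length(samples %||% character()), ncol = 0))
}

#' Merge genotype matrices on their shared variants
#'
#' Intersects the variant panels of two or more matrices on (chrom, pos) and
#' concatenates their samples, harmonising each matrix's allele coding to the
#' first matrix's: where a later matrix labels the same two alleles in swapped
#' order its codes are flipped 0<->2. Allele sets that disagree beyond a label
#' swap raise a strand/allele conflict error (palindromic strand flips are not
#' guessed at).
#'
#' @param matrices list of two or more \code{genotype_matrix} objects with
#'   disjoint sample ids.
#' @return A merged \code{genotype_matrix} restricted to the common variants,
#'   with population labels preserved.
#' @export
merge_on_common_variants <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  keys <- lapply(matrices, function(m) paste(m$variants$chrom, m$variants$pos))
  common <- Reduce(intersect, keys)
  if (length(common) == 0)
    stop("merge error: no variants shared by all matrices")
  all_samples <- unlist(lapply(matrices, `[[`, "samples"))
  if (anyDuplicated(all_samples))
    stop("sample ids must be disjoint across matrices")

  ref <- matrices[[1]]
  ref_idx <- match(common, keys[[1]])
  ref_var <- ref$variants[ref_idx, , drop = FALSE]

  call_blocks <- vector("list", length(matrices))
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    idx <- match(common, keys[[k]])
    ck <- m$calls[, idx, drop = FALSE]
    if (k > 1) {
      for (j in seq_along(common)) {
        aA <- m$variants$allele_A[idx[j]]; aB <- m$variants$allele_B[idx[j]]
        rA <- ref_var$allele_A[j]; rB <- ref_var$allele_B[j]
        if (identical(aA, rA) && (is.na(aB) || is.na(rB) || identical(aB, rB))) {
          # same orientation
        } else if (identical(aA, rB) && (is.na(aB) || identical(aB, rA))) {
          ck[, j] <- 2L - ck[, j]  # swapped labels: flip 0<->2
        } else {
          stop("strand/allele conflict at ", ref_var$chrom[j], ":",
               ref_var$pos[j], " ({", rA, ",", rB, "} vs {", aA, ",", aB, "})")
        }
      }
    }
    call_blocks[[k]] <- ck
  }
  calls <- do.call(rbind, call_blocks)

  pops <- unlist(lapply(matrices, function(m) {
    if (is.null(m$population)) structure(rep(NA_character_,
                                             length(m$samples)),
                                         names = m$samples)
    else m$population[m$samples]
  }))
  names(pops) <- all_samples
  if (all(is.na(pops))) pops <- NULL
  genotype_matrix(ref_var, all_samples, calls, pops)
}

#' Write a table of records as TSV or JSON
#'
#' Deterministic report writer: column order is preserved, TSV output is
#' tab-delimited with a header line, JSON output is an array of objects.
#' Identical input always produces byte-identical files.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @param format "tsv" or "json".
#' @param allow_empty write a header-only / empty-array file for zero rows
#'   instead of erroring.
#' @export
write_report <- function(rows, path, format = c("tsv", "json"),
                         allow_empty = FALSE) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0 && !allow_empty)
    stop("refusing to write an empty report (set allow_empty = TRUE)")
  if (format == "tsv") {
    con <- file(path, open = "wb")  # binary mode: stable newlines
    on.exit(close(con))
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read sample -> population labels from a two-column TSV
#'
#' @param path TSV with columns \code{sample_id} and \code{population}
#'   (header optional when exactly two columns).
#' @return Named character vector of labels.
#' @export
read_population_labels <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- any(c("sample_id", "population") %in% first)
  tab <- utils::read.table(path, header = header, sep = "\t",
                           colClasses = "character")
  structure(tab[[2]], names = tab[[1]])
}
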