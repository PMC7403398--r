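#' Construct a genotype matrix
#'
#' The central container of the package: biallelic genotype calls for a set of
#' samples at a set of mapped variants. Calls are coded as the number of copies
#' of \code{allele_B} (0, 1, 2) with \code{NA} for missing. Variants are kept
#' strictly sorted by (chromosome, position); duplicate positions on one
#' chromosome are rejected because a position identifies a variant within one
#' matrix.
#'
#' @param variants data.frame with columns \code{chrom} (character),
#'   \code{pos} (1-based integer position), \code{id} (variant identifier),
#'   \code{allele_A}, \code{allele_B} (allele labels; \code{allele_B} may be
#'   \code{NA} for a variant observed monomorphic in a text format that does
#'   not record the unobserved allele).
#' @param samples character vector of unique sample ids.
#' @param calls integer matrix, samples x variants, entries in
#'   \code{c(0L, 1L, 2L, NA)} counting copies of \code{allele_B}.
#' @param population optional named character vector mapping sample ids to
#'   population / breed labels.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(variants, samples, calls, population = NULL) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "id", "allele_A", "allele_B")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$id <- as.character(variants$id)
  variants$allele_A <- as.character(variants$allele_A)
  variants$allele_B <- as.character(variants$allele_B)
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  bad <- !is.na(variants$allele_B) & variants$allele_A == variants$allele_B
  if (any(bad))
    stop("allele_A must differ from allele_B (variant ",
         variants$id[which(bad)[1]], ")")

  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  calls <- as.matrix(calls)
  if (!all(dim(calls) == c(length(samples), nrow(variants))))
    stop("calls must be a ", length(samples), " x ", nrow(variants), " matrix")
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("calls must be 0, 1, 2 or NA")

  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos): ", key[duplicated(key)][1])
  rownames(variants) <- NULL
  dimnames(calls) <- list(samples, variants$id)

  if (!is.null(population)) {
    population <- structure(as.character(population), names = names(population))
    if (is.null(names(population)) || !all(names(population) %in% samples))
      stop("population labels must be named by sample id")
  }

  structure(list(variants = variants, samples = samples, calls = calls,
                 population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  if (!is.null(x$population))
    cat("  populations:", paste(names(table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# locate a variant by "chrom:pos" string or id; returns column index
variant_index <- function(matrix, what) {
  v <- matrix$variants
  if (grepl(":", what)) {
    parts <- strsplit(what, ":", fixed = TRUE)[[1]]
    i <- which(v$chrom == parts[1] & v$pos == as.integer(parts[2]))
  } else {
    i <- which(v$id == what)
  }
  if (length(i) != 1) stop("variant not found in matrix: ", what)
  i
}

#' Expand genotype class counts into a vector of genotype codes
#'
#' Convenience for building fixtures and Table-1 style matrices from published
#' genotype counts. The minor allele is taken to be \code{allele_B}, so minor
#' homozygotes are coded 2.
#'
#' @param n_minor_hom,n_het,n_major_hom non-negative genotype class counts.
#' @return Integer vector of length \code{n_minor_hom + n_het + n_major_hom}.
#' @export
counts_to_calls <- function(n_minor_hom, n_het, n_major_hom) {
  c(rep(2L, n_minor_hom), rep(1L, n_het), rep(0L, n_major_hom))
}

#' Build a one- or two-variant genotype matrix from per-population counts
#'
#' Takes a table of published genotype class counts (one row per population x
#' variant) and materialises a \code{genotype_matrix} whose tabulation
#' reproduces those counts exactly. Used to re-analyse printed summary tables.
#'
#' @param counts data.frame with columns \code{population}, \code{chrom},
#'   \code{pos}, \code{n_minor_hom}, \code{n_het}, \code{n_major_hom} and
#'   optionally \code{id}.
#' @return A \code{genotype_matrix} with population labels. Each population
#'   must have rows for the same set of variants; per-population sample sizes
#'   may differ across variants, in which case the shortfall at a variant is
#'   encoded as missing calls.
#' @export
matrix_from_counts <- function(counts) {
  stopifnot(all(c("population", "chrom", "pos", "n_minor_hom", "n_het",
                  "n_major_hom") %in% names(counts)))
  counts$key <- paste0(counts$chrom, ":", counts$pos)
  keys <- unique(counts$key)
  pops <- unique(counts$population)
  # per population, number of samples = max variant total
  totals <- with(counts, tapply(n_minor_hom + n_het + n_major_hom,
                                population, max))
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", p), seq_len(totals[[p]]))))
  population <- structure(rep(pops, times = totals[pops]), names = sample_ids)

  calls <- matrix(NA_integer_, nrow = length(sample_ids), ncol = length(keys))
  offset <- c(0, cumsum(totals[pops]))
  for (j in seq_along(keys)) {
    for (k in seq_along(pops)) {
      row <- counts[counts$key == keys[j] & counts$population == pops[k], ]
      if (nrow(row) == 0) next
      g <- counts_to_calls(row$n_minor_hom, row$n_het, row$n_major_hom)
      calls[offset[k] + seq_along(g), j] <- g
    }
  }
  first <- counts[match(keys, counts$key), ]
  variants <- data.frame(chrom = first$chrom, pos = first$pos,
                         id = if ("id" %in% names(first)) first$id else keys,
                         allele_A = "A", allele_B = "B",
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, sample_ids, calls, population)
}
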