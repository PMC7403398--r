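test_that("PED/MAP parsing encodes genotypes against lexicographic alleles", {
  map <- tempfile(fileext = ".map"); ped <- tempfile(fileext = ".ped")
  writeLines("6\tsnp1\t0\t38278097", map)
  writeLines(c("F1 s1 0 0 0 -9 A A",
               "F1 s2 0 0 0 -9 A G",
               "F1 s3 0 0 0 -9 0 0"), ped)
  m <- read_plink_text(ped, map)
  expect_equal(m$variants$allele_A, "A")
  expect_equal(m$variants$allele_B, "G")
  expect_equal(unname(m$calls[, 1]), c(0L, 1L, NA))
  expect_equal(m$variants$pos, 38278097L)
})

test_that("PED format errors name the offending line and triallelic sites", {
  map <- tempfile(fileext = ".map"); ped <- tempfile(fileext = ".ped")
  writeLines(c("1\tv1\t0\t100", "1\tv2\t0\t200"), map)
  writeLines(c("F1 s1 0 0 0 -9 A A C C",
               "F1 s2 0 0 0 -9 A G"), ped)  # line 2 short
  expect_error(read_plink_text(ped, map), "line 2")

  writeLines(c("F1 s1 0 0 0 -9 A A C C",
               "F1 s2 0 0 0 -9 G G C C",
               "F1 s3 0 0 0 -9 T T C C"), ped)
  expect_error(read_plink_text(ped, map), "triallelic")
})

test_that("PLINK text round trip reproduces calls, order and alleles", {
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 10)
  m <- make_matrix(calls, chrom = c("1", "1", "2", "2", "3", "3"))
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_plink_text(m, ped, map)
  m2 <- read_plink_text(ped, map)
  # a fully missing or monomorphic column cannot carry both allele labels in
  # PED text; this fixture keeps every variant polymorphic
  expect_equal(unname(m2$calls), unname(m$calls))
  expect_equal(m2$variants$pos, m$variants$pos)
  expect_equal(m2$variants$allele_A, m$variants$allele_A)
  expect_equal(m2$variants$allele_B, m$variants$allele_B)
})

test_that("VCF quality filter applies strict depth and quality thresholds", {
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_fixture(vcf, c(
    "1\t100\tkeep\tA\tG\t30\t.\t.\tGT:DP\t0/0:15\t0/1:15",
    "1\t200\tdepth10\tA\tG\t30\t.\t.\tGT:DP\t0/0:10\t0/1:10",
    "1\t300\tqual20\tA\tG\t20\t.\t.\tGT:DP\t0/0:15\t0/1:15",
    "1\t400\thalf\tA\tG\t30\t.\t.\tGT:DP\t./.:15\t1/1:15",
    "1\t500\tmulti\tA\tG,T\t90\t.\t.\tGT:DP\t0/1:30\t0/2:30"))
  expect_message(m <- read_vcf(vcf, variant_quality_filter()),
                 "multi-allelic")
  expect_setequal(m$variants$id, c("keep", "half"))
  expect_equal(unname(m$calls[, m$variants$id == "half"]), c(NA, 2L))

  m_all <- suppressMessages(read_vcf(vcf))   # no filter: only multi dropped
  expect_equal(nrow(m_all$variants), 4)

  # nothing survives an impossible filter
  expect_warning(
    suppressMessages(read_vcf(vcf, variant_quality_filter(min_depth = 1e6))),
    "no records survive")
})

test_that("merge intersects variants and harmonizes swapped allele labels", {
  v1 <- data.frame(chrom = "6", pos = c(100L, 200L), id = c("a", "b"),
                   allele_A = c("A", "A"), allele_B = c("G", "C"))
  m1 <- genotype_matrix(v1, c("s1", "s2"),
                        matrix(c(0L, 1L, 2L, 1L), nrow = 2))
  # second matrix shares only pos 100, with alleles swapped (G ref)
  v2 <- data.frame(chrom = "6", pos = c(100L, 300L), id = c("a2", "c"),
                   allele_A = c("G", "T"), allele_B = c("A", "C"))
  m2 <- genotype_matrix(v2, c("s3", "s4"),
                        matrix(c(0L, 2L, 1L, 1L), nrow = 2))
  mg <- merge_on_common_variants(list(m1, m2))
  expect_equal(nrow(mg$variants), 1)
  expect_equal(mg$variants$allele_B, "G")
  # s3 was G/G in m2's coding (0 copies of A) -> 2 copies of G here
  expect_equal(unname(mg$calls[, 1]), c(0L, 1L, 2L, 0L))

  # pooled genotype counts invariant to input order (up to orientation)
  mg2 <- merge_on_common_variants(list(m2, m1))
  expect_equal(sort(unname(table(mg$calls[, 1]))),
               sort(unname(table(2L - mg2$calls[, mg2$variants$pos == 100]))))

  # disjoint panels refuse to merge
  m3 <- genotype_matrix(v2, c("s5", "s6"), matrix(c(0L, 0L, 0L, 0L), 2))
  m4 <- genotype_matrix(
    data.frame(chrom = "1", pos = 1L, id = "z", allele_A = "A",
               allele_B = "T"), "s7", matrix(0L, 1, 1))
  expect_error(merge_on_common_variants(list(m4, m1)), "no variants shared")

  # incompatible allele sets are a conflict, not a guess
  v5 <- v1; v5$allele_B <- c("T", "C")
  m5 <- genotype_matrix(v5, c("s8", "s9"), matrix(c(0L, 1L, 2L, 1L), 2))
  expect_error(merge_on_common_variants(list(m1, m5)), "conflict")
})

test_that("report writer is deterministic and guards empty tables", {
  rows <- data.frame(chrom = "6", pos = 38278097L, p = 0.001)
  f1 <- tempfile(); f2 <- tempfile()
  write_report(rows, f1, "tsv"); write_report(rows, f2, "tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(length(readLines(f1)), 2)  # header + one row

  fj <- tempfile(fileext = ".json")
  write_report(rows, fj, "json")
  expect_equal(jsonlite::read_json(fj)[[1]]$pos, 38278097L)

  expect_error(write_report(rows[0, ], tempfile(), "tsv"), "empty")
  expect_silent(write_report(rows[0, ], tempfile(), "tsv",
                             allow_empty = TRUE))
})
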