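make_trio_files <- function(gt_rows, alts = NULL) {
  ped <- write_ped_lines(tempfile(), c("F1 P1 0 0", "F1 M1 0 0",
                                       "F1 C1 P1 M1"))
  vcf <- write_trio_vcf(tempfile(fileext = ".vcf"),
                        samples = c("P1", "M1", "C1"),
                        gt_rows = gt_rows, alts = alts)
  list(ped = read_pedigree(ped), vcf = vcf)
}

test_that("GT fields convert to minor-allele dosage with orientation", {
  f <- make_trio_files(list(c("0/1", "0/0", "0/1"),      # ALT minor
                            c("1/1", "1/1", "0/1")))     # ALT major -> flip
  gen <- read_genotypes(f$vcf, f$ped)
  expect_equal(unname(gen$dosage["P1", "v1"]), 1L)
  # v2: founder ALT freq = 1 > 0.5, so dosage counts REF
  expect_true(gen$variants$flipped[2L])
  expect_equal(unname(gen$dosage[, "v2"]), c(0L, 0L, 1L))
})

test_that("multi-allelic records are skipped with a warning", {
  f <- make_trio_files(list(c("0/1", "0/0", "0/1"),
                            c("0/1", "0/2", "0/0")),
                       alts = c("G", "G,T"))
  expect_warning(gen <- read_genotypes(f$vcf, f$ped), "multi-allelic")
  expect_equal(nrow(gen$variants), 1L)
})

test_that("no sample overlap with the pedigree is an error", {
  ped <- read_pedigree(write_ped_lines(tempfile(),
                                       c("F1 X1 0 0", "F1 X2 0 0")))
  vcf <- write_trio_vcf(tempfile(), samples = c("A", "B"),
                        gt_rows = list(c("0/0", "0/1")))
  expect_error(read_genotypes(vcf, ped), "no overlap")
})

founder_fixture <- function(founder_dosages) {
  # four founders, one variant with the requested founder dosages
  n <- length(founder_dosages)
  ids <- sprintf("I%d", seq_len(n))
  ped <- read_pedigree(write_ped_lines(tempfile(),
                                       sprintf("F%d %s 0 0", seq_len(n), ids)))
  gt <- c("0/0", "0/1", "1/1")[founder_dosages + 1L]
  gen <- read_genotypes(write_trio_vcf(tempfile(), ids, list(gt)), ped)
  list(ped = ped, gen = gen)
}

test_that("founder MAF follows the allele-count formula", {
  f <- founder_fixture(c(1L, 1L, 1L, 1L))
  expect_equal(unname(minor_allele_frequency(f$gen, f$ped)), 0.5)
  f <- founder_fixture(c(0L, 0L, 1L, 2L))
  expect_equal(unname(minor_allele_frequency(f$gen, f$ped)), 3 / 8)
})

test_that("variant filter excludes below the MAF boundary and monomorphics", {
  # 10 founders; dosages summing to 1 give MAF 0.05 exactly (retained),
  # monomorphic gives MAF 0 (excluded)
  ids <- sprintf("I%d", 1:10)
  ped <- read_pedigree(write_ped_lines(tempfile(),
                                       sprintf("F%d %s 0 0", 1:10, ids)))
  rows <- list(c("0/1", rep("0/0", 9)),   # MAF 0.05
               rep("0/0", 10))            # monomorphic
  gen <- read_genotypes(write_trio_vcf(tempfile(), ids, rows), ped)
  flt <- filter_variants(gen, ped)
  expect_equal(flt$retained, "v1")
  expect_equal(flt$exclusions$reason, "monomorphic")
  # MAF 0.049 < 0.05 is excluded
  maf <- minor_allele_frequency(gen, ped)
  flt2 <- filter_variants(gen, ped, maf_threshold = maf[["v1"]] + 1e-9)
  expect_true("v1" %in% flt2$exclusions$variant_id)
  # idempotence: re-filtering the retained set removes nothing
  gen_kept <- gen
  keep <- gen$variants$variant_id %in% flt$retained
  gen_kept$dosage <- gen$dosage[, keep, drop = FALSE]
  gen_kept$variants <- gen$variants[keep, ]
  expect_equal(filter_variants(gen_kept, ped)$retained, flt$retained)
})

test_that("flipping REF/ALT labels leaves MAF and encodings unchanged", {
  cfg <- sim_config(n_families = 25, n_variants = 5, seed = 99)
  out <- simulate_dataset(cfg, tempfile("ori"))
  ped <- read_pedigree(out$pedigree)
  gen1 <- read_genotypes(out$vcf, ped)

  # complement every GT in the VCF text (0<->1): same data, labels swapped
  txt <- readLines(out$vcf)
  body <- !startsWith(txt, "#")
  txt[body] <- vapply(txt[body], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    gt <- f[-(1:9)]
    gt <- chartr("01", "10", gt)
    f[4:5] <- c("G", "A")
    paste(c(f[1:9], gt), collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  flip_vcf <- tempfile(fileext = ".vcf")
  writeLines(txt, flip_vcf)
  gen2 <- read_genotypes(flip_vcf, ped)

  expect_equal(minor_allele_frequency(gen1, ped),
               minor_allele_frequency(gen2, ped))
  for (v in gen1$variants$variant_id) {
    u1 <- informative_families(v, ped, gen1)
    u2 <- informative_families(v, ped, gen2)
    expect_equal(u1$units, u2$units)
  }
})

test_that("informative families require a heterozygous parent and 21+ for testability", {
  # parents (1,0) informative; (0,2) not; missing parent skipped
  nf <- 25L
  ids <- c(sprintf("P%d", 1:nf), sprintf("M%d", 1:nf), sprintf("C%d", 1:nf))
  ped_lines <- c(sprintf("F%d P%d 0 0", 1:nf, 1:nf),
                 sprintf("F%d M%d 0 0", 1:nf, 1:nf),
                 sprintf("F%d C%d P%d M%d", 1:nf, 1:nf, 1:nf, 1:nf))
  ped <- read_pedigree(write_ped_lines(tempfile(), ped_lines))
  # 21 informative families (fathers het), 4 uninformative (0 x 2)
  fa <- c(rep("0/1", 21), rep("0/0", 4))
  mo <- c(rep("0/0", 21), rep("1/1", 4))
  kid <- c(rep("0/1", 21), rep("0/1", 4))
  gen <- read_genotypes(write_trio_vcf(tempfile(), ids,
                                       list(c(fa, mo, kid))), ped)
  fam <- informative_families("v1", ped, gen)
  expect_equal(fam$n_informative, 21L)
  expect_true(fam$testable)
  expect_true(all(vapply(fam$units, function(u) {
    u$father_dosage == 1L || u$mother_dosage == 1L
  }, TRUE)))
  fam20 <- informative_families("v1", ped, gen, min_informative = 22L)
  expect_false(fam20$testable)
})

test_that("Mendelian-inconsistent offspring are dropped with a warning", {
  ped <- read_pedigree(write_ped_lines(tempfile(), c(
    "F1 P1 0 0", "F1 M1 0 0", "F1 C1 P1 M1", "F1 C2 P1 M1"
  )))
  # parents 1 x 2: child dosage 0 impossible
  gen <- read_genotypes(write_trio_vcf(tempfile(), c("P1", "M1", "C1", "C2"),
                                       list(c("0/1", "1/1", "0/0", "1/1"))),
                        ped)
  expect_warning(fam <- informative_families("v1", ped, gen,
                                             min_informative = 1L),
                 "Mendelian")
  expect_equal(fam$n_mendel_dropped, 1L)
  expect_equal(fam$units[[1L]]$offspring_ids, "C2")
})
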