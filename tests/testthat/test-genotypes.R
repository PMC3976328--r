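vcfHeader <- function(samples) c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", samples), collapse = "\t"))

phenoLines <- function(ids, pop = "POP", sex = "female",
                       pheno = rep(c("case", "control"), length.out = length(ids))) {
  c("sample_id\tpopulation\tsex\tphenotype",
    paste(ids, pop, sex, pheno, sep = "\t"))
}

test_that("all-reference VCF reads as a zero matrix with MAF 0", {
  vcf <- writeLinesTmp(c(vcfHeader(c("a", "b", "c")),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0"), ".vcf")
  ph <- writeLinesTmp(phenoLines(c("a", "b", "c")), ".tsv")
  p <- readPanel(vcf, ph, "vcf")
  expect_equal(unname(genotypes(p)), matrix(0L, 2, 3))
  expect_equal(maf(p, "rs1"), 0)
  expect_equal(maf(p, "rs2"), 0)
})

test_that("VCF write/read round-trips a simulated panel exactly", {
  cfg <- defaultStudyScenario(scale = 0.004, seed = 1)  # ~100 samples, 14 SNPs
  cfg@missingRate <- 0.02
  sim <- simulatePanel(cfg)
  gp <- tempfile(fileext = ".vcf"); pp <- tempfile(fileext = ".tsv")
  writePanel(sim$panel, gp, pp, "vcf")
  back <- readPanel(gp, pp, "vcf")
  expect_identical(dim(back), dim(sim$panel))
  expect_equal(genotypes(back), genotypes(sim$panel))
  expect_identical(unname(rowRanges(back)$minorAllele),
                   unname(rowRanges(sim$panel)$minorAllele))
  expect_identical(colnames(back), colnames(sim$panel))
  expect_identical(as.data.frame(colData(back)), as.data.frame(colData(sim$panel)))
})

test_that("PED/MAP round-trips and encodes missing and het genotypes", {
  geno <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2, byrow = TRUE)
  p <- makePanel(geno, minor = c("G", "T"), major = c("A", "C"))
  ped <- tempfile(fileext = ".ped"); ph <- tempfile(fileext = ".tsv")
  writePanel(p, ped, ph, "plink_text")
  lines <- readLines(ped)
  # het genotype carries both allele characters
  f1 <- strsplit(lines[2], "\t")[[1]]
  expect_setequal(f1[7:8], c("A", "G"))
  # missing genotype written as 0 0
  fmiss <- strsplit(lines[1], "\t")[[1]]
  expect_equal(fmiss[9:10], c("0", "0"))
  back <- readPanel(ped, ph, "plink_text")
  expect_equal(genotypes(back), genotypes(p))
  expect_true(is.na(genotypes(back)[2, 1]))
})

test_that("malformed inputs raise informative errors", {
  vcf <- writeLinesTmp(c(vcfHeader("a"),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0"), ".vcf")
  phBad <- writeLinesTmp(c("sample_id\tpopulation\tsex\tphenotype",
                           "a\tPOP\tfemale\taffected"), ".tsv")
  expect_error(readPanel(vcf, phBad, "vcf"), "binary")
  phDup <- writeLinesTmp(c("sample_id\tpopulation\tsex\tphenotype",
                           "a\tPOP\tfemale\tcase", "a\tPOP\tmale\tcontrol"),
                         ".tsv")
  expect_error(readPanel(vcf, phDup, "vcf"), "[Dd]uplicate")
  vcfDup <- writeLinesTmp(c(vcfHeader("a"),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0",
    "chr1\t200\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0"), ".vcf")
  ph <- writeLinesTmp(phenoLines("a"), ".tsv")
  expect_error(readPanel(vcfDup, ph, "vcf"), "[Dd]uplicate")
})

test_that("MAF is invariant under sample reordering", {
  set.seed(7)
  p <- randomPanel(40, c(0.2, 0.45))
  perm <- sample(ncol(p))
  p2 <- p[, perm]
  for (v in rowRanges(p)$id) {
    expect_equal(maf(p, v), maf(p2, v))
    expect_equal(maf(p, v, "cases"), maf(p2, v, "cases"))
  }
})

test_that("BED intervals convert to 1-based inclusive and back", {
  bed <- writeLinesTmp("chr3\t10\t20\tDNase", ".bed")
  gr <- readBed(bed)
  expect_equal(start(gr), 11)
  expect_equal(end(gr), 20)
  expect_equal(gr$label, "DNase")
  # empty file
  empty <- writeLinesTmp(character(0), ".bed")
  expect_length(readBed(empty), 0)
  # overlapping lines preserved without merging
  bed3 <- writeLinesTmp(c("chr3\t0\t50\tA", "chr3\t10\t60\tB",
                          "chr3\t20\t70\tC"), ".bed")
  gr3 <- readBed(bed3)
  expect_length(gr3, 3)
  expect_equal(gr3$label, c("A", "B", "C"))
  # round-trip through export restores the same 0-based coordinates
  out <- tempfile(fileext = ".bed")
  rtracklayer::export(gr3, out, format = "BED")
  expect_equal(start(readBed(out)), start(gr3))
})
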