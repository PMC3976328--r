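jasparLines <- function(id = "MA0001", counts) {
  c(paste(">", id, "TEST"),
    vapply(1:4, function(r) {
      paste0(c("A", "C", "G", "T")[r], " [ ",
             paste(counts[r, ], collapse = " "), " ]")
    }, character(1)))
}

test_that("JASPAR text parses with pseudo-count and row normalization", {
  counts <- rbind(A = c(10, 0), C = c(0, 10), G = c(0, 0), T = c(0, 0))
  f <- writeLinesTmp(jasparLines(counts = counts), ".pfm")
  pwms <- readPwm(f)
  pwm <- pwms$MA0001
  expect_s4_class(pwm, "PWM")
  expect_equal(nrow(pwm@mat), 2)
  expect_true(all(pwm@mat > 0))
  expect_equal(rowSums(pwm@mat), c(1, 1), ignore_attr = TRUE)
  expect_gt(pwm@mat[1, "A"], 0.99)
})

test_that("a uniform PWM gives zero disruption for any substitution", {
  mat <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- new("PWM", motifId = "unif", mat = mat, background = rep(0.25, 4))
  d <- motifDisruption("ACGTACGTA", 5, "A", "G", pwm)
  expect_equal(d$delta, 0, tolerance = 1e-12)
})

test_that("a single-position PWM reproduces the closed-form log ratio", {
  mat <- matrix(c(0.01, 0.01, 0.97, 0.01), 1,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- new("PWM", motifId = "one", mat = mat, background = rep(0.25, 4))
  d <- motifDisruption("AGA", 2, "G", "A", pwm)
  expect_equal(d$bestRefScore, log2(0.97 / 0.25), tolerance = 1e-12)
  # reverse strand of alt A reads T (0.01), same as forward A: max is log2(.01/.25)
  expect_equal(d$bestAltScore, log2(0.01 / 0.25), tolerance = 1e-12)
  expect_lt(d$delta, 0)
})

test_that("best-placement scores match the brute-force enumeration oracle", {
  set.seed(61)
  for (rep in 1:10) {
    counts <- matrix(rexp(4 * 8), 4, 8)
    f <- writeLinesTmp(jasparLines(counts = round(counts * 50)), ".pfm")
    pwm <- readPwm(f)[[1]]
    ctx <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                 collapse = "")
    ref <- substr(ctx, 11, 11)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    d <- motifDisruption(ctx, 11, ref, alt, pwm)
    expect_equal(d$bestRefScore, oracleMotifBest(ctx, 11, ref, pwm),
                 tolerance = 1e-9)
    expect_equal(d$bestAltScore, oracleMotifBest(ctx, 11, alt, pwm),
                 tolerance = 1e-9)
  }
})

test_that("motif scoring is strand symmetric", {
  set.seed(67)
  counts <- matrix(rexp(4 * 6), 4, 6)
  f <- writeLinesTmp(jasparLines(counts = round(counts * 30 + 1)), ".pfm")
  pwm <- readPwm(f)[[1]]
  ctx <- "ATGGCAGTCAAGTCCAT"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcCtx <- paste(rev(unname(comp[strsplit(ctx, "")[[1]]])), collapse = "")
  i <- 9; ri <- nchar(ctx) - i + 1
  ref <- substr(ctx, i, i); alt <- "G"
  d1 <- motifDisruption(ctx, i, ref, alt, pwm)
  d2 <- motifDisruption(rcCtx, ri, comp[ref], comp[alt], pwm)
  expect_equal(d1$bestRefScore, d2$bestRefScore, tolerance = 1e-9)
  expect_equal(d1$delta, d2$delta, tolerance = 1e-9)
})

test_that("context must carry the reference allele and cover the motif", {
  mat <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- new("PWM", motifId = "u", mat = mat, background = rep(0.25, 4))
  expect_error(motifDisruption("AAAA", 1, "G", "A", pwm), "reference")
  expect_error(motifDisruption("AAA", 1, "A", "G", pwm), "shorter")
})

test_that("LD proxies include the anchor and exclude independent SNPs", {
  set.seed(71)
  g <- rbinom(2000, 2L, 0.4)
  indep <- rbinom(2000, 2L, 0.4)
  p <- makePanel(rbind(g, g, indep))
  pr <- ldProxies(p, "snp1", r2Min = 0.9)
  expect_setequal(pr$snp, c("snp1", "snp2"))
  expect_equal(pr$r2, c(1, 1), tolerance = 1e-9)
})

test_that("SNP-feature overlap respects the 1-based inclusive convention", {
  snps <- GRanges("chr3", IRanges(c(10, 15), c(10, 15)), id = c("a", "b"),
                  majorAllele = "A", minorAllele = "G")
  bed <- writeLinesTmp("chr3\t10\t20\tX", ".bed")
  feats <- readBed(bed)
  hits <- overlapFeatures(snps, feats)
  expect_equal(hits$snp, "b")  # pos 10 is outside BED [10, 20) -> internal 11..20
})

test_that("overlap equals brute-force pair enumeration", {
  set.seed(73)
  pos <- sample(1:100, 7)
  snps <- GRanges("chr1", IRanges(pos, pos), id = paste0("s", 1:7),
                  majorAllele = "A", minorAllele = "G")
  st <- sample(1:90, 9); en <- st + sample(5:20, 9, replace = TRUE)
  feats <- GRanges("chr1", IRanges(st, en))
  feats$label <- paste0("F", 1:9)
  hits <- overlapFeatures(snps, feats)
  brute <- sum(outer(pos, seq_len(9),
                     function(p, j) p >= st[j] & p <= en[j]))
  expect_equal(nrow(hits), brute)
  # chromosome mismatch warns
  snpsX <- GRanges("chrX", IRanges(5, 5), id = "x",
                   majorAllele = "A", minorAllele = "G")
  expect_warning(overlapFeatures(snpsX, feats), "chrX")
})

test_that("prioritization is a deterministic total order", {
  snps <- GRanges("chr1", IRanges(c(10, 20, 30), c(10, 20, 30)),
                  id = c("a", "b", "c"), majorAllele = "A", minorAllele = "G")
  hits <- data.frame(
    snp = c("b", "b", "b", "a"),
    pos = c(20, 20, 20, 10),
    label = c("DNase:GM12878", "H3K27ac:B", "TF:PU1", "DNase:K562"))
  r <- prioritizeSnps(snps, hits)
  expect_equal(r$snp[1], "b")
  expect_equal(r$n_classes, c(3L, 1L, 0L))
  # empty annotation: rank by position
  r0 <- prioritizeSnps(snps, hits[0, ])
  expect_equal(r0$snp, c("a", "b", "c"))
  # permuting inputs never changes the order
  r2 <- prioritizeSnps(rev(snps), hits[sample(nrow(hits)), ])
  expect_equal(r2$snp, r$snp)
})
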