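test_that("a SNP is in complete LD with itself", {
  set.seed(2)
  g <- rbinom(60, 2L, 0.4)
  p <- makePanel(rbind(g, g))
  ld <- ldPair(p, "snp1", "snp2")
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_equal(ld$dPrime, 1, tolerance = 1e-9)
})

test_that("LD from unambiguous genotypes matches direct haplotype counting", {
  # 6 individuals, no double heterozygotes: phase is certain
  ga <- c(0L, 0L, 2L, 2L, 1L, 0L)
  gb <- c(0L, 2L, 2L, 2L, 0L, 1L)
  p <- makePanel(rbind(ga, gb))
  ld <- ldPair(p, "snp1", "snp2")
  # direct counts: each individual's haplotype pair is determined
  h <- rbind(c(0,0),c(0,0), c(0,1),c(0,1), c(1,1),c(1,1), c(1,1),c(1,1),
             c(1,0),c(0,0), c(0,0),c(0,1))
  pAB <- mean(h[,1] & h[,2]); pA <- mean(h[,1]); pB <- mean(h[,2])
  d <- pAB - pA * pB
  expect_equal(ld$d, d, tolerance = 1e-8)
  expect_equal(ld$r2, d^2 / (pA*(1-pA)*pB*(1-pB)), tolerance = 1e-8)
})

test_that("independent SNPs show near-zero r2 at large n", {
  set.seed(31)
  p <- randomPanel(50000, c(0.3, 0.4))
  ld <- ldPair(p, "snp1", "snp2")
  expect_lt(ld$r2, 0.001)
})

test_that("monomorphic input is rejected", {
  p <- makePanel(rbind(rep(0L, 20), rbinom(20, 2L, 0.5)))
  expect_error(ldPair(p, "snp1", "snp2"), "monomorphic")
})

test_that("phasing homozygous individuals is exact and degenerate", {
  geno <- rbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 2L, 0L), c(2L, 0L, 2L, 0L))
  p <- makePanel(geno)
  hs <- phaseEM(p, freqFloor = 0)
  expect_equal(sum(hapFreq(hs) > 1e-9), length(unique(apply(geno/2, 2, paste, collapse=""))))
  # every individual's dosage is integral (no phase ambiguity)
  expect_true(all(abs(hapDosage(hs) - round(hapDosage(hs))) < 1e-9))
  expect_equal(unname(rowSums(hapDosage(hs))), rep(2, 4))
})

test_that("EM frequencies match the exhaustive per-individual oracle", {
  set.seed(13)
  for (rep in 1:5) {
    m <- sample(2:4, 1)
    G <- t(vapply(seq_len(m), function(i) rbinom(30, 2L, runif(1, 0.2, 0.7)),
                  integer(30)))
    p <- makePanel(G)
    hs <- phaseEM(p, freqFloor = 0, tol = 1e-12)
    oracle <- oracleEM(G)
    got <- hapFreq(hs)
    # align oracle names (0/1 strings) to allele strings
    key <- vapply(names(oracle), function(s) {
      b <- as.integer(strsplit(s, "")[[1]])
      paste(ifelse(b == 1, "G", "A"), collapse = "")
    }, character(1))
    names(oracle) <- key
    for (h in names(got))
      expect_equal(unname(got[h]), unname(oracle[h]), tolerance = 1e-6)
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(17)
  G <- t(vapply(1:4, function(i) rbinom(40, 2L, 0.4), integer(40)))
  p <- makePanel(G)
  m <- nrow(G)
  H <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1]
  colnames(H) <- NULL
  pAll <- rowMeans(G) / 2
  f <- apply(H, 1, function(h) prod(ifelse(h == 1, pAll, 1 - pAll)))
  patterns <- lapply(seq_len(ncol(G)), function(i) G[, i])
  fit <- haplofine:::emIterate(H, patterns, rep(1, length(patterns)), f,
                               tol = 1e-12, maxit = 500)
  expect_true(all(diff(fit$llTrace) > -1e-9))
})

test_that("phasing with missing genotypes marginalizes correctly", {
  set.seed(23)
  G <- t(vapply(1:3, function(i) rbinom(40, 2L, 0.4), integer(40)))
  G[1, 3] <- NA; G[2, 7] <- NA
  p <- makePanel(G)
  hs <- phaseEM(p, freqFloor = 0, tol = 1e-12)
  oracle <- oracleEM(G)
  key <- vapply(names(oracle), function(s) {
    b <- as.integer(strsplit(s, "")[[1]])
    paste(ifelse(b == 1, "G", "A"), collapse = "")
  }, character(1))
  names(oracle) <- key
  for (h in haplotypes(hs))
    expect_equal(unname(hapFreq(hs)[h]), unname(oracle[h]), tolerance = 1e-6)
  # an all-missing individual gets NA dosages
  G2 <- G; G2[, 5] <- NA
  hs2 <- phaseEM(makePanel(G2), freqFloor = 0)
  expect_true(all(is.na(hapDosage(hs2)[5, ])))
  expect_false(anyNA(hapDosage(hs2)[-5, ]))
})

test_that("progressive phasing recovers pool haplotype frequencies at depth", {
  cfg <- defaultStudyScenario(scale = 0.18, seed = 5)  # ~4500 samples pooled
  sim <- simulatePanel(cfg)
  hs <- phaseEM(sim$panel, freqFloor = 0.01)
  tr <- sim$truth
  fTrue <- mean(c(tr$hap1, tr$hap2) == "CCGATCTGGCGCAT")
  expect_lt(abs(unname(hapFreq(hs)["CCGATCTGGCGCAT"]) - fTrue), 0.01)
  expect_equal(sum(hapFreq(hs)), 1, tolerance = 1e-9)
  # dosage mass conservation
  expect_equal(unname(rowSums(hapDosage(hs))), rep(2, ncol(sim$panel)),
               tolerance = 1e-6)
})

test_that("oversized windows are refused", {
  G <- matrix(rbinom(26 * 10, 2, 0.5), nrow = 26)
  expect_error(phaseEM(makePanel(G)), "split")
})

test_that("blocks: a single haplotype pool gives one block over all SNPs", {
  cfg <- defaultStudyScenario(scale = 0.05, seed = 9)
  sim <- simulatePanel(cfg)
  blocks <- buildBlocks(sim$panel, "rs2030519")
  expect_length(blocks, 1)
  expect_equal(nsnp(blocks[[1]]), 14)
  expect_equal(start(blockInterval(blocks[[1]])), 188116907)
  expect_equal(end(blockInterval(blocks[[1]])), 188121019)
})

test_that("blocks: two SNPs in perfect LD form one 2-SNP block", {
  set.seed(41)
  g <- rbinom(500, 2L, 0.4)
  p <- makePanel(rbind(g, g))
  blocks <- buildBlocks(p, "snp1", windowBp = 10000)
  expect_length(blocks, 1)
  expect_equal(nsnp(blocks[[1]]), 2)
})

test_that("blocks: independent LD groups are recovered separately", {
  set.seed(43)
  n <- 800
  gA <- rbinom(n, 2L, 0.5); gB <- rbinom(n, 2L, 0.5)
  geno <- rbind(gA, gA, gA, gB, gB, gB)
  p <- makePanel(geno, pos = c(100, 200, 300, 5100, 5200, 5300))
  blocks <- buildBlocks(p, "snp1", windowBp = 50000)
  expect_length(blocks, 2)
  expect_equal(vapply(blocks, nsnp, integer(1)), c(3L, 3L))
  expect_equal(start(blockInterval(blocks[[1]])), 100)
  expect_equal(start(blockInterval(blocks[[2]])), 5100)
})
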