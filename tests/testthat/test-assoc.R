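test_that("maf counts minor alleles over non-missing genotypes", {
  p <- makePanel(matrix(c(0L, 1L, 2L), 1), phenotype = c("case", "case", "control"))
  expect_equal(maf(p, "snp1"), 0.5)
  p0 <- makePanel(matrix(0L, 1, 4))
  expect_equal(maf(p0, "snp1"), 0)
  pna <- makePanel(matrix(c(2L, NA, NA, NA), 1),
                   phenotype = c("control", "case", "case", "case"))
  expect_equal(maf(pna, "snp1", "controls"), 1)
  expect_error(maf(pna, "snp1", "cases"), "non-missing")
})

test_that("exact HWE test matches direct enumeration", {
  # perfect equilibrium at MAF 0.5
  expect_equal(hweExact(25, 50, 25), 1, tolerance = 1e-9)
  # extreme heterozygote deficit
  p <- hweExact(50, 0, 50)
  expect_equal(p, oracleHwe(50, 0, 50), tolerance = 1e-12)
  expect_lt(p, 1e-25)
  # tiny table with a two-term tail
  expect_equal(hweExact(3, 1, 0), oracleHwe(3, 1, 0), tolerance = 1e-12)
  # monomorphic convention
  expect_equal(hweExact(10, 0, 0), 1)
  # random tables up to n = 200
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    q <- runif(1, 0.05, 0.5)
    g <- sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    expect_equal(hweExact(sum(g == 0), sum(g == 1), sum(g == 2)),
                 oracleHwe(sum(g == 0), sum(g == 1), sum(g == 2)),
                 tolerance = 1e-12)
  }
})

test_that("qcFilter drops low-MAF and HWE-violating variants only", {
  set.seed(1)
  n <- 400
  good <- t(vapply(1:3, function(i) rbinom(n, 2L, 0.3), integer(n)))
  mono <- matrix(0L, 1, n)                       # MAF 0 -> dropped
  hweBad <- matrix(sample(c(0L, 2L), n, replace = TRUE), 1)  # no hets -> dropped
  p <- makePanel(rbind(good, mono, hweBad))
  filt <- qcFilter(p, mafMin = 0.01, hweMinP = 1e-4)
  expect_identical(rowRanges(filt)$id, paste0("snp", 1:3))
  # vacuous thresholds keep everything
  expect_equal(nrow(qcFilter(p, 0, 0)), 5)
})

test_that("crude OR is reciprocal and 1 at equal frequencies", {
  expect_equal(crudeOR(0.3, 0.4) * crudeOR(0.4, 0.3), 1, tolerance = 1e-12)
  for (x in c(0.05, 0.25, 0.5)) expect_equal(crudeOR(x, x), 1)
  expect_warning(o <- crudeOR(0, 0.2), "boundary")
  expect_equal(o, 0)
})

test_that("logistic fit on homozygote-only panels equals the closed-form 2x2 OR", {
  set.seed(9)
  for (rep in 1:5) {
    nc <- 300; nt <- 300
    gc <- sample(c(0L, 2L), nc, replace = TRUE, prob = c(0.4, 0.6))
    gt <- sample(c(0L, 2L), nt, replace = TRUE, prob = c(0.55, 0.45))
    p <- makePanel(matrix(c(gc, gt), 1),
                   phenotype = rep(c("case", "control"), c(nc, nt)))
    r <- logisticAssoc(p, "snp1", covariates = character(0))
    tableOR <- crudeOR(r$maf_cases, r$maf_controls)
    # per-allele beta doubles on the hom-only contrast
    expect_equal(exp(2 * r$beta), tableOR, tolerance = 1e-6)
  }
})

test_that("p-values are invariant under case/control swap with sign flip", {
  set.seed(4)
  p <- randomPanel(300, c(0.3, 0.45))
  r1 <- logisticAssoc(p, "snp1")
  cd <- colData(p)
  cd$phenotype <- ifelse(cd$phenotype == "case", "control", "case")
  p2 <- CohortPanel(genotypes(p), rowRanges(p), cd)
  r2 <- logisticAssoc(p2, "snp1")
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-9)
})

test_that("null logistic associations are calibrated (|beta| < 3 se)", {
  set.seed(3)
  cover <- vapply(1:100, function(i) {
    p <- randomPanel(200, 0.3)
    r <- logisticAssoc(p, "snp1")
    abs(r$beta) < 3 * r$se
  }, logical(1))
  expect_gte(mean(cover), 0.95)
})

test_that("joint fit on identical populations equals the single-population fit", {
  set.seed(8)
  p <- randomPanel(400, c(0.4, 0.2), population = rep("A", 400))
  cdB <- colData(p); cdB$population <- "B"
  rownames(cdB) <- paste0("b_", rownames(cdB))
  gB <- genotypes(p); colnames(gB) <- rownames(cdB)
  pB <- CohortPanel(gB, rowRanges(p), cdB)
  joint <- jointMeta(list(A = p, B = pB))
  single <- logisticAssoc(p, "snp1", covariates = "sex")
  expect_equal(joint$beta[joint$snp == "snp1"], single$beta, tolerance = 1e-6)
  # opposite effects of equal size cancel
  cdC <- colData(p)
  cdC$phenotype <- ifelse(cdC$phenotype == "case", "control", "case")
  rownames(cdC) <- paste0("c_", rownames(cdC))
  gC <- genotypes(p); colnames(gC) <- rownames(cdC)
  pC <- CohortPanel(gC, rowRanges(p), cdC)
  flip <- jointMeta(list(A = p, C = pC))
  expect_lt(abs(flip$beta[flip$snp == "snp1"]), 1e-6)
})

test_that("inverse-variance combination agrees with pooling for identical cohorts", {
  set.seed(12)
  p1 <- randomPanel(500, 0.35, population = rep("A", 500))
  r1 <- logisticAssoc(p1, "snp1")
  m <- metaInverseVariance(c(r1$beta, r1$beta), c(r1$se, r1$se))
  expect_equal(m$beta, r1$beta, tolerance = 1e-9)
  expect_equal(m$se, r1$se / sqrt(2), tolerance = 1e-9)
})

test_that("conditioning on a monomorphic SNP changes nothing", {
  set.seed(5)
  geno <- rbind(rbinom(300, 2L, 0.3), rep(0L, 300))
  p <- makePanel(geno, population = rep("A", 300))
  un <- jointMeta(list(A = p))
  cond <- conditionalScan(list(A = p), "snp2")
  expect_equal(cond$beta[cond$snp == "snp1"], un$beta[un$snp == "snp1"],
               tolerance = 1e-9)
})

test_that("conditioning on a perfect proxy flags the test SNP collinear", {
  set.seed(6)
  g <- rbinom(300, 2L, 0.4)
  p <- makePanel(rbind(g, g), population = rep("A", 300))
  cond <- conditionalScan(list(A = p), "snp2")
  expect_identical(cond$status[cond$snp == "snp1"], "collinear")
  expect_true(is.na(cond$p[cond$snp == "snp1"]))
})

test_that("complete separation is flagged rather than reported", {
  g <- c(rep(2L, 30), rep(0L, 30))
  p <- makePanel(matrix(g, 1), phenotype = rep(c("case", "control"), each = 30))
  r <- logisticAssoc(p, "snp1", covariates = character(0))
  expect_identical(r$status, "separation")
  expect_true(is.na(r$p))
})

test_that("an independent second signal survives conditioning on the first", {
  set.seed(21)
  n <- 3000
  g1 <- rbinom(n, 2L, 0.4); g2 <- rbinom(n, 2L, 0.4)
  eta <- -1 + 0.5 * g1 + 0.5 * g2
  y <- rbinom(n, 1L, plogis(eta))
  p <- makePanel(rbind(g1, g2), phenotype = ifelse(y == 1, "case", "control"),
                 population = rep("A", n))
  cond <- conditionalScan(list(A = p), "snp1")
  expect_lt(cond$p[cond$snp == "snp2"], 1e-6)
})
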