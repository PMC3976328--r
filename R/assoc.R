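CI_MULT <- 1.959964  # 97.5% normal quantile, fixed for reproducibility

resolveVariant <- function(panel, variant) {
  id <- if (is.character(variant)) variant else variant$id
  i <- match(id, rowRanges(panel)$id)
  if (is.na(i)) stop("variant not in panel: ", id)
  i
}

#' Minor-allele frequency in a sample stratum
#'
#' Minor-allele count divided by twice the number of non-missing genotypes,
#' in all samples, cases only, or controls only. Because the minor allele is
#' fixed by the pooled panel, stratified values can exceed 0.5 and are
#' reported unclamped.
#'
#' @param panel a [CohortPanel-class].
#' @param variant variant id (or a `GRanges` row with `id`).
#' @param stratum "all", "cases" or "controls".
#' @return frequency in `[0, 1]`.
#' @export
maf <- function(panel, variant, stratum = c("all", "cases", "controls")) {
  stratum <- match.arg(stratum)
  g <- genotypes(panel)[resolveVariant(panel, variant), ]
  g <- switch(stratum,
    all = g,
    cases = g[colData(panel)$phenotype == "case"],
    controls = g[colData(panel)$phenotype == "control"])
  n <- sum(!is.na(g))
  if (n == 0) stop("no non-missing genotypes in stratum '", stratum, "'")
  sum(g, na.rm = TRUE) / (2 * n)
}

# exact HWE probabilities for every heterozygote count compatible with the
# allele counts (Levene/Haldane distribution), via the standard recurrence
hweHetDistribution <- function(nAB, nA, nB) {
  n <- (nA + nB) / 2
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- rare * (2 * n - rare) / (2 * n)
  mid <- hets[which.min(abs(hets - mid))]
  i0 <- match(mid, hets)
  probs[i0] <- 1
  if (i0 > 1) for (k in seq(i0 - 1, 1)) {
    h <- hets[k + 1]  # going down: P(h-2) = P(h) * h*(h-1) / ((R-h+2)(C-h+2)) with
    homR <- (rare - h) / 2; homC <- n - h - homR
    probs[k] <- probs[k + 1] * h * (h - 1) / (4 * (homR + 1) * (homC + 1))
  }
  if (i0 < length(hets)) for (k in seq(i0 + 1, length(hets))) {
    h <- hets[k - 1]
    homR <- (rare - h) / 2; homC <- n - h - homR
    probs[k] <- probs[k - 1] * 4 * homR * homC / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  list(hets = hets, probs = probs)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts no more likely
#' than the observed one. Monomorphic sites return p = 1 by convention.
#'
#' `hweExact` works from genotype counts; `hweExactPanel` is the panel
#' wrapper (typically on the control stratum, as used by [qcFilter()]).
#'
#' @param nHomMajor,nHet,nHomMinor genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hweExact <- function(nHomMajor, nHet, nHomMinor) {
  stopifnot(nHomMajor >= 0, nHet >= 0, nHomMinor >= 0)
  if (nHomMajor + nHet + nHomMinor == 0) stop("no genotypes")
  nA <- 2 * nHomMajor + nHet
  nB <- 2 * nHomMinor + nHet
  if (nA == 0 || nB == 0) return(1)
  d <- hweHetDistribution(nHet, nA, nB)
  pObs <- d$probs[match(nHet, d$hets)]
  min(1, sum(d$probs[d$probs <= pObs * (1 + 1e-12)]))
}

#' @rdname hweExact
#' @param panel a [CohortPanel-class].
#' @param variant variant id.
#' @param stratum "all", "cases" or "controls".
#' @export
hweExactPanel <- function(panel, variant, stratum = c("controls", "cases", "all")) {
  stratum <- match.arg(stratum)
  g <- genotypes(panel)[resolveVariant(panel, variant), ]
  if (stratum != "all")
    g <- g[colData(panel)$phenotype == sub("s$", "", stratum)]
  g <- g[!is.na(g)]
  if (!length(g)) stop("no non-missing genotypes in stratum '", stratum, "'")
  hweExact(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Variant quality-control filter
#'
#' Retains variants with pooled MAF above `mafMin` and control-stratum exact
#' HWE p-value above `hweMinP` (both strict inequalities; a threshold of 0
#' disables that filter). Variant order is preserved.
#'
#' @param panel a [CohortPanel-class].
#' @param mafMin MAF threshold (default 0.01).
#' @param hweMinP HWE p-value threshold (default 1e-4).
#' @return Filtered [CohortPanel-class].
#' @export
qcFilter <- function(panel, mafMin = 0.01, hweMinP = 1e-4) {
  G <- genotypes(panel)
  n <- rowSums(!is.na(G))
  fr <- rowSums(G, na.rm = TRUE) / (2 * pmax(n, 1L))
  folded <- pmin(fr, 1 - fr)  # MAF proper, robust to population-split coding
  okM <- if (mafMin <= 0) rep(TRUE, nrow(G)) else folded > mafMin
  okH <- rep(TRUE, nrow(G))
  if (hweMinP > 0) {
    Gc <- G[, colData(panel)$phenotype == "control", drop = FALSE]
    okH <- apply(Gc, 1, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(TRUE)
      hweExact(sum(g == 0), sum(g == 1), sum(g == 2)) > hweMinP
    })
  }
  panel[okM & okH, ]
}

#' Crude (allelic) odds ratio from stratified frequencies
#'
#' `(p1/(1-p1)) / (p0/(1-p0))` for case frequency `p1` and control frequency
#' `p0`. Boundary frequencies (0 or 1) yield 0/Inf with a warning.
#'
#' @param mafCases,mafControls allele frequencies.
#' @return odds ratio (vectorized).
#' @export
crudeOR <- function(mafCases, mafControls) {
  if (any(mafCases %in% c(0, 1)) || any(mafControls %in% c(0, 1)))
    warning("boundary frequency: odds ratio is 0 or infinite")
  (mafCases / (1 - mafCases)) / (mafControls / (1 - mafControls))
}

# design matrix pieces shared by the single-SNP and haplotype models
covariateFrame <- function(panel, covariates, conditionOn = NULL) {
  cd <- colData(panel)
  df <- data.frame(row.names = colnames(panel))
  df$y <- as.integer(cd$phenotype == "case")
  if ("sex" %in% covariates) {
    sx <- ifelse(cd$sex == "unknown", NA_real_, as.numeric(cd$sex == "female"))
    df$sex <- sx
  }
  if ("population" %in% covariates) {
    # reference category: alphabetically first label
    df$population <- factor(cd$population, levels = sort(unique(cd$population)))
  }
  for (v in conditionOn)
    df[[paste0("cond_", v)]] <- genotypes(panel)[resolveVariant(panel, v), ]
  df
}

fitLogistic <- function(df, testCol) {
  covs <- setdiff(names(df), c("y", testCol))
  covs <- covs[vapply(covs, function(cl) {
    x <- df[[cl]]
    if (is.factor(x)) nlevels(droplevels(x[!is.na(x)])) > 1
    else stats::var(as.numeric(x), na.rm = TRUE) > 0
  }, logical(1))]
  form <- stats::reformulate(c(testCol, covs), response = "y")
  df <- df[stats::complete.cases(df[, c("y", testCol, covs), drop = FALSE]), ,
           drop = FALSE]
  if (length(unique(df$y)) < 2)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, status = "degenerate"))
  fit <- suppressWarnings(stats::glm(
    form, data = df, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  co <- stats::coef(summary(fit))
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  # an aliased conditioning dosage means the test SNP is collinear with a
  # lead SNP (r2 = 1): the fit silently kept the test effect, so flag it
  if (is.na(stats::coef(fit)[testCol]) || any(grepl("^cond_", aliased)))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, status = "collinear"))
  beta <- co[testCol, "Estimate"]; se <- co[testCol, "Std. Error"]
  status <- "ok"
  if (!fit$converged || abs(beta) > 15 || se > 100) {
    # (quasi-)separation: diverging estimate, Wald test meaningless
    return(list(beta = beta, se = se, p = NA_real_, status = "separation"))
  }
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)), status = status)
}

# precomputed pieces shared by every per-variant fit on one panel
panelContext <- function(panel, covariates, conditionOn = NULL) {
  list(G = genotypes(panel), rr = rowRanges(panel), cd = colData(panel),
       df0 = covariateFrame(panel, covariates, conditionOn))
}

assocOne <- function(ctx, i) {
  df <- ctx$df0
  df$dosage <- ctx$G[i, ]
  fit <- fitLogistic(df, "dosage")
  g <- ctx$G[i, ]
  case <- ctx$cd$phenotype == "case"
  mafOf <- function(x) {
    nn <- sum(!is.na(x))
    if (nn == 0) NA_real_ else sum(x, na.rm = TRUE) / (2 * nn)
  }
  rr <- ctx$rr[i]
  data.frame(
    snp = rr$id, chrom = as.character(seqnames(rr)), pos = start(rr),
    minor = rr$minorAllele, major = rr$majorAllele,
    n_cases = sum(case), n_controls = sum(!case),
    maf_all = mafOf(g), maf_cases = mafOf(g[case]),
    maf_controls = mafOf(g[!case]),
    beta = fit$beta, se = fit$se, or = exp(fit$beta),
    ci_lo = exp(fit$beta - CI_MULT * fit$se),
    ci_hi = exp(fit$beta + CI_MULT * fit$se),
    p = fit$p, status = fit$status, row.names = NULL)
}

#' Per-variant case/control logistic association
#'
#' Fits `case ~ minor-allele dosage (+ covariates)` by maximum likelihood
#' (IRLS; convergence at log-likelihood change < 1e-8 or 50 iterations) with
#' additive 0/1/2 coding and reports the Wald z-test. Samples with a missing
#' genotype or covariate are dropped (pairwise deletion); sex is a 0/1
#' covariate with `unknown` treated as missing; the population covariate
#' enters as indicator variables with the alphabetically first label as
#' reference. Separation is flagged (`status = "separation"`, p = NA), as is
#' a test dosage collinear with the conditioning covariates
#' (`status = "collinear"`).
#'
#' @param panel a [CohortPanel-class].
#' @param variant variant id to test.
#' @param covariates subset of `c("sex", "population")`.
#' @param conditionOn ids of variants whose dosages enter as covariates.
#' @return One-row data.frame with effect estimate, OR with 95% CI, Wald p,
#'   stratified MAFs and a status flag.
#' @export
logisticAssoc <- function(panel, variant, covariates = "sex",
                          conditionOn = NULL) {
  i <- resolveVariant(panel, variant)
  assocOne(panelContext(panel, covariates, conditionOn), i)
}

#' Association scan over all variants of a panel
#'
#' @inheritParams logisticAssoc
#' @return data.frame with one row per variant ([logisticAssoc()] columns).
#' @export
assocScan <- function(panel, covariates = "sex", conditionOn = NULL) {
  ctx <- panelContext(panel, covariates, conditionOn)
  ids <- setdiff(rowRanges(panel)$id, conditionOn)
  do.call(rbind, lapply(match(ids, ctx$rr$id), function(i) assocOne(ctx, i)))
}

#' Pooled multi-population ("mega") association
#'
#' Joint logistic fit on the pooled samples with sex and population-indicator
#' covariates — the usual implementation of a multi-cohort "meta-analysis"
#' with country of origin as covariate. A variant absent from a population
#' simply lacks that population's samples for its test; the populations used
#' are recorded per variant.
#'
#' @param panels named list of per-population [CohortPanel-class] objects.
#' @param covariates covariates for the pooled fit (default sex +
#'   population).
#' @param conditionOn ids of variants whose pooled dosages enter as
#'   covariates (conditional analysis).
#' @return data.frame, one row per variant in the union of the panels,
#'   with a `populations` column.
#' @export
jointMeta <- function(panels, covariates = c("sex", "population"),
                      conditionOn = NULL) {
  stopifnot(length(panels) >= 1)
  if (is.null(names(panels))) names(panels) <- paste0("pop", seq_along(panels))
  allIds <- unique(unlist(lapply(panels, function(p) rowRanges(p)$id)))
  shared <- Reduce(intersect, lapply(panels, function(p) rowRanges(p)$id))
  testIds <- setdiff(allIds, conditionOn)
  res <- NULL
  common <- intersect(testIds, shared)
  if (length(common) && all(conditionOn %in% shared)) {
    pooled <- poolPanels(panels, union(common, conditionOn))
    ctx <- panelContext(pooled, covariates, conditionOn)
    res <- do.call(rbind, lapply(match(common, ctx$rr$id), function(i)
      assocOne(ctx, i)))
    res$populations <- paste(names(panels), collapse = ",")
  }
  # variants missing from some population: pool only the panels that have them
  rest <- setdiff(testIds, common)
  if (length(rest)) {
    extra <- lapply(rest, function(v) {
      has <- vapply(panels, function(p) v %in% rowRanges(p)$id, logical(1))
      condOk <- vapply(panels, function(p)
        all(conditionOn %in% rowRanges(p)$id), logical(1))
      use <- panels[has & condOk]
      pooled <- poolPanels(use, c(v, conditionOn))
      row <- logisticAssoc(pooled, v, covariates, conditionOn)
      row$populations <- paste(names(use), collapse = ",")
      row
    })
    res <- rbind(res, do.call(rbind, extra))
  }
  res[order(res$p), ]
}

# pool per-population panels on a shared variant subset; minor-allele coding
# is re-harmonized to the pooled sample
poolPanels <- function(panels, ids) {
  parts <- lapply(panels, function(p) p[match(ids, rowRanges(p)$id), ])
  base <- rowRanges(parts[[1]])
  genos <- lapply(parts, function(p) {
    g <- genotypes(p)
    rr <- rowRanges(p)
    flip <- rr$minorAllele != base$minorAllele
    if (any(flip)) {
      if (any(rr$minorAllele[flip] != base$majorAllele[flip]))
        stop("allele mismatch across populations for ",
             paste(ids[flip][rr$minorAllele[flip] != base$majorAllele[flip]],
                   collapse = ", "))
      g[flip, ] <- 2L - g[flip, , drop = FALSE]
    }
    g
  })
  geno <- do.call(cbind, genos)
  samples <- do.call(rbind, lapply(parts, colData))
  harmonizeMinor(CohortPanel(geno, base, samples))
}

# re-derive the pooled minor allele: less frequent allele, ties broken by
# the alphabetically later allele
harmonizeMinor <- function(panel) {
  g <- genotypes(panel)
  fr <- rowSums(g, na.rm = TRUE) / (2 * pmax(rowSums(!is.na(g)), 1L))
  rr <- rowRanges(panel)
  flip <- fr > 0.5 | (fr == 0.5 & rr$minorAllele < rr$majorAllele)
  if (!any(flip)) return(panel)
  g[flip, ] <- 2L - g[flip, , drop = FALSE]
  tmp <- rr$minorAllele[flip]
  rr$minorAllele[flip] <- rr$majorAllele[flip]
  rr$majorAllele[flip] <- tmp
  CohortPanel(g, rr, colData(panel))
}

#' Conditional association scan
#'
#' [jointMeta()] with the dosage of one or more lead variants added as
#' covariates; iterate by growing `conditionOn` with the successive top
#' SNPs (stepwise conditional analysis). Variants collinear with the
#' conditioning dosage are flagged (`status = "collinear"`, p = NA).
#'
#' @param panels named list of per-population [CohortPanel-class] objects.
#' @param conditionOn character vector of lead variant ids.
#' @param covariates covariates for the pooled fit.
#' @return data.frame over the remaining variants, sorted by p.
#' @export
conditionalScan <- function(panels, conditionOn,
                            covariates = c("sex", "population")) {
  jointMeta(panels, covariates, conditionOn = conditionOn)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Secondary combiner for cross-checking the pooled regression: combines
#' per-population log-OR estimates with inverse-variance weights.
#'
#' @param betas per-population log-OR estimates.
#' @param ses their standard errors.
#' @return list with `beta`, `se`, `or`, `ci95`, `p`.
#' @export
metaInverseVariance <- function(betas, ses) {
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  w <- 1 / ses[ok]^2
  beta <- sum(w * betas[ok]) / sum(w)
  se <- sqrt(1 / sum(w))
  list(beta = beta, se = se, or = exp(beta),
       ci95 = exp(beta + c(-1, 1) * CI_MULT * se),
       p = 2 * stats::pnorm(-abs(beta / se)))
}
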