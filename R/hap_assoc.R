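hapStratFreq <- function(panel, snpIds, haplotypes, stratum, freqFloor) {
  sub <- panel[, colData(panel)$phenotype == stratum]
  hs <- phaseEM(sub, snpIds, freqFloor = freqFloor)
  f <- hapFreq(hs)[haplotypes]
  f[is.na(f)] <- 0
  unname(f)
}

#' Haplotype logistic regression (one-vs-rest)
#'
#' Tests each haplotype whose frequency reaches `freqFloor` one-vs-rest by
#' logistic regression of case status on the haplotype's expected dosage
#' (posterior expected copy count from the phase posteriors) plus
#' covariates. Case/control haplotype frequencies are re-estimated by
#' running the EM within each stratum, mirroring how stratified frequencies
#' are usually reported.
#'
#' @param panel the [CohortPanel-class] the haplotypes were phased from.
#' @param haps a [HaplotypeSet-class] from [phaseEM()].
#' @param covariates subset of `c("sex", "population")`.
#' @param freqFloor minimum overall frequency for a haplotype to be tested.
#' @param population label recorded in the result rows.
#' @param stratFreq recompute case/control frequencies by stratified EM
#'   (set `FALSE` to skip the two extra EM runs).
#' @return data.frame, one row per tested haplotype, sorted by p:
#'   haplotype, freq_all, freq_cases, freq_controls, beta, se, or, ci, p,
#'   status, population.
#' @export
hapLogistic <- function(panel, haps, covariates = "sex", freqFloor = 0.01,
                        population = "all", stratFreq = TRUE) {
  test <- which(haps@freq >= freqFloor)
  if (!length(test)) return(hapAssocEmpty())
  snpIds <- haps@snps$id
  fCase <- fCtl <- rep(NA_real_, length(test))
  if (stratFreq) {
    fCase <- hapStratFreq(panel, snpIds, haps@haplotypes[test], "case", freqFloor)
    fCtl <- hapStratFreq(panel, snpIds, haps@haplotypes[test], "control", freqFloor)
  }
  df0 <- covariateFrame(panel, covariates)
  rows <- lapply(seq_along(test), function(t) {
    k <- test[t]
    df <- df0
    df$dosage <- haps@dosage[, k]
    fit <- fitLogistic(df, "dosage")
    data.frame(haplotype = haps@haplotypes[k], freq_all = haps@freq[k],
               freq_cases = fCase[t], freq_controls = fCtl[t],
               beta = fit$beta, se = fit$se, or = exp(fit$beta),
               ci_lo = exp(fit$beta - CI_MULT * fit$se),
               ci_hi = exp(fit$beta + CI_MULT * fit$se),
               p = fit$p, status = fit$status, population = population,
               row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res[order(res$p), ]
}

hapAssocEmpty <- function() {
  data.frame(haplotype = character(), freq_all = numeric(),
             freq_cases = numeric(), freq_controls = numeric(),
             beta = numeric(), se = numeric(), or = numeric(),
             ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
             status = character(), population = character())
}

#' Joint multi-population haplotype association
#'
#' Phases each population separately over the same SNP window (haplotype
#' frequencies are population-specific), matches haplotypes by allele
#' string, and fits one pooled logistic regression per haplotype on the
#' concatenated expected dosages with sex and population-indicator
#' covariates. Overall and stratified frequencies are sample-size-weighted
#' averages of the per-population EM frequencies.
#'
#' @param panels named list of per-population [CohortPanel-class] objects.
#' @param snpIds window SNP ids (must be genotyped in every panel).
#' @param covariates covariates for the pooled fit.
#' @param freqFloor minimum pooled frequency for a haplotype to be tested.
#' @return data.frame as in [hapLogistic()], `population = "meta"`.
#' @export
hapLogisticJoint <- function(panels, snpIds,
                             covariates = c("sex", "population"),
                             freqFloor = 0.01) {
  stopifnot(length(panels) >= 1)
  sets <- lapply(panels, phaseEM, snpIds = snpIds, freqFloor = freqFloor)
  allHaps <- sort(unique(unlist(lapply(sets, haplotypes))))
  ns <- vapply(panels, ncol, integer(1))
  wts <- ns / sum(ns)
  fMat <- vapply(sets, function(s) {
    f <- hapFreq(s)[allHaps]; f[is.na(f)] <- 0; unname(f)
  }, numeric(length(allHaps)))
  fMat <- matrix(fMat, nrow = length(allHaps))
  fAll <- drop(fMat %*% wts)
  strat <- function(stratum) {
    per <- vapply(seq_along(panels), function(i) {
      f <- hapStratFreq(panels[[i]], snpIds, allHaps, stratum, freqFloor)
      f
    }, numeric(length(allHaps)))
    per <- matrix(per, nrow = length(allHaps))
    w <- vapply(panels, function(p) sum(colData(p)$phenotype == stratum),
                numeric(1))
    drop(per %*% (w / sum(w)))
  }
  fCase <- strat("case"); fCtl <- strat("control")
  dosage <- do.call(rbind, lapply(sets, function(s) {
    d <- matrix(0, nrow(s@dosage), length(allHaps),
                dimnames = list(rownames(s@dosage), allHaps))
    d[, haplotypes(s)] <- s@dosage
    d[apply(is.na(s@dosage), 1, any), ] <- NA
    d
  }))
  pooled <- do.call(rbind, lapply(panels, colData))
  df0 <- data.frame(row.names = rownames(pooled))
  df0$y <- as.integer(pooled$phenotype == "case")
  if ("sex" %in% covariates)
    df0$sex <- ifelse(pooled$sex == "unknown", NA_real_,
                      as.numeric(pooled$sex == "female"))
  if ("population" %in% covariates)
    df0$population <- factor(pooled$population,
                             levels = sort(unique(pooled$population)))
  test <- which(fAll >= freqFloor)
  if (!length(test)) return(hapAssocEmpty())
  rows <- lapply(test, function(k) {
    df <- df0
    df$dosage <- dosage[, k]
    fit <- fitLogistic(df, "dosage")
    data.frame(haplotype = allHaps[k], freq_all = fAll[k],
               freq_cases = fCase[k], freq_controls = fCtl[k],
               beta = fit$beta, se = fit$se, or = exp(fit$beta),
               ci_lo = exp(fit$beta - CI_MULT * fit$se),
               ci_hi = exp(fit$beta + CI_MULT * fit$se),
               p = fit$p, status = fit$status, population = "meta",
               row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res[order(res$p), ]
}

#' Most-associated haplotype per population
#'
#' Selects the minimum-p haplotype (and its block) for each population.
#' Ties are broken by larger |log OR|, then lexicographically by allele
#' string, so the winner is deterministic.
#'
#' @param results named list (per population) of [hapLogistic()] results;
#'   each may carry multiple blocks' rows if a `block` list-column or
#'   separate `blocks` argument is supplied.
#' @param blocks optional named list mapping each population to the
#'   [HaplotypeBlock-class] its results came from (single block per
#'   population), or a list of lists parallel to stacked results.
#' @return named list per population: `list(block = , result = )` where
#'   `result` is the winning row.
#' @export
topHaplotype <- function(results, blocks = NULL) {
  out <- lapply(names(results), function(lab) {
    res <- results[[lab]]
    if (!nrow(res)) stop("no tested haplotypes for population ", lab)
    ord <- order(res$p, -abs(res$beta), res$haplotype)
    win <- res[ord[1], , drop = FALSE]
    blk <- blocks[[lab]]
    if (is.list(blk) && !methods::is(blk, "HaplotypeBlock"))
      blk <- blk[[win$block_index %||% 1]]
    list(block = blk, result = win)
  })
  names(out) <- names(results)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
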