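#' Two-locus LD statistics by EM
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes by EM (double heterozygotes split between the two possible
#' phases by the current estimates; convergence when the largest frequency
#' change is < 1e-10), then reports `d = pAB - pA*pB`, `d_prime = d`
#' normalized by its maximum attainable magnitude given the allele margins
#' (signed), and `r2 = d^2 / (pA*pa*pB*pb)`. Individuals missing either
#' genotype are excluded pairwise.
#'
#' @param panel a [CohortPanel-class].
#' @param variantA,variantB variant ids (both must be polymorphic).
#' @return list with `r2`, `dPrime`, `d`, `pA`, `pB` and `hapFreq` (minor-
#'   minor, minor-major, major-minor, major-major).
#' @export
ldPair <- function(panel, variantA, variantB) {
  ia <- resolveVariant(panel, variantA)
  ib <- resolveVariant(panel, variantB)
  g <- genotypes(panel)
  ldPairCore(g[ia, ], g[ib, ])
}

ldPairCore <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic variant; LD undefined")
  # genotype table counts n[ga+1, gb+1]
  n <- table(factor(ga, levels = 0:2), factor(gb, levels = 0:2))
  N <- sum(n)
  # haplotype freqs: f11 (minor at both), f10, f01, f00
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  for (it in seq_len(1000)) {
    # unambiguous haplotype counts from the nine genotype cells
    c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
    c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
    c01 <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
    c00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
    dh <- n[2, 2]  # double heterozygotes: phase unknown
    w <- f[1] * f[4] / (f[1] * f[4] + f[2] * f[3])
    if (!is.finite(w)) w <- 0.5
    new <- c(c11 + dh * w, c10 + dh * (1 - w),
             c01 + dh * (1 - w), c00 + dh * w) / (2 * N)
    if (max(abs(new - f)) < 1e-10) { f <- new; break }
    f <- new
  }
  d <- f[1] - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dPrime <- if (dmax == 0) 0 else d / dmax
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(r2 = unname(r2), dPrime = unname(dPrime), d = unname(d),
       pA = unname(pA), pB = unname(pB),
       hapFreq = stats::setNames(unname(f), c("mm", "mM", "Mm", "MM")))
}

# profile-likelihood bracket for |D'|: likelihood of the genotype table as a
# function of |D'| at the EM allele margins, flat prior, 0.05/0.95 quantiles
dPrimeCICore <- function(ga, gb, grid = seq(0, 1, by = 0.005)) {
  ld <- ldPairCore(ga, gb)
  pA <- ld$pA; pB <- ld$pB
  sgn <- if (ld$d >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  ok <- !is.na(ga) & !is.na(gb)
  n <- table(factor(ga[ok], levels = 0:2), factor(gb[ok], levels = 0:2))
  d <- sgn * grid * dmax
  f11 <- pmax(pA * pB + d, 1e-12)
  f10 <- pmax(pA * (1 - pB) - d, 1e-12)
  f01 <- pmax((1 - pA) * pB - d, 1e-12)
  f00 <- pmax((1 - pA) * (1 - pB) + d, 1e-12)
  # genotype cell probabilities under random pairing (rows: minor count at A)
  lg <- function(x) log(pmax(x, 1e-300))
  ll <- n[1, 1] * lg(f00^2)        + n[1, 2] * lg(2 * f00 * f01) +
        n[1, 3] * lg(f01^2)        + n[2, 1] * lg(2 * f00 * f10) +
        n[2, 2] * lg(2 * (f00 * f11 + f01 * f10)) +
        n[2, 3] * lg(2 * f01 * f11) + n[3, 1] * lg(f10^2) +
        n[3, 2] * lg(2 * f10 * f11) + n[3, 3] * lg(f11^2)
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  c(low = grid[min(which(cum >= 0.05))], high = grid[min(which(cum >= 0.95))])
}

dPrimeCI <- function(panel, variantA, variantB, grid = seq(0, 1, by = 0.005)) {
  g <- genotypes(panel)
  dPrimeCICore(g[resolveVariant(panel, variantA), ],
               g[resolveVariant(panel, variantB), ], grid)
}

# ---- multi-locus EM phasing ----------------------------------------------

# pair enumeration for one genotype pattern against the candidate haplotypes
compatiblePairs <- function(H, g) {
  nm <- which(!is.na(g))
  if (!length(nm)) return(NULL)
  S <- H[, nm, drop = FALSE]
  gg <- g[nm]
  code <- apply(S, 1, paste, collapse = "")
  # haplotypes usable as one member of the pair
  first <- which(apply(S, 1, function(h) all(gg - h >= 0 & gg - h <= 1)))
  if (!length(first)) return(NULL)
  res_i <- integer(0); res_j <- integer(0)
  for (i in first) {
    target <- paste(gg - S[i, ], collapse = "")
    js <- which(code == target)
    js <- js[js >= i]
    if (length(js)) { res_i <- c(res_i, rep(i, length(js))); res_j <- c(res_j, js) }
  }
  if (!length(res_i)) return(NULL)
  cbind(i = res_i, j = res_j)
}

emIterate <- function(H, patterns, counts, f, tol, maxit) {
  K <- nrow(H)
  pairs <- lapply(patterns, function(g) compatiblePairs(H, g))
  bad <- vapply(pairs, is.null, logical(1)) &
    vapply(patterns, function(g) any(!is.na(g)), logical(1))
  if (any(bad))
    stop("genotype pattern incompatible with candidate haplotypes ",
         "(frequency floor pruned a required haplotype)")
  ll <- -Inf; it <- 0L; llTrace <- numeric(0)
  repeat {
    it <- it + 1L
    num <- numeric(K); llNew <- 0; Nin <- 0
    post <- vector("list", length(patterns))
    for (q in seq_along(patterns)) {
      pr <- pairs[[q]]
      if (is.null(pr)) next
      w <- f[pr[, 1]] * f[pr[, 2]] * ifelse(pr[, 1] == pr[, 2], 1, 2)
      s <- sum(w)
      if (s <= 0) { w <- rep(1 / length(w), length(w)); s <- 1e-300 }
      po <- w / sum(w)
      post[[q]] <- po
      llNew <- llNew + counts[q] * log(s)
      inc <- counts[q] * po
      num <- num + vapply(seq_len(K), function(k)
        sum(inc * ((pr[, 1] == k) + (pr[, 2] == k))), numeric(1))
      Nin <- Nin + counts[q]
    }
    fNew <- num / (2 * Nin)
    delta <- max(abs(fNew - f))
    f <- fNew
    llTrace <- c(llTrace, llNew)
    if (delta < tol || it >= maxit) {
      return(list(f = f, logLik = llNew, niter = it, pairs = pairs,
                  post = post, llTrace = llTrace))
    }
    ll <- llNew
  }
}

#' EM haplotype phasing over a SNP window
#'
#' Estimates haplotype frequencies and per-individual phase posteriors from
#' unphased genotypes by EM. Initialization is deterministic (product of
#' single-SNP allele frequencies). For small windows the EM runs over all
#' `2^m` haplotypes; larger windows are phased progressively — SNPs are
#' appended one at a time, each candidate haplotype splitting in two,
#' with haplotypes below `freqFloor` pruned between iterations and the
#' remaining mass renormalized — followed by a full EM pass to convergence.
#' With `freqFloor = 0` no pruning occurs and the result equals the
#' exhaustive EM.
#'
#' Individuals with every window genotype missing are excluded from the
#' posteriors (their dosage rows are `NA`).
#'
#' @param panel a [CohortPanel-class].
#' @param snpIds ids of the window SNPs (at most 25).
#' @param freqFloor pruning threshold between iterations (default 0.01).
#' @param tol EM convergence tolerance on the largest frequency change.
#' @param maxit maximum EM iterations for the final pass.
#' @return A [HaplotypeSet-class]; haplotypes sorted by decreasing
#'   frequency, ties broken lexicographically.
#' @export
phaseEM <- function(panel, snpIds = rowRanges(panel)$id, freqFloor = 0.01,
                    tol = 1e-10, maxit = 2000) {
  if (length(snpIds) > 25)
    stop("window of ", length(snpIds),
         " SNPs exceeds the enumeration guard (25); split the window")
  idx <- vapply(snpIds, function(v) resolveVariant(panel, v), integer(1))
  rr <- rowRanges(panel)[idx]
  o <- order(start(rr))
  idx <- idx[o]; rr <- rr[o]
  m <- length(idx)
  G <- genotypes(panel)[idx, , drop = FALSE]
  key <- apply(G, 2, function(g) paste(ifelse(is.na(g), "?", g), collapse = ""))
  patIdx <- match(key, unique(key))
  upat <- unique(key)
  patterns <- lapply(strsplit(upat, ""), function(s)
    suppressWarnings(as.integer(ifelse(s == "?", NA, s))))
  counts <- as.numeric(table(factor(patIdx, levels = seq_along(upat))))
  informative <- vapply(patterns, function(g) any(!is.na(g)), logical(1))
  counts[!informative] <- 0
  pAll <- rowMeans(G, na.rm = TRUE) / 2  # minor-allele freq per window SNP

  exhaustive <- m <= 8
  if (exhaustive) {
    H <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
    colnames(H) <- NULL
    f <- apply(H, 1, function(h) prod(ifelse(h == 1, pAll, 1 - pAll)))
    fit <- emIterate(H, patterns, counts, f, tol, maxit)
    H <- H[, , drop = FALSE]
  } else {
    H <- matrix(0:1, ncol = 1)
    f <- c(1 - pAll[1], pAll[1])
    for (s in 2:m) {
      H <- rbind(cbind(H, 0L), cbind(H, 1L))
      f <- c(f * (1 - pAll[s]), f * pAll[s])
      sub <- lapply(patterns, function(g) g[seq_len(s)])
      fit <- emIterate(H, sub, counts, f, tol = 1e-4, maxit = 50)
      f <- fit$f
      if (freqFloor > 0 && s < m) {
        keep <- f >= freqFloor
        if (!any(keep)) keep <- f == max(f)
        H <- H[keep, , drop = FALSE]
        f <- f[keep] / sum(f[keep])
      }
    }
    fit <- emIterate(H, patterns, counts, f, tol, maxit)
  }
  f <- fit$f
  keep <- if (freqFloor > 0) f >= min(freqFloor, max(f)) else f > 1e-9
  H <- H[keep, , drop = FALSE]
  f <- f[keep] / sum(f[keep])
  fit <- emIterate(H, patterns, counts, f, tol, maxit)
  f <- fit$f

  hapStr <- apply(H, 1, function(h)
    paste(ifelse(h == 1, rr$minorAllele, rr$majorAllele), collapse = ""))
  o2 <- order(-f, hapStr)
  H <- H[o2, , drop = FALSE]; f <- f[o2]; hapStr <- hapStr[o2]
  # pair posteriors/dosages recomputed on the final ordering
  fit <- emIterate(H, patterns, counts, f, tol = Inf, maxit = 1)
  K <- length(f)
  dosage <- matrix(NA_real_, ncol(panel), K,
                   dimnames = list(colnames(panel), hapStr))
  patDos <- matrix(NA_real_, length(patterns), K)
  for (q in seq_along(patterns)) {
    pr <- fit$pairs[[q]]; po <- fit$post[[q]]
    if (is.null(pr) || !informative[q]) next
    patDos[q, ] <- vapply(seq_len(K), function(k)
      sum(po * ((pr[, 1] == k) + (pr[, 2] == k))), numeric(1))
  }
  dosage[] <- patDos[patIdx, ]
  new("HaplotypeSet", snps = rr,
      haplotypes = hapStr, freq = unname(fit$f), dosage = dosage,
      sampleInfo = colData(panel),
      posteriors = list(patterns = upat, pairs = fit$pairs, post = fit$post,
                        patternOf = patIdx),
      logLik = fit$logLik, niter = fit$niter)
}

#' Confidence-interval haplotype blocks
#'
#' Partitions the SNPs within `windowBp` centered on an anchor SNP into
#' haplotype blocks by the confidence-interval (Gabriel-style) method: a
#' pair is in strong LD when the likelihood-profile bounds on |D'| satisfy
#' lower >= `ciLow` (0.70) and upper >= `ciHigh` (0.98); a pair shows strong
#' evidence of recombination when its upper bound < 0.90; other pairs are
#' uninformative. A candidate span is accepted when its outermost pair is in
#' strong LD and at least `strongFrac` (95%) of its informative pairs are
#' strong; candidates are taken greedily by decreasing bp length without
#' overlap.
#'
#' @param panel a [CohortPanel-class].
#' @param anchor anchor variant id.
#' @param windowBp full window width in bp centered on the anchor
#'   (default 250000).
#' @param ciLow,ciHigh,recombHigh,strongFrac method thresholds.
#' @return list of [HaplotypeBlock-class], sorted by position.
#' @export
buildBlocks <- function(panel, anchor, windowBp = 250000,
                        ciLow = 0.70, ciHigh = 0.98, recombHigh = 0.90,
                        strongFrac = 0.95) {
  ia <- resolveVariant(panel, anchor)
  rr <- rowRanges(panel)
  center <- start(rr)[ia]
  inWin <- which(abs(start(rr) - center) <= windowBp / 2 &
                 as.character(seqnames(rr)) == as.character(seqnames(rr))[ia])
  if (!length(inWin)) return(list())
  inWin <- inWin[order(start(rr)[inWin])]
  G <- genotypes(panel)
  poly <- vapply(inWin, function(i) {
    frq <- mean(G[i, ], na.rm = TRUE) / 2
    is.finite(frq) && frq > 0 && frq < 1
  }, logical(1))
  inWin <- inWin[poly]
  m <- length(inWin)
  if (m == 0) return(list())
  if (m == 1) {
    gr <- rr[inWin]
    return(list(new("HaplotypeBlock",
                    interval = GRanges(seqnames(gr), IRanges(start(gr), start(gr))),
                    snps = gr)))
  }
  ids <- rr$id[inWin]
  cls <- matrix(NA_character_, m, m)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    ci <- tryCatch(dPrimeCICore(G[inWin[i], ], G[inWin[j], ]),
                   error = function(e) NULL)
    cls[i, j] <- if (is.null(ci)) "uninf"
      else if (ci["low"] >= ciLow && ci["high"] >= ciHigh) "strong"
      else if (ci["high"] < recombHigh) "recomb"
      else "uninf"
  }
  cand <- which(cls == "strong", arr.ind = TRUE)
  if (nrow(cand)) {
    pos <- start(rr)[inWin]
    lens <- pos[cand[, 2]] - pos[cand[, 1]]
    cand <- cand[order(-lens, cand[, 1]), , drop = FALSE]
  }
  used <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (any(used[i:j])) next
    sub <- cls[i:j, i:j]
    nStrong <- sum(sub == "strong", na.rm = TRUE)
    nRecomb <- sum(sub == "recomb", na.rm = TRUE)
    if (nStrong + nRecomb == 0) next
    if (nStrong / (nStrong + nRecomb) < strongFrac) next
    used[i:j] <- TRUE
    gr <- rr[inWin[i:j]]
    blocks[[length(blocks) + 1]] <- new(
      "HaplotypeBlock",
      interval = GRanges(seqnames(gr)[1],
                         IRanges(min(start(gr)), max(start(gr)))),
      snps = gr)
  }
  if (!length(blocks)) return(blocks)
  blocks[order(vapply(blocks, function(b) start(b@interval), numeric(1)))]
}
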