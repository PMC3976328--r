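suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# small panel builder: geno is variants x samples (0/1/2/NA)
makePanel <- function(geno, pos = seq_len(nrow(geno)) * 100,
                      chrom = "chr1",
                      ids = paste0("snp", seq_len(nrow(geno))),
                      major = rep("A", nrow(geno)),
                      minor = rep("G", nrow(geno)),
                      phenotype = rep(c("case", "control"),
                                      length.out = ncol(geno)),
                      sex = rep("female", ncol(geno)),
                      population = rep("POP", ncol(geno))) {
  geno <- as.matrix(geno)
  colnames(geno) <- sprintf("s%03d", seq_len(ncol(geno)))
  gr <- GRanges(chrom, IRanges(pos, pos), id = ids,
                majorAllele = major, minorAllele = minor)
  samples <- DataFrame(population = population, sex = sex,
                       phenotype = phenotype, row.names = colnames(geno))
  CohortPanel(geno, gr, samples)
}

# panel with independent binomial genotypes at given allele freqs
randomPanel <- function(n, freqs, ...) {
  geno <- t(vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n)))
  makePanel(geno, ...)
}

# ---- independent oracles --------------------------------------------------

# exact HWE p by direct enumeration with log-factorials (independent of the
# package's recurrence implementation)
oracleHwe <- function(nHomMajor, nHet, nHomMinor) {
  n <- nHomMajor + nHet + nHomMinor
  nA <- 2 * nHomMajor + nHet
  nB <- 2 * nHomMinor + nHet
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    homR <- (rare - h) / 2
    homC <- n - h - homR
    lfactorial(n) - lfactorial(h) - lfactorial(homR) - lfactorial(homC) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  pObs <- p[match(nHet, hets)]
  min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}

# naive exhaustive EM over all 2^m haplotypes, looping over individuals
# (no pattern grouping, no pruning); product-of-frequencies init
oracleEM <- function(G, tol = 1e-12, maxit = 5000) {
  m <- nrow(G); n <- ncol(G)
  H <- as.matrix(expand.grid(rep(list(0:1), m)))
  pAll <- rowMeans(G, na.rm = TRUE) / 2
  f <- apply(H, 1, function(h) prod(ifelse(h == 1, pAll, 1 - pAll)))
  K <- nrow(H)
  pairsOf <- lapply(seq_len(n), function(i) {
    g <- G[, i]
    nm <- !is.na(g)
    if (!any(nm)) return(NULL)
    out <- NULL
    for (a in seq_len(K)) for (b in a:K) {
      if (all(H[a, nm] + H[b, nm] == g[nm])) out <- rbind(out, c(a, b))
    }
    out
  })
  for (it in seq_len(maxit)) {
    num <- numeric(K); used <- 0
    for (i in seq_len(n)) {
      pr <- pairsOf[[i]]
      if (is.null(pr)) next
      w <- f[pr[, 1]] * f[pr[, 2]] * ifelse(pr[, 1] == pr[, 2], 1, 2)
      w <- w / sum(w)
      for (r in seq_len(nrow(pr))) {
        num[pr[r, 1]] <- num[pr[r, 1]] + w[r]
        num[pr[r, 2]] <- num[pr[r, 2]] + w[r]
      }
      used <- used + 1
    }
    fNew <- num / (2 * used)
    if (max(abs(fNew - f)) < tol) { f <- fNew; break }
    f <- fNew
  }
  names(f) <- apply(H, 1, paste, collapse = "")
  f
}

# naive PWM best-placement score: loops over offsets and strands
oracleMotifBest <- function(ctx, snpIndex, allele, pwm) {
  seqv <- strsplit(toupper(ctx), "")[[1]]
  seqv[snpIndex] <- toupper(allele)
  L <- nrow(pwm@mat)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- -Inf
  for (o in 1:(length(seqv) - L + 1)) {
    if (!(snpIndex >= o && snpIndex <= o + L - 1)) next
    win <- seqv[o:(o + L - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    for (str in c("+", "-")) {
      w <- if (str == "+") win else rev(unname(comp[win]))
      s <- 0
      for (q in seq_len(L))
        s <- s + log2(pwm@mat[q, w[q]] / pwm@background[match(w[q], c("A","C","G","T"))])
      best <- max(best, s)
    }
  }
  best
}

writeLinesTmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
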