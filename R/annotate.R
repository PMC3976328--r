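#' Read JASPAR-style PWM text
#'
#' Parses one or more motifs in JASPAR text format (`>ID name` header, then
#' four rows `A [ 4 19 0 ... ]`, one per base; bare count rows without the
#' base letter and brackets are also accepted, in A/C/G/T order). Counts are
#' converted to per-position probabilities with a pseudo-count of 1e-3 added
#' to every count, so no entry is zero.
#'
#' @param path PWM text file.
#' @param background length-4 background base probabilities (A,C,G,T);
#'   default uniform.
#' @return named list of [PWM-class] objects.
#' @export
readPwm <- function(path, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[b]])
    motifId <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[seq(starts[b] + 1, ends[b])]
    rows <- lapply(body, function(l) {
      base <- NA_character_
      if (grepl("^[ACGTacgt]\\b", l)) {
        base <- toupper(substr(l, 1, 1))
        l <- sub("^[ACGTacgt]", "", l)
      }
      nums <- as.numeric(strsplit(gsub("[\\[\\]]", " ", l, perl = TRUE),
                                  "\\s+")[[1]] |> (\(x) x[nzchar(x)])())
      list(base = base, nums = nums)
    })
    rows <- rows[vapply(rows, function(r) length(r$nums) > 0, logical(1))]
    if (length(rows) != 4) stop("motif ", motifId, ": expected 4 count rows")
    bases <- vapply(rows, `[[`, character(1), "base")
    counts <- do.call(rbind, lapply(rows, `[[`, "nums"))
    if (!anyNA(bases)) counts <- counts[match(DNA_BASES, bases), , drop = FALSE]
    mat <- t(counts) + 1e-3
    mat <- mat / rowSums(mat)
    colnames(mat) <- DNA_BASES
    out[[motifId]] <- new("PWM", motifId = motifId, mat = mat,
                          background = background / sum(background))
  }
  out
}

revcompChar <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

pwmScoreWindow <- function(pwm, win) {
  if (any(!win %in% DNA_BASES)) return(NA_real_)
  idx <- cbind(seq_along(win), match(win, DNA_BASES))
  sum(log2(pwm@mat[idx] / pwm@background[idx[, 2]]))
}

#' PWM motif-disruption score for one SNP
#'
#' Scores every placement of the motif covering the SNP, on both strands,
#' against the reference and the alternative allele; each score is the sum
#' of `log2(p_base / background)` over the window, and the best placement is
#' chosen independently for each allele (`aggregate = "max"`; `"sum"`
#' aggregates `2^score` over placements instead). `delta = alt - ref` in
#' bits: negative means the alternative allele weakens the best motif match.
#' Windows containing ambiguous bases are skipped.
#'
#' @param context character string of sequence around the SNP.
#' @param snpIndex 1-based index of the SNP within `context`.
#' @param ref,alt the two alleles; `context` must carry `ref` at `snpIndex`.
#' @param pwm a [PWM-class].
#' @param aggregate "max" (best placement) or "sum".
#' @return list: `motifId`, `bestRefScore`, `bestAltScore`, `delta`,
#'   `refOffset`, `refStrand`, `altOffset`, `altStrand` (offsets are the
#'   1-based start of the best window in `context`).
#' @export
motifDisruption <- function(context, snpIndex, ref, alt, pwm,
                            aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  ctx <- strsplit(toupper(context), "")[[1]]
  L <- nrow(pwm@mat)
  stopifnot(snpIndex >= 1, snpIndex <= length(ctx))
  if (ctx[snpIndex] != toupper(ref))
    stop("context does not carry the reference allele at snpIndex")
  if (length(ctx) < L) stop("context shorter than the motif")
  offs <- seq(max(1, snpIndex - L + 1), min(snpIndex, length(ctx) - L + 1))
  if (!length(offs)) stop("no placement covers the SNP")
  scoreAllele <- function(allele) {
    seqv <- ctx
    seqv[snpIndex] <- toupper(allele)
    sc <- data.frame(offset = rep(offs, 2),
                     strand = rep(c("+", "-"), each = length(offs)),
                     score = NA_real_)
    for (r in seq_len(nrow(sc))) {
      win <- seqv[sc$offset[r]:(sc$offset[r] + L - 1)]
      if (sc$strand[r] == "-") win <- revcompChar(win)
      sc$score[r] <- pwmScoreWindow(pwm, win)
    }
    sc <- sc[!is.na(sc$score), , drop = FALSE]
    if (!nrow(sc)) stop("no valid placement (ambiguous bases) for allele ", allele)
    if (aggregate == "sum") {
      list(score = log2(sum(2^sc$score)), offset = NA_integer_,
           strand = NA_character_)
    } else {
      best <- which.max(sc$score)
      list(score = sc$score[best], offset = sc$offset[best],
           strand = sc$strand[best])
    }
  }
  r <- scoreAllele(ref); a <- scoreAllele(alt)
  list(motifId = pwm@motifId, bestRefScore = r$score, bestAltScore = a$score,
       delta = a$score - r$score, refOffset = r$offset, refStrand = r$strand,
       altOffset = a$offset, altStrand = a$strand)
}

#' LD proxies of an anchor SNP
#'
#' All panel variants whose EM-based r-squared with the anchor reaches
#' `r2Min`, sorted by decreasing r-squared (the anchor itself is included
#' with r-squared 1).
#'
#' @param panel a [CohortPanel-class].
#' @param anchor anchor variant id (must be polymorphic).
#' @param r2Min inclusion threshold (default 0.9).
#' @return data.frame: snp, pos, r2, d_prime.
#' @export
ldProxies <- function(panel, anchor, r2Min = 0.9) {
  rr <- rowRanges(panel)
  rows <- lapply(seq_along(rr), function(i) {
    ld <- tryCatch(ldPair(panel, anchor, rr$id[i]), error = function(e) NULL)
    if (is.null(ld)) return(NULL)
    data.frame(snp = rr$id[i], pos = start(rr)[i], r2 = ld$r2,
               d_prime = ld$dPrime)
  })
  res <- do.call(rbind, rows)
  res <- res[res$r2 >= r2Min, , drop = FALSE]
  res[order(-res$r2, res$pos), ]
}

#' Overlap SNPs with labeled regulatory features
#'
#' A SNP overlaps a feature when `start <= pos <= end` in the internal
#' 1-based inclusive convention (BED input is converted at the boundary by
#' [readBed()]). Feature labels are preserved. A warning lists chromosomes
#' present in the SNPs but absent from the features.
#'
#' @param snps `GRanges` with `id`.
#' @param features `GRanges` with `label` (from [readBed()]).
#' @return data.frame of (snp, pos, label) pairs, one row per overlap.
#' @export
overlapFeatures <- function(snps, features) {
  missing <- setdiff(as.character(unique(seqnames(snps))),
                     as.character(unique(seqnames(features))))
  if (length(missing))
    warning("chromosome(s) absent from features: ",
            paste(missing, collapse = ", "))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snps, features))
  data.frame(snp = snps$id[S4Vectors::queryHits(hits)],
             pos = start(snps)[S4Vectors::queryHits(hits)],
             label = features$label[S4Vectors::subjectHits(hits)])
}

featureClass <- function(label) sub(":.*$", "", label)

#' Rank candidate SNPs by regulatory evidence
#'
#' Orders SNPs by (1) the number of distinct feature classes they overlap
#' (a class is the label prefix before the first colon, e.g.
#' `DNase:GM12878` -> `DNase`), then (2) the largest absolute
#' motif-disruption delta, then (3) genomic position (ascending) — a total,
#' deterministic order.
#'
#' @param snps `GRanges` with `id`.
#' @param featureHits data.frame from [overlapFeatures()].
#' @param disruptions optional data.frame with columns `snp`, `delta`
#'   (possibly several motifs per SNP).
#' @return data.frame ranked best-first: snp, pos, n_classes, classes,
#'   max_abs_delta, rank.
#' @export
prioritizeSnps <- function(snps, featureHits, disruptions = NULL) {
  tab <- data.frame(snp = snps$id, pos = start(snps))
  tab$n_classes <- vapply(tab$snp, function(s) {
    length(unique(featureClass(featureHits$label[featureHits$snp == s])))
  }, integer(1))
  tab$classes <- vapply(tab$snp, function(s) {
    paste(sort(unique(featureClass(featureHits$label[featureHits$snp == s]))),
          collapse = ",")
  }, character(1))
  tab$max_abs_delta <- vapply(tab$snp, function(s) {
    if (is.null(disruptions)) return(0)
    d <- abs(disruptions$delta[disruptions$snp == s])
    if (length(d)) max(d) else 0
  }, numeric(1))
  ord <- order(-tab$n_classes, -tab$max_abs_delta, tab$pos)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
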