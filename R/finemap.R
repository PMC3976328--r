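#' Bonferroni population gate
#'
#' Includes a population when its association p-value at the anchor SNP is
#' below `round(alpha / k, 3)` — the family-wise threshold for `k`
#' populations, rounded to three decimals so the reported gate matches the
#' conventional printed value (0.05 / 6 -> 0.008).
#'
#' @param p named numeric: per-population p-value at the anchor SNP.
#' @param k number of populations tested (default `length(p)`).
#' @param alpha family-wise level (default 0.05).
#' @return list with `included` (labels), `excluded`, and `threshold`.
#' @export
gatePopulations <- function(p, k = length(p), alpha = 0.05) {
  stopifnot(k >= 1)
  thr <- round(alpha / k, 3)
  inc <- !is.na(p) & p < thr
  list(included = names(p)[inc], excluded = names(p)[!inc], threshold = thr)
}

#' Core-haplotype intersection across populations
#'
#' Computes the shared (core) haplotype region from each population's
#' most-associated block. In `strict` mode the core interval is
#' `[max(BP1), min(BP2)]` over the blocks and the member SNPs are those
#' inside it that are present in every population's block. In `consensus`
#' mode the strict core is extended outward SNP-by-SNP as long as every
#' population whose top haplotype covers the flanking SNP carries the same
#' allele there (documenting the behavior needed to grow a core beyond the
#' smallest block).
#'
#' @param blocks named list of per-population [HaplotypeBlock-class]
#'   objects (the top block of each population).
#' @param mode "strict" or "consensus".
#' @param topHaps for `consensus`: named character vector of each
#'   population's top-haplotype allele string, aligned to that population's
#'   block SNPs.
#' @return A [CoreRegion-class] (flags empty until
#'   [differentiatingSnps()] is applied).
#' @export
coreIntersection <- function(blocks, mode = c("strict", "consensus"),
                             topHaps = NULL) {
  mode <- match.arg(mode)
  if (length(blocks) < 2)
    stop("core intersection needs blocks from at least 2 populations")
  starts <- vapply(blocks, function(b) start(b@interval), numeric(1))
  ends <- vapply(blocks, function(b) end(b@interval), numeric(1))
  lo <- max(starts); hi <- min(ends)
  if (lo > hi) {
    labs <- names(blocks)
    ov <- utils::combn(seq_along(blocks), 2, function(ij) {
      sprintf("%s/%s: [%d,%d] vs [%d,%d]", labs[ij[1]], labs[ij[2]],
              starts[ij[1]], ends[ij[1]], starts[ij[2]], ends[ij[2]])
    })
    stop("blocks have empty intersection; pairwise overlaps:\n  ",
         paste(ov, collapse = "\n  "))
  }
  chrom <- as.character(seqnames(blocks[[1]]@interval))
  # SNPs inside the strict interval present in all blocks
  idLists <- lapply(blocks, blockSnps)
  shared <- Reduce(intersect, idLists)
  allSnps <- unique(do.call(c, unname(lapply(blocks, function(b) b@snps))))
  allSnps <- allSnps[order(start(allSnps))]
  core <- allSnps[allSnps$id %in% shared &
                  start(allSnps) >= lo & start(allSnps) <= hi]
  if (mode == "consensus") {
    if (is.null(topHaps) || is.null(names(topHaps)))
      stop("consensus mode needs named topHaps allele strings")
    alleleAt <- function(lab, id) {
      ids <- blockSnps(blocks[[lab]])
      i <- match(id, ids)
      if (is.na(i)) NA_character_ else substr(topHaps[[lab]], i, i)
    }
    inCore <- allSnps$id %in% core$id
    extend <- function(idxSeq) {
      added <- integer(0)
      for (i in idxSeq) {
        als <- vapply(names(blocks), alleleAt, character(1), id = allSnps$id[i])
        als <- als[!is.na(als)]
        if (length(als) >= 1 && length(unique(als)) == 1) added <- c(added, i)
        else break
      }
      added
    }
    first <- min(which(inCore)); last <- max(which(inCore))
    addL <- extend(rev(seq_len(first - 1)))
    addR <- extend(seq(last + 1, length.out = length(allSnps) - last))
    core <- allSnps[sort(c(which(inCore), addL, addR))]
    lo <- min(start(core)); hi <- max(end(core))
  }
  new("CoreRegion",
      interval = GRanges(chrom, IRanges(lo, hi)),
      snps = core, mode = mode, flags = logical(0), refined = GRanges())
}

#' SNPs whose minor allele separates the protective from the risk haplotype
#'
#' Given the core SNPs with their minor alleles and the allele strings of
#' the protective (OR < 1) and risk (OR > 1) haplotypes, flags each SNP
#' whose minor allele is carried by the protective haplotype while the risk
#' haplotype carries the major allele. The refined interval is the span of
#' the flagged SNPs.
#'
#' @param coreSnps `GRanges` with `id`, `majorAllele`, `minorAllele`,
#'   ordered by position.
#' @param protective,risk allele strings aligned to `coreSnps`.
#' @return list with `flags` (named logical), `ids` (flagged SNP ids) and
#'   `refined` (`GRanges` spanning the flagged SNPs; empty if none).
#' @export
differentiatingSnps <- function(coreSnps, protective, risk) {
  m <- length(coreSnps)
  stopifnot(nchar(protective) == m, nchar(risk) == m)
  pa <- strsplit(protective, "")[[1]]
  ra <- strsplit(risk, "")[[1]]
  ok <- (pa == coreSnps$minorAllele | pa == coreSnps$majorAllele) &
        (ra == coreSnps$minorAllele | ra == coreSnps$majorAllele)
  if (any(!ok))
    stop("haplotype allele not matching declared alleles at ",
         paste(coreSnps$id[!ok], collapse = ", "))
  flags <- pa == coreSnps$minorAllele & ra == coreSnps$majorAllele
  names(flags) <- coreSnps$id
  refined <- if (any(flags)) {
    GRanges(seqnames(coreSnps)[1],
            IRanges(min(start(coreSnps)[flags]), max(start(coreSnps)[flags])))
  } else GRanges()
  list(flags = flags, ids = coreSnps$id[flags], refined = refined)
}

#' Attach differentiating-SNP flags to a CoreRegion
#'
#' @param core a [CoreRegion-class].
#' @param protective,risk allele strings aligned to the core SNPs.
#' @return The [CoreRegion-class] with `flags` and `refined` filled in.
#' @export
refineCore <- function(core, protective, risk) {
  d <- differentiatingSnps(core@snps, protective, risk)
  core@flags <- d$flags
  core@refined <- d$refined
  validObject(core)
  core
}

#' Interval span in kilobases (one truncated decimal)
#'
#' `(end - start) / 1000`, truncated (floored) to one decimal place — the
#' convention under which a 53780 bp block prints as 53.7 kb.
#'
#' @param interval `GRanges` (length 1) or numeric `c(start, end)`.
#' @return span in kb at one decimal.
#' @export
intervalSpanKb <- function(interval) {
  if (methods::is(interval, "GRanges")) {
    s <- start(interval); e <- end(interval)
  } else {
    s <- interval[1]; e <- interval[2]
  }
  stopifnot(e >= s)
  floor((e - s) / 100) / 10
}
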