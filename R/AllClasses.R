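#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
NULL

VALID_SEX <- c("male", "female", "unknown")
VALID_PHENO <- c("case", "control")
DNA_BASES <- c("A", "C", "G", "T")

#' CohortPanel: genotypes with variant and sample annotation
#'
#' A `CohortPanel` holds a biallelic SNP genotype matrix (variants in rows,
#' samples in columns, entries counting copies of the declared minor allele:
#' 0/1/2 or `NA` for missing) together with variant coordinates and alleles
#' (`rowRanges`) and per-sample phenotype, sex and population labels
#' (`colData`). It extends `RangedSummarizedExperiment`, so all the usual
#' subsetting and accessor machinery applies.
#'
#' The minor allele is defined on the pooled sample (cases and controls
#' together) per panel; when a panel is split by population the stored
#' definition is kept, so population-stratified frequencies may exceed 0.5
#' and are reported unclamped.
#'
#' @slot .. see `RangedSummarizedExperiment`.
#' @export
setClass("CohortPanel", contains = "RangedSummarizedExperiment")

setValidity("CohortPanel", function(object) {
  msg <- character()
  rr <- rowRanges(object)
  cd <- colData(object)
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'geno' is required")
  need_rr <- c("id", "majorAllele", "minorAllele")
  if (!all(need_rr %in% names(S4Vectors::mcols(rr)))) {
    msg <- c(msg, paste("rowRanges must carry:", paste(need_rr, collapse = ", ")))
  } else {
    if (anyDuplicated(rr$id)) msg <- c(msg, "duplicate variant ids")
    bad <- !(rr$majorAllele %in% DNA_BASES) | !(rr$minorAllele %in% DNA_BASES)
    if (any(bad)) msg <- c(msg, "alleles must be single characters A/C/G/T")
    if (any(rr$majorAllele == rr$minorAllele))
      msg <- c(msg, "major and minor allele must differ")
  }
  need_cd <- c("population", "sex", "phenotype")
  if (!all(need_cd %in% names(cd))) {
    msg <- c(msg, paste("colData must carry:", paste(need_cd, collapse = ", ")))
  } else {
    if (!all(cd$sex %in% VALID_SEX)) msg <- c(msg, "sex must be male/female/unknown")
    if (!all(cd$phenotype %in% VALID_PHENO)) msg <- c(msg, "phenotype must be case/control")
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  g <- SummarizedExperiment::assay(object, "geno")
  if (!all(g[!is.na(g)] %in% 0:2)) msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortPanel
#'
#' @param geno integer matrix, variants x samples, minor-allele counts
#'   (0/1/2, `NA` = missing).
#' @param variants `GRanges` with metadata columns `id`, `majorAllele`,
#'   `minorAllele` (1-based positions).
#' @param samples `data.frame` or `DataFrame` with columns `population`,
#'   `sex` (male/female/unknown) and `phenotype` (case/control); row names
#'   are sample ids.
#' @param build genome build label carried as metadata (default "GRCh37").
#' @return A validated [CohortPanel-class] object with variants sorted by
#'   (chromosome, position).
#' @export
CohortPanel <- function(geno, variants, samples, build = "GRCh37") {
  geno <- as.matrix(geno)
  rownames(geno) <- variants$id  # variant ids are authoritative
  samples <- DataFrame(samples)
  if (nrow(geno) != length(variants))
    stop("genotype rows (", nrow(geno), ") != number of variants (", length(variants), ")")
  if (ncol(geno) != nrow(samples))
    stop("genotype columns (", ncol(geno), ") != number of samples (", nrow(samples), ")")
  names(variants) <- variants$id
  o <- order(as.character(seqnames(variants)), start(variants))
  se <- SummarizedExperiment(
    assays = list(geno = geno[o, , drop = FALSE]),
    rowRanges = variants[o],
    colData = samples
  )
  out <- new("CohortPanel", se)
  metadata(out)$build <- build
  validObject(out)
  out
}

#' @describeIn CohortPanel variant coordinates and alleles as `GRanges`.
#' @param x,object a `CohortPanel`.
#' @export
variants <- function(x) rowRanges(x)

#' @describeIn CohortPanel per-sample annotation (`DataFrame`).
#' @export
sampleInfo <- function(x) colData(x)

#' @describeIn CohortPanel minor-allele count matrix (variants x samples).
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "geno")

setMethod("show", "CohortPanel", function(object) {
  cd <- colData(object)
  cat("CohortPanel:", nrow(object), "variants x", ncol(object), "samples\n")
  cat("  populations:", paste(unique(cd$population), collapse = ", "), "\n")
  cat("  cases/controls:", sum(cd$phenotype == "case"), "/",
      sum(cd$phenotype == "control"), "\n")
  if (nrow(object)) {
    rr <- rowRanges(object)
    cat("  span: ", as.character(seqnames(rr))[1], ":", min(start(rr)), "-",
        max(start(rr)), " (", metadata(object)$build, ")\n", sep = "")
  }
})

#' HaplotypeSet: EM-phased haplotypes over a SNP window
#'
#' Holds the ordered SNPs of a phasing window, the estimated haplotype
#' allele strings with their population frequencies, the expected per-sample
#' haplotype dosages (posterior expected copy counts, rows sum to 2), and
#' the per-genotype-pattern pair posteriors from which they derive.
#'
#' @slot snps `GRanges` of the window SNPs in genomic order.
#' @slot haplotypes character vector of allele strings (one character per SNP).
#' @slot freq numeric haplotype frequencies (sum to 1).
#' @slot dosage samples x haplotypes matrix of expected copy counts.
#' @slot sampleInfo per-sample annotation carried over from the panel.
#' @slot posteriors list with per-pattern pair posteriors (`patterns`,
#'   `pairs`, `patternOf`).
#' @slot logLik final EM log-likelihood.
#' @slot niter EM iterations used.
#' @export
setClass("HaplotypeSet", representation(
  snps = "GRanges", haplotypes = "character", freq = "numeric",
  dosage = "matrix", sampleInfo = "DataFrame", posteriors = "list",
  logLik = "numeric", niter = "integer"
))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (length(object@haplotypes) != length(object@freq))
    msg <- c(msg, "haplotypes and freq lengths differ")
  if (length(object@freq) && abs(sum(object@freq) - 1) > 1e-6)
    msg <- c(msg, "haplotype frequencies must sum to 1")
  if (length(object@haplotypes) &&
      any(nchar(object@haplotypes) != length(object@snps)))
    msg <- c(msg, "haplotype string length must equal number of SNPs")
  if (length(msg)) msg else TRUE
})

#' @describeIn HaplotypeSet haplotype allele strings.
#' @param x,object a `HaplotypeSet`.
#' @export
haplotypes <- function(x) x@haplotypes

#' @describeIn HaplotypeSet haplotype frequencies.
#' @export
hapFreq <- function(x) stats::setNames(x@freq, x@haplotypes)

#' @describeIn HaplotypeSet expected per-sample haplotype dosages.
#' @export
hapDosage <- function(x) x@dosage

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object@snps), "SNPs,",
      length(object@haplotypes), "haplotypes,",
      nrow(object@dosage), "samples\n")
  k <- order(object@freq, decreasing = TRUE)
  k <- k[seq_len(min(6, length(k)))]
  for (i in k)
    cat(sprintf("  %s  %.4f\n", object@haplotypes[i], object@freq[i]))
  if (length(object@haplotypes) > 6) cat("  ...\n")
})

#' HaplotypeBlock: a contiguous strong-LD SNP set
#'
#' @slot interval `GRanges` (length 1) spanning the first to last SNP.
#' @slot snps `GRanges` of member SNPs (with `id`).
#' @export
setClass("HaplotypeBlock", representation(interval = "GRanges", snps = "GRanges"))

setValidity("HaplotypeBlock", function(object) {
  if (length(object@interval) != 1) return("interval must have length 1")
  if (length(object@snps) &&
      (min(start(object@snps)) < start(object@interval) ||
       max(start(object@snps)) > end(object@interval)))
    return("interval must span member SNPs")
  TRUE
})

#' @describeIn HaplotypeBlock number of SNPs in the block.
#' @param x,object a `HaplotypeBlock`.
#' @export
nsnp <- function(x) length(x@snps)

#' @describeIn HaplotypeBlock block interval as `GRanges`.
#' @export
blockInterval <- function(x) x@interval

#' @describeIn HaplotypeBlock member SNP ids.
#' @export
blockSnps <- function(x) x@snps$id

setMethod("show", "HaplotypeBlock", function(object) {
  cat(sprintf("HaplotypeBlock: %s:%d-%d, %d SNPs\n",
              as.character(seqnames(object@interval)),
              start(object@interval), end(object@interval), nsnp(object)))
})

#' CoreRegion: shared haplotype interval across populations
#'
#' Result of [coreIntersection()] optionally annotated by
#' [differentiatingSnps()]: the shared (core) interval, its member SNPs,
#' the per-SNP flags marking sites whose minor allele separates the
#' protective from the risk haplotype, and the refined interval spanned by
#' the flagged SNPs.
#'
#' @slot interval core interval (`GRanges`).
#' @slot snps member SNPs (`GRanges` with `id`).
#' @slot mode "strict" or "consensus".
#' @slot flags named logical, one per member SNP (may be empty).
#' @slot refined `GRanges` spanning flagged SNPs (may be empty).
#' @export
setClass("CoreRegion", representation(
  interval = "GRanges", snps = "GRanges", mode = "character",
  flags = "logical", refined = "GRanges"
))

setValidity("CoreRegion", function(object) {
  msg <- character()
  if (length(object@interval) != 1) msg <- c(msg, "interval must have length 1")
  if (length(object@flags) && length(object@flags) != length(object@snps))
    msg <- c(msg, "flags must align to member SNPs")
  if (length(object@refined) == 1 &&
      (start(object@refined) < start(object@interval) ||
       end(object@refined) > end(object@interval)))
    msg <- c(msg, "refined interval must lie within the core interval")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoreRegion", function(object) {
  cat(sprintf("CoreRegion (%s): %s:%d-%d, %d SNPs (%.1f kb)\n",
              object@mode, as.character(seqnames(object@interval)),
              start(object@interval), end(object@interval),
              length(object@snps), intervalSpanKb(object@interval)))
  if (length(object@flags)) {
    cat("  differentiating SNPs:", sum(object@flags), "\n")
    if (length(object@refined))
      cat(sprintf("  refined: %d-%d (%.1f kb)\n", start(object@refined),
                  end(object@refined), intervalSpanKb(object@refined)))
  }
})

#' PWM: position weight matrix for motif scoring
#'
#' @slot motifId motif identifier.
#' @slot mat positions x 4 matrix of base probabilities (columns A,C,G,T);
#'   a pseudo-count is applied at load so no entry is zero.
#' @slot background length-4 background base probabilities.
#' @export
setClass("PWM", representation(
  motifId = "character", mat = "matrix", background = "numeric"
))

setValidity("PWM", function(object) {
  msg <- character()
  if (ncol(object@mat) != 4) msg <- c(msg, "matrix must have 4 columns (A,C,G,T)")
  if (any(object@mat <= 0)) msg <- c(msg, "probabilities must be positive (pseudo-count at load)")
  if (any(abs(rowSums(object@mat) - 1) > 1e-6))
    msg <- c(msg, "each position must sum to 1")
  if (length(object@background) != 4 || abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PWM", function(object) {
  consensus <- paste(DNA_BASES[apply(object@mat, 1, which.max)], collapse = "")
  cat("PWM", object@motifId, ":", nrow(object@mat), "positions, consensus",
      consensus, "\n")
})

#' SimConfig: synthetic multi-population cohort scenario
#'
#' Defines a haplotype-pool simulation: per-population case/control quotas,
#' the SNP map, the pool of haplotypes with per-population frequencies, the
#' causal haplotype and its per-copy log-odds effect, and nuisance
#' parameters. [defaultStudyScenario()] builds the bundled six-population
#' scenario.
#'
#' @slot populations data.frame with columns label, n_cases, n_controls.
#' @slot snps `GRanges` with `id`, `majorAllele`, `minorAllele`.
#' @slot haplotypes character allele strings over the SNPs.
#' @slot hapFreq populations x haplotypes frequency matrix (rows sum to 1).
#' @slot causalIndex index into `haplotypes` (NA = no causal haplotype).
#' @slot causalPops labels of populations where the effect applies.
#' @slot beta per-copy log-odds of the causal haplotype.
#' @slot alpha baseline log-odds (disease prevalence under the null).
#' @slot sexBeta log-odds for the sex covariate (female = 1).
#' @slot missingRate fraction of genotypes masked to missing.
#' @slot seed RNG seed.
#' @export
setClass("SimConfig", representation(
  populations = "data.frame", snps = "GRanges", haplotypes = "character",
  hapFreq = "matrix", causalIndex = "integer", causalPops = "character",
  beta = "numeric", alpha = "numeric", sexBeta = "numeric",
  missingRate = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!all(c("label", "n_cases", "n_controls") %in% names(object@populations)))
    msg <- c(msg, "populations needs columns label, n_cases, n_controls")
  if (any(object@populations$n_cases < 0) || any(object@populations$n_controls < 0))
    msg <- c(msg, "cohort sizes must be non-negative")
  if (nrow(object@hapFreq) != nrow(object@populations))
    msg <- c(msg, "hapFreq rows must match populations")
  if (ncol(object@hapFreq) != length(object@haplotypes))
    msg <- c(msg, "hapFreq columns must match haplotypes")
  if (nrow(object@hapFreq) && any(abs(rowSums(object@hapFreq) - 1) > 1e-9))
    msg <- c(msg, "per-population haplotype frequencies must sum to 1")
  if (any(nchar(object@haplotypes) != length(object@snps)))
    msg <- c(msg, "haplotype strings must cover all SNPs")
  if (!is.na(object@causalIndex) &&
      (object@causalIndex < 1 || object@causalIndex > length(object@haplotypes)))
    msg <- c(msg, "causalIndex out of range")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", nrow(object@populations), "populations,",
      length(object@snps), "SNPs,", length(object@haplotypes), "pool haplotypes\n")
  cat("  total cases/controls:", sum(object@populations$n_cases), "/",
      sum(object@populations$n_controls), "\n")
  if (!is.na(object@causalIndex))
    cat(sprintf("  causal haplotype %s, per-copy OR %.3f in [%s]\n",
                object@haplotypes[object@causalIndex], exp(object@beta),
                paste(object@causalPops, collapse = ", ")))
})
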