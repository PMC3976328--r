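#' Pipeline configuration
#'
#' Bundles the knobs of [runPipeline()]: analysis region, block window,
#' family-wise level, QC thresholds, haplotype frequency floor and core
#' mode.
#'
#' @param region `GRanges` (length 1) restricting the analysis, or `NULL`
#'   for the full panel.
#' @param windowBp haplotype-block window around the anchor SNP
#'   (default 250000).
#' @param alpha family-wise level for the population gate (default 0.05).
#' @param mafMin,hweMinP QC thresholds (defaults 0.01 and 1e-4).
#' @param freqFloor haplotype frequency floor (default 0.01).
#' @param coreMode "strict" or "consensus".
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(region = NULL, windowBp = 250000, alpha = 0.05,
                           mafMin = 0.01, hweMinP = 1e-4, freqFloor = 0.01,
                           coreMode = c("strict", "consensus")) {
  coreMode <- match.arg(coreMode)
  stopifnot(windowBp > 0, alpha > 0, alpha < 1,
            mafMin >= 0, mafMin < 1, hweMinP >= 0, hweMinP < 1,
            freqFloor >= 0, freqFloor < 1)
  structure(list(region = region, windowBp = windowBp, alpha = alpha,
                 mafMin = mafMin, hweMinP = hweMinP, freqFloor = freqFloor,
                 coreMode = coreMode),
            class = "pipelineConfig")
}

stageMsg <- function(...) message("[haplofine] ", ...)

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         "\n  (inspect the stage inputs; earlier stage outputs are in the ",
         "returned bundle up to this stage)", call. = FALSE)
  })
}

#' Run the full fine-mapping pipeline
#'
#' Executes, in order: per-population QC; per-population association
#' (sex-adjusted); pooled joint ("meta") association with sex and
#' population covariates; conditional scan on the joint top SNP; the
#' Bonferroni population gate on each population's p at that anchor;
#' confidence-interval haplotype blocks and EM phasing in the gated
#' populations; haplotype association per block with selection of each
#' population's top haplotype; core-haplotype intersection (when a single
#' population passes the gate its top block is used as the core);
#' joint haplotype association restricted to the core SNPs; designation of
#' the protective (OR < 1) and risk (OR > 1) haplotype among the two most
#' frequent core haplotypes; differentiating-SNP flags and the refined
#' interval; and, when `features` are supplied, regulatory prioritization of
#' the flagged SNPs. The run is deterministic: the bundle is a pure
#' function of the inputs and config.
#'
#' @param panels named list of per-population [CohortPanel-class] objects.
#' @param config a [pipelineConfig()].
#' @param features optional `GRanges` of labeled regulatory features
#'   ([readBed()]).
#' @param disruptions optional data.frame (`snp`, `delta`) of
#'   motif-disruption scores from [motifDisruption()].
#' @param outDir optional directory; when given, every stage table is
#'   written as a tab-separated file and the summary as JSON.
#' @param verbose log stage progress to stderr.
#' @return list (report bundle) with elements `perPop`, `meta`,
#'   `conditional`, `gate`, `topHaps`, `core`, `coreHapAssoc`, `refined`,
#'   `prioritized`, `summary`.
#' @export
runPipeline <- function(panels, config = pipelineConfig(), features = NULL,
                        disruptions = NULL, outDir = NULL, verbose = FALSE) {
  stopifnot(is.list(panels), length(panels) >= 1, !is.null(names(panels)))
  log_ <- if (verbose) stageMsg else function(...) invisible()
  bundle <- list()

  if (!is.null(config$region)) {
    panels <- lapply(panels, function(p)
      p[S4Vectors::queryHits(GenomicRanges::findOverlaps(rowRanges(p),
                                                         config$region)), ])
  }
  if (all(vapply(panels, nrow, integer(1)) == 0)) {
    bundle$summary <- list(status = "no variants in the analysis region")
    return(bundle)
  }

  log_("qc filter")
  panels <- withStage("qc", lapply(panels, qcFilter,
                                   mafMin = config$mafMin,
                                   hweMinP = config$hweMinP))

  log_("per-population association")
  bundle$perPop <- withStage("assoc", lapply(panels, assocScan,
                                             covariates = "sex"))

  log_("joint (pooled) association")
  bundle$meta <- withStage("meta", jointMeta(panels))
  anchor <- bundle$meta$snp[which.min(bundle$meta$p)]

  log_("conditional scan on ", anchor)
  bundle$conditional <- withStage("conditional",
                                  conditionalScan(panels, anchor))

  log_("population gate at ", anchor)
  pAtAnchor <- vapply(names(panels), function(lab) {
    res <- bundle$perPop[[lab]]
    i <- match(anchor, res$snp)
    if (is.na(i)) NA_real_ else res$p[i]
  }, numeric(1))
  bundle$gate <- withStage("gate",
    gatePopulations(pAtAnchor, k = length(panels), alpha = config$alpha))
  gated <- bundle$gate$included
  if (!length(gated)) {
    bundle$summary <- list(status = "no population passes the gate",
                           anchor = anchor, gate = bundle$gate)
    return(bundle)
  }

  log_("blocks + phasing + haplotype association in: ",
       paste(gated, collapse = ", "))
  bundle$topHaps <- withStage("haplotypes", lapply(panels[gated], function(p) {
    blocks <- buildBlocks(p, anchor, windowBp = config$windowBp)
    if (!length(blocks)) stop("no haplotype block found around the anchor")
    perBlock <- lapply(blocks, function(b) {
      hs <- phaseEM(p, blockSnps(b), freqFloor = config$freqFloor)
      res <- hapLogistic(p, hs, covariates = "sex",
                         freqFloor = config$freqFloor, stratFreq = FALSE)
      list(block = b, result = res)
    })
    best <- which.min(vapply(perBlock, function(x)
      if (nrow(x$result)) min(x$result$p, na.rm = TRUE) else Inf, numeric(1)))
    res <- perBlock[[best]]$result
    ord <- order(res$p, -abs(res$beta), res$haplotype)
    list(block = perBlock[[best]]$block, result = res[ord[1], , drop = FALSE],
         all = res)
  }))

  log_("core region (", config$coreMode, ")")
  bundle$core <- withStage("core", {
    if (length(gated) == 1) {
      b <- bundle$topHaps[[gated]]$block
      new("CoreRegion", interval = b@interval, snps = b@snps,
          mode = "single-population", flags = logical(0), refined = GRanges())
    } else {
      blocks <- lapply(bundle$topHaps, `[[`, "block")
      tops <- vapply(bundle$topHaps, function(x) x$result$haplotype, character(1))
      coreIntersection(blocks, mode = config$coreMode, topHaps = tops)
    }
  })

  log_("joint haplotype association on ", length(bundle$core@snps), " core SNPs")
  coreIds <- bundle$core@snps$id
  bundle$coreHapAssoc <- withStage("coreHapAssoc", {
    perPop <- lapply(names(panels[gated]), function(lab) {
      hs <- phaseEM(panels[[lab]], coreIds, freqFloor = config$freqFloor)
      hapLogistic(panels[[lab]], hs, covariates = "sex",
                  freqFloor = config$freqFloor, population = lab)
    })
    names(perPop) <- names(panels[gated])
    meta <- hapLogisticJoint(panels[gated], coreIds,
                             freqFloor = config$freqFloor)
    c(perPop, list(meta = meta))
  })

  log_("differentiating SNPs")
  bundle$core <- withStage("differentiating", {
    metaRes <- bundle$coreHapAssoc$meta
    two <- metaRes[order(-metaRes$freq_all), ][1:2, ]
    if (all(two$or < 1) || all(two$or > 1))
      stop("the two most frequent core haplotypes do not have opposite ",
           "OR direction; protective/risk designation is ambiguous")
    protective <- two$haplotype[two$or < 1]
    risk <- two$haplotype[two$or > 1]
    refineCore(bundle$core, protective, risk)
  })
  refined <- bundle$core@refined
  bundle$refined <- refined

  if (!is.null(features)) {
    log_("regulatory prioritization")
    bundle$prioritized <- withStage("annotate", {
      flagged <- bundle$core@snps[bundle$core@flags]
      hits <- overlapFeatures(flagged, features)
      prioritizeSnps(flagged, hits, disruptions)
    })
  }

  coreIv <- bundle$core@interval
  bundle$summary <- list(
    status = "ok",
    anchor = anchor,
    anchor_p = min(bundle$meta$p, na.rm = TRUE),
    conditional_min_p = suppressWarnings(
      min(bundle$conditional$p, na.rm = TRUE)),
    gate_threshold = bundle$gate$threshold,
    gated_populations = gated,
    core_mode = bundle$core@mode,
    core_interval = sprintf("%s:%d-%d", as.character(seqnames(coreIv)),
                            start(coreIv), end(coreIv)),
    core_span_kb = intervalSpanKb(coreIv),
    core_nsnp = length(bundle$core@snps),
    differentiating_snps = bundle$core@snps$id[bundle$core@flags],
    refined_interval = if (length(refined))
      sprintf("%s:%d-%d", as.character(seqnames(refined)), start(refined),
              end(refined)) else NA_character_,
    refined_span_kb = if (length(refined)) intervalSpanKb(refined) else NA_real_,
    top_snp_prioritized = if (!is.null(bundle$prioritized) &&
                              nrow(bundle$prioritized))
      bundle$prioritized$snp[1] else NA_character_)

  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (lab in names(bundle$perPop))
    wt(bundle$perPop[[lab]], paste0("assoc_", lab, ".tsv"))
  if (!is.null(bundle$meta)) wt(bundle$meta, "assoc_meta.tsv")
  if (!is.null(bundle$conditional)) wt(bundle$conditional, "conditional.tsv")
  for (lab in names(bundle$coreHapAssoc))
    wt(bundle$coreHapAssoc[[lab]], paste0("hap_assoc_", lab, ".tsv"))
  if (!is.null(bundle$prioritized)) wt(bundle$prioritized, "prioritized.tsv")
  jsonlite::write_json(bundle$summary,
                       file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
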