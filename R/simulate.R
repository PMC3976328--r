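#' Build a SimConfig
#'
#' Convenience constructor validating all pieces of a haplotype-pool
#' simulation scenario; see [SimConfig-class] for the meaning of each field.
#'
#' @param populations data.frame with label, n_cases, n_controls.
#' @param snps `GRanges` with `id`, `majorAllele`, `minorAllele`.
#' @param haplotypes character allele strings over `snps`.
#' @param hapFreq populations x haplotypes matrix, rows summing to 1.
#' @param causalIndex which haplotype carries the effect (NA = none).
#' @param causalPops population labels where the effect applies (default:
#'   all).
#' @param beta per-copy log-odds for the causal haplotype.
#' @param alpha baseline log-odds; the default gives ~1% prevalence under
#'   the null.
#' @param sexBeta log-odds for the sex covariate (female = 1).
#' @param missingRate fraction of genotype entries masked to missing.
#' @param seed RNG seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(populations, snps, haplotypes, hapFreq,
                      causalIndex = NA_integer_, causalPops = populations$label,
                      beta = 0, alpha = stats::qlogis(0.01), sexBeta = 0,
                      missingRate = 0, seed = 1L) {
  new("SimConfig", populations = as.data.frame(populations), snps = snps,
      haplotypes = haplotypes, hapFreq = as.matrix(hapFreq),
      causalIndex = as.integer(causalIndex), causalPops = causalPops,
      beta = beta, alpha = alpha, sexBeta = sexBeta,
      missingRate = missingRate, seed = as.integer(seed))
}

# 0/1 (minor-allele indicator) matrix of the pool haplotypes
hapIndicator <- function(config) {
  snps <- config@snps
  H <- t(vapply(strsplit(config@haplotypes, ""), function(a) {
    bad <- a != snps$majorAllele & a != snps$minorAllele
    if (any(bad))
      stop("haplotype allele does not match declared alleles at ",
           paste(snps$id[bad], collapse = ", "))
    as.integer(a == snps$minorAllele)
  }, integer(length(snps))))
  rownames(H) <- config@haplotypes
  H
}

#' Simulate a multi-population case/control panel
#'
#' For each individual two haplotypes are drawn i.i.d. from the individual's
#' population pool (Hardy-Weinberg at the haplotype level, no recombination);
#' the genotype at each SNP is the minor-allele count. Disease status is
#' drawn from `logistic(alpha + beta * causal copies + sexBeta * sex)`
#' (the effect applies only in `causalPops`), and individuals are sampled
#' with rejection until the per-population case/control quotas are met
#' (retrospective design, so the odds ratio is the recoverable quantity).
#' Genotypes are then masked to missing at `missingRate`. Fully reproducible
#' from `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @param maxDraws attempt cap on total individuals drawn per population
#'   before declaring a quota unreachable.
#' @return list with `panel` (a [CohortPanel-class]) and `truth` (data.frame
#'   with per-individual haplotype pair and covariates; the generating
#'   config is attached as attribute `config`).
#' @export
simulatePanel <- function(config, maxDraws = 2e7) {
  validObject(config)
  set.seed(config@seed)
  H <- hapIndicator(config)
  K <- length(config@haplotypes)
  pops <- config@populations
  out <- vector("list", nrow(pops))
  for (p in seq_len(nrow(pops))) {
    lab <- pops$label[p]
    f <- config@hapFreq[p, ]
    bApply <- !is.na(config@causalIndex) && lab %in% config@causalPops
    nCase <- pops$n_cases[p]; nCtl <- pops$n_controls[p]
    accC <- list(); accT <- list(); gotC <- 0L; gotT <- 0L; drawn <- 0L
    while (gotC < nCase || gotT < nCtl) {
      if (drawn >= maxDraws)
        stop("population ", lab, ": case/control quota unreachable within ",
             maxDraws, " draws")
      B <- min(maxDraws - drawn,
               max(10000L, 4L * (nCase + nCtl)))
      drawn <- drawn + B
      h1 <- sample.int(K, B, replace = TRUE, prob = f)
      h2 <- sample.int(K, B, replace = TRUE, prob = f)
      sex <- stats::rbinom(B, 1L, 0.5)
      copies <- if (bApply)
        (h1 == config@causalIndex) + (h2 == config@causalIndex) else 0L
      eta <- config@alpha + config@beta * copies + config@sexBeta * sex
      y <- stats::rbinom(B, 1L, stats::plogis(eta))
      d <- data.frame(h1 = h1, h2 = h2, sex = sex, y = y)
      needC <- nCase - gotC
      ic <- which(d$y == 1L)[seq_len(min(needC, sum(d$y == 1L)))]
      needT <- nCtl - gotT
      it <- which(d$y == 0L)[seq_len(min(needT, sum(d$y == 0L)))]
      if (length(ic)) { accC[[length(accC) + 1L]] <- d[ic, ]; gotC <- gotC + length(ic) }
      if (length(it)) { accT[[length(accT) + 1L]] <- d[it, ]; gotT <- gotT + length(it) }
    }
    d <- rbind(do.call(rbind, accC), do.call(rbind, accT))
    d$population <- lab
    out[[p]] <- d
  }
  d <- do.call(rbind, out)
  n <- nrow(d)
  d$sample_id <- sprintf("%s_%05d", d$population, stats::ave(
    rep(1L, n), d$population, FUN = seq_along))
  geno <- t(H[d$h1, , drop = FALSE] + H[d$h2, , drop = FALSE])
  colnames(geno) <- d$sample_id
  rownames(geno) <- config@snps$id
  if (config@missingRate > 0) {
    mask <- stats::runif(length(geno)) < config@missingRate
    geno[mask] <- NA_integer_
  }
  samples <- DataFrame(
    population = d$population,
    sex = ifelse(d$sex == 1L, "female", "male"),
    phenotype = ifelse(d$y == 1L, "case", "control"),
    row.names = d$sample_id)
  # panels follow the pooled minor-allele rule, like panels read from disk
  panel <- harmonizeMinor(CohortPanel(geno, config@snps, samples))
  truth <- data.frame(
    sample_id = d$sample_id, population = d$population,
    phenotype = ifelse(d$y == 1L, "case", "control"),
    sex = ifelse(d$sex == 1L, "female", "male"),
    hap1 = config@haplotypes[d$h1], hap2 = config@haplotypes[d$h2])
  attr(truth, "config") <- config
  list(panel = panel, truth = truth)
}

#' The bundled six-population fine-mapping scenario
#'
#' Builds the default study scenario: six case/control cohorts (UK, Italy,
#' Netherlands, Spain, Poland, India) at `scale` times their full sizes
#' (UK 7728/8274, Italy 1486/1270, Netherlands 1150/1173, Spain 1131/662,
#' Poland 521/541, India 497/736), a pool of four haplotypes over 14 SNPs in
#' a single LD block with population-specific frequencies, and the common
#' protective haplotype `CCGATCTGGCGCAT` as causal with per-copy odds ratio
#' 0.75 in the four European cohorts that share the signal; Poland and India
#' carry the same pool but no effect (null populations at the anchor SNP).
#'
#' Five SNP positions are anchored to their known GRCh37 coordinates
#' (rs7634898, rs6790260, rs4686484, rs2030519, rs12634152); the remaining
#' nine positions are synthetic, interpolated monotonically between the
#' anchors. Per-population pool frequencies are the four haplotypes'
#' control-population frequencies, renormalized to sum to 1.
#'
#' @param scale cohort-size fraction in (0, 1]; sizes are rounded to the
#'   nearest integer with a floor of 1.
#' @param seed RNG seed stored in the config.
#' @return A [SimConfig-class].
#' @export
defaultStudyScenario <- function(scale = 1, seed = 1L) {
  stopifnot(scale > 0, scale <= 1)
  pops <- data.frame(
    label = c("India", "Italy", "Netherlands", "Poland", "Spain", "UK"),
    n_cases = c(497L, 1486L, 1150L, 521L, 1131L, 7728L),
    n_controls = c(736L, 1270L, 1173L, 541L, 662L, 8274L))
  pops$n_cases <- pmax(1L, as.integer(round(scale * pops$n_cases)))
  pops$n_controls <- pmax(1L, as.integer(round(scale * pops$n_controls)))
  ids <- c("rs7634898", "rs7635012", "rs6790260", "rs28637341", "rs6444284",
           "rs6444285", "rs4686483", "rs4686484", "rs6778720", "rs2030520",
           "rs2030519", "rs6785284", "rs1035765", "rs12634152")
  pos <- c(188116907L, 188117000L, 188117070L, 188117420L, 188117760L,
           188118060L, 188118300L, 188118485L, 188118930L, 188119350L,
           188119901L, 188120280L, 188120660L, 188121019L)
  minor <- c("C", "C", "G", "T", "C", "C", "T", "G", "G", "C", "G", "T", "T", "C")
  major <- c("T", "A", "C", "A", "T", "T", "A", "A", "A", "T", "A", "C", "A", "T")
  snps <- GRanges("chr3", IRanges(pos, pos), id = ids,
                  majorAllele = major, minorAllele = minor)
  haps <- c(protective = "CCGATCTGGCGCAT",
            risk       = "CCCTCTAAATATTC",
            minor3     = "TACATTAAATACAC",
            minor4     = "CACATTAAATACAT")
  # control-population frequencies of the four pool haplotypes
  fr <- rbind(
    India       = c(0.4857, 0.4081, 0.0440, 0.06003),
    Italy       = c(0.5248, 0.3980, 0.04567, 0.02677),
    Netherlands = c(0.4595, 0.4335, 0.04646, 0.05797),
    Poland      = c(0.4857, 0.4081, 0.0440, 0.06003),
    Spain       = c(0.5257, 0.3754, 0.04079, 0.05589),
    UK          = c(0.4818, 0.4100, 0.0423, 0.06442))
  fr <- fr / rowSums(fr)
  colnames(fr) <- unname(haps)
  simConfig(pops, snps, unname(haps), fr,
            causalIndex = 1L,
            causalPops = c("UK", "Italy", "Netherlands", "Spain"),
            beta = log(0.75), seed = seed)
}

#' Id of the causal tag SNP of a scenario
#'
#' A SNP perfectly tagging the causal haplotype (its minor allele is carried
#' by the causal haplotype and by no other pool haplotype); used as the
#' ground-truth location in parameter-recovery tests. Returns `NA` if no
#' such SNP exists or no haplotype is causal.
#'
#' @param config a [SimConfig-class].
#' @return SNP id (character) or `NA`.
#' @export
causalTagSnp <- function(config) {
  if (is.na(config@causalIndex)) return(NA_character_)
  H <- hapIndicator(config)
  k <- config@causalIndex
  uniq <- which(H[k, ] == 1L & colSums(H[-k, , drop = FALSE]) == 0L)
  if (!length(uniq)) return(NA_character_)
  # prefer the anchor most central among the unique tags
  config@snps$id[uniq[ceiling(length(uniq) / 2)]]
}

#' Split a panel by population
#'
#' @param panel a [CohortPanel-class].
#' @return Named list of per-population [CohortPanel-class] objects (minor
#'   allele coding kept from the pooled panel).
#' @export
splitByPopulation <- function(panel) {
  labs <- sort(unique(colData(panel)$population))
  out <- lapply(labs, function(l) panel[, colData(panel)$population == l])
  names(out) <- labs
  out
}

#' Write a simulated scenario to disk
#'
#' Runs [simulatePanel()] and writes one VCF + phenotype table per
#' population, the truth record as a tab-separated file, and the scenario
#' config as YAML. File names are `<label>.vcf`, `<label>.pheno.tsv`,
#' `truth.tsv`, `config.yaml`.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
simulateCohorts <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePanel(config)
  panels <- splitByPopulation(sim$panel)
  paths <- list()
  for (lab in names(panels)) {
    gp <- file.path(dir, paste0(lab, ".vcf"))
    pp <- file.path(dir, paste0(lab, ".pheno.tsv"))
    writePanel(panels[[lab]], gp, pp, format = "vcf")
    paths[[lab]] <- c(genotypes = gp, phenotypes = pp)
  }
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- file.path(dir, "config.yaml")
  writeSimConfig(config, cp)
  paths$truth <- tp
  paths$config <- cp
  invisible(paths)
}

#' Serialize / load a SimConfig as YAML
#'
#' The schema mirrors the [SimConfig-class] slots: `populations` (list of
#' label/n_cases/n_controls), `snps` (chrom/pos/id/major/minor), `haplotypes`,
#' `hap_freq` (per-population rows), `causal_index`, `causal_pops`, `beta`,
#' `alpha`, `sex_beta`, `missing_rate`, `seed`.
#'
#' @param config a [SimConfig-class].
#' @param path YAML file path.
#' @return `writeSimConfig`: invisibly, `path`; `readSimConfig`: a
#'   [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  snps <- config@snps
  obj <- list(
    populations = lapply(seq_len(nrow(config@populations)), function(i)
      as.list(config@populations[i, ])),
    snps = lapply(seq_along(snps), function(i) list(
      chrom = as.character(seqnames(snps))[i], pos = start(snps)[i],
      id = snps$id[i], major = snps$majorAllele[i], minor = snps$minorAllele[i])),
    haplotypes = as.list(config@haplotypes),
    hap_freq = lapply(seq_len(nrow(config@hapFreq)), function(i)
      as.list(unname(config@hapFreq[i, ]))),
    causal_index = config@causalIndex, causal_pops = as.list(config@causalPops),
    beta = config@beta, alpha = config@alpha, sex_beta = config@sexBeta,
    missing_rate = config@missingRate, seed = config@seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  o <- yaml::read_yaml(path)
  pops <- do.call(rbind, lapply(o$populations, as.data.frame))
  snps <- do.call(rbind, lapply(o$snps, as.data.frame))
  gr <- GRanges(snps$chrom, IRanges(snps$pos, snps$pos), id = snps$id,
                majorAllele = snps$major, minorAllele = snps$minor)
  fr <- do.call(rbind, lapply(o$hap_freq, unlist))
  fr <- fr / rowSums(fr)  # YAML prints limited precision; restore the simplex
  rownames(fr) <- pops$label
  simConfig(pops, gr, unlist(o$haplotypes), fr,
            causalIndex = o$causal_index, causalPops = unlist(o$causal_pops),
            beta = o$beta, alpha = o$alpha, sexBeta = o$sex_beta,
            missingRate = o$missing_rate, seed = o$seed)
}
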