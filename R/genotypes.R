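#' Read a genotype panel with its phenotype table
#'
#' Reads genotypes from a VCF (only the GT field is consumed) or from
#' PLINK-style text PED/MAP files, joins them with a tab-separated phenotype
#' table, and returns a validated [CohortPanel-class]. The minor allele of
#' each variant is recomputed as the less frequent allele in the full sample
#' (ties broken by the alphabetically later allele), and variants are sorted
#' by (chromosome, position).
#'
#' The phenotype table must have a header with columns `sample_id`,
#' `population`, `sex` (male/female/unknown) and `phenotype` (case/control).
#'
#' @param genotypePath VCF file, or the PED file when `format = "plink_text"`
#'   (the MAP file is found by swapping the extension, or via `mapPath`).
#' @param phenotypePath tab-separated phenotype/covariate table.
#' @param format "vcf" or "plink_text".
#' @param mapPath optional explicit MAP path for PLINK input.
#' @return A [CohortPanel-class].
#' @export
readPanel <- function(genotypePath, phenotypePath,
                      format = c("vcf", "plink_text"), mapPath = NULL) {
  format <- match.arg(format)
  pheno <- readPhenotypeTable(phenotypePath)
  raw <- if (format == "vcf") readVcfGeno(genotypePath)
         else readPedMap(genotypePath, mapPath)
  ids <- colnames(raw$alt_count)
  miss <- setdiff(ids, rownames(pheno))
  if (length(miss))
    stop("samples missing from phenotype table: ", paste(utils::head(miss, 5), collapse = ", "))
  pheno <- pheno[ids, , drop = FALSE]
  # orient counts to the pooled minor allele
  n <- rowSums(!is.na(raw$alt_count))
  altFreq <- rowSums(raw$alt_count, na.rm = TRUE) / (2 * pmax(n, 1L))
  a1 <- raw$allele1  # the counted allele
  a2 <- raw$allele2
  minorIsA1 <- altFreq < 0.5 | (altFreq == 0.5 & a1 > a2)
  geno <- raw$alt_count
  flip <- !minorIsA1
  geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
  minor <- unname(ifelse(minorIsA1, a1, a2))
  major <- unname(ifelse(minorIsA1, a2, a1))
  gr <- GRanges(raw$chrom, IRanges(raw$pos, raw$pos),
                id = raw$id, majorAllele = major, minorAllele = minor)
  CohortPanel(geno, gr, pheno)
}

readPhenotypeTable <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "population", "sex", "phenotype")
  if (!all(need %in% names(tab)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in phenotype table")
  if (!all(tab$phenotype %in% VALID_PHENO))
    stop("phenotype must be binary (case/control); got: ",
         paste(setdiff(unique(tab$phenotype), VALID_PHENO), collapse = ", "))
  if (!all(tab$sex %in% VALID_SEX))
    stop("sex must be male/female/unknown")
  out <- DataFrame(population = tab$population, sex = tab$sex,
                   phenotype = tab$phenotype, row.names = tab$sample_id)
  out
}

readVcfGeno <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  id <- fix[, "ID"]
  if (anyDuplicated(id)) stop("duplicate variant ids in VCF")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- nchar(ref) != 1 | nchar(alt) != 1 | !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES)
  if (any(bad))
    stop("only biallelic SNPs supported; offending variant(s): ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(id, names(gt)))
  cnt <- countAltFromGT(gt, id)
  list(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]), id = id,
       allele1 = alt, allele2 = ref, alt_count = cnt)
}

countAltFromGT <- function(gt, id) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(x) {
    a <- strsplit(x, "[/|]")[[1]]
    if (length(a) != 2 || any(!a %in% c("0", "1", "."))) return(NA_integer_)
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  badv <- u[is.na(map) & !grepl("\\.", u)]
  if (length(badv))
    stop("unsupported GT value(s): ", paste(utils::head(badv, 3), collapse = ", "))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  rownames(out) <- id
  out
}

readPedMap <- function(pedPath, mapPath = NULL) {
  if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", pedPath)
  if (!file.exists(mapPath)) stop("MAP file not found: ", mapPath)
  map <- utils::read.table(mapPath, header = FALSE, colClasses = "character")
  if (ncol(map) < 4) stop("MAP file needs 4 columns (chrom, id, cM, pos)")
  id <- map[[2]]
  if (anyDuplicated(id)) stop("duplicate variant ids in MAP")
  m <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6 + 2 * m)
  if (length(bad))
    stop("PED parse error at line ", bad[1], ": expected ", 6 + 2 * m,
         " fields, got ", nf[bad[1]])
  ped <- do.call(rbind, fields)
  samp <- ped[, 2]
  if (anyDuplicated(samp)) stop("duplicate sample ids in PED")
  al <- ped[, -(1:6), drop = FALSE]
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  cnt <- matrix(NA_integer_, m, nrow(ped), dimnames = list(id, samp))
  allele1 <- allele2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2)
    obs <- obs[obs != "0"]
    if (any(!obs %in% DNA_BASES))
      stop("non-ACGT allele for variant ", id[j])
    tab <- sort(table(factor(obs, levels = DNA_BASES)), decreasing = TRUE)
    tab <- tab[tab > 0]
    alls <- names(tab)
    if (length(alls) > 2) stop("variant ", id[j], " has >2 alleles")
    if (length(alls) == 0) alls <- c("A", "C")  # fully missing site
    if (length(alls) == 1) alls <- c(alls, setdiff(DNA_BASES, alls)[1])
    allele1[j] <- alls[2]  # counted allele: the rarer of the two
    allele2[j] <- alls[1]
    ok <- x1 != "0" & x2 != "0"
    cnt[j, ok] <- (x1[ok] == alls[2]) + (x2[ok] == alls[2])
  }
  list(chrom = map[[1]], pos = as.integer(map[[4]]), id = id,
       allele1 = allele1, allele2 = allele2, alt_count = cnt)
}

#' Write a genotype panel and its phenotype table
#'
#' Emits a panel as VCF 4.2 (REF = major allele, ALT = minor allele, GT
#' only) or PLINK-style text PED/MAP, plus the tab-separated phenotype
#' table. The emitted files re-read with [readPanel()] to an identical
#' panel (allele coding, missingness and sample order preserved) provided
#' the panel's minor-allele coding follows the pooled-sample rule.
#'
#' @param panel a [CohortPanel-class].
#' @param genotypePath output VCF (or PED; its MAP companion is written
#'   alongside with the extension swapped).
#' @param phenotypePath output phenotype table path.
#' @param format "vcf" or "plink_text".
#' @return Invisibly, the genotype path.
#' @export
writePanel <- function(panel, genotypePath, phenotypePath,
                       format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  writePhenotypeTable(panel, phenotypePath)
  if (format == "vcf") writeVcfGeno(panel, genotypePath)
  else writePedMap(panel, genotypePath)
  invisible(genotypePath)
}

writePhenotypeTable <- function(panel, path) {
  cd <- colData(panel)
  tab <- data.frame(sample_id = colnames(panel), population = cd$population,
                    sex = cd$sex, phenotype = cd$phenotype)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

writeVcfGeno <- function(panel, path) {
  rr <- rowRanges(panel)
  g <- genotypes(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", metadata(panel)$build),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(panel)), collapse = "\t")), con)
  if (nrow(panel)) {
    gtc <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    gt[ok] <- gtc[g[ok] + 1L]
    rows <- paste(as.character(seqnames(rr)), start(rr), rr$id,
                  rr$majorAllele, rr$minorAllele, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

writePedMap <- function(panel, pedPath) {
  mapPath <- sub("\\.ped$", ".map", pedPath)
  if (mapPath == pedPath) mapPath <- paste0(pedPath, ".map")
  rr <- rowRanges(panel)
  utils::write.table(
    data.frame(as.character(seqnames(rr)), rr$id, 0, start(rr)),
    mapPath, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  g <- genotypes(panel)
  cd <- colData(panel)
  sexCode <- c(male = "1", female = "2", unknown = "0")[cd$sex]
  phenoCode <- c(control = "1", case = "2")[cd$phenotype]
  lines <- vapply(seq_len(ncol(g)), function(i) {
    gi <- g[, i]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, rr$minorAllele, rr$majorAllele))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, rr$minorAllele, rr$majorAllele))
    paste(c(colnames(g)[i], colnames(g)[i], "0", "0", sexCode[i], phenoCode[i],
            as.vector(rbind(a1, a2))), collapse = "\t")
  }, character(1))
  writeLines(lines, pedPath)
  invisible(pedPath)
}

#' Read a BED file of labeled intervals
#'
#' Imports BED3/BED4 features (0-based half-open on disk) and returns a
#' `GRanges` in the package's internal 1-based inclusive convention, with
#' the label taken from the BED name column when present (column 4).
#'
#' @param path BED file.
#' @return `GRanges` with a `label` metadata column.
#' @export
readBed <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  if (!length(txt)) return(GRanges(label = character(0)))
  gr <- rtracklayer::import(path, format = "BED")
  lab <- gr$name
  if (is.null(lab)) lab <- rep(NA_character_, length(gr))
  S4Vectors::mcols(gr) <- DataFrame(label = lab)
  gr
}
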