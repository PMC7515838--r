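# Polygenic score engine: allele harmonization of GWAS summary statistics
# against target genotypes, greedy LD clumping (r^2 ceiling within a
# symmetric genomic window, most significant SNP first), p-value
# thresholding and dosage-weighted scoring.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize summary statistics against target genotypes
#'
#' Matches SNPs by id; SNPs absent from the genotypes are dropped. Where the
#' summary-statistic effect/other alleles are swapped relative to the
#' genotype coding the effect sign is flipped; strand flips (complement
#' alleles) are accepted; strand-ambiguous SNPs (A/T, C/G) and
#' irreconcilable allele pairs are dropped with a logged reason. The output
#' is aligned to the genotype column order.
#'
#' @param sumstats a `summary_stats` data.frame (SNP, CHR, BP, A1, A2, BETA,
#'   SE, P).
#' @param genotypes a `genotype_matrix`.
#' @return harmonized `summary_stats` with attribute `harmonization_log`
#'   (counts per disposition).
#' @export
harmonize_sumstats <- function(sumstats, genotypes) {
  g <- genotypes$snps
  ss <- sumstats[match(g$id, sumstats$SNP), , drop = FALSE]
  present <- !is.na(ss$SNP)
  log <- c(input = nrow(sumstats), absent_from_genotypes =
             nrow(sumstats) - sum(present))
  amb <- present &
    (COMPLEMENT[ss$A1] == ss$A2)             # A/T or C/G pairs
  amb[is.na(amb)] <- FALSE
  same <- present & !amb & ss$A1 == g$a1 & ss$A2 == g$a2
  swap <- present & !amb & ss$A1 == g$a2 & ss$A2 == g$a1
  flip <- present & !amb & !same & !swap &
    COMPLEMENT[ss$A1] == g$a1 & COMPLEMENT[ss$A2] == g$a2
  flipswap <- present & !amb & !same & !swap & !flip &
    COMPLEMENT[ss$A1] == g$a2 & COMPLEMENT[ss$A2] == g$a1
  flip[is.na(flip)] <- FALSE; flipswap[is.na(flipswap)] <- FALSE
  keep <- same | swap | flip | flipswap
  log <- c(log, matched = sum(same), swapped = sum(swap),
           strand_flipped = sum(flip), strand_flipped_swapped = sum(flipswap),
           ambiguous_dropped = sum(amb),
           irreconcilable_dropped = sum(present & !amb & !keep))
  out <- ss[keep, , drop = FALSE]
  gk <- g[keep, , drop = FALSE]
  neg <- (swap | flipswap)[keep]
  out$BETA[neg] <- -out$BETA[neg]
  out$A1 <- gk$a1; out$A2 <- gk$a2
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "harmonization_log") <- log
  out
}

#' Greedy LD clumping
#'
#' Visits SNPs in ascending p-value order (ties broken by chromosome, then
#' position, then id, so the result is invariant to input order). Each
#' not-yet-removed SNP becomes an index SNP and removes every other
#' unvisited SNP on the same chromosome within `window_kb` kilobases on
#' either side whose squared Pearson dosage correlation with it exceeds
#' `r2_max`.
#'
#' @param sumstats harmonized `summary_stats` aligned to `genotypes`.
#' @param genotypes a `genotype_matrix` providing dosages for the r^2
#'   computation in the target sample.
#' @param r2_max squared-correlation ceiling (SNPs above it are clumped
#'   away), in (0, 1].
#' @param window_kb half-width of the symmetric window around the index SNP.
#' @return object of class `clump_result`: `retained` (index SNP ids in
#'   visiting order) and `removed_by` (named map removed SNP -> its index).
#' @export
ld_clump <- function(sumstats, genotypes, r2_max = 0.25, window_kb = 250) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  if (window_kb <= 0) stop("window_kb must be positive")
  if (nrow(sumstats) == 0)
    return(structure(list(retained = character(0),
                          removed_by = character(0)), class = "clump_result"))
  ids <- sumstats$SNP
  D <- genotypes$dosage[, match(ids, colnames(genotypes$dosage)), drop = FALSE]
  if (anyNA(match(ids, colnames(genotypes$dosage))))
    stop("sumstats contain SNPs absent from the genotypes; harmonize first")
  ord <- order(sumstats$P, sumstats$CHR, sumstats$BP, ids)
  state <- integer(length(ids))          # 0 free, 1 index, 2 removed
  removed_by <- character(0)
  win <- window_kb * 1000
  for (k in ord) {
    if (state[k] != 0L) next
    state[k] <- 1L
    cand <- which(state == 0L & sumstats$CHR == sumstats$CHR[k] &
                    abs(sumstats$BP - sumstats$BP[k]) <= win)
    if (!length(cand)) next
    r2 <- suppressWarnings(cor(D[, k], D[, cand, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    hit <- cand[r2 > r2_max]
    if (length(hit)) {
      state[hit] <- 2L
      removed_by[ids[hit]] <- ids[k]
    }
  }
  structure(list(retained = ids[ord][state[ord] == 1L],
                 removed_by = removed_by), class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("LD clump:", length(x$retained), "index SNPs retained,",
      length(x$removed_by), "removed\n")
  invisible(x)
}

#' Compute a polygenic score
#'
#' Dosage-weighted sum of effect sizes over the clump-retained SNPs passing
#' the p-value threshold. Missing dosages are mean-imputed per SNP before
#' scoring (count logged in the provenance).
#'
#' @param genotypes a `genotype_matrix`.
#' @param sumstats harmonized `summary_stats`.
#' @param clump optional `clump_result`; if NULL all SNPs are eligible.
#' @param p_threshold association threshold in (0, 1]; SNPs with P above it
#'   are excluded.
#' @return object of class `pgs_vector`: `score` (raw per-person score),
#'   `score_std` (standardized), and provenance (`p_threshold`,
#'   `n_snps_used`, ...).
#' @export
pgs_score <- function(genotypes, sumstats, clump = NULL, p_threshold = 1.0) {
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must lie in (0, 1]")
  ids <- sumstats$SNP
  if (!is.null(clump)) {
    unknown <- setdiff(clump$retained, ids)
    if (length(unknown))
      stop("clump references SNPs not in sumstats: ",
           paste(head(unknown, 3), collapse = ", "))
    keep <- ids %in% clump$retained
  } else keep <- rep(TRUE, length(ids))
  keep <- keep & sumstats$P <= p_threshold
  use <- sumstats[keep, , drop = FALSE]
  D <- genotypes$dosage[, match(use$SNP, colnames(genotypes$dosage)),
                        drop = FALSE]
  n_imputed <- 0L
  if (anyNA(D)) {
    for (j in seq_len(ncol(D))) {
      nas <- is.na(D[, j])
      if (any(nas)) {
        D[nas, j] <- mean(D[, j], na.rm = TRUE)
        n_imputed <- n_imputed + sum(nas)
      }
    }
  }
  raw <- if (ncol(D)) drop(D %*% use$BETA) else rep(0, nrow(genotypes$dosage))
  sdr <- sd(raw)
  structure(list(score = raw,
                 score_std = if (isTRUE(sdr > 0)) (raw - mean(raw)) / sdr else
                   raw * 0,
                 p_threshold = p_threshold,
                 n_snps_used = ncol(D), n_dosages_imputed = n_imputed),
            class = "pgs_vector")
}

#' @export
print.pgs_vector <- function(x, ...) {
  cat("Polygenic score:", length(x$score), "individuals,",
      x$n_snps_used, "SNPs at p <=", x$p_threshold, "\n")
  invisible(x)
}

# ---- I/O for the standard text formats -------------------------------------

#' Write / read summary statistics as TSV
#'
#' Dialect: tab-separated with header `SNP CHR BP A1 A2 BETA SE P`.
#' @param sumstats a `summary_stats` data.frame.
#' @param path file path.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  if (!all(need %in% names(x)))
    stop("sumstats file lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Write / read a dosage matrix as TSV
#'
#' Wide layout: SNP metadata columns (`SNP CHR BP A1 A2`) followed by one
#' dosage column per individual.
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  s <- genotypes$snps
  tab <- cbind(data.frame(SNP = s$id, CHR = s$chr, BP = s$bp,
                          A1 = s$a1, A2 = s$a2, stringsAsFactors = FALSE),
               as.data.frame(t(genotypes$dosage)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("SNP", "CHR", "BP", "A1", "A2")
  D <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  colnames(D) <- tab$SNP
  maf <- colMeans(D) / 2
  snps <- data.frame(id = tab$SNP, chr = tab$CHR, bp = tab$BP,
                     a1 = tab$A1, a2 = tab$A2,
                     maf = pmin(maf, 1 - maf), stringsAsFactors = FALSE)
  structure(list(dosage = D, snps = snps), class = "genotype_matrix")
}

#' Write genotypes as a minimal VCF with dosage (DS) FORMAT field
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path (uncompressed `.vcf`).
#' @param sample_ids optional individual ids.
#' @export
write_vcf <- function(genotypes, path,
                      sample_ids = sprintf("p%05d", seq_len(nrow(genotypes$dosage)))) {
  s <- genotypes$snps
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  D <- genotypes$dosage
  for (j in seq_len(nrow(s))) {
    writeLines(paste(c(s$chr[j], s$bp[j], s$id[j], s$a2[j], s$a1[j], ".",
                       "PASS", ".", "DS", format(D[, j], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dosage VCF into a genotype matrix
#'
#' Uses VariantAnnotation when available (DS or GT fields); REF is taken as
#' the other allele and ALT as the effect allele, matching [write_vcf()].
#'
#' @param path VCF path.
#' @return a `genotype_matrix`.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path)
  gen <- VariantAnnotation::geno(v)
  if ("DS" %in% names(gen)) {
    D <- t(matrix(as.numeric(gen$DS), nrow = nrow(gen$DS)))
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    D <- t(matrix(vapply(strsplit(as.vector(gt), "[/|]"),
                         function(a) sum(a == "1"), numeric(1)),
                  nrow = nrow(gt)))
  } else stop("VCF has neither DS nor GT FORMAT fields")
  rr <- SummarizedExperiment::rowRanges(v)
  snps <- data.frame(
    id = names(rr),
    chr = as.character(GenomicRanges::seqnames(rr)),
    bp = GenomicRanges::start(rr),
    a1 = as.character(unlist(VariantAnnotation::alt(v))),
    a2 = as.character(VariantAnnotation::ref(v)),
    stringsAsFactors = FALSE)
  maf <- colMeans(D) / 2
  snps$maf <- pmin(maf, 1 - maf)
  colnames(D) <- snps$id
  structure(list(dosage = D, snps = snps), class = "genotype_matrix")
}
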