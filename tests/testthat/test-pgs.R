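# Polygenic score engine: harmonization, clumping, scoring, and the I/O
# round trips.

mk_geno <- function(dosage, chr, bp, a1, a2, ids = NULL) {
  m <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(m))
  colnames(dosage) <- ids
  maf <- pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
  structure(list(dosage = dosage,
                 snps = data.frame(id = ids, chr = chr, bp = bp, a1 = a1,
                                   a2 = a2, maf = maf,
                                   stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

mk_ss <- function(ids, a1, a2, beta, p, chr = 1, bp = seq_along(ids) * 1000) {
  structure(data.frame(SNP = ids, CHR = chr, BP = bp, A1 = a1, A2 = a2,
                       BETA = beta, SE = 0.01, P = p,
                       stringsAsFactors = FALSE),
            class = c("summary_stats", "data.frame"))
}

test_that("harmonization: identity, swap, ambiguity, irreconcilable", {
  D <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 1, 0, 0, 2), 3, 4)
  g <- mk_geno(D, chr = 1, bp = c(1e3, 2e3, 3e3, 4e3),
               a1 = c("A", "C", "A", "G"), a2 = c("G", "T", "T", "A"))
  ss <- mk_ss(g$snps$id,
              a1 = c("A", "T", "A", "C"),     # s2 swapped, s3 ambiguous,
              a2 = c("G", "C", "T", "A"),     # s4 irreconcilable ({C,A} vs {G,A})
              beta = c(0.5, 0.3, 0.2, 0.1), p = rep(0.5, 4))
  h <- harmonize_sumstats(ss, g)
  expect_identical(h$SNP, c("s01", "s02"))
  expect_equal(h$BETA, c(0.5, -0.3))          # swap flips the sign
  log <- attr(h, "harmonization_log")
  expect_identical(unname(log[["ambiguous_dropped"]]), 1L)
  expect_identical(unname(log[["irreconcilable_dropped"]]), 1L)

  # strand flip: A/G reported as T/C matches and keeps the sign
  ss2 <- mk_ss("s01", a1 = "T", a2 = "C", beta = 0.4, p = 0.5)
  h2 <- harmonize_sumstats(ss2, g)
  expect_equal(h2$BETA, 0.4)

  # SNPs absent from the genotypes are dropped silently
  ss3 <- mk_ss(c("s01", "nope"), a1 = c("A", "A"), a2 = c("G", "C"),
               beta = c(1, 1), p = c(0.5, 0.5))
  expect_identical(harmonize_sumstats(ss3, g)$SNP, "s01")
})

test_that("clumping: degenerate cases and the forced greedy example", {
  set.seed(60)
  x <- rbinom(200, 2, 0.4)
  g <- mk_geno(cbind(x, x), chr = 1, bp = c(1000, 2000),
               a1 = c("A", "A"), a2 = c("G", "G"))
  ss <- mk_ss(g$snps$id, a1 = c("A", "A"), a2 = c("G", "G"),
              beta = c(1, 1), p = c(1e-8, 1e-4), bp = c(1000, 2000))
  cl <- ld_clump(ss, g)
  expect_identical(cl$retained, "s01")
  expect_identical(unname(cl$removed_by["s02"]), "s01")

  # single SNP is its own index
  g1 <- mk_geno(matrix(x, 200, 1), 1, 1000, "A", "G")
  ss1 <- mk_ss("s01", "A", "G", 1, 0.5)
  expect_identical(ld_clump(ss1, g1)$retained, "s01")

  # empty input is fine
  expect_identical(ld_clump(ss1[0, ], g1)$retained, character(0))
  expect_error(ld_clump(ss1, g1, r2_max = 0), "r2_max")
})

test_that("clumping matches a brute-force oracle and ignores input order", {
  brute_clump <- function(ss, g, r2_max = 0.25, window_kb = 250) {
    R2 <- suppressWarnings(cor(g$dosage[, ss$SNP]))^2
    R2[is.na(R2)] <- 0
    ord <- order(ss$P, ss$CHR, ss$BP, ss$SNP)
    status <- setNames(rep("free", nrow(ss)), ss$SNP)
    for (i in ord) {
      id <- ss$SNP[i]
      if (status[id] != "free") next
      status[id] <- "index"
      for (j in seq_len(nrow(ss))) {
        jd <- ss$SNP[j]
        if (status[jd] != "free") next
        if (ss$CHR[j] == ss$CHR[i] &&
            abs(ss$BP[j] - ss$BP[i]) <= window_kb * 1000 &&
            R2[id, jd] > r2_max) status[jd] <- "removed"
      }
    }
    names(status)[status == "index"]
  }
  g <- simulate_genotypes(300, 50, block_size = 10, within_block_r = 0.7,
                          seed = 61)
  ss <- simulate_summary_stats(g, rnorm(50, 0, 0.05), 1e4, seed = 62)
  h <- harmonize_sumstats(ss, g)
  cl <- ld_clump(h, g)
  expect_setequal(cl$retained, brute_clump(h, g))

  # permuting the input rows leaves the retained set unchanged
  perm <- sample(nrow(h))
  hp <- h[perm, ]
  # genotype column alignment is by id, so shuffling rows is safe
  clp <- ld_clump(hp, g)
  expect_setequal(clp$retained, cl$retained)
})

test_that("scoring: null weights, arithmetic identity, dense oracle", {
  D <- matrix(c(0, 1, 2), 3, 1)
  g <- mk_geno(D, 1, 1000, "A", "G")
  ss <- mk_ss("s01", "A", "G", beta = 0.5, p = 0.5)
  expect_equal(pgs_score(g, ss)$score, c(0, 0.5, 1.0))
  ss0 <- mk_ss("s01", "A", "G", beta = 0, p = 0.5)
  expect_equal(pgs_score(g, ss0)$score, c(0, 0, 0))

  set.seed(63)
  g20 <- simulate_genotypes(40, 20, seed = 63)
  ss20 <- simulate_summary_stats(g20, rnorm(20, 0, 0.1), 1e4, seed = 64)
  h <- harmonize_sumstats(ss20, g20)
  sc <- pgs_score(g20, h)
  oracle <- drop(g20$dosage[, h$SNP] %*% h$BETA)
  expect_equal(sc$score, oracle, tolerance = 1e-12)

  # linearity in the weights
  h2 <- h; h2$BETA <- 3 * h$BETA
  expect_equal(pgs_score(g20, h2)$score, 3 * sc$score, tolerance = 1e-12)

  # lowering the threshold never uses more SNPs
  cl <- ld_clump(h, g20)
  n1 <- pgs_score(g20, h, cl, 1.0)$n_snps_used
  n01 <- pgs_score(g20, h, cl, 0.1)$n_snps_used
  n001 <- pgs_score(g20, h, cl, 0.01)$n_snps_used
  expect_true(n001 <= n01 && n01 <= n1)

  # unknown SNP in the clump is a consistency error
  clbad <- cl; clbad$retained <- c(cl$retained, "ghost")
  expect_error(pgs_score(g20, h, clbad), "ghost")

  # missing dosages are mean-imputed, not propagated
  gna <- g20; gna$dosage[1, h$SNP[1]] <- NA
  scna <- pgs_score(gna, h)
  expect_true(all(is.finite(scna$score)))
  expect_identical(scna$n_dosages_imputed, 1L)
})

test_that("a stringent threshold sharpens a large-effect locus signal", {
  set.seed(65)
  g <- simulate_genotypes(800, 400, seed = 65)
  tb <- numeric(400); tb[57] <- 0.5         # one strong locus, rest null
  ss <- simulate_summary_stats(g, tb, 5e4, seed = 66)
  h <- harmonize_sumstats(ss, g)
  cl <- ld_clump(h, g)
  s_all <- pgs_score(g, h, cl, 1.0)
  s_strict <- pgs_score(g, h, cl, 0.01)
  locus <- g$dosage[, g$snps$id[57]]
  expect_gt(abs(cor(s_strict$score, locus)), abs(cor(s_all$score, locus)))
})

test_that("sumstats and genotype I/O round-trip through text formats", {
  g <- simulate_genotypes(6, 8, seed = 67)
  ss <- simulate_summary_stats(g, rnorm(8, 0, 0.05), 1e4, seed = 68)
  tf <- tempfile(fileext = ".tsv")
  write_sumstats(ss, tf)
  ss2 <- read_sumstats(tf)
  expect_equal(ss2$BETA, ss$BETA, tolerance = 1e-12)
  expect_identical(ss2$SNP, ss$SNP)

  td <- tempfile(fileext = ".tsv")
  write_dosage_tsv(g, td)
  g2 <- read_dosage_tsv(td)
  expect_equal(unname(g2$dosage), unname(g$dosage))
  expect_identical(g2$snps$id, g$snps$id)

  tv <- tempfile(fileext = ".vcf")
  write_vcf(g, tv)
  g3 <- read_vcf_dosage(tv)
  expect_equal(unname(g3$dosage), unname(g$dosage), tolerance = 1e-6)
  expect_identical(g3$snps$a1, g$snps$a1)   # ALT carries the effect allele
})
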