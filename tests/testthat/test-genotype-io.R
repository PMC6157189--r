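# Genotype input, variant filtering, MAF-based imputation.

test_that("VCF genotypes are read as minor-allele dosages with missing calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeTinyVcf(path, c("A", "B", "C"), c(
    vcfRecord("1", 100, "rs1", "A", "G", c("0/1", "0/0", "1/1")),
    vcfRecord("1", 200, "rs2", "C", "T", c("./.", "0|1", "0/0")),
    vcfRecord("1", 300, "rs3", "G", "A", c("1/1", "1/1", "0/1"))))
  g <- readGenotypes(path, "vcf")
  d <- dosages(g)
  expect_equal(rownames(d), c("A", "B", "C"))
  expect_equal(unname(d[, "rs1"]), c(1, 0, 2))       # het counts 1
  expect_true(is.na(d["A", "rs2"]))                  # ./. is missing
  expect_equal(unname(d["B", "rs2"]), 1)             # phased sep accepted
  # rs3 alt frequency 5/6 > 0.5: re-oriented so dosage counts the minor (ref)
  expect_equal(unname(d[, "rs3"]), c(0, 0, 1))
  expect_equal(snpInfo(g)$maf, c(0.5, 0.25, 1 / 6), tolerance = 1e-12)
  expect_true(all(snpInfo(g)$maf <= 0.5))
})

test_that("malformed VCF genotypes fail with record and sample named", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeTinyVcf(path, c("A", "B"),
               vcfRecord("1", 100, "rs1", "A", "G", c("0/1/1", "0/0")))
  expect_error(readGenotypes(path, "vcf"), "non-diploid.*rs1.*sample A")
  writeTinyVcf(path, c("A", "B"),
               vcfRecord("1", 100, "rs1", "A", "G", c("./0", "0/0")))
  expect_error(readGenotypes(path, "vcf"), "half-missing.*rs1.*sample A")
  writeTinyVcf(path, c("A", "B"), c(
    vcfRecord("1", 100, "rs1", "A", "G,T", c("0/1", "0/0")),
    vcfRecord("1", 200, "rs2", "C", "T", c("0/1", "1/1"))))
  expect_error(readGenotypes(path, "vcf"), "multiallelic")
  g <- readGenotypes(path, "vcf", multiallelic = "drop")
  expect_equal(snpInfo(g)$id, "rs2")
  expect_error(readGenotypes(withr::local_tempfile(), "vcf"), "cannot read")
})

test_that("PLINK fileset round-trips the simulator's in-memory matrix", {
  sim <- simulateGenotypes(pedigreeSpec(20, "nuclear", nSnps = 30, seed = 5))
  prefix <- file.path(withr::local_tempdir(), "trio")
  writePlink(sim$genotypes, prefix)
  g2 <- readGenotypes(prefix, "plink-bed")
  expect_identical(dosages(g2), dosages(sim$genotypes))
  expect_equal(snpInfo(g2)$pos, snpInfo(sim$genotypes)$pos)
  expect_error(readGenotypes(file.path(withr::local_tempdir(), "nope"),
                             "plink-bed"), "incomplete")
})

test_that("PLINK codec preserves missing calls and odd sample counts", {
  co <- unrelatedCohort(n = 13, p = 7, seed = 3)   # n %% 4 != 0 pads bytes
  d <- dosages(co$g)
  d[2, 3] <- NA; d[13, 7] <- NA
  g <- GenotypeMatrix(d, as.data.frame(snpInfo(co$g)[, 1:5]))
  prefix <- file.path(withr::local_tempdir(), "odd")
  writePlink(g, prefix)
  expect_identical(dosages(readGenotypes(prefix, "plink-bed")), dosages(g))
})

test_that("variant filters are strict on both thresholds and idempotent", {
  n <- 100
  dos <- cbind(                       # engineered exact allele counts
    exact05 = c(rep(0, n / 2), rep(1, n / 2)),          # maf exactly 0.25
    keep1 = rep(c(0, 1, 1, 2), n / 4),                  # maf 0.5
    exactMiss = rep(c(0, 0, 1, 2), n / 4),              # maf 0.375 (pre-NA)
    keep2 = rep(c(0, 1, 2, 0, 1, 2, 1, 2, 1, 1), n / 10), # maf ~0.45
    rare = c(rep(1, 4), rep(0, n - 4)))                 # maf 0.02
  rownames(dos) <- sprintf("S%03d", 1:n)
  si <- data.frame(id = colnames(dos), chrom = "1", pos = 1:5 * 100,
                   ref = "A", alt = "B")
  dos[1, "exactMiss"] <- NA                             # missing exactly 1%
  g <- GenotypeMatrix(dos, si)
  expect_equal(snpInfo(g)$missRate[3], 0.01)

  f <- filterVariants(g, mafMin = 0.25, missMax = 0.01)
  ids <- snpInfo(f)$id
  expect_false("exact05" %in% ids)    # maf == threshold: removed (strict >)
  expect_false("exactMiss" %in% ids)  # missing == threshold: removed (strict <)
  expect_false("rare" %in% ids)
  expect_equal(ids, c("keep1", "keep2"))                # order preserved
  expect_identical(dosages(filterVariants(f, 0.25, 0.01)), dosages(f))

  # vacuous thresholds keep everything complete
  gc <- imputeMissing(g, seed = 1)
  expect_equal(snpInfo(filterVariants(gc, 0, 1))$id, snpInfo(g)$id)

  expect_warning(filterVariants(g, missMax = 0), class = "pedaSPU_empty_filter")
})

test_that("imputation is seeded, Binomial(2, maf), and leaves observed calls", {
  set.seed(7)
  n <- 60
  dos <- cbind(a = rbinom(n, 2, 0.3), zero = rep(0, n), b = rbinom(n, 2, 0.45))
  dos[c(3, 10), "a"] <- NA
  dos[5, "zero"] <- NA
  rownames(dos) <- sprintf("S%03d", 1:n)
  g <- GenotypeMatrix(dos, data.frame(id = colnames(dos), chrom = "1",
                                      pos = c(100, 200, 300), ref = "A",
                                      alt = "B"))
  out1 <- imputeMissing(g, seed = 9)
  out2 <- imputeMissing(g, seed = 9)
  expect_identical(dosages(out1), dosages(out2))        # deterministic
  expect_false(anyNA(dosages(out1)))
  obs <- !is.na(dos)
  expect_identical(dosages(out1)[obs], dos[obs])        # observed untouched
  expect_equal(dosages(out1)[5, "zero"], 0)             # maf 0 -> dosage 0

  # all-missing SNP is an error
  dos2 <- dos; dos2[, "b"] <- NA
  g2 <- GenotypeMatrix(dos2, as.data.frame(snpInfo(g)[, 1:5]))
  expect_error(imputeMissing(g2), "all genotypes missing")
})

test_that("imputed dosages have the Binomial mean and preserve the MAF", {
  # maf = 0.5, many missing entries: mean imputed dosage ~ 1.0 within 3 SE
  n <- 20000
  dos <- matrix(rep(c(0, 2), n / 2), ncol = 1,
                dimnames = list(sprintf("S%05d", 1:n), "snp1"))
  miss <- 5001:15000          # spans both homozygote classes equally
  dos[miss, 1] <- NA
  g <- GenotypeMatrix(dos, data.frame(id = "snp1", chrom = "1", pos = 1,
                                      ref = "A", alt = "B"))
  expect_equal(snpInfo(g)$maf, 0.5)
  out <- imputeMissing(g, seed = 4)
  se <- sqrt(2 * 0.5 * 0.5 / length(miss))
  expect_lt(abs(mean(dosages(out)[miss, 1]) - 1.0), 3 * se)

  # MAF drift after imputation bounded by binomial sampling error (4 SE)
  co <- unrelatedCohort(n = 500, p = 20, seed = 11)
  d <- dosages(co$g)
  set.seed(12)
  hole <- matrix(runif(length(d)) < 0.05, nrow(d))
  d[hole] <- NA
  g2 <- GenotypeMatrix(d, as.data.frame(snpInfo(co$g)[, 1:5]))
  mafBefore <- snpInfo(g2)$maf
  out2 <- imputeMissing(g2, seed = 13)
  mafAfter <- snpInfo(out2)$maf
  nmiss <- colSums(hole)
  bound <- 4 * sqrt(2 * mafBefore * (1 - mafBefore) * pmax(nmiss, 1)) /
    (2 * nrow(d))
  expect_true(all(abs(mafAfter - mafBefore) <= pmax(bound, 1e-12)))
})

test_that("trait tables drop incomplete samples and build the design matrix", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(sample = c("A", "B", "C", "D"),
                    trait = c(1.2, NA, 0.8, 1.5),
                    sex = c(0, 1, 1, NA), age = c(40, 50, 60, 45))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- readTraitTable(path, "trait", c("sex", "age"))
  expect_equal(names(tt$y), c("A", "C"))
  expect_equal(tt$dropped, c("B", "D"))
  expect_equal(colnames(tt$X), c("(Intercept)", "sex", "age"))
  expect_error(readTraitTable(path, "nope"), "lacks column")
})
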