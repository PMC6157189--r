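#' Specify a synthetic pedigree genotype study
#'
#' Describes a collection of independent families of identical structure with
#' independent biallelic SNPs. Founder allele frequencies are drawn uniformly
#' from `mafRange`; offspring genotypes follow Mendelian transmission of one
#' allele per parent per SNP (no linkage, no LD).
#'
#' Structures:
#' \describe{
#'   \item{`sib-pairs`}{two full siblings per family are sampled; their
#'     (unsampled) parents are simulated to generate the transmission.}
#'   \item{`nuclear`}{two founder parents plus `nKids` children, all sampled.}
#'   \item{`three-generation`}{four grandparents, two parents, two children
#'     (8 sampled individuals per family).}
#' }
#'
#' @param nFamilies number of independent families.
#' @param structure one of `"sib-pairs"`, `"nuclear"`, `"three-generation"`.
#' @param nSnps number of independent SNPs.
#' @param nKids children per nuclear family.
#' @param mafRange length-2 range for founder minor allele frequencies.
#' @param seed RNG seed for genotype generation.
#' @return a `pedigreeSpec` list, input to [simulateGenotypes()].
#' @export
pedigreeSpec <- function(nFamilies, structure = c("sib-pairs", "nuclear",
                         "three-generation"), nSnps, nKids = 2,
                         mafRange = c(0.05, 0.5), seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(nFamilies >= 1, nSnps >= 1, nKids >= 1,
            length(mafRange) == 2, mafRange[1] > 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2])
  structure(list(nFamilies = as.integer(nFamilies), structure = structure,
                 nSnps = as.integer(nSnps), nKids = as.integer(nKids),
                 mafRange = as.numeric(mafRange), seed = as.integer(seed)),
            class = "pedigreeSpec")
}

# Family template: pedigree rows (father/mother as 0 = founder) and which
# members enter the sample. Ordered so parents precede offspring.
.familyTemplate <- function(structure, nKids) {
  switch(structure,
    "sib-pairs" = list(
      ped = data.frame(member = c("p1", "p2", "k1", "k2"),
                       father = c(0L, 0L, 1L, 1L), mother = c(0L, 0L, 2L, 2L)),
      sampled = c(FALSE, FALSE, TRUE, TRUE)),
    "nuclear" = {
      m <- c("p1", "p2", paste0("k", seq_len(nKids)))
      list(ped = data.frame(member = m,
                            father = c(0L, 0L, rep(1L, nKids)),
                            mother = c(0L, 0L, rep(2L, nKids))),
           sampled = rep(TRUE, nKids + 2))
    },
    "three-generation" = list(
      ped = data.frame(
        member = c("gp1", "gp2", "gp3", "gp4", "f", "m", "k1", "k2"),
        father = c(0L, 0L, 0L, 0L, 1L, 3L, 5L, 5L),
        mother = c(0L, 0L, 0L, 0L, 2L, 4L, 6L, 6L)),
      sampled = rep(TRUE, 8)))
}

# Additive relationship matrix (correlation scale, self = 1) by the tabular
# method; founders are assumed unrelated and non-inbred.
.additiveRelationship <- function(father, mother) {
  n <- length(father)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- father[i]; m <- mother[i]
    A[i, i] <- if (f > 0L) 1 + 0.5 * A[f, m] else 1
    j <- seq_len(i - 1L)
    if (length(j)) {
      aij <- if (f > 0L) 0.5 * (A[j, f, drop = TRUE] + A[j, m, drop = TRUE])
             else 0
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

#' Simulate pedigree genotypes and the pedigree-theoretic kinship
#'
#' Founders are drawn under Hardy-Weinberg equilibrium at each SNP's allele
#' frequency; each offspring receives one uniformly chosen allele per parent
#' per SNP. Returns the sampled individuals' dosage matrix together with the
#' block-diagonal expected relationship matrix on the correlation scale
#' (self = 1, full sibs and parent-offspring = 0.5, unrelated = 0).
#'
#' @param spec a [pedigreeSpec()].
#' @return list with elements `genotypes` ([GenotypeMatrix-class]),
#'   `kinship` ([KinshipMatrix-class], pedigree-expected), and `pedigree`
#'   (data.frame of sampled individuals with family and parent labels).
#' @export
simulateGenotypes <- function(spec) {
  stopifnot(inherits(spec, "pedigreeSpec"))
  tpl <- .familyTemplate(spec$structure, spec$nKids)
  ped <- tpl$ped
  m <- nrow(ped)                      # members per family incl. unsampled
  nFam <- spec$nFamilies
  p <- spec$nSnps
  withSeed(spec$seed, {
    maf <- runif(p, spec$mafRange[1], spec$mafRange[2])
    nTot <- nFam * m
    # haplotype matrices over all family members
    h1 <- matrix(0L, nTot, p)
    h2 <- matrix(0L, nTot, p)
    idx <- function(fam, member) (fam - 1L) * m + member
    founders <- which(ped$father == 0L)
    for (fam in seq_len(nFam)) {
      for (mb in founders) {
        h1[idx(fam, mb), ] <- rbinom(p, 1L, maf)
        h2[idx(fam, mb), ] <- rbinom(p, 1L, maf)
      }
      for (mb in which(ped$father > 0L)) {
        fi <- idx(fam, ped$father[mb]); mi <- idx(fam, ped$mother[mb])
        pickF <- runif(p) < 0.5
        pickM <- runif(p) < 0.5
        h1[idx(fam, mb), ] <- ifelse(pickF, h1[fi, ], h2[fi, ])
        h2[idx(fam, mb), ] <- ifelse(pickM, h1[mi, ], h2[mi, ])
      }
    }
    keep <- as.vector(vapply(seq_len(nFam),
                             function(fam) idx(fam, which(tpl$sampled)),
                             integer(sum(tpl$sampled))))
    dos <- h1[keep, , drop = FALSE] + h2[keep, , drop = FALSE]
  })
  famId <- rep(seq_len(nFam), each = sum(tpl$sampled))
  member <- rep(ped$member[tpl$sampled], nFam)
  ids <- sprintf("F%03d_%s", famId, member)
  rownames(dos) <- ids
  si <- data.frame(id = sprintf("snp%05d", seq_len(p)), chrom = "1",
                   pos = 10000L * seq_len(p), ref = "A", alt = "B",
                   stringsAsFactors = FALSE)
  # orient stored dosages to the minor allele (drift can push freq past 0.5)
  freq <- colMeans(dos) / 2
  flip <- which(freq > 0.5)
  if (length(flip)) {
    dos[, flip] <- 2 - dos[, flip]
    si$ref[flip] <- "B"; si$alt[flip] <- "A"
  }
  g <- GenotypeMatrix(dos, si)
  Afam <- .additiveRelationship(ped$father, ped$mother)[tpl$sampled,
                                                        tpl$sampled,
                                                        drop = FALSE]
  psi <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  k <- sum(tpl$sampled)
  for (fam in seq_len(nFam)) {
    r <- (fam - 1L) * k + seq_len(k)
    psi[r, r] <- Afam
  }
  list(genotypes = g, kinship = KinshipMatrix(psi),
       pedigree = data.frame(id = ids, family = famId, member = member,
                             stringsAsFactors = FALSE))
}

#' Simulate a quantitative trait from the linear mixed model
#'
#' Generates y = X alpha + G beta + b + eps with b ~ N(0, tau * Psi) drawn
#' through a PSD square root of Psi and eps ~ N(0, phi * I). With
#' `beta = 0` this is a null dataset for type-I error studies.
#'
#' @param g a [GenotypeMatrix-class] (may have zero columns when beta is 0).
#' @param psi a [KinshipMatrix-class] aligned with `g`.
#' @param X covariate matrix (n x q) with sample rownames; use
#'   [simulateCovariates()] or an intercept-only matrix.
#' @param tau,phi variance components of the random intercept and the error.
#' @param alpha fixed effects (length q).
#' @param beta SNP effects (length `ncol(dosages(g))`, or a named sparse
#'   vector indexed by SNP id); defaults to all zero.
#' @param seed RNG seed.
#' @return named numeric trait vector.
#' @export
simulateTrait <- function(g, psi, X, tau, phi, alpha = rep(0, ncol(X)),
                          beta = NULL, seed = 1L) {
  stopifnot(is(g, "GenotypeMatrix"), is(psi, "KinshipMatrix"), tau >= 0,
            phi > 0)
  ids <- sampleIds(g)
  checkAligned(ids, sampleIds(psi), rownames(X), what = "genotypes/psi/X")
  n <- length(ids)
  p <- ncol(dosages(g))
  b0 <- rep(0, p)
  if (!is.null(beta)) {
    if (!is.null(names(beta))) {
      j <- match(names(beta), snpInfo(g)$id)
      if (anyNA(j)) stop("beta names not found among SNP ids")
      b0[j] <- beta
    } else {
      stopifnot(length(beta) == p)
      b0 <- beta
    }
  }
  e <- eigen(kinshipMatrix(psi), symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("psi is not positive semi-definite; run makePSD() first")
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  y <- withSeed(seed, {
    b <- sqrt(tau) * as.vector(sq %*% rnorm(n))
    eps <- rnorm(n, sd = sqrt(phi))
    as.vector(X %*% alpha) +
      (if (p) as.vector(dosages(g) %*% b0) else 0) + b + eps
  })
  setNames(y, ids)
}

#' Simulate the covariate design used throughout the package
#'
#' Intercept, a binary sex-like indicator and a continuous age-like
#' covariate, mirroring a typical GWAS adjustment set.
#'
#' @param samples sample ids.
#' @param seed RNG seed.
#' @return n x 3 design matrix with columns `(Intercept)`, `sex`, `age`.
#' @export
simulateCovariates <- function(samples, seed = 1L) {
  n <- length(samples)
  withSeed(seed, {
    X <- cbind(`(Intercept)` = 1, sex = rbinom(n, 1, 0.5),
               age = rnorm(n, 50, 10))
  })
  rownames(X) <- samples
  X
}

#' Write a named, fully reproducible test fixture to disk
#'
#' Emits PLINK bed/bim/fam genotypes, a trait/covariate table, a kinship
#' matrix, a BED gene annotation and a yaml manifest recording every seed
#' and parameter. Scenarios:
#' \describe{
#'   \item{`null-small`}{200 samples (100 sib-pair families), 50 SNPs,
#'     5 genes of 10 SNPs, no genetic effects; end-to-end smoke data.}
#'   \item{`power-dense`}{one 10-SNP target gene in which every SNP carries
#'     an equal effect, plus 4 null genes.}
#'   \item{`power-sparse`}{as `power-dense` but a single causal SNP of the
#'     ten carries the whole effect.}
#'   \item{`typeI-suite`}{20 null genes of 10 SNPs for family-wise error
#'     studies.}
#' }
#'
#' @param name scenario label.
#' @param outDir output directory (created if needed).
#' @param seed master seed recorded in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
makeFixture <- function(name, outDir, seed = 1L) {
  scenarios <- c("null-small", "power-dense", "power-sparse", "typeI-suite")
  if (!name %in% scenarios)
    stop("unknown scenario '", name, "'; available: ",
         paste(scenarios, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nGenes <- switch(name, "null-small" = 5L, "typeI-suite" = 20L, 5L)
  snpsPerGene <- 10L
  nSnps <- if (name == "null-small") 50L else nGenes * snpsPerGene
  spec <- pedigreeSpec(nFamilies = 100L, structure = "sib-pairs",
                       nSnps = nSnps, seed = seed)
  sim <- simulateGenotypes(spec)
  g <- sim$genotypes
  X <- simulateCovariates(sampleIds(g), seed = seed + 1L)
  beta <- NULL
  causal <- character(0)
  effect <- 0
  if (name == "power-dense") {
    causal <- snpInfo(g)$id[1:10]
    effect <- 0.25
    beta <- setNames(rep(effect, 10), causal)
  } else if (name == "power-sparse") {
    causal <- snpInfo(g)$id[1]
    effect <- 0.7
    beta <- setNames(effect, causal)
  }
  y <- simulateTrait(g, sim$kinship, X, tau = 1, phi = 1,
                     alpha = c(0, 0.5, 0.01), beta = beta, seed = seed + 2L)
  # genes tile the SNPs; window flank 0 keeps membership unambiguous
  pos <- snpInfo(g)$pos
  gstart <- pos[seq(1, nSnps, by = snpsPerGene)]
  gend <- pos[pmin(seq(snpsPerGene, nSnps + snpsPerGene - 1,
                       by = snpsPerGene), nSnps)]
  genes <- data.frame(geneId = sprintf("gene%02d", seq_along(gstart)),
                      chrom = "1", start = gstart, end = gend,
                      stringsAsFactors = FALSE)
  writePlink(g, file.path(outDir, "genotypes"), family = sim$pedigree$family)
  tab <- data.frame(sample = sampleIds(g), trait = y,
                    sex = X[, "sex"], age = X[, "age"])
  write.table(tab, file.path(outDir, "trait.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeKinship(sim$kinship, file.path(outDir, "kinship.tsv"))
  # BED: 0-based half-open
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$geneId)
  write.table(bed, file.path(outDir, "genes.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- list(scenario = name, seed = as.integer(seed),
                   nFamilies = 100L, structure = "sib-pairs",
                   nSnps = nSnps, nGenes = nrow(genes),
                   tau = 1, phi = 1, alpha = c(0, 0.5, 0.01),
                   causalSnps = as.list(causal), effectSize = effect,
                   files = list(plink = "genotypes.{bed,bim,fam}",
                                trait = "trait.tsv", kinship = "kinship.tsv",
                                genes = "genes.bed"))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}
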