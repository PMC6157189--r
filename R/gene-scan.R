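#' Scan configuration
#'
#' Bundles and validates every tunable of the genome-wide gene-level scan.
#' Round-trips losslessly through yaml via [writeScanConfig()] /
#' [readScanConfig()].
#'
#' @param alpha family-wise significance level for the Bonferroni
#'   adjustment over tested genes.
#' @param flank gene window extension in base pairs on each side of the
#'   annotated region.
#' @param mafMin,missMax variant filters (see [filterVariants()]).
#' @param gammas SPU gamma set.
#' @param B initial Monte-Carlo sample size per gene.
#' @param maxB escalation cap: a gene with p_aSPU < 5/B is retested at
#'   10x B until the p-value is resolvable or `maxB` is reached.
#' @param seed master seed; per-gene seeds derive deterministically from it
#'   and the gene id.
#' @param snpAlpha genome-wide single-SNP significance threshold.
#' @return validated `scanConfig` list.
#' @export
scanConfig <- function(alpha = 0.05, flank = 10000L, mafMin = 0.05,
                       missMax = 0.01, gammas = defaultGammas(),
                       B = 1000L, maxB = 100000L, seed = 1L,
                       snpAlpha = 5e-8) {
  stopifnot(alpha > 0, alpha < 1, flank >= 0, mafMin >= 0, mafMin < 0.5,
            missMax >= 0, missMax <= 1, B >= 99, maxB >= B,
            snpAlpha > 0, snpAlpha < 1)
  checkGammas(gammas)
  structure(list(alpha = alpha, flank = as.integer(flank), mafMin = mafMin,
                 missMax = missMax, gammas = gammas, B = as.integer(B),
                 maxB = as.integer(maxB), seed = as.integer(seed),
                 snpAlpha = snpAlpha),
            class = "scanConfig")
}

#' @rdname scanConfig
#' @param cfg a `scanConfig`.
#' @param path yaml file path.
#' @export
writeScanConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "scanConfig"))
  out <- unclass(cfg)
  out$gammas <- ifelse(is.infinite(out$gammas), "inf",
                       as.character(out$gammas))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname scanConfig
#' @export
readScanConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  g <- raw$gammas
  g <- ifelse(g == "inf", Inf, suppressWarnings(as.numeric(g)))
  do.call(scanConfig, c(raw[setdiff(names(raw), "gammas")],
                        list(gammas = g)))
}

#' Read a gene annotation table
#'
#' Accepts BED (0-based half-open; converted to 1-based inclusive
#' internally) or a 1-based delimited table with a header row containing
#' columns `geneId`, `chrom`, `start`, `end`. The convention is named
#' explicitly by `format`, never guessed.
#'
#' @param path file path.
#' @param format `"bed"` or `"table1"`.
#' @return data.frame with 1-based inclusive `start`/`end`.
#' @export
readGeneTable <- function(path, format = c("bed", "table1")) {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("BED gene file needs chrom,start,end,name")
    data.frame(geneId = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
               start = as.integer(tab[[2]]) + 1L, end = as.integer(tab[[3]]),
               stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("geneId", "chrom", "start", "end")
    if (!all(need %in% colnames(tab)))
      stop("gene table lacks column(s): ",
           paste(setdiff(need, colnames(tab)), collapse = ", "))
    tab <- tab[, need]
    tab$geneId <- as.character(tab$geneId)
    tab$chrom <- as.character(tab$chrom)
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
    tab
  }
}

#' Assign SNPs to gene windows
#'
#' A SNP belongs to gene g iff it lies on the same chromosome within
#' [start - flank, end + flank], both ends inclusive. Genes may overlap and
#' a SNP may belong to several genes; genes with no SNPs are returned as
#' empty index vectors (scan drivers skip them).
#'
#' @param snps SNP metadata (the `snpInfo` of a [GenotypeMatrix-class], or
#'   any data.frame with `chrom` and `pos`).
#' @param genes gene data.frame (`geneId`, `chrom`, `start`, `end`),
#'   1-based inclusive.
#' @param flank window extension in base pairs (default 10,000).
#' @return named list mapping geneId to the ordered integer indices of its
#'   SNPs in `snps`.
#' @export
assignSnpsToGenes <- function(snps, genes, flank = 10000L) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("chrom", "pos") %in% colnames(snps)),
            all(c("geneId", "chrom", "start", "end") %in% colnames(genes)),
            flank >= 0, all(genes$start <= genes$end))
  out <- setNames(vector("list", nrow(genes)), genes$geneId)
  if (!nrow(snps)) {
    out[] <- list(integer(0))
    return(out)
  }
  lev <- union(unique(as.character(snps$chrom)),
               unique(as.character(genes$chrom)))
  snpGr <- GenomicRanges::GRanges(factor(snps$chrom, lev),
                                  IRanges::IRanges(snps$pos, width = 1))
  geneGr <- GenomicRanges::GRanges(factor(genes$chrom, lev),
                                   IRanges::IRanges(pmax(genes$start - flank, 1L),
                                                    genes$end + flank))
  hits <- GenomicRanges::findOverlaps(snpGr, geneGr)
  for (i in seq_len(nrow(genes)))
    out[[i]] <- sort(S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == i])
  out
}

#' Genome-wide gene-level scan
#'
#' Drives the full pipeline over a gene list: fits the null model exactly
#' once, then per gene computes scores, the aSPU family and the
#' multivariate score test. Per-gene Monte-Carlo seeds derive from the
#' master seed and a stable hash of the gene id, so the scan is
#' reproducible and independent of gene order, and any gene rerun
#' standalone via [deriveGeneSeed()] matches the scan. A gene whose test
#' fails numerically is reported as missing, not fatal.
#'
#' @param g complete [GenotypeMatrix-class] (filtered and imputed).
#' @param y named trait vector.
#' @param X covariate design matrix.
#' @param psi [KinshipMatrix-class].
#' @param genes gene data.frame (`geneId`, `chrom`, `start`, `end`).
#' @param cfg [scanConfig()].
#' @return list of class `aspuScan`: `results` (one row per tested gene
#'   with p_SPU*, p_aSPU, p_score, B, seed), `fit` (the null model),
#'   `nTested`, `bonferroni` (alpha / nTested), `skipped` (genes without
#'   SNPs), `failed` (gene -> error message), `config`.
#' @export
runScan <- function(g, y, X, psi, genes, cfg = scanConfig()) {
  stopifnot(is(g, "GenotypeMatrix"), inherits(cfg, "scanConfig"))
  checkAligned(sampleIds(g), names(y), rownames(X), sampleIds(psi),
               what = "genotypes/y/X/psi")
  fit <- fitNull(y, X, psi)
  map <- assignSnpsToGenes(snpInfo(g), genes, flank = cfg$flank)
  skipped <- names(map)[lengths(map) == 0]
  tested <- names(map)[lengths(map) > 0]
  failed <- character(0)
  rows <- vector("list", length(tested))
  gnames <- paste0("p_SPU", ifelse(is.infinite(cfg$gammas), "inf",
                                   as.character(cfg$gammas)))
  for (k in seq_along(tested)) {
    gid <- tested[k]
    gi <- match(gid, genes$geneId)
    idx <- map[[gid]]
    gseed <- deriveGeneSeed(cfg$seed, gid)
    row <- tryCatch({
      ss <- computeScores(fit, dosages(g)[, idx, drop = FALSE])
      B <- cfg$B
      repeat {
        res <- aspuTest(ss, gammas = cfg$gammas, B = B, seed = gseed,
                        geneId = gid)
        if (res@aspuPvalue >= 5 / B || B >= cfg$maxB) break
        B <- min(B * 10L, cfg$maxB)
      }
      c(list(geneId = gid, chrom = genes$chrom[gi], start = genes$start[gi],
             end = genes$end[gi], nSnps = length(idx)),
        setNames(as.list(unname(res@spuPvalues)), gnames),
        list(p_aSPU = res@aspuPvalue, p_score = res@scorePvalue,
             B = res@B, seed = gseed))
    }, error = function(e) {
      failed[gid] <<- conditionMessage(e)
      c(list(geneId = gid, chrom = genes$chrom[gi], start = genes$start[gi],
             end = genes$end[gi], nSnps = length(idx)),
        setNames(as.list(rep(NA_real_, length(gnames))), gnames),
        list(p_aSPU = NA_real_, p_score = NA_real_, B = NA_integer_,
             seed = gseed))
    })
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(geneId = character(0))
  nTested <- sum(!is.na(results$p_aSPU))
  bonf <- if (nTested > 0) cfg$alpha / nTested else NA_real_
  structure(list(results = results, fit = fit, nTested = nTested,
                 bonferroni = bonf, skipped = skipped, failed = failed,
                 config = cfg),
            class = "aspuScan")
}

#' @export
print.aspuScan <- function(x, ...) {
  cat(sprintf("aSPU gene-level scan: %d genes tested (%d without SNPs%s)\n",
              x$nTested, length(x$skipped),
              if (length(x$failed)) paste0(", ", length(x$failed), " failed")
              else ""))
  cat(sprintf("  Bonferroni threshold: %.3g (alpha = %g)\n", x$bonferroni,
              x$config$alpha))
  r <- x$results[!is.na(x$results$p_aSPU), , drop = FALSE]
  if (nrow(r)) {
    r <- r[order(r$p_aSPU), , drop = FALSE]
    sig <- sum(r$p_aSPU <= x$bonferroni)
    cat(sprintf("  significant genes: %d; top hits:\n", sig))
    print(head(r[, c("geneId", "chrom", "nSnps", "p_aSPU", "p_score")], 5),
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot-ready Manhattan table
#'
#' Flattens scan results (gene level) or a single-SNP scan table into
#' (chrom, position, -log10 p) rows sorted by chromosome then position.
#' Genes are placed at their window midpoint. Rows with missing p-values
#' are omitted and their count attached as attribute `nMissing`.
#'
#' @param results an `aspuScan` object, its `results` data.frame, or a
#'   [singleSnpScan()] table.
#' @param pColumn which p-value column to plot (default `p_aSPU` for gene
#'   results, `p` for SNP tables).
#' @return data.frame `id`, `chrom`, `pos`, `negLog10P`.
#' @export
manhattanTable <- function(results, pColumn = NULL) {
  if (inherits(results, "aspuScan")) results <- results$results
  results <- as.data.frame(results)
  if (!nrow(results)) {
    warning("no results to tabulate")
    out <- data.frame(id = character(0), chrom = character(0),
                      pos = numeric(0), negLog10P = numeric(0))
    attr(out, "nMissing") <- 0L
    return(out)
  }
  isGene <- "geneId" %in% colnames(results)
  if (is.null(pColumn)) pColumn <- if (isGene) "p_aSPU" else "p"
  p <- results[[pColumn]]
  pos <- if (isGene) (results$start + results$end) / 2 else results$pos
  id <- if (isGene) results$geneId else results$id
  keep <- !is.na(p)
  out <- data.frame(id = id[keep], chrom = as.character(results$chrom[keep]),
                    pos = pos[keep], negLog10P = -log10(p[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nMissing") <- sum(!keep)
  out
}
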