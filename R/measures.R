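.MEASURE_METHODS <- c("minP", "2ndP", "simP", "fishP")

.check_pvalues <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]; zeros must be pre-clamped by the caller",
         call. = FALSE)
  as.numeric(p)
}

#' Aggregate SNP association p-values into one gene effect measure
#'
#' Given the association p-values of the K SNPs assigned to a gene, returns a
#' single p-value-scale measure of the gene's effect:
#' \describe{
#'   \item{minP}{the smallest p-value, \eqn{p_{(1)}}.}
#'   \item{2ndP}{the second-smallest p-value, \eqn{p_{(2)}}; less sensitive
#'     to a single outlying SNP than minP. With a single SNP the default
#'     falls back to \eqn{p_{(1)}} (see `strict`).}
#'   \item{simP}{Simes' combination adjusted for the number of SNPs,
#'     \eqn{\min_i \{K \, p_{(i)} / i\}}, capped at 1.}
#'   \item{fishP}{Fisher's combination: the upper-tail probability of a
#'     chi-square with 2K degrees of freedom at \eqn{-2\sum_i \ln p_i}.
#'     For a single SNP this equals the SNP's p-value exactly.}
#' }
#'
#' @param pvalues numeric vector of SNP p-values in (0, 1]. Exact zeros are
#'   rejected, not clamped: clamp upstream if your association tool emits 0.
#' @param method one of `"minP"`, `"2ndP"`, `"simP"`, `"fishP"`.
#' @param strict for `2ndP` only: if `TRUE`, a single-SNP gene yields `NA`
#'   (the gene is dropped by [compute_gene_measures()]); if `FALSE`
#'   (default), \eqn{p_{(1)}} is returned.
#' @return a single numeric in (0, 1] (or `NA` under `strict` 2ndP with
#'   K = 1).
#' @examples
#' gene_measure(c(0.01, 0.04, 0.9), "simP")  # 0.03
#' gene_measure(0.07, "fishP")               # 0.07
#' @export
gene_measure <- function(pvalues, method = c("minP", "2ndP", "simP", "fishP"),
                         strict = FALSE) {
  method <- match.arg(method)
  p <- .check_pvalues(pvalues)
  k <- length(p)
  switch(method,
    minP = min(p),
    `2ndP` = {
      if (k >= 2L) sort(p, partial = 2L)[2L]
      else if (strict) NA_real_
      else min(p)
    },
    simP = min(1, min(k * sort(p) / seq_len(k))),
    fishP = stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE))
}

#' Gene effect measures for all genes with mapped associations
#'
#' Joins a GWAS association table (rsid, pvalue) to SNP-gene pairs from
#' [snp_to_gene()]/[gene_to_snp()] and computes one measure per gene over the
#' SNPs that carry an association. SNP-gene pairs whose rsID has no
#' association are skipped and counted; a SNP shared by several overlapping
#' genes contributes to each of them.
#'
#' @param assoc data.frame with columns `rsid`, `pvalue` (values in (0, 1]).
#' @param pairs data.frame with columns `rsid`, `gene_id` (extra columns
#'   ignored).
#' @param method measure method, see [gene_measure()].
#' @param strict see [gene_measure()]; under strict `2ndP`, single-SNP genes
#'   are dropped.
#' @return data.frame with columns `gene_id`, `method`, `measure`, `n_snps`,
#'   `fallback` (logical: `2ndP` fell back to the minimum for a single-SNP
#'   gene). Attribute `"n_skipped"` counts pairs without an association.
#' @export
compute_gene_measures <- function(assoc, pairs,
                                  method = c("minP", "2ndP", "simP", "fishP"),
                                  strict = FALSE) {
  method <- match.arg(method)
  a <- data.table::as.data.table(assoc)[, .(rsid = as.character(rsid),
                                            pvalue = as.numeric(pvalue))]
  .check_pvalues(a$pvalue)
  pr <- data.table::as.data.table(pairs)[, .(rsid = as.character(rsid),
                                             gene_id = as.integer(gene_id))]
  pr <- unique(pr)
  m <- a[pr, on = "rsid", nomatch = NULL]
  n_skipped <- nrow(pr) - nrow(m)
  if (!nrow(m))
    stop("no association rsIDs overlap the SNP-gene pairs", call. = FALSE)
  out <- m[, .(measure = gene_measure(pvalue, method, strict = strict),
               n_snps = .N), by = gene_id]
  out[, fallback := method == "2ndP" & n_snps == 1L & !strict]
  out <- out[!is.na(measure)]
  out[, method := method]
  data.table::setorder(out, gene_id)
  res <- as.data.frame(out[, .(gene_id, method, measure, n_snps, fallback)])
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Gene measures taken directly from gene-level p-values
#'
#' For expression studies and other gene-based tests the per-gene p-value is
#' itself the effect measure; this validates and repackages it.
#'
#' @param gene_pvalues data.frame with columns `gene_id`, `pvalue`
#'   (values in (0, 1]), or a path to a TSV with those columns.
#' @return data.frame with columns `gene_id`, `method` (`"direct"`),
#'   `measure`, `n_snps` (0), `fallback` (`FALSE`).
#' @export
direct_measures <- function(gene_pvalues) {
  if (is.character(gene_pvalues) && length(gene_pvalues) == 1L)
    gene_pvalues <- data.table::fread(gene_pvalues, sep = "\t", header = TRUE)
  g <- data.table::as.data.table(gene_pvalues)
  stopifnot(all(c("gene_id", "pvalue") %in% names(g)))
  g <- g[, .(gene_id = as.integer(gene_id), pvalue = as.numeric(pvalue))]
  .check_pvalues(g$pvalue)
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in gene-level p-value table", call. = FALSE)
  data.frame(gene_id = g$gene_id, method = "direct", measure = g$pvalue,
             n_snps = 0L, fallback = FALSE, stringsAsFactors = FALSE)
}

#' Uniform scores (U-scores) of gene measures
#'
#' The U-score of gene *i* with measure \eqn{M_i} among L measured genes is
#' the midrank-based empirical quantile
#' \deqn{U_i = \left(\sum_j I(M_j < M_i) + 0.5 \sum_j I(M_j = M_i)\right)/L,}
#' where both sums run over all L genes including *j = i* (so every
#' observation contributes 0.5 to its own tie count). U-scores lie in
#' `[0.5/L, (L - 0.5)/L]`, average exactly 0.5 for any input, and are
#' approximately Uniform(0, 1), making measures with heterogeneous null
#' distributions comparable on one scale: a U-score near 0 marks a gene
#' stronger than almost all others.
#'
#' @param x numeric vector of measures, or a data.frame with a `measure`
#'   column (e.g. from [compute_gene_measures()]).
#' @return for a numeric input, the numeric U-scores; for a data.frame, the
#'   same data.frame with a `uscore` column added.
#' @examples
#' uscore(c(0.1, 0.2, 0.3))  # 1/6, 1/2, 5/6
#' uscore(c(0.1, 0.1))       # 0.5, 0.5
#' @export
uscore <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("measure" %in% names(x))
    x$uscore <- uscore(x$measure)
    return(x)
  }
  m <- as.numeric(x)
  if (!length(m)) stop("no measures to score", call. = FALSE)
  if (anyNA(m)) stop("measures must not contain NA", call. = FALSE)
  (rank(m, ties.method = "average") - 0.5) / length(m)
}
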