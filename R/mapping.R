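#' Gene boundary specification
#'
#' Kilobases added beyond the transcribed span on each side, following
#' transcription direction: `up_kb` extends beyond the transcription start
#' site (TSS), `down_kb` beyond the transcription termination site (TTS).
#' The default of 2 kb on both sides is the conventional window for
#' assigning GWAS SNPs to nearby genes.
#'
#' @param up_kb,down_kb non-negative kilobases.
#' @return a `boundary_spec` list.
#' @export
boundary_spec <- function(up_kb = 2, down_kb = 2) {
  stopifnot(is.numeric(up_kb), is.numeric(down_kb), up_kb >= 0, down_kb >= 0)
  structure(list(up_kb = up_kb, down_kb = down_kb), class = "boundary_spec")
}

#' Retrieve SNP map positions
#'
#' Order-preserving lookup of rsIDs in one genome build; every input rsID
#' lands exactly once in either the matched table or the unmatched vector.
#'
#' @param kb a `gws_store` handle.
#' @param rsids character vector of rsIDs.
#' @param build genome build label (`"GRCh37"` or `"GRCh38"`).
#' @return list with `matched` (data.frame: rsid, build, chrom, pos, in input
#'   order) and `unmatched` (character vector).
#' @export
get_snp_map <- function(kb, rsids, build = "GRCh37") {
  .check_build(build)
  rsids <- as.character(rsids)
  hits <- .kb_query(kb, "SELECT rsid, build, chrom, pos FROM snpmaps
                         WHERE build = ?", params = list(build))
  idx <- match(rsids, hits$rsid)
  list(matched = as.data.frame(hits[idx[!is.na(idx)]]),
       unmatched = rsids[is.na(idx)])
}

#' Retrieve gene map records
#'
#' Accepts gene IDs and/or symbols; each identifier is looked up first as an
#' integer gene ID, then as a symbol. Order-preserving.
#'
#' @param kb a `gws_store` handle.
#' @param ids character or integer vector of gene IDs or symbols.
#' @param build genome build label.
#' @return list with `matched` (data.frame: gene_id, symbol, build, chrom,
#'   start, end, strand) and `unmatched`.
#' @export
get_gene_map <- function(kb, ids, build = "GRCh37") {
  .check_build(build)
  ids <- as.character(ids)
  g <- .kb_query(kb, "SELECT gene_id, symbol, build, chrom, start, end, strand
                      FROM genemaps WHERE build = ?", params = list(build))
  idx <- match(ids, as.character(g$gene_id))
  miss <- is.na(idx)
  idx[miss] <- match(ids[miss], g$symbol)
  list(matched = as.data.frame(g[idx[!is.na(idx)]]),
       unmatched = ids[is.na(idx)])
}

#' Extended gene interval under a boundary specification
#'
#' The transcribed span `[start, end]` is widened by `up_kb` kb on the TSS
#' side and `down_kb` kb on the TTS side. On the plus strand the TSS is at
#' `start`; on the minus strand it is at `end`, so the extensions swap ends.
#' The low bound is clamped at position 1.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (e.g. the `matched` component of [get_gene_map()]).
#' @param boundary a [boundary_spec()].
#' @return the input with columns `lo`, `hi` added.
#' @export
extended_interval <- function(genes, boundary = boundary_spec()) {
  up <- round(1000 * boundary$up_kb)
  dn <- round(1000 * boundary$down_kb)
  g <- data.table::as.data.table(genes)
  g[, `:=`(lo = ifelse(strand == "+", start - up, start - dn),
           hi = ifelse(strand == "+", end + dn, end + up))]
  g[, lo := pmax(1L, as.integer(lo))]
  g[, hi := as.integer(hi)]
  as.data.frame(g)
}

.classify_location <- function(pos, start, end, strand) {
  within <- pos >= start & pos <= end
  before <- pos < start
  ifelse(within, "within",
         ifelse((before & strand == "+") | (!before & strand == "-"),
                "upstream_flank", "downstream_flank"))
}

.snp_gene_pairs <- function(kb, build, boundary, rsids = NULL, gene_ids = NULL) {
  .check_build(build)
  build_label <- build
  snp <- .kb_query(kb, "SELECT rsid, chrom, pos FROM snpmaps WHERE build = ?",
                   params = list(build))
  gene <- .kb_query(kb, "SELECT gene_id, chrom, start, end, strand
                         FROM genemaps WHERE build = ?", params = list(build))
  if (!is.null(rsids)) snp <- snp[rsid %in% as.character(rsids)]
  if (!is.null(gene_ids)) gene <- gene[gene_id %in% as.integer(gene_ids)]
  empty <- data.frame(rsid = character(), gene_id = integer(),
                      build = character(), pos = integer(),
                      location_class = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(snp) || !nrow(gene)) return(empty)
  g <- data.table::as.data.table(extended_interval(gene, boundary))
  snp[, `:=`(p1 = pos, p2 = pos)]
  pairs <- snp[g, on = .(chrom, p1 >= lo, p2 <= hi), nomatch = NULL,
               .(rsid = x.rsid, gene_id = i.gene_id, pos = x.pos,
                 start = i.start, end = i.end, strand = i.strand)]
  if (!nrow(pairs)) return(empty)
  pairs[, location_class := .classify_location(pos, start, end, strand)]
  pairs[, build := build_label]
  data.table::setorder(pairs, gene_id, pos, rsid)
  as.data.frame(pairs[, .(rsid, gene_id, build, pos, location_class)])
}

#' Map SNPs to genes under flexible gene boundaries
#'
#' A SNP is paired with every gene whose extended interval (see
#' [extended_interval()]) contains its position on the same chromosome;
#' boundary positions are inclusive. A SNP may therefore map to zero, one or
#' several genes. `location_class` records whether the SNP lies within the
#' transcribed span or in the upstream/downstream flank (relative to the
#' gene's transcription direction).
#'
#' @param kb a `gws_store` handle.
#' @param rsids rsIDs to map, or `NULL` for every stored SNP.
#' @param build genome build label.
#' @param boundary a [boundary_spec()].
#' @return data.frame with columns `rsid`, `gene_id`, `build`, `pos`,
#'   `location_class`.
#' @export
snp_to_gene <- function(kb, rsids = NULL, build = "GRCh37",
                        boundary = boundary_spec()) {
  .snp_gene_pairs(kb, build, boundary, rsids = rsids)
}

#' Map genes to SNPs (inverse of [snp_to_gene()])
#'
#' @param kb a `gws_store` handle.
#' @param gene_ids gene IDs, or `NULL` for every stored gene.
#' @param build genome build label.
#' @param boundary a [boundary_spec()].
#' @return same shape as [snp_to_gene()]; on a shared store the two
#'   directions are exact transposes.
#' @export
gene_to_snp <- function(kb, gene_ids = NULL, build = "GRCh37",
                        boundary = boundary_spec()) {
  .snp_gene_pairs(kb, build, boundary, gene_ids = gene_ids)
}

#' Gene sets containing a gene
#'
#' @param kb a `gws_store` handle.
#' @param gene_id single integer gene ID.
#' @param category optional category filter.
#' @return ascending integer vector of PIDs (empty for an unknown gene).
#' @export
gene_to_sets <- function(kb, gene_id, category = NULL) {
  if (is.null(category)) {
    .kb_query(kb, "SELECT DISTINCT pid FROM geneInfo WHERE gene_id = ?
                   ORDER BY pid", params = list(as.integer(gene_id)))$pid
  } else {
    .kb_query(kb, "SELECT DISTINCT pid FROM geneInfo
                   WHERE gene_id = ? AND category = ? ORDER BY pid",
              params = list(as.integer(gene_id), category))$pid
  }
}

#' Member genes of a gene set
#'
#' @param kb a `gws_store` handle.
#' @param pid single integer pathway ID.
#' @return ascending integer vector of member gene IDs.
#' @export
set_to_genes <- function(kb, pid) {
  .kb_query(kb, "SELECT gene_id FROM geneInfo WHERE pid = ? ORDER BY gene_id",
            params = list(as.integer(pid)))$gene_id
}

#' SNPs in a genomic region
#'
#' @param kb a `gws_store` handle.
#' @param chrom chromosome label.
#' @param lo,hi 1-based closed region bounds, `lo <= hi`.
#' @param build genome build label.
#' @return data.frame of SNP records with `lo <= pos <= hi`.
#' @export
get_region_snps <- function(kb, chrom, lo, hi, build = "GRCh37") {
  .check_build(build)
  if (lo > hi) stop("region bounds: lo must be <= hi", call. = FALSE)
  as.data.frame(.kb_query(
    kb, "SELECT rsid, build, chrom, pos FROM snpmaps
         WHERE build = ? AND chrom = ? AND pos BETWEEN ? AND ? ORDER BY pos",
    params = list(build, as.character(chrom), as.integer(lo), as.integer(hi))))
}

#' Genes overlapping a genomic region
#'
#' A gene is reported when its `[start, end]` span shares at least one base
#' with the closed region `[lo, hi]`.
#'
#' @inheritParams get_region_snps
#' @return data.frame of gene records.
#' @export
get_region_genes <- function(kb, chrom, lo, hi, build = "GRCh37") {
  .check_build(build)
  if (lo > hi) stop("region bounds: lo must be <= hi", call. = FALSE)
  as.data.frame(.kb_query(
    kb, "SELECT gene_id, symbol, build, chrom, start, end, strand
         FROM genemaps
         WHERE build = ? AND chrom = ? AND start <= ? AND \"end\" >= ?
         ORDER BY start",
    params = list(build, as.character(chrom), as.integer(hi), as.integer(lo))))
}
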