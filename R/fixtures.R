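#' Specification of a synthetic annotation fixture
#'
#' Describes a toy genome (chromosomes, non-overlapping gene spans, uniform
#' SNP positions), gene-set collections per category, and GWAS/GWES result
#' files in which the member genes of "planted" sets carry association
#' signal. Non-planted p-values are Uniform(0, 1); planted gene p-values are
#' drawn from Beta(delta, 1), which is stochastically smaller than uniform
#' for `delta < 1` with a single strength knob (`delta = 1` reduces to the
#' uniform null).
#'
#' @param seed integer RNG seed; a fixed seed makes every output file
#'   byte-identical across runs.
#' @param n_chrom number of chromosomes (labelled `"1"`, `"2"`, ...).
#' @param n_genes total genes, packed round-robin across chromosomes.
#' @param n_snps total SNPs, positions uniform along each chromosome.
#' @param n_sets gene sets per category.
#' @param categories category labels, one GMT file each.
#' @param set_size members per set, sampled without replacement from the
#'   gene pool (sets may overlap one another).
#' @param planted_sets list of `list(pid =, delta =)`: global PID of a
#'   planted set and its signal strength `delta` in (0, 1]. Default plants
#'   PID 1 at `delta = 0.1`; use `list()` for a pure null fixture.
#' @param gene_span_kb length-2 range of gene span lengths (kb).
#' @param chrom_mb chromosome capacity in Mb; the generator stops with an
#'   error if the gene packing would exceed it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chrom = 2L, n_genes = 1000L,
                         n_snps = 4000L, n_sets = 200L, categories = "KEGG",
                         set_size = 30L,
                         planted_sets = list(list(pid = 1L, delta = 0.1)),
                         gene_span_kb = c(5, 50), chrom_mb = 30) {
  stopifnot(n_chrom >= 1, n_genes >= 1, n_snps >= 1, n_sets >= 1,
            set_size >= 1, set_size <= n_genes, length(gene_span_kb) == 2L)
  for (p in planted_sets)
    stopifnot(p$pid >= 1, p$pid <= n_sets * length(categories),
              p$delta > 0, p$delta <= 1)
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 n_genes = as.integer(n_genes), n_snps = as.integer(n_snps),
                 n_sets = as.integer(n_sets), categories = categories,
                 set_size = as.integer(set_size), planted_sets = planted_sets,
                 gene_span_kb = gene_span_kb, chrom_mb = chrom_mb),
            class = "fixture_spec")
}

.fmt_p <- function(p) sprintf("%.10g", p)

#' Generate a synthetic fixture file set
#'
#' Writes the full input dialect consumed by [kb_build()] and the analysis
#' functions: SNP-map and gene-map TSVs for both genome builds (GRCh38
#' positions are the GRCh37 ones under a per-chromosome offset, with a few
#' SNPs present only in GRCh37), one GMT per category, `gwas.tsv`
#' (rsid, pvalue), `gwes.tsv` (gene_id, pvalue) and `truth.json` recording
#' the planted sets. GWAS signal is planted on SNPs lying within 2 kb of a
#' planted gene's span; GWES signal directly on planted genes.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named list of the file paths plus `truth`.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  # --- gene layout: sequential packing with random gaps, per chromosome ---
  chrom_of <- rep_len(seq_len(spec$n_chrom), spec$n_genes)
  span <- round(1000 * stats::runif(spec$n_genes, spec$gene_span_kb[1L],
                                    spec$gene_span_kb[2L]))
  gap <- round(1000 * stats::runif(spec$n_genes, 2, 20))
  start <- integer(spec$n_genes); end <- integer(spec$n_genes)
  cursor <- rep(10000L, spec$n_chrom)
  for (i in seq_len(spec$n_genes)) {
    cc <- chrom_of[i]
    start[i] <- cursor[cc] + gap[i]
    end[i] <- start[i] + span[i]
    cursor[cc] <- end[i]
    if (end[i] > spec$chrom_mb * 1e6)
      stop("infeasible packing: chromosome ", cc, " exceeds ", spec$chrom_mb,
           " Mb at gene ", i, "; reduce n_genes or enlarge chrom_mb",
           call. = FALSE)
  }
  genes <- data.frame(
    gene_id = 1000L + seq_len(spec$n_genes),
    symbol = paste0("G", seq_len(spec$n_genes)),
    chrom = as.character(chrom_of), start = start, end = end,
    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  chrom_len <- vapply(seq_len(spec$n_chrom),
                      function(cc) max(end[chrom_of == cc]) + 10000L, numeric(1))

  # --- SNPs: uniform over chromosomes proportional to length ---
  snp_chrom <- sample(seq_len(spec$n_chrom), spec$n_snps, replace = TRUE,
                      prob = chrom_len / sum(chrom_len))
  snp_pos <- vapply(snp_chrom,
                    function(cc) sample.int(chrom_len[cc], 1L), integer(1))
  snps <- data.frame(rsid = paste0("rs", 100000L + seq_len(spec$n_snps)),
                     chrom = as.character(snp_chrom), pos = snp_pos,
                     stringsAsFactors = FALSE)
  # GRCh38: per-chromosome offset; the tail 2% of SNPs stay GRCh37-only.
  offset38 <- 5000L * seq_len(spec$n_chrom)
  snps38 <- snps
  snps38$pos <- snps$pos + offset38[snp_chrom]
  keep38 <- seq_len(floor(spec$n_snps * 0.98))
  snps38 <- snps38[keep38, ]
  genes38 <- genes
  genes38$start <- genes$start + offset38[chrom_of]
  genes38$end <- genes$end + offset38[chrom_of]

  # --- gene sets ---
  sets <- list(); pid <- 0L
  for (cat in spec$categories) {
    for (j in seq_len(spec$n_sets)) {
      pid <- pid + 1L
      sets[[pid]] <- list(pid = pid, category = cat,
                          name = sprintf("%s_SET%03d", cat, j),
                          members = sort(sample(genes$gene_id, spec$set_size)))
    }
  }
  planted_genes <- integer(0)
  for (p in spec$planted_sets)
    planted_genes <- union(planted_genes, sets[[p$pid]]$members)

  # --- result files: planted signal via Beta(delta, 1) ---
  delta_of_gene <- function(gid) {
    d <- 1
    for (p in spec$planted_sets)
      if (gid %in% sets[[p$pid]]$members) d <- min(d, p$delta)
    d
  }
  gwes_p <- vapply(genes$gene_id, function(gid) {
    d <- delta_of_gene(gid)
    if (d < 1) stats::rbeta(1, d, 1) else stats::runif(1)
  }, numeric(1))

  pg <- genes[genes$gene_id %in% planted_genes, , drop = FALSE]
  snp_planted <- rep(FALSE, spec$n_snps)
  if (nrow(pg)) {
    for (i in seq_len(nrow(pg)))
      snp_planted <- snp_planted |
        (snps$chrom == pg$chrom[i] &
         snps$pos >= pg$start[i] - 2000L & snps$pos <= pg$end[i] + 2000L)
  }
  dmin <- if (length(spec$planted_sets))
    min(vapply(spec$planted_sets, `[[`, numeric(1), "delta")) else 1
  gwas_p <- ifelse(snp_planted & dmin < 1,
                   stats::rbeta(spec$n_snps, dmin, 1),
                   stats::runif(spec$n_snps))
  gwas_p <- pmax(gwas_p, 1e-300)  # the analysis rejects exact zeros
  gwes_p <- pmax(gwes_p, 1e-300)

  # --- write (explicit formatting => byte-identical under a fixed seed) ---
  fp <- function(name) file.path(out_dir, name)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- list(
    snp_map_GRCh37 = write_tsv(snps, fp("snp_map_GRCh37.tsv")),
    snp_map_GRCh38 = write_tsv(snps38, fp("snp_map_GRCh38.tsv")),
    gene_map_GRCh37 = write_tsv(genes, fp("gene_map_GRCh37.tsv")),
    gene_map_GRCh38 = write_tsv(genes38, fp("gene_map_GRCh38.tsv")))
  for (cat in spec$categories) {
    lines <- vapply(Filter(function(s) s$category == cat, sets), function(s)
      paste(c(s$name, paste0("http://example.org/", s$name), s$members),
            collapse = "\t"), character(1))
    path <- fp(paste0(cat, ".gmt"))
    writeLines(lines, path)
    files[[paste0("gmt_", cat)]] <- path
  }
  files$gwas <- {
    writeLines(c("rsid\tpvalue",
                 paste(snps$rsid, .fmt_p(gwas_p), sep = "\t")), fp("gwas.tsv"))
    fp("gwas.tsv")
  }
  files$gwes <- {
    writeLines(c("gene_id\tpvalue",
                 paste(genes$gene_id, .fmt_p(gwes_p), sep = "\t")), fp("gwes.tsv"))
    fp("gwes.tsv")
  }
  truth <- list(seed = spec$seed,
                planted = lapply(spec$planted_sets, function(p)
                  list(pid = p$pid, name = sets[[p$pid]]$name,
                       delta = p$delta, members = sets[[p$pid]]$members)),
                n_genes = spec$n_genes, n_snps = spec$n_snps,
                n_sets = length(sets), categories = spec$categories)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE, digits = NA)
  files$truth_json <- fp("truth.json")
  files$truth <- truth
  invisible(files)
}

#' Build a knowledge store directly from a fixture directory
#'
#' Convenience wrapper: [generate_fixture()] output in, `gws_store` out.
#'
#' @param fixture_dir directory written by [generate_fixture()].
#' @param store_path output store path; defaults to `store.db` inside the
#'   fixture directory.
#' @param categories category labels whose GMT files should be loaded, in
#'   PID-assignment order; defaults to the generator's category order from
#'   `truth.json` (falling back to every `*.gmt` present, alphabetically), so
#'   PIDs match the recorded truth.
#' @return a `gws_store` handle.
#' @export
fixture_store <- function(fixture_dir, store_path = file.path(fixture_dir, "store.db"),
                          categories = NULL) {
  if (is.null(categories) && file.exists(file.path(fixture_dir, "truth.json")))
    categories <- unlist(jsonlite::read_json(
      file.path(fixture_dir, "truth.json"), simplifyVector = TRUE)$categories)
  gmts <- list.files(fixture_dir, pattern = "\\.gmt$", full.names = TRUE)
  if (!is.null(categories)) {
    want <- file.path(fixture_dir, paste0(categories, ".gmt"))
    gmts <- want[file.exists(want)]
  }
  kb_build(store_path,
           snp_maps = list(GRCh37 = file.path(fixture_dir, "snp_map_GRCh37.tsv"),
                           GRCh38 = file.path(fixture_dir, "snp_map_GRCh38.tsv")),
           gene_maps = list(GRCh37 = file.path(fixture_dir, "gene_map_GRCh37.tsv"),
                            GRCh38 = file.path(fixture_dir, "gene_map_GRCh38.tsv")),
           gene_sets = lapply(gmts, function(g)
             list(path = g, category = sub("\\.gmt$", "", basename(g)))))
}
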