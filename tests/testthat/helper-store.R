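# Build a tiny knowledge store from in-code tables; all files land in a
# fresh temp directory.
mini_store <- function(snps37 = NULL, genes37 = NULL, sets = NULL,
                       snps38 = NULL, genes38 = NULL, id_map = NULL,
                       dir = tempfile("ministore")) {
  dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  snp_maps <- list(); gene_maps <- list()
  if (!is.null(snps37)) snp_maps$GRCh37 <- w(snps37, "snp37.tsv")
  if (!is.null(snps38)) snp_maps$GRCh38 <- w(snps38, "snp38.tsv")
  if (!is.null(genes37)) gene_maps$GRCh37 <- w(genes37, "gene37.tsv")
  if (!is.null(genes38)) gene_maps$GRCh38 <- w(genes38, "gene38.tsv")
  # sets: named list category -> named list of member vectors
  gs <- list()
  for (cat in names(sets)) {
    lines <- vapply(names(sets[[cat]]), function(nm)
      paste(c(nm, "http://x", sets[[cat]][[nm]]), collapse = "\t"),
      character(1))
    p <- file.path(dir, paste0(cat, ".gmt"))
    writeLines(lines, p)
    gs[[length(gs) + 1L]] <- list(path = p, category = cat)
  }
  kb_build(file.path(dir, "store.db"), snp_maps, gene_maps, gs, id_map = id_map)
}

# Single genes table usable on both builds.
toy_genes <- function() {
  data.frame(gene_id = c(11L, 12L, 13L),
             symbol = c("GA", "GB", "GC"),
             chrom = c("1", "1", "2"),
             start = c(10000L, 50000L, 30000L),
             end = c(20000L, 70000L, 31000L),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

toy_snps <- function() {
  data.frame(rsid = paste0("rs", 1:6),
             chrom = c("1", "1", "1", "1", "2", "2"),
             pos = c(500L, 8000L, 7999L, 15000L, 30500L, 90000L),
             stringsAsFactors = FALSE)
}
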