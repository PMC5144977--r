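#' @import data.table
#' @importFrom stats setNames
NULL

# Allowed chromosome vocabulary: autosomes, sex chromosomes, mitochondrion.
.CHROMS <- c(as.character(1:22), "X", "Y", "MT")
.BUILDS <- c("GRCh37", "GRCh38")

.check_build <- function(build) {
  if (length(build) != 1L || !build %in% .BUILDS)
    stop("invalid genome build '", paste(build, collapse = ","),
         "'; must be one of ", paste(.BUILDS, collapse = ", "), call. = FALSE)
  build
}

#' Read a gene-set file in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line with
#' fields `name`, `description` (usually a URL), then one or more member gene
#' tokens. Member tokens that are all-digit strings are taken as integer gene
#' IDs; any other token is resolved through `id_map` (a symbol-to-ID lookup)
#' and dropped with a warning when it cannot be resolved.
#'
#' @param path path to a GMT file.
#' @param id_map optional named integer vector or two-column data.frame
#'   (`symbol`, `gene_id`) used to resolve non-numeric member tokens.
#' @return a list with one element per set: `name`, `url`, `members`
#'   (integer gene IDs, deduplicated, input order), `unresolved` (character
#'   tokens that could not be resolved).
#' @export
read_gmt <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  map <- .as_id_map(id_map)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, " of ", path,
           ": expected >= 3 tab-separated fields, got ", length(f),
           call. = FALSE)
    tokens <- f[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    is_id <- grepl("^[0-9]+$", tokens)
    ids <- suppressWarnings(as.integer(tokens[is_id]))
    unresolved <- character(0)
    if (any(!is_id)) {
      if (is.null(map)) {
        unresolved <- tokens[!is_id]
      } else {
        hit <- map[tokens[!is_id]]
        unresolved <- tokens[!is_id][is.na(hit)]
        ids <- c(ids, hit[!is.na(hit)])
      }
    }
    if (length(unresolved))
      warning("GMT set '", f[[1]], "': dropped ", length(unresolved),
              " unresolved member token(s): ",
              paste(utils::head(unresolved, 5L), collapse = ", "),
              if (length(unresolved) > 5L) ", ..." else "", call. = FALSE)
    out[[i]] <- list(name = f[[1]], url = f[[2]],
                     members = unique(as.integer(ids)),
                     unresolved = unresolved)
  }
  out
}

.as_id_map <- function(id_map) {
  if (is.null(id_map)) return(NULL)
  if (is.data.frame(id_map)) {
    stopifnot(all(c("symbol", "gene_id") %in% names(id_map)))
    return(setNames(as.integer(id_map$gene_id), as.character(id_map$symbol)))
  }
  setNames(as.integer(id_map), names(id_map))
}

.read_snp_map <- function(path, build) {
  if (!file.exists(path)) stop("SNP map file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("rsid", "chrom")))
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stop("SNP map ", path, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dt <- dt[, .(rsid = as.character(rsid), chrom = as.character(chrom),
               pos = as.integer(pos))]
  if (any(dt$pos < 1L)) stop("SNP map ", path, ": pos must be >= 1", call. = FALSE)
  bad <- setdiff(unique(dt$chrom), .CHROMS)
  if (length(bad))
    stop("SNP map ", path, ": chromosome label(s) outside allowed vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- dt$rsid[duplicated(dt$rsid)]
  if (length(dup))
    stop("duplicate rsid within build ", build, ": ",
         paste(unique(utils::head(dup, 5L)), collapse = ", "), call. = FALSE)
  dt[, build := build]
  dt[]
}

.read_gene_map <- function(path, build) {
  if (!file.exists(path)) stop("gene map file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("symbol", "chrom", "strand")))
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  if (!all(need %in% names(dt)))
    stop("gene map ", path, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dt <- dt[, .(gene_id = as.integer(gene_id), symbol = as.character(symbol),
               chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), strand = as.character(strand))]
  if (!all(dt$strand %in% c("+", "-")))
    stop("gene map ", path, ": strand must be '+' or '-'", call. = FALSE)
  if (any(dt$start > dt$end))
    stop("gene map ", path, ": start must be <= end", call. = FALSE)
  bad <- setdiff(unique(dt$chrom), .CHROMS)
  if (length(bad))
    stop("gene map ", path, ": chromosome label(s) outside allowed vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # Multiple transcript rows per gene collapse to the union span
  # (min start, max end); symbol/chrom/strand taken from the first row.
  dt <- dt[, .(symbol = symbol[1L], chrom = chrom[1L],
               start = min(start), end = max(end), strand = strand[1L]),
           by = gene_id]
  dt[, build := build]
  dt[]
}

#' Build the annotation knowledge store
#'
#' Parses flat SNP-map and gene-map tables (one per genome build) plus one or
#' more GMT gene-set files (each carrying a category label) into a
#' self-contained, single-file SQLite database with four tables:
#' `snpmaps` (rsid, build, chrom, pos), `genemaps` (gene_id, symbol, build,
#' chrom, start, end, strand), `geneSets` (pid, name, category, url, size)
#' and `geneInfo` (gene_id, symbol, pid, category) -- the inverted
#' gene-to-set membership index. Every gene set receives a pathway ID (PID):
#' consecutive integers in input order, starting at 1. Indexes are created on
#' rsid, (chrom, pos), gene_id, symbol, pid and category, so the store
#' supports fast read-only concurrent querying after the build.
#'
#' @param path output path of the SQLite store file (overwritten if present).
#' @param snp_maps named list of SNP-map TSV paths, names are genome builds
#'   (`GRCh37`, `GRCh38`); columns `rsid`, `chrom`, `pos`. A build may be
#'   omitted.
#' @param gene_maps named list of gene-map TSV paths per build; columns
#'   `gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`. Multiple rows
#'   (transcripts) per gene are collapsed to the union span.
#' @param gene_sets list of `list(path =, category =)` entries, or a
#'   character vector of `"path:CATEGORY"` strings; parsed in order.
#' @param id_map optional symbol-to-gene-ID map (see [read_gmt()]).
#' @return a `gws_store` handle (see [kb_open()]), invisibly carrying a build
#'   report in attribute `"report"`: per-file unresolved member tokens and
#'   row counts.
#' @examples
#' \dontrun{
#' kb <- kb_build("store.db",
#'                snp_maps = list(GRCh37 = "snp37.tsv"),
#'                gene_maps = list(GRCh37 = "gene37.tsv"),
#'                gene_sets = list(list(path = "kegg.gmt", category = "KEGG")))
#' }
#' @export
kb_build <- function(path, snp_maps, gene_maps, gene_sets, id_map = NULL) {
  gene_sets <- .norm_geneset_arg(gene_sets)
  for (b in names(snp_maps)) .check_build(b)
  for (b in names(gene_maps)) .check_build(b)

  snp_dt <- data.table::rbindlist(
    lapply(names(snp_maps), function(b) .read_snp_map(snp_maps[[b]], b)))
  gene_dt <- data.table::rbindlist(
    lapply(names(gene_maps), function(b) .read_gene_map(gene_maps[[b]], b)))

  sets <- list(); info <- list(); report <- list()
  pid <- 0L
  for (gs in gene_sets) {
    parsed <- read_gmt(gs$path, id_map = id_map)
    unresolved <- unlist(lapply(parsed, `[[`, "unresolved"))
    report[[length(report) + 1L]] <- list(
      path = gs$path, category = gs$category, n_sets = length(parsed),
      unresolved = unresolved, n_unresolved = length(unresolved))
    for (s in parsed) {
      pid <- pid + 1L
      if (!length(s$members)) {
        warning("gene set '", s$name, "' (PID ", pid,
                ") has no resolvable members; dropped", call. = FALSE)
        next
      }
      sets[[length(sets) + 1L]] <- data.table::data.table(
        pid = pid, name = s$name, category = gs$category, url = s$url,
        size = length(s$members))
      info[[length(info) + 1L]] <- data.table::data.table(
        gene_id = s$members, pid = pid, category = gs$category)
    }
  }
  sets_dt <- data.table::rbindlist(sets)
  info_dt <- data.table::rbindlist(info)
  # geneInfo carries the official symbol where the gene map knows it.
  sym <- unique(gene_dt[, .(gene_id, symbol)], by = "gene_id")
  info_dt <- sym[info_dt, on = "gene_id"]
  info_dt[is.na(symbol), symbol := ""]
  data.table::setcolorder(info_dt, c("gene_id", "symbol", "pid", "category"))

  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbWriteTable(con, "snpmaps", snp_dt)
  DBI::dbWriteTable(con, "genemaps", gene_dt)
  DBI::dbWriteTable(con, "geneSets", sets_dt)
  DBI::dbWriteTable(con, "geneInfo", info_dt)
  for (sql in c(
    "CREATE INDEX idx_snp_rsid ON snpmaps(build, rsid)",
    "CREATE INDEX idx_snp_pos ON snpmaps(build, chrom, pos)",
    "CREATE INDEX idx_gene_id ON genemaps(build, gene_id)",
    "CREATE INDEX idx_gene_sym ON genemaps(build, symbol)",
    "CREATE INDEX idx_gene_pos ON genemaps(build, chrom, start, end)",
    "CREATE INDEX idx_set_pid ON geneSets(pid)",
    "CREATE INDEX idx_set_cat ON geneSets(category)",
    "CREATE INDEX idx_info_gene ON geneInfo(gene_id)",
    "CREATE INDEX idx_info_pid ON geneInfo(pid)",
    "CREATE INDEX idx_info_cat ON geneInfo(category)"))
    DBI::dbExecute(con, sql)
  DBI::dbDisconnect(con)
  on.exit(NULL)

  kb <- kb_open(path)
  attr(kb, "report") <- report
  invisible(kb)
}

.norm_geneset_arg <- function(gene_sets) {
  if (is.character(gene_sets)) {
    gene_sets <- lapply(gene_sets, function(s) {
      i <- regexpr(":[^:]*$", s)
      if (i < 0) stop("gene set spec must be 'path:CATEGORY': ", s, call. = FALSE)
      list(path = substr(s, 1L, i - 1L), category = substring(s, i + 1L))
    })
  }
  gene_sets
}

#' Open an existing knowledge store
#'
#' @param path path to a store file produced by [kb_build()].
#' @return a `gws_store` handle (an environment holding the open SQLite
#'   connection).
#' @export
kb_open <- function(path) {
  if (!file.exists(path)) stop("store file not found: ", path, call. = FALSE)
  h <- new.env(parent = emptyenv())
  h$path <- path
  h$con <- DBI::dbConnect(RSQLite::SQLite(), path, flags = RSQLite::SQLITE_RO)
  class(h) <- "gws_store"
  h
}

#' Close a knowledge store handle
#' @param kb a `gws_store` handle.
#' @export
kb_close <- function(kb) {
  stopifnot(inherits(kb, "gws_store"))
  if (!is.null(kb$con) && DBI::dbIsValid(kb$con)) DBI::dbDisconnect(kb$con)
  kb$con <- NULL
  invisible(NULL)
}

.kb_con <- function(kb) {
  if (!inherits(kb, "gws_store") || is.null(kb$con) || !DBI::dbIsValid(kb$con))
    stop("not an open gws_store handle", call. = FALSE)
  kb$con
}

.kb_query <- function(kb, sql, params = NULL) {
  res <- DBI::dbGetQuery(.kb_con(kb), sql, params = params)
  data.table::setDT(res)
  res
}

#' @export
print.gws_store <- function(x, ...) {
  con <- .kb_con(x)
  n <- function(tab) DBI::dbGetQuery(con, paste0("SELECT COUNT(*) n FROM ", tab))$n
  cat("gws annotation store:", x$path, "\n")
  cat("  snpmaps :", n("snpmaps"), "rows\n")
  cat("  genemaps:", n("genemaps"), "rows\n")
  cat("  geneSets:", n("geneSets"), "sets\n")
  cat("  geneInfo:", n("geneInfo"), "membership rows\n")
  invisible(x)
}

#' Summarize gene-set categories
#'
#' One row per category with the number of sets and the number of distinct
#' member genes.
#'
#' @param kb a `gws_store` handle.
#' @return data.frame with columns `category`, `n_sets`, `n_genes`.
#' @export
get_set_type <- function(kb) {
  sets <- .kb_query(kb, "SELECT category, COUNT(*) n_sets FROM geneSets
                         GROUP BY category ORDER BY category")
  genes <- .kb_query(kb, "SELECT category, COUNT(DISTINCT gene_id) n_genes
                          FROM geneInfo GROUP BY category ORDER BY category")
  out <- merge(sets, genes, by = "category", all.x = TRUE)
  out[is.na(n_genes), n_genes := 0L]
  as.data.frame(out)
}

#' List pathway IDs of a category
#'
#' @param kb a `gws_store` handle.
#' @param category category label; an unknown category yields an empty vector.
#' @return ascending integer vector of PIDs.
#' @export
set_type_to_pids <- function(kb, category) {
  .kb_query(kb, "SELECT pid FROM geneSets WHERE category = ? ORDER BY pid",
            params = list(category))$pid
}

#' Membership index of a category (or the whole store)
#'
#' @param kb a `gws_store` handle.
#' @param category optional category label; `NULL` returns all rows.
#' @return data.frame with columns `gene_id`, `symbol`, `pid`, `category`
#'   (the `geneInfo` inverted index).
#' @export
get_set_genes <- function(kb, category = NULL) {
  if (is.null(category)) {
    out <- .kb_query(kb, "SELECT gene_id, symbol, pid, category FROM geneInfo
                          ORDER BY pid, gene_id")
  } else {
    out <- .kb_query(kb, "SELECT gene_id, symbol, pid, category FROM geneInfo
                          WHERE category = ? ORDER BY pid, gene_id",
                     params = list(category))
  }
  as.data.frame(out)
}

#' Gene-set annotation records
#'
#' @param kb a `gws_store` handle.
#' @param pids optional integer PIDs to restrict to.
#' @return data.frame with columns `pid`, `name`, `category`, `url`, `size`.
#' @export
get_set_info <- function(kb, pids = NULL) {
  if (is.null(pids)) {
    out <- .kb_query(kb, "SELECT * FROM geneSets ORDER BY pid")
  } else {
    out <- .kb_query(kb, sprintf(
      "SELECT * FROM geneSets WHERE pid IN (%s) ORDER BY pid",
      paste(as.integer(pids), collapse = ",")))
  }
  as.data.frame(out)
}
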