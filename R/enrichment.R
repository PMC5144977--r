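#' Upper-tail hypergeometric exact p-value
#'
#' Probability that a hypergeometric draw overlaps a gene set at least as
#' much as observed: with a universe of `L` genes of which `S` belong to the
#' set, and `l` genes selected (candidates or top-ranked), returns
#' \eqn{P(X \ge K)} where X is the number of selected genes falling in the
#' set. The sum \eqn{\sum_{i=K}^{\min(l,S)} \binom{S}{i}\binom{L-S}{l-i} /
#' \binom{L}{l}} is accumulated from log-scale binomial coefficients so that
#' extreme tails (p below 1e-300) remain accurate. `K = 0` returns 1.
#'
#' @param L universe size (total genes).
#' @param l number of selected genes, `l <= L`.
#' @param S gene-set size within the universe, `S <= L`.
#' @param K observed overlap, `0 <= K <= min(l, S)`.
#' @return the exact upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_upper_p(5267, 27, 25, 4)  # 6.44e-06
#' @export
hypergeom_upper_p <- function(L, l, S, K) {
  stopifnot(length(L) == 1L, length(l) == 1L, length(S) == 1L, length(K) == 1L)
  if (l > L || S > L || K < 0 || K > min(l, S))
    stop("hypergeometric bounds violated: need K <= min(l, S) and l, S <= L",
         call. = FALSE)
  .hyper_upper_vec(L, l, S, K)
}

# Vectorized over S and K (L, l scalar).
.hyper_upper_vec <- function(L, l, S, K) {
  n <- max(length(S), length(K))
  S <- rep_len(as.numeric(S), n); K <- rep_len(as.numeric(K), n)
  denom <- lchoose(L, l)
  vapply(seq_len(n), function(j) {
    if (K[j] <= 0) return(1)
    i <- K[j]:min(l, S[j])
    lt <- lchoose(S[j], i) + lchoose(L - S[j], l - i) - denom
    mx <- max(lt)
    if (!is.finite(mx)) return(0)
    min(1, exp(mx + log(sum(exp(lt - mx)))))
  }, numeric(1))
}

# Per-set statistics over a fixed universe; membership restricted to it.
.enrich_core <- function(sets, membership, L, l, selected) {
  pid_idx <- match(membership$pid, sets$pid)
  K <- tabulate(pid_idx[membership$gene_id %in% selected], nbins = nrow(sets))
  frac <- l / L
  res <- data.frame(pid = sets$pid, name = sets$name, L = L, l = l,
                    S = sets$S, K = K,
                    effect = K / sets$S - frac,
                    se = sqrt(frac * (1 - frac) / sets$S),
                    p_e = .hyper_upper_vec(L, l, sets$S, K),
                    stringsAsFactors = FALSE)
  res[order(res$p_e, res$pid), , drop = FALSE]
}

.category_universe <- function(kb, category) {
  mem <- data.table::as.data.table(get_set_genes(kb, category))
  if (!nrow(mem)) stop("no gene sets in category '", category, "'", call. = FALSE)
  mem[, .(pid, gene_id)]
}

.new_enrich <- function(res, type, category, alpha, universe, membership, sets) {
  rownames(res) <- NULL
  structure(res, class = c("gws_enrich", "data.frame"),
            type = type, category = category, alpha = alpha,
            universe = universe,
            membership = as.data.frame(membership),
            sets = as.data.frame(sets))
}

#' Candidate gene enrichment analysis (CGEA, type 1 test)
#'
#' Tests each gene set of a category for over-representation of a fixed
#' candidate gene list. The universe holds the `L` distinct genes annotated
#' to any set of the category; `l` of them are candidates. For each set of
#' size `S` with `K` candidate members, the enrichment effect is
#' `K/S - l/L` (the excess probability that a set gene is a candidate,
#' relative to chance), its standard error `sqrt((l/L)(1 - l/L)/S)`, and the
#' exact p-value is the upper hypergeometric tail [hypergeom_upper_p()].
#'
#' @param kb a `gws_store` handle.
#' @param candidates integer vector of candidate gene IDs.
#' @param category gene-set category to test.
#' @return a `gws_enrich` data.frame (one row per set, ordered by `p_e`) with
#'   columns `pid`, `name`, `L`, `l`, `S`, `K`, `effect`, `se`, `p_e`.
#'   Candidates outside the universe are dropped from `l`.
#' @seealso [enrich_test2()], [perm_adjust()]
#' @export
enrich_test1 <- function(kb, candidates, category) {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  mem <- .category_universe(kb, category)
  universe <- sort(unique(mem$gene_id))
  L <- length(universe)
  cand <- intersect(unique(as.integer(candidates)), universe)
  l <- length(cand)
  if (l == 0L)
    stop("no candidate gene belongs to any '", category, "' gene set",
         call. = FALSE)
  info <- get_set_info(kb, unique(mem$pid))
  sets <- data.frame(pid = info$pid, name = info$name, S = info$size,
                     stringsAsFactors = FALSE)
  res <- .enrich_core(sets, mem, L, l, cand)
  .new_enrich(res, "CGEA", category, NA_real_, universe, mem, sets)
}

#' Uniform-score gene set analysis (USGSA, type 2 test)
#'
#' Tests each gene set of a category for over-representation of the genes
#' whose U-scores fall in the top `alpha` fraction (`U <= alpha`; ties at the
#' threshold are included). The universe holds the `L` measured genes that
#' belong to at least one set of the category; set sizes `S` and overlaps `K`
#' are counted within that universe. Effect, SE and exact p-value are as in
#' [enrich_test1()].
#'
#' @param kb a `gws_store` handle.
#' @param measures data.frame with columns `gene_id` and `uscore` (see
#'   [uscore()]).
#' @param alpha top U-score fraction, in (0, 1); default 0.05.
#' @param category gene-set category to test.
#' @return a `gws_enrich` data.frame, as [enrich_test1()].
#' @export
enrich_test2 <- function(kb, measures, alpha = 0.05, category = "KEGG") {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  stopifnot(all(c("gene_id", "uscore") %in% names(measures)))
  mem <- .category_universe(kb, category)
  measured <- unique(as.integer(measures$gene_id))
  mem <- mem[mem$gene_id %in% measured, ]
  if (!nrow(mem))
    stop("no measured gene belongs to any '", category, "' gene set",
         call. = FALSE)
  universe <- sort(unique(mem$gene_id))
  L <- length(universe)
  sel_all <- unique(as.integer(measures$gene_id[measures$uscore <= alpha]))
  selected <- intersect(sel_all, universe)
  l <- length(selected)
  if (l == 0L)
    stop("no gene with U-score <= ", alpha, " belongs to the '", category,
         "' universe", call. = FALSE)
  S_tab <- table(mem$pid)
  info <- get_set_info(kb, as.integer(names(S_tab)))
  sets <- data.frame(pid = info$pid, name = info$name,
                     S = as.integer(S_tab[as.character(info$pid)]),
                     stringsAsFactors = FALSE)
  res <- .enrich_core(sets, mem, L, l, selected)
  .new_enrich(res, "USGSA", category, alpha, universe, mem, sets)
}

#' @export
print.gws_enrich <- function(x, n = 10L, ...) {
  cat(sprintf("%s enrichment, category %s: L = %d universe genes, l = %d selected, %d sets\n",
              attr(x, "type"), attr(x, "category"), x$L[1L], x$l[1L], nrow(x)))
  if (!is.na(attr(x, "alpha")))
    cat(sprintf("  top U-score fraction alpha = %g\n", attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4, row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more sets\n")
  invisible(x)
}

#' @export
summary.gws_enrich <- function(object, p_cutoff = 0.05, ...) {
  cat(sprintf("%s: %d sets tested, %d with exact p <= %g; minimum p_e = %.3g (%s)\n",
              attr(object, "type"), nrow(object),
              sum(object$p_e <= p_cutoff), p_cutoff,
              min(object$p_e), object$name[which.min(object$p_e)]))
  invisible(object)
}

# Shared permutation stream: per permutation, draw l universe genes uniformly
# without replacement and record the minimum p_e overall and per set-size
# stratum. Both perm_adjust() and build_null_table() call this, so a common
# seed yields an identical stream.
.perm_min_pe <- function(sets, membership, L, l, B, seed) {
  stopifnot(B >= 1)
  set.seed(as.integer(seed))
  universe <- sort(unique(membership$gene_id))
  gidx <- match(membership$gene_id, universe)
  pid_idx <- match(membership$pid, sets$pid)
  sizes <- sort(unique(sets$S))
  size_idx <- match(sets$S, sizes)
  # p_e depends only on (S, K) once (L, l) are fixed: precompute per size.
  lut <- lapply(sizes, function(s) .hyper_upper_vec(L, l, s, 0:min(l, s)))
  overall <- numeric(B)
  by_size <- matrix(NA_real_, nrow = B, ncol = length(sizes),
                    dimnames = list(NULL, as.character(sizes)))
  flag <- logical(L)
  for (b in seq_len(B)) {
    flag[] <- FALSE
    flag[sample.int(L, l)] <- TRUE
    K <- tabulate(pid_idx[flag[gidx]], nbins = nrow(sets))
    pe <- vapply(seq_along(K), function(j) lut[[size_idx[j]]][K[j] + 1L],
                 numeric(1))
    overall[b] <- min(pe)
    by_size[b, ] <- vapply(seq_along(sizes),
                           function(si) min(pe[size_idx == si]), numeric(1))
  }
  list(overall = overall, by_size = by_size, sizes = sizes)
}

#' Permutation-adjusted p-values (min-p, family-wise)
#'
#' Westfall-Young-style adjustment: in each of `B` permutations the selected
#' genes are redrawn uniformly without replacement from the universe (for
#' USGSA this is equivalent to permuting U-scores across genes), every set's
#' exact p-value is recomputed, and the minimum over sets is kept. A set's
#' adjusted p-value is the fraction of permutations whose minimum reaches its
#' observed `p_e`: reported both as the raw proportion (`p_perm_raw`, which
#' can be exactly 0) and with the add-one correction `(x + 1)/(B + 1)`
#' (`p_perm`, a valid p-value).
#'
#' @param result a `gws_enrich` object from [enrich_test1()] or
#'   [enrich_test2()].
#' @param B number of permutations (>= 1).
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return the input with columns `p_perm_raw` and `p_perm` added.
#' @export
perm_adjust <- function(result, B = 1000L, seed = 1L) {
  stopifnot(inherits(result, "gws_enrich"))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  sets <- attr(result, "sets")
  mins <- .perm_min_pe(sets, attr(result, "membership"),
                       result$L[1L], result$l[1L], B, seed)$overall
  cnt <- vapply(result$p_e, function(p) sum(mins <= p), numeric(1))
  result$p_perm_raw <- cnt / B
  result$p_perm <- (cnt + 1) / (B + 1)
  result
}

.universe_fingerprint <- function(category, alpha, L, l, universe, sizes) {
  u <- as.numeric(universe)
  paste(category, format(alpha), L, l, length(u),
        format(sum(u)), format(sum(u * u) %% 2^48),
        length(sizes), sum(sizes), sep = "|")
}

.enrich_fingerprint <- function(result) {
  .universe_fingerprint(attr(result, "category"), attr(result, "alpha"),
                        result$L[1L], result$l[1L], attr(result, "universe"),
                        attr(result, "sets")$S)
}

#' Pregenerate a null distribution table for fast adjusted p-values
#'
#' Runs the [perm_adjust()] permutation stream once (default B = 10000) for a
#' fixed universe and stores, per permutation, the minimum exact p-value over
#' all sets and within each set-size stratum. [get_enrich2_p()] then turns
#' any observed `p_e` into a permutation-adjusted p-value instantly, without
#' re-permuting. The table is tied to the universe it was built for by a
#' fingerprint (category, alpha, L, l, gene IDs, set sizes).
#'
#' @param result a `gws_enrich` object defining the universe (typically from
#'   [enrich_test2()]).
#' @param B number of permutations.
#' @param seed integer RNG seed.
#' @param file optional path; when given, the table is written there with
#'   [saveRDS()].
#' @return a `gws_null_table` object.
#' @export
build_null_table <- function(result, B = 10000L, seed = 1L, file = NULL) {
  stopifnot(inherits(result, "gws_enrich"))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  mins <- .perm_min_pe(attr(result, "sets"), attr(result, "membership"),
                       result$L[1L], result$l[1L], B, seed)
  tab <- structure(list(overall = mins$overall, by_size = mins$by_size,
                        sizes = mins$sizes, B = B, seed = seed,
                        category = attr(result, "category"),
                        alpha = attr(result, "alpha"),
                        L = result$L[1L], l = result$l[1L],
                        fingerprint = .enrich_fingerprint(result)),
                   class = "gws_null_table")
  if (!is.null(file)) saveRDS(tab, file)
  tab
}

#' Adjusted p-value from a pregenerated null table
#'
#' Returns the empirical exceedance fraction of an observed exact p-value
#' under the stored min-p permutation distribution: the proportion of
#' permutations whose minimum p-value (overall, or within the given set-size
#' stratum) is at or below `p_e`. A step function of `p_e`; no interpolation.
#'
#' @param table a `gws_null_table` (object or RDS path).
#' @param p_e observed exact p-value(s).
#' @param size optional set size; when given, the comparison uses the min-p
#'   stratum of sets of that size (must exist in the table). `NULL` uses the
#'   overall minimum across all sets (family-wise adjustment, identical to
#'   [perm_adjust()]'s raw proportion under the same seed and B).
#' @param result optional `gws_enrich` object; when supplied its universe
#'   fingerprint must match the table's, otherwise an error is raised.
#' @return adjusted p-value(s) in `[0, 1]`.
#' @export
get_enrich2_p <- function(table, p_e, size = NULL, result = NULL) {
  if (is.character(table)) table <- readRDS(table)
  stopifnot(inherits(table, "gws_null_table"))
  if (!is.null(result)) {
    stopifnot(inherits(result, "gws_enrich"))
    if (!identical(.enrich_fingerprint(result), table$fingerprint))
      stop("null table was built for a different universe (fingerprint mismatch)",
           call. = FALSE)
  }
  if (is.null(size)) {
    mins <- table$overall
  } else {
    j <- match(as.character(size), colnames(table$by_size))
    if (is.na(j))
      stop("no set-size stratum of size ", size, " in null table", call. = FALSE)
    mins <- table$by_size[, j]
  }
  vapply(p_e, function(p) mean(mins <= p), numeric(1))
}

#' @export
print.gws_null_table <- function(x, ...) {
  cat(sprintf("min-p null table: %s category, L = %d, l = %d, B = %d permutations, %d size strata\n",
              x$category, x$L, x$l, x$B, length(x$sizes)))
  invisible(x)
}

#' One-sided proportion test for top-ranked U-scores
#'
#' For a candidate gene subset, tests whether the proportion of genes with
#' U-score at or below `alpha0` exceeds the value `alpha0` expected under
#' uniformity. Each gene contributes a binary indicator `I(U <= alpha0)`;
#' the test is a one-sample t-test of the indicator mean against `alpha0`
#' (sample SD with n - 1 denominator, df = n - 1), one-sided greater.
#'
#' @param uscores numeric vector of U-scores for the candidate genes (n >= 2).
#' @param alpha0 threshold and null proportion, e.g. 0.05.
#' @return an object of class `htest` with `statistic` (t), `parameter`
#'   (df), `p.value`, `estimate` (observed proportion) plus fields `n` and
#'   `k` (number of indicators set).
#' @examples
#' u <- c(rep(0.01, 20), seq(0.2, 0.9, length.out = 82))
#' uscore_proportion_test(u, 0.05)  # t = 3.70, p = 1.77e-04
#' @export
uscore_proportion_test <- function(uscores, alpha0 = 0.05) {
  u <- as.numeric(uscores)
  n <- length(u)
  if (n < 2L) stop("need at least 2 U-scores", call. = FALSE)
  x <- as.numeric(u <= alpha0)
  if (stats::var(x) == 0)
    stop("zero variance: all ", n, " indicators are ",
         if (x[1L] == 1) "below" else "above", " the threshold ", alpha0,
         "; the t-test is undefined", call. = FALSE)
  ht <- stats::t.test(x, mu = alpha0, alternative = "greater")
  ht$data.name <- sprintf("indicators I(U <= %g), n = %d", alpha0, n)
  ht$method <- "One-sample t-test of top-U-score proportion"
  names(ht$estimate) <- "proportion"
  ht$n <- n
  ht$k <- as.integer(sum(x))
  ht
}
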