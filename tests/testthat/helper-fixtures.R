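# One moderately sized fixture store shared across test files; generated
# once per session.
.fixture_cache <- new.env(parent = emptyenv())

test_fixture <- function() {
  if (is.null(.fixture_cache$kb)) {
    d <- file.path(tempdir(), "gwsets-test-fixture")
    spec <- fixture_spec(seed = 42L, n_chrom = 2L, n_genes = 300L,
                         n_snps = 2000L, n_sets = 50L, set_size = 10L,
                         categories = c("KEGG", "GO"),
                         planted_sets = list(list(pid = 1L, delta = 0.1)))
    .fixture_cache$files <- generate_fixture(spec, d)
    .fixture_cache$dir <- d
    .fixture_cache$spec <- spec
    .fixture_cache$kb <- fixture_store(d)
  }
  .fixture_cache
}

# Independent enumeration oracle for the upper hypergeometric tail.
enum_hyper_upper <- function(L, l, S, K) {
  if (K <= 0) return(1)
  i <- K:min(l, S)
  sum(choose(S, i) * choose(L - S, l - i)) / choose(L, l)
}
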