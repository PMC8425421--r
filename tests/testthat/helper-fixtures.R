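# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small planted-promoter world reused by io/curation/profile tests
small_truth <- function() memo("small_truth", {
  g <- generateBackground(20000, 0.5, seed = 101)
  plantPromoters(g, nSites = 30,
                 motifs = promoterMotifs(mutationRate = 0, jitter = 0L),
                 minSpacing = 400L, seed = 102)
})

tiny_config <- function(seed = 7L)
  modelConfig(segment_length = 16L, num_layers = 2L, heads_per_layer = 2L,
              head_dim = 4L, embed_dim = 8L, head_hidden = 8L, seed = seed)

random_tss_sets <- function(n_sources, n_sites, span = 400L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_sources), function(i) {
    n <- sample.int(n_sites, 1L)
    tssSet(sample.int(span, n) - 1L,
           sample(c("+", "-"), n, replace = TRUE),
           sourceName = paste0("src", i), priority = i)
  })
}
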