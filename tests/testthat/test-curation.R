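mk <- function(pos, strand = "+", src = "A", pr = 1L)
  tssSet(pos, strand, src, pr)

test_that("sharing clusters follow the pairwise window, with chaining", {
  # |10 - 14| <= 5: one cluster of two
  cl <- clusterShared(list(mk(10, src = "A"), mk(14, src = "B")), 5L)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 2L)

  # distance 6: two singletons
  cl <- clusterShared(list(mk(10, src = "A"), mk(16, src = "B")), 5L)
  expect_length(cl, 2L)

  # chaining 10-14-18 joins into one cluster of three (and is reported)
  expect_message(
    cl <- clusterShared(list(mk(10, src = "A"), mk(14, src = "B"),
                             mk(18, src = "C")), 5L),
    "chaining")
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 3L)

  # strands never mix
  cl <- clusterShared(list(mk(10, "+", "A"), mk(10, "-", "B")), 5L)
  expect_length(cl, 2L)
})

test_that("clusters equal brute-force connected components on random instances", {
  for (seed in 1:20) {
    sets <- random_tss_sets(n_sources = sample(2:4, 1), n_sites = 30,
                            span = 200L, seed = seed)
    got <- clusterShared(sets, 5L)
    want <- oracle_components(do.call(rbind, lapply(sets, function(s) {
      e <- tssEntries(s)
      data.frame(source = sourceName(s), pos = e$pos, strand = e$strand)
    })), 5L)
    canon <- function(cls) sort(vapply(cls, function(cl)
      paste(cl$strand[1], paste(sort(paste(cl$source, cl$pos)), collapse = "|")),
      character(1)))
    expect_equal(canon(got), canon(want))
  }
})

test_that("venn counts partition the clusters", {
  a <- mk(c(10, 100), src = "A"); b <- mk(c(12, 300), src = "B")
  v <- vennCounts(list(a, b), 5L)
  expect_equal(unname(v[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(sum(v), length(clusterShared(list(a, b), 5L)))

  # identical sets put all mass on the full subset
  v2 <- vennCounts(list(mk(c(10, 100), src = "A"), mk(c(10, 100), src = "B")))
  expect_equal(unname(v2["A&B"]), 2L)
  expect_equal(sum(v2), 2L)

  # random instances: sum over subsets = number of clusters
  for (seed in 21:26) {
    sets <- random_tss_sets(3, 25, span = 300L, seed = seed)
    expect_equal(sum(vennCounts(sets, 5L)),
                 length(oracle_components(do.call(rbind, lapply(sets, function(s) {
                   e <- tssEntries(s)
                   data.frame(source = sourceName(s), pos = e$pos,
                              strand = e$strand)
                 })), 5L)))
  }
})

test_that("offset histograms are centred on the first set and antisymmetric", {
  a <- mk(c(10, 50)); b <- mk(c(10, 50), src = "B")
  h <- offsetHistogram(a, b, 5L)
  expect_equal(unname(h["0"]), 2L)
  expect_equal(sum(h), 2L)

  shifted <- mk(c(12, 52), src = "B")
  h2 <- offsetHistogram(a, shifted, 5L)
  expect_equal(unname(h2["2"]), 2L)

  for (seed in 31:36) {
    sets <- random_tss_sets(2, 25, span = 120L, seed = seed)
    hab <- offsetHistogram(sets[[1]], sets[[2]], 5L)
    hba <- offsetHistogram(sets[[2]], sets[[1]], 5L)
    expect_equal(unname(hab), unname(rev(hba)))
  }
})

test_that("curation rules: majority, novelty tie-break, preferred top-up", {
  # majority 2-of-3 at position 10
  sets <- list(mk(10, src = "A", pr = 1L), mk(10, src = "B", pr = 2L),
               mk(12, src = "C", pr = 3L))
  cur <- curatedEntries(curateTss(sets))
  expect_equal(cur$pos, 10L)
  expect_equal(cur$chosen_by, "majority")

  # tie between A:10 and B:12 with B newer -> 12
  sets <- list(mk(10, src = "A", pr = 1L), mk(12, src = "B", pr = 2L))
  cur <- curatedEntries(curateTss(sets))
  expect_equal(cur$pos, 12L)
  expect_equal(cur$chosen_by, "priority_tiebreak")

  # singletons are excluded unless from the preferred source
  sets <- list(mk(c(10, 100), src = "A"), mk(c(11, 300), src = "Pref", pr = 5L))
  cur <- curatedEntries(curateTss(sets, preferredSource = "Pref"))
  expect_true(300L %in% cur$pos)     # preferred singleton added
  expect_false(100L %in% cur$pos)    # plain singleton dropped
  expect_equal(cur$chosen_by[cur$pos == 300L], "preferred_source")

  # unknown source in the priority ranking errors
  expect_error(curateTss(sets, priorityOrder = c("Nope", "A", "Pref")),
               "unknown source")
})

test_that("curate matches the brute-force rule oracle on random instances", {
  for (seed in 1:60) {
    n_src <- sample(2:4, 1)
    sets <- random_tss_sets(n_src, 30, span = 250L, seed = 1000 + seed)
    pr_order <- paste0("src", rev(seq_len(n_src)))   # srcN newest
    pref <- if (seed %% 2 == 0) "src1" else NULL
    got <- curatedEntries(suppressMessages(
      curateTss(sets, priorityOrder = pr_order, window = 5L,
                preferredSource = pref)))[, c("pos", "strand")]
    rownames(got) <- NULL
    want <- oracle_curate(sets, pr_order, 5L, pref)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("adding a source never removes rule-1/2 entries (monotonicity)", {
  for (seed in 41:46) {
    sets <- random_tss_sets(3, 20, span = 300L, seed = seed)
    base <- curatedEntries(suppressMessages(curateTss(sets)))
    extra <- random_tss_sets(1, 10, span = 300L, seed = seed + 100)[[1]]
    extra@sourceName <- "srcX"; extra@priority <- 0L
    grown <- curatedEntries(suppressMessages(curateTss(c(sets, list(extra)))))
    # every cluster that produced an entry still produces one within window
    for (i in seq_len(nrow(base))) {
      near <- grown$pos[grown$strand == base$strand[i]]
      expect_true(length(near) > 0 && min(abs(near - base$pos[i])) <= 5L)
    }
  }
})

test_that("curation recovers the truth from noisy derived sets", {
  tr <- small_truth()
  sets <- lapply(1:3, function(i)
    deriveNoisySet(tr, noiseSpec(maxShift = 2L, dropoutRate = 0.2,
                                 fpRate = 0.05, seed = 70L + i),
                   paste0("exp", i), i))
  cur <- curatedEntries(suppressMessages(curateTss(sets)))
  truth <- tssEntries(truthTss(tr))
  near_truth <- vapply(seq_len(nrow(cur)), function(i) {
    same <- truth$pos[truth$strand == cur$strand[i]]
    min(abs(same - cur$pos[i])) <= 2L
  }, logical(1))
  expect_gte(mean(near_truth), 0.95)
  # and most true sites are recovered
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    same <- cur$pos[cur$strand == truth$strand[i]]
    length(same) > 0 && min(abs(same - truth$pos[i])) <= 2L
  }, logical(1))
  expect_gte(mean(recovered), 0.8)
})
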