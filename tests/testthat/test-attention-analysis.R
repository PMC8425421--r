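# records with hand-set score arrays for arithmetic checks
fake_records <- function(scores, outputs, cfg = tiny_config()) {
  n <- dim(scores)[1]
  new("AttentionRecords", scores = scores,
      queries = data.frame(pos = seq_len(n) * 100L, strand = "+",
                           output = outputs),
      config = unclass(cfg))
}

test_that("head profiles average and track the maximum per offset", {
  cfg <- tiny_config()
  l <- cfg$segment_length
  nH <- cfg$num_layers * cfg$heads_per_layer
  # two records for head (1,1): uniform and one-hot at offset -5
  sc <- array(0, dim = c(2, l, nH))
  sc[1, , 1] <- 1 / l
  sc[2, l - 5, 1] <- 1            # offset -5 is index l - 5
  r <- fake_records(sc, c(0.2, 0.9))
  hp <- headProfile(r, 1, 1)
  expect_equal(hp$mean[hp$offset == -5], (1 / l + 1) / 2)
  expect_equal(sum(hp$mean), 1, tolerance = 1e-12)
  expect_equal(hp$max[hp$offset == -5], 1)
  expect_equal(attr(hp, "n_samples"), 2L)
  # single record: mean == max == the record
  one <- fake_records(sc[1, , , drop = FALSE], 0.2)
  hp1 <- headProfile(one, 1, 1)
  expect_equal(hp1$mean, hp1$max)
})

test_that("collected attention matches the forward pass and counts records", {
  tr <- small_truth()
  g <- truthGenome(tr)
  m <- transformerModel(modelConfig(segment_length = 32L, num_layers = 2L,
                                    heads_per_layer = 4L, head_dim = 8L,
                                    embed_dim = 32L, seed = 3))
  q <- data.frame(pos = c(500L, 501L, 700L, 900L, 1100L),
                  strand = c("+", "+", "-", "+", "-"))
  rec <- collectAttention(m, g, q)
  # k=2 layers x 4 heads x 5 positions = 40 score vectors
  expect_equal(dim(rec@scores), c(5L, 32L, 8L))
  # every full-context record sums to 1
  sums <- apply(rec@scores, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # outputs equal the prediction track (same forward, bit for bit)
  track <- predictTrack(m, g)
  expect_identical(rec@queries$output[1], track@fwd[501L])
  expect_identical(rec@queries$output[3], track@rev[701L])
  expect_error(collectAttention(m, g, data.frame(pos = -1L, strand = "+")),
               "outside")
})

test_that("sample frames are seeded, ranked and in-split", {
  set.seed(2)
  L <- 2000L
  tk <- predictionTrack(seq(0, 1, length.out = L), rep(0.5, L))
  split <- data.frame(start = 1000L, end = 2000L)
  fr <- buildSampleFrame(tk, split, fraction = 0.05, nExtreme = 100L,
                         seed = 42L)
  fr2 <- buildSampleFrame(tk, split, fraction = 0.05, nExtreme = 100L,
                          seed = 42L)
  expect_identical(fr, fr2)
  expect_true(all(fr$random$pos >= 1000L & fr$random$pos < 2000L))
  # strictly increasing fwd track: top = last 100 plus-strand coordinates
  expect_setequal(fr$top$pos[fr$top$strand == "+"], 1900:1999)
  expect_equal(nrow(merge(fr$top, fr$bottom, by = c("pos", "strand"))), 0L)
  expect_error(buildSampleFrame(tk, split, nExtreme = 2000L), "nExtreme")
  # fraction 1 returns every split position (both strands)
  all_fr <- buildSampleFrame(tk, split, fraction = 1, nExtreme = 10L)
  expect_equal(nrow(all_fr$random), 2000L)
})

test_that("PFMs count columns correctly and bound information content", {
  p <- pfmFromSeqs(rep("TATAATG", 50), anchor = -9L)
  expect_equal(unname(colSums(p@counts)), rep(50L, 7))
  expect_equal(informationContent(p), rep(2, 7))
  expect_equal(pfmConsensus(p), "TATAATG")
  m <- pfmConsensusMatch(p, "TATAAT")
  expect_equal(m$match, 1)
  expect_equal(m$shift, 0L)

  # near-uniform random columns: information content near 0
  set.seed(3)
  seqs <- vapply(1:400, function(i)
    paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = ""),
    character(1))
  expect_lt(max(informationContent(pfmFromSeqs(seqs))), 0.1)
})

test_that("top-scoring motif recovers a planted sequence deterministically", {
  # build records whose anchor scores single out queries sitting 10 nt
  # downstream of a planted TATAAT, so the extracted 7-mers contain it
  g <- genome("x", paste(rep("ACGT", 200), collapse = ""))
  chars <- strsplit(as.character(genomeSeq(g)), "")[[1]]
  anchor_off <- -9L
  qpos <- seq(100L, 700L, by = 12L)
  for (p in qpos) {
    chars[(p + anchor_off - 3L):(p + anchor_off + 3L) + 1L] <-
      c("G", "T", "A", "T", "A", "A", "T")   # 7-mer centred at p + anchor
  }
  g <- genome("x", paste(chars, collapse = ""))
  cfg <- tiny_config()
  l <- cfg$segment_length
  nH <- cfg$num_layers * cfg$heads_per_layer
  n <- length(qpos)
  sc <- array(0, dim = c(n, l, nH))
  sc[, l + anchor_off, 2] <- seq(1, 2, length.out = n)   # head (1,2)
  rec <- new("AttentionRecords", scores = sc,
             queries = data.frame(pos = qpos, strand = "+",
                                  output = runif(n)),
             config = unclass(cfg))
  pfm <- topScoringMotif(rec, g, 1, 2, nTop = 20L)
  expect_equal(pfm@anchor, anchor_off)
  expect_equal(pfmConsensus(pfm), "GTATAAT")   # the planted 7-mer
  m <- pfmConsensusMatch(pfm, "TATAAT")
  expect_equal(m$match, 1)
  expect_equal(m$shift, 1L)
})

test_that("Spearman correlations match the hand-rank oracle", {
  cfg <- tiny_config()
  l <- cfg$segment_length
  nH <- cfg$num_layers * cfg$heads_per_layer
  set.seed(5)
  n <- 10L
  sc <- array(runif(n * l * nH), dim = c(n, l, nH))
  out <- runif(n)
  r <- fake_records(sc, out)
  rho <- headOutputCorrelation(r)
  for (pick in list(c(1, 1, -3), c(2, 2, 0), c(1, 2, -7))) {
    col <- l + pick[3]
    want <- oracle_spearman(sc[, col, (pick[1] - 1) * cfg$heads_per_layer + pick[2]],
                            out)
    got <- rho$rho[rho$layer == pick[1] & rho$head == pick[2] &
                     rho$offset == pick[3]]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # perfect monotone relations
  sc2 <- array(0, dim = c(n, l, nH))
  sc2[, 5, 1] <- out; sc2[, 5, 2] <- -out
  r2 <- fake_records(sc2, out)
  rho2 <- headOutputCorrelation(r2)
  expect_equal(rho2$rho[rho2$layer == 1 & rho2$head == 1 &
                          rho2$offset == 5 - l], 1)
  expect_equal(rho2$rho[rho2$layer == 1 & rho2$head == 2 &
                          rho2$offset == 5 - l], -1)
  # zero-variance offsets are NA
  expect_true(is.na(rho2$rho[rho2$layer == 1 & rho2$head == 1 &
                               rho2$offset == 0]))
})

test_that("group contrasts localise a one-hot difference and control type I", {
  cfg <- tiny_config()
  l <- cfg$segment_length
  nH <- cfg$num_layers * cfg$heads_per_layer
  n <- 30L
  set.seed(6)
  # top group one-hot at offset -12 (+ tiny noise), bottom uniform
  top <- array(0, dim = c(n, l, nH))
  top[, l - 12, 1] <- 1
  bot <- array(1 / l, dim = c(n, l, nH))
  d <- compareScoreGroups(fake_records(top, runif(n)),
                          fake_records(bot, runif(n)), 1, 1)
  expect_equal(d$offset[which.max(d$diff)], -12L)
  expect_lt(d$p_adj[d$offset == -12L], 0.01)
  # identical groups: zero difference everywhere
  same <- array(runif(n * l * nH), dim = c(n, l, nH))
  d0 <- compareScoreGroups(fake_records(same, runif(n)),
                           fake_records(same, runif(n)), 1, 1)
  expect_true(all(d0$diff == 0))
  # null simulation: few BH-significant offsets when both groups share
  # one distribution
  fp <- 0
  for (repn in 1:20) {
    a <- array(runif(n * l * nH), dim = c(n, l, nH))
    b <- array(runif(n * l * nH), dim = c(n, l, nH))
    dn <- compareScoreGroups(fake_records(a, runif(n)),
                             fake_records(b, runif(n)), 1, 1)
    fp <- fp + sum(dn$p_adj < 0.05)
  }
  expect_lte(fp / 20, 0.05 * l)
})

test_that("head-head correlation matrices are symmetric with unit diagonal", {
  cfg <- tiny_config()
  l <- cfg$segment_length
  nH <- cfg$num_layers * cfg$heads_per_layer
  set.seed(7)
  sc <- array(runif(40 * l * nH), dim = c(40, l, nH))
  sc[, , 3] <- sc[, , 1]                     # duplicated head
  m <- headHeadCorrelation(fake_records(sc, runif(40)))
  expect_equal(dim(m), c(nH, nH))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, nH))
  expect_equal(m[1, 3], 1)
  off_diag <- m[1, -c(1, 3)]
  expect_lt(max(abs(off_diag)), 0.1)         # independent heads ~ 0
})

test_that("MEME minimal output lists every motif with valid frequencies", {
  p1 <- pfmFromSeqs(rep("TATAATG", 10))
  p2 <- pfmFromSeqs(c(rep("TTGACAG", 6), rep("TTGACAT", 4)))
  path <- withr::local_tempfile(fileext = ".meme")
  writeMeme(list(h1 = p1, h2 = p2), path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^MOTIF", txt)), 2L)
  rows <- grep("^ [0-9]", txt, value = TRUE)
  vals <- do.call(rbind, lapply(strsplit(trimws(rows), " +"), as.numeric))
  expect_true(all(abs(rowSums(vals) - 1) < 1e-4))
})
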