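test_that("attentionHead matches a naive double-loop implementation", {
  set.seed(1)
  for (rep in 1:25) {
    m <- sample(1:8, 1)      # attendable positions
    dh <- 4L
    q <- rnorm(dh)
    K <- matrix(rnorm(m * dh), m, dh)
    V <- matrix(rnorm(m * dh), m, dh)
    bias <- if (rep %% 2) rnorm(m) else numeric(m)
    got <- attentionHead(q, K, V, dh, bias)
    # naive: explicit loops
    raw <- numeric(m)
    for (j in 1:m) {
      s <- 0
      for (d in 1:dh) s <- s + q[d] * K[j, d]
      raw[j] <- s / sqrt(dh) + bias[j]
    }
    e <- exp(raw - max(raw)); sc <- e / sum(e)
    z <- numeric(dh)
    for (j in 1:m) for (d in 1:dh) z[d] <- z[d] + sc[j] * V[j, d]
    expect_equal(got$scores, sc, tolerance = 1e-12)
    expect_equal(got$z, z, tolerance = 1e-12)
    expect_equal(sum(got$scores), 1, tolerance = 1e-12)
  }
})

test_that("attention degenerate cases: constant products and single key", {
  q <- rep(0, 4)                       # all products zero -> uniform
  K <- matrix(rnorm(20), 5, 4)
  V <- diag(4)[c(1, 2, 3, 4, 1), ]
  got <- attentionHead(q, K, V, 4)
  expect_equal(got$scores, rep(0.2, 5))
  one <- attentionHead(rnorm(4), matrix(rnorm(4), 1, 4),
                       matrix(rnorm(4), 1, 4), 4)
  expect_equal(one$scores, 1)
})

test_that("compiled forward matches the naive R reimplementation", {
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed)
    m <- transformerModel(cfg)
    set.seed(seed)
    tok <- sample(0:4, 16, replace = TRUE)
    got <- forwardSegment(m, tok, recordAttention = TRUE)
    want <- naive_forward(m@params, m@config, tok)
    expect_equal(got$prob, want$prob, tolerance = 1e-10)
    expect_equal(got$attention, want$attention, tolerance = 1e-10)
  }
})

test_that("attention records are normalised and probabilities are valid", {
  m <- transformerModel(tiny_config())
  res <- forwardSegment(m, "ACGTACGTACGTAACC", recordAttention = TRUE)
  expect_true(all(res$prob >= 0 & res$prob <= 1))
  sums <- apply(res$attention, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # two-class normalisation: P(positive) + P(negative) = 1 by construction
  # (softmax); the exported probability is the positive class
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_config(seed = 3)
  m <- transformerModel(cfg)
  set.seed(3)
  tok <- sample(0:3, 16, replace = TRUE)
  lab <- as.integer(runif(16) < 0.3)
  mem0 <- forwardSegment(m, sample(0:3, 16, replace = TRUE))$newMemory
  for (mem in list(list(), mem0)) {
    gr <- tssformer:::.tx_segment_grad(m@params, m@config, tok, lab, mem)
    idx <- sort(sample(seq_along(m@params), 25))
    h <- 1e-6
    num <- vapply(idx, function(j) {
      p1 <- m@params; p1[j] <- p1[j] + h
      p2 <- m@params; p2[j] <- p2[j] - h
      (tssformer:::.tx_segment_grad(p1, m@config, tok, lab, mem)$loss -
         tssformer:::.tx_segment_grad(p2, m@config, tok, lab, mem)$loss) / (2 * h)
    }, numeric(1))
    expect_equal(num, gr$grad[idx], tolerance = 1e-5)
  }
})

test_that("identical weights, segment and memory give identical outputs", {
  m <- transformerModel(tiny_config())
  seg <- "ACGTACGTACGTAACC"
  r1 <- forwardSegment(m, seg, recordAttention = TRUE)
  r2 <- forwardSegment(m, seg, recordAttention = TRUE)
  expect_identical(r1$prob, r2$prob)
  expect_identical(r1$attention, r2$attention)
  # and initialisation is seed-deterministic
  expect_identical(transformerModel(tiny_config(seed = 5))@params,
                   transformerModel(tiny_config(seed = 5))@params)
})

test_that("relocating identical context yields identical outputs", {
  # no absolute position enters the model: the same 4l of context at a
  # different genomic offset must produce bit-identical scores
  cfg <- tiny_config(seed = 11)
  m <- transformerModel(cfg)
  l <- cfg$segment_length
  set.seed(11)
  C <- sample(0:3, 4 * l, replace = TRUE)
  R <- sample(0:3, l, replace = TRUE)
  run <- function(tokens) {
    mem <- list(); out <- NULL
    for (s in seq(1, length(tokens), by = l)) {
      out <- forwardSegment(m, tokens[s:(s + l - 1)], mem,
                            recordAttention = TRUE)
      mem <- out$newMemory
    }
    out   # final segment
  }
  a <- run(C)
  b <- run(c(R, C))
  expect_identical(a$prob, b$prob)
  expect_identical(a$attention, b$attention)
})

test_that("positional encodings at distinct offsets are distinct", {
  cfg <- tiny_config(seed = 2)
  m <- transformerModel(cfg)
  lay <- tssformer:::.tx_param_layout(m@config)
  off <- cumsum(c(0, unlist(lay$size)))
  i <- which(lay$block == "layer1.relb")
  relb <- matrix(m@params[(off[i] + 1):off[i + 1]],
                 cfg$segment_length, cfg$heads_per_layer)
  for (h in seq_len(ncol(relb)))
    expect_equal(anyDuplicated(relb[, h]), 0L)
})

test_that("upstream and downstream receptive-field bounds hold exactly", {
  cfg <- tiny_config(seed = 4)
  m <- transformerModel(cfg)
  l <- cfg$segment_length; k <- cfg$num_layers; cw <- cfg$conv_width
  bound <- k * (l + cw)                 # upstream reach in nt
  set.seed(4)
  n_seg <- 5L
  tokens <- sample(0:3, n_seg * l, replace = TRUE)
  run_last <- function(tokens) {
    mem <- list()
    for (s in seq(1, length(tokens), by = l)) {
      out <- forwardSegment(m, tokens[s:(s + l - 1)], mem)
      mem <- out$newMemory
    }
    out$prob
  }
  base <- run_last(tokens)
  query_gpos <- length(tokens) - 1L     # 0-based position of last output
  # perturb beyond the architectural upstream bound: no change
  far <- tokens
  far_pos <- query_gpos - bound - 1L
  far[far_pos + 1L] <- (far[far_pos + 1L] + 1L) %% 4L
  expect_identical(run_last(far)[l], base[l])
  # perturb just upstream of the query: output changes
  near <- tokens
  near[query_gpos - 3L] <- (near[query_gpos - 3L] + 1L) %% 4L
  expect_false(isTRUE(all.equal(run_last(near)[l], base[l])))
  # downstream: the centred conv reaches 3 nt per layer; beyond 3k the
  # output at a position cannot change
  mid <- 3L * l + 8L                    # 0-based, mid-genome query
  pert <- tokens
  pert[mid + 3L * k + 2L] <- (pert[mid + 3L * k + 2L] + 1L) %% 4L
  run_at <- function(tokens, gpos) {
    mem <- list()
    for (s in seq(1, length(tokens), by = l)) {
      out <- forwardSegment(m, tokens[s:(s + l - 1)], mem)
      mem <- out$newMemory
      if (s + l - 1 >= gpos + 1) return(out$prob[gpos + 1 - (s - 1)])
    }
  }
  expect_identical(run_at(pert, mid), run_at(tokens, mid))
})

test_that("model checkpoints round trip through YAML", {
  m <- transformerModel(tiny_config(seed = 12))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeModel(m, path)
  m2 <- readModel(path)
  expect_equal(m2@config$segment_length, m@config$segment_length)
  seg <- "ACGTACGTACGTAACC"
  expect_equal(forwardSegment(m2, seg)$prob, forwardSegment(m, seg)$prob,
               tolerance = 1e-12)
})

test_that("invalid segments are rejected", {
  m <- transformerModel(tiny_config())
  expect_error(forwardSegment(m, "ACGX"), "outside")
  expect_error(forwardSegment(m, paste(rep("A", 17), collapse = "")),
               "longer")
})
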