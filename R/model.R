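#' Model architecture configuration
#'
#' The published full-scale architecture uses a 512-nt segment, six
#' residual blocks of six attention heads; the default here is a
#' desk-scale variant (128-nt segment, two blocks of four heads) that
#' trains on a synthetic genome in minutes while exercising the same
#' mechanics. `heads_per_layer * head_dim` must equal `embed_dim`;
#' `conv_width` must be odd (centred receptive field).
#'
#' @param segment_length segment (and attention window) length `l`.
#' @param num_layers number of residual blocks `k`.
#' @param heads_per_layer attention heads per block.
#' @param head_dim per-head query/key/value dimension.
#' @param embed_dim hidden-state dimension.
#' @param conv_width width of the convolution feeding q/k/v.
#' @param head_hidden width of the hidden layer of the output head.
#' @param pos_bias_init_sd initial spread of the relative-position
#'   score biases. Non-zero values break the symmetry between heads so
#'   that each starts with a (weak) random positional preference, which
#'   speeds up positional specialisation; 0 starts all heads uniform.
#' @param seed seed for weight initialisation.
#' @return named list (class `"tssformer_config"`).
#' @export
modelConfig <- function(segment_length = 128L, num_layers = 2L,
                        heads_per_layer = 4L, head_dim = 8L,
                        embed_dim = 32L, conv_width = 7L,
                        head_hidden = 32L, pos_bias_init_sd = 2,
                        seed = 1L) {
  cfg <- list(segment_length = as.integer(segment_length),
              num_layers = as.integer(num_layers),
              heads_per_layer = as.integer(heads_per_layer),
              head_dim = as.integer(head_dim),
              embed_dim = as.integer(embed_dim),
              conv_width = as.integer(conv_width),
              head_hidden = as.integer(head_hidden),
              pos_bias_init_sd = as.numeric(pos_bias_init_sd),
              output_classes = 2L,
              seed = as.integer(seed))
  if (cfg$heads_per_layer * cfg$head_dim != cfg$embed_dim)
    stop("heads_per_layer * head_dim must equal embed_dim")
  if (cfg$conv_width %% 2L == 0L) stop("conv_width must be odd")
  class(cfg) <- "tssformer_config"
  cfg
}

#' Full-scale configuration
#'
#' The full-scale architecture: 512-nt segments, six residual blocks,
#' six heads of dimension 16 (embedding 96).
#'
#' @param ... overrides passed to [modelConfig()].
#' @export
modelConfigFullScale <- function(...) {
  modelConfig(segment_length = 512L, num_layers = 6L, heads_per_layer = 6L,
              head_dim = 16L, embed_dim = 96L, ...)
}

#' Initialise a TransformerModel
#'
#' Weight matrices are drawn `N(0, 1/fan_in)` (per-block fan-in),
#' layer-norm gains start at 1, biases at 0, embeddings `N(0, 0.5^2)`,
#' and the relative-position biases `N(0, pos_bias_init_sd^2)` so heads
#' start with distinct weak positional preferences. Initialisation is
#' fully determined by `config$seed`.
#'
#' @param config a [modelConfig()].
#' @return a [TransformerModel-class].
#' @export
transformerModel <- function(config = modelConfig()) {
  lay <- .tx_param_layout(unclass(config))
  params <- .with_seed(config$seed, {
    unlist(lapply(seq_along(lay$block), function(i) {
      nm <- lay$block[[i]]; n <- lay$size[[i]]; fi <- lay$fan_in[[i]]
      if (grepl("ln_g$|lnf_g$", nm)) rep(1, n)
      else if (nm == "embed") rnorm(n, sd = 0.5)
      else if (grepl("relb$", nm)) rnorm(n, sd = config$pos_bias_init_sd)
      else if (fi > 0) rnorm(n, sd = sqrt(1 / fi))
      else rep(0, n)
    }))
  })
  new("TransformerModel", config = unclass(config), params = params)
}

#' Apply one attention head to explicit query/key/value vectors
#'
#' The core attention primitive: scores are the softmax over the
#' attendable rows of `q . K' / sqrt(dHead)` plus an optional additive
#' (relative-position) bias, and `z` is the score-weighted sum of the
#' value rows. Masked positions are simply not passed in; the query's
#' own position is always attendable, so the set is never empty.
#'
#' @param q numeric query vector (length `dHead`).
#' @param K,V matrices with one row per attendable position.
#' @param dHead scaling dimension (default `length(q)`).
#' @param bias optional additive score bias, one value per row of `K`.
#' @return list with `scores` (non-negative, summing to 1) and `z`.
#' @export
attentionHead <- function(q, K, V, dHead = length(q), bias = NULL) {
  K <- as.matrix(K); V <- as.matrix(V)
  if (is.null(bias)) bias <- numeric(nrow(K))
  .tx_attention_head(as.numeric(q), K, V, dHead, as.numeric(bias))
}

.encode_segment <- function(segment) {
  if (is.character(segment)) {
    codes <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
    s <- strsplit(toupper(segment), "", fixed = TRUE)[[1]]
    if (!all(s %in% names(codes)))
      stop("segment contains characters outside {A,C,G,T,N}")
    unname(codes[s])
  } else as.integer(segment)
}

#' Run one segment through the model
#'
#' Low-level entry point (training and prediction call it in a loop).
#' Returns per-position positive-class probabilities, the new per-layer
#' memory to pass to the next consecutive segment, and optionally every
#' attention record.
#'
#' @param model a [TransformerModel-class].
#' @param segment nucleotide string (or integer tokens, A=0..N=4) of
#'   length at most `segment_length`.
#' @param memory per-layer memory from the previous segment, or `NULL`
#'   for a segment with no left context.
#' @param recordAttention if `TRUE`, return the attention score array
#'   `[query, offset-index, layer*heads + head]`; offset index `i` maps
#'   to upstream offset `i - segment_length` + 1... i.e. the last column
#'   is the query position itself (offset 0).
#' @return list with `prob`, `newMemory`, and optionally `attention`.
#' @export
forwardSegment <- function(model, segment, memory = NULL,
                           recordAttention = FALSE) {
  tok <- .encode_segment(segment)
  cfg <- model@config
  if (length(tok) > cfg$segment_length) stop("segment longer than segment_length")
  mem <- if (is.null(memory)) list() else memory
  res <- .tx_segment_forward(model@params, cfg, tok, mem, recordAttention)
  out <- list(prob = res$prob, newMemory = res$new_mem)
  if (recordAttention) out$attention <- res$attention
  out
}

# forward one strand-local interval set; returns vector of length L
# (strand-local coordinates), zero outside the intervals
.predict_strand_local <- function(params, cfg, tokens, intervals_local) {
  L <- length(tokens)
  out <- numeric(L)
  l <- cfg$segment_length
  for (i in seq_len(nrow(intervals_local))) {
    a <- intervals_local$start[i]; b <- intervals_local$end[i]
    mem <- list()
    s <- a
    while (s < b) {
      e <- min(s + l, b)
      res <- .tx_segment_forward(params, cfg, tokens[(s + 1L):e], mem, FALSE)
      out[(s + 1L):e] <- res$prob
      mem <- res$new_mem
      s <- e
    }
  }
  out
}

.mirror_intervals <- function(iv, L) {
  out <- data.frame(start = L - iv$end, end = L - iv$start)
  out[order(out$start), , drop = FALSE]
}

#' Predict the output probability track along a genome
#'
#' Runs the model over both strands (the minus strand is processed as
#' the reverse complement, strand-locally) in consecutive segments with
#' carried memory, and returns the per-position probability of the
#' positive class in plus-strand coordinates.
#'
#' @param model a trained [TransformerModel-class].
#' @param g a [Genome-class].
#' @param intervals optional `data.frame(start, end)` restricting
#'   prediction to those plus-strand intervals (memory is reset at each
#'   interval start); positions outside are 0.
#' @return a [PredictionTrack-class].
#' @export
predictTrack <- function(model, g, intervals = NULL) {
  L <- genomeLength(g)
  if (is.null(intervals)) intervals <- data.frame(start = 0L, end = L)
  cfg <- model@config
  fwd <- .predict_strand_local(model@params, cfg, .tokenize(g, "+"), intervals)
  rev_local <- .predict_strand_local(model@params, cfg, .tokenize(g, "-"),
                                     .mirror_intervals(intervals, L))
  predictionTrack(fwd, rev(rev_local))
}

# cross-entropy of probabilities against 0/1 labels
.ce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(ifelse(y == 1L, log(p), log(1 - p)))
}

#' Train the model on a labelled genome
#'
#' Full-genome training: segments are visited in genomic order per
#' strand (plus strand, then the reverse-complemented minus strand),
#' carrying memory across consecutive segments within each training
#' interval; every position contributes to the unweighted two-class
#' cross-entropy (no negative subsampling). One segment is one Adam
#' step. After each epoch the validation loss is computed; the
#' parameters with minimal validation loss are kept, and training halts
#' once `patience` consecutive epochs fail to improve it.
#'
#' @param model a freshly initialised [TransformerModel-class].
#' @param g a [Genome-class].
#' @param labels a [LabelTrack-class].
#' @param splits interval list from [makeSplits()].
#' @param epochs maximum epochs.
#' @param lr,beta1,beta2,eps Adam hyper-parameters.
#' @param weightDecay decoupled (AdamW-style) weight decay applied to
#'   the weight matrices (convolution banks, head mixing, output head)
#'   but not to biases, layer norms, embeddings or the positional
#'   biases. With very few positive labels per epoch, decay steers the
#'   fit towards features shared across sites (the planted motifs)
#'   rather than per-position memorisation.
#' @param patience epochs without validation improvement before stopping.
#' @param verbose print per-epoch losses.
#' @return list with elements `model` (best checkpoint) and `report`
#'   (a [TrainReport-class]).
#' @export
trainModel <- function(model, g, labels, splits, epochs = 30L, lr = 3e-3,
                       beta1 = 0.9, beta2 = 0.98, eps = 1e-8,
                       weightDecay = 0.2, patience = 5L, verbose = FALSE) {
  cfg <- model@config
  L <- genomeLength(g)
  l <- cfg$segment_length
  tok <- list(`+` = .tokenize(g, "+"), `-` = .tokenize(g, "-"))
  lab <- list(`+` = labels@fwd, `-` = rev(labels@rev))
  tr_iv <- list(`+` = splits$train, `-` = .mirror_intervals(splits$train, L))
  va_iv <- list(`+` = splits$val, `-` = .mirror_intervals(splits$val, L))
  n_pos_train <- sum(vapply(c("+", "-"), function(st) {
    sum(unlist(lapply(seq_len(nrow(tr_iv[[st]])), function(i)
      lab[[st]][(tr_iv[[st]]$start[i] + 1L):tr_iv[[st]]$end[i]])))
  }, numeric(1)))
  if (n_pos_train == 0L)
    stop("no positive labels in the training split; cannot train")

  params <- model@params
  mAdam <- numeric(length(params)); vAdam <- numeric(length(params))
  step <- 0L
  lay <- .tx_param_layout(cfg)
  decay_mask <- rep(grepl("^(layer[0-9]+\\.W[qkvo]|W[12])$",
                          unlist(lay$block)),
                    times = unlist(lay$size))
  val_loss_of <- function(p) {
    tot <- 0; n <- 0
    for (st in c("+", "-")) {
      iv <- va_iv[[st]]
      pr <- .predict_strand_local(p, cfg, tok[[st]], iv)
      for (i in seq_len(nrow(iv))) {
        idx <- (iv$start[i] + 1L):iv$end[i]
        tot <- tot + .ce_loss(pr[idx], lab[[st]][idx]) * length(idx)
        n <- n + length(idx)
      }
    }
    tot / n
  }

  hist_tr <- numeric(0); hist_va <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad <- 0L
  for (ep in seq_len(epochs)) {
    ep_loss <- 0; ep_n <- 0
    for (st in c("+", "-")) {
      iv <- tr_iv[[st]]
      for (i in seq_len(nrow(iv))) {
        a <- iv$start[i]; b <- iv$end[i]
        mem <- list()
        s <- a
        while (s < b) {
          e <- min(s + l, b)
          res <- .tx_segment_grad(params, cfg, tok[[st]][(s + 1L):e],
                                  lab[[st]][(s + 1L):e], mem)
          mem <- res$new_mem
          if (res$n_loss > 0L) {
            step <- step + 1L
            gvec <- res$grad
            mAdam <- beta1 * mAdam + (1 - beta1) * gvec
            vAdam <- beta2 * vAdam + (1 - beta2) * gvec * gvec
            mh <- mAdam / (1 - beta1^step)
            vh <- vAdam / (1 - beta2^step)
            params <- params - lr * mh / (sqrt(vh) + eps) -
              lr * weightDecay * decay_mask * params
            ep_loss <- ep_loss + res$loss * res$n_loss
            ep_n <- ep_n + res$n_loss
          }
          s <- e
        }
      }
    }
    vl <- val_loss_of(params)
    hist_tr <- c(hist_tr, ep_loss / ep_n); hist_va <- c(hist_va, vl)
    if (verbose)
      message(sprintf("epoch %d: train %.5f, val %.5f", ep, ep_loss / ep_n, vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  report <- new("TrainReport",
                history = data.frame(epoch = seq_along(hist_tr),
                                     train_loss = hist_tr,
                                     val_loss = hist_va),
                bestEpoch = best$epoch, metrics = list())
  list(model = new("TransformerModel", config = cfg, params = best$params),
       report = report)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing plain-text YAML file holding the
#' configuration and the flat parameter vector.
#'
#' @param model a [TransformerModel-class].
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  yaml::write_yaml(list(config = model@config,
                        params = model@params), path, precision = 17L)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- do.call(modelConfig, x$config[intersect(names(x$config),
                                                 names(formals(modelConfig)))])
  new("TransformerModel", config = unclass(cfg),
      params = as.numeric(x$params))
}
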