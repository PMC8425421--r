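# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, exhaustive enumeration) and never
# share code with the implementation they check.

# connected components of the "within `window` nt, same strand" relation,
# by O(n^2) breadth-first search over an explicit adjacency matrix
oracle_components <- function(pool, window) {
  n <- nrow(pool)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- pool$strand[i] == pool$strand[j] &&
      abs(pool$pos[i] - pool$pos[j]) <= window
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; members <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- pool[sort(members), , drop = FALSE]
  }
  comps
}

# literal application of the three curation rules on top of
# oracle_components; returns a sorted data.frame(pos, strand)
oracle_curate <- function(sets, priorityOrder, window, preferred = NULL) {
  pool <- do.call(rbind, lapply(sets, function(s) {
    e <- tssformer::tssEntries(s)
    if (!nrow(e)) return(NULL)
    data.frame(source = tssformer::sourceName(s), pos = e$pos,
               strand = e$strand)
  }))
  rank_of <- stats::setNames(seq_along(priorityOrder), priorityOrder)
  out <- data.frame(pos = integer(), strand = character())
  for (cl in oracle_components(pool, window)) {
    if (length(unique(cl$source)) < 2) next
    # one vote per source: position closest to cluster median, ties -> smaller
    votes <- c()
    vote_src <- c()
    for (src in unique(cl$source)) {
      p <- cl$pos[cl$source == src]
      med <- stats::median(cl$pos)
      p <- p[order(abs(p - med), p)]
      votes <- c(votes, p[1]); vote_src <- c(vote_src, src)
    }
    cnt <- table(votes)
    winners <- as.integer(names(cnt)[cnt == max(cnt)])
    if (length(winners) == 1) {
      pos <- winners
    } else {
      best_rank <- Inf; pos <- NA
      for (i in order(votes)) {          # deterministic sweep
        if (votes[i] %in% winners && rank_of[vote_src[i]] < best_rank) {
          best_rank <- rank_of[vote_src[i]]; pos <- votes[i]
        } else if (votes[i] %in% winners && rank_of[vote_src[i]] == best_rank) {
          pos <- min(pos, votes[i])
        }
      }
    }
    out <- rbind(out, data.frame(pos = pos, strand = cl$strand[1]))
  }
  if (!is.null(preferred)) {
    pe <- tssformer::tssEntries(sets[[which(vapply(sets, tssformer::sourceName,
                                                   character(1)) == preferred)]])
    for (i in seq_len(nrow(pe))) {
      near <- out$pos[out$strand == pe$strand[i]]
      if (!length(near) || min(abs(near - pe$pos[i])) > window)
        out <- rbind(out, data.frame(pos = pe$pos[i], strand = pe$strand[i]))
    }
  }
  out <- unique(out)
  out <- out[order(out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ROC AUC by exhaustive positive/negative pair comparison, ties = 1/2
oracle_roc_auc <- function(scores, labels) {
  ip <- which(labels == 1); ineg <- which(labels == 0)
  tot <- 0
  for (i in ip) for (j in ineg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(ip) * length(ineg))
}

# PR AUC by stepping through every distinct threshold (step-wise curve)
oracle_pr_auc <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  auc <- 0; prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    auc <- auc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  auc
}

# Spearman rho via hand-computed average ranks + explicit Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- naive R re-implementation of the full forward pass (no memory) ----
# follows the documented parameter layout; used as the oracle for the
# compiled forward on small configurations

unpack_params <- function(params, cfg) {
  lay <- tssformer:::.tx_param_layout(cfg)
  out <- list(); off <- 0L
  E <- cfg$embed_dim; cw <- cfg$conv_width; l <- cfg$segment_length
  H <- cfg$heads_per_layer; hh <- cfg$head_hidden
  dims <- function(nm) {
    if (nm == "embed") c(5L, E)
    else if (grepl("W[qkv]$", nm)) c(cw * E, E)
    else if (grepl("relb$", nm)) c(l, H)
    else if (grepl("Wo$", nm)) c(E, E)
    else if (nm == "W1") c(E, hh)
    else if (nm == "W2") c(hh, 2L)
    else NULL
  }
  for (i in seq_along(lay$block)) {
    nm <- lay$block[[i]]; n <- lay$size[[i]]
    v <- params[(off + 1):(off + n)]; off <- off + n
    d <- dims(nm)
    out[[nm]] <- if (is.null(d)) v else matrix(v, d[1], d[2])
  }
  out
}

naive_forward <- function(params, cfg, tok) {
  W <- unpack_params(params, cfg)
  E <- cfg$embed_dim; cw <- cfg$conv_width; l <- cfg$segment_length
  H <- cfg$heads_per_layer; dh <- cfg$head_dim
  n <- length(tok)
  ln <- function(X, g, b) t(apply(X, 1, function(x) {
    mu <- mean(x); v <- mean((x - mu)^2)
    (x - mu) / sqrt(v + 1e-5) * g + b
  }))
  h <- W$embed[tok + 1L, , drop = FALSE]
  attn <- array(0, dim = c(n, l, cfg$num_layers * H))
  c2 <- (cw - 1) / 2
  for (li in seq_len(cfg$num_layers)) {
    p <- function(nm) W[[sprintf("layer%d.%s", li, nm)]]
    Xn <- ln(h, p("ln_g"), p("ln_b"))
    U <- matrix(0, n, cw * E)
    for (t in seq_len(n)) for (w0 in 0:(cw - 1)) {
      src <- t + w0 - c2
      if (src >= 1 && src <= n) U[t, (w0 * E + 1):((w0 + 1) * E)] <- Xn[src, ]
    }
    Q <- sweep(U %*% p("Wq"), 2, p("bq"), "+")
    K <- sweep(U %*% p("Wk"), 2, p("bk"), "+")
    V <- sweep(U %*% p("Wv"), 2, p("bv"), "+")
    Z <- matrix(0, n, E)
    for (hd in seq_len(H)) {
      cols <- ((hd - 1) * dh + 1):(hd * dh)
      for (t in seq_len(n)) {
        js <- max(1, t - l + 1):t
        s <- sapply(js, function(j)
          sum(Q[t, cols] * K[j, cols]) / sqrt(dh) + p("relb")[t - j + 1, hd])
        s <- exp(s - max(s)); s <- s / sum(s)
        Z[t, cols] <- colSums(s * V[js, cols, drop = FALSE])
        attn[t, l - (t - js), (li - 1) * H + hd] <- s
      }
    }
    h <- h + sweep(Z %*% p("Wo"), 2, p("bo"), "+")
  }
  Y <- ln(h, W$lnf_g, W$lnf_b)
  O1 <- pmax(sweep(Y %*% W$W1, 2, W$b1, "+"), 0)
  logit <- sweep(O1 %*% W$W2, 2, W$b2, "+")
  prob <- apply(logit, 1, function(z) { z <- exp(z - max(z)); z[2] / sum(z) })
  list(prob = prob, attention = attn)
}
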