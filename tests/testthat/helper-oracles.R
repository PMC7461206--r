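# Independent oracles used by the test suite. These deliberately re-derive
# results by brute force / closed form, never by calling the code they check.

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Gotoh affine-gap global alignment score (gap of length L costs
# open + L * extend, matching Biostrings' gapOpening/gapExtension model).
gotoh_score <- function(a, b, submat, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -(open + extend * (j - 1))
  for (i in 2:(n + 1)) X[i, 1] <- -(open + extend * (i - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                     Y[i - 1, j] - open - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                     X[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Enumerate all unrooted binary topologies on tips 1..n (n <= 6) as edge
# matrices; internal nodes are numbered n+1, n+2, ...
enumerate_topologies <- function(n) {
  base <- list(list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                    next_node = n + 2))
  trees <- base
  for (tip in seq(4, length.out = max(0, n - 3))) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        u <- ed[e, 1]; v <- ed[e, 2]
        w <- tr$next_node
        ed <- ed[-e, , drop = FALSE]
        ed <- rbind(ed, c(u, w), c(w, v), c(w, tip))
        nxt[[length(nxt) + 1]] <- list(edges = ed, next_node = w + 1)
      }
    }
    trees <- nxt
  }
  lapply(trees, `[[`, "edges")
}

# Tips on each side of every internal edge -> canonical split keys.
topology_splits <- function(edges, n, labels) {
  adj <- lapply(seq_len(max(edges)), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  reach <- function(start, blocked) {
    seen <- c(start); queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (w == blocked || w %in% seen) next
        seen <- c(seen, w); queue <- c(queue, w)
      }
    }
    seen
  }
  keys <- character(0)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    side <- sort(intersect(reach(v, u), seq_len(n)))
    if (length(side) < 2 || length(side) > n - 2) next
    if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
    keys <- c(keys, paste(labels[side], collapse = "|"))
  }
  sort(unique(keys))
}

# Least-squares branch-length fit of a distance matrix on a fixed topology;
# returns the residual sum of squares (0 for the generating topology of an
# additive matrix, with nonnegative branch lengths).
ls_fit_rss <- function(edges, d) {
  n <- nrow(d)
  adj <- lapply(seq_len(max(edges)), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], k)
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], k)
  }
  other_end <- function(k, v) setdiff(edges[k, ], v)
  path_edges <- function(from, to) {
    # DFS carrying the edge trail
    stack <- list(list(node = from, used = integer(0)))
    while (length(stack)) {
      st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (st$node == to) return(st$used)
      for (k in adj[[st$node]]) {
        if (k %in% st$used) next
        stack[[length(stack) + 1]] <-
          list(node = other_end(k, st$node), used = c(st$used, k))
      }
    }
    stop("disconnected topology")
  }
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(edges))
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    A[p, path_edges(pairs[1, p], pairs[2, p])] <- 1
    y[p] <- d[pairs[1, p], pairs[2, p]]
  }
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

# Naive average-linkage agglomeration returning sorted merge heights.
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); besth <- Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < besth - 1e-12) { besth <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, besth)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  sort(heights)
}

# Canonical split keys of an ape tree (oracle-side reimplementation).
phylo_splits <- function(tree) {
  labs_all <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs_all)
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (labs_all[1] %in% side) side <- setdiff(labs_all, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
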