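# Brute-force reference implementations used as independent oracles.
# Each is written directly from the rule's definition, deliberately
# ignoring efficiency, and is only ever run on small inputs.

# clusters = connected components of the graph joining positions at most
# `gap` apart (transitive closure over the pairwise distance relation)
oracle_partition <- function(positions, gap = 100) {
  n <- length(positions)
  adj <- abs(outer(positions, positions, "-")) <= gap
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  lapply(unique(comp), function(k) positions[comp == k])
}

# all compositions of 1..n into contiguous blocks
all_compositions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (first in seq_len(n)) {
    head <- seq_len(first)
    if (first == n) {
      out[[length(out) + 1L]] <- list(head)
    } else {
      for (rest in all_compositions(n - first)) {
        out[[length(out) + 1L]] <- c(list(head),
                                     lapply(rest, function(b) b + first))
      }
    }
  }
  out
}

# among all ordered partitions, pick the greedy-equivalent one: every
# prefix of every block keeps sd < thr (blocks grow one position at a
# time), and each block is maximal (adding the next block's first
# position would reach sd >= thr). Exactly one composition qualifies.
oracle_subcluster <- function(positions, thr = 10) {
  sd0 <- function(x) if (length(x) == 1L) 0 else stats::sd(x)
  prefix_ok <- function(b) {
    all(vapply(seq_along(b), function(i) sd0(positions[b[seq_len(i)]]) < thr,
               logical(1)))
  }
  valid <- Filter(function(comp) {
    if (!all(vapply(comp, prefix_ok, logical(1)))) return(FALSE)
    for (i in seq_along(comp)[-length(comp)]) {
      ext <- c(comp[[i]], comp[[i + 1L]][1L])
      if (sd0(positions[ext]) < thr) return(FALSE)  # block not maximal
    }
    TRUE
  }, all_compositions(length(positions)))
  stopifnot(length(valid) == 1L)
  lapply(valid[[1L]], function(b) positions[b])
}

# classification by testing every (TSS, gene) pair against the window
# definition, then resolving primaries per gene
oracle_classify <- function(cands, genes, upstream = 500, downstream = 150) {
  n <- nrow(cands)
  lab <- rep(NA_character_, n)
  gene_of <- rep(NA_character_, n)
  sc <- ifelse(genes$strand == "+", genes$start, genes$end)
  assigned <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best_g <- NA_integer_; best_d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (genes$strand[g] != cands$strand[i]) next
      off <- if (genes$strand[g] == "+") cands$position[i] - sc[g] else sc[g] - cands$position[i]
      if (off >= -upstream && off <= downstream) {
        d <- abs(cands$position[i] - sc[g])
        if (d < best_d || (d == best_d && genes$start[g] < genes$start[best_g])) {
          best_g <- g; best_d <- d
        }
      }
    }
    assigned[i] <- best_g
  }
  for (g in unique(assigned[!is.na(assigned)])) {
    idx <- which(assigned == g)
    hmax <- max(cands$height[idx])
    top <- idx[cands$height[idx] == hmax]
    if (length(top) > 1L) {
      dd <- abs(cands$position[top] - sc[g])
      top <- top[dd == min(dd)]
      top <- if (genes$strand[g] == "+") top[which.min(cands$position[top])] else
        top[which.max(cands$position[top])]
    }
    lab[idx] <- "S"; lab[top[1L]] <- "P"
    gene_of[idx] <- genes$gene_id[g]
  }
  for (i in which(is.na(lab))) {
    inside <- genes$start <= cands$position[i] & genes$end >= cands$position[i]
    if (any(inside & genes$strand == cands$strand[i])) lab[i] <- "I"
    else if (any(inside)) lab[i] <- "A"
    else lab[i] <- "N"
  }
  list(class_label = lab, gene_id = gene_of)
}

IUPAC_SET <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

# regex-free sliding-window IUPAC match
oracle_scan <- function(window, pattern) {
  w <- strsplit(window, "")[[1L]]
  p <- strsplit(pattern, "")[[1L]]
  k <- length(p)
  hits <- integer(0)
  for (s in seq_len(length(w) - k + 1L)) {
    if (all(mapply(function(a, b) a %in% IUPAC_SET[[b]],
                   w[s:(s + k - 1L)], p))) {
      hits <- c(hits, s)
    }
  }
  hits
}

# naive O(n^3) agglomerative clustering; returns membership at k clusters
oracle_hclust <- function(mat, k, metric = "manhattan") {
  dfun <- function(a, b) {
    if (metric == "manhattan") sum(abs(a - b)) else sqrt(sum((a - b)^2))
  }
  clusters <- as.list(seq_len(nrow(mat)))
  while (length(clusters) > k) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        # complete linkage: max pairwise distance
        d <- max(outer(clusters[[i]], clusters[[j]],
                       Vectorize(function(a, b) dfun(mat[a, ], mat[b, ]))))
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  memb <- integer(nrow(mat))
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  memb
}

# two labellings describe the same partition?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
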