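# Independent brute-force oracles. These deliberately share no code with
# the package internals: distances are computed on split character
# vectors, orientation uses Biostrings, and clustering is re-derived from
# the stated rules step by step.

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

oracle_majority <- function(seqs, weights) {
  cols <- nchar(seqs[1])
  chars <- strsplit(seqs, "")
  paste(vapply(seq_len(cols), function(j) {
    votes <- c(A = 0, C = 0, G = 0, T = 0)
    for (i in seq_along(seqs)) {
      b <- chars[[i]][j]
      votes[b] <- votes[b] + weights[i]
    }
    names(votes)[votes == max(votes)][1] # names sorted A<C<G<T
  }, character(1)), collapse = "")
}

# Exhaustive re-derivation of the stacking rule: group identical canonical
# reads, order by (depth desc, consensus), assign each to the earliest
# retained founder within max_dist of its founding read, majority
# consensus, depth filter.
oracle_stacks <- function(reads, min_depth = 3, max_dist = 2) {
  reads <- oracle_canonical(reads)
  tab <- sort(table(reads), decreasing = TRUE)
  df <- data.frame(seq = names(tab), depth = as.integer(tab),
    stringsAsFactors = FALSE)
  df <- df[order(-df$depth, df$seq), ]
  founders <- list() # each: list(founder_seq, members, depths)
  for (i in seq_len(nrow(df))) {
    placed <- FALSE
    for (k in seq_along(founders)) {
      if (oracle_hamming(df$seq[i], founders[[k]]$founder) <= max_dist) {
        founders[[k]]$members <- c(founders[[k]]$members, df$seq[i])
        founders[[k]]$depths <- c(founders[[k]]$depths, df$depth[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      founders[[length(founders) + 1]] <- list(founder = df$seq[i],
        members = df$seq[i], depths = df$depth[i])
    }
  }
  out <- lapply(founders, function(f) {
    list(consensus = oracle_majority(f$members, f$depths),
      depth = sum(f$depths))
  })
  out[vapply(out, `[[`, numeric(1), "depth") >= min_depth]
}

# Catalog rule: pool (sample, consensus, depth), order by depth desc then
# consensus then sample, greedy single-linkage against existing loci.
oracle_catalog <- function(pooled, max_dist = 1) {
  pooled <- pooled[order(-pooled$depth, pooled$consensus, pooled$sample), ]
  loci <- list() # each: list(members = row indices)
  for (i in seq_len(nrow(pooled))) {
    placed <- FALSE
    for (k in seq_along(loci)) {
      dmin <- min(vapply(loci[[k]]$members, function(m) {
        oracle_hamming(pooled$consensus[i], pooled$consensus[m])
      }, numeric(1)))
      if (dmin <= max_dist) {
        loci[[k]]$members <- c(loci[[k]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) loci[[length(loci) + 1]] <- list(members = i)
  }
  lapply(loci, function(l) {
    list(
      consensus = oracle_majority(pooled$consensus[l$members],
        pooled$depth[l$members]),
      depth = sum(pooled$depth[l$members]),
      samples = sort(unique(pooled$sample[l$members])))
  })
}

# Stack multiset as a sortable signature for set comparison.
stack_signature <- function(consensus, depth) {
  sort(paste(consensus, depth, sep = ":"))
}

oracle_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- which(m[i, ] == 1)
      b <- which(m[j, ] == 1)
      u <- length(union(a, b))
      d[i, j] <- if (u == 0) 0 else 1 - length(intersect(a, b)) / u
    }
  }
  d
}

# Brute-force UPGMA (average linkage over original distances).
oracle_average_linkage <- function(d) {
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  avg <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    besth <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- avg(clusters[[i]], clusters[[j]])
          if (h < besth) {
            besth <- h
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, besth)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

oracle_p_distance <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  ok <- !(va %in% c("-", "N")) & !(vb %in% c("-", "N"))
  if (!any(ok)) stop("no comparable sites")
  sum(va[ok] != vb[ok]) / sum(ok)
}

# Random additive distance matrix from a random tree with branch lengths
# in [0.01, 0.5]; returns the matrix and the generating tree.
random_additive_matrix <- function(n) {
  tree <- ape::rtree(n, br = function(k) runif(k, 0.01, 0.5))
  tree$tip.label <- sprintf("t%02d", seq_len(n))
  d <- stats::cophenetic(tree)
  o <- order(rownames(d))
  list(d = d[o, o], tree = tree)
}

random_reads <- function(n, len = 12) {
  base_pool <- replicate(max(2, n %/% 5),
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
      collapse = ""))
  vapply(seq_len(n), function(i) {
    s <- sample(base_pool, 1)
    v <- strsplit(s, "")[[1]]
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(len, k)
      v[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    paste(v, collapse = "")
  }, character(1))
}
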