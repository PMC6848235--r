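#' Pairwise p-distances with pairwise deletion
#'
#' Proportion of differing sites between every pair of aligned sequences,
#' counting only columns where neither sequence carries a gap (`-`) or an
#' `N`. Computed through [ape::dist.dna()] with the raw model and pairwise
#' deletion.
#'
#' @param alignment named character vector of aligned sequences over
#'   {A,C,G,T,N,-}, equal length, unique labels.
#' @return Symmetric matrix of p-distances. A pair with zero comparable
#'   sites is an error naming the pair.
#' @export
p_distance <- function(alignment) {
  if (length(alignment) < 2) stop("alignment needs >= 2 sequences")
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    stop("alignment rows must carry unique labels")
  }
  if (length(unique(nchar(alignment))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  bad <- grepl("[^ACGTN-]", alignment)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N,-}: ",
      paste(names(alignment)[bad], collapse = ", "))
  }
  chars <- do.call(rbind, strsplit(tolower(alignment), "", fixed = TRUE))
  rownames(chars) <- names(alignment)
  bin <- ape::as.DNAbin(chars)
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE,
    as.matrix = TRUE)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop("no comparable sites between ", rownames(d)[bad[1]], " and ",
      colnames(d)[bad[2]])
  }
  d[names(alignment), names(alignment)]
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differing sites into expected
#' substitutions per site under the one-parameter equal-rates model:
#' `d = -(3/4) * log(1 - 4p/3)`. The correction saturates at p = 0.75.
#'
#' @param p proportion(s) of differing sites; scalar, vector or matrix in
#'   `[0, 0.75)`.
#' @return Corrected distance(s), same shape as `p`.
#' @export
jc_distance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) {
    stop("p >= 0.75: Jukes-Cantor correction is saturated")
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  d[p == 0] <- 0
  d
}

# label of a cluster = its lexicographically smallest leaf label
pair_key <- function(a, b) {
  if (a <= b) c(a, b) else c(b, a)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q
#' are broken toward the lexicographically smallest pair of (smallest-leaf)
#' cluster labels; negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling edge. For two taxa the result is the
#' single edge of their distance (split evenly across the root).
#'
#' @param d symmetric distance matrix with unique labels.
#' @return Unrooted `phylo` tree (class from \pkg{ape}).
#' @export
nj_tree <- function(d) {
  check_square_distance(d)
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2) stop("need >= 2 taxa")
  fmt <- function(x) sprintf("%.15g", x)
  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(d[1, 2] / 2),
      labs[2], fmt(d[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  D <- d
  frag <- labs        # Newick fragment per active node
  minlab <- labs      # smallest contained leaf label per active node
  while (length(frag) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(pair_key(minlab[ij[1]], minlab[ij[2]]), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newmin <- pair_key(minlab[i], minlab[j])[1]
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- pmax(dnew, 0)[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], newfrag)
    minlab <- c(minlab[-c(i, j)], newmin)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  x <- max(0, (d12 + d13 - d23) / 2)
  y <- max(0, (d12 + d23 - d13) / 2)
  z <- max(0, (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(x), frag[2], fmt(y),
    frag[3], fmt(z))
  ape::read.tree(text = txt)
}

#' Patristic distances between tree tips
#'
#' Sum of branch lengths along the unique path between every pair of
#' leaves; invariant under re-rooting.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Symmetric matrix of patristic distances, tips sorted by label.
#' @export
patristic <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree is missing branch lengths")
  }
  d <- ape::cophenetic.phylo(tree)
  o <- order(rownames(d))
  d[o, o]
}

#' Fixed-threshold clustering of taxa by genetic distance
#'
#' Groups taxa whose pairwise distances fall within a fixed threshold
#' (default 0.025, i.e. 2.5% — a conventional inter-species cutoff for
#' mitochondrial barcodes). Single linkage (default) takes the connected
#' components of the graph with an edge wherever distance <= threshold;
#' complete linkage cuts an agglomerative complete-linkage dendrogram at
#' the threshold, so every within-cluster pair satisfies it. Clusters are
#' numbered by their smallest member label; a cluster of size one is an
#' orphan taxon — a tip with no sampled close relative.
#'
#' @param d symmetric distance matrix (patristic or sequence distances).
#' @param threshold maximum distance (default 0.025).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return A data frame of class `cluster_assignment`: `taxon`, `cluster`,
#'   `orphan`; attributes `threshold`, `linkage` and `sizes` (taxa per
#'   cluster).
#' @export
threshold_clusters <- function(d, threshold = 0.025,
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  check_square_distance(d)
  if (threshold < 0) stop("threshold must be >= 0")
  labs <- rownames(d)
  n <- length(labs)
  if (linkage == "single") {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (d[i, j] <= threshold) {
          a <- find(i); b <- find(j)
          if (a != b) parent[b] <- a
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
  } else {
    if (n == 1) {
      comp <- 1L
    } else {
      o <- order(labs)
      hc <- stats::hclust(as.dist(d[o, o, drop = FALSE]),
        method = "complete")
      grp <- rep(NA_integer_, n)
      merged <- cut_groups(hc, height = threshold + .Machine$double.eps *
          max(1, threshold) * 4)
      grp[o] <- merged[labs[o]]
      comp <- grp
    }
  }
  # number clusters by smallest member label
  reps <- tapply(labs, comp, min)
  cluster_of_comp <- match(reps, sort(reps))
  cluster <- cluster_of_comp[match(comp, as.integer(names(reps)))]
  sizes <- as.integer(table(cluster))
  out <- data.frame(taxon = labs, cluster = cluster,
    orphan = sizes[cluster] == 1L, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "linkage") <- linkage
  attr(out, "sizes") <- sizes
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Sampling-occupancy summary of a cluster assignment
#'
#' Describes how evenly taxa fill the clusters: how many clusters exist,
#' how many are orphans (single taxa), and how many taxa sit inside the
#' `top_m` largest clusters — the pattern used to expose uneven sampling
#' across a summary phylogeny.
#'
#' @param assignment a [threshold_clusters()] result.
#' @param top_m number of largest clusters to aggregate (capped at the
#'   cluster count, with a warning).
#' @return List with `n_clusters`, `n_taxa`, `orphan_clusters`,
#'   `n_orphans`, `taxa_in_top_m`, `largest_cluster_size`, `top_m`.
#' @export
occupancy_report <- function(assignment, top_m = 1) {
  stopifnot(inherits(assignment, "cluster_assignment"),
    nrow(assignment) > 0)
  sizes <- table(assignment$cluster)
  k <- length(sizes)
  if (top_m > k) {
    warning("top_m exceeds cluster count; capped at ", k)
    top_m <- k
  }
  sorted <- sort(as.integer(sizes), decreasing = TRUE)
  list(
    n_clusters = k,
    n_taxa = nrow(assignment),
    orphan_clusters = sort(unique(assignment$cluster[assignment$orphan])),
    n_orphans = sum(sizes == 1L),
    taxa_in_top_m = sum(sorted[seq_len(top_m)]),
    largest_cluster_size = sorted[1],
    top_m = top_m
  )
}

#' Reference divergence thresholds for mitochondrial barcodes
#'
#' Conventional CO1 divergence landmarks: the maximum divergence commonly
#' observed among populations within one species (3.78%) and the range
#' spanned by species within one genus (11.06%).
#'
#' @param intraspecific_max maximum intraspecific divergence (proportion).
#' @param congeneric_max maximum congeneric interspecific divergence.
#' @return List of class `divergence_reference`.
#' @export
divergence_reference <- function(intraspecific_max = 0.0378,
                                 congeneric_max = 0.1106) {
  if (intraspecific_max >= congeneric_max) {
    stop("intraspecific_max must be below congeneric_max")
  }
  structure(list(intraspecific_max = intraspecific_max,
    congeneric_max = congeneric_max), class = "divergence_reference")
}

#' Divergence report against reference thresholds
#'
#' For every cluster, the maximum within-cluster distance (NA for an
#' orphan); for every cluster pair, the minimum between-cluster distance.
#' Both are compared against the reference thresholds in each direction —
#' whether within-cluster divergence stays inside the intraspecific range
#' (consistent with one species per cluster) and whether between-cluster
#' divergence exceeds it and sits within the congeneric range.
#'
#' @param d distance matrix over the clustered taxa.
#' @param assignment a [threshold_clusters()] result on the same taxa.
#' @param ref a [divergence_reference()].
#' @return List of class `divergence_report` with data frames `intra`
#'   (`cluster`, `size`, `max_intra`, `within_intraspecific_range`) and
#'   `inter` (`cluster_a`, `cluster_b`, `min_inter`,
#'   `above_intraspecific_max`, `within_congeneric_range`); `inter` has
#'   zero rows when all taxa share one cluster.
#' @export
divergence_report <- function(d, assignment, ref = divergence_reference()) {
  check_square_distance(d)
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!setequal(rownames(d), assignment$taxon)) {
    stop("assignment must partition the distance-matrix labels")
  }
  cl <- setNames(assignment$cluster, assignment$taxon)[rownames(d)]
  ids <- sort(unique(cl))
  intra <- do.call(rbind, lapply(ids, function(g) {
    idx <- which(cl == g)
    mx <- if (length(idx) < 2) NA_real_ else max(d[idx, idx])
    data.frame(cluster = g, size = length(idx), max_intra = mx,
      within_intraspecific_range = mx <= ref$intraspecific_max)
  }))
  inter <- if (length(ids) < 2) {
    data.frame(cluster_a = integer(), cluster_b = integer(),
      min_inter = numeric(), above_intraspecific_max = logical(),
      within_congeneric_range = logical())
  } else {
    do.call(rbind, lapply(utils::combn(ids, 2, simplify = FALSE),
      function(pr) {
        mn <- min(d[cl == pr[1], cl == pr[2], drop = FALSE])
        data.frame(cluster_a = pr[1], cluster_b = pr[2], min_inter = mn,
          above_intraspecific_max = mn > ref$intraspecific_max,
          within_congeneric_range = mn <= ref$congeneric_max)
      }))
  }
  structure(list(intra = intra, inter = inter, reference = ref),
    class = "divergence_report")
}

#' Delimit species from an aligned marker (or a supplied tree)
#'
#' The marker-side delimitation chain: p-distances with pairwise deletion,
#' Jukes-Cantor correction, neighbor joining, patristic distances on the
#' resulting (or a user-supplied) tree, and fixed-threshold tip
#' clustering. With `source = "sequence"` the JC distances are clustered
#' directly, skipping the tree.
#'
#' @param alignment named character vector of aligned sequences; may be
#'   `NULL` when `tree` is given and `source = "patristic"`.
#' @param tree optional `phylo` tree; inferred by [nj_tree()] when absent.
#' @param threshold clustering threshold (default 0.025).
#' @param linkage `"single"` or `"complete"`.
#' @param source `"patristic"` (default) or `"sequence"` distances.
#' @return List with `clusters` (a [threshold_clusters()] assignment),
#'   `tree` (`phylo` or `NULL`), `distances` (the matrix clustered) and
#'   `jc` (JC-corrected sequence distances, when an alignment was given).
#' @export
delimit_markers <- function(alignment = NULL, tree = NULL,
                            threshold = 0.025,
                            linkage = c("single", "complete"),
                            source = c("patristic", "sequence")) {
  linkage <- match.arg(linkage)
  source <- match.arg(source)
  jc <- NULL
  if (!is.null(alignment)) jc <- jc_distance(p_distance(alignment))
  if (source == "sequence") {
    if (is.null(jc)) stop("source = \"sequence\" requires an alignment")
    dmat <- jc
    tree <- NULL
  } else {
    if (is.null(tree)) {
      if (is.null(jc)) stop("supply an alignment or a tree")
      tree <- nj_tree(jc)
    }
    dmat <- patristic(tree)
  }
  list(clusters = threshold_clusters(dmat, threshold, linkage),
    tree = tree, distances = dmat, jc = jc)
}
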