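#' Pairwise distances between presence/absence profiles
#'
#' Jaccard distance treats each row as the set of loci present:
#' `1 - |A intersect B| / |A union B|` (0 when both sets are empty).
#' Hamming distance is the fraction of columns where the two rows differ.
#' Jaccard is the default throughout the pipeline because catalog columns
#' are dominated by shared absence, which Jaccard ignores.
#'
#' @param m presence/absence matrix (rows samples, entries 0/1).
#' @param metric `"jaccard"` or `"hamming"`.
#' @return Symmetric distance matrix with zero diagonal, labels from
#'   `rownames(m)`.
#' @export
row_distance <- function(m, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  if (!is.matrix(m) || nrow(m) < 2) stop("need a matrix with >= 2 rows")
  if (is.null(rownames(m))) stop("matrix rows must be labelled")
  if (!all(m %in% c(0, 1))) stop("matrix entries must be 0 or 1")
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  if (metric == "jaccard") {
    sizes <- rowSums(m)
    un <- outer(sizes, sizes, "+") - inter
    d <- 1 - inter / un
    d[un == 0] <- 0
  } else {
    if (ncol(m) == 0) {
      d <- matrix(0, nrow(m), nrow(m))
    } else {
      both0 <- tcrossprod(1 - m)
      d <- (ncol(m) - inter - both0) / ncol(m)
    }
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Agglomerative clustering of samples
#'
#' Standard hierarchical agglomeration of a distance matrix via
#' [stats::hclust()]. Rows are put in lexicographic label order first so
#' that tie-breaking among equal merge candidates is deterministic and
#' follows the smallest label pair.
#'
#' @param d symmetric distance matrix with labels.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return An [stats::hclust] dendrogram; `$order` gives the leaf order
#'   used to arrange matrix rows for display.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  check_square_distance(d)
  o <- order(rownames(d))
  stats::hclust(as.dist(d[o, o, drop = FALSE]), method = linkage)
}

#' Cut a dendrogram into sample groups
#'
#' Either into exactly `k` groups, or at a height: groups are the
#' components formed by merges strictly below `height`.
#'
#' @param dendrogram an [stats::hclust] object.
#' @param k number of groups (1..n).
#' @param height cut height (>= 0); used when `k` is missing.
#' @return Named integer vector: sample -> group id.
#' @export
cut_groups <- function(dendrogram, k = NULL, height = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("k must lie in 1..", n)
    return(cutree(dendrogram, k = k))
  }
  if (is.null(height)) stop("supply k or height")
  if (height < 0) stop("height must be >= 0")
  # union-find over merges with height strictly below the cut
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  node_rep <- integer(nrow(dendrogram$merge)) # leaf representative per merge
  for (r in seq_len(nrow(dendrogram$merge))) {
    ch <- dendrogram$merge[r, ]
    reps <- ifelse(ch < 0, -ch, node_rep[pmax(ch, 1L)])
    node_rep[r] <- reps[1]
    if (dendrogram$height[r] < height) {
      a <- find(reps[1]); b <- find(reps[2])
      parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- match(roots, unique(roots))
  setNames(grp, dendrogram$labels)
}

#' Exclusive shared-locus report per sample group
#'
#' For each group, counts the catalog loci present in the group (under the
#' chosen quantifier: present in ALL members, the default, or in ANY
#' member) and absent from every sample outside the group, and expresses
#' the count as a fraction of all catalog loci. These exclusive fractions
#' are the SNP-coverage evidence for species boundaries: a clean species
#' group privately shares a sizable fraction of the catalog.
#'
#' @param m presence/absence matrix.
#' @param partition named vector: sample -> group, covering `rownames(m)`.
#' @param quantifier `"all"` (default) or `"any"` membership rule.
#' @return A data frame of class `group_report`: `group`, `n_samples`,
#'   `exclusive_count`, `exclusive_fraction`.
#' @export
group_shared_fraction <- function(m, partition,
                                  quantifier = c("all", "any")) {
  quantifier <- match.arg(quantifier)
  if (!all(rownames(m) %in% names(partition))) {
    stop("partition must cover every matrix row")
  }
  partition <- partition[rownames(m)]
  groups <- sort(unique(partition))
  rows <- lapply(groups, function(g) {
    inside <- rownames(m)[partition == g]
    if (length(inside) == 0) stop("empty group: ", g)
    outside <- setdiff(rownames(m), inside)
    pres <- colSums(m[inside, , drop = FALSE])
    in_group <- if (quantifier == "all") pres == length(inside) else pres >= 1
    out_absent <- if (length(outside)) {
      colSums(m[outside, , drop = FALSE]) == 0
    } else {
      rep(TRUE, ncol(m))
    }
    cnt <- sum(in_group & out_absent)
    data.frame(group = g, n_samples = length(inside),
      exclusive_count = cnt,
      exclusive_fraction = if (ncol(m) > 0) cnt / ncol(m) else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_report", class(out))
  out
}
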