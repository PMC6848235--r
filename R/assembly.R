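#' Parameters of the simplified de-novo RAD assembly
#'
#' The three rules of the assembly: a per-sample stack must reach a minimum
#' read depth to be called a locus, stacks within one sample are merged at
#' a fixed Hamming distance, and per-sample consensus loci are merged
#' across samples into catalog loci at a (typically tighter) Hamming
#' distance. Distances are mismatch counts on fixed-length reads; indels
#' are not modeled.
#'
#' @param min_depth minimum total read depth for a stack to be retained
#'   (default 3).
#' @param within_sample_max_dist maximum Hamming distance for merging
#'   stacks within a sample (default 2).
#' @param cross_sample_max_dist maximum Hamming distance for merging
#'   per-sample consensus loci across samples (default 1; set 0 for the
#'   strict reading of "distance less than 1").
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(min_depth = 3,
                            within_sample_max_dist = 2,
                            cross_sample_max_dist = 1) {
  stopifnot(min_depth >= 0, within_sample_max_dist >= 0,
    cross_sample_max_dist >= 0)
  structure(
    list(min_depth = as.integer(min_depth),
      within_sample_max_dist = as.integer(within_sample_max_dist),
      cross_sample_max_dist = as.integer(cross_sample_max_dist)),
    class = "assembly_params")
}

#' Build read stacks for one sample
#'
#' Groups identical (canonically oriented) reads into primary stacks, then
#' greedily merges them: primary stacks are processed in decreasing depth
#' order (ties broken by lexicographic consensus); each stack merges into
#' the earliest-processed retained stack whose founding consensus lies
#' within `within_sample_max_dist` mismatches, otherwise it is retained
#' itself. Consensus sequences are then recomputed as the depth-weighted
#' per-column majority (ties to the lexicographically smallest base), and
#' stacks below `min_depth` total reads are discarded.
#'
#' @param reads character vector of equal-length reads; orientation is
#'   canonicalized internally.
#' @param params an [assembly_params()].
#' @return A data frame of retained stacks with columns `consensus`,
#'   `depth` and a list column `members` (named integer vector: distinct
#'   read -> count). Ordered by decreasing depth then consensus. Attribute
#'   `n_reads` records the input read count (retained + discarded depth
#'   always sums to it).
#' @export
build_stacks <- function(reads, params = assembly_params()) {
  stopifnot(inherits(params, "assembly_params"))
  if (length(reads) == 0) {
    out <- data.frame(consensus = character(), depth = integer())
    out$members <- list()
    attr(out, "n_reads") <- 0L
    return(out)
  }
  lens <- nchar(reads)
  if (length(unique(lens)) != 1L) stop("reads must all have equal length")
  if (params$within_sample_max_dist >= lens[1]) {
    stop("within_sample_max_dist must be smaller than the read length")
  }
  reads <- canonical_orientation(unname(reads))
  tab <- table(reads)
  primary <- data.frame(consensus = names(tab),
    depth = as.integer(tab), stringsAsFactors = FALSE)
  primary <- primary[order(-primary$depth, primary$consensus), , drop = FALSE]
  raws <- lapply(primary$consensus, charToRaw)

  founder <- integer(0)        # indices (into primary) of retained founders
  assignment <- integer(nrow(primary))
  for (i in seq_len(nrow(primary))) {
    hit <- 0L
    for (f in founder) {
      if (sum(raws[[i]] != raws[[f]]) <= params$within_sample_max_dist) {
        hit <- f
        break
      }
    }
    if (hit == 0L) {
      founder <- c(founder, i)
      assignment[i] <- i
    } else {
      assignment[i] <- hit
    }
  }

  stacks <- lapply(founder, function(f) {
    idx <- which(assignment == f)
    members <- setNames(primary$depth[idx], primary$consensus[idx])
    list(
      consensus = weighted_consensus(primary$consensus[idx],
        primary$depth[idx]),
      depth = sum(primary$depth[idx]),
      members = members
    )
  })
  depth <- vapply(stacks, `[[`, integer(1), "depth")
  cons <- vapply(stacks, `[[`, character(1), "consensus")
  keep <- depth >= params$min_depth
  ord <- order(-depth[keep], cons[keep])
  out <- data.frame(consensus = cons[keep][ord],
    depth = depth[keep][ord], stringsAsFactors = FALSE)
  out$members <- lapply(stacks[keep][ord], `[[`, "members")
  attr(out, "n_reads") <- length(reads)
  out
}

#' Merge per-sample stacks into a cross-sample locus catalog
#'
#' Pools every sample's stack consensus sequences, sorts them by
#' decreasing depth (ties by lexicographic consensus then sample label),
#' and merges them greedily by single linkage: a stack joins the first
#' catalog locus holding any member within `cross_sample_max_dist`
#' mismatches, otherwise founds a new locus. Catalog consensus sequences
#' are the depth-weighted per-column majority over member stacks; a sample
#' is a member of every catalog locus that absorbed at least one of its
#' stacks.
#'
#' @param per_sample_stacks named list: sample label -> [build_stacks()]
#'   output. Every sample to appear in the matrix must be a key, even with
#'   zero stacks.
#' @param params an [assembly_params()].
#' @return An object of class `rad_catalog`: a list with `loci` (data frame
#'   `id`, `consensus`, `depth`; ids dense from 0) and `membership` (named
#'   list: sample -> sorted integer vector of catalog ids).
#' @export
build_catalog <- function(per_sample_stacks, params = assembly_params()) {
  stopifnot(inherits(params, "assembly_params"))
  if (is.null(names(per_sample_stacks)) ||
      any(!nzchar(names(per_sample_stacks)))) {
    stop("per_sample_stacks must be a named list (sample labels)")
  }
  samples <- names(per_sample_stacks)
  pooled <- do.call(rbind, lapply(samples, function(s) {
    st <- per_sample_stacks[[s]]
    if (nrow(st) == 0) return(NULL)
    data.frame(sample = s, consensus = st$consensus, depth = st$depth,
      stringsAsFactors = FALSE)
  }))
  empty <- function() {
    cat <- list(
      loci = data.frame(id = integer(), consensus = character(),
        depth = integer()),
      membership = setNames(rep(list(integer(0)), length(samples)), samples))
    class(cat) <- "rad_catalog"
    cat
  }
  if (is.null(pooled) || nrow(pooled) == 0) return(empty())
  if (length(unique(nchar(pooled$consensus))) != 1L) {
    stop("all stacks must share one read length")
  }
  pooled <- pooled[order(-pooled$depth, pooled$consensus, pooled$sample), ,
    drop = FALSE]
  raws <- lapply(pooled$consensus, charToRaw)

  locus_members <- list() # list of integer vectors (rows of pooled)
  for (i in seq_len(nrow(pooled))) {
    placed <- FALSE
    for (l in seq_along(locus_members)) {
      for (m in locus_members[[l]]) {
        if (sum(raws[[i]] != raws[[m]]) <= params$cross_sample_max_dist) {
          locus_members[[l]] <- c(locus_members[[l]], i)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) locus_members[[length(locus_members) + 1L]] <- i
  }

  loci <- data.frame(
    id = seq_along(locus_members) - 1L,
    consensus = vapply(locus_members, function(idx) {
      weighted_consensus(pooled$consensus[idx], pooled$depth[idx])
    }, character(1)),
    depth = vapply(locus_members, function(idx) sum(pooled$depth[idx]),
      numeric(1)),
    stringsAsFactors = FALSE)
  membership <- setNames(rep(list(integer(0)), length(samples)), samples)
  for (l in seq_along(locus_members)) {
    for (s in unique(pooled$sample[locus_members[[l]]])) {
      membership[[s]] <- c(membership[[s]], l - 1L)
    }
  }
  membership <- lapply(membership, sort)
  cat <- list(loci = loci, membership = membership)
  class(cat) <- "rad_catalog"
  cat
}

#' @export
print.rad_catalog <- function(x, ...) {
  cat("rad_catalog:", nrow(x$loci), "loci across",
    length(x$membership), "samples\n")
  invisible(x)
}

#' Presence/absence matrix from a locus catalog
#'
#' One row per sample, one column per catalog locus; a cell is 1 when the
#' sample contributed a stack to that locus and 0 otherwise — a 0 marks a
#' missing locus, indicative of a divergent (mutated) enzymatic cut site
#' or flank. Columns with no presence among the requested samples are
#' dropped so that no all-zero column remains.
#'
#' @param catalog a [build_catalog()] result.
#' @param samples ordered sample labels for the rows; defaults to the
#'   catalog's samples. Labels unknown to the catalog are an error.
#' @return Integer matrix with `samples` as rownames and `L<id>` colnames.
#' @export
to_matrix <- function(catalog, samples = names(catalog$membership)) {
  stopifnot(inherits(catalog, "rad_catalog"))
  unknown <- setdiff(samples, names(catalog$membership))
  if (length(unknown)) {
    stop("unknown sample label(s): ", paste(unknown, collapse = ", "))
  }
  n_loci <- nrow(catalog$loci)
  m <- matrix(0L, nrow = length(samples), ncol = n_loci,
    dimnames = list(samples, sprintf("L%d", catalog$loci$id)))
  for (s in samples) {
    ids <- catalog$membership[[s]]
    if (length(ids)) m[s, ids + 1L] <- 1L
  }
  m[, colSums(m) > 0, drop = FALSE]
}
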