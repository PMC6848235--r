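#' @importFrom stats rpois runif setNames as.dist cutree hclust
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom ape read.tree write.tree
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1000003) %%
    2147483647)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
      collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Canonical orientation: lexicographic min of a sequence and its reverse
# complement. Digestion yields flanks on both strands, so catalog matching
# needs one deterministic representative per locus.
canonical_orientation <- function(x) {
  rc <- reverse_complement(x)
  ifelse(x <= rc, x, rc)
}

hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming distance requires equal-length sequences")
  }
  sum(ra != rb)
}

# Integer genome codec: bases A,C,G,T as 0:3.
dna_to_int <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}")
  v
}

int_to_dna <- function(v) paste(DNA_BASES[v + 1L], collapse = "")

# Evolve an integer-coded sequence along one branch of length `t` expected
# substitutions/site under Jukes-Cantor: each site substitutes with the
# exact JC probability 3/4 * (1 - exp(-4 t / 3)) and, conditional on a
# substitution, takes one of the 3 other bases uniformly. JC transition
# matrices compose, so chaining branches gives exactly the JC process for
# the total path length.
evolve_jc <- function(x, t) {
  if (t < 0) stop("branch length must be non-negative")
  if (t == 0) return(x)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- which(runif(length(x)) < p)
  if (length(hit)) {
    x[hit] <- (x[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  }
  x
}

# Depth-weighted per-column majority consensus over equal-length sequences;
# ties resolved to the lexicographically smallest base.
weighted_consensus <- function(seqs, weights) {
  if (length(seqs) == 1L) return(seqs)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE)
  apply_col <- function(col) {
    w <- vapply(DNA_BASES, function(b) sum(weights[col == b]), numeric(1))
    DNA_BASES[which.max(w)] # which.max takes the first, i.e. smallest base
  }
  paste(vapply(seq_len(ncol(mat)), function(j) apply_col(mat[, j]),
    character(1)), collapse = "")
}

check_square_distance <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square")
  }
  if (is.null(rownames(d))) stop("distance matrix must carry taxon labels")
  if (!identical(rownames(d), colnames(d))) {
    stop("distance matrix row and column labels differ")
  }
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be non-negative")
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
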