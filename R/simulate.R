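#' Simulation settings for a multi-species RAD-seq experiment
#'
#' Collects the knobs of the synthetic-data generator: a set of species
#' diverging on a star tree, genomes digested in silico with a restriction
#' enzyme, short reads drawn per locus, and one aligned mitochondrial-style
#' marker evolved on the same tree. Divergences are expected substitutions
#' per site (Jukes-Cantor branch lengths): two individuals of the same
#' species are separated by `within_species_divergence`, two individuals of
#' different species by
#' `between_species_divergence + within_species_divergence`.
#'
#' Defaults emulate the sampling design the pipeline targets: three
#' parapatric species, between-species marker divergence well above 5% and
#' within-species divergence well below 3%, EcoRI-digested genomes and
#' 150 bp reads.
#'
#' @param n_species number of species on the star tree.
#' @param individuals_per_species individuals sampled per species.
#' @param genome_length genome size in bases (>= 10 * `read_length`).
#' @param enzyme_motif restriction recognition site over {A,C,G,T}
#'   (default the EcoRI site `GAATTC`).
#' @param read_length sequencing read length in bases.
#' @param locus_flank_length length of the locus flank retained on each
#'   side of a cut site; defaults to `read_length`.
#' @param depth_mean expected (Poisson) read depth per locus per individual.
#' @param sequencing_error_rate per-base substitution error probability.
#' @param within_species_divergence expected substitutions/site between two
#'   conspecific individuals.
#' @param between_species_divergence expected substitutions/site added
#'   between species (stem length `between/2` per species).
#' @param marker_length length in bases of the aligned marker locus.
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_genomes()], [simulate_markers()], [simulate_rad_reads()]
#' @export
simulation_config <- function(n_species = 3,
                              individuals_per_species = 6,
                              genome_length = 100000,
                              enzyme_motif = "GAATTC",
                              read_length = 150,
                              locus_flank_length = read_length,
                              depth_mean = 10,
                              sequencing_error_rate = 0.001,
                              within_species_divergence = 0.002,
                              between_species_divergence = 0.10,
                              marker_length = 1500,
                              seed = 1L) {
  stopifnot(
    n_species >= 1, individuals_per_species >= 1,
    read_length >= 1, locus_flank_length >= 1,
    marker_length >= 2, depth_mean > 0
  )
  if (genome_length < 10 * read_length) {
    stop("genome_length must be at least 10 * read_length")
  }
  rates <- c(sequencing_error_rate, within_species_divergence,
    between_species_divergence)
  if (any(rates < 0) || any(rates >= 0.75)) {
    stop("rates must lie in [0, 0.75): the Jukes-Cantor process saturates ",
      "at 0.75 expected differences/site")
  }
  if (between_species_divergence < within_species_divergence) {
    stop("between_species_divergence must be >= within_species_divergence")
  }
  if (!nzchar(enzyme_motif) ||
      grepl("[^ACGT]", enzyme_motif)) {
    stop("enzyme_motif must be a non-empty string over {A,C,G,T}")
  }
  cfg <- list(
    n_species = as.integer(n_species),
    individuals_per_species = as.integer(individuals_per_species),
    genome_length = as.integer(genome_length),
    enzyme_motif = enzyme_motif,
    read_length = as.integer(read_length),
    locus_flank_length = as.integer(locus_flank_length),
    depth_mean = depth_mean,
    sequencing_error_rate = sequencing_error_rate,
    within_species_divergence = within_species_divergence,
    between_species_divergence = between_species_divergence,
    marker_length = as.integer(marker_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("RAD-seq simulation config:",
    x$n_species, "species x", x$individuals_per_species, "individuals,",
    x$genome_length, "bp genomes,", x$enzyme_motif, "digestion,",
    x$read_length, "bp reads\n")
  cat("  divergence between/within:", x$between_species_divergence, "/",
    x$within_species_divergence,
    "; depth", x$depth_mean, "; error", x$sequencing_error_rate,
    "; seed", x$seed, "\n")
  invisible(x)
}

sample_labels <- function(config) {
  unlist(lapply(seq_len(config$n_species), function(s) {
    sprintf("sp%d_ind%02d", s, seq_len(config$individuals_per_species))
  }))
}

# Evolve one ancestral integer-coded sequence over the star species tree:
# stem branch between/2 per species, terminal branch within/2 per
# individual. Returns a named list of integer-coded sequences plus the
# species label of each individual.
evolve_star_tree <- function(ancestor, config) {
  labels <- sample_labels(config)
  species <- rep(sprintf("sp%d", seq_len(config$n_species)),
    each = config$individuals_per_species)
  names(species) <- labels
  seqs <- vector("list", length(labels))
  names(seqs) <- labels
  i <- 0L
  for (s in seq_len(config$n_species)) {
    stem <- evolve_jc(ancestor, config$between_species_divergence / 2)
    for (k in seq_len(config$individuals_per_species)) {
      i <- i + 1L
      seqs[[i]] <- evolve_jc(stem, config$within_species_divergence / 2)
    }
  }
  list(seqs = seqs, species = species)
}

#' Simulate one genome per individual on a star species tree
#'
#' Draws a uniform ancestral genome over {A,C,G,T} and evolves it under the
#' Jukes-Cantor process: each species receives a stem branch of length
#' `between_species_divergence / 2` and each individual a terminal branch
#' of `within_species_divergence / 2`. Substitutions are placed per site
#' with the exact JC substitution probability for the branch length, so the
#' expected p-distance between two genomes is `3/4 * (1 - exp(-4 d / 3))`
#' for their total path divergence `d`.
#'
#' @param config a [simulation_config()].
#' @return An object of class `genome_set`: a list with `genomes` (named
#'   character vector, one genome per individual), `species` (named
#'   character vector of true species labels) and the `config` used.
#'   Deterministic given `config$seed`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ancestor <- sample.int(4L, config$genome_length, replace = TRUE) - 1L
    ev <- evolve_star_tree(ancestor, config)
    out <- list(
      genomes = vapply(ev$seqs, int_to_dna, character(1)),
      species = ev$species,
      config = config
    )
    class(out) <- "genome_set"
    out
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$genomes), "genomes of",
    nchar(x$genomes[[1]]), "bp across",
    length(unique(x$species)), "species\n")
  invisible(x)
}

#' Simulate an aligned marker locus on the same star tree
#'
#' Evolves a single gapless marker (a CO1-like mitochondrial barcode) over
#' the identical star-tree structure used by [simulate_genomes()], with the
#' same per-branch divergences; the realization is independent of the
#' genomes but deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A named character vector of aligned sequences (equal length, no
#'   gaps), one row per individual, labels matching [simulate_genomes()];
#'   carries the true species partition as attribute `species`.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    ancestor <- sample.int(4L, config$marker_length, replace = TRUE) - 1L
    ev <- evolve_star_tree(ancestor, config)
    aln <- vapply(ev$seqs, int_to_dna, character(1))
    attr(aln, "species") <- ev$species
    aln
  })
}

#' Digest a genome in silico at a restriction motif
#'
#' Scans the forward strand for every (possibly overlapping) occurrence of
#' the recognition motif and emits up to two RAD loci per occurrence: the
#' `flank_length` bases immediately left of the site and the
#' `flank_length` bases immediately right of it. Flanks truncated by a
#' genome end are discarded. Coordinates are 0-based, half-open. Each locus
#' sequence is stored in canonical orientation (lexicographic minimum of
#' the sequence and its reverse complement), since digestion exposes flanks
#' on both strands.
#'
#' @param genome a single genome string over {A,C,G,T}.
#' @param motif restriction recognition site (default EcoRI, `GAATTC`).
#' @param flank_length locus length retained on each side of the site.
#' @return A data frame with columns `start`, `end` (0-based half-open
#'   coordinates of the flank on the genome), `site_start` (coordinate of
#'   the motif occurrence), `side` (`"left"`/`"right"`) and `sequence`
#'   (canonical orientation). Zero rows when the motif never occurs.
#' @export
digest_genome <- function(genome, motif = "GAATTC", flank_length = 150) {
  if (!nzchar(genome)) stop("empty genome")
  if (!nzchar(motif)) stop("empty motif")
  if (nchar(motif) > nchar(genome)) stop("motif longer than genome")
  len <- nchar(genome)
  m <- nchar(motif)
  # lookahead regex finds overlapping occurrences
  hits <- gregexpr(paste0("(?=", motif, ")"), genome, perl = TRUE)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
      site_start = integer(), side = character(), sequence = character(),
      stringsAsFactors = FALSE))
  }
  starts0 <- as.integer(hits) - 1L
  rows <- lapply(starts0, function(s) {
    out <- list()
    if (s - flank_length >= 0L) {
      out$left <- data.frame(start = s - flank_length, end = s,
        site_start = s, side = "left",
        sequence = substr(genome, s - flank_length + 1L, s),
        stringsAsFactors = FALSE)
    }
    if (s + m + flank_length <= len) {
      out$right <- data.frame(start = s + m, end = s + m + flank_length,
        site_start = s, side = "right",
        sequence = substr(genome, s + m + 1L, s + m + flank_length),
        stringsAsFactors = FALSE)
    }
    out
  })
  loci <- do.call(rbind, unlist(rows, recursive = FALSE))
  if (is.null(loci)) {
    return(data.frame(start = integer(), end = integer(),
      site_start = integer(), side = character(), sequence = character(),
      stringsAsFactors = FALSE))
  }
  rownames(loci) <- NULL
  loci$sequence <- canonical_orientation(loci$sequence)
  loci
}

#' Draw sequencing reads from a set of loci
#'
#' Per locus the read count is Poisson(`depth_mean`); each read is the
#' locus sequence with independent per-base substitution errors at
#' `error_rate` (an error replaces the base with one of the 3 other bases,
#' uniformly). No PCR-duplicate or coverage-bias model is applied.
#'
#' @param loci character vector of locus sequences (equal length).
#' @param depth_mean expected reads per locus.
#' @param error_rate per-base error probability.
#' @param seed integer seed; output is deterministic given the inputs.
#' @return Named character vector of reads; names are `L<locus>_r<read>`.
#' @export
generate_reads <- function(loci, depth_mean, error_rate, seed) {
  if (length(loci) == 0) stop("loci must be non-empty")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (error_rate < 0 || error_rate >= 0.75) {
    stop("error_rate must lie in [0, 0.75)")
  }
  with_seed(seed, {
    counts <- rpois(length(loci), depth_mean)
    reads <- character(sum(counts))
    nms <- character(sum(counts))
    pos <- 0L
    for (i in seq_along(loci)) {
      if (counts[i] == 0L) next
      base <- dna_to_int(loci[i])
      for (r in seq_len(counts[i])) {
        pos <- pos + 1L
        v <- base
        if (error_rate > 0) {
          hit <- which(runif(length(v)) < error_rate)
          if (length(hit)) {
            v[hit] <- (v[hit] +
              sample.int(3L, length(hit), replace = TRUE)) %% 4L
          }
        }
        reads[pos] <- int_to_dna(v)
        nms[pos] <- sprintf("L%d_r%d", i, r)
      }
    }
    setNames(reads, nms)
  })
}

#' Simulate demultiplexed RAD reads for every individual
#'
#' Digests each individual's genome at the configured motif and draws reads
#' from the resulting loci, with an independent deterministic read stream
#' per individual.
#'
#' @param genome_set output of [simulate_genomes()].
#' @return A list with `reads` (named list: individual -> read vector),
#'   `loci` (named list: individual -> digest data frame) and `species`
#'   (true labels).
#' @export
simulate_rad_reads <- function(genome_set) {
  stopifnot(inherits(genome_set, "genome_set"))
  cfg <- genome_set$config
  loci <- lapply(genome_set$genomes, digest_genome,
    motif = cfg$enzyme_motif, flank_length = cfg$locus_flank_length)
  reads <- vector("list", length(loci))
  names(reads) <- names(loci)
  for (i in seq_along(loci)) {
    if (nrow(loci[[i]]) == 0) {
      reads[[i]] <- character(0)
      next
    }
    reads[[i]] <- generate_reads(loci[[i]]$sequence, cfg$depth_mean,
      cfg$sequencing_error_rate, seed = derive_seed(cfg$seed, 100L + i))
  }
  list(reads = reads, loci = loci, species = genome_set$species)
}
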