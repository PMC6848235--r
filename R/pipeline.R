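#' Rand index between two partitions
#'
#' Fraction of taxon pairs on which two partitions agree (placed together
#' in both, or apart in both). 1 means identical partitions up to label
#' renaming. Used to score recovered sample groups against simulation
#' truth and to quantify concordance between the SNP-coverage and marker
#' lines of evidence.
#'
#' @param a,b named vectors mapping the same taxa to group labels.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (!setequal(names(a), names(b))) {
    stop("partitions must cover the same taxa")
  }
  b <- b[names(a)]
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  (choose(n, 2) + 2 * s(tab) - s(rowSums(tab)) - s(colSums(tab))) /
    choose(n, 2)
}

output_header <- function(seed, config_hash) {
  c(paste("radelim", as.character(utils::packageVersion("radelim"))),
    paste("seed:", seed),
    paste("config:", config_hash))
}

# md5 of the config echo; base tools only. The output location does not
# shape the analysis, so it is excluded: reruns into different directories
# hash identically.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  config$out_dir <- NULL
  dump_config(config, f)
  unname(tools::md5sum(f))
}

dump_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste0(names(flat), "=",
    vapply(flat, format, character(1), scientific = FALSE)), path)
  invisible(path)
}

#' Configuration of a full delineation run
#'
#' Bundles everything [run_delineate()] needs. Inputs are either simulated
#' (give `simulation`) or read from disk (give `reads_dir` with one FASTQ
#' per sample and `marker_path` with an aligned FASTA; `tree_path`
#' optionally supplies the marker tree instead of neighbor joining).
#'
#' @param simulation a [simulation_config()], or `NULL` to read inputs.
#' @param reads_dir directory of demultiplexed per-sample FASTQ files
#'   (`<sample>.fastq[.gz]`); ignored when simulating.
#' @param marker_path aligned marker FASTA; ignored when simulating.
#' @param tree_path optional Newick tree for the marker side.
#' @param assembly an [assembly_params()].
#' @param k number of sample groups to cut from the presence/absence
#'   dendrogram; defaults to the simulated species count when simulating.
#' @param metric,matrix_linkage distance metric and linkage for the
#'   presence/absence side.
#' @param threshold,marker_linkage,source marker-side clustering settings
#'   (see [delimit_markers()]).
#' @param quantifier group-membership quantifier for the exclusive
#'   shared-locus report (`"all"` or `"any"`).
#' @param out_dir optional output directory; created if missing.
#' @param seed integer seed recorded in every output header (and used for
#'   simulation when `simulation` carries no seed of its own).
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, reads_dir = NULL,
                       marker_path = NULL, tree_path = NULL,
                       assembly = assembly_params(), k = NULL,
                       metric = "jaccard", matrix_linkage = "average",
                       threshold = 0.025, marker_linkage = "single",
                       source = "patristic",
                       quantifier = "all", out_dir = NULL, seed = 1L) {
  if (is.null(simulation) &&
      (is.null(reads_dir) || is.null(marker_path))) {
    stop("either request simulation or supply reads_dir and marker_path")
  }
  if (!is.null(reads_dir) && !dir.exists(reads_dir)) {
    stop("reads_dir does not exist: ", reads_dir)
  }
  if (!is.null(marker_path) && !file.exists(marker_path)) {
    stop("marker_path does not exist: ", marker_path)
  }
  if (!is.null(tree_path) && !file.exists(tree_path)) {
    stop("tree_path does not exist: ", tree_path)
  }
  if (is.null(k) && !is.null(simulation)) k <- simulation$n_species
  if (is.null(k)) stop("k (number of sample groups) is required when ",
    "reading real inputs")
  structure(list(simulation = simulation, reads_dir = reads_dir,
    marker_path = marker_path, tree_path = tree_path, assembly = assembly,
    k = as.integer(k), metric = metric, matrix_linkage = matrix_linkage,
    threshold = threshold, marker_linkage = marker_linkage,
    source = source, quantifier = quantifier, out_dir = out_dir,
    seed = as.integer(seed)), class = "run_config")
}

read_sample_fastqs <- function(reads_dir) {
  files <- sort(list.files(reads_dir, pattern = "\\.fastq(\\.gz)?$",
    full.names = TRUE))
  if (!length(files)) stop("no FASTQ files in ", reads_dir)
  samples <- sub("\\.fastq(\\.gz)?$", "", basename(files))
  setNames(lapply(files, function(f) read_fastq(f)$sequences), samples)
}

#' Run the full species-delineation pipeline
#'
#' Chains both lines of evidence and confronts them: (1) SNP-coverage
#' side — assemble per-sample stacks, build the cross-sample catalog,
#' form the presence/absence matrix, cluster samples and cut `k` groups,
#' and compute each group's exclusive shared-locus fraction; (2) marker
#' side — distance-based threshold clustering of the aligned marker via
#' [delimit_markers()]. The two partitions are compared per sample (after
#' greedily mapping marker clusters onto matrix groups by maximal
#' overlap) and globally by the Rand index.
#'
#' @param config a [run_config()].
#' @return List of class `delineation_report`: `matrix` (presence/absence
#'   matrix), `dendrogram`, `matrix_groups`, `group_report`,
#'   `marker` ([delimit_markers()] output), `concordance` (data frame:
#'   sample, matrix group, marker cluster, agree), `rand_index`,
#'   `n_matrix_groups`, `n_marker_clusters`, and `truth` (simulated
#'   species labels, when simulating). When `config$out_dir` is set, the
#'   matrix (raw and leaf-ordered), dendrogram and marker trees, group
#'   and cluster tables, concordance table and a run log are written
#'   there, each TSV prefixed with a `#` header carrying the package
#'   version, seed and config hash.
#' @export
run_delineate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  hdr <- output_header(config$seed, hash)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    note("simulating ", sim$n_species, " species x ",
      sim$individuals_per_species, " individuals (seed ", sim$seed, ")")
    gs <- simulate_genomes(sim)
    rad <- simulate_rad_reads(gs)
    reads <- rad$reads
    marker <- simulate_markers(sim)
    truth <- gs$species
  } else {
    note("reading FASTQ from ", config$reads_dir)
    reads <- read_sample_fastqs(config$reads_dir)
    marker <- read_fasta(config$marker_path)
  }
  tree_in <- if (!is.null(config$tree_path)) {
    read_newick(config$tree_path)
  }

  note("assembling stacks for ", length(reads), " samples")
  stacks <- lapply(reads, build_stacks, params = config$assembly)
  catalog <- build_catalog(stacks, config$assembly)
  note("catalog: ", nrow(catalog$loci), " loci")
  m <- to_matrix(catalog)
  dmat <- row_distance(m, config$metric)
  dendro <- hierarchical_cluster(dmat, config$matrix_linkage)
  groups <- cut_groups(dendro, k = config$k)
  report <- group_shared_fraction(m, groups, config$quantifier)

  mk <- delimit_markers(alignment = marker, tree = tree_in,
    threshold = config$threshold, linkage = config$marker_linkage,
    source = config$source)
  clusters <- setNames(mk$clusters$cluster, mk$clusters$taxon)

  shared <- intersect(names(groups), names(clusters))
  if (!length(shared)) stop("matrix samples and marker taxa do not overlap")
  # map marker clusters onto matrix groups by greedy maximal overlap
  tab <- table(clusters[shared], groups[shared])
  mapping <- setNames(rep(NA_integer_, nrow(tab)), rownames(tab))
  t2 <- tab
  repeat {
    if (max(t2) == 0 || all(!is.na(mapping))) break
    ij <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
    mapping[rownames(t2)[ij[1]]] <- as.integer(colnames(t2)[ij[2]])
    t2[ij[1], ] <- 0
    t2[, ij[2]] <- 0
  }
  mapped <- mapping[as.character(clusters[shared])]
  concordance <- data.frame(sample = shared,
    matrix_group = unname(groups[shared]),
    marker_cluster = unname(clusters[shared]),
    agree = !is.na(mapped) & mapped == unname(groups[shared]),
    stringsAsFactors = FALSE)
  ri <- rand_index(groups[shared], clusters[shared])
  note("concordance: ", sum(concordance$agree), "/", nrow(concordance),
    " samples agree; Rand index ", format(ri, digits = 6))

  out <- list(matrix = m, dendrogram = dendro, matrix_groups = groups,
    group_report = report, marker = mk, concordance = concordance,
    rand_index = ri, n_matrix_groups = length(unique(groups)),
    n_marker_clusters = length(unique(clusters)), truth = truth,
    catalog = catalog, seed = config$seed)
  class(out) <- "delineation_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_matrix_tsv(m, p("matrix.tsv"), comment = hdr)
    write_matrix_tsv(m[dendro$labels[dendro$order], , drop = FALSE],
      p("matrix_ordered.tsv"), comment = hdr)
    write_newick(ape::as.phylo(dendro), p("dendrogram.nwk"))
    if (!is.null(mk$tree)) write_newick(mk$tree, p("marker_tree.nwk"))
    gr <- report
    gr$group <- as.character(gr$group)
    write_tsv_table(as.data.frame(gr), p("group_report.tsv"), hdr)
    write_tsv_table(as.data.frame(mk$clusters), p("marker_clusters.tsv"),
      hdr)
    write_tsv_table(concordance, p("concordance.tsv"), hdr)
    writeLines(c(paste0("# ", hdr), log_lines), p("run.log"))
    note("outputs written to ", config$out_dir)
  }
  out
}

write_tsv_table <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), con, sep = "\n")
  }
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(df))) {
    writeLines(paste(vapply(df[i, ], function(x) {
      format(x, trim = TRUE, scientific = FALSE)
    }, character(1)), collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.delineation_report <- function(x, ...) {
  cat("Species delineation report\n")
  cat("  samples:", nrow(x$matrix), " catalog loci:", ncol(x$matrix), "\n")
  cat("  matrix groups:", x$n_matrix_groups,
    " marker clusters:", x$n_marker_clusters, "\n")
  cat("  exclusive shared-locus fractions:",
    paste(sprintf("%s=%.3f", x$group_report$group,
      x$group_report$exclusive_fraction), collapse = ", "), "\n")
  cat("  concordance:", sum(x$concordance$agree), "/",
    nrow(x$concordance), "samples agree (Rand index ",
    format(x$rand_index, digits = 6), ")\n")
  invisible(x)
}
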