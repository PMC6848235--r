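#' Write a simulated experiment to disk
#'
#' Materializes one simulated experiment in the pipeline's external
#' formats: per-sample FASTQ (fixed Q40 qualities), genome and marker
#' FASTA, a truth TSV (individual, species, and each individual's digest
#' coordinates) and a key-value echo of the configuration.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the list of files written.
#' @export
write_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- simulate_genomes(config)
  rad <- simulate_rad_reads(gs)
  markers <- simulate_markers(config)
  p <- function(f) file.path(out_dir, f)
  files <- c(p("genomes.fasta"), p("markers.fasta"), p("truth.tsv"),
    p("config.txt"))
  write_fasta(gs$genomes, p("genomes.fasta"))
  write_fasta(markers, p("markers.fasta"))
  for (s in names(rad$reads)) {
    f <- p(paste0(s, ".fastq"))
    write_fastq(rad$reads[[s]], f)
    files <- c(files, f)
  }
  truth <- do.call(rbind, lapply(names(rad$loci), function(s) {
    li <- rad$loci[[s]]
    if (nrow(li) == 0) return(NULL)
    data.frame(individual = s, species = unname(gs$species[s]),
      locus_start = li$start, locus_end = li$end, side = li$side,
      stringsAsFactors = FALSE)
  }))
  write_tsv_table(truth, p("truth.tsv"),
    output_header(config$seed, config_hash(config)))
  dump_config(config, p("config.txt"))
  invisible(files)
}
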