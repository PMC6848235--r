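# Stacking, catalog merging and the presence/absence matrix.

test_that("near-identical reads collapse into one majority-consensus stack", {
  reads <- c(rep("ACGTACGA", 3), "ACGTACGT")
  # ACGTACGT is palindromic under revcomp; ACGTACGA stays as is
  st <- build_stacks(reads, assembly_params())
  expect_equal(nrow(st), 1)
  expect_equal(st$depth, 4L)
  expect_equal(st$consensus, "ACGTACGA") # depth-3 majority wins column 8
})

test_that("stacks below the minimum depth are discarded", {
  st <- build_stacks(rep("ACGTACGT", 2), assembly_params(min_depth = 3))
  expect_equal(nrow(st), 0)
  st <- build_stacks(rep("ACGTACGT", 3), assembly_params(min_depth = 3))
  expect_equal(st$depth, 3L)
})

test_that("reads beyond the within-sample distance form separate stacks", {
  reads <- c(rep("AAAAAAAA", 3), rep("AAATTTAA", 3)) # Hamming 3 > 2
  st <- build_stacks(reads, assembly_params())
  expect_equal(nrow(st), 2)
  expect_setequal(st$consensus, c("AAAAAAAA", "AAATTTAA"))
})

test_that("stacking is invariant to read order and conserves depth", {
  set.seed(31)
  for (rep_i in 1:5) {
    reads <- random_reads(30)
    p <- assembly_params(min_depth = 1)
    a <- build_stacks(reads, p)
    b <- build_stacks(sample(reads), p)
    expect_identical(a$consensus, b$consensus)
    expect_identical(a$depth, b$depth)
    expect_equal(sum(a$depth), length(reads)) # min_depth 1: nothing dropped
    # with a depth filter, retained + discarded depth still sums to input
    filt <- build_stacks(reads, assembly_params(min_depth = 3))
    expect_equal(attr(filt, "n_reads"), length(reads))
    expect_lte(sum(filt$depth), length(reads))
  }
})

test_that("unequal read lengths are rejected", {
  expect_error(build_stacks(c("ACGT", "ACGTA")), "equal length")
  expect_equal(nrow(build_stacks(character(0))), 0)
})

test_that("stacks match the exhaustive brute-force clustering", {
  set.seed(17)
  for (rep_i in 1:20) {
    reads <- random_reads(sample(5:40, 1))
    st <- build_stacks(reads, assembly_params(min_depth = 2))
    oracle <- oracle_stacks(reads, min_depth = 2, max_dist = 2)
    expect_identical(
      stack_signature(st$consensus, st$depth),
      stack_signature(vapply(oracle, `[[`, character(1), "consensus"),
        vapply(oracle, `[[`, numeric(1), "depth")))
  }
})

test_that("catalog merges per-sample loci at the cross-sample distance", {
  p1 <- assembly_params(min_depth = 1)
  sA <- build_stacks(rep("AAAA", 3), p1)
  sB1 <- build_stacks(rep("AAAT", 3), p1) # Hamming 1 from AAAA
  sB2 <- build_stacks(rep("AATT", 3), p1) # Hamming 2 from AAAA
  cat1 <- build_catalog(list(A = sA, B = sB1), p1)
  expect_equal(nrow(cat1$loci), 1)
  expect_equal(cat1$membership, list(A = 0L, B = 0L))
  cat2 <- build_catalog(list(A = sA, B = sB2), p1)
  expect_equal(nrow(cat2$loci), 2)
  expect_length(intersect(cat2$membership$A, cat2$membership$B), 0)
  # identical consensus across samples: one locus, both members
  cat3 <- build_catalog(list(A = sA, B = sA), p1)
  expect_equal(nrow(cat3$loci), 1)
  expect_equal(cat3$loci$depth, 6)
})

test_that("catalog equals the brute-force pooled merge on random input", {
  set.seed(23)
  for (rep_i in 1:10) {
    p <- assembly_params(min_depth = 1)
    stacks <- list(A = build_stacks(random_reads(15), p),
      B = build_stacks(random_reads(15), p))
    cat <- build_catalog(stacks, p)
    pooled <- do.call(rbind, lapply(names(stacks), function(s) {
      data.frame(sample = s, consensus = stacks[[s]]$consensus,
        depth = stacks[[s]]$depth, stringsAsFactors = FALSE)
    }))
    oracle <- oracle_catalog(pooled, max_dist = 1)
    expect_identical(
      stack_signature(cat$loci$consensus, cat$loci$depth),
      stack_signature(vapply(oracle, `[[`, character(1), "consensus"),
        vapply(oracle, `[[`, numeric(1), "depth")))
  }
})

test_that("empty input gives an empty catalog and a 0-column matrix", {
  p <- assembly_params()
  cat <- build_catalog(list(A = build_stacks(character(0), p)), p)
  expect_equal(nrow(cat$loci), 0)
  m <- to_matrix(cat)
  expect_equal(dim(m), c(1, 0))
})

test_that("the presence/absence matrix mirrors catalog membership", {
  p1 <- assembly_params(min_depth = 1)
  stacks <- list(
    A = build_stacks(c(rep("AAAA", 3), rep("GGCC", 3)), p1),
    B = build_stacks(rep("AAAA", 3), p1))
  cat <- build_catalog(stacks, p1)
  m <- to_matrix(cat, samples = c("A", "B"))
  expect_equal(rownames(m), c("A", "B"))
  expect_equal(sum(m["A", ]), 2)
  expect_equal(sum(m["B", ]), 1)
  # column sums equal membership sizes; no all-zero column
  sizes <- table(unlist(cat$membership))
  expect_equal(unname(colSums(m)), as.vector(sizes))
  expect_true(all(colSums(m) > 0))
  expect_error(to_matrix(cat, samples = c("A", "Z")), "unknown sample")
})

test_that("conspecific samples share more catalog loci than heterospecific",
{
  # small end-to-end check of restriction-site dropout
  for (s in 1:3) {
    cfg <- simulation_config(n_species = 3, individuals_per_species = 2,
      genome_length = 30000, depth_mean = 10, sequencing_error_rate = 0.001,
      between_species_divergence = 0.10, within_species_divergence = 0.002,
      seed = 400 + s)
    gs <- simulate_genomes(cfg)
    rad <- simulate_rad_reads(gs)
    stacks <- lapply(rad$reads, build_stacks)
    m <- to_matrix(build_catalog(stacks))
    sp <- gs$species[rownames(m)]
    share <- tcrossprod(m) / ncol(m)
    con <- c()
    het <- c()
    for (i in 1:(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        if (sp[i] == sp[j]) con <- c(con, share[i, j])
        else het <- c(het, share[i, j])
      }
    }
    expect_gt(min(con), max(het))
  }
})
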