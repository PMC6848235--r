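# Marker distances, neighbor joining, patristic distances, threshold
# clustering, occupancy and divergence reports.

test_that("p-distance uses pairwise deletion of gap and N columns", {
  aln <- c(a = "ACGT", b = "ACGA")
  expect_equal(p_distance(aln)["a", "b"], 0.25)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "AC-T", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "ACNT", b = "ACGA"))["a", "b"], 1 / 3)
  expect_error(p_distance(c(a = "--AA", b = "GG--")), "no comparable")
  expect_error(p_distance(c(a = "ACRT", b = "ACGT")), "outside")
  set.seed(41)
  pool <- c("A", "C", "G", "T", "-", "N")
  aln <- vapply(1:5, function(i) paste(sample(pool, 60, replace = TRUE,
    prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = ""), character(1))
  names(aln) <- paste0("x", 1:5)
  d <- p_distance(aln)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(d[i, j], oracle_p_distance(aln[[i]], aln[[j]]))
    }
  }
})

test_that("Jukes-Cantor correction matches its closed form and limits", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(jc_distance(0.3), 0.38312, tolerance = 1e-5)
  p <- c(0.001, 0.005, 0.01)
  expect_true(all(abs(jc_distance(p) - p) / p < 0.01))
  expect_error(jc_distance(0.75), "saturated")
  expect_error(jc_distance(-0.1), "non-negative")
})

test_that("three-taxon NJ solves the closed-form edge system", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  pd <- patristic(tr)
  expect_equal(pd, d[rownames(pd), colnames(pd)], tolerance = 1e-12)
  # x + y = 3, x + z = 4, y + z = 5 -> x = 1, y = 2, z = 3
  edges <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(edges[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("NJ recovers an additive quartet exactly", {
  # topology AB|CD with leaf branches 1,2,3,4 and internal edge 5
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 1 + 2
  d["A", "C"] <- d["C", "A"] <- 1 + 5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 5 + 4
  d["C", "D"] <- d["D", "C"] <- 3 + 4
  tr <- nj_tree(d)
  expect_equal(patristic(tr), d, tolerance = 1e-12)
  # AB must be a cherry: their path avoids C and D's branches
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")) ||
    ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
})

test_that("two taxa give a single edge of their distance", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"),
    c("A", "B")))
  tr <- nj_tree(d)
  expect_equal(patristic(tr)["A", "B"], 0.3)
})

test_that("NJ reproduces random additive matrices and agrees with ape", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    ad <- random_additive_matrix(n)
    tr <- nj_tree(ad$d)
    expect_lt(max(abs(patristic(tr) - ad$d)), 1e-6)
    ref <- ape::nj(ad$d) # independent implementation
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
      ignore_attr = TRUE)
  }
})

test_that("patristic distances sum branch lengths and ignore rooting", {
  tr <- ape::read.tree(text = "(A:0.01,B:0.02);")
  expect_equal(patristic(tr)["A", "B"], 0.03)
  tr2 <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.1):0.15);")
  p1 <- patristic(tr2)
  p2 <- patristic(ape::root(tr2, "C", resolve.root = TRUE))
  expect_equal(p1, p2[rownames(p1), colnames(p1)], tolerance = 1e-12)
  tr3 <- ape::read.tree(text = "(A,B,C);")
  expect_error(patristic(tr3), "branch lengths")
})

test_that("threshold clustering separates tight groups and chains", {
  labs <- c("A", "B", "C")
  d <- matrix(0, 3, 3, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 0.02
  d["B", "C"] <- d["C", "B"] <- 0.02
  d["A", "C"] <- d["C", "A"] <- 0.04
  single <- threshold_clusters(d, 0.025, "single")
  expect_equal(length(unique(single$cluster)), 1)
  complete <- threshold_clusters(d, 0.025, "complete")
  expect_equal(length(unique(complete$cluster)), 2)
  # five taxa all within threshold: one cluster, no orphans
  d5 <- matrix(0.01, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d5) <- 0
  a5 <- threshold_clusters(d5, 0.025)
  expect_equal(unique(a5$cluster), 1)
  expect_false(any(a5$orphan))
  # three well-separated groups
  dg <- matrix(0.10, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  dg[1:2, 1:2] <- dg[3:4, 3:4] <- dg[5:6, 5:6] <- 0.01
  diag(dg) <- 0
  expect_equal(length(unique(threshold_clusters(dg, 0.025)$cluster)), 3)
})

test_that("cluster count shrinks as the threshold grows", {
  set.seed(61)
  x <- matrix(runif(30), 10)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("t", 1:10), paste0("t", 1:10))
  prev <- Inf
  for (thr in c(0, 0.1, 0.3, 0.6, 1, max(d))) {
    k <- length(unique(threshold_clusters(d, thr)$cluster))
    expect_lte(k, prev)
    prev <- k
  }
  expect_equal(length(unique(threshold_clusters(d, 0)$cluster)), 10)
  expect_equal(length(unique(threshold_clusters(d, max(d))$cluster)), 1)
})

test_that("a distant taxon joins as a new orphan cluster", {
  set.seed(67)
  d <- as.matrix(dist(matrix(runif(12), 6))) / 10
  labs <- paste0("t", 1:6)
  dimnames(d) <- list(labs, labs)
  base <- threshold_clusters(d, 0.025)
  d2 <- rbind(cbind(d, zz = 0.5), zz = c(rep(0.5, 6), 0))
  rownames(d2) <- c(labs, "zz")
  aug <- threshold_clusters(d2, 0.025)
  expect_equal(length(unique(aug$cluster)),
    length(unique(base$cluster)) + 1)
  expect_true(aug$orphan[aug$taxon == "zz"])
})

test_that("occupancy report counts clusters, orphans and top-m taxa", {
  d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  singletons <- threshold_clusters(d, 0.01)
  occ <- occupancy_report(singletons, top_m = 1)
  expect_equal(occ$n_clusters, 4)
  expect_equal(occ$n_orphans, 4)
  expect_equal(occ$largest_cluster_size, 1)
  # sizes {5, 3, 1, 1}: top-2 clusters hold 8 taxa, 2 orphans remain
  sizes <- c(5, 3, 1, 1)
  labs <- sprintf("x%02d", 1:10)
  dd <- matrix(1, 10, 10, dimnames = list(labs, labs))
  grp <- rep(seq_along(sizes), sizes)
  for (g in seq_along(sizes)) {
    dd[grp == g, grp == g] <- 0.01
  }
  diag(dd) <- 0
  asg <- threshold_clusters(dd, 0.025)
  occ2 <- occupancy_report(asg, top_m = 2)
  expect_equal(occ2$n_clusters, 4)
  expect_equal(occ2$taxa_in_top_m, 8)
  expect_equal(occ2$n_orphans, 2)
  expect_warning(occupancy_report(asg, top_m = 9), "capped")
})

test_that("occupancy fields equal a brute-force recount", {
  set.seed(73)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    labs <- sprintf("t%02d", 1:n)
    d <- as.matrix(dist(matrix(runif(2 * n), n)))
    dimnames(d) <- list(labs, labs)
    asg <- threshold_clusters(d, runif(1, 0.05, 0.6))
    sizes <- as.integer(table(asg$cluster))
    occ <- occupancy_report(asg, top_m = min(2, length(sizes)))
    expect_equal(occ$n_clusters, length(sizes))
    expect_equal(occ$n_taxa, n)
    expect_equal(occ$n_orphans, sum(sizes == 1))
    expect_equal(occ$taxa_in_top_m,
      sum(sort(sizes, decreasing = TRUE)[1:min(2, length(sizes))]))
  }
})

test_that("divergence report flags intra and inter ranges explicitly", {
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(0.06, 4, 4, dimnames = list(labs, labs))
  d[1:2, 1:2] <- 0.01
  d[3:4, 3:4] <- 0.01
  diag(d) <- 0
  asg <- threshold_clusters(d, 0.025)
  rep <- divergence_report(d, asg)
  expect_equal(rep$intra$max_intra, c(0.01, 0.01))
  expect_true(all(rep$intra$within_intraspecific_range))
  expect_equal(rep$inter$min_inter, 0.06)
  expect_true(rep$inter$above_intraspecific_max)
  expect_true(rep$inter$within_congeneric_range)
  # all taxa in one cluster: no inter rows, singleton intra is NA
  one <- threshold_clusters(d, 1)
  rep1 <- divergence_report(d, one)
  expect_equal(nrow(rep1$inter), 0)
  d3 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("x", "y"),
    c("x", "y")))
  rep2 <- divergence_report(d3, threshold_clusters(d3, 0.01))
  expect_true(all(is.na(rep2$intra$max_intra)))
})

test_that("divergence extremes match brute-force scans", {
  set.seed(79)
  n <- 9
  labs <- sprintf("t%02d", 1:n)
  d <- as.matrix(dist(matrix(runif(2 * n), n)))
  dimnames(d) <- list(labs, labs)
  asg <- threshold_clusters(d, 0.4)
  rep <- divergence_report(d, asg)
  cl <- setNames(asg$cluster, asg$taxon)
  for (r in seq_len(nrow(rep$intra))) {
    g <- rep$intra$cluster[r]
    members <- names(cl)[cl == g]
    if (length(members) >= 2) {
      expect_equal(rep$intra$max_intra[r],
        max(apply(expand.grid(members, members), 1,
          function(pr) d[pr[1], pr[2]])))
    }
  }
  for (r in seq_len(nrow(rep$inter))) {
    a <- names(cl)[cl == rep$inter$cluster_a[r]]
    b <- names(cl)[cl == rep$inter$cluster_b[r]]
    expect_equal(rep$inter$min_inter[r],
      min(apply(expand.grid(a, b), 1, function(pr) d[pr[1], pr[2]])))
  }
})

test_that("marker delimitation recovers simulated species at 0.025", {
  cfg <- simulation_config(n_species = 3, individuals_per_species = 4,
    genome_length = 2000, read_length = 100, marker_length = 1500,
    between_species_divergence = 0.08, within_species_divergence = 0.005,
    seed = 83)
  aln <- simulate_markers(cfg)
  res <- delimit_markers(aln, threshold = 0.025)
  truth <- attr(aln, "species")
  part <- setNames(res$clusters$cluster, res$clusters$taxon)
  expect_equal(length(unique(part)), 3)
  expect_equal(rand_index(part, truth), 1)
  # sequence-distance source clusters the same clean data identically
  res2 <- delimit_markers(aln, threshold = 0.025, source = "sequence")
  part2 <- setNames(res2$clusters$cluster, res2$clusters$taxon)
  expect_equal(rand_index(part2, truth), 1)
})
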