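test_that("graph thresholding matches a brute-force double loop", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    m <- matrix(runif(n * n), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    ids <- sprintf("rs%02d", seq_len(n))
    dimnames(m) <- list(ids, ids)
    cutoff <- runif(1, 0.2, 0.9)
    adj <- buildLdGraph(LDMatrix(m, ids, "sim"), cutoff)
    brute <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && m[i, j] >= cutoff) brute[i, j] <- TRUE
    expect_identical(unname(adj), brute)
  }
})

test_that("cutoff boundaries behave: 1.0 keeps only perfect LD, 0 merges all", {
  m <- rbind(c(1, 0.951), c(0.951, 1))
  lm2 <- LDMatrix(m, c("a", "b"), "2")
  expect_equal(sum(buildLdGraph(lm2, 0.5)), 2L)   # one undirected edge
  expect_equal(sum(buildLdGraph(lm2, 1.0)), 0L)
  expect_equal(nrow(clusterVariants(lm2, r2_cutoff = 0)), 1L)
})

test_that("missing R-squared gives no edge by default, errors on request", {
  m <- rbind(c(1, NA), c(NA, 1))
  lmNA <- LDMatrix(m, c("a", "b"), "8")
  expect_equal(sum(buildLdGraph(lmNA, 0.5)), 0L)
  expect_error(buildLdGraph(lmNA, 0.5, missing_policy = "error"), "missing")
})

test_that("transitive chains split the two clustering rules as documented", {
  # A-B 0.6, B-C 0.55, A-C 0.1: one component, but the greedy sweep from A
  # claims only B, leaving C alone
  m <- rbind(c(1, 0.6, 0.1), c(0.6, 1, 0.55), c(0.1, 0.55, 1))
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  lm3 <- LDMatrix(m, c("A", "B", "C"), "sim")
  expect_equal(nrow(clusterVariants(lm3, method = "connected_components")), 1L)
  greedy <- clusterVariants(lm3, method = "greedy_sentinel")
  expect_equal(nrow(greedy), 2L)
  expect_identical(sort(greedy$sentinel), c("A", "C"))

  # an order permutation exists that changes the greedy count (start at B:
  # B claims A and C, one cluster) while components stay invariant
  perm <- c("B", "A", "C")
  lm3p <- LDMatrix(m[perm, perm], perm, "sim")
  expect_equal(nrow(clusterVariants(lm3p, method = "greedy_sentinel")), 1L)
  expect_equal(nrow(clusterVariants(lm3p, method = "connected_components")),
               1L)
})

test_that("an all-zero matrix yields all singletons under both rules", {
  n <- 6
  m <- diag(n); ids <- sprintf("rs%d", 1:n); dimnames(m) <- list(ids, ids)
  lm0 <- LDMatrix(m, ids, "sim")
  for (meth in c("connected_components", "greedy_sentinel"))
    expect_equal(nrow(clusterVariants(lm0, method = meth)), n)
})

test_that("clustering equals the union-find oracle on random matrices", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    m <- matrix(round(runif(n * n), 3), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    ids <- sprintf("rs%02d", seq_len(n)); dimnames(m) <- list(ids, ids)
    cutoff <- runif(1, 0.3, 0.8)
    cl <- clusterVariants(LDMatrix(m, ids, "sim"), r2_cutoff = cutoff)
    oracle <- unionFindClusters(m, cutoff)
    expect_equal(nrow(cl), length(unique(oracle)))
    # identical partition, not just identical counts
    got <- integer(n); names(got) <- ids
    for (k in seq_len(nrow(cl))) got[cl$members[[k]]] <- k
    expect_equal(length(unique(paste(got, oracle))),
                 length(unique(oracle)))
  }
})

test_that("cluster count is monotone non-increasing as the cutoff falls", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 10
    m <- matrix(runif(n * n), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1
    ids <- sprintf("rs%02d", 1:n); dimnames(m) <- list(ids, ids)
    lmr <- LDMatrix(m, ids, "sim")
    counts <- vapply(seq(1, 0, by = -0.1), function(ct)
      nrow(clusterVariants(lmr, r2_cutoff = ct)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("connected components are invariant to rsid input order", {
  set.seed(5)
  n <- 9
  m <- matrix(runif(n * n, 0, 1), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1
  ids <- sprintf("rs%02d", 1:n); dimnames(m) <- list(ids, ids)
  signature <- function(cl) sort(vapply(cl$members, function(mm)
    paste(sort(mm), collapse = ","), character(1)))
  base <- signature(clusterVariants(LDMatrix(m, ids, "sim")))
  for (k in 1:5) {
    p <- sample(ids)
    perm <- clusterVariants(LDMatrix(m[p, p], p, "sim"))
    expect_identical(signature(perm), base)
  }
})

test_that("published chromosome blocks cluster as printed", {
  chr2 <- readLdMatrix(fixturePath("ld", "chr2.csv"), "2")
  expect_equal(nrow(clusterVariants(chr2)), 1L)
  chr15 <- readLdMatrix(fixturePath("ld", "chr15.csv"), "15")
  expect_equal(nrow(clusterVariants(chr15)), 1L)  # all pairwise >= 0.746
  # the chromosome-8 variant with unmeasured LD stays a singleton
  chr8 <- readLdMatrix(fixturePath("ld", "chr8.csv"), "8")
  cl8 <- clusterVariants(chr8)
  expect_true("rs28365964" %in% cl8$sentinel[cl8$n_members == 1])
})

test_that("the full panel reports both rules' counts without forcing either", {
  mats <- readLdMatrixDir(fixturePath("ld"))
  snps <- readSnpTable(fixturePath("snp_panel.csv"))
  counts <- countIndependentVariants(mats, snps = snps)
  # greedy sentinel can only split components, never merge them
  expect_true(counts["greedy_sentinel"] >= counts["connected_components"])
  # both land in the neighbourhood of the published figure of ~70
  expect_true(all(counts >= 60 & counts <= 80))
  expect_error(clusterVariants(c(mats, mats[1])), "more than one matrix")
})

test_that("sentinels take the lowest chromosomal position when known", {
  snps <- readSnpTable(fixturePath("snp_panel.csv"))
  chr2 <- readLdMatrix(fixturePath("ld", "chr2.csv"), "2")
  cl <- clusterVariants(chr2, snps = snps)
  expect_identical(cl$sentinel, "rs11125529")  # 54248729 < 54258545
})

test_that("panel summaries count SNPs, chromosomes and clusters", {
  snps <- readSnpTable(fixturePath("snp_panel.csv"))
  mats <- readLdMatrixDir(fixturePath("ld"))
  cl <- clusterVariants(mats, snps = snps)
  s <- summarizeSnpPanel(snps, cl)
  expect_equal(s$n_snps, 106L)
  expect_equal(s$n_chromosomes, 18L)
  expect_equal(s$n_clusters, nrow(cl))
  expect_equal(nrow(s$sentinels), nrow(cl))
  # empty panel gives zero counts
  s0 <- summarizeSnpPanel(snps[0, ], cl[0, ])
  expect_equal(s0$n_snps, 0L)
  expect_equal(s0$n_clusters, 0L)
  # orphan members are an error
  expect_error(summarizeSnpPanel(snps[snps$chromosome != "2", ], cl),
               "absent")
})
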