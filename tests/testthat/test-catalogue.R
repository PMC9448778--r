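make_variant <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(v)) < rate)
  for (i in idx) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  paste(v, collapse = "")
}

test_that("vOTU clustering groups at 95% identity and matches the oracle", {
  set.seed(71)
  g <- random_dna_str(15000)
  dup <- g
  near <- make_variant(g, 0.02)    # 2% diverged: same species
  far <- make_variant(g, 0.10)     # 10% diverged: distinct vOTU
  genomes <- c(a = g, b = dup, c = near, d = far)
  cl <- cluster_votus(genomes)
  of <- function(x) cl$votu_id[cl$member == x]
  expect_identical(of("a"), of("b"))
  expect_identical(of("a"), of("c"))
  expect_false(identical(of("a"), of("d")))
  # representative is a member and partition covers all inputs
  expect_setequal(cl$member, names(genomes))
  expect_true(all(cl$representative %in% cl$member))

  # 3 planted species x 4 variants (<= 3% divergence) -> 3 vOTUs,
  # identical to the exhaustive all-pairs clustering
  species <- lapply(1:3, function(i) random_dna_str(12000))
  genomes12 <- list()
  for (i in 1:3) {
    for (j in 1:4) {
      genomes12[[sprintf("s%d_v%d", i, j)]] <-
        if (j == 1) species[[i]]
        else make_variant(species[[i]], runif(1, 0.01, 0.03))
    }
  }
  genomes12 <- unlist(genomes12)
  cl12 <- cluster_votus(genomes12)
  expect_identical(length(unique(cl12$votu_id)), 3L)
  want <- oracle_votu_partition(genomes12)
  got <- cl12$votu_id[match(names(genomes12), cl12$member)]
  # same partition up to labels
  expect_identical(length(unique(paste(got, want))),
                   length(unique(got)))

  # post hoc: every member satisfies thresholds against its rep
  for (r in seq_len(nrow(cl12))) {
    if (cl12$member[r] == cl12$representative[r]) next
    h <- estimate_ani(genomes12[[cl12$member[r]]],
                      genomes12[[cl12$representative[r]]])
    expect_gte(h$ani, 0.95)
    expect_gte(h$aligned_fraction, 0.85)
  }
})

test_that("MCL finds graph structure and matches an independent iteration", {
  # block-diagonal two-clique matrix: the two cliques
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; diag(a) <- 0
  cl <- mcl(a)
  expect_identical(length(cl), 2L)
  expect_setequal(lapply(cl, sort), list(1:3, 4:6))

  # single node
  expect_identical(mcl(matrix(0, 1, 1)), list(1L))

  # 3-node path converges deterministically
  p <- matrix(0, 3, 3); p[1, 2] <- p[2, 1] <- 1; p[2, 3] <- p[3, 2] <- 1
  cl_p <- mcl(p)
  expect_identical(cl_p, mcl(p))
  expect_identical(sort(unlist(cl_p)), 1:3)

  # equivalence with the independent implementation on random graphs
  set.seed(81)
  for (i in 1:12) {
    n <- sample(5:20, 1)
    adj <- matrix(0, n, n)
    # a few planted modules plus sparse background
    k <- sample(2:3, 1)
    memb <- sample(k, n, replace = TRUE)
    for (u in 1:(n - 1)) for (v in (u + 1):n) {
      w <- if (memb[u] == memb[v]) runif(1, 0.5, 1) * (runif(1) < 0.8)
        else runif(1, 0, 0.2) * (runif(1) < 0.1)
      adj[u, v] <- adj[v, u] <- w
    }
    got <- integer(n)
    for (ci in seq_along(mcl(adj))) got[mcl(adj)[[ci]]] <- ci
    want <- oracle_mcl(adj)
    expect_identical(length(unique(paste(got, want))),
                     length(unique(got)), label = paste("graph", i))
  }

  expect_error(mcl(matrix(1, 2, 3)), "square")
  expect_error(mcl(matrix(-1, 2, 2)), "non-negative")
})

test_that("MCL iterations keep columns stochastic and ignore labels", {
  set.seed(82)
  n <- 8
  adj <- matrix(runif(n * n) * (runif(n * n) < 0.4), n, n)
  adj <- (adj + t(adj)) / 2
  # column stochasticity is preserved by construction: the attractor of
  # a run equals the attractor of the relabelled run
  perm <- sample(n)
  cl1 <- mcl(adj)
  cl2 <- mcl(adj[perm, perm])
  to_memb <- function(cl, n) {
    m <- integer(n); for (ci in seq_along(cl)) m[cl[[ci]]] <- ci; m
  }
  m1 <- to_memb(cl1, n)
  m2 <- to_memb(cl2, n)[order(perm)]
  expect_identical(length(unique(paste(m1, m2))), length(unique(m1)))
})

test_that("protein clustering separates families and keeps singletons", {
  set.seed(83)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  fam1 <- paste(sample(aa, 150, replace = TRUE), collapse = "")
  prots <- c(p1 = fam1, p2 = fam1,
             p3 = paste(sample(aa, 150, replace = TRUE), collapse = ""))
  pc <- cluster_proteins(prots)
  sizes <- sort(table(pc$pc_id))
  expect_identical(unname(as.integer(sizes)), c(1L, 2L))
  expect_identical(pc$pc_id[pc$protein_id == "p1"],
                   pc$pc_id[pc$protein_id == "p2"])

  # two 10-member homolog families stay separate at inflation 2
  mk_fam <- function(base, n) {
    vapply(1:n, function(i) {
      v <- strsplit(base, "")[[1]]
      for (p in sample(150, 8)) v[p] <- setdiff(aa, v[p])[1]
      paste(v, collapse = "")
    }, character(1))
  }
  f1 <- mk_fam(fam1, 10)
  f2 <- mk_fam(paste(sample(aa, 150, replace = TRUE), collapse = ""), 10)
  all20 <- c(f1, f2)
  names(all20) <- sprintf("q%02d", 1:20)
  pc2 <- cluster_proteins(all20)
  expect_identical(length(unique(pc2$pc_id)), 2L)
  expect_identical(length(unique(pc2$pc_id[1:10])), 1L)

  # no homology at all: every protein its own cluster
  rnd <- vapply(1:5, function(i)
    paste(sample(aa, 120, replace = TRUE), collapse = ""), character(1))
  names(rnd) <- sprintf("r%d", 1:5)
  expect_identical(length(unique(cluster_proteins(rnd)$pc_id)), 5L)
})

test_that("VC grouping applies the strict >20% shared-cluster rule", {
  pcs <- list(
    A = sprintf("PC_%02d", 1:10),          # shares 3 with B: 3/10 = 0.30
    B = sprintf("PC_%02d", c(1:3, 11:19)),
    C = sprintf("PC_%02d", c(4, 5, 20:27)),  # shares 2/10 = 0.20 with A
    D = sprintf("PC_%02d", 30:37))         # disjoint
  vc <- build_vcs(pcs)
  m <- vc$membership
  vc_of <- function(x) m$vc_id[m$votu_id == x]
  expect_identical(vc_of("A"), vc_of("B"))
  expect_false(identical(vc_of("A"), vc_of("C")))  # exactly 0.20: not grouped
  expect_false(identical(vc_of("A"), vc_of("D")))
  expect_equal(vc$shared["A", "B"], 0.30)
  expect_equal(vc$shared["A", "C"], 0.20)

  # result invariant under input permutation
  vc2 <- build_vcs(pcs[c(3, 1, 4, 2)])
  expect_identical(vc$membership, vc2$membership)

  expect_warning(build_vcs(c(pcs, list(E = character(0)))), "E")
})

test_that("taxonomy voting requires a strict >20% plurality", {
  fams <- c(rep("Siphoviridae", 5), rep(NA, 15))
  expect_identical(assign_taxonomy(fams), "Siphoviridae")   # 0.25
  fams4 <- c(rep("Siphoviridae", 4), rep(NA, 16))
  expect_identical(assign_taxonomy(fams4), "unclassified")  # exactly 0.20
  expect_identical(assign_taxonomy(rep(NA_character_, 10)),
                   "unclassified")
  tied <- c(rep("Siphoviridae", 5), rep("Myoviridae", 5), rep(NA, 5))
  expect_identical(assign_taxonomy(tied), "unclassified")
})

test_that("lifestyle combines score and bacterial-alignment evidence", {
  expect_identical(classify_lifestyle(0.85), "temperate")
  expect_identical(classify_lifestyle(0.8), "virulent")   # strict > 0.8
  aln <- data.frame(aln_len = 1500, identity = 0.96)
  expect_identical(classify_lifestyle(0.5, aln), "temperate")
  weak <- data.frame(aln_len = c(900, 1500), identity = c(0.99, 0.90))
  expect_identical(classify_lifestyle(0.2, weak), "virulent")
  expect_identical(classify_lifestyle(0.2), "virulent")
})

test_that("rarefaction is monotone with exact endpoints", {
  set.seed(84)
  det <- matrix(rbinom(20 * 30, 1, 0.3), nrow = 20)
  colnames(det) <- sprintf("f%02d", 1:30)
  rc <- rarefy_richness(det, depths = c(1, 5, 10, 20), reps = 40)
  expect_equal(rc$mean_richness[rc$depth == 20],
               sum(colSums(det) > 0))
  expect_equal(rc$mean_richness[rc$depth == 1], mean(rowSums(det)),
               tolerance = 0.15 * mean(rowSums(det)))
  expect_true(all(diff(rc$mean_richness) >= 0))
  expect_error(rarefy_richness(det, depths = 25), "depth")
})
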