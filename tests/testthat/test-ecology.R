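test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(0, 5, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  # scale invariance and zero handling
  expect_equal(shannon(c(2, 1, 1, 0)), shannon(c(0.5, 0.25, 0.25)))
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "negative")
  # maximal iff uniform
  set.seed(5)
  for (i in 1:20) {
    p <- runif(6)
    expect_lte(shannon(p), log(6) + 1e-12)
  }
})

test_that("Bray-Curtis attains its bounds and matches hand evaluation", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 0), c(0.5, 0.5)), 0.5)
  a <- c(0.2, 0.5, 0.3); b <- c(0.4, 0.1, 0.5)
  expect_equal(bray_curtis(a, b), bray_curtis(b, a))
  expect_gte(bray_curtis(a, b), 0)
  expect_lte(bray_curtis(a, b), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(1:2, 1:3), "length")
})

test_that("mean pairwise distance matches the hand-computed matrix", {
  m <- rbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(0, 1))
  mp <- mean_pairwise_distance(m)
  expect_equal(unname(mp["s1"]), mean(c(0, 1)))
  expect_equal(unname(mp["s3"]), 1)
  expect_equal(mean_pairwise_distance(rbind(a = c(1, 2), b = c(1, 2))),
               c(a = 0, b = 0))
  # order invariance
  expect_equal(sort(mean_pairwise_distance(m[c(3, 1, 2), ])),
               sort(mp))
  expect_error(mean_pairwise_distance(m[1, , drop = FALSE]), "two")
})

test_that("Spearman correlation handles monotone data and midranks", {
  expect_equal(spearman(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  # tie-containing fixture equals the rank-then-Pearson oracle
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  got <- spearman(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)))
  expect_error(spearman(c(1, 1, 1), 1:3), "variance")
  expect_error(spearman(1:2, 1:2), "observations")
})

test_that("rank-sum test is exact for small groups and matches enumeration", {
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6))$p,
               oracle_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(6)
  for (i in 1:10) {
    a <- round(rnorm(sample(3:6, 1)), 3)
    b <- round(rnorm(sample(3:6, 1)) + runif(1, -1, 1), 3)
    expect_equal(compare_groups(a, b)$p, oracle_wilcoxon_p(a, b),
                 label = paste("case", i))
  }
  # invariant to within-group ordering
  a <- rnorm(8); b <- rnorm(9)
  expect_equal(compare_groups(a, b)$p,
               compare_groups(sample(a), sample(b))$p)
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("phage-host correlations follow inclusion and exclusion rules", {
  co <- fixture("cohort_cpl", function()
    generate_cohort(n_samples = 400, rng_seed = 61))
  hosts <- data.frame(votu_id = co$coupling$votu,
                      genus = co$coupling$host_genus,
                      label = co$coupling$label,
                      stringsAsFactors = FALSE)
  recs <- phage_host_correlations(co$votu_relative, co$genus_relative,
                                  hosts, min_votu_abund = 0,
                                  min_genus_abund = 0)
  # one record per (vOTU, genus) pair; n_used at most n_samples
  expect_false(any(duplicated(paste(recs$votu_id, recs$genus))))
  expect_true(all(recs$n_used <= 400))
  # co-absent samples are excluded
  v <- recs$votu_id[1]; g <- recs$genus[1]
  both0 <- sum(co$votu_relative[, v] == 0 & co$genus_relative[, g] == 0)
  expect_identical(recs$n_used[1], as.integer(400 - both0))

  # a vOTU below the abundance floor yields no record
  strict <- phage_host_correlations(co$votu_relative, co$genus_relative,
                                    hosts, min_votu_abund = 1)
  expect_identical(nrow(strict), 0L)

  # a generalist with several predicted genera contributes one record
  # per genus
  multi <- data.frame(votu_id = rep(co$coupling$votu[1], 3),
                      genus = colnames(co$genus_relative)[1:3],
                      label = "generalist", stringsAsFactors = FALSE)
  recs3 <- phage_host_correlations(co$votu_relative, co$genus_relative,
                                   multi, min_votu_abund = 0,
                                   min_genus_abund = 0)
  expect_identical(nrow(recs3), 3L)
})

test_that("defence tertiles track a monotone diversity relationship", {
  co <- fixture("cohort_cpl", function()
    generate_cohort(n_samples = 400, rng_seed = 61))
  da <- defence_association(co$defence_abundance, co$votu_relative)
  # tertile sizes differ by at most 1
  expect_lte(diff(range(table(da$groups))), 1)
  # defence abundance is built as a monotone function of Shannon
  # diversity plus noise: high group exceeds low group
  lh <- da$comparisons[da$comparisons$group_a == "low" &
                         da$comparisons$group_b == "high", ]
  expect_gt(lh$median_b, lh$median_a)
  expect_lt(lh$p, 0.05)
  expect_true(all(da$per_system$rho > 0))
  expect_true(all(da$per_system$q >= da$per_system$p))

  # strictly increasing construction gives rho = 1
  div <- apply(co$votu_relative, 1, shannon)
  mono <- cbind(sys1 = 1 + 2 * div)
  rownames(mono) <- rownames(co$votu_relative)
  expect_equal(defence_association(mono, co$votu_relative)$per_system$rho,
               1)
  # independent defence abundance: small correlation
  set.seed(62)
  indep <- cbind(sys1 = runif(400))
  rownames(indep) <- rownames(co$votu_relative)
  expect_lt(abs(defence_association(indep,
                                    co$votu_relative)$per_system$rho),
            0.15)
  expect_error(defence_association(cbind(s = rep(1, 400)),
                                   co$votu_relative),
               "tertiles")
})

test_that("host-group aggregation distributes generalists to all groups", {
  m <- matrix(c(0.3, 0.2, 0.5,
                0.1, 0.6, 0.3), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("v1", "v2", "v3")))
  hosts <- data.frame(
    votu_id = c("v1", "v2", "v3"),
    genera = c("Bacteroides", "Bacteroides;Prevotella", ""),
    stringsAsFactors = FALSE)
  agg <- aggregate_by_host(m, hosts)
  expect_equal(agg["s1", "Bacteroides"], 0.5)   # v1 + generalist v2
  expect_equal(agg["s1", "Prevotella"], 0.2)
  expect_equal(agg["s1", "host_unknown"], 0.5)
  # generalist duplication means columns can exceed the total
  expect_gte(sum(agg["s1", ]), sum(m["s1", ]))

  # specialists only: group sums equal the direct partition
  sp <- data.frame(votu_id = c("v1", "v2", "v3"),
                   genera = c("A", "B", "A"), stringsAsFactors = FALSE)
  agg2 <- aggregate_by_host(m, sp)
  expect_equal(agg2["s2", "A"], 0.1 + 0.3)
  expect_equal(sum(agg2["s2", ]), 1)

  # phylum-level rollup via a genus map
  map <- c(Bacteroides = "Bacteroidota", Prevotella = "Bacteroidota")
  agg3 <- aggregate_by_host(m, hosts, group_map = map)
  expect_equal(agg3["s1", "Bacteroidota"], 0.5)  # v2 counted once
})
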