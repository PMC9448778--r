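# An independently scripted rule table used to cross-check the
# classifier: a direct transcription of the six exclusion rules.
oracle_six_criteria <- function(len, genes, kmer_p, provirus) {
  if (len < 10000) return(1L)
  if (kmer_p > 0.05) return(2L)
  if (sum(genes$plasmid_hallmark) > 0 || sum(genes$viral_hallmark) == 0)
    return(3L)
  if (sum(genes$bacterial_marker) > 0 || sum(genes$rRNA) > 0) return(4L)
  if (sum(genes$plasmid_db_hit) > sum(genes$viral_db_hit)) return(5L)
  if (provirus < 0.8) return(6L)
  NA_integer_
}

test_that("the six criteria fire in printed order", {
  ph <- generate_phage_genome(30000, 3, rng_seed = 51, id = "p")

  # undersized contig fails criterion 1 regardless of evidence
  small <- classify_contig(8000, ph$genes, 0.01, contig_id = "s")
  expect_identical(small$rejected_at, 1L)
  expect_identical(small$verdict, "rejected")

  # single bacterial marker gene fails criterion 4
  g <- ph$genes
  g$bacterial_marker[5] <- TRUE
  r4 <- classify_contig(30000, g, 0.01, provirus_fraction = 1,
                        contig_id = "m")
  expect_identical(r4$rejected_at, 4L)

  # a fully viral planted phage passes everything
  ok <- classify_contig(30000, ph$genes, 0.01, contig_id = "p")
  expect_identical(ok$verdict, "phage")
  expect_true(is.na(ok$rejected_at))

  # equal plasmid/viral db hits are kept (exclusion needs strictly more)
  g2 <- ph$genes
  nv <- sum(g2$viral_db_hit)
  g2$plasmid_db_hit <- FALSE
  g2$plasmid_db_hit[seq_len(nv)] <- TRUE
  expect_true(classify_contig(30000, g2, 0.01,
                              contig_id = "tie")$dbcount_pass)

  expect_error(classify_contig(30000, NULL, 0.01, contig_id = "x"),
               "x")
  expect_error(classify_contig(30000, ph$genes, NA, contig_id = "x"),
               "x")
})

test_that("classifier agrees with a rule-table oracle on random evidence", {
  set.seed(61)
  ph <- generate_phage_genome(30000, 3, rng_seed = 52, id = "p")
  for (i in 1:50) {
    g <- ph$genes
    n <- nrow(g)
    g$viral_hallmark <- runif(n) < 0.2
    g$plasmid_hallmark <- runif(n) < 0.05
    g$bacterial_marker <- runif(n) < 0.05
    g$rRNA <- runif(n) < 0.03
    g$viral_db_hit <- runif(n) < 0.5
    g$plasmid_db_hit <- runif(n) < 0.3
    len <- sample(c(8000, 15000, 30000), 1)
    p <- runif(1)
    got <- classify_contig(len, g, p, contig_id = "r")
    pv <- got$provirus_fraction
    expect_identical(got$rejected_at, oracle_six_criteria(len, g, p, pv),
                     label = paste("case", i))
    expect_identical(got$verdict == "phage",
                     all(c(got$size_pass, got$kmer_pass, got$hallmark_pass,
                           got$marker_pass, got$dbcount_pass,
                           got$provirus_pass)))
  }
})

test_that("verdict is monotone in the individual criteria", {
  ph <- generate_phage_genome(30000, 3, rng_seed = 53, id = "p")
  base <- classify_contig(30000, ph$genes, 0.01, contig_id = "p")
  expect_identical(base$verdict, "phage")
  # flipping any single criterion to fail always rejects
  breakers <- list(
    function(g, p) list(g = g, p = 0.2, len = 30000),
    function(g, p) { g$plasmid_hallmark[1] <- TRUE
                     list(g = g, p = p, len = 30000) },
    function(g, p) { g$rRNA[2] <- TRUE; list(g = g, p = p, len = 30000) },
    function(g, p) { g$viral_db_hit <- FALSE
                     g$viral_hallmark <- FALSE
                     g$viral_hallmark[1] <- TRUE
                     g$plasmid_db_hit <- TRUE
                     list(g = g, p = p, len = 30000) },
    function(g, p) list(g = g, p = p, len = 9000))
  for (b in breakers) {
    x <- b(ph$genes, 0.01)
    expect_identical(classify_contig(x$len, x$g, x$p,
                                     contig_id = "b")$verdict,
                     "rejected")
  }
})

test_that("provirus fraction reflects the viral interval", {
  ph <- generate_phage_genome(30000, 3, rng_seed = 54, id = "p")
  allv <- ph$genes
  allv$viral_db_hit <- TRUE
  expect_equal(estimate_provirus_fraction(30000, allv), 1.0)
  expect_equal(estimate_provirus_fraction(30000, ph$genes[0, ]), 0)

  # 30 kb viral island inside a 100 kb host contig scores ~0.3
  bac <- generate_bacterial_contig(70000, "Bacteroides", prophage = ph,
                                   rng_seed = 55, id = "b")
  iv <- bac$prophage_interval
  frac <- estimate_provirus_fraction(nchar(bac$seq), bac$genes)
  expect_equal(frac, (iv$end - iv$start + 1) / nchar(bac$seq),
               tolerance = 0.05)
})

test_that("circular screening and linear recovery route contigs correctly", {
  com <- fixture("com_clean", function() small_community(5, flip_noise = 0))
  disc <- fixture("disc_clean", function() {
    com <- fixture("com_clean", function() small_community(5, flip_noise = 0))
    discover_phages(com)
  })
  circ_ids <- disc$calls$contig_id[disc$calls$circular]
  lin_ids <- disc$calls$contig_id[!disc$calls$circular]
  truth <- com$truth$phages

  # circular planted phages are complete calls, trimmed
  expect_setequal(circ_ids, truth$contig_id[truth$circular])
  expect_true(all(disc$calls$tier[disc$calls$circular] == "complete"))
  tr <- disc$calls[disc$calls$circular, ]
  expect_identical(tr$trimmed_length,
                   nchar(disc$genomes[tr$contig_id]),
                   ignore_attr = TRUE)

  # linear drafts are recovered with completeness-consistent tiers
  expect_setequal(lin_ids, truth$contig_id[!truth$circular])
  lin <- disc$calls[!disc$calls$circular, ]
  expect_true(all(lin$tier[lin$completeness >= 0.9] == "high"))
  expect_true(all(lin$tier[lin$completeness < 0.9] == "medium"))

  # plasmids and bacterial contigs are never called
  expect_identical(evaluate_pipeline(disc$calls, com$truth$labels)$fpr, 0)
  # outputs of the two arms are disjoint
  expect_length(intersect(circ_ids, lin_ids), 0L)
})

test_that("fragment size gates linear recovery", {
  # a 50%-length fragment violates the >70% size rule and is dropped
  ph <- generate_phage_genome(30000, 3, circular = TRUE, rng_seed = 56,
                              id = "sp")
  half <- mutate_phage_variant(ph, nuc_rate = 0.005, aa_rate = 0.005,
                               keep_frac = 0.5, id = "half")
  ok <- mutate_phage_variant(ph, nuc_rate = 0.005, aa_rate = 0.005,
                             keep_frac = 0.8, id = "ok")
  ents <- list(ph, half, ok)
  contigs <- data.frame(
    contig_id = vapply(ents, `[[`, character(1), "id"),
    seq = vapply(ents, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE)
  contigs$length <- nchar(contigs$seq)
  com <- list(contigs = contigs,
              genes = do.call(rbind, lapply(ents, `[[`, "genes")),
              kmer_p = c(sp = 0.01, half = 0.01, ok = 0.01))
  disc <- discover_phages(com, external = NULL)
  expect_true("sp" %in% disc$calls$contig_id)
  expect_true("ok" %in% disc$calls$contig_id)
  expect_false("half" %in% disc$calls$contig_id)
  expect_identical(disc$calls$tier[disc$calls$contig_id == "ok"],
                   "medium")
  expect_equal(disc$calls$completeness[disc$calls$contig_id == "ok"],
               0.8, tolerance = 0.01)
})

test_that("pipeline evaluation computes the printed rate definitions", {
  calls <- data.frame(contig_id = c("p1", "p2", "x1"))
  truth <- c(p1 = "phage", p2 = "phage", p3 = "phage", p4 = "phage",
             p5 = "phage", x1 = "plasmid", x2 = "plasmid",
             b1 = "bacterial", b2 = "bacterial", b3 = "bacterial")
  ev <- evaluate_pipeline(calls, truth)
  expect_equal(ev$tpr, 2 / 5)
  expect_equal(ev$fpr, 1 / 5)
  expect_error(evaluate_pipeline(calls, character(0)), "empty")
})
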