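# Virome ecology statistics: Shannon alpha-diversity, Bray-Curtis
# beta-diversity, phage-host Spearman correlations with the catalogue's
# inclusion/exclusion rules, specialist-vs-generalist comparison,
# defence-system tertile analysis and host-group aggregation.

#' Shannon diversity of an abundance profile
#'
#' H = -sum p_i ln p_i over the normalized profile (natural log, zero
#' entries contribute nothing).
#'
#' @param profile non-negative vector with positive sum.
#' @return scalar diversity.
#' @export
shannon <- function(profile) {
  if (any(profile < 0)) stop("negative abundance")
  s <- sum(profile)
  if (s <= 0) stop("all-zero profile has undefined diversity")
  p <- profile[profile > 0] / s
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' 1 - 2 * sum(min(a, b)) / (sum(a) + sum(b)).
#'
#' @param a,b equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (any(a < 0) || any(b < 0)) stop("negative abundance")
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("both profiles all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Per-sample mean Bray-Curtis distance to all other samples
#'
#' @param matrix samples x features abundance matrix (>= 2 samples).
#' @return named vector of per-sample means (self excluded).
#' @export
mean_pairwise_distance <- function(matrix) {
  n <- nrow(matrix)
  if (n < 2L) stop("need at least two samples")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(matrix[i, ], matrix[j, ])
    }
  }
  stats::setNames(rowSums(d) / (n - 1L), rownames(matrix))
}

#' Spearman correlation with t-approximation p-value
#'
#' Pearson correlation of midranked values; two-sided p-value from the
#' t approximation.
#'
#' @param x,y paired observations (n >= 3).
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need >= 3 paired observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Spearman correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Phage-host Spearman correlations across samples
#'
#' One record per (vOTU, predicted host genus) pair: vOTUs with mean
#' relative abundance above `min_votu_abund` and genera above
#' `min_genus_abund` are included; samples where the pair is co-absent
#' (both zero; or either zero with `exclude = "either_zero"`) are
#' excluded from that pair's correlation. Pairs with fewer than three
#' usable samples are dropped with a warning.
#'
#' @param votu_rel samples x vOTU relative abundance matrix.
#' @param genus_rel samples x genus relative abundance matrix.
#' @param hosts data.frame with `votu_id`, `genus` (one row per
#'   predicted host; generalists appear once per genus) and optional
#'   `label`, `lifestyle` columns carried through.
#' @param min_votu_abund,min_genus_abund inclusion thresholds on mean
#'   relative abundance (defaults 1e-4 and 5e-3, i.e. 0.01% and 0.5%).
#' @param exclude sample-exclusion rule: "both_zero" (default) or
#'   "either_zero".
#' @return data.frame of correlation records (votu_id, genus, r_s, p,
#'   n_used, plus carried columns).
#' @export
phage_host_correlations <- function(votu_rel, genus_rel, hosts,
                                    min_votu_abund = 1e-4,
                                    min_genus_abund = 5e-3,
                                    exclude = c("both_zero",
                                                "either_zero")) {
  exclude <- match.arg(exclude)
  if (!identical(rownames(votu_rel), rownames(genus_rel))) {
    stop("sample sets of the two matrices differ")
  }
  if ("genera" %in% names(hosts) && !("genus" %in% names(hosts))) {
    # expand semicolon-separated host sets into one row per genus
    hosts <- do.call(rbind, lapply(seq_len(nrow(hosts)), function(i) {
      gs <- strsplit(hosts$genera[i], ";", fixed = TRUE)[[1]]
      if (!length(gs) || !nzchar(gs[1L])) return(NULL)
      data.frame(votu_id = hosts$votu_id[i], genus = gs,
                 label = hosts$label[i], stringsAsFactors = FALSE)
    }))
  }
  keep_v <- colnames(votu_rel)[colMeans(votu_rel) > min_votu_abund]
  keep_g <- colnames(genus_rel)[colMeans(genus_rel) > min_genus_abund]
  recs <- list()
  dropped <- 0L
  for (i in seq_len(nrow(hosts))) {
    v <- hosts$votu_id[i]; g <- hosts$genus[i]
    if (!(v %in% keep_v) || !(g %in% keep_g)) next
    x <- votu_rel[, v]; y <- genus_rel[, g]
    use <- if (exclude == "both_zero") !(x == 0 & y == 0)
      else !(x == 0 | y == 0)
    if (sum(use) < 3L || stats::sd(x[use]) == 0 ||
        stats::sd(y[use]) == 0) {
      dropped <- dropped + 1L
      next
    }
    sp <- spearman(x[use], y[use])
    rec <- data.frame(votu_id = v, genus = g, r_s = sp$rho, p = sp$p,
                      n_used = sum(use), stringsAsFactors = FALSE)
    for (col in intersect(c("label", "lifestyle"), names(hosts))) {
      rec[[col]] <- hosts[[col]][i]
    }
    recs[[length(recs) + 1L]] <- rec
  }
  if (dropped > 0L) {
    warning(dropped, " phage-host pair(s) dropped (insufficient samples)")
  }
  if (!length(recs)) {
    return(data.frame(votu_id = character(), genus = character(),
                      r_s = numeric(), p = numeric(), n_used = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(recs, make.row.names = FALSE))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test: exact when the pooled size is at most 12
#' and there are no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param values_a,values_b numeric vectors.
#' @return list with `W` and `p`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty group")
  na <- length(values_a); nb <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= 12L) {
    # exact two-sided p by enumerating all group assignments
    # (midranks make this valid in the presence of ties)
    mu <- na * nb / 2
    w_all <- utils::combn(na + nb, na, function(idx)
      sum(r[idx]) - na * (na + 1) / 2)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      values_a, values_b, alternative = "two.sided", exact = FALSE,
      correct = TRUE))
    p <- wt$p.value
  }
  list(W = unname(w_obs), p = p)
}

#' Defence-system abundance vs virome diversity
#'
#' Samples are split at the empirical tertiles of total defence-gene
#' abundance (ties go to the lower group); virome Shannon diversity is
#' compared pairwise between the low/middle/high groups with the
#' rank-sum test, and each defence system is correlated (Spearman)
#' with Shannon diversity, BH-adjusted across systems.
#'
#' @param defence_abund samples x defence-system abundance matrix.
#' @param votu_rel samples x vOTU relative abundance matrix.
#' @return list with `groups` (per-sample tertile), `comparisons`
#'   (pairwise rank-sum results) and `per_system` (rho, p, q per
#'   system).
#' @export
defence_association <- function(defence_abund, votu_rel) {
  if (nrow(defence_abund) < 3L) stop("need at least 3 samples")
  total <- rowSums(defence_abund)
  if (stats::sd(total) == 0) stop("constant defence abundance: tertiles undefined")
  div <- apply(votu_rel, 1L, shannon)
  qs <- stats::quantile(total, c(1 / 3, 2 / 3), type = 7)
  grp <- cut(total, breaks = c(-Inf, qs[1L], qs[2L], Inf),
             labels = c("low", "middle", "high"), right = TRUE)
  pairs <- list(c("low", "middle"), c("middle", "high"),
                c("low", "high"))
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    cg <- compare_groups(div[grp == pr[1L]], div[grp == pr[2L]])
    data.frame(group_a = pr[1L], group_b = pr[2L], W = cg$W, p = cg$p,
               median_a = stats::median(div[grp == pr[1L]]),
               median_b = stats::median(div[grp == pr[2L]]),
               stringsAsFactors = FALSE)
  }))
  per_system <- do.call(rbind, lapply(colnames(defence_abund), function(s) {
    sp <- spearman(defence_abund[, s], div)
    data.frame(system = s, rho = sp$rho, p = sp$p,
               stringsAsFactors = FALSE)
  }))
  per_system$q <- bh_fdr(per_system$p)
  list(groups = stats::setNames(as.character(grp),
                                rownames(defence_abund)),
       comparisons = comparisons, per_system = per_system)
}

#' Aggregate phage relative abundance by predicted host group
#'
#' Sums the relative abundance of phages per predicted host group
#' (genus, or phylum via `group_map`). Generalists contribute to every
#' predicted group, so group sums can exceed the total phage
#' abundance; host-unknown phages go to "host_unknown".
#'
#' @param votu_rel samples x vOTU relative abundance matrix.
#' @param hosts data.frame with `votu_id` and `genera`
#'   (semicolon-separated, "" for unknown).
#' @param group_map optional named vector mapping genus to a higher
#'   group (e.g. phylum); identity when NULL.
#' @return samples x host-group matrix.
#' @export
aggregate_by_host <- function(votu_rel, hosts, group_map = NULL) {
  groups_of <- function(votu) {
    i <- match(votu, hosts$votu_id)
    gs <- if (is.na(i)) character(0)
      else strsplit(hosts$genera[i], ";", fixed = TRUE)[[1]]
    gs <- gs[nzchar(gs)]
    if (!length(gs)) return("host_unknown")
    if (!is.null(group_map)) gs <- unname(group_map[gs])
    unique(gs)
  }
  gsets <- lapply(colnames(votu_rel), groups_of)
  all_groups <- sort(unique(unlist(gsets)))
  out <- matrix(0, nrow(votu_rel), length(all_groups),
                dimnames = list(rownames(votu_rel), all_groups))
  for (v in seq_along(gsets)) {
    for (g in gsets[[v]]) out[, g] <- out[, g] + votu_rel[, v]
  }
  out
}
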