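# vOTU / viral-cluster catalogue: greedy ANI clustering at the
# species level, Markov clustering of the protein similarity graph,
# shared-protein-cluster viral clusters, taxonomy voting, lifestyle
# calls and empirical rarefaction.

#' Greedy centroid clustering of phage genomes into vOTUs
#'
#' Genomes are sorted by quality tier then length (descending); each
#' genome joins the first established centroid it matches at
#' ANI >= 95% with >= 85% of its length aligned, otherwise it seeds a
#' new vOTU. The centroid (first, hence best, member) is the
#' representative.
#'
#' @param genomes named character vector of genome sequences.
#' @param tiers optional named character vector of quality tiers
#'   ("complete" > "high" > "medium" > "low"); unnamed genomes rank last.
#' @param cfg a [pipeline_config()].
#' @return data.frame with columns `votu_id`, `member`,
#'   `representative`.
#' @export
cluster_votus <- function(genomes, tiers = NULL,
                          cfg = pipeline_config()) {
  if (!length(genomes)) stop("no genomes to cluster")
  tier_rank <- c(complete = 1L, high = 2L, medium = 3L, low = 4L)
  rank <- rep(5L, length(genomes))
  if (!is.null(tiers)) {
    rank <- tier_rank[tiers[names(genomes)]]
    rank[is.na(rank)] <- 5L
  }
  ord <- order(rank, -nchar(genomes))
  ids <- names(genomes)[ord]
  reps <- character(0)
  rep_idx <- list()  # cached target indexes for established centroids
  assign <- character(length(ids)); names(assign) <- ids
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      hit <- estimate_ani(genomes[[id]], target_index = rep_idx[[r]])
      if (!is.na(hit$ani) && hit$ani >= cfg$ani_cluster &&
          hit$aligned_fraction >= cfg$cov_cluster) {
        assign[id] <- r; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      rep_idx[[id]] <- ani_target_index(genomes[[id]])
      assign[id] <- id
    }
  }
  votu_id <- stats::setNames(sprintf("vOTU_%03d", seq_along(reps)), reps)
  data.frame(votu_id = unname(votu_id[assign]), member = names(assign),
             representative = unname(assign), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Canonical MCL on a symmetric non-negative adjacency matrix:
#' self-loops are added (weight = the column maximum), columns are
#' normalized to stochastic, then expansion (matrix squaring) and
#' inflation (elementwise powering with renormalization and pruning)
#' alternate until the matrix change falls below `tol`. Clusters are the
#' connected components of the non-zero structure of the attractor
#' matrix.
#'
#' @param adjacency square symmetric non-negative matrix.
#' @param inflation inflation exponent (default 2).
#' @param expansion matrix power used for expansion (default 2).
#' @param prune_below entries below this are zeroed after inflation.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the max entry change.
#' @return list of integer vectors (cluster memberships, by column
#'   index; named when the matrix has dimnames).
#' @export
mcl <- function(adjacency, inflation = 2, expansion = 2,
                prune_below = 1e-5, max_iter = 100L, tol = 1e-8) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(a < 0)) stop("adjacency must be non-negative")
  if (max(abs(a - t(a))) > 1e-9) stop("adjacency must be symmetric")
  n <- nrow(a)
  loop <- apply(a, 2L, max)
  loop[loop == 0] <- 1
  diag(a) <- loop
  m <- sweep(a, 2L, colSums(a), "/")
  for (it in seq_len(max_iter)) {
    prev <- m
    ex <- m
    for (e in seq_len(expansion - 1L)) ex <- ex %*% m
    m <- ex^inflation
    m[m < prune_below] <- 0
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2L, cs, "/")
    if (max(abs(m - prev)) < tol) break
  }
  # connected components of the symmetrized non-zero structure
  link <- (m > 1e-6) | t(m > 1e-6)
  comp <- integer(n); cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (comp[u] > 0L) next
      comp[u] <- cur
      queue <- c(queue, which(link[u, ] & comp == 0L))
    }
  }
  out <- split(seq_len(n), comp)
  if (!is.null(colnames(a))) {
    out <- lapply(out, function(i) stats::setNames(i, colnames(a)[i]))
  }
  unname(out)
}

#' Cluster proteins into homolog families
#'
#' All-vs-all local protein alignment (prescreened by shared 6-mers),
#' an edge wherever the alignment score reaches `score_min`, then MCL
#' at inflation 2 on the score-weighted graph. Singletons are allowed.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param score_min alignment score cutoff for an edge (default 100).
#' @param inflation MCL inflation (default 2).
#' @return data.frame with columns `pc_id`, `protein_id`.
#' @export
cluster_proteins <- function(proteins, score_min = 100, inflation = 2) {
  if (!length(proteins)) stop("no proteins to cluster")
  n <- length(proteins)
  adj <- matrix(0, n, n, dimnames = list(names(proteins),
                                         names(proteins)))
  idx <- protein_kmer_index(proteins)
  k <- 6L
  for (i in seq_len(n)) {
    p <- proteins[[i]]
    if (nchar(p) < k) next
    st <- seq_len(nchar(p) - k + 1L)
    cand <- unique(unlist(lapply(unique(substring(p, st, st + k - 1L)),
                                 function(km) idx[[km]])))
    for (j in cand[cand > i]) {
      sc <- align_protein(p, proteins[[j]])$score
      if (sc >= score_min) { adj[i, j] <- sc; adj[j, i] <- sc }
    }
  }
  cl <- mcl(adj, inflation = inflation)
  do.call(rbind, lapply(seq_along(cl), function(ci)
    data.frame(pc_id = sprintf("PC_%04d", ci),
               protein_id = names(proteins)[cl[[ci]]],
               stringsAsFactors = FALSE)))
}

#' Group vOTUs into viral clusters by shared protein clusters
#'
#' The shared fraction of a vOTU pair is the number of protein
#' clusters present in both, divided by the smaller of the two protein
#' cluster repertoires. Pairs sharing strictly more than 20% are
#' linked; viral clusters are the connected components (single
#' linkage).
#'
#' @param votu_pcs named list: for each vOTU, the character vector of
#'   protein-cluster ids of its representative's proteins.
#' @param cfg a [pipeline_config()].
#' @return list with `membership` (data.frame vc_id/votu_id) and
#'   `shared` (matrix of pairwise shared fractions).
#' @export
build_vcs <- function(votu_pcs, cfg = pipeline_config()) {
  empty <- lengths(votu_pcs) == 0L
  if (any(empty)) {
    warning("excluding vOTUs with no protein clusters: ",
            paste(names(votu_pcs)[empty], collapse = ", "))
    votu_pcs <- votu_pcs[!empty]
  }
  ids <- sort(names(votu_pcs))
  votu_pcs <- lapply(votu_pcs[ids], unique)
  n <- length(ids)
  shared <- matrix(0, n, n, dimnames = list(ids, ids))
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      f <- length(intersect(votu_pcs[[i]], votu_pcs[[j]])) /
        min(length(votu_pcs[[i]]), length(votu_pcs[[j]]))
      shared[i, j] <- shared[j, i] <- f
      link[i, j] <- link[j, i] <- f > cfg$shared_pc_min
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (comp[u] > 0L) next
      comp[u] <- cur
      queue <- c(queue, which(link[u, ] & comp == 0L))
    }
  }
  # number VCs by decreasing membership for stable reporting
  sizes <- table(comp)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  membership <- data.frame(
    vc_id = sprintf("VC_%03d", relabel[as.character(comp)]),
    votu_id = ids, stringsAsFactors = FALSE)
  list(membership = membership[order(membership$vc_id), ],
       shared = shared)
}

#' Vote a family-level taxonomy for a phage
#'
#' The most common per-protein best-hit family is assigned iff its
#' share of the phage's proteins strictly exceeds 20%; ties between
#' top families, or share at or below the cutoff, give "unclassified".
#'
#' @param besthit_families character vector of per-protein best-hit
#'   families (NA for proteins without a hit).
#' @param cfg a [pipeline_config()].
#' @return character scalar: family name or "unclassified".
#' @export
assign_taxonomy <- function(besthit_families, cfg = pipeline_config()) {
  if (!length(besthit_families)) return("unclassified")
  hits <- besthit_families[!is.na(besthit_families)]
  if (!length(hits)) return("unclassified")
  tab <- sort(table(hits), decreasing = TRUE)
  share <- tab[1L] / length(besthit_families)
  if (share <= cfg$tax_vote_min) return("unclassified")
  if (length(tab) > 1L && tab[2L] == tab[1L]) return("unclassified")
  names(tab)[1L]
}

#' Classify phage lifestyle as temperate or virulent
#'
#' Temperate iff the temperate score exceeds 0.8 or any alignment to a
#' bacterial genome spans more than 1000 bp at more than 95% identity.
#'
#' @param temperate_score score in [0, 1]; see
#'   [temperate_score_from_genes()] for the annotation-based stand-in.
#' @param bacterial_alignments data.frame with columns `aln_len` and
#'   `identity` (may be empty or NULL).
#' @param cfg a [pipeline_config()].
#' @return "temperate" or "virulent".
#' @export
classify_lifestyle <- function(temperate_score,
                               bacterial_alignments = NULL,
                               cfg = pipeline_config()) {
  stopifnot(temperate_score >= 0, temperate_score <= 1)
  aligned <- !is.null(bacterial_alignments) &&
    nrow(bacterial_alignments) > 0L &&
    any(bacterial_alignments$aln_len > cfg$lifestyle_aln &
          bacterial_alignments$identity > cfg$lifestyle_ident)
  if (temperate_score > cfg$lifestyle_score || aligned) "temperate"
  else "virulent"
}

#' Temperate score from gene annotations
#'
#' Annotation-based score: 1 when any gene carries the temperate
#' (integrase/lysogeny) marker flag, else 0. A table of externally
#' computed scores can be used instead wherever a score is accepted.
#'
#' @param genes gene annotation rows of one genome.
#' @return score in [0, 1].
#' @export
temperate_score_from_genes <- function(genes) {
  as.numeric(any(genes$temperate_marker))
}

#' Empirical rarefaction of feature richness
#'
#' For each depth d, the mean (over random sample subsets of size d) of
#' the number of features detected in at least one subset member.
#'
#' @param detection binary samples x features matrix.
#' @param depths subset sizes.
#' @param reps random subsets per depth (default 30).
#' @return data.frame with `depth` and `mean_richness`.
#' @export
rarefy_richness <- function(detection, depths, reps = 30L) {
  det <- detection > 0
  n <- nrow(det)
  if (any(depths > n)) stop("depth exceeds number of samples")
  out <- vapply(depths, function(d) {
    if (d == n) {
      sum(colSums(det) > 0)
    } else {
      mean(vapply(seq_len(reps), function(r) {
        sub <- det[sample(n, d), , drop = FALSE]
        sum(colSums(sub) > 0)
      }, numeric(1)))
    }
  }, numeric(1))
  data.frame(depth = depths, mean_richness = out)
}
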