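# Independent oracle implementations used to cross-check the package's
# algorithms, plus memoised fixtures shared across test files.

# Exhaustive suffix-prefix overlap scan (integer-coded, computes every
# candidate length and returns the longest passing one).
oracle_terminal_redundancy <- function(seq, min_overlap = 131L,
                                       min_identity = 0.97) {
  v <- utf8ToInt(seq)
  n <- length(v)
  best <- NULL
  for (len in seq.int(min_overlap, n %/% 2L)) {
    ident <- mean(v[1:len] == v[(n - len + 1L):n])
    if (ident > min_identity - 1e-12) {
      best <- list(overlap_len = len, overlap_identity = ident)
    }
  }
  if (is.null(best)) {
    list(is_circular = FALSE, overlap_len = 0L)
  } else {
    c(list(is_circular = TRUE), best)
  }
}

# Brute-force protospacer scan: every window of width len-1..len+1 on
# both strands, Levenshtein distance via utils::adist.
oracle_match_spacer <- function(spacer, genome) {
  len <- nchar(spacer)
  n <- nchar(genome)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else phagepipe::revcomp(spacer)
    for (w in (len - 1L):(len + 1L)) {
      if (w < 1L || w > n) next
      starts <- seq_len(n - w + 1L)
      wins <- substring(genome, starts, starts + w - 1L)
      d <- drop(utils::adist(pat, wins))
      ok <- which(d <= 1L)
      for (s in ok) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = starts[s], strand = strand, edits = d[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), strand = character(),
                      edits = integer()))
  }
  h <- do.call(rbind, hits)
  # minimal edits per (strand, start)
  h <- h[order(h$strand, h$start, h$edits), ]
  h[!duplicated(h[, c("strand", "start")]), ]
}

# Quadratic Smith-Waterman with affine gaps (open + per-residue
# extension), BLOSUM62; returns the maximal local score.
oracle_sw_score <- function(q, t, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  qa <- strsplit(q, "")[[1]]; ta <- strsplit(t, "")[[1]]
  n <- length(qa); m <- length(ta)
  M <- matrix(0, n + 1L, m + 1L)   # match/mismatch state
  Ix <- matrix(-Inf, n + 1L, m + 1L)  # gap in t (consume q)
  Iy <- matrix(-Inf, n + 1L, m + 1L)  # gap in q (consume t)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- sub[qa[i - 1L], ta[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s, Ix[i - 1L, j - 1L] + s,
                     Iy[i - 1L, j - 1L] + s)
      Ix[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                      Ix[i - 1L, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                      Iy[i, j - 1L] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Textbook MCL as an explicit column-wise fixed-point iteration,
# written independently of the package implementation.
oracle_mcl <- function(adj, inflation = 2, max_iter = 200L,
                       tol = 1e-8) {
  n <- nrow(adj)
  a <- adj
  for (j in 1:n) a[j, j] <- if (max(adj[, j]) > 0) max(adj[, j]) else 1
  normalize <- function(m) {
    for (j in 1:n) {
      s <- sum(m[, j])
      if (s > 0) m[, j] <- m[, j] / s
    }
    m
  }
  m <- normalize(a)
  for (it in 1:max_iter) {
    old <- m
    m <- m %*% m
    m <- m^inflation
    m[m < 1e-5] <- 0
    m <- normalize(m)
    if (max(abs(m - old)) < tol) break
  }
  memb <- rep(0L, n)
  cur <- 0L
  adj2 <- (m > 1e-6) | t(m > 1e-6)
  for (v in 1:n) {
    if (memb[v]) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[1L]; stack <- stack[-1L]
      if (memb[u]) next
      memb[u] <- cur
      stack <- c(stack, which(adj2[u, ] & memb == 0L))
    }
  }
  memb
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2L, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# BH q-values straight from the definition:
# q_i = min over {j : p_j >= p_i} of min(1, p_j * m / rank_j).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i] - 1e-15)
    min(1, min(p[j] * m / r[j]))
  }, numeric(1))
}

# Single-linkage clustering over the pairwise ANI graph (edge iff the
# thresholds hold in either direction) -- the exhaustive counterpart of
# the greedy centroid pass on well-separated inputs.
oracle_votu_partition <- function(genomes, ani_min = 0.95,
                                  cov_min = 0.85) {
  n <- length(genomes)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      h <- phagepipe::estimate_ani(genomes[[i]], genomes[[j]])
      if (!is.na(h$ani) && h$ani >= ani_min &&
          h$aligned_fraction >= cov_min) {
        link[i, j] <- link[j, i] <- TRUE
      }
    }
  }
  memb <- rep(0L, n); cur <- 0L
  for (v in seq_len(n)) {
    if (memb[v]) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[1L]; stack <- stack[-1L]
      if (memb[u]) next
      memb[u] <- cur
      stack <- c(stack, which(link[u, ] & memb == 0L))
    }
  }
  stats::setNames(memb, names(genomes))
}

# Direct distance decomposition of explained variance for PERMANOVA:
# SS_total = sum d^2 / n; SS_within from group-internal distances.
oracle_permanova_r2 <- function(D, groups) {
  n <- nrow(D)
  ss_tot <- sum(D[lower.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- D[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
    }
  }
  1 - ss_within / ss_tot
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Memoised fixtures shared across test files (built once per session).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_community <- function(seed, flip_noise = 0.02) {
  generate_community(n_phage_species = 4L, n_linear = 4L,
                     n_plasmids = 3L, n_bacteria = 5L, n_prophage = 1L,
                     n_crispr = 3L, flip_noise = flip_noise,
                     rng_seed = seed)
}
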