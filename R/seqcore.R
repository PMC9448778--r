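# Sequence and alignment primitives shared by all pipeline stages:
# terminal-redundancy circularity detection, protein local alignment,
# fragment-based ANI estimation and a seed-and-extend read mapper.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate a nucleotide sequence
#'
#' @param seq character scalar over A/C/G/T/N, uppercase.
#' @param id identifier used in error messages.
#' @return the sequence, invisibly.
#' @keywords internal
check_dna <- function(seq, id = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("'", id, "' must be a non-empty character scalar")
  }
  if (grepl("[^ACGTN]", seq)) {
    stop("'", id, "' contains characters outside A/C/G/T/N")
  }
  invisible(seq)
}

AA_ALPHABET20 <- "ACDEFGHIKLMNPQRSTVWY"

check_protein <- function(seq, id = "protein") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("'", id, "' must be a non-empty character scalar")
  }
  if (grepl(paste0("[^", AA_ALPHABET20, "]"), seq)) {
    stop("'", id, "' contains non-standard amino-acid characters")
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Detect terminal redundancy (circularity) in an assembled contig
#'
#' A contig assembled from a circular genome carries an identical (up to
#' sequencing/assembly error) copy of its start at its end. The detector
#' scans ungapped suffix-prefix overlaps from the longest candidate down
#' and reports the first (hence longest) overlap exceeding both the
#' length and identity thresholds. Thresholds are strict: an overlap of
#' exactly 130 bp, or at exactly 97% identity, does not qualify.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param min_overlap minimum qualifying overlap length in bp (default
#'   131, i.e. strictly more than 130 bp).
#' @param min_identity identity threshold; overlaps must exceed it
#'   (default 0.97).
#' @param max_overlap longest overlap length considered; bounds the
#'   quadratic scan on long contigs (default 5000 bp, far above the
#'   terminal repeats produced by real assemblers).
#' @return list with elements `is_circular`, `overlap_len`,
#'   `overlap_identity` and `trimmed_length` (contig length with the
#'   redundant terminal copy removed when circular, full length
#'   otherwise).
#' @export
detect_terminal_redundancy <- function(seq, min_overlap = 131L,
                                       min_identity = 0.97,
                                       max_overlap = 5000L) {
  check_dna(seq)
  n <- nchar(seq)
  if (n <= 2L * min_overlap) {
    stop("sequence too short for circularity check (", n, " bp <= 2 * ",
         min_overlap, ")")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  l_max <- min(n %/% 2L, max_overlap)
  for (len in seq.int(l_max, min_overlap)) {
    ident <- sum(chars[seq_len(len)] ==
                   chars[seq.int(n - len + 1L, n)]) / len
    if (ident > min_identity - 1e-12) {
      return(list(is_circular = TRUE, overlap_len = len,
                  overlap_identity = ident, trimmed_length = n - len))
    }
  }
  list(is_circular = FALSE, overlap_len = 0L, overlap_identity = 0,
       trimmed_length = n)
}

#' Local protein alignment under BLOSUM62 with affine gaps
#'
#' Thin wrapper around Smith-Waterman alignment (BLOSUM62, gap open 11,
#' gap extension 1) returning an alignment-hit record with identity and
#' coverage fractions.
#'
#' @param q,t amino-acid sequences (standard 20-letter alphabet).
#' @param query_id,target_id identifiers copied into the record.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return list with `query_id`, `target_id`, `identity`, `aln_len`,
#'   `query_cov`, `target_cov`, `mismatches`, `gaps`, `score`.
#' @export
align_protein <- function(q, t, query_id = "query", target_id = "target",
                          gap_opening = 11, gap_extension = 1) {
  check_protein(q, "q")
  check_protein(t, "t")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  ind <- Biostrings::nindel(pa)
  gap_len <- sum(Biostrings::insertion(ind)[, "WidthSum"],
                 Biostrings::deletion(ind)[, "WidthSum"])
  aln_len <- nm + nmm + gap_len
  score <- max(0, Biostrings::score(pa))
  qspan <- Biostrings::width(Biostrings::pattern(pa))
  tspan <- Biostrings::width(Biostrings::subject(pa))
  list(query_id = query_id, target_id = target_id,
       identity = if (aln_len > 0) nm / aln_len else 0,
       aln_len = aln_len,
       query_cov = qspan / nchar(q), target_cov = tspan / nchar(t),
       mismatches = nmm, gaps = gap_len, score = score)
}

# Hash index mapping every k-mer of a sequence to its start positions.
# Returned as an environment keyed by k-mer string.
kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (n < k) return(env)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  grouped <- split(starts, kmers)
  list2env(grouped, envir = env)
  env
}

# Ungapped identity of `frag` placed against `t_chars` at 1-based offset
# `off` (may clip at either end). Returns c(matches, compared_len).
ungapped_compare <- function(f_chars, t_chars, off) {
  lf <- length(f_chars)
  lt <- length(t_chars)
  f_from <- max(1L, 1L - off + 1L)
  f_to <- min(lf, lt - off + 1L)
  if (f_to < f_from) return(c(0L, 0L))
  idx_f <- seq.int(f_from, f_to)
  idx_t <- idx_f + off - 1L
  c(sum(f_chars[idx_f] == t_chars[idx_t]), length(idx_f))
}

#' Estimate average nucleotide identity between two genomes
#'
#' Genome `a` is cut into consecutive non-overlapping fragments; each
#' fragment is placed on `b` by exact k-mer seeding followed by ungapped
#' comparison (both orientations). Fragments aligning at >= 80% identity
#' contribute to the ANI estimate.
#'
#' @param a,b nucleotide sequences.
#' @param fragment fragment size in bp (default 1000).
#' @param k seed k-mer size (default 15).
#' @param target_index optional prebuilt [ani_target_index()] of `b`
#'   (avoids re-indexing the same target across many queries).
#' @return list with `ani` (mean identity of aligned fragments, NA when
#'   none align) and `aligned_fraction` (summed aligned fragment length
#'   over `nchar(a)`).
#' @export
estimate_ani <- function(a, b, fragment = 1000L, k = 15L,
                         target_index = NULL) {
  check_dna(a, "a")
  if (is.null(target_index)) {
    check_dna(b, "b")
    target_index <- ani_target_index(b, k)
  }
  if (nchar(a) < fragment || target_index$len < fragment) {
    stop("both sequences must be at least one fragment (", fragment, " bp) long")
  }
  idx <- target_index$idx
  t_chars <- target_index$chars
  starts <- seq.int(1L, nchar(a), by = fragment)
  idents <- numeric(0)
  aligned_bp <- 0L
  for (s in starts) {
    e <- min(s + fragment - 1L, nchar(a))
    if (e - s + 1L < k) next
    frag <- substr(a, s, e)
    best <- best_ungapped_placement(frag, idx, t_chars, k)
    if (!is.null(best) && best[["identity"]] >= 0.8) {
      idents <- c(idents, best[["identity"]])
      aligned_bp <- aligned_bp + best[["len"]]
    }
  }
  list(ani = if (length(idents)) mean(idents) else NA_real_,
       aligned_fraction = aligned_bp / nchar(a))
}

#' Prebuilt ANI target index
#'
#' @param b target nucleotide sequence.
#' @param k seed k-mer size.
#' @return list with `idx`, `chars`, `len`, reusable across
#'   [estimate_ani()] calls.
#' @export
ani_target_index <- function(b, k = 15L) {
  list(idx = kmer_positions(b, k),
       chars = strsplit(b, "", fixed = TRUE)[[1]], len = nchar(b))
}

# Seed a fragment against a k-mer index (trying both orientations) and
# return the best ungapped placement as c(identity=, len=), or NULL.
best_ungapped_placement <- function(frag, idx, t_chars, k,
                                    seed_step = 40L, max_seeds = 25L) {
  best <- NULL
  for (orient in c("fwd", "rev")) {
    fr <- if (orient == "fwd") frag else revcomp(frag)
    lf <- nchar(fr)
    if (lf < k) next
    f_chars <- strsplit(fr, "", fixed = TRUE)[[1]]
    seed_offs <- unique(pmin(seq.int(1L, lf - k + 1L, by = seed_step),
                             lf - k + 1L))
    if (length(seed_offs) > max_seeds) seed_offs <- seed_offs[seq_len(max_seeds)]
    offsets <- integer(0)
    for (so in seed_offs) {
      hit_pos <- idx[[substr(fr, so, so + k - 1L)]]
      if (!is.null(hit_pos)) offsets <- c(offsets, hit_pos - so + 1L)
    }
    for (off in unique(offsets)) {
      cmp <- ungapped_compare(f_chars, t_chars, off)
      if (cmp[2L] == 0L) next
      ident <- cmp[1L] / cmp[2L]
      if (is.null(best) || ident > best[["identity"]]) {
        best <- c(identity = ident, len = cmp[2L])
      }
    }
  }
  best
}

#' Build a read-mapping index over a gene set
#'
#' Indexes every k-mer of every gene; used by [map_read()] for
#' seed-and-extend placement.
#'
#' @param genes named character vector of gene nucleotide sequences.
#' @param gene_group named character vector mapping gene id to its group
#'   (e.g. owning vOTU); defaults to each gene being its own group.
#' @param k seed k-mer size (default 21).
#' @return an object of class `read_index`.
#' @export
build_read_index <- function(genes, gene_group = NULL, k = 21L) {
  if (length(genes) == 0L) stop("cannot build an index over zero genes")
  if (is.null(names(genes))) stop("'genes' must be named by gene id")
  if (is.null(gene_group)) {
    gene_group <- stats::setNames(names(genes), names(genes))
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  all_kmers <- character(0); all_gene <- integer(0); all_pos <- integer(0)
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    n <- nchar(g)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    all_kmers <- c(all_kmers, substring(g, starts, starts + k - 1L))
    all_gene <- c(all_gene, rep.int(gi, length(starts)))
    all_pos <- c(all_pos, starts)
  }
  grouped <- split(seq_along(all_kmers), all_kmers)
  for (km in names(grouped)) {
    sel <- grouped[[km]]
    env[[km]] <- cbind(gene = all_gene[sel], pos = all_pos[sel])
  }
  structure(list(hash = env, genes = genes,
                 gene_chars = lapply(genes, function(g)
                   strsplit(g, "", fixed = TRUE)[[1]]),
                 gene_group = gene_group[names(genes)], k = k),
            class = "read_index")
}

#' Map a read to an indexed gene set
#'
#' Seed-and-extend placement of a read (both orientations) against the
#' index. A hit requires identity >= `min_identity` over at least
#' `min_cov` of the read. When two equal-best placements fall in
#' distinct gene groups the read is discarded as ambiguous, so that
#' multi-mapping reads are never counted twice.
#'
#' @param read nucleotide sequence of the read.
#' @param index a `read_index` from [build_read_index()].
#' @param min_identity identity threshold (default 0.95).
#' @param min_cov minimum fraction of the read aligned (default 0.9).
#' @return list with `status` ("mapped", "tie" or "unmapped") and, when
#'   mapped, `gene_id`, `group`, `identity`, `aligned_len`.
#' @export
map_read <- function(read, index, min_identity = 0.95, min_cov = 0.9) {
  stopifnot(inherits(index, "read_index"))
  check_dna(read, "read")
  k <- index$k
  if (nchar(read) < k) stop("read shorter than seed size ", k)
  cand <- list()
  for (r in c(read, revcomp(read))) {
    lf <- nchar(r)
    f_chars <- strsplit(r, "", fixed = TRUE)[[1]]
    seed_offs <- unique(c(seq.int(1L, lf - k + 1L, by = 10L), lf - k + 1L))
    hits <- list()
    for (so in seed_offs) {
      h <- index$hash[[substr(r, so, so + k - 1L)]]
      if (!is.null(h)) {
        hits[[length(hits) + 1L]] <- cbind(h[, "gene"], h[, "pos"] - so + 1L)
      }
    }
    if (!length(hits)) next
    placements <- unique(do.call(rbind, hits))
    for (i in seq_len(nrow(placements))) {
      gi <- placements[i, 1L]
      cmp <- ungapped_compare(f_chars, index$gene_chars[[gi]],
                              placements[i, 2L])
      if (cmp[2L] < min_cov * lf) next
      ident <- cmp[1L] / cmp[2L]
      if (ident >= min_identity) {
        cand[[length(cand) + 1L]] <- list(gene = gi, identity = ident,
                                          aligned_len = cmp[2L])
      }
    }
  }
  if (!length(cand)) return(list(status = "unmapped"))
  idents <- vapply(cand, `[[`, numeric(1), "identity")
  best <- which(idents >= max(idents) - 1e-12)
  groups <- unique(index$gene_group[vapply(cand[best], `[[`, integer(1),
                                           "gene")])
  if (length(groups) > 1L) return(list(status = "tie"))
  top <- cand[[best[1L]]]
  list(status = "mapped", gene_id = names(index$genes)[top$gene],
       group = unname(groups), identity = top$identity,
       aligned_len = top$aligned_len)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' Gene tables are TSV with one row per predicted gene: `contig_id`,
#' `gene_id`, `start`, `end`, `strand` and `protein_seq`, plus the
#' boolean evidence columns consumed by the discovery classifier.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_gene_table
#' @param genes data.frame of gene annotations.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
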