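# Abundance quantification: reads are mapped to the viral hallmark
# genes (VHGs) of vOTU representatives only — restricting the target
# space avoids over-counting reads from horizontally transferred genes
# — and summarized as RPKM per vOTU, aggregated to VC level.

#' Build the VHG mapping index over vOTU representatives
#'
#' Extracts the hallmark-flagged genes of every representative genome
#' and indexes them for [map_read()], keyed by owning vOTU. The summed
#' VHG length per vOTU is recorded for the RPKM denominator.
#'
#' @param reps named list: for each vOTU id, a list with `seq` (genome)
#'   and `genes` (annotation table).
#' @param k seed k-mer size (default 21).
#' @return list with `index` (a `read_index`) and `vhg_len` (named
#'   vector, bp per vOTU).
#' @export
build_vhg_index <- function(reps, k = 21L) {
  gene_seqs <- character(0)
  gene_group <- character(0)
  vhg_len <- stats::setNames(numeric(0), character(0))
  for (vid in names(reps)) {
    g <- reps[[vid]]$genes
    vhg <- g[g$viral_hallmark, , drop = FALSE]
    if (!nrow(vhg)) {
      warning("vOTU representative without hallmark genes excluded: ", vid)
      next
    }
    seqs <- substring(reps[[vid]]$seq, vhg$start, vhg$end)
    names(seqs) <- vhg$gene_id
    gene_seqs <- c(gene_seqs, seqs)
    gene_group <- c(gene_group,
                    stats::setNames(rep(vid, nrow(vhg)), vhg$gene_id))
    vhg_len[vid] <- sum(vhg$end - vhg$start + 1L)
  }
  if (!length(gene_seqs)) stop("no hallmark genes to index")
  list(index = build_read_index(gene_seqs, gene_group, k = k),
       vhg_len = vhg_len)
}

#' Quantify vOTU abundance in one sample
#'
#' Maps every read against the VHG index (>= 95% identity over >= 90%
#' of the read, ambiguous equal-best hits discarded) and reports
#' RPKM(v) = count(v) / VHG_kb(v) / (total_reads / 1e6).
#'
#' @param reads named character vector of read sequences.
#' @param vhg a list from [build_vhg_index()].
#' @param cfg a [pipeline_config()].
#' @return list with `rpkm` (named by vOTU), `counts`, `mapped_fraction`
#'   and `accounting` (mapped / tie / unmapped / total).
#' @export
quantify_sample <- function(reads, vhg, cfg = pipeline_config()) {
  total <- length(reads)
  if (total == 0L) stop("zero reads in sample")
  counts <- stats::setNames(rep(0L, length(vhg$vhg_len)),
                            names(vhg$vhg_len))
  n_tie <- 0L; n_unmapped <- 0L
  for (r in reads) {
    hit <- map_read(r, vhg$index, min_identity = cfg$map_ident)
    if (hit$status == "mapped") {
      counts[hit$group] <- counts[hit$group] + 1L
    } else if (hit$status == "tie") {
      n_tie <- n_tie + 1L
    } else {
      n_unmapped <- n_unmapped + 1L
    }
  }
  rpkm <- counts / (vhg$vhg_len / 1000) / (total / 1e6)
  list(rpkm = rpkm, counts = counts,
       mapped_fraction = sum(counts) / total,
       accounting = c(mapped = sum(counts), tie = n_tie,
                      unmapped = n_unmapped, total = total))
}

#' Aggregate a vOTU abundance matrix to VC level
#'
#' The VC value is the sum of its member vOTUs' values, per sample.
#'
#' @param votu_matrix samples x vOTU matrix.
#' @param vc_membership named character vector (vOTU id -> VC id).
#' @return samples x VC matrix.
#' @export
aggregate_to_vc <- function(votu_matrix, vc_membership) {
  orphan <- setdiff(colnames(votu_matrix), names(vc_membership))
  if (length(orphan)) {
    stop("vOTUs without a VC: ", paste(orphan, collapse = ", "))
  }
  groups <- vc_membership[colnames(votu_matrix)]
  t(rowsum(t(votu_matrix), group = groups))
}

#' Convert an abundance matrix to per-sample relative abundance
#'
#' @param matrix samples x features non-negative matrix.
#' @return matrix with rows summing to one (all-zero rows are left
#'   unchanged with a warning).
#' @export
to_relative <- function(matrix) {
  totals <- rowSums(matrix)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) left unnormalized")
    totals[zero] <- 1
  }
  matrix / totals
}

#' Detection calls and per-sample richness
#'
#' A feature counts as detected in a sample when at least one read
#' mapped (abundance > 0).
#'
#' @param matrix samples x features RPKM matrix.
#' @return list with `detected` (binary matrix) and `richness`
#'   (per-sample detected feature count).
#' @export
detect_features <- function(matrix) {
  det <- matrix > 0
  list(detected = det, richness = rowSums(det))
}
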