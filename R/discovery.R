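# Six-criterion phage discovery over annotated contigs: circular-first
# screening, linear draft recovery against complete genomes, quality
# tiering and sensitivity/false-positive evaluation.

#' Pipeline configuration
#'
#' All tunable thresholds of the discovery, catalogue, host-prediction,
#' quantification and association stages, with the published defaults.
#'
#' @param ... named overrides of any default.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_size = 10000L,        # criterion 1: minimum contig size (bp)
    kmer_p_max = 0.05,        # criterion 2: viral k-mer p-value cutoff
    provirus_min = 0.8,       # criterion 6: minimum provirus fraction
    recovery_gene_frac = 0.4, # linear recovery: gene-alignment fraction
    recovery_size_lo = 0.7,   # linear recovery: size ratio bounds
    recovery_size_hi = 1.2,
    recovery_score = 100,     # protein alignment score cutoff
    contamination_max = 0.10,
    ani_cluster = 0.95,       # vOTU clustering identity
    cov_cluster = 0.85,       # vOTU clustering coverage
    shared_pc_min = 0.20,     # VC grouping: shared protein clusters
    tax_vote_min = 0.20,      # taxonomy voting share
    lifestyle_score = 0.8,    # temperate score cutoff
    lifestyle_aln = 1000L,    # bacterial alignment length (bp)
    lifestyle_ident = 0.95,
    spacer_min = 25L, spacer_max = 100L, spacer_cov = 0.95,
    ctg_tax_ident = 0.90, ctg_tax_cov = 0.70,
    map_ident = 0.95,
    corr_votu_min = 1e-4,     # phage-host correlation inclusion
    corr_genus_min = 5e-3,
    assoc_votu_min = 5e-4,    # association-scan inclusion
    assoc_vc_min = 1e-3,
    fdr = 0.05, n_perm = 10000L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Estimate the provirus fraction of a contig
#'
#' Fraction of the contig covered by the widest host-free run of genes
#' containing viral evidence (hallmark or viral-database hit). Genes
#' flagged as bacterial markers or rRNA break runs; the run spans from
#' its first to its last viral-evidence gene, and extends to the contig
#' start (end) when the contig's first (last) gene is itself viral. A
#' contig that is entirely viral therefore scores 1; a prophage island
#' inside a host contig scores roughly its span.
#'
#' @param contig_len contig length in bp.
#' @param genes gene annotation rows for this contig.
#' @return fraction in [0, 1].
#' @export
estimate_provirus_fraction <- function(contig_len, genes) {
  if (is.null(genes) || nrow(genes) == 0L) return(0)
  genes <- genes[order(genes$start), , drop = FALSE]
  host <- genes$bacterial_marker | genes$rRNA
  viral <- genes$viral_hallmark | genes$viral_db_hit
  # split gene indices into maximal host-free runs
  runs <- split(seq_len(nrow(genes)), cumsum(host))
  best <- 0
  for (r in runs) {
    r <- r[!host[r]]
    if (!length(r) || !any(viral[r])) next
    vr <- r[viral[r]]
    lo <- if (min(vr) == 1L) 1L else min(genes$start[vr])
    hi <- if (max(vr) == nrow(genes)) contig_len else max(genes$end[vr])
    best <- max(best, (hi - lo + 1L) / contig_len)
  }
  min(best, 1)
}

#' Apply the six phage-discovery criteria to one contig
#'
#' Criteria, in order: (1) size >= 10 kb; (2) viral k-mer p-value
#' <= 0.05; (3) at least one viral hallmark gene and no plasmid hallmark
#' gene; (4) no bacterial single-copy marker gene and no rRNA gene;
#' (5) not more genes hitting the plasmid database than the viral
#' database (ties kept); (6) provirus fraction >= 0.8. The verdict is
#' "phage" iff all six pass; `rejected_at` reports the first failure
#' while all six are still evaluated for reporting.
#'
#' @param contig_len contig length in bp.
#' @param genes gene annotation rows for this contig.
#' @param kmer_p viral k-mer p-value for this contig.
#' @param cfg a [pipeline_config()].
#' @param provirus_fraction optional externally supplied provirus
#'   fraction; computed by [estimate_provirus_fraction()] when NULL.
#' @param contig_id id used in error messages.
#' @return list (class `criteria_report`) with the six pass flags,
#'   `kmer_p`, `provirus_fraction`, `verdict` and `rejected_at`.
#' @export
classify_contig <- function(contig_len, genes, kmer_p,
                            cfg = pipeline_config(),
                            provirus_fraction = NULL,
                            contig_id = "contig") {
  if (is.null(genes)) stop("missing gene annotations for ", contig_id)
  if (is.null(kmer_p) || is.na(kmer_p)) {
    stop("missing k-mer p-value for ", contig_id)
  }
  if (is.null(provirus_fraction)) {
    provirus_fraction <- estimate_provirus_fraction(contig_len, genes)
  }
  pass <- c(
    size = contig_len >= cfg$min_size,
    kmer = kmer_p <= cfg$kmer_p_max,
    hallmark = sum(genes$viral_hallmark) >= 1L &&
      sum(genes$plasmid_hallmark) == 0L,
    marker = sum(genes$bacterial_marker) == 0L && sum(genes$rRNA) == 0L,
    dbcount = !(sum(genes$plasmid_db_hit) > sum(genes$viral_db_hit)),
    provirus = provirus_fraction >= cfg$provirus_min)
  rejected_at <- if (all(pass)) NA_integer_ else unname(which(!pass)[1L])
  structure(list(
    contig_id = contig_id,
    size_pass = pass[["size"]], kmer_pass = pass[["kmer"]],
    hallmark_pass = pass[["hallmark"]], marker_pass = pass[["marker"]],
    dbcount_pass = pass[["dbcount"]], provirus_pass = pass[["provirus"]],
    kmer_p = kmer_p, provirus_fraction = provirus_fraction,
    verdict = if (all(pass)) "phage" else "rejected",
    rejected_at = rejected_at), class = "criteria_report")
}

# Gene annotations for one contig from the community-wide table.
contig_genes <- function(genes, contig_id) {
  genes[genes$contig_id == contig_id, , drop = FALSE]
}

#' Screen circular contigs for complete phage genomes
#'
#' Contigs at least 10 kb long are checked for terminal redundancy; the
#' circular ones that pass all six criteria become complete phage calls
#' with the redundant terminal copy trimmed.
#'
#' @param community a `phage_community` (or any list with `contigs`,
#'   `genes`, `kmer_p` of the same shape).
#' @param cfg a [pipeline_config()].
#' @return list with `calls` (data.frame contig_id/circular/
#'   completeness/contamination/tier/trimmed_length), `genomes`
#'   (named vector of trimmed sequences) and `reports`.
#' @export
screen_circular <- function(community, cfg = pipeline_config()) {
  contigs <- community$contigs
  calls <- list(); genomes <- character(0); reports <- list()
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    len <- contigs$length[i]
    if (len < cfg$min_size) next
    circ <- detect_terminal_redundancy(contigs$seq[i])
    if (!circ$is_circular) next
    rep_i <- classify_contig(len, contig_genes(community$genes, cid),
                             community$kmer_p[[cid]], cfg,
                             contig_id = cid)
    reports[[cid]] <- rep_i
    if (rep_i$verdict != "phage") next
    calls[[cid]] <- data.frame(
      contig_id = cid, circular = TRUE, completeness = 1,
      contamination = 0, tier = "complete",
      matched_complete_ref = NA_character_,
      trimmed_length = circ$trimmed_length, stringsAsFactors = FALSE)
    genomes[cid] <- substr(contigs$seq[i], 1L, circ$trimmed_length)
  }
  list(calls = if (length(calls)) do.call(rbind, c(calls,
         make.row.names = FALSE)) else NULL,
       genomes = genomes, reports = reports)
}

# Amino-acid k-mer index over a protein set, used to prescreen
# candidate homolog pairs before running the quadratic alignment.
protein_kmer_index <- function(prots, k = 6L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(prots)) {
    p <- prots[[j]]
    if (nchar(p) < k) next
    st <- seq_len(nchar(p) - k + 1L)
    for (km in unique(substring(p, st, st + k - 1L))) {
      env[[km]] <- c(env[[km]], j)
    }
  }
  env
}

# Does a linear contig look like a fragment of the given complete
# genome? Fraction of its genes with a protein alignment above the
# score cutoff, prescreened by shared amino-acid 6-mers.
gene_alignment_fraction <- function(cand_prots, ref_prots, score_min,
                                    k = 6L, ref_kmers = NULL) {
  if (is.null(ref_kmers)) ref_kmers <- protein_kmer_index(ref_prots, k)
  aligned <- 0L
  for (p in cand_prots) {
    if (nchar(p) < k) next
    st <- seq_len(nchar(p) - k + 1L)
    cand_idx <- unique(unlist(lapply(
      unique(substring(p, st, st + k - 1L)),
      function(km) ref_kmers[[km]])))
    hit <- FALSE
    for (j in cand_idx) {
      if (align_protein(p, ref_prots[[j]])$score >= score_min) {
        hit <- TRUE; break
      }
    }
    if (hit) aligned <- aligned + 1L
  }
  aligned / length(cand_prots)
}

#' Recover draft phage genomes among linear contigs
#'
#' A linear contig becomes a candidate if, against some complete
#' genome, more than 40% of its genes align at the protein level and
#' its size is more than 70% and at most 120% of that genome. The six
#' criteria are then applied; completeness is the length ratio to the
#' matched complete genome, and tiers follow the conventional bounds
#' (complete-quality circular genomes are handled by
#' [screen_circular()]): high >= 0.9, medium 0.5-0.9, low < 0.5.
#' Low-quality calls and calls with contamination above 10% are
#' excluded.
#'
#' @param community a `phage_community`.
#' @param completes result of [screen_circular()] (or a compatible list
#'   with `genomes` and per-genome gene tables in the community).
#' @param cfg a [pipeline_config()].
#' @param external optional external complete-genome reference set (a
#'   database of known complete phage genomes): list with `genomes`
#'   (named character vector) and `proteins` (named list of protein
#'   vectors).
#' @return list with `calls` (data.frame) and `genomes`.
#' @export
recover_linear <- function(community, completes,
                           cfg = pipeline_config(), external = NULL) {
  contigs <- community$contigs
  complete_ids <- names(completes$genomes)
  ref_prots <- lapply(complete_ids, function(id)
    contig_genes(community$genes, id)$protein_seq)
  ref_len <- nchar(completes$genomes)
  if (!is.null(external)) {
    complete_ids <- c(complete_ids, names(external$genomes))
    ref_prots <- c(ref_prots, external$proteins[names(external$genomes)])
    ref_len <- c(ref_len, nchar(external$genomes))
  }
  if (!length(complete_ids)) {
    return(list(calls = NULL, genomes = character(0)))
  }
  ref_idx <- lapply(ref_prots, protein_kmer_index)
  calls <- list(); genomes <- character(0)
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    if (cid %in% complete_ids) next
    len <- contigs$length[i]
    genes <- contig_genes(community$genes, cid)
    if (!nrow(genes)) next
    matched <- NA_character_
    for (j in seq_along(complete_ids)) {
      ratio <- len / ref_len[j]
      if (ratio <= cfg$recovery_size_lo || ratio > cfg$recovery_size_hi) next
      frac <- gene_alignment_fraction(genes$protein_seq, ref_prots[[j]],
                                      cfg$recovery_score,
                                      ref_kmers = ref_idx[[j]])
      if (frac > cfg$recovery_gene_frac) { matched <- complete_ids[j]; break }
    }
    if (is.na(matched)) next
    rep_i <- classify_contig(len, genes, community$kmer_p[[cid]], cfg,
                             contig_id = cid)
    if (rep_i$verdict != "phage") next
    completeness <- min(len / ref_len[[matched]], 1)
    provirus_run <- rep_i$provirus_fraction
    host_flag <- genes$bacterial_marker | genes$rRNA
    contamination <- if (nrow(genes)) mean(host_flag) else 0
    tier <- if (completeness >= 0.9) "high" else
      if (completeness >= 0.5) "medium" else "low"
    if (tier == "low" || contamination > cfg$contamination_max) next
    calls[[cid]] <- data.frame(
      contig_id = cid, circular = FALSE, completeness = completeness,
      contamination = contamination, tier = tier,
      matched_complete_ref = matched, trimmed_length = len,
      stringsAsFactors = FALSE)
    genomes[cid] <- contigs$seq[i]
  }
  list(calls = if (length(calls)) do.call(rbind, c(calls,
         make.row.names = FALSE)) else NULL,
       genomes = genomes)
}

#' Run the full discovery stage on a community
#'
#' Circular-first screening followed by linear recovery against the
#' complete genomes found in the same community plus, when available,
#' an external complete-genome reference database (the community
#' generator provides one under `$references`).
#'
#' @inheritParams screen_circular
#' @param external external reference set passed to [recover_linear()];
#'   defaults to `community$references`.
#' @return list with `calls` (combined data.frame), `genomes` and
#'   `reports`.
#' @export
discover_phages <- function(community, cfg = pipeline_config(),
                            external = community$references) {
  circ <- screen_circular(community, cfg)
  lin <- recover_linear(community, circ, cfg, external = external)
  calls <- rbind(circ$calls, lin$calls)
  list(calls = calls, genomes = c(circ$genomes, lin$genomes),
       reports = circ$reports)
}

#' Evaluate discovery calls against planted truth
#'
#' @param calls data.frame of phage calls (column `contig_id`).
#' @param truth_labels named character vector labelling every input
#'   contig as "phage", "plasmid" or "bacterial".
#' @return list with `tpr` (true phages called / true phages) and
#'   `fpr` (non-phages called / non-phages).
#' @export
evaluate_pipeline <- function(calls, truth_labels) {
  if (!length(truth_labels)) stop("empty truth labels")
  called <- if (is.null(calls)) character(0) else calls$contig_id
  is_phage <- truth_labels == "phage"
  tp <- sum(names(truth_labels)[is_phage] %in% called)
  fp <- sum(names(truth_labels)[!is_phage] %in% called)
  list(tpr = tp / sum(is_phage), fpr = fp / sum(!is_phage))
}
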