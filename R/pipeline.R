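# End-to-end orchestration over a synthetic community: discovery,
# catalogue construction, host prediction and single-sample
# quantification, with deterministic TSV/JSON outputs.

#' Build the vOTU/VC catalogue from discovery output
#'
#' Clusters the discovered genomes into vOTUs (greedy ANI), clusters
#' the representatives' proteins (alignment graph + MCL) and groups
#' vOTUs into viral clusters by shared protein clusters; votes a
#' family-level taxonomy and calls a lifestyle per vOTU
#' representative.
#'
#' @param discovery result of [discover_phages()].
#' @param community the `phage_community` the genomes came from.
#' @param cfg a [pipeline_config()].
#' @return list with `votus`, `vc` (membership + shared matrix),
#'   `protein_clusters`, `taxonomy`, `lifestyle`, `representatives`.
#' @export
build_catalogue <- function(discovery, community,
                            cfg = pipeline_config()) {
  tiers <- stats::setNames(discovery$calls$tier,
                           discovery$calls$contig_id)
  votus <- cluster_votus(discovery$genomes, tiers, cfg)
  reps <- unique(votus$representative)
  rep_votu <- stats::setNames(
    votus$votu_id[match(reps, votus$member)], reps)
  prots <- character(0)
  prot_votu <- character(0)
  for (r in reps) {
    g <- contig_genes(community$genes, r)
    ps <- stats::setNames(g$protein_seq, g$gene_id)
    prots <- c(prots, ps)
    prot_votu <- c(prot_votu,
                   stats::setNames(rep(rep_votu[[r]], nrow(g)), g$gene_id))
  }
  pcs <- cluster_proteins(prots, score_min = cfg$recovery_score)
  pc_of <- stats::setNames(pcs$pc_id, pcs$protein_id)
  votu_pcs <- lapply(split(names(prot_votu), prot_votu), function(gids)
    unique(unname(pc_of[gids])))
  vc <- build_vcs(votu_pcs, cfg)
  taxonomy <- vapply(reps, function(r)
    assign_taxonomy(contig_genes(community$genes, r)$besthit_family,
                    cfg), character(1))
  lifestyle <- vapply(reps, function(r)
    classify_lifestyle(
      temperate_score_from_genes(contig_genes(community$genes, r)),
      cfg = cfg), character(1))
  list(votus = votus, vc = vc, protein_clusters = pcs,
       taxonomy = data.frame(votu_id = unname(rep_votu),
                             representative = reps,
                             family = unname(taxonomy),
                             lifestyle = unname(lifestyle),
                             stringsAsFactors = FALSE),
       representatives = rep_votu)
}

#' Run the sequence-level pipeline on a synthetic community
#'
#' Generates a community from the seed, discovers phages, builds the
#' catalogue, predicts hosts and quantifies one read sample; when
#' `outdir` is given, writes `calls.tsv`, `votus.tsv`, `vcs.tsv`,
#' `hosts.tsv`, `abundance.tsv` and `manifest.json` (byte-identical
#' across reruns with the same seed).
#'
#' @param seed integer seed controlling every random choice.
#' @param outdir optional output directory.
#' @param flip_noise annotation noise rate (default 0.02).
#' @param depth_per_votu reads per genome for quantification.
#' @param community_args named list of extra arguments for
#'   [generate_community()] (e.g. smaller community sizes).
#' @param cfg a [pipeline_config()].
#' @return list with `community`, `discovery`, `evaluation`,
#'   `catalogue`, `hosts`, `quantification`.
#' @export
run_pipeline <- function(seed, outdir = NULL, flip_noise = 0.02,
                         depth_per_votu = 200L, community_args = list(),
                         cfg = pipeline_config()) {
  community <- do.call(generate_community,
                       c(list(flip_noise = flip_noise, rng_seed = seed),
                         community_args))
  discovery <- discover_phages(community, cfg)
  evaluation <- evaluate_pipeline(discovery$calls,
                                  community$truth$labels)
  catalogue <- build_catalogue(discovery, community, cfg)
  reps <- names(catalogue$representatives)
  rep_genomes <- discovery$genomes[reps]
  bact <- community$contigs[
    community$contigs$contig_id %in%
      community$truth$bacteria$contig_id, , drop = FALSE]
  genus_of <- stats::setNames(community$truth$bacteria$genus,
                              community$truth$bacteria$contig_id)
  hosts <- predict_hosts(rep_genomes, bact, genus_of, cfg)

  set.seed(seed + 1L)
  rep_entities <- lapply(reps, function(r) {
    list(id = r, seq = rep_genomes[[r]],
         genes = contig_genes(community$genes, r))
  })
  names(rep_entities) <- reps
  rd <- generate_reads(rep_entities, depth_per_votu)
  vhg <- build_vhg_index(rep_entities)
  quant <- quantify_sample(rd$reads, vhg, cfg)

  out <- list(community = community, discovery = discovery,
              evaluation = evaluation, catalogue = catalogue,
              hosts = hosts,
              quantification = c(quant, list(truth = rd$truth)))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.table(
      df, file.path(outdir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    w(discovery$calls, "calls.tsv")
    w(catalogue$votus, "votus.tsv")
    w(catalogue$vc$membership, "vcs.tsv")
    w(hosts$assignments, "hosts.tsv")
    w(data.frame(votu_id = names(quant$rpkm), rpkm = quant$rpkm,
                 count = quant$counts, row.names = NULL), "abundance.tsv")
    jsonlite::write_json(
      list(seed = seed, flip_noise = flip_noise,
           depth_per_votu = depth_per_votu,
           tpr = evaluation$tpr, fpr = evaluation$fpr,
           n_votus = length(unique(catalogue$votus$votu_id)),
           n_vcs = length(unique(catalogue$vc$membership$vc_id))),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(out)
}
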