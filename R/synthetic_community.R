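# Synthetic communities with planted ground truth: phage genomes
# (circular or linear drafts), plasmids, bacterial contigs carrying
# marker genes, prophages and CRISPR arrays, plus cohort-level abundance
# and metadata tables. Every generator is a pure function of its seed.

GUT_GENERA <- c("Bacteroides", "Prevotella", "Faecalibacterium",
                "Roseburia", "Bifidobacterium", "Alistipes",
                "Ruminococcus", "Blautia", "Eubacterium", "Akkermansia")

PHAGE_FAMILIES <- c("Siphoviridae", "Myoviridae", "Podoviridae",
                    "Herelleviridae", "crAss-like")

#' Genera excluded from host assignment
#'
#' Non-intestinal genera whose CRISPR matches are treated as spurious
#' and removed before host labelling.
#' @export
EXCLUDED_HOST_GENERA <- c(
  "Dickeya", "Anaerobutyricum", "Rubellimicrobium", "Eisenbergiella",
  "Harryflintia", "Leucothrix", "Photorhabdus", "Spirosoma",
  "Syntrophobotulus", "Thermincola", "Algoriphagus", "Franconibacter",
  "Kandleria", "Lawsonibacter", "Methylomonas", "Provencibacterium",
  "Pseudoruminoccoccus", "Rhodanobacter", "Romboutsia", "Sharpea",
  "Varibaculum", "Thioalkalivibrio")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit(AA_ALPHABET20, "")[[1]], n, replace = TRUE),
        collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  aa <- strsplit(AA_ALPHABET20, "")[[1]]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) chars[i] <- sample(setdiff(aa, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Empty gene-annotation table with the full evidence schema.
empty_gene_table <- function() {
  data.frame(contig_id = character(), gene_id = character(),
             start = integer(), end = integer(), strand = character(),
             protein_seq = character(), viral_hallmark = logical(),
             plasmid_hallmark = logical(), bacterial_marker = logical(),
             rRNA = logical(), viral_db_hit = logical(),
             plasmid_db_hit = logical(), temperate_marker = logical(),
             besthit_family = character(), stringsAsFactors = FALSE)
}

# Sequentially lay non-overlapping genes on a backbone of `len` bp.
layout_genes <- function(len, contig_id, min_gene = 600L, max_gene = 1500L) {
  pos <- 1L + sample(30:80, 1L)
  rows <- list()
  i <- 0L
  while (pos + min_gene + 50L <= len) {
    w <- sample(seq.int(min_gene, max_gene, by = 3L), 1L)
    if (pos + w - 1L > len - 30L) w <- ((len - 30L - pos) %/% 3L) * 3L
    if (w < min_gene) break
    i <- i + 1L
    rows[[i]] <- data.frame(
      contig_id = contig_id, gene_id = sprintf("%s_g%03d", contig_id, i),
      start = pos, end = pos + w - 1L,
      strand = sample(c("+", "-"), 1L),
      protein_seq = random_protein(w %/% 3L),
      viral_hallmark = FALSE, plasmid_hallmark = FALSE,
      bacterial_marker = FALSE, rRNA = FALSE, viral_db_hit = FALSE,
      plasmid_db_hit = FALSE, temperate_marker = FALSE,
      besthit_family = NA_character_, stringsAsFactors = FALSE)
    pos <- pos + w + sample(30:120, 1L)
  }
  if (!length(rows)) stop("gene layout does not fit contig length ", len)
  do.call(rbind, rows)
}

#' Generate a phage genome with annotated genes
#'
#' Produces a random genome carrying `n_hallmarks` genes flagged as
#' viral hallmark genes (terminase/capsid/portal analogues), optional
#' integrase (temperate marker) and, for circular genomes, a 150-300 bp
#' terminal repeat appended so that the circularity detector fires.
#'
#' @param length genome length in bp before the terminal repeat.
#' @param n_hallmarks number of viral hallmark genes to plant.
#' @param temperate plant one integrase-flagged gene?
#' @param circular append a terminal repeat?
#' @param rng_seed optional seed; when NULL the current RNG stream is
#'   used (so an orchestrating generator stays a pure function of its
#'   own seed).
#' @param id contig id.
#' @param genus planted host genus (truth only).
#' @param family planted viral family used for best-hit labels.
#' @return list with `id`, `seq`, `body_length`, `circular`,
#'   `repeat_len`, `temperate`, `genus`, `family` and `genes`
#'   (annotation data.frame).
#' @export
generate_phage_genome <- function(length, n_hallmarks, temperate = FALSE,
                                  circular = FALSE, rng_seed = NULL,
                                  id = "phage_1", genus = NA_character_,
                                  family = NA_character_) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- layout_genes(length, id)
  n <- nrow(genes)
  if (n < n_hallmarks + as.integer(temperate)) {
    stop("gene layout does not fit: ", n, " genes for ", n_hallmarks,
         " hallmarks")
  }
  # hallmarks sit in the front 60% of the genome so that truncated
  # drafts (>= 70% length) retain them
  eligible <- which(genes$end <= 0.6 * length)
  if (length(eligible) < n_hallmarks) eligible <- seq_len(n)
  if (n_hallmarks > 0L) {
    hall <- sample(eligible, n_hallmarks)
    genes$viral_hallmark[hall] <- TRUE
  }
  genes$viral_db_hit <- genes$viral_hallmark |
    stats::runif(n) < 0.7
  genes$plasmid_db_hit <- stats::runif(n) < 0.03
  if (!is.na(family)) {
    lab <- genes$viral_db_hit & stats::runif(n) < 0.8
    genes$besthit_family[lab] <- family
  }
  if (temperate) {
    genes$temperate_marker[sample(n, 1L)] <- TRUE
  }
  body <- random_dna(length)
  repeat_len <- 0L
  seq <- body
  if (circular) {
    repeat_len <- sample(150:300, 1L)
    seq <- paste0(body, substr(body, 1L, repeat_len))
  }
  list(id = id, seq = seq, body_length = length, circular = circular,
       repeat_len = repeat_len, temperate = temperate, genus = genus,
       family = family, genes = genes)
}

#' Derive a diverged (optionally truncated) draft from a phage genome
#'
#' Substitutes nucleotides and amino acids i.i.d. at the given rates and
#' keeps the leading `keep_frac` of the parent body (genes falling off
#' the end are dropped). The result is linear.
#'
#' @param phage output of [generate_phage_genome()].
#' @param nuc_rate,aa_rate substitution rates.
#' @param keep_frac fraction of the parent body retained.
#' @param id new contig id.
#' @return a phage-genome list (see [generate_phage_genome()]).
#' @export
mutate_phage_variant <- function(phage, nuc_rate = 0.01, aa_rate = 0.01,
                                 keep_frac = 1, id = paste0(phage$id, "_v")) {
  body <- substr(phage$seq, 1L, phage$body_length)
  new_len <- floor(phage$body_length * keep_frac)
  body <- mutate_dna(substr(body, 1L, new_len), nuc_rate)
  genes <- phage$genes[phage$genes$end <= new_len, , drop = FALSE]
  if (!nrow(genes)) stop("truncation removed all genes of ", phage$id)
  genes$contig_id <- id
  genes$gene_id <- sprintf("%s_g%03d", id, seq_len(nrow(genes)))
  genes$protein_seq <- vapply(genes$protein_seq, mutate_protein,
                              character(1), rate = aa_rate,
                              USE.NAMES = FALSE)
  out <- phage
  out$id <- id
  out$seq <- body
  out$body_length <- new_len
  out$circular <- FALSE
  out$repeat_len <- 0L
  out$genes <- genes
  out$parent <- phage$id
  out
}

#' Generate a plasmid genome (negative control)
#'
#' Carries plasmid hallmark genes and more plasmid-database hits than
#' viral-database hits, so that the discovery classifier rejects it at
#' the hallmark or database-comparison criterion.
#'
#' @inheritParams generate_phage_genome
#' @return a genome list mirroring [generate_phage_genome()].
#' @export
generate_plasmid <- function(length, rng_seed = NULL, id = "plasmid_1") {
  if (length < 10000L) stop("plasmid length must be >= 10000 bp")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- layout_genes(length, id)
  n <- nrow(genes)
  genes$plasmid_hallmark[sample(n, min(2L, n))] <- TRUE
  genes$plasmid_db_hit <- genes$plasmid_hallmark | stats::runif(n) < 0.6
  genes$viral_db_hit <- stats::runif(n) < 0.1
  # guarantee the planted inequality: plasmid hits strictly exceed viral
  if (sum(genes$plasmid_db_hit) <= sum(genes$viral_db_hit)) {
    genes$viral_db_hit[sample(which(genes$viral_db_hit),
                              sum(genes$viral_db_hit) -
                                sum(genes$plasmid_db_hit) + 1L)] <- FALSE
  }
  list(id = id, seq = random_dna(length), body_length = length,
       circular = FALSE, repeat_len = 0L, temperate = FALSE,
       genus = NA_character_, family = NA_character_, genes = genes)
}

# Build the CRISPR array string: copies of one repeat interleaved with
# spacers lifted (with at most one substitution) from target phages.
build_crispr_array <- function(target_phages, n_copies = NULL) {
  if (!length(target_phages)) stop("CRISPR array needs target phages")
  if (is.null(n_copies)) n_copies <- sample(4:8, 1L)
  repeat_seq <- random_dna(30L)
  spacers <- list()
  parts <- repeat_seq
  for (i in seq_len(n_copies - 1L)) {
    ph <- target_phages[[sample(length(target_phages), 1L)]]
    w <- sample(30:40, 1L)
    s0 <- sample(ph$body_length - w, 1L)
    spacer <- substr(ph$seq, s0, s0 + w - 1L)
    edited <- spacer
    if (stats::runif(1) < 0.5) edited <- mutate_dna_exactly_one(spacer)
    spacers[[i]] <- data.frame(spacer_seq = edited, source_phage = ph$id,
                               source_pos = s0, stringsAsFactors = FALSE)
    parts <- paste0(parts, edited, repeat_seq)
  }
  list(seq = parts, repeat_seq = repeat_seq,
       spacers = do.call(rbind, spacers), n_copies = n_copies)
}

mutate_dna_exactly_one <- function(seq) {
  i <- sample(nchar(seq), 1L)
  ch <- substr(seq, i, i)
  substr(seq, i, i) <- sample(setdiff(c("A", "C", "G", "T"), ch), 1L)
  seq
}

#' Generate a bacterial contig with markers, rRNA, optional CRISPR
#' array and optional embedded prophage
#'
#' @param length approximate host-backbone length in bp (prophage and
#'   array sequence are inserted on top).
#' @param genus genus label (ground truth for host prediction).
#' @param with_crispr plant a CRISPR array targeting `target_phages`?
#' @param target_phages list of phage-genome lists the array spacers are
#'   lifted from.
#' @param prophage optional phage-genome list inserted verbatim (its
#'   linear body) with host genes flanking.
#' @param rng_seed optional seed.
#' @param id contig id.
#' @return list with `id`, `seq`, `genus`, `genes`, `array` (truth, or
#'   NULL), `prophage_interval` (truth, or NULL).
#' @export
generate_bacterial_contig <- function(length, genus, with_crispr = FALSE,
                                      target_phages = list(),
                                      prophage = NULL, rng_seed = NULL,
                                      id = "bact_1") {
  if (with_crispr && !length(target_phages)) {
    stop("with_crispr requires non-empty target_phages")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (!is.null(prophage) && prophage$body_length >= length) {
    stop("prophage longer than host contig")
  }
  backbone <- random_dna(length)
  genes <- layout_genes(length, id)
  n <- nrow(genes)
  genes$bacterial_marker[sample(n, min(2L, n))] <- TRUE
  non_marker <- which(!genes$bacterial_marker)
  genes$rRNA[non_marker[sample(length(non_marker), 1L)]] <- TRUE
  genes$viral_db_hit <- stats::runif(n) < 0.02

  seq <- backbone
  prophage_interval <- NULL
  if (!is.null(prophage)) {
    body <- substr(prophage$seq, 1L, prophage$body_length)
    # insert between host genes near the middle of the backbone
    mid <- length %/% 2L
    after <- genes$end[which.min(abs(genes$end - mid))] + 5L
    seq <- paste0(substr(seq, 1L, after), body,
                  substr(seq, after + 1L, nchar(seq)))
    shift <- nchar(body)
    moved <- genes$start > after
    genes$start[moved] <- genes$start[moved] + shift
    genes$end[moved] <- genes$end[moved] + shift
    pg <- prophage$genes
    pg$contig_id <- id
    pg$gene_id <- sprintf("%s_pro%03d", id, seq_len(nrow(pg)))
    pg$start <- pg$start + after
    pg$end <- pg$end + after
    genes <- rbind(genes, pg)
    genes <- genes[order(genes$start), , drop = FALSE]
    prophage_interval <- data.frame(contig_id = id, phage_id = prophage$id,
                                    start = after + 1L,
                                    end = after + shift,
                                    stringsAsFactors = FALSE)
  }
  array_truth <- NULL
  if (with_crispr) {
    arr <- build_crispr_array(target_phages)
    arr_start <- nchar(seq) + 51L
    seq <- paste0(seq, random_dna(50L), arr$seq, random_dna(50L))
    sp <- arr$spacers
    rownames(sp) <- NULL
    sp$contig_id <- id
    sp$genus <- genus
    array_truth <- list(contig_id = id, genus = genus,
                        repeat_seq = arr$repeat_seq, start = arr_start,
                        spacers = sp)
  }
  list(id = id, seq = seq, genus = genus, genes = genes,
       array = array_truth, prophage_interval = prophage_interval)
}

# Perturb annotation evidence: with probability `rate` a contig's
# annotation is corrupted by flipping one uniformly chosen gene's flag
# in one uniformly chosen evidence channel; independently, with
# probability `rate`, its k-mer p-value is redrawn from the opposite
# class. Emulates occasional misclassification by individual upstream
# annotation tools without destroying whole evidence channels.
apply_flip_noise <- function(genes, kmer_p, rate) {
  if (rate <= 0) return(list(genes = genes, kmer_p = kmer_p))
  flags <- c("viral_hallmark", "plasmid_hallmark", "bacterial_marker",
             "rRNA", "viral_db_hit", "plasmid_db_hit", "temperate_marker")
  for (cid in unique(genes$contig_id)) {
    rows <- which(genes$contig_id == cid)
    if (stats::runif(1) < rate) {
      fl <- sample(flags, 1L)
      i <- rows[sample(length(rows), 1L)]
      genes[i, fl] <- !genes[i, fl]
    }
  }
  for (cid in names(kmer_p)) {
    if (stats::runif(1) < rate) {
      kmer_p[cid] <- if (kmer_p[cid] <= 0.05) stats::runif(1, 0.05, 1)
        else stats::runif(1, 0, 0.05)
    }
  }
  list(genes = genes, kmer_p = kmer_p)
}

#' Generate the default benchmark community
#'
#' Plants circular complete phages, linear phage drafts derived from
#' them, plasmids and bacterial contigs (some carrying prophages, some
#' CRISPR arrays targeting the planted phages), then assigns viral
#' k-mer p-values (phages ~ U(0, 0.05), others ~ U(0.05, 1)) and
#' applies annotation flip-noise.
#'
#' @param n_phage_species circular complete phage genomes (default 10).
#' @param n_linear linear drafts derived from the species (default 20).
#' @param n_plasmids plasmid contigs (default 20).
#' @param n_bacteria bacterial contigs (default 30).
#' @param n_prophage prophage-carrying bacterial contigs (default 5).
#' @param n_crispr CRISPR-carrying bacterial contigs (default 10).
#' @param flip_noise annotation perturbation rate (default 0.02).
#' @param rng_seed seed (default 42).
#' @return object of class `phage_community`: list with `contigs`
#'   (data.frame contig_id/seq/length), `genes`, `kmer_p`, `phages`
#'   (genome lists by id) and `truth`.
#' @export
generate_community <- function(n_phage_species = 10L, n_linear = 20L,
                               n_plasmids = 20L, n_bacteria = 30L,
                               n_prophage = 5L, n_crispr = 10L,
                               flip_noise = 0.02, rng_seed = 42L) {
  set.seed(rng_seed)
  species <- list()
  for (i in seq_len(n_phage_species)) {
    species[[i]] <- generate_phage_genome(
      length = sample(20000:40000, 1L), n_hallmarks = sample(2:4, 1L),
      temperate = stats::runif(1) < 0.4, circular = TRUE,
      id = sprintf("phage_sp%02d", i),
      genus = GUT_GENERA[(i - 1L) %% length(GUT_GENERA) + 1L],
      family = sample(PHAGE_FAMILIES, 1L))
  }
  names(species) <- vapply(species, `[[`, character(1), "id")
  drafts <- list()
  for (i in seq_len(n_linear)) {
    parent <- species[[sample(n_phage_species, 1L)]]
    drafts[[i]] <- mutate_phage_variant(
      parent, nuc_rate = 0.01, aa_rate = 0.01,
      keep_frac = stats::runif(1, 0.75, 1.0),
      id = sprintf("phage_dr%02d", i))
  }
  plasmids <- lapply(seq_len(n_plasmids), function(i)
    generate_plasmid(sample(12000:25000, 1L),
                     id = sprintf("plasmid_%02d", i)))
  bacts <- list()
  host_genus <- vapply(species, `[[`, character(1), "genus")
  for (i in seq_len(n_bacteria)) {
    pro <- NULL
    if (i <= n_prophage) pro <- species[[sample(n_phage_species, 1L)]]
    crispr <- i > n_prophage && i <= n_prophage + n_crispr
    if (crispr) {
      sp_idx <- (i - n_prophage - 1L) %% n_phage_species + 1L
      genus <- host_genus[sp_idx]
      targets <- species[host_genus == genus]
    } else {
      genus <- sample(GUT_GENERA, 1L)
      targets <- list()
    }
    bacts[[i]] <- generate_bacterial_contig(
      length = sample(40000:80000, 1L), genus = genus,
      with_crispr = crispr, target_phages = targets, prophage = pro,
      id = sprintf("bact_%02d", i))
  }
  all_entities <- c(species, drafts, plasmids, bacts)
  contigs <- data.frame(
    contig_id = vapply(all_entities, `[[`, character(1), "id"),
    seq = vapply(all_entities, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE)
  contigs$length <- nchar(contigs$seq)
  genes <- do.call(rbind, lapply(all_entities, `[[`, "genes"))
  rownames(genes) <- NULL
  is_phage <- contigs$contig_id %in% c(names(species),
                                       vapply(drafts, `[[`, character(1),
                                              "id"))
  kmer_p <- stats::setNames(
    ifelse(is_phage, stats::runif(nrow(contigs), 0, 0.05),
           stats::runif(nrow(contigs), 0.05, 1)),
    contigs$contig_id)
  noised <- apply_flip_noise(genes, kmer_p, flip_noise)

  crispr_truth <- do.call(rbind, lapply(bacts, function(b)
    if (!is.null(b$array)) b$array$spacers else NULL))
  prophage_truth <- do.call(rbind, lapply(bacts, function(b)
    b$prophage_interval))
  phage_truth <- data.frame(
    contig_id = c(names(species), vapply(drafts, `[[`, character(1), "id")),
    species = c(names(species), vapply(drafts, `[[`, character(1),
                                       "parent")),
    circular = c(rep(TRUE, n_phage_species), rep(FALSE, n_linear)),
    temperate = c(vapply(species, `[[`, logical(1), "temperate"),
                  vapply(drafts, `[[`, logical(1), "temperate")),
    host_genus = unname(c(host_genus,
                          host_genus[vapply(drafts, `[[`, character(1),
                                            "parent")])),
    family = c(vapply(species, `[[`, character(1), "family"),
               vapply(drafts, `[[`, character(1), "family")),
    stringsAsFactors = FALSE)
  labels <- stats::setNames(
    c(rep("phage", n_phage_species + n_linear),
      rep("plasmid", n_plasmids), rep("bacterial", n_bacteria)),
    contigs$contig_id)
  # which phage species are actually targeted by a planted array
  targeted <- unique(crispr_truth$source_phage)
  # stand-in for a public database of known complete phage genomes:
  # the untrimmed species bodies and their proteomes, used by the
  # linear-recovery arm alongside the pipeline's own completes
  references <- list(
    genomes = stats::setNames(
      vapply(species, function(s) substr(s$seq, 1L, s$body_length),
             character(1)),
      paste0("ref_", names(species))),
    proteins = stats::setNames(
      lapply(species, function(s) s$genes$protein_seq),
      paste0("ref_", names(species))))
  structure(list(
    contigs = contigs, genes = noised$genes, kmer_p = noised$kmer_p,
    references = references,
    phages = c(species, stats::setNames(
      drafts, vapply(drafts, `[[`, character(1), "id"))),
    truth = list(phages = phage_truth, labels = labels,
                 crispr = crispr_truth, prophages = prophage_truth,
                 targeted_species = targeted,
                 host_genus = host_genus,
                 bacteria = data.frame(
                   contig_id = vapply(bacts, `[[`, character(1), "id"),
                   genus = vapply(bacts, `[[`, character(1), "genus"),
                   stringsAsFactors = FALSE))),
    class = "phage_community")
}

#' Generate shotgun reads from phage genomes
#'
#' Uniform-position reads with i.i.d. substitution errors, drawn from
#' both strands. The truth table records, per genome, the total reads
#' emitted and how many originate fully inside a viral hallmark gene.
#'
#' @param phages list of phage-genome lists (with `genes`).
#' @param depth_per_votu reads emitted per genome (scalar or vector).
#' @param read_len read length (default 150).
#' @param error_rate substitution rate (default 0.005).
#' @param rng_seed optional seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame phage_id/total_reads/vhg_reads).
#' @export
generate_reads <- function(phages, depth_per_votu, read_len = 150L,
                           error_rate = 0.005, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  depth <- rep_len(depth_per_votu, length(phages))
  reads <- character(0)
  truth <- list()
  for (i in seq_along(phages)) {
    ph <- phages[[i]]
    glen <- nchar(ph$seq)
    if (read_len > glen) stop("read length exceeds genome ", ph$id)
    starts <- sample(glen - read_len + 1L, depth[i], replace = TRUE)
    vhg <- ph$genes[ph$genes$viral_hallmark, , drop = FALSE]
    in_vhg <- rep(FALSE, depth[i])
    for (j in seq_len(nrow(vhg))) {
      in_vhg <- in_vhg | (starts >= vhg$start[j] &
                            starts + read_len - 1L <= vhg$end[j])
    }
    rds <- substring(ph$seq, starts, starts + read_len - 1L)
    rds <- vapply(rds, mutate_dna, character(1), rate = error_rate,
                  USE.NAMES = FALSE)
    flip <- stats::runif(depth[i]) < 0.5
    rds[flip] <- vapply(rds[flip], revcomp, character(1),
                        USE.NAMES = FALSE)
    names(rds) <- sprintf("%s_r%05d", ph$id, seq_len(depth[i]))
    reads <- c(reads, rds)
    truth[[i]] <- data.frame(phage_id = ph$id, total_reads = depth[i],
                             vhg_reads = sum(in_vhg),
                             stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Generate a multi-sample cohort with planted structure
#'
#' Genus abundances are log-normal; each vOTU's raw abundance mixes its
#' host genus signal with independent log-normal noise
#' (`alpha * genus + (1 - alpha) * noise`), is scaled by planted
#' metadata effects on the log10 scale, and is zero-inflated with
#' per-sample detection probability `detection_prob`. Defence-system
#' abundance is a monotone function of the realized virome Shannon
#' diversity plus Gaussian noise.
#'
#' @param n_samples cohort size (default 500).
#' @param n_votus number of vOTUs (default 30).
#' @param n_genera number of bacterial genera (default 10).
#' @param alpha_s,alpha_g coupling coefficients for specialist and
#'   generalist phages (defaults 0.8 and 0.2).
#' @param frac_generalist fraction of vOTUs labelled generalist
#'   (default 0.3).
#' @param planted_effects data.frame with columns `votu`, `variable`,
#'   `beta`: additive effects on log10 abundance per unit of the
#'   metadata variable.
#' @param detection_prob per-sample probability that a vOTU is observed
#'   (default 0.6).
#' @param rng_seed seed.
#' @return object of class `cohort_truth`: list with `votu_abundance`,
#'   `genus_abundance` (samples x features, raw), relative versions,
#'   `metadata`, `defence_abundance`, `coupling` (votu/host
#'   genus/alpha/label) and `planted_effects`.
#' @export
generate_cohort <- function(n_samples = 500L, n_votus = 30L,
                            n_genera = 10L, alpha_s = 0.8, alpha_g = 0.2,
                            frac_generalist = 0.3, planted_effects = NULL,
                            detection_prob = 0.6, rng_seed = 1L) {
  if (!(alpha_g >= 0 && alpha_g <= alpha_s && alpha_s <= 1)) {
    stop("need 0 <= alpha_g <= alpha_s <= 1")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genera <- GUT_GENERA[seq_len(min(n_genera, length(GUT_GENERA)))]
  if (n_genera > length(GUT_GENERA)) {
    genera <- c(genera, sprintf("Genus%02d",
                                seq_len(n_genera - length(GUT_GENERA))))
  }
  samples <- sprintf("S%04d", seq_len(n_samples))
  # uneven community: genus-specific means on the log10 scale
  mu_g <- stats::rnorm(n_genera, 0, 0.5)
  genus_ab <- 10^(matrix(stats::rnorm(n_samples * n_genera, 0, 0.6),
                         n_samples) +
                    matrix(mu_g, n_samples, n_genera, byrow = TRUE))
  dimnames(genus_ab) <- list(samples, genera)

  votus <- sprintf("vOTU_%03d", seq_len(n_votus))
  label <- ifelse(seq_len(n_votus) <= round(frac_generalist * n_votus),
                  "generalist", "specialist")
  label <- sample(label)
  host <- genera[(seq_len(n_votus) - 1L) %% n_genera + 1L]
  alpha <- ifelse(label == "specialist", alpha_s, alpha_g)
  meta <- data.frame(
    age = stats::runif(n_samples, 20, 80),
    sex = stats::rbinom(n_samples, 1L, 0.5),
    bmi = stats::rnorm(n_samples, 23, 3),
    medication = stats::rbinom(n_samples, 1L, 0.3),
    diet_score = stats::rnorm(n_samples, 0, 1),
    row.names = samples)

  votu_ab <- matrix(0, n_samples, n_votus,
                    dimnames = list(samples, votus))
  for (v in seq_len(n_votus)) {
    noise <- 10^stats::rnorm(n_samples, mu_g[match(host[v], genera)], 0.6)
    raw <- alpha[v] * genus_ab[, host[v]] + (1 - alpha[v]) * noise
    votu_ab[, v] <- raw
  }
  if (!is.null(planted_effects)) {
    for (k in seq_len(nrow(planted_effects))) {
      v <- planted_effects$votu[k]
      x <- meta[[planted_effects$variable[k]]]
      xs <- scale(x)[, 1L]  # unit-variance predictor
      votu_ab[, v] <- votu_ab[, v] * 10^(planted_effects$beta[k] * xs)
    }
  }
  detected <- matrix(stats::runif(n_samples * n_votus) < detection_prob,
                     n_samples, n_votus)
  votu_ab[!detected] <- 0

  votu_rel <- votu_ab / pmax(rowSums(votu_ab), .Machine$double.eps)
  genus_rel <- genus_ab / rowSums(genus_ab)
  shannon_v <- apply(votu_rel, 1L, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(0)
    -sum(p * log(p))
  })
  systems <- c("RM", "CRISPR-Cas", "Abi", "BREX", "DISARM")
  defence <- vapply(seq_along(systems), function(s)
    0.5 + 0.3 * s / 5 * shannon_v + stats::rnorm(n_samples, 0, 0.15),
    numeric(n_samples))
  defence <- pmax(defence, 0)
  dimnames(defence) <- list(samples, systems)

  structure(list(
    votu_abundance = votu_ab, genus_abundance = genus_ab,
    votu_relative = votu_rel, genus_relative = genus_rel,
    metadata = meta, defence_abundance = defence,
    coupling = data.frame(votu = votus, host_genus = host, alpha = alpha,
                          label = label, stringsAsFactors = FALSE),
    planted_effects = planted_effects,
    shannon_virome = shannon_v),
    class = "cohort_truth")
}

#' Reference coupling correlation of the cohort model
#'
#' Monte-Carlo reference value for the mean phage-host Spearman
#' correlation produced by the abundance model at a given coupling
#' coefficient, computed on a large internally seeded cohort with the
#' same generative code and the same correlation procedure
#' (relative abundances, co-absent samples excluded). Used as the
#' recovery target in coupling-recovery checks.
#'
#' @param alpha coupling coefficient in [0, 1].
#' @param detection_prob zero-inflation detection probability.
#' @param n_samples size of the reference cohort (default 4000).
#' @return scalar mean Spearman correlation.
#' @export
expected_coupling_correlation <- function(alpha, detection_prob = 0.6,
                                          n_samples = 4000L) {
  co <- generate_cohort(n_samples = n_samples, n_votus = 30L,
                        alpha_s = alpha, alpha_g = alpha,
                        detection_prob = detection_prob, rng_seed = 777L)
  hosts <- data.frame(votu_id = co$coupling$votu,
                      genus = co$coupling$host_genus,
                      label = co$coupling$label,
                      stringsAsFactors = FALSE)
  recs <- phage_host_correlations(co$votu_relative, co$genus_relative,
                                  hosts, min_votu_abund = 0,
                                  min_genus_abund = 0)
  mean(recs$r_s)
}
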