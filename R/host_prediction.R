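# CRISPR-based host prediction: array detection in bacterial contigs,
# spacer length filtering, protospacer matching at edit distance <= 1
# on both strands, and genus-level host assignment with a
# specialist/generalist label.

#' Detect CRISPR arrays in a contig
#'
#' Greedy seed-and-extend detector: exact 20-mers occurring at least
#' three times with consecutive spacings compatible with a
#' repeat-spacer period (40-160 bp) seed candidate arrays; repeat
#' boundaries are extended while the column is unanimous across copies
#' and the repeat stays within 20-50 bp. Arrays need >= `min_copies`
#' repeat copies, and spacers between 20 and 110 bp.
#'
#' @param contig nucleotide sequence.
#' @param min_copies minimum repeat copies (default 3).
#' @param repeat_range allowed repeat length range (default 20-50 bp).
#' @param spacer_range allowed spacer length range (default 20-110 bp).
#' @param contig_id id carried into the output.
#' @return list of arrays; each array is a list with `contig_id`,
#'   `repeat_seq`, `repeat_positions` and `spacers` (data.frame
#'   spacer_seq/start).
#' @export
detect_crispr_arrays <- function(contig, min_copies = 3L,
                                 repeat_range = c(20L, 50L),
                                 spacer_range = c(20L, 110L),
                                 contig_id = "contig") {
  check_dna(contig)
  n <- nchar(contig)
  if (n < 200L) return(list())
  k <- 20L
  starts <- seq_len(n - k + 1L)
  kmers <- substring(contig, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  occ <- occ[lengths(occ) >= min_copies]
  if (!length(occ)) return(list())
  # strongest evidence first: more repeat copies win, ties by position;
  # later seeds overlapping claimed territory are skipped
  occ <- occ[order(-lengths(occ), vapply(occ, min, numeric(1)))]
  chars <- strsplit(contig, "", fixed = TRUE)[[1]]
  period_lo <- repeat_range[1L] + spacer_range[1L]
  period_hi <- repeat_range[2L] + spacer_range[2L]
  claimed <- rep(FALSE, n)
  arrays <- list()
  for (pos in occ) {
    pos <- sort(pos)
    if (any(claimed[pos])) next
    gaps <- diff(pos)
    ok <- gaps >= period_lo & gaps <= period_hi
    if (!any(ok)) next
    # longest run of compatible consecutive occurrences
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    best <- which(runs$values & runs$lengths == max(runs$lengths[runs$values]))[1L]
    hi <- ends[best]; lo <- hi - runs$lengths[best] + 1L
    p <- pos[lo:(hi + 1L)]
    if (length(p) < min_copies) next
    rep_start <- p
    rep_len <- k
    # extend the repeat while the column is unanimous across all copies
    # (with 4+ copies a chance-unanimous column beyond the true
    # boundary is rare and costs at most a spacer-edge base)
    unanimous <- function(offsets) {
      all(offsets >= 1L & offsets <= n) &&
        length(unique(chars[offsets])) == 1L
    }
    while (rep_len < repeat_range[2L] &&
           unanimous(rep_start + rep_len) &&
           min(diff(rep_start)) - rep_len > spacer_range[1L]) {
      rep_len <- rep_len + 1L
    }
    while (rep_len < repeat_range[2L] && unanimous(rep_start - 1L) &&
           min(diff(rep_start)) - rep_len > spacer_range[1L]) {
      rep_start <- rep_start - 1L
      rep_len <- rep_len + 1L
    }
    spacer_start <- rep_start[-length(rep_start)] + rep_len
    spacer_end <- rep_start[-1L] - 1L
    sp_len <- spacer_end - spacer_start + 1L
    if (any(sp_len < spacer_range[1L] | sp_len > spacer_range[2L])) next
    claimed[seq.int(min(rep_start), max(rep_start) + rep_len - 1L)] <- TRUE
    arrays[[length(arrays) + 1L]] <- list(
      contig_id = contig_id,
      repeat_seq = substr(contig, rep_start[1L],
                          rep_start[1L] + rep_len - 1L),
      repeat_positions = rep_start,
      spacers = data.frame(
        spacer_seq = substring(contig, spacer_start, spacer_end),
        start = spacer_start, stringsAsFactors = FALSE))
  }
  arrays
}

#' Filter spacers by length
#'
#' Keeps spacers between 25 and 100 bp inclusive; shorter or longer
#' spacers are discarded.
#'
#' @param spacers character vector (or data.frame with `spacer_seq`).
#' @param cfg a [pipeline_config()].
#' @return filtered object of the same shape.
#' @export
filter_spacers <- function(spacers, cfg = pipeline_config()) {
  seqs <- if (is.data.frame(spacers)) spacers$spacer_seq else spacers
  keep <- nchar(seqs) >= cfg$spacer_min & nchar(seqs) <= cfg$spacer_max
  if (is.data.frame(spacers)) spacers[keep, , drop = FALSE]
  else spacers[keep]
}

#' Match a spacer against a phage genome at edit distance <= 1
#'
#' Reports every placement (both strands) where the spacer matches its
#' protospacer with at most one mismatch or indel and with more than
#' 95% of the spacer aligned. Exact matches report 0 edits.
#'
#' @param spacer spacer sequence (should already be length-filtered).
#' @param genome phage genome sequence.
#' @param cfg a [pipeline_config()].
#' @return data.frame with `start`, `end`, `strand`, `edits`,
#'   `coverage`; zero rows when there is no hit.
#' @export
match_spacer <- function(spacer, genome, cfg = pipeline_config()) {
  check_dna(spacer, "spacer")
  check_dna(genome, "genome")
  subj <- Biostrings::DNAString(genome)
  len <- nchar(spacer)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else revcomp(spacer)
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = 1L,
                                     with.indels = TRUE)
    if (!length(hits)) next
    st <- Biostrings::start(hits)
    en <- Biostrings::end(hits)
    matched <- as.character(hits)
    edits <- drop(utils::adist(pat, matched))
    cov <- 1 - pmax(0L, len - nchar(matched)) / len
    keep <- edits <= 1L & cov > cfg$spacer_cov
    if (!any(keep)) next
    out[[strand]] <- data.frame(start = st[keep], end = en[keep],
                                strand = strand,
                                edits = as.integer(edits[keep]),
                                coverage = cov[keep],
                                stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), edits = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  # collapse overlapping placements of the same strand, keep min edits
  res <- res[order(res$strand, res$start, res$edits), , drop = FALSE]
  dup <- duplicated(res[, c("strand", "start")])
  res[!dup, , drop = FALSE]
}

#' Transfer a genus label to a contig from reference genomes
#'
#' The genus of the best-aligning reference is transferred when the
#' alignment exceeds 90% identity with more than 70% of the contig
#' aligned.
#'
#' @param contig nucleotide sequence.
#' @param references named character vector of reference genome
#'   sequences; `ref_genus` maps reference id to genus.
#' @param ref_genus named character vector (reference id -> genus).
#' @param cfg a [pipeline_config()].
#' @return genus name or NA.
#' @export
assign_contig_taxonomy <- function(contig, references, ref_genus,
                                   cfg = pipeline_config()) {
  best_genus <- NA_character_
  best_ani <- -Inf
  for (rid in names(references)) {
    hit <- estimate_ani(contig, references[[rid]])
    if (is.na(hit$ani)) next
    if (hit$ani > cfg$ctg_tax_ident &&
        hit$aligned_fraction > cfg$ctg_tax_cov && hit$ani > best_ani) {
      best_ani <- hit$ani
      best_genus <- ref_genus[[rid]]
    }
  }
  best_genus
}

#' Assign genus-level hosts to a vOTU from spacer hits
#'
#' The host genera are the distinct source genera of the matching
#' CRISPR arrays, minus the exclusion list of non-intestinal genera.
#' One genus gives a specialist label, several a generalist label,
#' none gives unknown.
#'
#' @param votu_id vOTU identifier.
#' @param hit_genera character vector of source genera of the arrays
#'   whose spacers matched this vOTU (NA entries are dropped).
#' @param exclusion character vector of excluded genera (default
#'   [EXCLUDED_HOST_GENERA]).
#' @return list with `votu_id`, `genera`, `label`.
#' @export
assign_hosts <- function(votu_id, hit_genera,
                         exclusion = EXCLUDED_HOST_GENERA) {
  genera <- setdiff(unique(hit_genera[!is.na(hit_genera)]), exclusion)
  label <- if (length(genera) == 0L) "unknown"
  else if (length(genera) == 1L) "specialist" else "generalist"
  list(votu_id = votu_id, genera = genera, label = label)
}

#' Predict hosts for a set of phage genomes from community contigs
#'
#' Detects CRISPR arrays in the given (bacterial/metagenomic) contigs,
#' filters spacers, matches them to every phage genome and assigns
#' genus-level hosts. Array taxonomy is taken from `contig_genus`
#' (e.g. reference labels or [assign_contig_taxonomy()] output).
#'
#' @param phage_genomes named character vector of phage genome
#'   sequences.
#' @param contigs data.frame with `contig_id` and `seq`.
#' @param contig_genus named character vector (contig id -> genus).
#' @param cfg a [pipeline_config()].
#' @return list with `hits` (data.frame spacer/contig/genus/phage/
#'   edits) and `assignments` (data.frame votu_id/genera/label).
#' @export
predict_hosts <- function(phage_genomes, contigs, contig_genus,
                          cfg = pipeline_config()) {
  spacer_tab <- list()
  for (i in seq_len(nrow(contigs))) {
    arrays <- detect_crispr_arrays(contigs$seq[i],
                                   contig_id = contigs$contig_id[i])
    for (arr in arrays) {
      sp <- filter_spacers(arr$spacers, cfg)
      if (!nrow(sp)) next
      sp$contig_id <- arr$contig_id
      sp$genus <- unname(contig_genus[arr$contig_id])
      spacer_tab[[length(spacer_tab) + 1L]] <- sp
    }
  }
  if (!length(spacer_tab)) {
    return(list(hits = NULL, assignments = data.frame(
      votu_id = names(phage_genomes), genera = "", label = "unknown",
      stringsAsFactors = FALSE)))
  }
  spacers <- do.call(rbind, c(spacer_tab, make.row.names = FALSE))
  hits <- list()
  for (s in seq_len(nrow(spacers))) {
    for (pid in names(phage_genomes)) {
      m <- match_spacer(spacers$spacer_seq[s], phage_genomes[[pid]], cfg)
      if (nrow(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          spacer_seq = spacers$spacer_seq[s],
          contig_id = spacers$contig_id[s], genus = spacers$genus[s],
          phage_id = pid, edits = min(m$edits),
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, c(hits,
    make.row.names = FALSE)) else NULL
  assignments <- do.call(rbind, lapply(names(phage_genomes), function(pid) {
    hg <- if (is.null(hits)) character(0)
      else hits$genus[hits$phage_id == pid]
    a <- assign_hosts(pid, hg)
    data.frame(votu_id = pid,
               genera = paste(sort(a$genera), collapse = ";"),
               label = a$label, stringsAsFactors = FALSE)
  }))
  list(hits = hits, assignments = assignments)
}
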