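# Synthetic-data generator: genome, annotation, truncation-model iCLIP reads
# with PCR duplication and random barcodes, binomial junction counts,
# log-normal FPKM tables, and ChIP clusters -- all with a ground-truth
# manifest so every pipeline stage can be checked against what was planted.

#' Simulation configuration
#'
#' Defaults describe a desk-scale dataset: 300 genes of five exons each, one
#' designated cassette event per gene, 50 events with a planted binding site
#' in the transcript-upstream intron flank, junction depth 200 per replicate,
#' and truncation-model iCLIP reads with PCR duplication and 9-nt random
#' barcodes.
#'
#' @param n_genes Number of genes.
#' @param n_exons_per_gene Exons per gene model (>= 3 so every gene carries
#'   internal exons).
#' @param exon_length_range,intron_length_range Length ranges in nt.
#' @param gene_spacing Intergenic gap in nt (kept large so 1-kb ChIP windows
#'   of neighbouring genes never touch).
#' @param n_cassette_events Number of genes given a designated cassette event
#'   with simulated junction evidence (the middle internal exon).
#' @param n_binding_sites Number of events with one planted crosslink site in
#'   the upstream intron flank (the "bound" events).
#' @param n_direct_repressed,n_direct_activated Bound events that are also
#'   knockdown-responsive and differentiation-changed (the planted direct
#'   targets); the remaining bound events are splicing-unchanged.
#' @param n_responsive_unbound Events responsive to knockdown and changed in
#'   differentiation but with no binding site (split evenly between
#'   repressed-like and activated-like directions).
#' @param n_diff_only Events changed in differentiation only.
#' @param delta_psi_range True |ΔPSI| range (percent points) for regulated
#'   events.
#' @param junction_depth Expected junction reads per event per replicate.
#' @param n_junction_replicates Replicates per condition.
#' @param binding_site_motif Pentamer planted (sense strand) around each
#'   crosslink site.
#' @param motif_copies Copies of the motif planted per site window.
#' @param iclip_site_read_mean Expected unique molecules per planted site.
#' @param background_read_rate Background crosslink molecules per kb of gene
#'   span.
#' @param pcr_duplication_rate Expected extra PCR copies per unique molecule.
#' @param barcode_random_length Random-barcode length in nt (>= 1).
#' @param read_length iCLIP read length in nt.
#' @param fpkm_meanlog_range Range of per-gene baseline `meanlog` for the
#'   log-normal FPKM model.
#' @param fpkm_sdlog Replicate noise (`sdlog`).
#' @param n_induced_strong,n_induced_mild,n_repressed_genes Genes planted
#'   with expression fold-changes `fold_change_strong`, `fold_change_mild`,
#'   and `1/fold_change_strong` respectively (mutant over wild type).
#' @param fold_change_strong,fold_change_mild Planted fold-changes.
#' @param n_wt_replicates,n_mut_replicates Expression replicates per group.
#' @param chip_bound_fraction Fraction of non-induced genes given a ChIP
#'   cluster within the gene span.
#' @param chip_bound_fraction_induced Same for induced genes (enriched).
#' @param seed Integer RNG seed; every generator output is deterministic
#'   given it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 300,
                              n_exons_per_gene = 5,
                              exon_length_range = c(80, 250),
                              intron_length_range = c(1100, 2500),
                              gene_spacing = 4000,
                              n_cassette_events = 300,
                              n_binding_sites = 50,
                              n_direct_repressed = 25,
                              n_direct_activated = 15,
                              n_responsive_unbound = 30,
                              n_diff_only = 30,
                              delta_psi_range = c(25, 45),
                              junction_depth = 200,
                              n_junction_replicates = 2,
                              binding_site_motif = "TCTCT",
                              motif_copies = 3,
                              iclip_site_read_mean = 30,
                              background_read_rate = 5,
                              pcr_duplication_rate = 1,
                              barcode_random_length = 9,
                              read_length = 35,
                              fpkm_meanlog_range = c(log(5), log(150)),
                              fpkm_sdlog = 0.25,
                              n_induced_strong = 40,
                              n_induced_mild = 20,
                              n_repressed_genes = 10,
                              fold_change_strong = 3,
                              fold_change_mild = 1.7,
                              n_wt_replicates = 3,
                              n_mut_replicates = 5,
                              chip_bound_fraction = 0.15,
                              chip_bound_fraction_induced = 0.45,
                              seed = 1L) {
  cfg <- as.list(environment())
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 1, cfg$n_exons_per_gene >= 3,
    cfg$barcode_random_length >= 1,
    cfg$junction_depth >= 0, cfg$iclip_site_read_mean >= 0,
    cfg$background_read_rate >= 0, cfg$pcr_duplication_rate >= 0,
    cfg$chip_bound_fraction >= 0, cfg$chip_bound_fraction <= 1,
    cfg$chip_bound_fraction_induced >= 0, cfg$chip_bound_fraction_induced <= 1,
    all(cfg$delta_psi_range > 0), all(cfg$delta_psi_range <= 100)
  )
  if (cfg$exon_length_range[1] < 10 || diff(cfg$exon_length_range) < 0 ||
      diff(cfg$intron_length_range) < 0) {
    abort("infeasible exon/intron length ranges")
  }
  if (cfg$n_binding_sites > 0 && cfg$intron_length_range[1] < 1100) {
    abort(paste("infeasible intron length range: flank-bound events need",
                "introns of at least 1100 nt so the 500-nt flank and the",
                "site window fit inside the intron"))
  }
  if (cfg$n_cassette_events > cfg$n_genes) {
    abort("n_cassette_events cannot exceed n_genes")
  }
  n_planted <- cfg$n_binding_sites + cfg$n_responsive_unbound + cfg$n_diff_only
  if (n_planted > cfg$n_cassette_events) {
    abort("more planted event classes than cassette events")
  }
  if (cfg$n_direct_repressed + cfg$n_direct_activated > cfg$n_binding_sites) {
    abort("direct targets cannot exceed n_binding_sites")
  }
  if (cfg$n_induced_strong + cfg$n_induced_mild + cfg$n_repressed_genes > cfg$n_genes) {
    abort("more planted expression classes than genes")
  }
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate genome and annotation with ground truth
#'
#' Lays out genes with alternating random strands on four chromosomes,
#' designates the middle internal exon of each of the first
#' `n_cassette_events` genes as a cassette event, assigns event classes
#' (direct targets, bound-unchanged, responsive-unbound, differentiation-only,
#' unchanged) to a random permutation of the events, draws true PSI per
#' condition for each class, places one crosslink site in the
#' transcript-upstream 500-nt intron flank of every bound event, and plants
#' the binding motif on the sense strand around each site.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (`DNAStringSet`), `genes`, `exons`, `introns`,
#'   `events` (all enumerated trios) and `truth` (list of `events` and
#'   `sites` tibbles).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  n_chrom <- min(4L, config$n_genes)
  chroms <- paste0("chr", seq_len(n_chrom))
  cursor <- setNames(rep(200L, n_chrom), chroms)

  exon_rows <- vector("list", config$n_genes)
  gene_rows <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("g%04d", i)
    chrom <- chroms[((i - 1) %% n_chrom) + 1]
    strand <- sample(c("+", "-"), 1)
    ne <- config$n_exons_per_gene
    exon_len <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                       ne, replace = TRUE)
    intron_len <- sample(config$intron_length_range[1]:config$intron_length_range[2],
                         ne - 1, replace = TRUE)
    starts <- cursor[chrom] + c(0L, cumsum(exon_len[-ne] + intron_len))
    ends <- starts + exon_len
    rank <- if (strand == "+") seq_len(ne) else rev(seq_len(ne))
    exon_rows[[i]] <- tibble(gene_id = gid, exon_rank = rank, chrom = chrom,
                             start = as.integer(starts), end = as.integer(ends),
                             strand = strand)
    gene_rows[[i]] <- tibble(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                             chrom = chrom, start = as.integer(starts[1]),
                             end = as.integer(ends[ne]), strand = strand)
    cursor[chrom] <- as.integer(ends[ne] + config$gene_spacing)
  }
  exons <- arrange(list_rbind(exon_rows), .data$gene_id, .data$exon_rank)
  genes <- list_rbind(gene_rows)
  events <- cassette_events(exons)
  introns <- derive_introns(exons)

  # genome as character vectors first so motif planting is cheap
  seqs <- lapply(cursor + 500L, random_dna)

  # designated event per gene: middle internal exon
  mid <- (config$n_exons_per_gene + 1) %/% 2
  designated <- tibble(
    gene_id = genes$gene_id[seq_len(config$n_cassette_events)]
  ) |>
    mutate(event_id = paste0(.data$gene_id, ":cas", mid - 1)) |>
    left_join(events, by = c("event_id", "gene_id"))

  truth_events <- assign_event_classes(config, designated)

  # one planted crosslink site per bound event, in the upstream intron flank
  bound <- filter(truth_events, .data$bound)
  site_rows <- NULL
  if (nrow(bound) > 0) {
    ev <- semi_join(designated, bound, by = "event_id")
    pos <- integer(nrow(ev))
    for (j in seq_len(nrow(ev))) {
      pos[j] <- if (ev$strand[j] == "+") {
        sample((ev$cas_start[j] - 450L):(ev$cas_start[j] - 60L), 1)
      } else {
        sample((ev$cas_end[j] + 60L):(ev$cas_end[j] + 450L), 1)
      }
    }
    site_rows <- tibble(chrom = ev$chrom, pos = pos, strand = ev$strand,
                        gene_id = ev$gene_id, event_id = ev$event_id,
                        motif = sample(config$binding_site_motif, nrow(ev),
                                       replace = TRUE))
    offsets <- round(seq(-10, 10, length.out = max(1, config$motif_copies)))
    for (j in seq_len(nrow(site_rows))) {
      for (off in offsets) {
        seqs[[site_rows$chrom[j]]] <- plant_motif(
          seqs[[site_rows$chrom[j]]], site_rows$pos[j], site_rows$strand[j],
          off, site_rows$motif[j])
      }
    }
  } else {
    site_rows <- tibble(chrom = character(), pos = integer(),
                        strand = character(), gene_id = character(),
                        event_id = character(), motif = character())
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(seqs)
  list(genome = genome, genes = genes, exons = exons, introns = introns,
       events = events,
       truth = list(events = truth_events, sites = site_rows))
}

# write `motif` so that the *sense* sequence reads the motif centred at
# sense-offset `off` from the 0-based site position
plant_motif <- function(seq, pos, strand, off, motif) {
  k <- nchar(motif)
  half <- k %/% 2
  if (strand == "+") {
    g0 <- pos + off - half                       # 0-based genomic start
    substr(seq, g0 + 1, g0 + k) <- motif
  } else {
    g0 <- pos - off - half
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    substr(seq, g0 + 1, g0 + k) <- rc
  }
  seq
}

assign_event_classes <- function(config, designated) {
  n <- nrow(designated)
  classes <- rep("unchanged", n)
  n_bound_other <- config$n_binding_sites -
    config$n_direct_repressed - config$n_direct_activated
  n_ru <- config$n_responsive_unbound
  lab <- c(rep("direct_repressed", config$n_direct_repressed),
           rep("direct_activated", config$n_direct_activated),
           rep("bound_unchanged", n_bound_other),
           rep("responsive_repressed", ceiling(n_ru / 2)),
           rep("responsive_activated", floor(n_ru / 2)),
           rep("diff_only", config$n_diff_only))
  idx <- sample(n, length(lab))
  classes[idx] <- lab

  delta <- runif(n, config$delta_psi_range[1], config$delta_psi_range[2])
  low <- runif(n, 15, 35)
  high <- runif(n, 65, 85)
  flat <- runif(n, 10, 90)
  diff_sign <- sample(c(-1, 1), n, replace = TRUE)

  repressed_like <- classes %in% c("direct_repressed", "responsive_repressed")
  activated_like <- classes %in% c("direct_activated", "responsive_activated")

  psi_control <- ifelse(repressed_like, low, ifelse(activated_like, high, flat))
  psi_knockdown <- ifelse(repressed_like, low + delta,
                          ifelse(activated_like, high - delta, psi_control))
  psi_progenitor <- psi_control
  psi_neuron <- ifelse(repressed_like, low + delta,
                ifelse(activated_like, high - delta,
                ifelse(classes == "diff_only",
                       pmin(pmax(flat + diff_sign * delta, 0), 100),
                       psi_control)))

  tibble(
    event_id = designated$event_id,
    gene_id = designated$gene_id,
    class = classes,
    bound = classes %in% c("direct_repressed", "direct_activated", "bound_unchanged"),
    responsive = repressed_like | activated_like,
    diff_changed = repressed_like | activated_like | classes == "diff_only",
    direction = ifelse(repressed_like, "repressed",
                ifelse(activated_like, "activated", NA_character_)),
    psi_control = psi_control, psi_knockdown = psi_knockdown,
    psi_progenitor = psi_progenitor, psi_neuron = psi_neuron
  )
}

draw_barcodes <- function(n, len) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate truncation-model iCLIP reads
#'
#' cDNAs truncate at the crosslinked nucleotide, so every read starts one
#' nucleotide downstream (transcript orientation) of its crosslink site: a
#' plus-strand site at 0-based position `p` yields reads starting at `p + 1`;
#' a minus-strand site at `p` yields alignments ending (half-open) at `p`.
#' Each unique molecule receives an independent random barcode, drawn so that
#' molecules sharing a start position never collide (which makes molecule
#' recovery after deduplication exactly checkable); PCR copies inherit the
#' position and barcode of their template.  Background molecules crosslink
#' uniformly over gene spans on the gene strand.
#'
#' @param config A [simulation_config()].
#' @param ann Result of [simulate_annotation()].
#' @return Tibble of reads: `chrom`, `start`, `end`, `strand`, `name`
#'   (`readID#BARCODE`), `barcode`, `molecule_id` (generator bookkeeping).
#' @export
simulate_iclip_reads <- function(config, ann) {
  set.seed(config$seed + 1L)
  L <- config$read_length
  sites <- ann$truth$sites

  mol <- list()
  if (nrow(sites) > 0) {
    n_mol <- rpois(nrow(sites), config$iclip_site_read_mean)
    mol$planted <- tibble(
      chrom = rep(sites$chrom, n_mol),
      pos = rep(sites$pos, n_mol),
      strand = rep(sites$strand, n_mol)
    )
  }
  g <- ann$genes
  n_bg <- rpois(nrow(g), (g$end - g$start) / 1000 * config$background_read_rate)
  if (sum(n_bg) > 0) {
    bg_start <- rep(g$start, n_bg)
    bg_end <- rep(g$end, n_bg)
    mol$background <- tibble(
      chrom = rep(g$chrom, n_bg),
      strand = rep(g$strand, n_bg),
      pos = as.integer(floor(runif(length(bg_start), bg_start, bg_end)))
    )
  }
  mols <- list_rbind(mol)
  if (nrow(mols) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character(),
                  barcode = character(), molecule_id = integer()))
  }
  mols <- mols |>
    mutate(
      start = as.integer(ifelse(.data$strand == "+", .data$pos + 1L, .data$pos - L)),
      end = as.integer(ifelse(.data$strand == "+", .data$pos + 1L + L, .data$pos)),
      molecule_id = seq_len(n()),
      barcode = draw_barcodes(n(), config$barcode_random_length)
    )
  # enforce distinct barcodes among molecules sharing a start position
  repeat {
    key <- paste(mols$chrom, mols$start, mols$strand, mols$barcode)
    dup <- duplicated(key)
    if (!any(dup)) break
    mols$barcode[dup] <- draw_barcodes(sum(dup), config$barcode_random_length)
  }
  copies <- 1L + rpois(nrow(mols), config$pcr_duplication_rate)
  reads <- mols[rep(seq_len(nrow(mols)), copies), ]
  reads |>
    mutate(name = paste0("r", seq_len(n()), "#", .data$barcode)) |>
    select("chrom", "start", "end", "strand", "name", "barcode", "molecule_id") |>
    arrange(.data$chrom, .data$start, .data$strand, .data$barcode)
}

#' Simulate cassette-exon junction counts
#'
#' For each designated event, condition, and replicate, the number of
#' informative junction reads is Poisson with mean `junction_depth`; each
#' read reflects an included transcript with probability PSI/100.  Included
#' transcripts contribute both inclusion junctions (`I1 = I2 = k`), skipped
#' ones the exclusion junction (`E = n - k`), so the PSI estimator
#' `100 * m / (m + E)` with `m = (I1 + I2) / 2` is unbiased for the true PSI.
#'
#' @param config A [simulation_config()].
#' @param ann Result of [simulate_annotation()].
#' @return Tibble `event_id`, `condition`, `replicate`, `I1`, `I2`, `E` over
#'   the four conditions `control`, `knockdown`, `progenitor`, `neuron`.
#' @export
simulate_junction_counts <- function(config, ann) {
  set.seed(config$seed + 2L)
  tr <- ann$truth$events
  grid <- tidyr::expand_grid(
    event_id = tr$event_id,
    condition = c("control", "knockdown", "progenitor", "neuron"),
    replicate = seq_len(config$n_junction_replicates)
  ) |>
    left_join(
      tr |>
        select("event_id", "psi_control", "psi_knockdown",
               "psi_progenitor", "psi_neuron") |>
        pivot_longer(-"event_id", names_to = "condition",
                     names_prefix = "psi_", values_to = "psi"),
      by = c("event_id", "condition")
    )
  n <- rpois(nrow(grid), config$junction_depth)
  k <- rbinom(nrow(grid), n, grid$psi / 100)
  grid |>
    mutate(I1 = k, I2 = k, E = n - k) |>
    select("event_id", "condition", "replicate", "I1", "I2", "E")
}

#' Simulate a normalized FPKM expression table
#'
#' Per-gene baseline `meanlog` is uniform over `fpkm_meanlog_range`;
#' replicates are log-normal with `fpkm_sdlog` noise.  Planted induced and
#' repressed genes have their mutant-group `meanlog` shifted by the log of
#' the configured fold-change, so group geometric means sit in the planted
#' ratio.
#'
#' @param config A [simulation_config()].
#' @param ann Result of [simulate_annotation()].
#' @return List with `fpkm` tibble (`gene_id`, `group`, `replicate`, `fpkm`)
#'   and `truth` tibble (`gene_id`, `expr_class`, `true_fold`).
#' @export
simulate_expression_table <- function(config, ann) {
  set.seed(config$seed + 3L)
  g <- ann$genes$gene_id
  n <- length(g)
  cls <- rep("unchanged", n)
  lab <- c(rep("induced_strong", config$n_induced_strong),
           rep("induced_mild", config$n_induced_mild),
           rep("repressed", config$n_repressed_genes))
  cls[sample(n, length(lab))] <- lab
  fold <- dplyr::case_when(
    cls == "induced_strong" ~ config$fold_change_strong,
    cls == "induced_mild" ~ config$fold_change_mild,
    cls == "repressed" ~ 1 / config$fold_change_strong,
    .default = 1
  )
  base <- runif(n, config$fpkm_meanlog_range[1], config$fpkm_meanlog_range[2])
  fpkm <- tidyr::expand_grid(gene_idx = seq_len(n),
                             group = c("wild_type", "mutant")) |>
    mutate(n_rep = ifelse(.data$group == "wild_type",
                          config$n_wt_replicates, config$n_mut_replicates)) |>
    tidyr::uncount(.data$n_rep, .id = "replicate") |>
    mutate(
      gene_id = g[.data$gene_idx],
      meanlog = base[.data$gene_idx] +
        ifelse(.data$group == "mutant", log(fold[.data$gene_idx]), 0),
      fpkm = rlnorm(n(), meanlog = .data$meanlog, sdlog = config$fpkm_sdlog)
    ) |>
    select("gene_id", "group", "replicate", "fpkm")
  list(fpkm = fpkm,
       truth = tibble(gene_id = g, expr_class = cls, true_fold = fold))
}

#' Simulate ChIP clusters over a chosen gene subset
#'
#' Induced genes are bound with probability `chip_bound_fraction_induced`,
#' all others with `chip_bound_fraction`.  Each bound gene receives one
#' 200-nt cluster inside its span (therefore within the 1-kb assignment
#' window); a few unbound genes receive decoy clusters 2 kb past their span,
#' outside every gene's window.
#'
#' @param config A [simulation_config()].
#' @param ann Result of [simulate_annotation()].
#' @param expr_truth Expression truth tibble from
#'   [simulate_expression_table()].
#' @return List with `clusters` (BED-style tibble) and `bound_genes`
#'   (character vector of truth-bound gene ids).
#' @export
simulate_chip_clusters <- function(config, ann, expr_truth) {
  set.seed(config$seed + 4L)
  g <- ann$genes
  induced <- expr_truth$expr_class %in% c("induced_strong", "induced_mild")
  p <- ifelse(induced, config$chip_bound_fraction_induced,
              config$chip_bound_fraction)
  bound <- runif(nrow(g)) < p
  rows <- list()
  if (any(bound)) {
    gb <- g[bound, ]
    center <- as.integer(gb$start + round(runif(nrow(gb)) * (gb$end - gb$start - 200)))
    rows$bound <- tibble(chrom = gb$chrom, start = center,
                         end = center + 200L, strand = "+",
                         name = paste0("chip_", gb$gene_id), score = 0)
  }
  unbound_idx <- which(!bound)
  n_decoy <- min(5L, length(unbound_idx))
  if (n_decoy > 0) {
    gd <- g[sample(unbound_idx, n_decoy), ]
    rows$decoy <- tibble(chrom = gd$chrom, start = gd$end + 2000L,
                         end = gd$end + 2200L, strand = "+",
                         name = paste0("decoy_", gd$gene_id), score = 0)
  }
  clusters <- if (length(rows)) list_rbind(rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), name = character(), score = numeric())
  list(clusters = arrange(clusters, .data$chrom, .data$start),
       bound_genes = g$gene_id[bound])
}

#' Simulate a complete dataset with ground truth
#'
#' Runs every generator in sequence with seeds derived from `config$seed`,
#' so two calls with the same configuration are identical.
#'
#' @param config A [simulation_config()].
#' @return List: `genome`, `genes`, `exons`, `introns`, `events`, `reads`,
#'   `junctions`, `fpkm`, `chip`, and `truth` (list of `events`, `sites`,
#'   `expression`, `chip_bound_genes`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  reads <- simulate_iclip_reads(config, ann)
  junctions <- simulate_junction_counts(config, ann)
  expr <- simulate_expression_table(config, ann)
  chip <- simulate_chip_clusters(config, ann, expr$truth)
  list(
    genome = ann$genome, genes = ann$genes, exons = ann$exons,
    introns = ann$introns, events = ann$events,
    reads = reads, junctions = junctions, fpkm = expr$fpkm,
    chip = chip$clusters,
    truth = list(events = ann$truth$events, sites = ann$truth$sites,
                 expression = expr$truth, chip_bound_genes = chip$bound_genes)
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genome.fa`, `annotation.gtf`, `iclip_reads.bed` (barcode carried in
#' the name field as `readID#BARCODE`), `chip_clusters.bed`,
#' `junction_counts.tsv`, `fpkm.tsv`, and the ground-truth manifest as
#' `truth_*.tsv`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, p("genome.fa"))
  write_gene_models(list(genes = sim$genes, exons = sim$exons), p("annotation.gtf"))
  write_bed6(select(sim$reads, -"barcode", -"molecule_id"), p("iclip_reads.bed"))
  write_bed6(sim$chip, p("chip_clusters.bed"))
  readr::write_tsv(sim$junctions, p("junction_counts.tsv"))
  readr::write_tsv(sim$fpkm, p("fpkm.tsv"))
  readr::write_tsv(sim$truth$events, p("truth_events.tsv"))
  readr::write_tsv(sim$truth$sites, p("truth_sites.tsv"))
  readr::write_tsv(sim$truth$expression, p("truth_expression.tsv"))
  readr::write_tsv(tibble(gene_id = sim$truth$chip_bound_genes),
                   p("truth_chip_bound.tsv"))
  invisible(dir)
}

#' Read barcoded iCLIP reads from a BED6 file
#'
#' Splits `readID#BARCODE` names back into read id and barcode.
#'
#' @param path BED6 file written by [write_dataset()] or equivalent.
#' @return Read tibble with `chrom`, `start`, `end`, `strand`, `name`,
#'   `barcode` columns.
#' @export
read_iclip_bed <- function(path) {
  x <- read_bed6(path)
  parts <- stringr::str_split_fixed(x$name, stringr::fixed("#"), 2)
  x$barcode <- ifelse(parts[, 2] == "", NA_character_, parts[, 2])
  x
}
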