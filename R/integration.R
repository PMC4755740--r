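# Integration of binding clusters, splicing response, differentiation
# changes, expression changes, and ChIP data into direct-target calls and
# overlap enrichment statistics; the end-to-end pipeline driver lives here.

#' Flag cassette events with a nearby binding cluster
#'
#' An event is `bound` when at least one filtered cluster on the host gene's
#' strand overlaps (>= 1 nt) the cassette exon body or the 500-nt intronic
#' flanks up- and downstream of it (transcript orientation, clipped at the
#' neighbouring exons).  Antisense clusters are tabulated but never confer
#' bound status.
#'
#' @param events Cassette-event tibble.
#' @param clusters Filtered cluster tibble from [filter_clusters()].
#' @param flank_length Intronic flank length in nt.
#' @return Tibble `event_id`, `bound`, `n_sense_clusters`,
#'   `n_antisense_clusters`.
#' @export
associate_clusters <- function(events, clusters, flank_length = 500L) {
  regions <- bind_rows(
    event_flank(events, "exon_body"),
    event_flank(events, "upstream_intron", flank_length),
    event_flank(events, "downstream_intron", flank_length)
  ) |>
    filter(.data$end > .data$start)
  out <- tibble(event_id = events$event_id, n_sense_clusters = 0L,
                n_antisense_clusters = 0L)
  if (nrow(regions) > 0 && nrow(clusters) > 0) {
    reg_gr <- tbl_to_gr(regions)
    clu_gr <- tbl_to_gr(clusters)
    sense <- GenomicRanges::findOverlaps(reg_gr, clu_gr, ignore.strand = FALSE)
    anti <- GenomicRanges::findOverlaps(reg_gr, clu_gr, ignore.strand = TRUE)
    tally <- function(hits) {
      tibble(event_id = regions$event_id[S4Vectors::queryHits(hits)],
             cluster = S4Vectors::subjectHits(hits)) |>
        distinct() |>
        count(.data$event_id)
    }
    n_sense <- tally(sense)
    n_all <- tally(anti)
    out <- out |>
      left_join(rename(n_sense, ns = "n"), by = "event_id") |>
      left_join(rename(n_all, na = "n"), by = "event_id") |>
      mutate(n_sense_clusters = dplyr::coalesce(.data$ns, 0L),
             n_antisense_clusters = dplyr::coalesce(.data$na, 0L) -
               dplyr::coalesce(.data$ns, 0L)) |>
      select(-"ns", -"na")
  }
  mutate(out, bound = .data$n_sense_clusters > 0) |>
    select("event_id", "bound", "n_sense_clusters", "n_antisense_clusters")
}

#' Upper-tail hypergeometric overlap enrichment
#'
#' Probability of drawing at least `k` marked items in a sample of `n` from
#' a population of `N` containing `K` marked items.
#'
#' @param N Population size.
#' @param K Marked items in the population.
#' @param n Sample size.
#' @param k Marked items observed in the sample.
#' @return One-row tibble `N`, `K`, `n`, `k`, `fraction_sample`,
#'   `fraction_population`, `p_value`.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n))) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(K, n) <= N")
  }
  tibble(N = N, K = K, n = n, k = k,
         fraction_sample = ifelse(n > 0, k / n, NA_real_),
         fraction_population = ifelse(N > 0, K / N, NA_real_),
         p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Overlap partition of two identifier sets
#'
#' @param targets_a,targets_b Character vectors of identifiers.
#' @return One-row tibble `shared`, `unique_a`, `unique_b`.
#' @export
dataset_overlap <- function(targets_a, targets_b) {
  a <- unique(targets_a)
  b <- unique(targets_b)
  tibble(shared = length(intersect(a, b)),
         unique_a = length(setdiff(a, b)),
         unique_b = length(setdiff(b, a)))
}

#' Call direct targets from binding, response, and differentiation evidence
#'
#' A direct target is an event that is knockdown-responsive, carries a
#' nearby binding cluster, and changes during differentiation, with
#' concordant direction between the two splicing contrasts.  Events where
#' both contrasts pass but disagree in sign are flagged as conflicts,
#' classed `other`, and excluded from the tally (their count is reported).
#'
#' @param kd_result [diff_splice()] result for the knockdown contrast
#'   (knockdown minus control).
#' @param bound Tibble `event_id`, `bound` from [associate_clusters()].
#' @param diff_result [diff_splice()] result for the differentiation
#'   contrast (differentiated minus progenitor).
#' @return Tibble `event_id`, `responsive`, `bound`,
#'   `differentiation_changed`, `direction`, `conflict`, `direct_target`,
#'   with the direction tally (`n_repressed`, `n_activated`, `total`)
#'   attached as attribute `tally` (see [target_tally()]).
#' @export
define_direct_targets <- function(kd_result, bound, diff_result) {
  out <- kd_result |>
    select("event_id", kd_passes = "passes", kd_delta = "delta_psi") |>
    full_join(select(diff_result, "event_id", diff_passes = "passes",
                     diff_delta = "delta_psi"),
              by = "event_id") |>
    left_join(select(bound, "event_id", "bound"), by = "event_id") |>
    mutate(
      responsive = dplyr::coalesce(.data$kd_passes, FALSE),
      bound = dplyr::coalesce(.data$bound, FALSE),
      differentiation_changed = dplyr::coalesce(.data$diff_passes, FALSE),
      conflict = .data$responsive & .data$differentiation_changed &
        sign(.data$kd_delta) != sign(.data$diff_delta),
      direction = dplyr::case_when(
        .data$conflict ~ NA_character_,
        .data$responsive & .data$kd_delta > 0 ~ "repressed",
        .data$responsive & .data$kd_delta < 0 ~ "activated",
        .default = NA_character_
      ),
      direct_target = .data$responsive & .data$bound &
        .data$differentiation_changed & !.data$conflict
    ) |>
    select("event_id", "responsive", "bound", "differentiation_changed",
           "direction", "conflict", "direct_target")
  n_conflict <- sum(out$conflict)
  if (n_conflict > 0) {
    inform(paste0(n_conflict, " event(s) with discordant knockdown/",
                  "differentiation direction were excluded"))
  }
  dt <- filter(out, .data$direct_target)
  attr(out, "tally") <- tibble(
    n_repressed = sum(dt$direction == "repressed"),
    n_activated = sum(dt$direction == "activated"),
    total = nrow(dt)
  )
  out
}

#' Direction tally of a direct-target table
#'
#' @param targets Result of [define_direct_targets()].
#' @return One-row tibble `n_repressed`, `n_activated`, `total`.
#' @export
target_tally <- function(targets) attr(targets, "tally")

# Welch's unequal-variance t-test with the degenerate-input convention:
# both groups constant -> p = 1 when the means agree, p = 0 otherwise
welch_test <- function(x, y) {
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  fit <- t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), p = fit$p.value)
}

#' Expression changes from a normalized FPKM table
#'
#' Per gene, the fold change is the ratio of group mean FPKM
#' (test over reference) with a pseudocount added to both, and significance
#' is a two-sided Welch's unequal-variance t-test on the raw FPKM values.
#' At each cutoff `c`, a gene is `induced` when `fold_change >= c` and
#' `p < p_cutoff`, `repressed` when `fold_change <= 1/c` and `p < p_cutoff`,
#' otherwise `unchanged`.  Genes with fewer than two replicates in either
#' group are skipped (count reported).
#'
#' @param fpkm Tibble `gene_id`, `group`, `replicate`, `fpkm`.
#' @param test,reference Group labels (fold change is test over reference).
#' @param cutoffs Fold-change cutoffs; one class column per cutoff.
#' @param pseudocount FPKM pseudocount guarding against division by zero.
#' @param p_cutoff Welch p-value threshold.
#' @return Tibble `gene_id`, `mean_reference`, `mean_test`, `fold_change`,
#'   `welch_t`, `welch_p`, and a `class_<cutoff>` column per cutoff.
#' @export
expression_changes <- function(fpkm, test = "mutant", reference = "wild_type",
                               cutoffs = c(2.0, 1.5), pseudocount = 0.1,
                               p_cutoff = 0.05) {
  wide <- fpkm |>
    filter(.data$group %in% c(test, reference)) |>
    group_by(.data$gene_id) |>
    summarise(
      x = list(.data$fpkm[.data$group == reference]),
      y = list(.data$fpkm[.data$group == test]),
      .groups = "drop"
    )
  enough <- map_int(wide$x, length) >= 2 & map_int(wide$y, length) >= 2
  if (any(!enough)) {
    inform(paste0(sum(!enough), " gene(s) with fewer than 2 replicates per ",
                  "group were skipped"))
    wide <- wide[enough, ]
  }
  tests <- map2(wide$x, wide$y, welch_test)
  out <- tibble(
    gene_id = wide$gene_id,
    mean_reference = map_dbl(wide$x, mean),
    mean_test = map_dbl(wide$y, mean),
    welch_t = map_dbl(tests, function(t) -t$t),  # sign: test minus reference
    welch_p = map_dbl(tests, "p")
  ) |>
    mutate(fold_change = (.data$mean_test + pseudocount) /
             (.data$mean_reference + pseudocount))
  for (co in cutoffs) {
    out[[sprintf("class_%g", co)]] <- dplyr::case_when(
      out$fold_change >= co & out$welch_p < p_cutoff ~ "induced",
      out$fold_change <= 1 / co & out$welch_p < p_cutoff ~ "repressed",
      .default = "unchanged"
    )
  }
  select(out, "gene_id", "mean_reference", "mean_test", "fold_change",
         "welch_t", "welch_p", everything())
}

#' Genes considered expressed
#'
#' The background population for enrichment tests: genes with mean FPKM of
#' at least `min_fpkm` in either group.
#'
#' @param fpkm Tibble `gene_id`, `group`, `fpkm`.
#' @param min_fpkm Expression floor in FPKM.
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(fpkm, min_fpkm = 1) {
  fpkm |>
    group_by(.data$gene_id, .data$group) |>
    summarise(m = mean(.data$fpkm), .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(expressed = any(.data$m >= min_fpkm), .groups = "drop") |>
    filter(.data$expressed) |>
    pull("gene_id")
}

#' Assign ChIP clusters to genes and test enrichment in a gene set
#'
#' A gene is ChIP-bound when any cluster overlaps (>= 1 nt) its span
#' extended `window` nt on both sides, irrespective of strand.  Enrichment
#' of bound genes within `sample_genes` against the expressed-gene
#' population is an upper-tail hypergeometric test.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param chip_clusters Interval tibble of ChIP clusters.
#' @param window Window in nt on each side of the gene span.
#' @param sample_genes Character vector: the gene set tested for enrichment
#'   (e.g. induced genes).
#' @param population Character vector: the expressed-gene background
#'   (defaults to all genes in `genes`).
#' @return List with `assignments` (tibble `gene_id`, `bound`) and
#'   `enrichment` (one-row tibble from [hypergeom_enrichment()]).
#' @export
chip_gene_overlap <- function(genes, chip_clusters, window = 1000L,
                              sample_genes = character(),
                              population = NULL) {
  population <- population %||% genes$gene_id
  if (length(population) == 0) abort("empty expressed-gene population")
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start + 1L - as.integer(window)),
                     genes$end + as.integer(window))
  )
  bound <- rep(FALSE, nrow(genes))
  if (nrow(chip_clusters) > 0) {
    hits <- GenomicRanges::findOverlaps(win, tbl_to_gr(chip_clusters),
                                        ignore.strand = TRUE)
    bound[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  assignments <- tibble(gene_id = genes$gene_id, bound = bound)
  pop <- filter(assignments, .data$gene_id %in% population)
  samp <- filter(pop, .data$gene_id %in% sample_genes)
  enrichment <- hypergeom_enrichment(
    N = nrow(pop), K = sum(pop$bound),
    n = nrow(samp), k = sum(samp$bound)
  )
  list(assignments = assignments, enrichment = enrichment)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes deduplication, crosslink-site calling, positional FDR, cluster
#' building and filtering, motif enrichment, PSI and differential splicing
#' for the knockdown and differentiation contrasts, cluster-to-event
#' association, direct-target calling, expression changes, and ChIP
#' enrichment.  Fully reproducible given the configuration seed.
#'
#' @param config A [simulation_config()].
#' @param n_perm Permutations for the positional FDR.
#' @param min_cluster_reads Cluster support filter.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there as BED/TSV plus a plain-text summary.
#' @return An object of class `clip_pipeline`: a list of stage results
#'   (`sim`, `reads`, `sites`, `clusters`, `filtered_clusters`, `motifs`,
#'   `psi`, `kd`, `diff`, `quadrants`, `bound`, `targets`, `expression`,
#'   `chip`, `summary`).  Use [tidy()] for the per-event target table,
#'   [glance()] for the one-row summary, and [autoplot()] for the quadrant
#'   scatter.
#' @export
run_pipeline <- function(config = simulation_config(), n_perm = 100L,
                         min_cluster_reads = 4L, out_dir = NULL) {
  sim <- simulate_dataset(config)
  reads <- deduplicate_reads(sim$reads)
  sites <- call_crosslink_sites(reads)
  sites <- assign_site_fdr(sites, sim$genes, n_perm = n_perm,
                           seed = config$seed + 5L)
  sig <- filter(sites, .data$significant)
  clusters <- build_clusters(sig)
  fclusters <- filter_clusters(clusters, min_cluster_reads)
  motifs <- pentamer_zscores(sig, sim$genome, sim$introns,
                             seed = config$seed + 6L)
  psi <- estimate_psi(sim$junctions)
  kd <- diff_splice(sim$junctions, "control", "knockdown")
  dif <- diff_splice(sim$junctions, "progenitor", "neuron")
  quad <- classify_quadrant(kd, dif)
  ev <- semi_join(sim$events, distinct(sim$junctions, .data$event_id),
                  by = "event_id")
  bound <- associate_clusters(ev, fclusters)
  targets <- define_direct_targets(kd, bound, dif)
  expr <- expression_changes(sim$fpkm)
  induced <- expr$gene_id[expr$class_1.5 == "induced"]
  chip <- chip_gene_overlap(sim$genes, sim$chip, window = 1000L,
                            sample_genes = induced,
                            population = expressed_genes(sim$fpkm))
  tally <- target_tally(targets)
  summary <- tibble(
    n_reads = nrow(sim$reads), n_unique_reads = nrow(reads),
    n_sites = nrow(sites), n_significant_sites = sum(sites$significant),
    n_clusters = nrow(clusters), n_filtered_clusters = nrow(fclusters),
    top_pentamer = motifs$pentamer[1], top_pentamer_z = motifs$z[1],
    n_kd_responsive = sum(kd$passes), n_diff_changed = sum(dif$passes),
    n_bound_events = sum(bound$bound),
    n_direct_targets = tally$total,
    n_direct_repressed = tally$n_repressed,
    n_direct_activated = tally$n_activated,
    n_induced_genes = length(induced),
    chip_enrichment_p = chip$enrichment$p_value
  )
  res <- structure(
    list(config = config, sim = sim, reads = reads, sites = sites,
         clusters = clusters, filtered_clusters = fclusters, motifs = motifs,
         psi = psi, kd = kd, diff = dif, quadrants = quad, bound = bound,
         targets = targets, expression = expr, chip = chip, summary = summary),
    class = "clip_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_sites_bed(res$sites, p("crosslink_sites.bed"))
  write_clusters_bed(res$filtered_clusters, p("clusters.bed"))
  readr::write_tsv(res$motifs, p("pentamer_zscores.tsv"))
  readr::write_tsv(res$psi, p("psi.tsv"))
  readr::write_tsv(res$kd, p("diffsplice_knockdown.tsv"))
  readr::write_tsv(res$diff, p("diffsplice_differentiation.tsv"))
  readr::write_tsv(res$targets, p("direct_targets.tsv"))
  readr::write_tsv(res$expression, p("expression_changes.tsv"))
  readr::write_tsv(res$chip$assignments, p("chip_assignments.tsv"))
  s <- res$summary
  writeLines(c("clipsplice pipeline summary",
               paste0(names(s), ": ", vapply(s, format, ""))),
             p("summary.txt"))
  invisible(dir)
}

#' Compare recovered direct targets with the simulation ground truth
#'
#' @param result A `clip_pipeline` object.
#' @return One-row tibble with `n_true`, `n_called`, `n_correct`,
#'   `sensitivity`, `precision`.
#' @export
evaluate_recovery <- function(result) {
  truth <- result$sim$truth$events
  true_ids <- truth$event_id[truth$class %in%
                               c("direct_repressed", "direct_activated")]
  called <- filter(result$targets, .data$direct_target)$event_id
  tp <- length(intersect(true_ids, called))
  tibble(n_true = length(true_ids), n_called = length(called),
         n_correct = tp,
         sensitivity = tp / length(true_ids),
         precision = ifelse(length(called) > 0, tp / length(called), NA_real_))
}

#' @export
print.clip_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<clip_pipeline>\n")
  cat(sprintf("  reads: %d (%d unique molecules)\n", s$n_reads, s$n_unique_reads))
  cat(sprintf("  crosslink sites: %d (%d significant at FDR < 0.01)\n",
              s$n_sites, s$n_significant_sites))
  cat(sprintf("  clusters: %d (%d with >= 4 significant reads)\n",
              s$n_clusters, s$n_filtered_clusters))
  cat(sprintf("  top pentamer: %s (z = %.1f)\n", s$top_pentamer, s$top_pentamer_z))
  cat(sprintf("  knockdown-responsive events: %d; differentiation-changed: %d\n",
              s$n_kd_responsive, s$n_diff_changed))
  cat(sprintf("  direct targets: %d (%d repressed, %d activated)\n",
              s$n_direct_targets, s$n_direct_repressed, s$n_direct_activated))
  cat(sprintf("  ChIP enrichment in induced genes: p = %.3g\n",
              s$chip_enrichment_p))
  invisible(x)
}

#' Tidy the per-event results of a pipeline run
#'
#' One row per cassette event with both splicing contrasts, the binding
#' flag, quadrant, and the direct-target call.
#'
#' @param x A `clip_pipeline` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy clip_pipeline
#' @export
tidy.clip_pipeline <- function(x, ...) {
  x$targets |>
    left_join(select(x$kd, "event_id", delta_psi_kd = "delta_psi",
                     p_kd = "p_value"), by = "event_id") |>
    left_join(select(x$diff, "event_id", delta_psi_diff = "delta_psi",
                     p_diff = "p_value"), by = "event_id") |>
    left_join(select(x$quadrants, "event_id", "quadrant"), by = "event_id")
}

#' One-row summary of a pipeline run
#'
#' @param x A `clip_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance clip_pipeline
#' @export
glance.clip_pipeline <- function(x, ...) x$summary
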