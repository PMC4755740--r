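# Generator properties: determinism, containment, the truncation read model,
# barcode bookkeeping, junction-count calibration, expression and ChIP truth.

test_that("minimal configuration yields one gene and one designated event", {
  cfg <- simulation_config(n_genes = 1, n_cassette_events = 1,
                           n_binding_sites = 1, n_direct_repressed = 1,
                           n_direct_activated = 0, n_responsive_unbound = 0,
                           n_diff_only = 0, n_induced_strong = 1,
                           n_induced_mild = 0, n_repressed_genes = 0)
  sim <- simulate_annotation(cfg)
  expect_equal(nrow(sim$genes), 1)
  expect_equal(nrow(sim$truth$events), 1)
})

test_that("equal seeds give byte-identical output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(small_config(seed = 7L)), d1)
  write_dataset(simulate_dataset(small_config(seed = 7L)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("generated coordinates are internally consistent", {
  sim <- simulate_annotation(small_config())
  ex <- dplyr::left_join(sim$exons,
                         dplyr::select(sim$genes, gene_id,
                                       g_start = start, g_end = end),
                         by = "gene_id")
  expect_true(all(ex$start >= ex$g_start & ex$end <= ex$g_end))
  # genome covers every gene
  glen <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  expect_true(all(sim$genes$end <= glen[sim$genes$chrom]))
  # every planted site lies inside its host gene span
  st <- dplyr::left_join(sim$truth$sites,
                         dplyr::select(sim$genes, gene_id,
                                       g_start = start, g_end = end),
                         by = "gene_id")
  expect_true(all(st$pos >= st$g_start & st$pos < st$g_end))
})

test_that("every bound event has its planted site inside the 500-nt upstream flank", {
  sim <- simulate_annotation(small_config())
  fl <- event_flank(
    dplyr::semi_join(sim$events, sim$truth$sites, by = "event_id"),
    "upstream_intron", 500)
  joined <- dplyr::left_join(sim$truth$sites, fl, by = "event_id")
  expect_true(all(joined$pos >= joined$start & joined$pos < joined$end))
})

test_that("reads follow the truncation model around planted sites", {
  cfg <- small_config(background_read_rate = 0, pcr_duplication_rate = 0)
  ann <- simulate_annotation(cfg)
  reads <- simulate_iclip_reads(cfg, ann)
  plus_sites <- ann$truth$sites[ann$truth$sites$strand == "+", ]
  plus_reads <- reads[reads$strand == "+", ]
  expect_setequal(unique(plus_reads$start), plus_sites$pos + 1L)
  minus_sites <- ann$truth$sites[ann$truth$sites$strand == "-", ]
  minus_reads <- reads[reads$strand == "-", ]
  expect_setequal(unique(minus_reads$end), minus_sites$pos)
})

test_that("deduplication recovers the exact pre-amplification molecule count", {
  cfg <- small_config(pcr_duplication_rate = 1.5)
  ann <- simulate_annotation(cfg)
  reads <- simulate_iclip_reads(cfg, ann)
  n_molecules <- length(unique(reads$molecule_id))
  expect_gt(nrow(reads), n_molecules)  # duplication actually happened
  expect_equal(nrow(deduplicate_reads(reads)), n_molecules)

  cfg0 <- small_config(pcr_duplication_rate = 0)
  ann0 <- simulate_annotation(cfg0)
  reads0 <- simulate_iclip_reads(cfg0, ann0)
  expect_equal(nrow(deduplicate_reads(reads0)), nrow(reads0))
})

test_that("junction counts hit the PSI boundaries and expected depth", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  # force boundary PSI values
  ann$truth$events$psi_control <- 100
  ann$truth$events$psi_knockdown <- 0
  jc <- simulate_junction_counts(cfg, ann)
  expect_true(all(jc$E[jc$condition == "control"] == 0))
  expect_true(all(jc$I1[jc$condition == "knockdown"] == 0))
  expect_true(all(jc$I2[jc$condition == "knockdown"] == 0))
})

test_that("estimated PSI is within 3 binomial standard errors at high depth", {
  cfg <- small_config(junction_depth = 10000, n_junction_replicates = 1)
  ann <- simulate_annotation(cfg)
  jc <- simulate_junction_counts(cfg, ann)
  est <- estimate_psi(jc)
  truth_long <- tidyr::pivot_longer(
    ann$truth$events[, c("event_id", "psi_control", "psi_knockdown",
                         "psi_progenitor", "psi_neuron")],
    -event_id, names_to = "condition", names_prefix = "psi_",
    values_to = "true_psi")
  # number of transcripts observed: each contributes I1 (included) or E
  depth <- jc |>
    dplyr::group_by(event_id, condition) |>
    dplyr::summarise(n_tx = sum(I1 + E), .groups = "drop")
  cmp <- dplyr::inner_join(est, truth_long, by = c("event_id", "condition")) |>
    dplyr::inner_join(depth, by = c("event_id", "condition"))
  p <- cmp$true_psi / 100
  se <- 100 * sqrt(p * (1 - p) / cmp$n_tx)
  frac_ok <- mean(abs(cmp$psi - cmp$true_psi) <= pmax(3 * se, 1e-9))
  expect_gte(frac_ok, 0.99)
})

test_that("planted expression fold-changes shape the group means", {
  cfg <- small_config(fpkm_sdlog = 0.05)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression_table(cfg, ann)
  means <- expr$fpkm |>
    dplyr::group_by(gene_id, group) |>
    dplyr::summarise(m = mean(fpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m) |>
    dplyr::inner_join(expr$truth, by = "gene_id")
  strong <- means[means$expr_class == "induced_strong", ]
  expect_true(all(strong$mutant / strong$wild_type > 2))
  null <- means[means$expr_class == "unchanged", ]
  expect_true(all(null$mutant / null$wild_type < 1.5))
  expect_true(all(null$mutant / null$wild_type > 1 / 1.5))
})

test_that("ChIP clusters respect the bound-gene truth and the 1-kb window", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression_table(cfg, ann)

  none <- simulate_chip_clusters(
    small_config(chip_bound_fraction = 0, chip_bound_fraction_induced = 0),
    ann, expr$truth)
  expect_equal(length(none$bound_genes), 0)
  expect_true(all(startsWith(none$clusters$name, "decoy_")))

  all_bound <- simulate_chip_clusters(
    small_config(chip_bound_fraction = 1, chip_bound_fraction_induced = 1),
    ann, expr$truth)
  res <- chip_gene_overlap(ann$genes, all_bound$clusters,
                           sample_genes = ann$genes$gene_id)
  expect_true(all(res$assignments$bound))

  # decoys 2 kb past a gene span never confer bound status
  decoy_only <- none$clusters
  res0 <- chip_gene_overlap(ann$genes, decoy_only,
                            sample_genes = ann$genes$gene_id)
  expect_false(any(res0$assignments$bound))
})

test_that("the truth manifest is consistent with the emitted junction table", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  # every designated truth event has junction rows for all four conditions
  per_event <- dplyr::count(sim$junctions, event_id, condition)
  expect_setequal(unique(sim$junctions$event_id), sim$truth$events$event_id)
  expect_true(all(per_event$n == cfg$n_junction_replicates))
  # planted motif occurs in the genome around each planted site
  seqs <- as.character(sim$genome)
  for (i in seq_len(nrow(sim$truth$sites))) {
    s <- sim$truth$sites[i, ]
    win <- substr(seqs[[s$chrom]], s$pos - 29, s$pos + 31)
    if (s$strand == "-") {
      win <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    }
    expect_true(grepl(s$motif, win, fixed = TRUE))
  }
})

test_that("infeasible configurations are rejected with explanations", {
  expect_error(simulation_config(intron_length_range = c(300, 600)),
               "flank-bound")
  expect_error(simulation_config(n_cassette_events = 10, n_genes = 5),
               "exceed")
  expect_error(simulation_config(n_binding_sites = 2, n_direct_repressed = 3,
                                 n_direct_activated = 0),
               "direct targets")
  expect_error(simulation_config(barcode_random_length = 0))
})
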