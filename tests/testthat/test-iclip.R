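# Deduplication, crosslink-site calling, positional FDR, clusters, motifs.

mk_reads <- function(start, end, strand = "+", barcode = "AAAA",
                     chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                 barcode = barcode)
}

test_that("deduplication collapses only identical (position, strand, barcode)", {
  same <- mk_reads(c(100, 100), c(135, 135))
  expect_equal(nrow(deduplicate_reads(same)), 1)
  diff_bc <- mk_reads(c(100, 100), c(135, 135), barcode = c("AAAA", "CCCC"))
  expect_equal(nrow(deduplicate_reads(diff_bc)), 2)
  diff_start <- mk_reads(c(100, 101), c(135, 136))
  expect_equal(nrow(deduplicate_reads(diff_start)), 2)
  # minus-strand reads collapse on the alignment end, not start
  minus_same <- mk_reads(c(100, 102), c(140, 140), strand = "-")
  expect_equal(nrow(deduplicate_reads(minus_same)), 1)
  # a missing barcode is rejected with the count reported
  nobc <- mk_reads(c(100, 200), c(135, 235), barcode = c("AAAA", NA))
  expect_warning(out <- deduplicate_reads(nobc), "1 read")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_rejected"), 1L)
})

test_that("deduplication matches the pairwise-comparison oracle on random reads", {
  set.seed(11)
  for (n in c(200, 1000)) {
    reads <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample(50:70, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      barcode = sample(c("AA", "AC", "AG", "AT"), n, replace = TRUE)
    ) |>
      dplyr::mutate(end = start + 35L)
    expect_equal(nrow(deduplicate_reads(reads)), oracle_dedup_count(reads))
  }
})

test_that("crosslink sites sit one nucleotide upstream in transcript orientation", {
  plus <- call_crosslink_sites(mk_reads(101, 131))
  expect_equal(plus$pos, 100)
  minus <- call_crosslink_sites(mk_reads(200, 230, strand = "-"))
  expect_equal(minus$pos, 230)
  # aggregation: three unique reads sharing a start give height 3
  three <- mk_reads(rep(101, 3), rep(131, 3), barcode = c("AA", "CC", "GG"))
  sites <- call_crosslink_sites(deduplicate_reads(three))
  expect_equal(sites$height, 3)
  # reads at the contig edge are skipped with a warning
  edge <- mk_reads(0, 30)
  expect_warning(out <- call_crosslink_sites(edge), "contig edge")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("site heights conserve the unique read count", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  uniq <- deduplicate_reads(sim$reads)
  sites <- call_crosslink_sites(uniq)
  expect_equal(sum(sites$height), nrow(uniq) - attr(sites, "n_skipped"))
})

test_that("an isolated tall spike is significant; uniform saturation is not", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                          end = 10000L, strand = "+")
  spike <- tibble::tibble(chrom = "chr1", pos = 5000L, strand = "+",
                          height = 50L)
  res <- assign_site_fdr(spike, genes, n_perm = 100, seed = 3)
  expect_lt(res$fdr, 0.01)
  expect_true(res$significant)

  # every position covered once: observed structure is what uniform
  # placement produces, so nothing stands out
  sat <- tibble::tibble(chrom = "chr1", pos = 0:9999, strand = "+",
                        height = 1L)
  res <- assign_site_fdr(sat, genes, n_perm = 20, seed = 3)
  expect_true(all(res$fdr > 0.5))
  expect_false(any(res$significant))

  # no sites in, none out
  none <- spike[0, ]
  expect_equal(nrow(assign_site_fdr(none, genes)), 0)
})

test_that("FDR is monotone non-increasing in height within a gene", {
  set.seed(5)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                          end = 5000L, strand = "+")
  pos <- sample.int(5000, 400, replace = TRUE) - 1L
  sites <- dplyr::count(tibble::tibble(pos = pos), pos, name = "height") |>
    dplyr::mutate(chrom = "chr1", strand = "+", pos = as.integer(pos))
  res <- assign_site_fdr(sites, genes, n_perm = 50, seed = 9)
  byh <- res |>
    dplyr::group_by(height) |>
    dplyr::summarise(fdr = unique(fdr)) |>
    dplyr::arrange(height)
  expect_true(all(diff(byh$fdr) <= 1e-12))
})

test_that("sites outside every gene model are excluded and reported", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                          end = 1000L, strand = "+")
  sites <- tibble::tibble(chrom = "chr1", pos = c(500L, 5000L),
                          strand = "+", height = c(10L, 10L))
  expect_message(res <- assign_site_fdr(sites, genes, n_perm = 10),
                 "outside all gene models")
  expect_equal(res$pos, 500L)
})

test_that("clusters merge overlapping 20-nt extensions and sum member heights", {
  s2 <- tibble::tibble(chrom = "chr1", pos = c(100L, 130L), strand = "+",
                       height = c(3L, 2L))
  cl <- build_clusters(s2)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(80, 151))
  expect_equal(cl$significant_read_total, 5)

  far <- tibble::tibble(chrom = "chr1", pos = c(100L, 150L), strand = "+",
                        height = c(3L, 2L))
  cl <- build_clusters(far)
  expect_equal(cl$start, c(80, 130))
  expect_equal(cl$end, c(121, 171))

  single <- tibble::tibble(chrom = "chr1", pos = 100L, strand = "+",
                           height = 5L)
  cl <- build_clusters(single)
  expect_equal(cl$end - cl$start, 41)
  expect_equal(cl$significant_read_total, 5)

  expect_error(build_clusters(single, extension = -1), ">= 0")
})

test_that("clusters are strand-specific and disjoint, covering each site once", {
  set.seed(21)
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = sample.int(2000, 120, replace = TRUE),
    strand = sample(c("+", "-"), 120, replace = TRUE),
    height = sample(1:5, 120, replace = TRUE)
  ) |> dplyr::distinct(chrom, pos, strand, .keep_all = TRUE)
  cl <- build_clusters(sites)
  for (s in c("+", "-")) {
    d <- dplyr::arrange(cl[cl$strand == s, ], start)
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= head(d$end, -1)))
    # each site of this strand in exactly one cluster
    within <- vapply(sites$pos[sites$strand == s], function(p)
      sum(p >= d$start & p < d$end), 0L)
    expect_true(all(within == 1))
  }
  expect_equal(sum(cl$significant_read_total), sum(sites$height))
})

test_that("cluster filtering keeps totals at or above the read threshold", {
  cl <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(41L, 91L),
                       strand = "+", gene_id = NA_character_,
                       n_sites = c(2L, 1L),
                       significant_read_total = c(4L, 3L))
  expect_equal(nrow(filter_clusters(cl, 4)), 1)   # 4 >= 4 kept, 3 dropped
  expect_equal(nrow(filter_clusters(cl, 0)), 2)   # identity filter
  expect_error(filter_clusters(cl, -1), ">= 0")
})

test_that("pentamer z-scores recover a planted motif and handle degeneracy", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  sites <- sim$truth$sites |>
    dplyr::rename(site_gene = gene_id)
  z <- pentamer_zscores(sites, sim$genome, sim$introns, n_rand = 50, seed = 2)
  expect_equal(nrow(z), 1024)
  expect_equal(z$pentamer[1], "TCTCT")  # planted motif attains the top rank
  # z = 0 whenever observed equals the null mean by formula
  exact_zero <- z[abs(z$observed - z$null_mean) < 1e-12 & z$null_sd > 0, ]
  if (nrow(exact_zero) > 0) expect_true(all(exact_zero$z == 0))
  expect_true(all(is.infinite(z$z[z$degenerate])))
})

test_that("sites outside introns are excluded from the motif analysis", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  exonic <- tibble::tibble(chrom = sim$exons$chrom[1],
                           pos = sim$exons$start[1] + 5L,
                           strand = sim$exons$strand[1])
  expect_message(
    z <- pentamer_zscores(exonic, sim$genome, sim$introns, n_rand = 5),
    "outside introns")
  expect_equal(nrow(z), 1024)
  expect_true(all(z$observed == 0))
})
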