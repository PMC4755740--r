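# iCLIP analysis: PCR-duplicate removal via random barcodes, crosslink-site
# calling under the truncation model, permutation-based positional FDR,
# cluster building, and pentamer motif enrichment against intron-matched
# random intervals.

#' Remove PCR duplicates by random barcode
#'
#' Reads sharing chromosome, strand, crosslink-defining start (the alignment
#' start on the plus strand, the alignment end on the minus strand), and
#' random barcode are collapsed to one molecule.  Reads with a missing
#' barcode are rejected and their count reported.
#'
#' @param reads Tibble with `chrom`, `start`, `end`, `strand`, `barcode`.
#' @return Deduplicated read tibble, sorted; the number of barcode-less
#'   records dropped is attached as attribute `n_rejected`.
#' @export
deduplicate_reads <- function(reads) {
  missing_bc <- is.na(reads$barcode) | reads$barcode == ""
  if (any(missing_bc)) {
    warn(paste0(sum(missing_bc), " read(s) without a barcode were rejected"))
    reads <- reads[!missing_bc, ]
  }
  out <- reads |>
    mutate(.tx_start = ifelse(.data$strand == "+", .data$start, .data$end)) |>
    group_by(.data$chrom, .data$.tx_start, .data$strand, .data$barcode) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$chrom, .data$start, .data$strand, .data$barcode) |>
    select(-".tx_start")
  attr(out, "n_rejected") <- sum(missing_bc)
  out
}

#' Call crosslink sites from deduplicated reads
#'
#' Under the iCLIP truncation model the crosslinked nucleotide is the one
#' transcript-orientation upstream of the read start: a plus-strand read
#' starting at genomic `s` maps its crosslink to `s - 1`; a minus-strand
#' alignment `[a, b)` maps it to `b`.  Heights count unique reads per
#' (chrom, position, strand).
#'
#' @param reads Deduplicated read tibble.
#' @return Site tibble `chrom`, `pos` (0-based), `strand`, `height`.  Reads
#'   whose crosslink would fall before position 0 are skipped; their count is
#'   in attribute `n_skipped`.
#' @export
call_crosslink_sites <- function(reads) {
  if (nrow(reads) == 0) {
    out <- tibble(chrom = character(), pos = integer(), strand = character(),
                  height = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  pos <- ifelse(reads$strand == "+", reads$start - 1L, reads$end)
  skip <- pos < 0
  if (any(skip)) {
    warn(paste0(sum(skip), " read(s) at a contig edge were skipped"))
  }
  out <- tibble(chrom = reads$chrom[!skip], pos = as.integer(pos[!skip]),
                strand = reads$strand[!skip]) |>
    count(.data$chrom, .data$pos, .data$strand, name = "height") |>
    arrange(.data$chrom, .data$pos, .data$strand)
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Assign a permutation-based positional FDR to crosslink sites
#'
#' Within each gene, the observed crosslink events (one per unique read,
#' `T` in total) are compared with `n_perm` randomizations in which `T`
#' events are placed uniformly over the gene span.  For each height `h`,
#' `FDR(h)` is the mean permuted number of positions of height at least `h`
#' divided by the observed number, capped at 1 and made non-increasing in
#' `h`.  A site is significant when its FDR falls below `fdr_cutoff`.
#'
#' @param sites Site tibble from [call_crosslink_sites()].
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param n_perm Number of permutations (>= 1).
#' @param fdr_cutoff Significance cutoff on the FDR.
#' @param seed RNG seed for the permutations.
#' @return Site tibble with `gene_id`, `fdr`, `significant` added.  Sites
#'   outside every gene model are excluded and their count reported.
#' @export
assign_site_fdr <- function(sites, genes, n_perm = 100, fdr_cutoff = 0.01,
                            seed = 1L) {
  stopifnot(n_perm >= 1)
  if (nrow(sites) == 0) {
    return(mutate(sites, gene_id = character(), fdr = numeric(),
                  significant = logical()))
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, sites$pos + 1L),
                                    strand = sites$strand)
  gene_gr <- tbl_to_gr(genes)
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = FALSE)
  first <- !duplicated(S4Vectors::queryHits(hits))
  gene_of <- rep(NA_character_, nrow(sites))
  gene_of[S4Vectors::queryHits(hits)[first]] <-
    genes$gene_id[S4Vectors::subjectHits(hits)[first]]
  n_unassigned <- sum(is.na(gene_of))
  if (n_unassigned > 0) {
    inform(paste0(n_unassigned, " site(s) outside all gene models were ",
                  "excluded from the FDR computation"))
  }
  sites$gene_id <- gene_of
  sites <- filter(sites, !is.na(.data$gene_id))
  if (nrow(sites) == 0) {
    return(mutate(sites, fdr = numeric(), significant = logical()))
  }

  set.seed(seed)
  span <- setNames(genes$end - genes$start, genes$gene_id)
  out <- sites |>
    group_by(.data$gene_id) |>
    group_modify(function(d, key) {
      d$fdr <- gene_fdr(d$height, L = span[[key$gene_id]], n_perm = n_perm)
      d
    }) |>
    ungroup() |>
    mutate(significant = .data$fdr < fdr_cutoff) |>
    select("chrom", "pos", "strand", "gene_id", "height", "fdr", "significant") |>
    arrange(.data$chrom, .data$pos)
  out
}

# FDR per observed height within one gene of span L
gene_fdr <- function(heights, L, n_perm) {
  max_h <- max(heights)
  total <- sum(heights)
  # observed number of positions with height >= h, h = 1..max_h
  obs_ge <- rev(cumsum(rev(tabulate(heights, nbins = max_h))))
  perm_ge <- numeric(max_h)
  for (p in seq_len(n_perm)) {
    cnt <- tabulate(sample.int(L, total, replace = TRUE), nbins = L)
    hh <- pmin.int(cnt[cnt > 0L], max_h)
    perm_ge <- perm_ge + rev(cumsum(rev(tabulate(hh, nbins = max_h))))
  }
  fdr_h <- pmin(1, (perm_ge / n_perm) / obs_ge)
  fdr_h <- cummin(fdr_h)  # non-increasing in height
  fdr_h[heights]
}

#' Build binding clusters from significant crosslink sites
#'
#' Each site is extended `extension` nt on both sides (`[pos - ext,
#' pos + ext + 1)`) and overlapping extensions are merged, per chromosome and
#' strand.  Abutting extensions are not merged.  The cluster's
#' `significant_read_total` is the sum of its member site heights.
#'
#' @param sites Significant-site tibble (`chrom`, `pos`, `strand`, `height`,
#'   optionally `gene_id`).
#' @param extension Extension in nt (>= 0).
#' @return Cluster tibble `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `n_sites`, `significant_read_total`.
#' @export
build_clusters <- function(sites, extension = 20L) {
  if (extension < 0) abort("extension must be >= 0")
  extension <- as.integer(extension)
  if (!"gene_id" %in% names(sites)) sites$gene_id <- NA_character_
  if (nrow(sites) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  n_sites = integer(), significant_read_total = integer()))
  }
  sites |>
    mutate(start = pmax(0L, .data$pos - extension),
           end = .data$pos + extension + 1L) |>
    arrange(.data$chrom, .data$strand, .data$start, .data$end) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(run_end = cummax(.data$end),
           block = cumsum(.data$start >= lag(.data$run_end, default = -1L))) |>
    group_by(.data$chrom, .data$strand, .data$block) |>
    summarise(start = min(.data$start), end = max(.data$end),
              gene_id = .data$gene_id[1], n_sites = n(),
              significant_read_total = sum(.data$height), .groups = "drop") |>
    select("chrom", "start", "end", "strand", "gene_id", "n_sites",
           "significant_read_total") |>
    arrange(.data$chrom, .data$start)
}

#' Filter clusters by significant-read support
#'
#' Keeps clusters whose member sites carry at least `min_reads` unique reads
#' in total.
#'
#' @param clusters Cluster tibble from [build_clusters()].
#' @param min_reads Minimum summed height (default 4).
#' @return Filtered cluster tibble.
#' @export
filter_clusters <- function(clusters, min_reads = 4L) {
  if (min_reads < 0) abort("min_reads must be >= 0")
  filter(clusters, .data$significant_read_total >= min_reads)
}

#' Pentamer motif enrichment around crosslink sites
#'
#' Sequences `window` nt up- and downstream of each intronic crosslink site
#' (clipped to the host intron, sense strand of the host gene) are scanned
#' for all 1024 overlapping pentamers.  The null distribution draws, in each
#' of `n_rand` replicates, one random interval of the same width uniformly
#' from the same intron per observed window, and `z = (observed - null_mean)
#' / null_sd`.
#'
#' Sites falling outside every intron are skipped (count reported).  When a
#' pentamer's null standard deviation is zero, its `z` is 0 if the observed
#' count equals the null mean and signed infinity otherwise, with the
#' `degenerate` flag set.
#'
#' @param sites Significant-site tibble (`chrom`, `pos`, `strand`).
#' @param genome `DNAStringSet` keyed by chromosome.
#' @param introns Intron tibble from [derive_introns()].
#' @param window Half-window in nt (default 30).
#' @param n_rand Number of null randomization replicates.
#' @param seed RNG seed for the null draws.
#' @return Tibble of 1024 rows: `pentamer`, `observed`, `null_mean`,
#'   `null_sd`, `z`, `degenerate`, sorted by `z` descending.
#' @export
pentamer_zscores <- function(sites, genome, introns, window = 30L,
                             n_rand = 100L, seed = 1L) {
  chrseqs <- as.character(genome)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, sites$pos + 1L),
                                    strand = sites$strand)
  intron_gr <- tbl_to_gr(introns)
  hits <- GenomicRanges::findOverlaps(site_gr, intron_gr, ignore.strand = FALSE)
  first <- !duplicated(S4Vectors::queryHits(hits))
  qi <- S4Vectors::queryHits(hits)[first]
  si <- S4Vectors::subjectHits(hits)[first]
  n_skipped <- nrow(sites) - length(qi)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " site(s) outside introns were excluded from ",
                  "the motif analysis"))
  }
  w <- tibble(
    chrom = sites$chrom[qi],
    strand = sites$strand[qi],
    start = pmax(sites$pos[qi] - as.integer(window), introns$start[si]),
    end = pmin(sites$pos[qi] + as.integer(window) + 1L, introns$end[si]),
    intron_start = introns$start[si],
    intron_end = introns$end[si]
  ) |>
    filter(.data$end > .data$start)

  pent <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 5)
  if (nrow(w) == 0) {
    return(tibble(pentamer = pent, observed = 0L, null_mean = 0,
                  null_sd = 0, z = 0, degenerate = TRUE))
  }
  observed <- count_pentamers(chrseqs, w$chrom, w$start, w$end, w$strand)
  pent <- names(observed)

  set.seed(seed)
  width <- w$end - w$start
  null_counts <- matrix(0, nrow = 1024, ncol = n_rand)
  for (r in seq_len(n_rand)) {
    rs <- w$intron_start +
      as.integer(floor(runif(nrow(w)) * (w$intron_end - w$intron_start - width + 1)))
    null_counts[, r] <- count_pentamers(chrseqs, w$chrom, rs, rs + width, w$strand)
  }
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1, sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd,
              ifelse(observed == null_mean, 0,
                     sign(observed - null_mean) * Inf))
  tibble(pentamer = pent, observed = as.integer(observed),
         null_mean = null_mean, null_sd = null_sd, z = z,
         degenerate = null_sd == 0 & observed != null_mean) |>
    arrange(desc(.data$z), .data$pentamer)
}

# overlapping pentamer counts over sense-strand windows, summed
count_pentamers <- function(chrseqs, chrom, start0, end0, strand) {
  s <- substring(chrseqs[chrom], start0 + 1, end0)
  dss <- Biostrings::DNAStringSet(s)
  neg <- which(strand == "-")
  if (length(neg)) dss[neg] <- Biostrings::reverseComplement(dss[neg])
  colSums(Biostrings::oligonucleotideFrequency(dss, width = 5))
}

#' Write crosslink sites or clusters as BED6
#'
#' Sites: the name field carries the FDR, the score the height.  Clusters:
#' the name is the host gene, the score the significant-read total.
#'
#' @param sites Site tibble with `fdr` and `height`.
#' @param path Output file.
#' @export
write_sites_bed <- function(sites, path) {
  write_bed6(tibble(chrom = sites$chrom, start = sites$pos,
                    end = sites$pos + 1L, strand = sites$strand,
                    name = sprintf("fdr=%.4g", sites$fdr),
                    score = sites$height), path)
}

#' @rdname write_sites_bed
#' @param clusters Cluster tibble from [build_clusters()].
#' @export
write_clusters_bed <- function(clusters, path) {
  write_bed6(tibble(chrom = clusters$chrom, start = clusters$start,
                    end = clusters$end, strand = clusters$strand,
                    name = ifelse(is.na(clusters$gene_id), ".", clusters$gene_id),
                    score = clusters$significant_read_total), path)
}
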