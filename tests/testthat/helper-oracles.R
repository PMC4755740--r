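# Independent oracles and small fixture builders shared across the suite.

# Connected-component oracle for interval merging under the overlap-only
# rule: two intervals join iff they share >= 1 nt; abutment does not join.
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    n <- nrow(d)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (comp[i] != comp[j] &&
              d$start[i] < d$end[j] && d$start[j] < d$end[i]) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    out[[ch]] <- do.call(rbind, lapply(sort(unique(comp)), function(cc) {
      data.frame(chrom = ch, start = min(d$start[comp == cc]),
                 end = max(d$end[comp == cc]), strand = d$strand[1])
    }))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# Pairwise-comparison deduplication oracle: read i is a duplicate iff some
# earlier read matches it on chrom, crosslink-defining start, strand, and
# barcode.
oracle_dedup_count <- function(reads) {
  key_start <- ifelse(reads$strand == "+", reads$start, reads$end)
  n <- nrow(reads)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)[-1]) {
    j <- seq_len(i - 1)
    if (any(reads$chrom[j] == reads$chrom[i] &
            key_start[j] == key_start[i] &
            reads$strand[j] == reads$strand[i] &
            reads$barcode[j] == reads$barcode[i])) {
      keep[i] <- FALSE
    }
  }
  sum(keep)
}

# Closed-form upper-tail hypergeometric probability from binomial
# coefficients (independent of phyper).
oracle_hyper <- function(N, K, n, k) {
  j <- seq(k, min(K, n))
  if (length(j) == 0 || k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exhaustive-enumeration hypergeometric oracle over all C(N, n) samples.
oracle_hyper_enum <- function(N, K, n, k) {
  samples <- utils::combn(N, n)
  marked <- colSums(samples <= K)  # items 1..K are the marked ones
  mean(marked >= k)
}

gtf_exon_line <- function(chrom, start1, end1, strand, gid, tid) {
  sprintf('%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start1, end1, strand, gid, tid)
}

write_gtf_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

random_intervals <- function(n, max_pos = 200, strand = "+") {
  s <- sample.int(max_pos - 2, n, replace = TRUE)
  w <- sample.int(30, n, replace = TRUE)
  tibble::tibble(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                 start = s, end = pmin(s + w, max_pos), strand = strand)
}

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes = 20, n_cassette_events = 20, n_binding_sites = 8,
    n_direct_repressed = 4, n_direct_activated = 2,
    n_responsive_unbound = 4, n_diff_only = 4,
    n_induced_strong = 4, n_induced_mild = 2, n_repressed_genes = 2,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# The study-condition default run is shared by several acceptance checks;
# compute it once per session.
.run_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- suppressMessages(run_pipeline(simulation_config()))
  }
  .run_cache$default
}
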