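# Genomic coordinate arithmetic and the gene / cassette-exon data model.
#
# All intervals inside the package are 0-based half-open [start, end) tibbles
# with columns chrom, start, end, strand.  GTF I/O converts to/from 1-based
# inclusive; BED is native 0-based half-open.  "Upstream"/"downstream" are
# always in transcript orientation (strand-aware).

#' Construct a validated tibble of genomic intervals
#'
#' Intervals are 0-based half-open: `start` is the first base, `end` one past
#' the last, so `width = end - start`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like vectors, `0 <= start < end`.
#' @param strand Character vector, `"+"` or `"-"` (recycled).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+") {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, allow_empty = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  bad_strand <- !x$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(paste0("unknown strand symbol in record(s): ",
                 paste(which(bad_strand), collapse = ", ")))
  }
  bad <- if (allow_empty) x$start > x$end else x$start >= x$end
  if (any(x$start < 0) || any(bad)) {
    abort(paste0("malformed coordinates (need 0 <= start < end) in record(s): ",
                 paste(which(bad | x$start < 0), collapse = ", ")))
  }
  invisible(x)
}

# tibble (0-based half-open) <-> GRanges (1-based closed)
tbl_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
}

gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Merge overlapping genomic intervals
#'
#' Collapses intervals that overlap by at least one nucleotide into their
#' union.  Abutting intervals (gap 0) are *not* merged: merging requires
#' genuine overlap.  All input intervals must be on a single strand; they are
#' grouped by chromosome internally.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, `strand`).
#' @return Tibble of disjoint intervals sorted by chromosome and start, with
#'   an `n_merged` column giving the number of input intervals in each.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_merged = integer()))
  }
  if (length(unique(x$strand)) > 1) {
    abort("merge_intervals() requires a single strand; got mixed strands")
  }
  x |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(
      run_end = cummax(.data$end),
      # new block whenever this interval starts at/after everything seen so
      # far ends: start == previous end is abutment, not overlap
      block = cumsum(.data$start >= lag(.data$run_end, default = -1L))
    ) |>
    group_by(.data$chrom, .data$block) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1], n_merged = n(), .groups = "drop"
    ) |>
    select("chrom", "start", "end", "strand", "n_merged") |>
    arrange(.data$chrom, .data$start)
}

#' Read gene models and cassette-exon events from a GTF file
#'
#' Keeps one model per gene: the transcript with the greatest total exon
#' length (ties broken by transcript id).  Every internal exon of the chosen
#' model, together with its two neighbours, is enumerated as a cassette-exon
#' trio event.
#'
#' @param path GTF file (1-based inclusive coordinates; `exon` features with
#'   `gene_id` and `transcript_id` attributes).
#' @return A list with tibbles `genes` (gene_id, transcript_id, chrom, start,
#'   end, strand), `exons` (gene_id, exon_rank in transcript orientation,
#'   chrom, start, end, strand), and `events` (see [cassette_events()]).
#' @export
read_gene_models <- function(path) {
  if (check_gtf_coords(path) == 0L) {
    return(list(genes = empty_genes(), exons = empty_exons(),
                events = empty_events()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) {
    return(list(genes = empty_genes(), exons = empty_exons(),
                events = empty_events()))
  }
  str <- as.character(GenomicRanges::strand(gr))
  if (any(!str %in% c("+", "-"))) {
    abort("unknown strand symbol in GTF exon record(s)")
  }
  ex <- tibble(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = str
  )
  # longest transcript per gene by summed exon width
  chosen <- ex |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(tx_len = sum(.data$end - .data$start), .groups = "drop") |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$tx_len), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  ex <- semi_join(ex, chosen, by = c("gene_id", "transcript_id"))
  exons <- ex |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (.data$strand[1] == "+") seq_len(n()) else rev(seq_len(n()))) |>
    ungroup() |>
    arrange(.data$gene_id, .data$exon_rank) |>
    select("gene_id", "exon_rank", "chrom", "start", "end", "strand")
  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), strand = .data$strand[1],
              .groups = "drop") |>
    left_join(select(chosen, "gene_id", "transcript_id"), by = "gene_id") |>
    select("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  list(genes = genes, exons = exons, events = cassette_events(exons))
}

# GTF start > end is malformed; report the offending line before IRanges
# turns it into an opaque negative-width error
check_gtf_coords <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) return(0L)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  bad <- which(!is.na(s) & !is.na(e) & s > e)
  if (length(bad)) {
    abort(paste0("malformed GTF coordinates (start > end) at line(s): ",
                 paste(which(body)[bad], collapse = ", ")))
  }
  sum(body)
}

empty_genes <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         chrom = character(), start = integer(), end = integer(),
         strand = character())
}
empty_exons <- function() {
  tibble(gene_id = character(), exon_rank = integer(), chrom = character(),
         start = integer(), end = integer(), strand = character())
}
empty_events <- function() {
  tibble(event_id = character(), gene_id = character(), chrom = character(),
         strand = character(), up_start = integer(), up_end = integer(),
         cas_start = integer(), cas_end = integer(), dn_start = integer(),
         dn_end = integer())
}

#' Enumerate cassette-exon trio events from an exon table
#'
#' Each internal exon of a gene model becomes one event, flanked by its
#' transcript-orientation upstream and downstream neighbours.
#'
#' @param exons Exon tibble as returned by [read_gene_models()].
#' @return Tibble with one row per event: `event_id`, `gene_id`, `chrom`,
#'   `strand`, and genomic (0-based half-open) coordinates of the upstream,
#'   cassette, and downstream exons (`up_*`, `cas_*`, `dn_*`), upstream and
#'   downstream in transcript orientation.
#' @export
cassette_events <- function(exons) {
  if (nrow(exons) == 0) return(empty_events())
  exons |>
    group_by(.data$gene_id) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$exon_rank)
      k <- nrow(d)
      if (k < 3) return(empty_events()[, -2])
      idx <- 2:(k - 1)
      tibble(
        event_id = paste0(key$gene_id, ":cas", idx - 1),
        chrom = d$chrom[1], strand = d$strand[1],
        up_start = d$start[idx - 1], up_end = d$end[idx - 1],
        cas_start = d$start[idx], cas_end = d$end[idx],
        dn_start = d$start[idx + 1], dn_end = d$end[idx + 1]
      )
    }) |>
    ungroup() |>
    select("event_id", "gene_id", "chrom", "strand", "up_start", "up_end",
           "cas_start", "cas_end", "dn_start", "dn_end")
}

#' Derive introns from an exon table
#'
#' @param exons Exon tibble (`gene_id`, `exon_rank`, coordinates).
#' @return Tibble of intron intervals per gene, `intron_rank` in transcript
#'   orientation.
#' @export
derive_introns <- function(exons) {
  if (nrow(exons) == 0) {
    return(tibble(gene_id = character(), intron_rank = integer(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  exons |>
    group_by(.data$gene_id) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$start)
      if (nrow(d) < 2) {
        return(tibble(intron_rank = integer(), chrom = character(),
                      start = integer(), end = integer(), strand = character()))
      }
      out <- tibble(
        chrom = d$chrom[1],
        start = head(d$end, -1),
        end = d$start[-1],
        strand = d$strand[1]
      )
      out <- filter(out, .data$end > .data$start)
      n <- nrow(out)
      out$intron_rank <- if (d$strand[1] == "+") seq_len(n) else rev(seq_len(n))
      out
    }) |>
    ungroup() |>
    select("gene_id", "intron_rank", "chrom", "start", "end", "strand")
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gene_models()]: writes one `exon` feature per exon, with
#' `gene_id` and `transcript_id` attributes, converting back to 1-based
#' inclusive coordinates.
#'
#' @param models List with `genes` and `exons` tibbles.
#' @param path Output file.
#' @export
write_gene_models <- function(models, path) {
  ex <- left_join(models$exons,
                  select(models$genes, "gene_id", "transcript_id"),
                  by = "gene_id")
  gr <- tbl_to_gr(ex)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "clipsplice"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Strand-aware flanks of a cassette exon
#'
#' Builds, for every event, the intronic interval extending `length` nt
#' upstream or downstream of the cassette exon in transcript orientation, or
#' the exon body itself.  Flanks are truncated at the neighbouring exon
#' boundary when the intron is shorter than `length`; a fully truncated or
#' zero-length flank comes back with `start == end` (an explicitly empty
#' interval).
#'
#' @param events Cassette-event tibble from [cassette_events()].
#' @param side One of `"upstream_intron"`, `"downstream_intron"`,
#'   `"exon_body"`.
#' @param length Flank length in nucleotides (ignored for `exon_body`).
#' @return Tibble `event_id`, `chrom`, `start`, `end`, `strand`, `side`.
#' @export
event_flank <- function(events, side = c("upstream_intron", "downstream_intron", "exon_body"),
                        length = 500L) {
  side <- match.arg(side)
  if (length < 0) abort("flank length must be >= 0")
  length <- as.integer(length)
  plus <- events$strand == "+"
  if (side == "exon_body") {
    start <- events$cas_start
    end <- events$cas_end
  } else if (side == "upstream_intron") {
    # transcript-upstream intron: left of the exon on +, right on -
    start <- ifelse(plus, pmax(events$cas_start - length, events$up_end),
                    events$cas_end)
    end <- ifelse(plus, events$cas_start,
                  pmin(events$cas_end + length, events$up_start))
  } else {
    start <- ifelse(plus, events$cas_end,
                    pmax(events$cas_start - length, events$dn_end))
    end <- ifelse(plus, pmin(events$cas_end + length, events$dn_start),
                  events$cas_start)
  }
  tibble(event_id = events$event_id, chrom = events$chrom,
         start = as.integer(pmin(start, end)), end = as.integer(end),
         strand = events$strand, side = side)
}

#' Read a BED6 file as a 0-based interval tibble
#'
#' @param path BED file.
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mc <- S4Vectors::mcols(gr)
  out <- gr_to_tbl(gr)
  out$name <- if ("name" %in% names(mc)) as.character(mc$name) else NA_character_
  out$score <- if ("score" %in% names(mc)) as.numeric(mc$score) else 0
  select(out, "chrom", "start", "end", "name", "score", "strand")
}

#' Write an interval tibble as BED6
#'
#' @param x Tibble with `chrom`, `start`, `end`, `strand` and optionally
#'   `name` and `score` columns.
#' @param path Output file.
#' @export
write_bed6 <- function(x, path) {
  gr <- tbl_to_gr(x)
  S4Vectors::mcols(gr)$name <- if ("name" %in% names(x)) x$name else "."
  S4Vectors::mcols(gr)$score <- if ("score" %in% names(x)) x$score else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write a genome FASTA
#'
#' Thin wrappers over Biostrings, returning/accepting a `DNAStringSet` keyed
#' by chromosome name.
#'
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @param genome `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
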