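#' Tile a genome into overlapping k-mers
#'
#' Splits every sequence into k-mers at a fixed step, emulating the
#' shred-and-remap strategy for conserved-region discovery: one genome is
#' cut into short overlapping pieces which are then mapped to the other
#' genome, and every region receiving at least one confidently placed piece
#' is called conserved.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param k tile length in bp; default 30.
#' @param step offset between consecutive tile starts; default 1.
#' @return data.frame with `chrom`, `start` (0-based tile origin), `name`
#'   (`"<chrom>:<start0>"`), `seq`, and `has_n` (tiles containing N are
#'   emitted but flagged; they never match). Sequences shorter than `k`
#'   contribute zero tiles, with a warning.
#' @export
tile_sequences <- function(genome, k = 30L, step = 1L) {
  stopifnot(k >= 1L, step >= 1L)
  g <- as_dnastringset(genome)
  out <- vector("list", length(g))
  for (i in seq_along(g)) {
    L <- Biostrings::width(g)[i]
    if (L < k) {
      warning("sequence ", names(g)[i], " (", L, " bp) is shorter than k = ",
              k, "; no tiles emitted")
      out[[i]] <- NULL
      next
    }
    starts <- as.integer(seq.int(0L, L - k, by = step))
    seqs <- as.character(Biostrings::DNAStringSet(g[[i]],
                                                  start = starts + 1L,
                                                  width = k))
    out[[i]] <- data.frame(chrom = names(g)[i], start = starts,
                           name = paste0(names(g)[i], ":", starts),
                           seq = seqs,
                           has_n = grepl("N", seqs, fixed = TRUE),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      name = character(0), seq = character(0),
                      has_n = logical(0)))
  do.call(rbind, out)
}

## Forward-strand k-mer position table of a genome: data.table(kmer, chrom,
## start). A query hits the reverse strand iff its reverse complement hits
## the forward table, so one forward table serves both strands.
kmer_position_table <- function(genome, k) {
  g <- as_dnastringset(genome)
  parts <- vector("list", length(g))
  for (i in seq_along(g)) {
    L <- Biostrings::width(g)[i]
    if (L < k) next
    starts <- seq.int(0L, L - k)
    parts[[i]] <- data.table::data.table(
      kmer = as.character(Biostrings::DNAStringSet(g[[i]],
                                                   start = starts + 1L,
                                                   width = k)),
      chrom = names(g)[i], start = starts)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    return(data.table::data.table(kmer = character(0), chrom = character(0),
                                  start = integer(0)))
  tab <- data.table::rbindlist(parts)
  data.table::setkey(tab, kmer)
  tab
}

## All exact placements of `queries` across both strands of the destination
## (forward-strand coordinates). Returns data.table(query_idx, chrom, start,
## strand), deduplicated on (query_idx, chrom, start) so palindromic queries
## are not double-counted.
exact_placements <- function(queries, kmer_tab, k) {
  hit_one <- function(qs, strand) {
    idx <- data.table::data.table(kmer = qs, query_idx = seq_along(qs))
    m <- kmer_tab[idx, on = "kmer", nomatch = NULL,
                  .(query_idx = i.query_idx, chrom, start)]
    m$strand <- rep(strand, nrow(m))
    m
  }
  fwd <- hit_one(queries, "+")
  rev <- hit_one(revcomp(queries), "-")
  all <- data.table::rbindlist(list(fwd, rev))
  if (nrow(all) == 0L)
    return(data.table::data.table(query_idx = integer(0),
                                  chrom = character(0), start = integer(0),
                                  strand = character(0)))
  unique(all, by = c("query_idx", "chrom", "start"))
}

#' Map tiles to a destination genome, keeping uniquely placed tiles
#'
#' A tile is *unique* iff it has exactly one placement with at most
#' `max_mismatches` mismatches across both strands of the destination
#' genome; tiles with zero or two-plus placements are non-unique.
#' N-containing tiles never match. Unique placement is the stand-in for the
#' "mapping quality >= 30" filter an external aligner would apply to 30 bp
#' tiles: for reads that short, a MAPQ that high effectively means a single
#' confident placement.
#'
#' With `max_mismatches = 0` (default) a hash of destination k-mers makes
#' this fast; the mismatch-tolerant path scans each tile against the
#' destination with [Biostrings::matchPattern()] and is intended for small
#' genomes only.
#'
#' @param tiles data.frame from [tile_sequences()].
#' @param destination_genome FASTA path or `DNAStringSet`.
#' @param max_mismatches maximum mismatches for a placement; default 0.
#' @return data.frame with `tile_chrom`, `tile_start`, `hit_chrom`,
#'   `hit_start` (NA when not unique), `n_hits`, and `unique`.
#' @export
map_tiles_unique <- function(tiles, destination_genome, max_mismatches = 0L) {
  dest <- as_dnastringset(destination_genome)
  k <- if (nrow(tiles)) nchar(tiles$seq[1]) else 0L
  out <- data.frame(tile_chrom = tiles$chrom, tile_start = tiles$start,
                    hit_chrom = NA_character_, hit_start = NA_integer_,
                    n_hits = 0L, unique = FALSE, stringsAsFactors = FALSE)
  if (nrow(tiles) == 0L) return(out)
  eligible <- which(!tiles$has_n)
  if (!length(eligible)) return(out)
  if (max_mismatches == 0L) {
    tab <- kmer_position_table(dest, k)
    pl <- exact_placements(tiles$seq[eligible], tab, k)
    if (nrow(pl)) {
      cnt <- pl[, .N, by = "query_idx"]
      first <- pl[!duplicated(pl$query_idx), ]
      out$n_hits[eligible[cnt$query_idx]] <- cnt$N
      uniq <- cnt$query_idx[cnt$N == 1L]
      rows <- eligible[uniq]
      fm <- match(uniq, first$query_idx)
      out$unique[rows] <- TRUE
      out$hit_chrom[rows] <- first$chrom[fm]
      out$hit_start[rows] <- first$start[fm]
    }
    return(out)
  }
  ## mismatch-tolerant path: exhaustive scan, small genomes only
  for (i in eligible) {
    pat <- Biostrings::DNAString(tiles$seq[i])
    rcp <- Biostrings::reverseComplement(pat)
    hits <- list()
    for (ch in names(dest)) {
      for (p in list(pat, rcp)) {
        mt <- Biostrings::matchPattern(p, dest[[ch]],
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE)
        if (length(mt))
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = ch, start = Biostrings::start(mt) - 1L)
      }
    }
    if (length(hits)) {
      h <- unique(do.call(rbind, hits))
      out$n_hits[i] <- nrow(h)
      if (nrow(h) == 1L) {
        out$unique[i] <- TRUE
        out$hit_chrom[i] <- h$chrom
        out$hit_start[i] <- h$start
      }
    }
  }
  out
}

#' Merge unique tile hits into conserved-region intervals
#'
#' Takes the union of `[hit_start, hit_start + k)` over all uniquely placed
#' tiles and merges it into maximal sorted non-overlapping intervals in
#' destination-genome coordinates.
#'
#' @param hits data.frame from [map_tiles_unique()] (or any data.frame with
#'   `hit_chrom`, `hit_start`, `unique`).
#' @param k tile length used.
#' @return a sorted, reduced `GRanges`; empty input gives an empty track.
#' @export
call_conserved_regions <- function(hits, k) {
  h <- hits[hits$unique & !is.na(hits$hit_start), , drop = FALSE]
  if (nrow(h) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    h$hit_chrom,
    IRanges::IRanges(start = h$hit_start + 1L, width = k))
  GenomicRanges::reduce(sort(gr))
}

#' Conserved regions between two genomes by k-mer tiling
#'
#' Convenience pipeline: tile the source genome, map tiles uniquely to the
#' destination genome, and merge hits into a BED-style interval track.
#' Intervals are reported in destination-genome coordinates, since loss
#' accounting intersects target-genome alignments.
#'
#' @param source_genome genome to shred (the human genome in the intended
#'   use).
#' @param dest_genome genome in whose coordinates conserved regions are
#'   called (the target species).
#' @inheritParams tile_sequences
#' @inheritParams map_tiles_unique
#' @param bed_out optional path to write a 3-column BED.
#' @return a `GRanges` of conserved intervals.
#' @export
conserved_regions <- function(source_genome, dest_genome, k = 30L,
                              step = 1L, max_mismatches = 0L,
                              bed_out = NULL) {
  tiles <- tile_sequences(source_genome, k = k, step = step)
  hits <- map_tiles_unique(tiles, dest_genome, max_mismatches)
  gr <- call_conserved_regions(hits, k)
  if (!is.null(bed_out)) write_bed(gr, bed_out)
  gr
}

#' Conserved regions from an externally aligned tile SAM
#'
#' Alternate ingestion path for users who map the tiles with an external
#' aligner: applies the literal mapping-quality filter (`mapq >=
#' mq_threshold`; placements below 30 are filtered out) and merges the
#' remaining alignments' reference spans.
#'
#' @param sam_path SAM file of tile alignments against the destination
#'   genome.
#' @param mq_threshold minimum MAPQ kept; default 30 (`>= 30`).
#' @param bed_out optional path to write a 3-column BED.
#' @return a `GRanges` of conserved intervals.
#' @export
conserved_from_sam <- function(sam_path, mq_threshold = 30L,
                               bed_out = NULL) {
  x <- read_alignments(sam_path)
  aln <- x$alignments
  keep <- !is_unmapped(aln) & !is.na(aln$rname) & aln$mapq >= mq_threshold
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::reduce(sort(GenomicRanges::GRanges(
      aln$rname, IRanges::IRanges(start = aln$start + 1L, end = aln$end))))
  }
  if (!is.null(bed_out)) write_bed(gr, bed_out)
  gr
}

#' Write intervals as 3-column BED (0-based half-open)
#'
#' @param gr a `GRanges` (or data.frame with `chrom`, `start`, `end`
#'   already 0-based).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (methods::is(gr, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
  } else df <- gr[, c("chrom", "start", "end")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED into a GRanges
#'
#' @param path BED path (0-based half-open; no header).
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(GenomicRanges::GRanges())
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df[[1]],
                         IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]))
}
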