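FATE_LEVELS <- c("TARGET", "CONTAMINANT", "AMBIGUOUS", "UNMAPPED", "TOO_SHORT")

read_query_length <- function(aln) {
  len <- nchar(aln$seq)
  no_seq <- aln$seq == "*" | is.na(aln$seq)
  len[no_seq] <- (aln$end - aln$start)[no_seq]
  len
}

#' Assign a read fate under competitive mapping
#'
#' Classifies each alignment record against the concatenated reference into
#' one of five fates, applied in this order: `UNMAPPED` for unmapped
#' records; `TOO_SHORT` when the read is shorter than `min_length`;
#' `AMBIGUOUS` when mapping quality is at or below `mq_threshold` (reads
#' fitting both parts of a concatenated reference receive low MAPQ from the
#' aligner, so the MQ filter is what discards dual-part reads); otherwise
#' `TARGET` or `CONTAMINANT` according to the manifest part of the reference
#' sequence the read aligns to.
#'
#' @param aln aligned read table (see [read_alignments()]).
#' @param manifest part manifest (see [build_concatenated_reference()]).
#' @param mq_threshold reads with `mapq <= mq_threshold` are `AMBIGUOUS`;
#'   default 30, i.e. the strict "mapping quality > 30" filter.
#' @param min_length minimum read length in bp; default 30.
#' @param target_label,human_label the manifest labels mapping to `TARGET`
#'   and `CONTAMINANT` fates.
#' @return factor of fates with levels
#'   `TARGET, CONTAMINANT, AMBIGUOUS, UNMAPPED, TOO_SHORT`.
#' @export
assign_fate <- function(aln, manifest, mq_threshold = 30L, min_length = 30L,
                        target_label = "target", human_label = "human") {
  if (!all(c(target_label, human_label) %in% manifest$part_label))
    stop("manifest does not contain both part labels '", target_label,
         "' and '", human_label, "'")
  n <- nrow(aln)
  fate <- character(n)
  unm <- is_unmapped(aln) | is.na(aln$rname)
  part <- rep(NA_character_, n)
  part[!unm] <- manifest_part_of(manifest, aln$rname[!unm])
  bad <- !unm & !(part %in% c(target_label, human_label))
  if (any(bad))
    stop("reference ", aln$rname[bad][1], " has part label '",
         part[bad][1], "', expected '", target_label, "' or '",
         human_label, "'")
  len <- read_query_length(aln)
  fate[unm] <- "UNMAPPED"
  fate[!unm & len < min_length] <- "TOO_SHORT"
  rest <- !nzchar(fate)
  fate[rest & aln$mapq <= mq_threshold] <- "AMBIGUOUS"
  rest <- !nzchar(fate)
  fate[rest] <- ifelse(part[rest] == target_label, "TARGET", "CONTAMINANT")
  factor(fate, levels = FATE_LEVELS)
}

#' Tabulate read fates
#'
#' @param fates factor from [assign_fate()].
#' @return a list of class `fate_counts` with `n_total` and one count per
#'   fate; the five fate counts always sum to `n_total`.
#' @export
fate_counts <- function(fates) {
  tab <- table(factor(fates, levels = FATE_LEVELS))
  out <- list(n_total = length(fates),
              n_target = unname(tab[["TARGET"]]),
              n_contaminant = unname(tab[["CONTAMINANT"]]),
              n_ambiguous = unname(tab[["AMBIGUOUS"]]),
              n_unmapped = unname(tab[["UNMAPPED"]]),
              n_too_short = unname(tab[["TOO_SHORT"]]))
  class(out) <- "fate_counts"
  out
}

#' @export
print.fate_counts <- function(x, ...) {
  cat("read fates (n =", x$n_total, "):\n")
  for (f in c("target", "contaminant", "ambiguous", "unmapped", "too_short"))
    cat(sprintf("  %-12s %d\n", f, x[[paste0("n_", f)]]))
  invisible(x)
}

#' Split a competitively mapped alignment file by read fate
#'
#' Writes the `TARGET`-fate records to one SAM file and the
#' `CONTAMINANT`-fate records to another. Each output header contains only
#' the sequences of the corresponding part, with names restored to their
#' original (pre-concatenation) form and coordinates unchanged. Secondary
#' and supplementary records are dropped before classification so that
#' reads, not alignments, are counted.
#'
#' @param aln aligned read table against the concatenated reference.
#' @param seqinfo header `@SQ` table from [read_alignments()].
#' @param manifest part manifest.
#' @param target_out,contaminant_out output SAM paths (`NULL` to skip
#'   writing that part).
#' @inheritParams assign_fate
#' @return a list with `counts` (a `fate_counts`), `fates` (per-record
#'   factor), and the two output tables `target` and `contaminant` (with
#'   `rname` restored to original names).
#' @export
split_by_fate <- function(aln, seqinfo, manifest,
                          target_out = NULL, contaminant_out = NULL,
                          mq_threshold = 30L, min_length = 30L,
                          target_label = "target", human_label = "human") {
  mapped_names <- seqinfo$name[seqinfo$name != "*"]
  unknown <- setdiff(mapped_names, manifest$sequence_name)
  if (length(unknown))
    stop("header sequence absent from manifest: ", unknown[1])
  aln <- aln[is_primary(aln), , drop = FALSE]
  fates <- assign_fate(aln, manifest, mq_threshold, min_length,
                       target_label, human_label)
  counts <- fate_counts(fates)

  restore <- function(part_aln) {
    idx <- match(part_aln$rname, manifest$sequence_name)
    part_aln$rname <- manifest$original_name[idx]
    part_aln
  }
  part_seqinfo <- function(label) {
    m <- manifest[manifest$part_label == label, ]
    data.frame(name = m$original_name, length = m$length,
               stringsAsFactors = FALSE)
  }
  tgt <- restore(aln[fates == "TARGET", , drop = FALSE])
  ctm <- restore(aln[fates == "CONTAMINANT", , drop = FALSE])
  if (!is.null(target_out))
    write_alignments(tgt, part_seqinfo(target_label), target_out)
  if (!is.null(contaminant_out))
    write_alignments(ctm, part_seqinfo(human_label), contaminant_out)
  list(counts = counts, fates = fates, target = tgt, contaminant = ctm)
}

#' Remove PCR duplicates using both start and end coordinates
#'
#' Among mapped records sharing reference, start, end and (by default)
#' strand, exactly one is retained: the record with the highest sum of base
#' qualities, ties broken by first occurrence in file order. Start-only
#' duplicate marking (the common heuristic) over-collapses ancient DNA
#' libraries, where distinct short molecules frequently share a 5' endpoint;
#' keying on both fragment ends avoids that.
#'
#' @param aln aligned read table.
#' @param ignore_strand collapse opposite-strand records with equal
#'   coordinates too; default `FALSE` (opposite-strand fragments are
#'   distinct molecules under standard practice).
#' @return the deduplicated table, in original record order. Unmapped
#'   records pass through unchanged.
#' @export
deduplicate_alignments <- function(aln, ignore_strand = FALSE) {
  if (nrow(aln) == 0L) return(aln)
  unm <- is_unmapped(aln) | is.na(aln$rname)
  mapped <- aln[!unm, , drop = FALSE]
  if (nrow(mapped)) {
    qsum <- vapply(mapped$qual, function(q) sum(char_to_phred(q)),
                   numeric(1), USE.NAMES = FALSE)
    dupkey <- paste(mapped$rname, mapped$start, mapped$end,
                    if (ignore_strand) "" else mapped$strand, sep = "\r")
    dt <- data.table::data.table(dupkey = dupkey, qsum = qsum,
                                 ord = seq_len(nrow(mapped)))
    keep_ord <- dt[order(-qsum, ord), .(ord = ord[1]), by = dupkey]$ord
    mapped <- mapped[sort(keep_ord), , drop = FALSE]
  }
  out <- rbind(mapped, aln[unm, , drop = FALSE])
  out[order(c(which(!unm)[seq_len(nrow(mapped))], which(unm))), ,
      drop = FALSE]
}

#' Quantify data loss caused by competitive mapping
#'
#' Compares the reads retained against the target genome before and after
#' competitive mapping, genome-wide and restricted to conserved regions.
#' True endogenous reads from regions identical between the two genomes
#' align to both parts of the concatenated reference, receive low MAPQ, and
#' are lost to the mapping-quality filter; that loss concentrates in
#' conserved regions.
#'
#' A read "maps to conserved regions" iff its `[start, end)` interval
#' overlaps any conserved interval by at least 1 bp.
#'
#' @param original aligned read table of MQ-passing reads from
#'   single-reference mapping to the target genome.
#' @param competitive aligned read table of `TARGET`-fate reads after
#'   competitive mapping, in the same target-genome coordinates.
#' @param conserved_regions conserved intervals: a `GRanges` or a
#'   data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return a list of class `loss_report` with counts and loss fractions at
#'   both scales. When `original` is empty the losses are `NA` with a
#'   warning.
#' @export
compute_loss <- function(original, competitive, conserved_regions) {
  gr <- as_intervals(conserved_regions)
  n_orig <- nrow(original)
  n_comp <- nrow(competitive)
  overlaps_conserved <- function(aln) {
    if (nrow(aln) == 0L || length(gr) == 0L) return(0L)
    reads <- GenomicRanges::GRanges(
      aln$rname, IRanges::IRanges(start = aln$start + 1L, end = aln$end))
    sum(IRanges::overlapsAny(reads, gr, minoverlap = 1L))
  }
  n_orig_cons <- overlaps_conserved(original)
  n_comp_cons <- overlaps_conserved(competitive)
  if (n_orig == 0L) {
    warning("no reads in the original alignment set; loss is undefined")
    lg <- NA_real_
  } else lg <- 1 - n_comp / n_orig
  lc <- if (n_orig_cons == 0L) NA_real_ else 1 - n_comp_cons / n_orig_cons
  out <- list(n_original = n_orig, n_competitive = n_comp,
              loss_genomewide = lg,
              n_original_conserved = n_orig_cons,
              n_competitive_conserved = n_comp_cons,
              loss_conserved = lc)
  class(out) <- "loss_report"
  out
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("genome-wide: %d -> %d reads (loss %.4f)\n",
              x$n_original, x$n_competitive, x$loss_genomewide))
  cat(sprintf("conserved:   %d -> %d reads (loss %.4f)\n",
              x$n_original_conserved, x$n_competitive_conserved,
              x$loss_conserved))
  invisible(x)
}

as_intervals <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) return(GenomicRanges::GRanges())
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    return(GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end)))
  }
  stop("cannot interpret intervals of class ", class(x)[1])
}
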