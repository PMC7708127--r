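#' Fragment-length model
#'
#' Lognormal fragment lengths truncated to `[min_len, max_len]` and rounded
#' to whole bases. Ancient DNA fragments are short (tens of bp); modern
#' contaminant fragments are longer.
#'
#' @param meanlog,sdlog lognormal parameters on the log scale.
#' @param min_len,max_len truncation bounds in bp.
#' @return an object of class `fraglen_model`.
#' @export
fraglen_model <- function(meanlog, sdlog, min_len, max_len) {
  stopifnot(min_len >= 1L, max_len >= min_len, sdlog > 0)
  structure(list(meanlog = meanlog, sdlog = sdlog,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "fraglen_model")
}

sample_fraglen <- function(n, fm) {
  if (n == 0L) return(integer(0))
  lo <- plnorm(fm$min_len, fm$meanlog, fm$sdlog)
  hi <- plnorm(fm$max_len, fm$meanlog, fm$sdlog)
  u <- runif(n, lo, hi)
  pmin(pmax(as.integer(round(qlnorm(u, fm$meanlog, fm$sdlog))),
            fm$min_len), fm$max_len)
}

#' Simulation configuration
#'
#' The stated world of the simulator: short damaged fragments from the
#' target genome mixed with longer undamaged fragments from a contaminant
#' (human-like) genome. Defaults describe a typical ancient-DNA library:
#' target fragments lognormal around a ~55 bp median truncated to
#' 25--150 bp with terminal deamination (`p = 0.3`, `c = 0.01`), modern
#' contaminant fragments around ~120 bp truncated to 35--300 bp with no
#' damage, and a flat Q30 (0.001) sequencing error rate. Contaminant length
#' is a knob on purpose: short contaminants (lower the contaminant
#' `min_len`/`meanlog`) reproduce the regime where contaminant reads in
#' faunal alignment files are paradoxically *shorter* than endogenous ones,
#' because only short human fragments align to conserved regions of a
#' foreign genome.
#'
#' @param target_genome,contaminant_genome FASTA paths or `DNAStringSet`s.
#' @param n_reads total reads to simulate.
#' @param contamination_fraction probability a read originates from the
#'   contaminant genome.
#' @param fraglen_target,fraglen_contaminant [fraglen_model()]s.
#' @param damage_target,damage_contaminant [damage_model()]s; the modern
#'   contaminant default has `p = 0, c = 0` (no damage).
#' @param error_rate per-base sequencing error probability in `[0, 1)`.
#' @param target_label,human_label,sep naming convention of the
#'   concatenated reference the truth alignments are expressed against.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(target_genome, contaminant_genome,
                       n_reads = 10000L,
                       contamination_fraction = 0.05,
                       fraglen_target = fraglen_model(log(55), 0.35, 25, 150),
                       fraglen_contaminant = fraglen_model(log(120), 0.3,
                                                           35, 300),
                       damage_target = damage_model(p = 0.3, c = 0.01,
                                                    pi = 0.001),
                       damage_contaminant = damage_model(p = 0, c = 0,
                                                         pi = 0.001),
                       error_rate = 0.001,
                       target_label = "target", human_label = "human",
                       sep = "|") {
  stopifnot(n_reads >= 0L,
            contamination_fraction >= 0, contamination_fraction <= 1,
            error_rate >= 0, error_rate < 1,
            inherits(fraglen_target, "fraglen_model"),
            inherits(fraglen_contaminant, "fraglen_model"),
            inherits(damage_target, "damage_model"),
            inherits(damage_contaminant, "damage_model"))
  structure(list(target_genome = target_genome,
                 contaminant_genome = contaminant_genome,
                 n_reads = as.integer(n_reads),
                 contamination_fraction = contamination_fraction,
                 fraglen_target = fraglen_target,
                 fraglen_contaminant = fraglen_contaminant,
                 damage_target = damage_target,
                 damage_contaminant = damage_contaminant,
                 error_rate = error_rate,
                 target_label = target_label, human_label = human_label,
                 sep = sep),
            class = "sim_config")
}

#' Sample genomic fragments
#'
#' Placements are uniform over all valid (chromosome, start) positions for
#' each fragment's length; strand is uniform; the sequence is the genome
#' substring, reverse-complemented for minus-strand fragments. Consumes the
#' R random number stream, so wrap in `set.seed()` for determinism.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param n number of fragments.
#' @param fm a [fraglen_model()].
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `seq`.
#' @export
sample_fragments <- function(genome, n, fm) {
  g <- as_dnastringset(genome)
  if (any(Biostrings::width(g) < fm$min_len))
    stop("genome sequence shorter than min_len = ", fm$min_len,
         "; cannot place fragments")
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  lens <- sample_fraglen(n, fm)
  wch <- Biostrings::width(g)
  nm <- names(g)
  ## choose chromosome with probability proportional to valid placements
  ## (wch - L + 1, floored at 0), then a uniform start
  chrom <- character(n); start <- integer(n)
  wmat <- vapply(wch, function(w) pmax(w - lens + 1L, 0L), integer(n))
  wmat <- matrix(wmat, nrow = n)
  tot <- rowSums(wmat)
  if (any(tot == 0L)) stop("genome too short for some fragment lengths")
  r <- floor(runif(n) * tot)
  cum <- rep(0, n)
  for (j in seq_along(nm)) {
    sel <- which(!nzchar(chrom) & r < cum + wmat[, j])
    chrom[sel] <- nm[j]
    start[sel] <- as.integer(r[sel] - cum[sel])
    cum <- cum + wmat[, j]
  }
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  gchar <- setNames(as.character(g), nm)
  seq <- character(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    seq[sel] <- substring(gchar[[ch]], start[sel] + 1L, start[sel] + lens[sel])
  }
  minus <- strand == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])
  data.frame(chrom = chrom, start = start, end = start + lens,
             strand = strand, seq = seq, stringsAsFactors = FALSE)
}

#' Apply post-mortem damage to fragment sequences
#'
#' Each C at 1-based distance `z` from the 5' end becomes T with
#' probability `D(z)`; independently each G at distance `z` from the 3' end
#' becomes A with probability `D(z)`. Other bases are untouched, so an
#' undamaged fragment remains an exact substring of its source genome.
#'
#' @param seqs character vector of fragment sequences (molecule
#'   orientation).
#' @param model a [damage_model()].
#' @return list with `seq` (damaged sequences) and `n_damage_events`
#'   (integer per fragment).
#' @export
apply_damage <- function(seqs, model) {
  stopifnot(inherits(model, "damage_model"))
  n <- length(seqs)
  if (n == 0L) return(list(seq = character(0), n_damage_events = integer(0)))
  lens <- nchar(seqs)
  chars <- unlist(strsplit(seqs, ""), use.names = FALSE)
  frag <- rep.int(seq_len(n), lens)
  pos <- sequence(lens)
  z3 <- rep.int(lens, lens) - pos + 1L
  events <- integer(length(chars))
  ic <- which(chars == "C")
  if (length(ic)) {
    hit <- runif(length(ic)) < damage_probability(pos[ic], model)
    chars[ic[hit]] <- "T"
    events[ic[hit]] <- 1L
  }
  ig <- which(chars == "G")
  if (length(ig)) {
    hit <- runif(length(ig)) < damage_probability(z3[ig], model)
    chars[ig[hit]] <- "A"
    events[ig[hit]] <- events[ig[hit]] + 1L
  }
  out <- vapply(split(chars, frag), paste, character(1), collapse = "")
  list(seq = unname(out[as.character(seq_len(n))]),
       n_damage_events = as.integer(tapply(events, frag, sum)[
         as.character(seq_len(n))]))
}

#' Apply uniform sequencing errors and emit base qualities
#'
#' Each base is substituted by a uniformly chosen different base with
#' probability `error_rate`. The emitted constant Phred quality is
#' `round(-10 * log10(error_rate))`, capped at 41 (and 41 when
#' `error_rate = 0`).
#'
#' @param seqs character vector of sequences.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @return list with `seq`, `qual` (Phred+33 strings), and `q` (the
#'   integer quality used).
#' @export
apply_sequencing_errors <- function(seqs, error_rate) {
  stopifnot(error_rate >= 0, error_rate < 1)
  q <- if (error_rate == 0) 41L else min(41L, as.integer(round(
    -10 * log10(error_rate))))
  n <- length(seqs)
  if (n == 0L) return(list(seq = character(0), qual = character(0), q = q))
  lens <- nchar(seqs)
  if (error_rate > 0) {
    chars <- unlist(strsplit(seqs, ""), use.names = FALSE)
    frag <- rep.int(seq_len(n), lens)
    hit <- which(runif(length(chars)) < error_rate & chars %in%
                   c("A", "C", "G", "T"))
    if (length(hit)) {
      alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
      pick <- ceiling(runif(length(hit)) * 3)
      chars[hit] <- vapply(seq_along(hit), function(j)
        alt[[chars[hit[j]]]][pick[j]], character(1))
    }
    out <- vapply(split(chars, frag), paste, character(1), collapse = "")
    seqs <- unname(out[as.character(seq_len(n))])
  }
  list(seq = seqs, qual = qual_string(q, lens), q = q)
}

#' Simulate an ancient sequencing dataset with truth labels
#'
#' Draws each read from the contaminant genome with probability
#' `contamination_fraction` and from the target genome otherwise, applies
#' origin-specific fragment-length and damage models plus sequencing
#' errors, and writes three artifacts: a FASTQ (Phred+33), a truth table
#' TSV, and a truth SAM that places every read at its true origin with
#' MAPQ 60 against the concatenated reference (target-origin reads on the
#' target part, contaminant-origin reads on the human part). The truth SAM
#' lets the competitive-mapping classifier be exercised end-to-end without
#' an external aligner.
#'
#' Fully deterministic for a fixed seed: a single Mersenne-Twister stream
#' drives origin choice, fragment placement, damage and errors, in that
#' order.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @param prefix basename for the output files.
#' @return list with paths `fastq`, `truth_tsv`, `truth_sam`, plus the
#'   in-memory `truth` data.frame, the part `manifest` of the concatenated
#'   reference, and the truth `alignments` table.
#' @export
simulate_dataset <- function(config, outdir, seed, prefix = "sim") {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  tg <- as_dnastringset(config$target_genome)
  ct <- as_dnastringset(config$contaminant_genome)
  ref <- build_concatenated_reference(tg, ct,
                                      target_label = config$target_label,
                                      human_label = config$human_label,
                                      sep = config$sep)
  n <- config$n_reads
  from_ct <- runif(n) < config$contamination_fraction
  origin <- ifelse(from_ct, "contaminant", "target")
  frags <- data.frame(chrom = character(n), start = integer(n),
                      end = integer(n), strand = character(n),
                      seq = character(n), stringsAsFactors = FALSE)
  it <- which(!from_ct); ic <- which(from_ct)
  if (length(it))
    frags[it, ] <- sample_fragments(tg, length(it), config$fraglen_target)
  if (length(ic))
    frags[ic, ] <- sample_fragments(ct, length(ic),
                                    config$fraglen_contaminant)
  n_damage <- integer(n)
  if (length(it)) {
    d <- apply_damage(frags$seq[it], config$damage_target)
    frags$seq[it] <- d$seq; n_damage[it] <- d$n_damage_events
  }
  if (length(ic)) {
    d <- apply_damage(frags$seq[ic], config$damage_contaminant)
    frags$seq[ic] <- d$seq; n_damage[ic] <- d$n_damage_events
  }
  er <- apply_sequencing_errors(frags$seq, config$error_rate)
  frags$seq <- er$seq
  read_name <- sprintf("%s%06d", prefix, seq_len(n))
  truth <- data.frame(read_name = read_name, origin = origin,
                      chrom = frags$chrom, start = frags$start,
                      end = frags$end, strand = frags$strand,
                      n_damage_events = n_damage, stringsAsFactors = FALSE)

  fastq <- file.path(outdir, paste0(prefix, ".fastq"))
  con <- file(fastq, open = "wb")
  if (n > 0L)
    writeLines(rbind(paste0("@", read_name), frags$seq, "+", er$qual),
               con, sep = "\n")
  close(con)

  truth_tsv <- file.path(outdir, paste0(prefix, ".truth.tsv"))
  write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  ## truth SAM against the concatenated reference
  part <- ifelse(from_ct, config$human_label, config$target_label)
  minus <- frags$strand == "-"
  sam_seq <- frags$seq
  sam_qual <- er$qual
  if (any(minus)) {
    sam_seq[minus] <- revcomp(sam_seq[minus])
    sam_qual[minus] <- vapply(strsplit(sam_qual[minus], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
  }
  aln <- data.frame(qname = read_name,
                    flag = ifelse(minus, 16L, 0L),
                    rname = paste0(part, config$sep, frags$chrom),
                    start = frags$start, end = frags$end, mapq = 60L,
                    cigar = paste0(frags$end - frags$start, "M"),
                    strand = frags$strand, seq = sam_seq, qual = sam_qual,
                    tags = "", stringsAsFactors = FALSE)
  if (n == 0L) aln <- empty_alignments()
  truth_sam <- file.path(outdir, paste0(prefix, ".truth.sam"))
  seqinfo <- data.frame(name = ref$manifest$sequence_name,
                        length = ref$manifest$length,
                        stringsAsFactors = FALSE)
  write_alignments(aln, seqinfo, truth_sam)

  list(fastq = fastq, truth_tsv = truth_tsv, truth_sam = truth_sam,
       truth = truth, manifest = ref$manifest, alignments = aln,
       reference = ref$sequences)
}

#' Generate a random genome for simulations
#'
#' Uniform i.i.d. bases; two genomes drawn independently are fully
#' divergent for mapping purposes (a shared 30-mer arises by chance with
#' probability ~ L^2 / 4^30, negligible at desk scale). Consumes the R
#' random number stream.
#'
#' @param lengths named integer vector: chromosome name -> length.
#' @return a `DNAStringSet`.
#' @export
random_genome <- function(lengths) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  seqs <- vapply(lengths, function(L)
    paste(c("A", "C", "G", "T")[ceiling(runif(L) * 4)], collapse = ""),
    character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(lengths)))
}
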