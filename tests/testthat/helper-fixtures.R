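## Shared fixtures and independent oracles. Oracles are deliberately naive
## (per-site loops, exhaustive string search, full enumeration) and share no
## code with the implementation paths they check.

make_aln <- function(qname = "r1", flag = 0L, rname = "chr1", start = 0L,
                     len = 40L, mapq = 60L, seq = strrep("A", len),
                     qual = strrep("I", nchar(seq)), cigar = paste0(nchar(seq), "M"),
                     end = start + nchar(seq), tags = "") {
  data.frame(qname = qname, flag = flag, rname = rname, start = start,
             end = end, mapq = mapq, cigar = cigar,
             strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
             seq = seq, qual = qual, tags = tags, stringsAsFactors = FALSE)
}

unmapped_aln <- function(qname = "u1", seq = strrep("A", 40L)) {
  data.frame(qname = qname, flag = 4L, rname = NA_character_,
             start = NA_integer_, end = NA_integer_, mapq = 0L,
             cigar = NA_character_, strand = NA_character_, seq = seq,
             qual = strrep("I", nchar(seq)), tags = "",
             stringsAsFactors = FALSE)
}

toy_manifest <- function() {
  data.frame(sequence_name = c("target|chrT", "human|chr1"),
             part_label = c("target", "human"),
             original_name = c("chrT", "chr1"),
             length = c(600L, 400L), stringsAsFactors = FALSE)
}

## Plant `segment` into `genome_char` at 0-based `at`, forcing the bases
## immediately flanking the planted copy to differ from the corresponding
## flanks in the source context, so the shared region is exactly the
## segment and tiling tests are not confounded by coincidental junction
## extension.
plant_segment <- function(genome_char, segment, at, guard_left = NA,
                          guard_right = NA) {
  L <- nchar(segment)
  substr(genome_char, at + 1L, at + L) <- segment
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  if (!is.na(guard_left) && at >= 1L)
    substr(genome_char, at, at) <- other(guard_left)
  if (!is.na(guard_right) && at + L < nchar(genome_char))
    substr(genome_char, at + L + 1L, at + L + 1L) <- other(guard_right)
  genome_char
}

## Brute-force PMD score: explicit per-site likelihood products over every
## aligned position, recomputing everything from scratch.
oracle_pmd_score <- function(seq, qual, strand, refseq, p, cc, pi) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  obs <- strsplit(seq, "")[[1]]
  refb <- strsplit(refseq, "")[[1]]
  q <- as.integer(charToRaw(qual)) - 33L
  stopifnot(length(obs) == length(refb))  # oracle assumes all-M alignments
  L <- length(obs)
  if (strand == "-") {
    obs <- unname(comp[rev(obs)])
    refb <- unname(comp[rev(refb)])
    q <- rev(q)
  }
  ld_total <- 1; ln_total <- 1; nsites <- 0L
  for (i in seq_len(L)) {
    eps <- 10^(-q[i] / 10)
    lik <- function(mm, observed_mut) {
      if (observed_mut) mm * (1 - eps) + (1 - mm) * eps / 3
      else (1 - mm) * (1 - eps) + mm * eps / 3
    }
    if (refb[i] == "C" && obs[i] %in% c("C", "T")) {
      z <- i
      d <- p * (1 - p)^(z - 1) + cc
      m <- d + pi - d * pi
      ld_total <- ld_total * lik(m, obs[i] == "T")
      ln_total <- ln_total * lik(pi, obs[i] == "T")
      nsites <- nsites + 1L
    } else if (refb[i] == "G" && obs[i] %in% c("G", "A")) {
      z <- L - i + 1L
      d <- p * (1 - p)^(z - 1) + cc
      m <- d + pi - d * pi
      ld_total <- ld_total * lik(m, obs[i] == "A")
      ln_total <- ln_total * lik(pi, obs[i] == "A")
      nsites <- nsites + 1L
    }
  }
  list(score = log(ld_total / ln_total), n_informative_sites = nsites)
}

## Brute-force conserved regions: slide every k-mer of the source and count
## its occurrences in the destination by exhaustive string search on both
## strands; keep single-occurrence k-mers and union their placements.
oracle_conserved <- function(src, dst, k) {
  rc1 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  find_all <- function(pat, subject) {
    hits <- integer(0); from <- 1L
    repeat {
      i <- regexpr(pat, substring(subject, from), fixed = TRUE)
      if (i == -1L) break
      hits <- c(hits, from + i - 1L)
      from <- from + i  # allow overlapping occurrences
    }
    hits
  }
  # as.character() drops names from character vectors; convert only
  # DNAStringSet-like inputs (where names survive)
  if (!is.character(src)) src <- as.character(src)
  if (!is.character(dst)) dst <- as.character(dst)
  stopifnot(!is.null(names(src)), !is.null(names(dst)))
  cover <- list()
  for (sn in names(src)) {
    L <- nchar(src[[sn]])
    if (L < k) next
    for (s0 in 0:(L - k)) {
      tile <- substring(src[[sn]], s0 + 1L, s0 + k)
      if (grepl("N", tile, fixed = TRUE)) next
      placements <- NULL
      for (dn in names(dst)) {
        for (pat in unique(c(tile, rc1(tile)))) {
          at <- find_all(pat, dst[[dn]])
          if (length(at))
            placements <- rbind(placements,
                                data.frame(chrom = dn, start = at - 1L))
        }
      }
      if (!is.null(placements)) {
        placements <- unique(placements)
        if (nrow(placements) == 1L)
          cover[[length(cover) + 1L]] <- placements
      }
    }
  }
  if (!length(cover)) return(GenomicRanges::GRanges())
  cv <- do.call(rbind, cover)
  GenomicRanges::reduce(sort(GenomicRanges::GRanges(
    cv$chrom, IRanges::IRanges(start = cv$start + 1L, width = k))))
}

## Exact Wilcoxon p by full enumeration of all choose(n1+n2, n1) group
## assignments of the pooled values.
oracle_wilcoxon_p <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  pl <- mean(us <= u_obs)
  pg <- mean(us >= u_obs)
  switch(alternative,
         less = pl, greater = pg,
         two_sided = min(1, 2 * min(pl, pg)))
}
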