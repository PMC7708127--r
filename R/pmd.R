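#' Construct a post-mortem damage model
#'
#' Cytosine deamination in the single-stranded overhangs of degraded DNA is
#' read as C->T substitutions near the 5' end of a fragment and G->A near
#' the 3' end, with probability decaying geometrically with distance from
#' the end:
#' \deqn{D(z) = p (1-p)^{z-1} + c}
#' for 1-based distance `z` from the relevant fragment end. `c` is a
#' constant baseline (damage far from the ends), and `pi` is the
#' polymorphism probability used as the null-model mismatch rate in PMD
#' scoring.
#'
#' @param p geometric damage amplitude/decay parameter in `[0, 1]`.
#'   Default 0.3.
#' @param c constant baseline damage probability in `[0, 1)`. Default 0.01.
#' @param pi polymorphism probability in `[0, 1)`. Default 0.001.
#' @return an object of class `damage_model`.
#' @export
damage_model <- function(p = 0.3, c = 0.01, pi = 0.001) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(c), length(c) == 1L, c >= 0, c < 1,
            is.numeric(pi), length(pi) == 1L, pi >= 0, pi < 1)
  structure(list(p = p, c = c, pi = pi), class = "damage_model")
}

#' @export
print.damage_model <- function(x, ...) {
  cat(sprintf("damage model: D(z) = %g * (1 - %g)^(z-1) + %g, pi = %g\n",
              x$p, x$p, x$c, x$pi))
  invisible(x)
}

#' Position-dependent damage probability D(z)
#'
#' @param z integer vector of 1-based distances from the fragment end;
#'   all must be >= 1.
#' @param model a [damage_model()].
#' @return numeric vector of probabilities, clamped to `[0, 1]`.
#' @examples
#' damage_probability(1:5, damage_model(p = 0.3, c = 0.01))
#' @export
damage_probability <- function(z, model) {
  stopifnot(inherits(model, "damage_model"))
  if (length(z) == 0L) return(numeric(0))
  if (any(is.na(z)) || any(z < 1))
    stop("z must be >= 1 (1-based distance from the fragment end)")
  pmin(pmax(model$p * (1 - model$p)^(z - 1) + model$c, 0), 1)
}

## Aligned (query position, observed base, quality, reference base) tuples
## for one record; positions are 1-based in the stored SEQ orientation.
aligned_sites <- function(seq, qual, cigar, refseq) {
  co <- cigar_ops(cigar)
  if (is.null(co)) stop("record has no CIGAR; cannot locate aligned bases")
  obs <- strsplit(seq, "")[[1]]
  q <- char_to_phred(qual)
  if (length(q) != length(obs))
    stop("quality string length does not match read length")
  refb <- strsplit(refseq, "")[[1]]
  qpos <- integer(0); rpos <- integer(0)
  qi <- 1L; ri <- 1L
  for (j in seq_along(co$op)) {
    len <- co$len[j]
    switch(co$op[j],
           "M" = , "=" = , "X" = {
             qpos <- c(qpos, qi:(qi + len - 1L))
             rpos <- c(rpos, ri:(ri + len - 1L))
             qi <- qi + len; ri <- ri + len
           },
           "I" = , "S" = { qi <- qi + len },
           "D" = , "N" = { ri <- ri + len },
           "H" = , "P" = NULL,
           stop("unsupported CIGAR op: ", co$op[j]))
  }
  data.frame(qpos = qpos, obs = obs[qpos], q = q[qpos], ref = refb[rpos],
             read_len = length(obs), stringsAsFactors = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## log likelihood-ratio contribution of sites with reference base C,
## observed C or T, mismatch probability m (damage) vs m0 (null), error eps.
pmd_site_llr <- function(obs_is_t, m, m0, eps) {
  l_d <- ifelse(obs_is_t,
                m * (1 - eps) + (1 - m) * eps / 3,
                (1 - m) * (1 - eps) + m * eps / 3)
  l_n <- ifelse(obs_is_t,
                m0 * (1 - eps) + (1 - m0) * eps / 3,
                (1 - m0) * (1 - eps) + m0 * eps / 3)
  log(l_d / l_n)
}

#' Per-read post-mortem damage (PMD) scores
#'
#' For each mapped read, sums over informative aligned sites the natural-log
#' likelihood ratio of a position-dependent damage model against a null
#' (polymorphism-only) model. Informative sites are aligned positions whose
#' reference base is C (scored with `z` = 1-based distance from the read's
#' 5' molecule end) or G (`z` from the 3' molecule end). Scoring happens in
#' original-molecule orientation: minus-strand alignments are flipped first,
#' because damage is a property of fragment ends, not of reference
#' orientation.
#'
#' At a reference-C site with damage-model mismatch probability
#' `m(z) = D(z) + pi - D(z) * pi` and per-base sequencing error
#' `eps = 10^(-Q/10)`:
#' \deqn{L(T) = m(1-\epsilon) + (1-m)\epsilon/3, \quad
#'       L(C) = (1-m)(1-\epsilon) + m\epsilon/3}
#' and the null model uses `m = pi`. Reference-G sites mirror with G->A.
#' Observed bases other than C/T (resp. G/A) and non-informative sites
#' contribute zero. Insertions and soft-clips advance the molecule position
#' but are never scored; deletions are skipped.
#'
#' @param aln aligned read table of mapped records.
#' @param model a [damage_model()].
#' @param reference named `DNAStringSet` (or FASTA path) supplying the
#'   reference bases over aligned positions; names must match `aln$rname`.
#' @return data.frame with `query_name`, `score`, `n_informative_sites`.
#'   A read with no informative sites scores exactly 0.
#' @export
pmd_score <- function(aln, model, reference) {
  stopifnot(inherits(model, "damage_model"))
  if (missing(reference) || is.null(reference))
    stop("reference bases are required: supply a reference FASTA ",
         "(path or DNAStringSet) covering all aligned positions")
  ref <- as_dnastringset(reference)
  if (nrow(aln) == 0L)
    return(data.frame(query_name = character(0), score = numeric(0),
                      n_informative_sites = integer(0)))
  if (any(is_unmapped(aln) | is.na(aln$rname)))
    stop("pmd_score requires mapped records; filter unmapped reads first")
  missing_ref <- setdiff(unique(aln$rname), names(ref))
  if (length(missing_ref))
    stop("reference FASTA lacks sequence(s): ",
         paste(missing_ref, collapse = ", "))
  score <- numeric(nrow(aln))
  nsites <- integer(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    refseq <- as.character(Biostrings::subseq(ref[[aln$rname[i]]],
                                              aln$start[i] + 1L, aln$end[i]))
    st <- aligned_sites(aln$seq[i], aln$qual[i], aln$cigar[i], refseq)
    if (aln$strand[i] == "-") {
      st$qpos <- st$read_len - st$qpos + 1L
      st$obs <- unname(COMPLEMENT[st$obs])
      st$ref <- unname(COMPLEMENT[st$ref])
    }
    L <- st$read_len[1] %||% 0L
    eps <- 10^(-st$q / 10)
    m0 <- model$pi
    ## reference C: z from 5' molecule end, observe C or T
    cs <- st$ref == "C" & st$obs %in% c("C", "T")
    llr_c <- if (any(cs)) {
      m <- {
        d <- damage_probability(st$qpos[cs], model)
        d + m0 - d * m0
      }
      pmd_site_llr(st$obs[cs] == "T", m, m0, eps[cs])
    } else numeric(0)
    ## reference G: z from 3' molecule end, observe G or A
    gs <- st$ref == "G" & st$obs %in% c("G", "A")
    llr_g <- if (any(gs)) {
      z3 <- L - st$qpos[gs] + 1L
      m <- {
        d <- damage_probability(z3, model)
        d + m0 - d * m0
      }
      pmd_site_llr(st$obs[gs] == "A", m, m0, eps[gs])
    } else numeric(0)
    score[i] <- sum(llr_c) + sum(llr_g)
    nsites[i] <- sum(cs) + sum(gs)
  }
  data.frame(query_name = aln$qname, score = score,
             n_informative_sites = nsites, stringsAsFactors = FALSE)
}

#' PMD ratio: fraction of reads with PMD score above a threshold
#'
#' The per-sample authentication summary: a higher value means the sample
#' contains more reads bearing the terminal deamination signature of
#' authentic ancient molecules.
#'
#' @param scores numeric vector of PMD scores, or the data.frame returned
#'   by [pmd_score()].
#' @param threshold reads with `score > threshold` (strictly) count;
#'   default 5.
#' @return fraction in `[0, 1]`; `NA` with a warning for an empty input.
#' @export
pmd_ratio <- function(scores, threshold = 5) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) == 0L) {
    warning("no PMD scores supplied; PMD ratio is undefined")
    return(NA_real_)
  }
  mean(scores > threshold)
}

#' Median read length (mRL)
#'
#' Ancient DNA is characteristically short; the median alignment length is
#' the per-sample fragment-size summary used alongside the PMD ratio.
#'
#' @param reads numeric vector of lengths, or an aligned read table (mapped
#'   records use the reference span `end - start`; unmapped records the
#'   read length).
#' @return median length; even-sized inputs return the mean of the two
#'   central values. `NA` with a warning for an empty input.
#' @export
median_read_length <- function(reads) {
  if (is.data.frame(reads)) {
    unm <- is_unmapped(reads) | is.na(reads$rname)
    reads <- ifelse(unm, read_query_length(reads), reads$end - reads$start)
  }
  if (length(reads) == 0L) {
    warning("no reads supplied; median read length is undefined")
    return(NA_real_)
  }
  median(as.numeric(reads))
}
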