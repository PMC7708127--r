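## Alignment records are held in a plain data.frame ("aligned read table")
## with one row per alignment record and columns:
##   qname   query name
##   flag    SAM bitwise flag
##   rname   reference sequence name (NA if unmapped)
##   start   0-based leftmost aligned position (NA if unmapped)
##   end     0-based exclusive end on the reference (NA if unmapped)
##   mapq    mapping quality
##   cigar   CIGAR string ("*" if unmapped)
##   strand  "+" or "-" (NA if unmapped)
##   seq     read bases as stored in SAM (reference-forward orientation)
##   qual    Phred+33 quality string ("*" allowed)
##   tags    optional SAM tags, tab-joined ("" if none)
## Coordinates are 0-based half-open throughout; conversion to SAM's 1-based
## POS happens only at the file boundary.

SAM_COLS <- c("qname", "flag", "rname", "start", "end", "mapq", "cigar",
              "strand", "seq", "qual", "tags")

empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             start = integer(0), end = integer(0), mapq = integer(0),
             cigar = character(0), strand = character(0), seq = character(0),
             qual = character(0), tags = character(0),
             stringsAsFactors = FALSE)
}

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(len = lens, op = ops)
}

cigar_ref_width <- function(cigar) {
  co <- cigar_ops(cigar)
  if (is.null(co)) return(NA_integer_)
  sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
}

is_unmapped <- function(aln) bitwAnd(aln$flag, 4L) != 0L
is_reverse <- function(aln) bitwAnd(aln$flag, 16L) != 0L
is_primary <- function(aln) bitwAnd(aln$flag, 256L + 2048L) == 0L

#' Read a SAM (or BAM) alignment file
#'
#' Plain-text SAM is parsed directly; `.bam` input is routed through
#' \pkg{Rsamtools} when available. All records (including unmapped,
#' secondary and supplementary) are returned; downstream operations decide
#' what to keep.
#'
#' @param path SAM or BAM file.
#' @return a list with `alignments` (aligned read table, see package
#'   internals), and `seqinfo` (data.frame of `name`, `length` from the
#'   header `@SQ` lines).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package; ",
           "convert to SAM with `samtools view -h` instead")
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    path <- tmp
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  seqinfo <- data.frame(name = character(0), length = integer(0),
                        stringsAsFactors = FALSE)
  if (length(sq)) {
    sn <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
    ln <- as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
    seqinfo <- data.frame(name = sn, length = ln, stringsAsFactors = FALSE)
  }
  if (!length(body))
    return(list(alignments = empty_alignments(), seqinfo = seqinfo))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) stop("SAM record with fewer than 11 fields in ", path)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  pos1 <- as.integer(get(4))
  cigar <- get(6)
  rname <- get(3)
  unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*"
  start0 <- ifelse(unmapped, NA_integer_, pos1 - 1L)
  width <- vapply(cigar, cigar_ref_width, integer(1), USE.NAMES = FALSE)
  aln <- data.frame(
    qname = get(1),
    flag = flag,
    rname = ifelse(unmapped, NA_character_, rname),
    start = start0,
    end = ifelse(unmapped, NA_integer_, start0 + width),
    mapq = as.integer(get(5)),
    cigar = cigar,
    strand = ifelse(unmapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")),
    seq = get(10),
    qual = get(11),
    tags = vapply(fields, function(f)
      if (length(f) > 11L) paste(f[12:length(f)], collapse = "\t") else "",
      character(1)),
    stringsAsFactors = FALSE)
  list(alignments = aln, seqinfo = seqinfo)
}

#' Write alignment records to a SAM file
#'
#' @param aln aligned read table.
#' @param seqinfo data.frame with `name` and `length` columns for the
#'   header `@SQ` lines.
#' @param path output SAM path.
#' @param sort_order value for the `SO:` header field.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, seqinfo, path, sort_order = "unsorted") {
  stopifnot(all(c("name", "length") %in% names(seqinfo)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl(paste0("@HD\tVN:1.6\tSO:", sort_order))
  if (nrow(seqinfo))
    wl(paste0("@SQ\tSN:", seqinfo$name, "\tLN:", seqinfo$length))
  wl("@PG\tID:compmap\tPN:compmap")
  if (nrow(aln)) {
    unm <- is.na(aln$rname)
    rec <- paste(aln$qname, aln$flag,
                 ifelse(unm, "*", aln$rname),
                 ifelse(unm, 0L, aln$start + 1L),
                 aln$mapq,
                 ifelse(is.na(aln$cigar), "*", aln$cigar),
                 "*", 0L, 0L,
                 aln$seq, aln$qual, sep = "\t")
    tg <- aln$tags %||% character(nrow(aln))
    has_tags <- !is.na(tg) & nzchar(tg)
    rec[has_tags] <- paste(rec[has_tags], tg[has_tags], sep = "\t")
    wl(rec)
  }
  invisible(path)
}
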