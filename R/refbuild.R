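#' Build a concatenated two-species reference
#'
#' Merges all sequences of a target-species genome and a human genome into a
#' single reference so that reads can be mapped competitively: each read ends
#' up attributed to the genome part it fits best, and reads fitting both
#' parts receive low mapping quality from the aligner and are discarded by
#' mapping-quality filters downstream.
#'
#' Each output sequence is renamed `"<part_label><sep><original_name>"`. The
#' accompanying part manifest maps every output sequence name back to its
#' source part and is the authoritative attribution (the name prefix is a
#' human-readable convenience; aligners truncate names at whitespace, so an
#' explicit table is more robust).
#'
#' @param target_fasta path to the target-species genome FASTA (or a
#'   `DNAStringSet`).
#' @param human_fasta path to the human (contaminant-source) genome FASTA
#'   (or a `DNAStringSet`).
#' @param target_label,human_label part labels recorded in the manifest;
#'   defaults `"target"` and `"human"`.
#' @param sep separator between part label and original sequence name in the
#'   output FASTA; default `"|"`. Configurable for aligner compatibility.
#' @param out_fasta optional path; when given, the concatenated FASTA is
#'   written there (60-column lines).
#' @param manifest_path optional path; when given, the manifest TSV is
#'   written there.
#' @return a list with `sequences` (the concatenated `DNAStringSet`, target
#'   part first) and `manifest` (data.frame with columns `sequence_name`,
#'   `part_label`, `original_name`, `length`).
#' @examples
#' tg <- Biostrings::DNAStringSet(c(chrT = "ACGTACGTAC"))
#' hs <- Biostrings::DNAStringSet(c(chr1 = "TTTTGGGGCC"))
#' ref <- build_concatenated_reference(tg, hs)
#' ref$manifest
#' @export
build_concatenated_reference <- function(target_fasta, human_fasta,
                                         target_label = "target",
                                         human_label = "human",
                                         sep = "|",
                                         out_fasta = NULL,
                                         manifest_path = NULL) {
  if (!nzchar(target_label) || !nzchar(human_label) ||
      target_label == human_label)
    stop("part labels must be non-empty and distinct")
  tg <- as_dnastringset(target_fasta)
  hs <- as_dnastringset(human_fasta)
  if (is.null(names(tg)) || is.null(names(hs)) ||
      any(!nzchar(names(tg))) || any(!nzchar(names(hs))))
    stop("all input sequences must be named")
  for (set in list(tg, hs)) {
    d <- names(set)[duplicated(names(set))]
    if (length(d)) stop("duplicate sequence name within one input: ", d[1])
  }
  out_names <- c(paste0(target_label, sep, names(tg)),
                 paste0(human_label, sep, names(hs)))
  if (anyDuplicated(out_names))
    stop("sequence name collision after prefixing: ",
         out_names[duplicated(out_names)][1])
  concat <- c(tg, hs)
  names(concat) <- out_names
  manifest <- data.frame(
    sequence_name = out_names,
    part_label = rep(c(target_label, human_label), c(length(tg), length(hs))),
    original_name = c(names(tg), names(hs)),
    length = Biostrings::width(concat),
    stringsAsFactors = FALSE)
  if (!is.null(out_fasta)) write_fasta(concat, out_fasta)
  if (!is.null(manifest_path)) write_part_manifest(manifest, manifest_path)
  list(sequences = concat, manifest = manifest)
}

#' Write a part manifest to a 4-column TSV
#'
#' @param manifest data.frame with columns `sequence_name`, `part_label`,
#'   `original_name`, `length`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_part_manifest <- function(manifest, path) {
  validate_part_manifest(manifest)
  write.table(manifest[, c("sequence_name", "part_label", "original_name",
                           "length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a part manifest TSV
#'
#' @param path manifest path (tab-separated, header, 4 columns).
#' @param labels optional character vector of permitted part labels; any
#'   other label in the file is an error. `NULL` (default) accepts the
#'   labels as found.
#' @return the manifest data.frame.
#' @export
load_part_manifest <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  m <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                error = function(e) stop("cannot parse manifest ", path,
                                         ": ", conditionMessage(e)))
  need <- c("sequence_name", "part_label", "original_name", "length")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  m <- m[, need]
  m$length <- as.integer(m$length)
  validate_part_manifest(m)
  if (!is.null(labels)) {
    bad <- setdiff(unique(m$part_label), labels)
    if (length(bad))
      stop("unknown part_label in manifest: ", paste(bad, collapse = ", "),
           " (declared labels: ", paste(labels, collapse = ", "), ")")
  }
  m
}

validate_part_manifest <- function(m) {
  if (!is.data.frame(m) || nrow(m) == 0L) stop("manifest is empty")
  if (anyDuplicated(m$sequence_name))
    stop("duplicate sequence_name in manifest: ",
         m$sequence_name[duplicated(m$sequence_name)][1])
  if (any(!nzchar(m$part_label)) || anyNA(m$part_label))
    stop("manifest part_label must be non-empty")
  if (any(is.na(m$length)) || any(m$length <= 0L))
    stop("manifest lengths must be positive integers")
  invisible(m)
}

manifest_part_of <- function(manifest, rnames) {
  idx <- match(rnames, manifest$sequence_name)
  if (anyNA(idx[!is.na(rnames)]))
    stop("reference sequence absent from manifest: ",
         rnames[!is.na(rnames) & is.na(idx)][1])
  manifest$part_label[idx]
}
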