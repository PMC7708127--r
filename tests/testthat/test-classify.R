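test_that("assign_fate applies the fate rules in order", {
  m <- toy_manifest()
  aln <- rbind(
    make_aln("contam", 0L, "human|chr1", 10L, seq = strrep("A", 45),
             mapq = 37L),
    make_aln("dual", 0L, "target|chrT", 10L, seq = strrep("A", 45),
             mapq = 0L),
    unmapped_aln("unm"),
    make_aln("short", 0L, "target|chrT", 10L, seq = strrep("A", 25),
             mapq = 60L),
    make_aln("endog", 0L, "target|chrT", 50L, seq = strrep("A", 40),
             mapq = 60L))
  fates <- assign_fate(aln, m)
  expect_identical(as.character(fates),
                   c("CONTAMINANT", "AMBIGUOUS", "UNMAPPED", "TOO_SHORT",
                     "TARGET"))
  # MQ threshold is strict: mapq == 30 is still ambiguous, 31 passes
  expect_identical(
    as.character(assign_fate(make_aln(mapq = 30L, rname = "target|chrT",
                                      seq = strrep("A", 40)), m)),
    "AMBIGUOUS")
  expect_identical(
    as.character(assign_fate(make_aln(mapq = 31L, rname = "target|chrT",
                                      seq = strrep("A", 40)), m)),
    "TARGET")
  # unknown reference is an error
  expect_error(assign_fate(make_aln(rname = "target|chrX"), m),
               "absent from manifest")
})

test_that("raising the MQ threshold never rescues a read from AMBIGUOUS", {
  m <- toy_manifest()
  set.seed(42)
  aln <- do.call(rbind, lapply(1:50, function(i)
    make_aln(paste0("r", i),
             rname = sample(m$sequence_name, 1),
             mapq = sample(0:60, 1), seq = strrep("A", sample(20:60, 1)))))
  prev <- assign_fate(aln, m, mq_threshold = 0L)
  for (mq in c(10L, 30L, 50L)) {
    cur <- assign_fate(aln, m, mq_threshold = mq)
    moved <- prev == "AMBIGUOUS" & cur %in% c("TARGET", "CONTAMINANT")
    expect_false(any(moved))
    prev <- cur
  }
})

test_that("fate counts always conserve the total", {
  m <- toy_manifest()
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(1:40, 1)
    aln <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (runif(1) < 0.2) return(unmapped_aln(paste0("u", i)))
      make_aln(paste0("r", i), rname = sample(m$sequence_name, 1),
               mapq = sample(0:60, 1), seq = strrep("A", sample(10:80, 1)))
    }))
    cnt <- fate_counts(assign_fate(aln, m))
    expect_identical(cnt$n_total, n)
    expect_identical(cnt$n_target + cnt$n_contaminant + cnt$n_ambiguous +
                       cnt$n_unmapped + cnt$n_too_short, n)
  }
})

test_that("split_by_fate writes per-part files with restored names", {
  m <- toy_manifest()
  aln <- rbind(
    do.call(rbind, lapply(1:6, function(i)
      make_aln(paste0("t", i), 0L, "target|chrT", i * 10L,
               seq = strrep("A", 40), mapq = 60L))),
    do.call(rbind, lapply(1:2, function(i)
      make_aln(paste0("c", i), 0L, "human|chr1", i * 10L,
               seq = strrep("A", 40), mapq = 60L))),
    make_aln("a1", 0L, "target|chrT", 5L, seq = strrep("A", 40), mapq = 0L),
    unmapped_aln("u1"))
  seqinfo <- data.frame(name = m$sequence_name, length = m$length)
  tout <- tempfile(fileext = ".sam"); cout <- tempfile(fileext = ".sam")
  res <- split_by_fate(aln, seqinfo, m, target_out = tout,
                       contaminant_out = cout)
  expect_identical(res$counts$n_total, 10L)
  expect_identical(res$counts$n_target, 6L)
  expect_identical(res$counts$n_contaminant, 2L)
  expect_identical(res$counts$n_ambiguous, 1L)
  expect_identical(res$counts$n_unmapped, 1L)

  t <- read_alignments(tout)
  expect_identical(nrow(t$alignments), 6L)
  expect_identical(unique(t$alignments$rname), "chrT")  # restored name
  expect_identical(t$seqinfo, data.frame(name = "chrT", length = 600L))
  # coordinates unchanged
  expect_identical(t$alignments$start, aln$start[1:6])

  c <- read_alignments(cout)
  expect_identical(nrow(c$alignments), 2L)
  expect_identical(c$seqinfo$name, "chr1")

  # all-target input still yields a valid empty contaminant file
  res2 <- split_by_fate(aln[1:6, ], seqinfo, m, contaminant_out = cout)
  expect_identical(nrow(read_alignments(cout)$alignments), 0L)
  expect_identical(read_alignments(cout)$seqinfo$name, "chr1")

  # header sequence missing from manifest is an error
  bad <- rbind(seqinfo, data.frame(name = "rogue", length = 10L))
  expect_error(split_by_fate(aln, bad, m), "absent from manifest")
})

test_that("secondary and supplementary records are not counted", {
  m <- toy_manifest()
  aln <- rbind(
    make_aln("r1", 0L, "target|chrT", 10L, seq = strrep("A", 40),
             mapq = 60L),
    make_aln("r1", 256L, "target|chrT", 90L, seq = strrep("A", 40),
             mapq = 60L),
    make_aln("r1", 2048L, "human|chr1", 90L, seq = strrep("A", 40),
             mapq = 60L))
  res <- split_by_fate(aln, data.frame(name = m$sequence_name,
                                       length = m$length), m)
  expect_identical(res$counts$n_total, 1L)
  expect_identical(res$counts$n_target, 1L)
})

test_that("deduplication keys on both coordinates and strand", {
  base <- function(q, start, end, flag = 0L, qual = NULL) {
    len <- end - start
    make_aln(q, flag, "chrT", start, seq = strrep("A", len),
             qual = qual %||% strrep("I", len), end = end)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  # same chrom/start/end/strand -> one survives
  dup <- rbind(base("a", 100L, 140L), base("b", 100L, 140L))
  expect_identical(nrow(deduplicate_alignments(dup)), 1L)

  # same start, different end -> both retained (the point of end-aware dedup)
  d2 <- rbind(base("a", 100L, 140L), base("b", 100L, 150L))
  expect_identical(nrow(deduplicate_alignments(d2)), 2L)

  # opposite strands -> distinct molecules unless ignore_strand
  d3 <- rbind(base("a", 100L, 140L), base("b", 100L, 140L, flag = 16L))
  expect_identical(nrow(deduplicate_alignments(d3)), 2L)
  expect_identical(nrow(deduplicate_alignments(d3, ignore_strand = TRUE)), 1L)

  # the best-quality copy wins; ties keep the first in file order
  d4 <- rbind(base("low", 100L, 140L, qual = strrep("#", 40)),
              base("high", 100L, 140L, qual = strrep("I", 40)))
  expect_identical(deduplicate_alignments(d4)$qname, "high")
  d5 <- rbind(base("first", 100L, 140L), base("second", 100L, 140L))
  expect_identical(deduplicate_alignments(d5)$qname, "first")

  # unmapped records pass unchanged; empty input is fine
  d6 <- rbind(base("a", 100L, 140L), unmapped_aln("u"))
  expect_identical(nrow(deduplicate_alignments(d6)), 2L)
  expect_identical(nrow(deduplicate_alignments(d6[0, ])), 0L)
})

test_that("compute_loss reports both scales with interval overlap", {
  mk <- function(n, start_fn) do.call(rbind, lapply(seq_len(n), function(i)
    make_aln(paste0("r", i), 0L, "chrT", start_fn(i), seq = strrep("A", 40))))
  orig <- mk(1000, function(i) (i %% 100) * 50L)
  comp <- orig[1:987, ]
  cons <- data.frame(chrom = "chrT", start = 0L, end = 200L)
  loss <- compute_loss(orig, comp, cons)
  expect_equal(loss$loss_genomewide, 0.013)
  expect_true(loss$n_original_conserved <= loss$n_original)

  # identical inputs -> zero loss on both scales
  l0 <- compute_loss(orig, orig, cons)
  expect_identical(l0$loss_genomewide, 0)
  expect_identical(l0$loss_conserved, 0)

  # 1 bp overlap counts; abutting interval does not
  one <- make_aln("x", 0L, "chrT", 199L, seq = strrep("A", 40))
  l1 <- compute_loss(one, one, cons)
  expect_identical(l1$n_original_conserved, 1L)
  l2 <- compute_loss(one, one,
                     data.frame(chrom = "chrT", start = 0L, end = 199L))
  expect_identical(l2$n_original_conserved, 0L)

  expect_warning(l3 <- compute_loss(orig[0, ], comp[0, ], cons),
                 "undefined")
  expect_true(is.na(l3$loss_genomewide))
})
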