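test_that("fragment sampling is deterministic and respects the genome", {
  set.seed(1)
  g <- random_genome(c(c1 = 3000L, c2 = 2000L))
  fm <- fraglen_model(log(55), 0.35, 25, 150)
  expect_identical(nrow(sample_fragments(g, 0L, fm)), 0L)

  set.seed(5); a <- sample_fragments(g, 200L, fm)
  set.seed(5); b <- sample_fragments(g, 200L, fm)
  expect_identical(a, b)

  # fragments are genuine genome substrings (reverse-complemented on minus)
  gchar <- as.character(g)
  for (i in seq_len(20)) {
    sub <- substring(gchar[[a$chrom[i]]], a$start[i] + 1L, a$end[i])
    if (a$strand[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    expect_identical(a$seq[i], sub)
  }
  expect_true(all(a$end - a$start >= 25L & a$end - a$start <= 150L))
  expect_error(sample_fragments(random_genome(c(tiny = 10L)), 5L, fm),
               "shorter than min_len")
})

test_that("fragment lengths track the truncated-lognormal median", {
  fm <- fraglen_model(log(55), 0.35, 25, 150)
  set.seed(17)
  got <- median(sample_fraglen <- {
    f <- sample_fragments(random_genome(c(c1 = 2000L)), 10000L, fm)
    f$end - f$start
  })
  # independent Monte-Carlo oracle: rejection sampling from the plain
  # lognormal, then the same round-and-clamp discretisation
  set.seed(404)
  draws <- numeric(0)
  while (length(draws) < 20000) {
    x <- stats::rlnorm(30000, log(55), 0.35)
    draws <- c(draws, x[x >= 25 & x <= 150])
  }
  want <- median(pmin(pmax(round(draws[1:20000]), 25), 150))
  se <- 1.2533 * stats::sd(pmin(pmax(round(draws[1:20000]), 25), 150)) /
    sqrt(10000)
  expect_lt(abs(got - want), 3 * se + 1)  # +1 for median discreteness
})

test_that("damage is applied only at the prescribed positions", {
  null <- damage_model(p = 0, c = 0)
  out <- apply_damage(c("ACGTACGT", "CCCC"), null)
  expect_identical(out$seq, c("ACGTACGT", "CCCC"))
  expect_identical(out$n_damage_events, c(0L, 0L))

  # p = 1, c = 0: D(1) = 1, D(z>1) = 0 -> only the terminal C and G flip
  set.seed(3)
  det <- apply_damage("CCCC", damage_model(p = 1, c = 0))
  expect_identical(det$seq, "TCCC")
  expect_identical(det$n_damage_events, 1L)
  det2 <- apply_damage("GGGG", damage_model(p = 1, c = 0))
  expect_identical(det2$seq, "GGGA")

  # A and T are never touched; damaged sequence keeps its length
  set.seed(4)
  heavy <- apply_damage(strrep("AT", 30), damage_model(p = 0.9, c = 0.1))
  expect_identical(heavy$seq, strrep("AT", 30))
})

test_that("empirical terminal C->T rates match D(z)", {
  model <- damage_model(p = 0.3, c = 0.01)
  n <- 20000L
  set.seed(8)
  out <- apply_damage(rep(strrep("C", 40), n), model)
  first <- substring(out$seq, 1, 1)
  fifth <- substring(out$seq, 5, 5)
  for (case in list(list(obs = mean(first == "T"), z = 1L),
                    list(obs = mean(fifth == "T"), z = 5L))) {
    p_exp <- damage_probability(case$z, model)
    sd3 <- 3 * sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(case$obs - p_exp), sd3)
  }
})

test_that("sequencing errors follow the Phred convention", {
  set.seed(12)
  clean <- apply_sequencing_errors(c("ACGT", "GGGG"), 0)
  expect_identical(clean$seq, c("ACGT", "GGGG"))
  expect_identical(clean$q, 41L)
  expect_identical(clean$qual, c(strrep("J", 4), strrep("J", 4)))

  q30 <- apply_sequencing_errors("ACGT", 0.001)
  expect_identical(q30$q, 30L)
  expect_identical(q30$qual, strrep("?", 4))

  # binomial calibration at 1% on 1e6 bases
  set.seed(13)
  seqs <- rep(strrep("A", 100), 10000)
  noisy <- apply_sequencing_errors(seqs, 0.01)
  n_sub <- sum(vapply(seq_along(seqs), function(i)
    sum(strsplit(noisy$seq[i], "")[[1]] != "A"), integer(1)))
  expect_lt(abs(n_sub - 10000), 3 * sqrt(1e6 * 0.01 * 0.99))
})

test_that("simulate_dataset writes consistent truth artifacts", {
  set.seed(2)
  tg <- random_genome(c(chrT = 8000L))
  hs <- random_genome(c(chr1 = 8000L))
  cfg <- sim_config(tg, hs, n_reads = 400L, contamination_fraction = 0.2)
  out1 <- file.path(tempfile(), "a")
  res <- simulate_dataset(cfg, out1, seed = 42)

  expect_identical(nrow(res$truth), 400L)
  # FASTQ names match truth records, in order
  fq <- readLines(res$fastq)
  expect_identical(sub("^@", "", fq[seq(1, length(fq), 4)]),
                   res$truth$read_name)
  # truth SAM places reads on the right part with MAPQ 60
  x <- read_alignments(res$truth_sam)
  expect_true(all(x$alignments$mapq == 60L))
  expect_identical(startsWith(x$alignments$rname, "human|"),
                   res$truth$origin == "contaminant")
  expect_identical(x$alignments$start, res$truth$start)

  # an undamaged, error-free read is an exact substring of its genome
  cfg0 <- sim_config(tg, hs, n_reads = 50L, contamination_fraction = 0.5,
                     damage_target = damage_model(p = 0, c = 0),
                     error_rate = 0)
  res0 <- simulate_dataset(cfg0, file.path(tempfile(), "b"), seed = 9)
  gchar <- list(target = as.character(tg), contaminant = as.character(hs))
  for (i in seq_len(50)) {
    tr <- res0$truth[i, ]
    sub <- substring(gchar[[tr$origin]][[tr$chrom]], tr$start + 1L, tr$end)
    if (tr$strand == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    fqseq <- readLines(res0$fastq)[4 * (i - 1) + 2]
    expect_identical(fqseq, sub)
    expect_identical(tr$n_damage_events, 0L)
  }

  # zero contamination -> zero contaminant truth records
  cfgz <- sim_config(tg, hs, n_reads = 300L, contamination_fraction = 0)
  resz <- simulate_dataset(cfgz, file.path(tempfile(), "c"), seed = 5)
  expect_identical(sum(resz$truth$origin == "contaminant"), 0L)
})

test_that("the same seed reproduces byte-identical outputs", {
  set.seed(2)
  tg <- random_genome(c(chrT = 5000L))
  hs <- random_genome(c(chr1 = 5000L))
  cfg <- sim_config(tg, hs, n_reads = 200L)
  d1 <- file.path(tempfile(), "x"); d2 <- file.path(tempfile(), "y")
  r1 <- simulate_dataset(cfg, d1, seed = 77)
  r2 <- simulate_dataset(cfg, d2, seed = 77)
  for (f in c("fastq", "truth_tsv", "truth_sam"))
    expect_identical(readBin(r1[[f]], "raw", file.size(r1[[f]])),
                     readBin(r2[[f]], "raw", file.size(r2[[f]])))
  r3 <- simulate_dataset(cfg, file.path(tempfile(), "z"), seed = 78)
  expect_false(identical(readLines(r1$fastq), readLines(r3$fastq)))
})

test_that("binomial contaminant counts honour the configured fraction", {
  set.seed(2)
  tg <- random_genome(c(chrT = 5000L))
  hs <- random_genome(c(chr1 = 5000L))
  cfg <- sim_config(tg, hs, n_reads = 5000L, contamination_fraction = 0.05)
  res <- simulate_dataset(cfg, file.path(tempfile(), "w"), seed = 11)
  n_ct <- sum(res$truth$origin == "contaminant")
  expect_lt(abs(n_ct - 250), 3 * sqrt(5000 * 0.05 * 0.95))
})
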