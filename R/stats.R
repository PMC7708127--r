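#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties. The exact p-value is computed from the exact
#' null distribution of U when `n1 + n2 <= exact_threshold` and there are
#' no ties; otherwise a normal approximation with tie correction and (by
#' default) continuity correction is used. Both the Mann-Whitney `U` and
#' the rank-sum of `x` are reported; the conventional "W" printed by most
#' statistical software equals `U`, so `W` is returned as an alias.
#'
#' @param x,y numeric samples.
#' @param alternative one of `"two_sided"`, `"less"`, `"greater"` (relative
#'   position of `x` versus `y`).
#' @param exact_threshold use the exact distribution when
#'   `n1 + n2 <= exact_threshold` and the pooled data are tie-free;
#'   default 10.
#' @param correct apply the continuity correction in the normal
#'   approximation; default `TRUE`.
#' @return a list of class `wilcoxon_result` with `U`, `W` (= `U`),
#'   `rank_sum` (rank sum of `x`, `= U + n1(n1+1)/2`), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), and `alternative`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less",
                                              "greater"),
                              exact_threshold = 10L, correct = TRUE) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  rank_sum <- sum(r[seq_len(n1)])
  u <- rank_sum - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && (n1 + n2) <= exact_threshold) {
    method <- "exact"
    pl <- pwilcox(u, n1, n2)
    pg <- 1 - pwilcox(u - 1, n1, n2)
    p <- switch(alternative,
                less = pl,
                greater = pg,
                two_sided = min(1, 2 * min(pl, pg)))
  } else {
    method <- "normal_approx"
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                                (N * (N - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- if (correct) 0.5 else 0
      p <- switch(alternative,
                  less = pnorm((u - mu + cc) / sigma),
                  greater = pnorm((u - mu - cc) / sigma,
                                  lower.tail = FALSE),
                  two_sided = {
                    z <- (u - mu - sign(u - mu) * cc) / sigma
                    min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
                  })
    }
  }
  structure(list(U = u, W = u, rank_sum = rank_sum, p_value = p,
                 method = method, alternative = alternative,
                 n1 = n1, n2 = n2),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g (rank sum of x = %g), p = %.4g [%s, %s]\n",
              x$W, x$rank_sum, x$p_value, x$method, x$alternative))
  invisible(x)
}

#' Simple linear regression with r-squared and F statistic
#'
#' Ordinary least squares `y = a + b x` with the usual `(1, n - 2)`-df F
#' test of the slope and two-sided p-value. With one predictor, `F` equals
#' the squared t statistic of the slope and `r2` the squared Pearson
#' correlation.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; `x` must not be
#'   constant.
#' @return a list of class `fit_result` with `r2`, `F`, `p_value`, `slope`,
#'   `intercept`, `n`.
#' @export
linear_fit_r2_f <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 points")
  if (length(unique(x)) == 1L) stop("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  ## a perfect fit is legitimate input (summary.lm warns about it)
  sm <- suppressWarnings(summary(fit))
  fstat <- unname(sm$fstatistic[1])
  structure(list(r2 = sm$r.squared, F = fstat,
                 p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("r^2 = %.3f, F = %.3g (df 1, %d), p = %.4g; y = %.4g + %.4g x\n",
              x$r2, x$F, x$n - 2, x$p_value, x$intercept, x$slope))
  invisible(x)
}

#' Per-sample summary statistics
#'
#' Combines fate counts with the authentication summaries: fate fractions,
#' median read length and PMD ratio of the retained reads.
#'
#' @param sample_id sample name.
#' @param counts a `fate_counts` (from [fate_counts()] or
#'   [split_by_fate()]).
#' @param pmd_results data.frame from [pmd_score()] (or numeric scores)
#'   for the sample's reads.
#' @param reads aligned read table (or numeric lengths) used for the
#'   median read length.
#' @param pmd_threshold threshold passed to [pmd_ratio()]; default 5.
#' @return a one-row data.frame (class `sample_stats`).
#' @export
summarize_sample <- function(sample_id, counts, pmd_results, reads,
                             pmd_threshold = 5) {
  stopifnot(inherits(counts, "fate_counts"))
  if (counts$n_total == 0L) stop("sample has zero reads")
  nt <- counts$n_total
  out <- data.frame(
    sample_id = sample_id,
    n_reads = nt,
    frac_target = counts$n_target / nt,
    frac_contaminant = counts$n_contaminant / nt,
    frac_ambiguous = counts$n_ambiguous / nt,
    frac_unmapped = counts$n_unmapped / nt,
    frac_too_short = counts$n_too_short / nt,
    mRL = median_read_length(reads),
    PMDR = pmd_ratio(pmd_results, threshold = pmd_threshold),
    stringsAsFactors = FALSE)
  class(out) <- c("sample_stats", "data.frame")
  out
}

REPORT_COLS <- c("sample_id", "n_reads", "frac_target", "frac_contaminant",
                 "frac_ambiguous", "frac_unmapped", "frac_too_short",
                 "mRL", "PMDR")

#' Write a per-sample report (TSV plus JSON twin)
#'
#' Fixed column order; numeric values survive a round trip to at least six
#' decimals. The JSON twin is written next to the TSV with a `.json`
#' extension.
#'
#' @param rows data.frame of per-sample rows (e.g. rbind-ed
#'   [summarize_sample()] outputs).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("report rows must be a non-empty data.frame")
  missing <- setdiff(REPORT_COLS, names(rows))
  if (length(missing))
    stop("report rows missing column(s): ", paste(missing, collapse = ", "))
  rows <- rows[, REPORT_COLS]
  ok <- tryCatch({
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rows, sub("\\.[^.]*$", ".json", path),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
    TRUE
  }, error = function(e)
    stop("failed writing report to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a per-sample report TSV
#'
#' @param path TSV written by [write_report()].
#' @return data.frame with the fixed report columns.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}
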