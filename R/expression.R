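# Expression-statistics layer: FPKM, activity filtering, trimmed-mean-of-M
# (TMM) library scaling, rank-sum contrasts, and the before/after change
# summary for labeled gene sets.

#' Fragments per kilobase per million (FPKM)
#'
#' `FPKM = count * 1e9 / (length_bp * library_size)`; library size defaults
#' to the per-sample total count.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Gene lengths in bp (named or aligned with rows).
#' @param lib_sizes Optional per-sample library sizes (> 0).
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  counts * 1e9 / outer(as.numeric(lengths), as.numeric(lib_sizes))
}

#' Transcriptionally active genes
#'
#' Keeps genes with FPKM above `threshold` in at least
#' `ceiling(min_fraction * n_samples)` samples.
#'
#' @param fpkm FPKM matrix.
#' @param threshold FPKM threshold (exceeded strictly).
#' @param min_fraction Minimum fraction of samples.
#' @return Logical vector per gene (named by rownames).
#' @export
filter_active <- function(fpkm, threshold = 1, min_fraction = 0.5) {
  need <- ceiling(min_fraction * ncol(fpkm))
  stats::setNames(rowSums(fpkm > threshold) >= need, rownames(fpkm))
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Per-sample scaling factors combining library size with a trimmed, weighted
#' mean of log expression ratios against a reference sample: genes with a
#' zero count in either sample are excluded, the top and bottom `trim_m` of
#' M-values and `trim_a` of A-values are trimmed, and the remaining M-values
#' are averaged with inverse approximate-variance weights. Factors are the
#' effective per-sample scalings (library size x TMM ratio), normalized to
#' geometric mean 1, so dividing counts by them makes samples comparable.
#'
#' @param counts Genes x samples count matrix (>= 2 samples).
#' @param trim_m,trim_a Trim fractions for M and A values.
#' @param ref Reference sample (index or name); default: sample whose upper
#'   quartile of scaled counts is closest to the mean upper quartile.
#' @return Named numeric vector of factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample")
  if (is.null(ref)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  }
  if (is.character(ref)) ref <- match(ref, colnames(counts))
  tmm_one <- function(k) {
    if (k == ref) return(1)
    ok <- counts[, k] > 0 & counts[, ref] > 0
    yk <- counts[ok, k]; yr <- counts[ok, ref]
    nk <- lib[k]; nr <- lib[ref]
    m <- log2((yk / nk) / (yr / nr))
    a <- 0.5 * log2((yk / nk) * (yr / nr))
    if (length(m) == 0L) return(1)
    keep_m <- rank(m) > trim_m * length(m) &
      rank(m) <= (1 - trim_m) * length(m)
    keep_a <- rank(a) > trim_a * length(a) &
      rank(a) <= (1 - trim_a) * length(a)
    keep <- keep_m & keep_a
    if (!any(keep)) keep <- rep(TRUE, length(m))
    w <- 1 / ((nk - yk) / (nk * yk) + (nr - yr) / (nr * yr))
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }
  ratio <- vapply(seq_len(ncol(counts)), tmm_one, numeric(1))
  f <- lib * ratio
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Wilcoxon rank-sum test
#'
#' Exact null distribution when `m + n <= 20` and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric samples (non-empty).
#' @param sides `"two"` or `"greater"` (a tends larger than b).
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, sides = c("two", "greater")) {
  sides <- match.arg(sides)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  exact <- (length(a) + length(b) <= 20L) && !anyDuplicated(c(a, b))
  stats::wilcox.test(a, b, alternative = if (sides == "two") "two.sided"
                     else "greater", exact = exact, correct = TRUE)$p.value
}

#' Before/after expression-change summary for labeled gene sets
#'
#' Computes per-gene mean FPKM per condition, the absolute change and the
#' log2 fold change, then rank-sum compares each labeled gene set against
#' its complement on expression levels and on absolute changes.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Gene lengths (bp).
#' @param condition Per-sample labels, exactly two levels; the first level
#'   (alphabetically, or of a factor) is "before".
#' @param sets Named list of logical vectors (per gene) defining partitions,
#'   e.g. `list(olfc = ..., expanded = ...)`.
#' @param focal Optional name of a set whose mean-change direction is
#'   reported (e.g. the expanded subfamily).
#' @return List with `per_gene` (data.frame), `tests` (per set: rank-sum p
#'   on levels and on absolute changes), `focal_direction`.
#' @export
expression_change_summary <- function(counts, lengths, condition, sets,
                                      focal = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("need exactly two conditions")
  if (any(table(condition) < 1L)) stop("missing condition")
  fpkm <- compute_fpkm(counts, lengths)
  lev <- levels(condition)
  m_before <- rowMeans(fpkm[, condition == lev[1], drop = FALSE])
  m_after <- rowMeans(fpkm[, condition == lev[2], drop = FALSE])
  per_gene <- data.frame(
    gene = rownames(counts),
    mean_before = m_before, mean_after = m_after,
    abs_change = abs(m_after - m_before),
    log2fc = log2((m_after + 1) / (m_before + 1)),
    level = rowMeans(fpkm),
    stringsAsFactors = FALSE)
  tests <- NULL
  for (nm in names(sets)) {
    inset <- sets[[nm]]
    if (sum(inset) == 0L || sum(!inset) == 0L) next
    p_level <- wilcoxon_rank_sum(per_gene$level[inset],
                                 per_gene$level[!inset])
    p_change <- wilcoxon_rank_sum(per_gene$abs_change[inset],
                                  per_gene$abs_change[!inset])
    tests <- rbind(tests, data.frame(
      set = nm, n_in = sum(inset), n_out = sum(!inset),
      p_level = p_level, p_abs_change = p_change,
      stringsAsFactors = FALSE))
  }
  focal_direction <- NULL
  if (!is.null(focal) && focal %in% names(sets)) {
    idx <- sets[[focal]]
    delta <- mean(m_after[idx]) - mean(m_before[idx])
    focal_direction <- list(set = focal, mean_change = delta,
                            direction = if (delta < 0) "decreased"
                                        else "increased")
  }
  list(per_gene = per_gene, tests = tests, focal_direction = focal_direction)
}
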