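# Nonparametric group statistics: median/IQR summaries and the
# Mann-Whitney U test (exact enumeration for small untied samples).

#' Median and interquartile range of a group
#'
#' Quantiles use linear interpolation (R type 7) so results are exactly
#' reproducible.
#'
#' @param values nonempty numeric vector
#' @return list with `median` and `IQR` (Q3 - Q1)
#' @export
summarize_group <- function(values) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty group")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], IQR = q[3] - q[1])
}

#' Mann-Whitney U test (two-sided)
#'
#' U counts the pairs where a value of `a` exceeds a value of `b` (ties
#' count one half). For combined n <= 12 with no ties the two-sided p-value
#' is computed by exact enumeration of all rank assignments,
#' `p = min(1, 2 * min(P(U <= u), P(U >= u)))`; otherwise the normal
#' approximation with tie correction is used (no continuity correction).
#' Samples with zero rank variance (all values identical) give p = 1.
#'
#' @param a,b nonempty numeric vectors
#' @param alpha significance level for the `significant` flag
#'   (default 0.01)
#' @return list: `U`, `p_value`, `method` (`"exact"` or `"normal"`),
#'   `significant` (p <= alpha)
#' @export
mann_whitney_u <- function(a, b, alpha = 0.01) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n <= 12L) {
    us <- exact_u_distribution(n1, n2)
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    s2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(s2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = u, p_value = p, method = method, significant = p <= alpha)
}

# All possible U values over the C(n, n1) assignments of ranks to sample a.
exact_u_distribution <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  colSums(combos) - n1 * (n1 + 1) / 2
}

#' Gold-standard disease labels from the D2 descriptor
#'
#' The labeling rule of the classifier harness: the threshold is the 3rd
#' quartile (type-7 linear interpolation) of the control animals' D2, and
#' an animal is labeled diseased iff its D2 strictly exceeds it.
#'
#' @param table feature table with columns `group` and `D2`
#' @return logical vector (TRUE = diseased), one per row, with the
#'   threshold attached as attribute `"threshold"`
#' @export
gold_standard_labels <- function(table) {
  stopifnot(all(c("group", "D2") %in% names(table)))
  ctrl <- table$D2[table$group == "control" & !is.na(table$D2)]
  if (!length(ctrl)) stop("no control D2 values to derive the gold standard")
  thr <- stats::quantile(ctrl, 0.75, type = 7, names = FALSE)
  structure(table$D2 > thr, threshold = thr)
}

#' Descriptor summary table by group
#'
#' Median/IQR per group plus the control-vs-treated Mann-Whitney test for
#' each requested feature column.
#'
#' @param table feature table with a `group` column
#' @param features character vector of feature column names
#' @param alpha significance level (default 0.01)
#' @return data.frame with one row per feature
#' @export
group_statistics <- function(table, features, alpha = 0.01) {
  stopifnot("group" %in% names(table), all(features %in% names(table)))
  rows <- lapply(features, function(ft) {
    ctrl <- table[[ft]][table$group == "control"]
    trt <- table[[ft]][table$group == "treated"]
    sc <- summarize_group(ctrl); st <- summarize_group(trt)
    mw <- mann_whitney_u(ctrl, trt, alpha)
    data.frame(feature = ft,
               control_median = sc$median, control_IQR = sc$IQR,
               treated_median = st$median, treated_IQR = st$IQR,
               U = mw$U, p_value = mw$p_value,
               significant = mw$significant)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
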