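# Exploratory segment and sample statistics on aggregated matrices:
# normalized Manhattan distance (NMD), outlier and contrastive outlier
# scores, per-chromosome peak scores, and the Mann-Whitney U
# discriminatory-feature test with Benjamini-Hochberg correction.

as_value_matrix <- function(x) {
  if (inherits(x, "cn_matrix")) total_matrix(x) else as.matrix(x)
}

#' Normalized Manhattan distance between two aggregated profiles
#'
#' Each vector is divided by its own sum before the Manhattan distance is
#' taken, which makes the score invariant to whole-genome doubling:
#' `nmd(S, k * S) = 0` for any `k > 0`.
#'
#' @param s,r Numeric vectors of equal length with positive sums and no
#'   missing cells (aggregate imputed profiles to guarantee this).
#' @return A value in `[0, 2]`.
#' @examples
#' nmd(c(1, 3), c(2, 2))  # 0.5
#' @export
nmd <- function(s, r) {
  if (length(s) != length(r))
    stop("nmd: vectors differ in length", call. = FALSE)
  if (anyNA(s) || anyNA(r))
    stop("nmd: missing cells are not allowed; aggregate imputed profiles",
         call. = FALSE)
  ss <- sum(s); sr <- sum(r)
  if (ss <= 0 || sr <= 0)
    stop("nmd: vectors must have positive sums", call. = FALSE)
  sum(abs(s / ss - r / sr))
}

#' Pairwise NMD matrix for a cohort matrix
#' @param x A [cn_matrix] (total CN is used) or numeric samples x segments
#'   matrix.
#' @return Symmetric matrix with zero diagonal, values in `[0, 2]`.
#' @export
nmd_matrix <- function(x) {
  m <- as_value_matrix(x)
  norm <- m / rowSums(m)
  n <- nrow(norm)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d <- sum(abs(norm[i, ] - norm[j, ]))
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Outlier score of a sample against a cluster
#'
#' Mean NMD from the sample to the members of a cluster; when the sample
#' itself is a member it is excluded from the mean (its zero self-distance
#' would deflate the score).
#'
#' @param s Numeric vector (one aggregated sample).
#' @param cluster Numeric matrix, one row per cluster member.
#' @param self Optional row index or row name of `s` within `cluster` to
#'   exclude; with the default `"auto"`, the first row identical to `s`
#'   (if any) is treated as the sample itself and excluded.
#' @return Mean NMD (non-negative).
#' @export
outlier_score <- function(s, cluster, self = "auto") {
  m <- as_value_matrix(cluster)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  drop_rows <- if (identical(self, "auto")) {
    hits <- which(apply(m, 1, function(r)
      isTRUE(all.equal(unname(r), unname(s)))))
    utils::head(hits, 1L)
  } else if (is.character(self)) which(rownames(m) %in% self)
  else as.integer(self)
  if (length(drop_rows)) m <- m[-drop_rows, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("outlier_score: cluster is empty after self-exclusion", call. = FALSE)
  mean(apply(m, 1, function(r) nmd(s, r)))
}

#' Contrastive outlier score between two classes
#'
#' `OS(S, C2) - OS(S, C1)` for a sample conceptually belonging to `C1`:
#' low or negative values flag samples that resemble the other class more
#' than their own (candidate mislabels). Threshold selection on the score
#' distribution is delegated to [knee_point()].
#'
#' @param s Numeric vector (one aggregated sample).
#' @param c1 Matrix of the sample's own class (self excluded
#'   automatically).
#' @param c2 Matrix of the contrasting class.
#' @return `OS(s, c2) - OS(s, c1)`.
#' @export
contrastive_outlier_score <- function(s, c1, c2) {
  outlier_score(s, c2) - outlier_score(s, c1)
}

#' Peak score of an aggregated profile
#'
#' Discrete second-difference `PS(i) = (s_i - s_{i-1}) - (s_{i+1} - s_i)`
#' with reflected boundaries (`s_0 = s_1`, `s_{n+1} = s_n`): positive at
#' bins above their neighbors, negative at dips, ~0 in monotone runs. Bins
#' must be contiguous and of comparable size; with a `chrom` grouping the
#' score is computed independently per chromosome, and a chromosome with a
#' single bin scores 0. The scores of each chromosome telescope to 0.
#'
#' @param s Numeric vector of binned CN values (e.g. a class mean profile).
#' @param chrom Optional grouping vector (chromosome per bin).
#' @return Numeric vector of peak scores, same length as `s`.
#' @examples
#' peak_score(c(1, 3, 1))  # -2 4 -2: the middle bin is a peak of 4
#' @export
peak_score <- function(s, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("all", length(s))
  stopifnot(length(chrom) == length(s))
  out <- numeric(length(s))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    v <- s[ix]
    n <- length(v)
    if (n < 2) { out[ix] <- 0; next }
    left <- c(v[1], v[-n])    # s_0 = s_1
    right <- c(v[-1], v[n])   # s_{n+1} = s_n
    out[ix] <- (v - left) - (right - v)
  }
  out
}

# Mann-Whitney U with normal approximation and tie correction (no
# continuity correction); two-sided. Constant pooled values give p = 1.
mwu_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u, p = 1))
  z <- (u - na * nb / 2) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Discriminatory segments between two sample groups
#'
#' Per-segment two-sided Mann-Whitney U test (normal approximation with
#' tie correction) comparing the copy numbers of two groups, with
#' Benjamini-Hochberg adjustment across all segments as one family.
#'
#' @param a,b [cn_matrix] objects (total CN is used) or numeric
#'   samples x segments matrices over the same segments, each with at
#'   least 2 samples.
#' @return data.table with one row per segment (`segment`, `u`, `p`, `q`),
#'   sorted by `q` then `p`.
#' @export
discriminatory_features <- function(a, b) {
  ma <- as_value_matrix(a); mb <- as_value_matrix(b)
  if (ncol(ma) != ncol(mb))
    stop("groups are aggregated on different segments", call. = FALSE)
  if (nrow(ma) < 2 || nrow(mb) < 2)
    stop("both groups need at least 2 samples", call. = FALSE)
  labs <- colnames(ma) %||% as.character(seq_len(ncol(ma)))
  res <- lapply(seq_len(ncol(ma)), function(j) mwu_test(ma[, j], mb[, j]))
  out <- data.table::data.table(
    segment = labs,
    u = vapply(res, `[[`, 0, "u"),
    p = vapply(res, `[[`, 0, "p"))
  out[, q := stats::p.adjust(p, method = "BH")]
  data.table::setorder(out, q, p)
  out[]
}
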