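#' Copy number from the depth ratio
#'
#' Estimates rDNA copy number as the mean read depth over an rRNA gene
#' interval divided by the mean depth over a single-copy background
#' interval (the published baseline uses the first 10 Mb of chromosome 3;
#' the simulator's backbone plays that role).
#'
#' @param depth_gene Integer/numeric vector of per-base depths over the
#'   gene interval (e.g. a slice of an `rdna_depth`).
#' @param depth_background Per-base depths over the background interval.
#' @return The depth ratio (a single non-negative number).
#' @examples
#' estimate_cnv(rep(800, 100), rep(1, 1000))  # 800
#' @export
estimate_cnv <- function(depth_gene, depth_background) {
  if (inherits(depth_gene, "rdna_depth")) depth_gene <- depth_gene$depth
  if (inherits(depth_background, "rdna_depth"))
    depth_background <- depth_background$depth
  if (!length(depth_background))
    stop("background interval is empty", call. = FALSE)
  bg <- mean(depth_background)
  if (bg <= 0)
    stop("background interval has zero mean coverage; cannot estimate copy number",
         call. = FALSE)
  mean(depth_gene) / bg
}

# Slice an rdna_depth over a 1-based inclusive interval.
depth_slice <- function(depth, interval) {
  depth$depth[interval[1]:interval[2]]
}

#' Per-individual 18S and 25S copy-number estimates
#'
#' @param unit_depth `rdna_depth` on the rDNA unit.
#' @param background_depth `rdna_depth` on the single-copy background.
#' @param annotation An `rdna_annotation` giving the 18S and 25S intervals.
#' @param id Individual identifier.
#' @return One-row data.frame (id, cnv_18S, cnv_25S).
#' @export
estimate_cnv_18S_25S <- function(unit_depth, background_depth, annotation,
                                 id = "individual") {
  bg <- background_depth$depth
  data.frame(
    id = id,
    cnv_18S = estimate_cnv(depth_slice(unit_depth,
                                       annotation$intervals$`18S`), bg),
    cnv_25S = estimate_cnv(depth_slice(unit_depth,
                                       annotation$intervals$`25S`), bg))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison with the W statistic defined as the sum
#' of the ranks of `x` in the pooled sample minus n_x(n_x+1)/2, midranks
#' for ties; p-values are exact for small samples without ties and use the
#' normal approximation with continuity and tie correction otherwise
#' (delegates to the vetted [stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `W` and two-sided `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 50 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` and `p`.
#' @export
normality_test <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("sample size must be in [3, 5000]", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("sample is constant; normality is undefined", call. = FALSE)
  st <- stats::shapiro.test(x)
  list(statistic = unname(st$statistic), p = st$p.value)
}

#' Cohort summary of copy-number estimates
#'
#' Min, Q1, median, mean, Q3 and max per gene; quartiles by linear
#' interpolation of order statistics (quantile type 7).
#'
#' @param cohort data.frame with columns `cnv_18S` and `cnv_25S` (one row
#'   per individual), or a numeric vector for a single gene.
#' @return data.frame with one row per gene.
#' @export
cnv_cohort_summary <- function(cohort) {
  summ <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(min = min(v), q1 = q[1], median = q[2], mean = mean(v),
               q3 = q[3], max = max(v))
  }
  if (is.numeric(cohort)) {
    if (!length(cohort)) stop("empty cohort", call. = FALSE)
    return(cbind(gene = "cnv", summ(cohort)))
  }
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  rbind(cbind(gene = "18S", summ(cohort$cnv_18S)),
        cbind(gene = "25S", summ(cohort$cnv_25S)))
}
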