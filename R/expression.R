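# Joining binding classes to gene expression: rank-quantile categories,
# percent-bound-per-category curves, and class-wise Welch tests.

#' Rank-based expression categories
#'
#' Splits genes into `n` contiguous, near-equal-size categories of
#' increasing log2 expression (quantile split by stable rank; ties keep the
#' category of their stable-sorted position; sizes differ by at most 1,
#' with the lower categories taking any remainder).
#'
#' @param expression an expression table.
#' @param n number of categories (default 5).
#' @return The expression table with a `category` integer column added and
#'   attribute `"boundaries"` (upper expression bound per category).
#' @export
expression_categories <- function(expression, n = 5) {
  if (n < 2) stop("n must be at least 2")
  N <- nrow(expression)
  if (N < n) stop("need at least n genes")
  sizes <- rep(N %/% n, n) + (seq_len(n) <= N %% n)
  ord <- order(expression$expression)  # stable
  category <- integer(N)
  category[ord] <- rep.int(seq_len(n), sizes)
  out <- expression
  out$category <- category
  attr(out, "boundaries") <- as.numeric(tapply(expression$expression,
                                               category, max))
  out
}

#' Percentage of bound promoters per expression category
#'
#' Per expression category and stratum, 100 x (promoters in the stratum) /
#' (promoters in the category). Strata are either binding of one factor
#' (`"otx2"`: >=1 primary peak; `"myc"`) or each co-binding class.
#'
#' @param summaries per-promoter summaries from [classify_promoters()].
#' @param categories output of [expression_categories()].
#' @param stratify_by `"otx2"`, `"myc"`, or `"cobind_class"`.
#' @return `data.frame(category, stratum, n_category, n_in_stratum,
#'   percent)`.
#' @export
percent_bound_by_category <- function(summaries, categories,
                                      stratify_by = c("cobind_class", "otx2", "myc")) {
  stratify_by <- match.arg(stratify_by)
  cat_of <- categories$category[match(summaries$gene_id, categories$gene_id)]
  keep <- !is.na(cat_of)
  s <- summaries[keep, , drop = FALSE]
  cat_of <- cat_of[keep]
  n_cat <- max(categories$category)
  sizes <- tabulate(cat_of, nbins = n_cat)
  if (any(sizes == 0)) stop("empty expression category")
  strata <- switch(stratify_by,
                   otx2 = list(OTX2 = s$n_otx2_peaks > 0),
                   myc = list(MYC = s$myc_bound),
                   cobind_class = lapply(setNames(nm = cobind_levels()),
                                         function(cl) s$cobind_class == cl))
  out <- lapply(names(strata), function(nm) {
    inb <- tabulate(cat_of[strata[[nm]]], nbins = n_cat)
    data.frame(category = seq_len(n_cat), stratum = nm,
               n_category = sizes, n_in_stratum = inb,
               percent = 100 * inb / sizes, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Class-wise expression comparison (Welch t-tests)
#'
#' Compares log2 expression of genes in the reference co-binding class
#' (default `multi+MYC`) against each other class separately, and against
#' all other classes pooled, with a two-sample t-test (Welch by default).
#' Degenerate comparisons (all values identical) are reported with `NA`
#' statistics instead of failing.
#'
#' @param expression an expression table.
#' @param summaries per-promoter summaries from [classify_promoters()].
#' @param reference reference class.
#' @param dataset_label free-text label recorded in the report (e.g. which
#'   expression dataset was used).
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return A list of class `class_expression_report` with the per-class
#'   sample sizes/means/sds and a `tests` data.frame (comparison, t, df,
#'   two-sided p).
#' @export
class_expression_test <- function(expression, summaries,
                                  reference = "multi+MYC",
                                  dataset_label = "dataset",
                                  var_equal = FALSE) {
  expr <- expression$expression[match(summaries$gene_id, expression$gene_id)]
  keep <- !is.na(expr)
  if (any(!keep))
    message(sum(!keep), " promoter(s) excluded: no expression measurement")
  cls <- as.character(summaries$cobind_class[keep])
  expr <- expr[keep]
  groups <- split(expr, factor(cls, levels = cobind_levels()))
  stats_tab <- data.frame(
    class = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, function(x) if (length(x)) mean(x) else NA_real_, 0),
    sd = vapply(groups, function(x) if (length(x) > 1) sd(x) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  ref <- groups[[reference]]
  if (length(ref) < 2) stop("reference class needs at least 2 genes")
  run_test <- function(x, y) {
    if (length(y) < 2) return(c(NA_real_, NA_real_, NA_real_))
    tt <- tryCatch(t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) return(c(NA_real_, NA_real_, NA_real_))  # degenerate
    c(unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }
  others <- setdiff(names(groups)[vapply(groups, length, 0L) > 0], reference)
  tests <- lapply(others, function(cl) {
    r <- run_test(ref, groups[[cl]])
    data.frame(comparison = paste(reference, "vs", cl), t = r[1], df = r[2],
               p_value = r[3], stringsAsFactors = FALSE)
  })
  pooled <- run_test(ref, unlist(groups[others], use.names = FALSE))
  tests <- rbind(do.call(rbind, tests),
                 data.frame(comparison = paste(reference, "vs pooled others"),
                            t = pooled[1], df = pooled[2], p_value = pooled[3],
                            stringsAsFactors = FALSE))
  structure(list(dataset = dataset_label, reference = reference,
                 class_stats = stats_tab, tests = tests,
                 welch = !var_equal),
            class = "class_expression_report")
}

#' @export
print.class_expression_report <- function(x, ...) {
  cat(sprintf("<class_expression_report> dataset=%s reference=%s (%s t-test)\n",
              x$dataset, x$reference, if (x$welch) "Welch" else "pooled"))
  print(x$class_stats, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
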