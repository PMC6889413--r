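#' Responder labeling from CAPS scores
#'
#' Treatment response is a >= 30 percent decrease of the total CAPS score
#' at follow-up relative to baseline (boundary inclusive).
#'
#' @param caps_pre,caps_post Baseline and follow-up total CAPS scores
#'   (vectors; `caps_pre > 0`, both non-negative).
#' @return Character vector, `"responder"` / `"non-responder"`.
#' @export
label_response <- function(caps_pre, caps_post) {
  if (any(caps_pre <= 0)) stop("caps_pre must be positive")
  if (any(caps_post < 0)) stop("CAPS scores cannot be negative")
  ifelse((caps_pre - caps_post) / caps_pre >= 0.30,
         "responder", "non-responder")
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with pooled variance, `df = n1 + n2 - 2`, two-sided p. The
#' t sign follows the difference `mean2 - mean1`, so the caller's group
#' order determines the sign (printed tables are not always consistent
#' about it).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p`.
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means")
  }
  tt <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Pooled two-sample t test on raw data
#'
#' @param x1,x2 Numeric vectors.
#' @return List with `t`, `df`, `p` (sign follows `mean(x2) - mean(x1)`,
#'   matching [pooled_t()]).
#' @export
pooled_t_raw <- function(x1, x2) {
  res <- t.test(x2, x1, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pearson chi-square test without continuity correction
#'
#' The uncorrected statistic is the variant that reproduces the printed
#' 2x2 clinical-table values; `df = (r-1)(c-1)`.
#'
#' @param tab Matrix of non-negative counts, at least 2x2.
#' @return List with `chisq`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) stop("degenerate margin: row ", which(rs == 0)[1],
                         " has zero total")
  if (any(cs == 0)) stop("degenerate margin: column ", which(cs == 0)[1],
                         " has zero total")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-rank ties correction (the standard statistic).
#'
#' @param groups List of numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  res <- kruskal.test(x, g)
  list(H = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' One-way ANOVA
#'
#' @param groups List of numeric vectors.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- summary(aov(x ~ g))[[1]]
  Fv <- res[["F value"]][1]
  if (is.na(Fv)) Fv <- 0
  list(F = Fv, df1 = res[["Df"]][1], df2 = res[["Df"]][2],
       p = if (Fv == 0) 1 else res[["Pr(>F)"]][1])
}

#' One-way ANOVA from group summary statistics
#'
#' @param means,sds,ns Per-group summaries.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(sds) == length(ns),
            all(ns >= 2))
  k <- length(means)
  gm <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- sum(ns) - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    stop("zero within-group variance with unequal means")
  }
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Recompute the demographics/clinical table from printed summary data
#'
#' Reads the shipped fixture of printed counts, means and SDs, recomputes
#' every statistic this supports (chi-square from counts, pooled t and
#' ANOVA from moments) and reports observed vs printed values with
#' absolute differences. Rows whose printed inputs are insufficient or
#' whose printed statistic does not match any standard formula (several
#' post-treatment rows, plausibly due to unreported missing data) carry
#' `reproducible = FALSE` and are reported, never force-fitted.
#'
#' @param path Fixture TSV; default: the copy shipped with the package.
#' @return data.frame: `id`, `test`, `printed`, `computed`, `abs_diff`,
#'   `reproducible`, `note`.
#' @export
reproduce_table1 <- function(path = system.file("extdata",
                                                "table1_printed.tsv",
                                                package = "rsnpredict")) {
  fx <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "test", "printed", "data", "reproducible", "note")
  missing_cols <- setdiff(required, names(fx))
  if (length(missing_cols))
    stop("fixture lacks columns: ", paste(missing_cols, collapse = ", "))
  computed <- vapply(seq_len(nrow(fx)), function(i) {
    if (fx$test[i] == "none") return(NA_real_)
    vals <- as.numeric(strsplit(fx$data[i], ",")[[1]])
    switch(fx$test[i],
           chi2_2x2 = pearson_chi2(matrix(vals, 2, byrow = TRUE))$chisq,
           chi2_3x3 = pearson_chi2(matrix(vals, 3, byrow = TRUE))$chisq,
           t_summary = pooled_t(vals[1], vals[2], vals[3],
                                vals[4], vals[5], vals[6])$t,
           anova_summary = anova_from_summary(vals[1:3], vals[4:6],
                                              vals[7:9])$F,
           none = NA_real_,
           stop("unknown test type: ", fx$test[i]))
  }, numeric(1))
  out <- data.frame(id = fx$id, test = fx$test, printed = fx$printed,
                    computed = computed,
                    abs_diff = abs(computed - fx$printed),
                    reproducible = as.logical(fx$reproducible),
                    note = fx$note, stringsAsFactors = FALSE)
  out
}
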