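# Statistical comparison layer: descriptives, normality, rank
# correlations, regressions of the pedigree coefficient on each genomic
# coefficient, autozygosity partitioning and birth-year trends.

#' Descriptive statistics
#'
#' @param values Numeric vector; missing values are dropped.
#' @return Named list `n`, `mean`, `sd` (sample, n-1), `min`, `max`,
#'   `median`.
#' @export
describe <- function(values) {
  x <- values[!is.na(values)]
  if (!length(x)) stop("no non-missing values")
  list(n = length(x), mean = mean(x), sd = stats::sd(x), min = min(x),
       max = max(x), median = stats::median(x))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard routine with explicit domain checks
#' (3 <= n <= 5000).
#'
#' @param values Numeric vector (missing dropped).
#' @return list `W`, `p`.
#' @export
shapiro_wilk <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (n = ", length(x), ")")
  }
  r <- stats::shapiro.test(x)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value from the t approximation (pairwise
#' complete observations).
#'
#' @param x,y Paired numeric vectors.
#' @return list `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  r <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                        exact = FALSE))
  list(rho = unname(r$estimate), p = r$p.value, n = sum(ok))
}

#' Regress the pedigree coefficient on a genomic coefficient
#'
#' Ordinary least squares with F_PED as response; reports slope,
#' intercept, R-squared, adjusted R-squared, the slope p-value, and the
#' residual/fitted values for visual diagnostics.
#'
#' @param table An inbreeding table with an `f_ped` column.
#' @param predictor Name of the predictor column (e.g. `"f_roh"`).
#' @return list `predictor`, `beta`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p`, `n`, `residuals`, `fitted`.
#' @export
regress_fped <- function(table, predictor) {
  stopifnot(predictor %in% names(table), "f_ped" %in% names(table))
  d <- data.frame(y = table$f_ped, x = table[[predictor]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("need at least 3 complete pairs")
  if (stats::var(d$x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x, data = d)
  s <- summary(fit)
  list(predictor = predictor,
       beta = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
       p = unname(s$coefficients[2, 4]), n = nrow(d),
       residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)))
}

#' Proportional contribution of length/rate classes to total autozygosity
#'
#' Per individual, each class's share of the total coefficient; shares are
#' averaged across individuals. Individuals with zero total are excluded
#' (and counted in the output) rather than contributing 0/0.
#'
#' @param table Inbreeding table.
#' @param class_cols Names of the class columns (e.g. the `f_roh_*`
#'   columns).
#' @param total_col Name of the total column they partition.
#' @return list `mean_share` (named), `n_used`, `n_excluded`.
#' @export
partition_autozygosity <- function(table, class_cols, total_col) {
  stopifnot(all(class_cols %in% names(table)), total_col %in% names(table))
  tot <- table[[total_col]]
  use <- !is.na(tot) & tot > 0
  shares <- sapply(class_cols, function(cc) {
    mean(table[[cc]][use] / tot[use])
  })
  list(mean_share = shares, n_used = sum(use),
       n_excluded = sum(!use, na.rm = TRUE))
}

#' Segment summaries by class
#'
#' Count, minimum, maximum and mean segment length per class, in the
#' layout of a class-contribution table.
#'
#' @param segments Segment table with `length_bp` and a class column.
#' @param class_col Name of the class column (default `"length_class"`).
#' @return data.frame `class`, `n`, `min_bp`, `max_bp`, `mean_bp`.
#' @export
segment_class_summary <- function(segments, class_col = "length_class") {
  cls <- segments[[class_col]]
  levs <- if (is.factor(cls)) levels(cls) else sort(unique(cls))
  out <- do.call(rbind, lapply(levs, function(lv) {
    x <- segments$length_bp[cls == lv]
    data.frame(class = lv, n = length(x),
               min_bp = if (length(x)) min(x) else NA_real_,
               max_bp = if (length(x)) max(x) else NA_real_,
               mean_bp = if (length(x)) mean(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-birth-year medians of each coefficient
#'
#' @param table Inbreeding table with a `birth_year` column.
#' @param coefficients Coefficient columns to summarise.
#' @param min_cohort Cohorts smaller than this are flagged (default 1, so
#'   nothing is flagged unless raised).
#' @return data.frame `birth_year`, `n`, `small_cohort`, one median column
#'   per coefficient.
#' @export
birth_year_trend <- function(table,
                             coefficients = intersect(
                               c("f_ped", "f_hom", "f_roh", "f_hbd", "f_grm"),
                               names(table)),
                             min_cohort = 1) {
  stopifnot("birth_year" %in% names(table))
  yrs <- sort(unique(stats::na.omit(table$birth_year)))
  out <- do.call(rbind, lapply(yrs, function(y) {
    sel <- !is.na(table$birth_year) & table$birth_year == y
    row <- data.frame(birth_year = y, n = sum(sel),
                      small_cohort = sum(sel) < min_cohort)
    for (cc in coefficients) {
      row[[paste0("median_", cc)]] <- stats::median(table[[cc]][sel], na.rm = TRUE)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Assemble the per-individual inbreeding table
#'
#' Joins the five estimators (any subset) on individual id.
#'
#' @param ids Individual ids defining the rows.
#' @param ... Named data.frames each with an `id` column plus value
#'   columns (e.g. the outputs of [f_ped()], [f_hom()], [f_roh()],
#'   [f_grm()], and the `table` element of [run_hbd()]).
#' @param birth_year Optional named vector of birth years.
#' @return data.frame, one row per id.
#' @export
inbreeding_table <- function(ids, ..., birth_year = NULL) {
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(birth_year)) out$birth_year <- unname(birth_year[ids])
  for (d in list(...)) {
    stopifnot("id" %in% names(d))
    i <- match(out$id, d$id)
    for (cc in setdiff(names(d), c("id", "complete", "loglik"))) {
      out[[cc]] <- d[[cc]][i]
    }
  }
  out
}
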