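# Statistical layer: one-sample t tests (from raw values or printed
# summary statistics), Welch pairwise comparisons, one-way ANOVA across
# PEEP groups, five-number summaries, and the experiment-level report.

#' One-sample Student's t-test
#'
#' Tests a mean against a null value, either from raw values or directly
#' from printed summary statistics (mean, SEM, n): `t = (mean - null) / sem`
#' with `df = n - 1` and a two-sided p from the t distribution. The two
#' input routes agree to machine precision on the same data.
#'
#' @param values numeric vector of raw observations (or `NULL`).
#' @param mean,sem,n summary-statistic route (used when `values` is `NULL`).
#' @param null_value null-hypothesis mean.
#' @param group optional label carried into the result.
#' @return one-row data.frame of class `stat_result`: group, n, mean, sem,
#'   t, df, p, null_value.
#' @export
one_sample_t <- function(values = NULL, mean = NULL, sem = NULL, n = NULL,
                         null_value = 0, group = NA_character_) {
  if (!is.null(values)) {
    n <- length(values)
    if (n < 2) stop("one-sample t requires n >= 2")
    mean <- base::mean(values)
    sem <- stats::sd(values) / sqrt(n)
  }
  if (is.null(mean) || is.null(sem) || is.null(n))
    stop("supply either raw values or (mean, sem, n)")
  if (n < 2) stop("one-sample t requires n >= 2")
  if (sem < 0) stop("sem must be non-negative")
  if (sem == 0) {
    if (mean != null_value)
      stop("degenerate variance: sem = 0 with mean != null")
    tstat <- 0
  } else {
    tstat <- (mean - null_value) / sem
  }
  df <- n - 1
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(data.frame(group = group, n = as.integer(n), mean = mean,
                       sem = sem, t = tstat, df = df, p = p,
                       null_value = null_value, stringsAsFactors = FALSE),
            class = c("stat_result", "data.frame"))
}

#' Pairwise Welch t-tests between groups
#'
#' Unpaired Student's t-test for samples of unequal variances
#' (Welch-Satterthwaite degrees of freedom), applied to every pair of
#' groups; no multiplicity adjustment by default, Holm available.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame of class `stat_result`, one row per pair.
#' @export
welch_pairwise <- function(groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop("at least two groups are required")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  comb <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(comb)), function(ci) {
    i <- comb[1, ci]; j <- comb[2, ci]
    xi <- groups[[i]]; xj <- groups[[j]]
    ni <- length(xi); nj <- length(xj)
    vi <- stats::var(xi) / ni; vj <- stats::var(xj) / nj
    tstat <- (base::mean(xi) - base::mean(xj)) / sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (ni - 1) + vj^2 / (nj - 1))
    data.frame(group = paste(nm[i], "vs", nm[j]),
               n = as.integer(ni + nj),
               mean = base::mean(xi) - base::mean(xj),
               sem = sqrt(vi + vj), t = tstat, df = df,
               p = 2 * stats::pt(-abs(tstat), df),
               null_value = 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  structure(out, class = c("stat_result", "data.frame"))
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way F test (equal-variance form), as used to
#' compare morphometric measures across PEEP groups.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("at least two groups are required")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(y) == 0) {
    return(list(F = 0, df1 = length(groups) - 1,
                df2 = length(y) - length(groups), p = 1))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Five-number summary
#'
#' Minimum, first quartile, median, third quartile, maximum; quartiles use
#' linear interpolation with inclusive median (quantile type 7).
#'
#' @param values numeric vector (n >= 1).
#' @return named numeric vector (min, q1, median, q3, max).
#' @export
five_number <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty sample")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Summarize a multi-condition dynamics experiment
#'
#' Produces the per-condition mean +/- SEM table for the headline measures,
#' the one-sample tests of q against 1 and of d_theta against 0 per
#' condition, and (with two or more conditions) the one-way ANOVA plus Welch
#' pairwise post-hocs for each measure. Deterministic row ordering.
#'
#' @param dynamics named list (one entry per condition, e.g. per PEEP) of
#'   [pair_dynamics] tables.
#' @param angles optional named list (same names) of [pair_angles] tables.
#' @return list of class `alveodyn_report`: `summary`, `tests`, `anova`,
#'   `posthoc`, `text` (plain-text report lines).
#' @export
summarize_experiment <- function(dynamics, angles = NULL) {
  if (length(dynamics) == 0) stop("at least one condition table is required")
  nm <- names(dynamics)
  if (is.null(nm)) nm <- paste0("condition", seq_along(dynamics))
  need <- c("structure_id", "role", "q", "dS", "eps_A", "eps_ER")
  for (d in dynamics)
    if (!all(need %in% names(d)))
      stop(sprintf("schema error: dynamics table lacks columns {%s}",
                   paste(setdiff(need, names(d)), collapse = ", ")))
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  measures <- c("q", "eps_A", "eps_ER", "dD_A", "dT_A")
  summary <- do.call(rbind, lapply(seq_along(dynamics), function(i) {
    d <- dynamics[[i]]
    alv <- d[d$role == "alveolus", , drop = FALSE]
    un <- d[d$role == "unit_AAD", , drop = FALSE]
    get <- function(m) {
      x <- if (m == "q") un$q else alv[[m]]
      x <- x[!is.na(x)]
      data.frame(condition = nm[i], measure = m, n = length(x),
                 mean = if (length(x)) base::mean(x) else NA_real_,
                 sem = sem(x), stringsAsFactors = FALSE)
    }
    do.call(rbind, lapply(measures, get))
  }))

  tests <- list()
  for (i in seq_along(dynamics)) {
    un <- dynamics[[i]][dynamics[[i]]$role == "unit_AAD", , drop = FALSE]
    if (nrow(un) >= 2)
      tests[[length(tests) + 1]] <-
        one_sample_t(un$q, null_value = 1,
                     group = paste0(nm[i], ": q vs 1"))
    if (!is.null(angles) && !is.null(angles[[nm[i]]]) &&
        nrow(angles[[nm[i]]]) >= 2)
      tests[[length(tests) + 1]] <-
        one_sample_t(angles[[nm[i]]]$d_theta, null_value = 0,
                     group = paste0(nm[i], ": d_theta vs 0"))
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL

  anova <- NULL; posthoc <- NULL
  if (length(dynamics) >= 2) {
    grab <- function(m) lapply(dynamics, function(d) {
      x <- if (m == "q") d$q[d$role == "unit_AAD"] else
        d[[m]][d$role == "alveolus"]
      x[!is.na(x)]
    })
    usable <- function(gr) length(gr) >= 2 &&
      all(vapply(gr, length, 1L) >= 2)
    anova <- do.call(rbind, lapply(measures, function(m) {
      gr <- grab(m)
      if (!usable(gr)) return(NULL)
      a <- anova_oneway(gr)
      data.frame(measure = m, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
                 stringsAsFactors = FALSE)
    }))
    posthoc <- do.call(rbind, lapply(measures, function(m) {
      gr <- grab(m)
      if (!usable(gr)) return(NULL)
      names(gr) <- nm
      cbind(measure = m, welch_pairwise(gr))
    }))
  }

  text <- c("Alveolar micro-dynamics report",
            strrep("=", 32), "")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    text <- c(text, sprintf("%-12s %-8s n=%3d  mean %+.4g +/- %.3g (SEM)",
                            s$condition, s$measure, s$n, s$mean, s$sem))
  }
  if (!is.null(tests)) {
    text <- c(text, "", "One-sample tests")
    for (i in seq_len(nrow(tests))) {
      tr <- tests[i, ]
      text <- c(text, sprintf("%-24s t(%d) = %+.3f, p = %.3g",
                              tr$group, tr$df, tr$t, tr$p))
    }
  }
  if (!is.null(anova)) {
    text <- c(text, "", "One-way ANOVA across conditions")
    for (i in seq_len(nrow(anova))) {
      a <- anova[i, ]
      text <- c(text, sprintf("%-8s F(%d, %d) = %.3f, p = %.3g",
                              a$measure, a$df1, a$df2, a$F, a$p))
    }
  }
  structure(list(summary = summary, tests = tests, anova = anova,
                 posthoc = posthoc, text = text),
            class = "alveodyn_report")
}

#' @export
print.alveodyn_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
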