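## Cohort statistics report ----------------------------------------------------

.reportMetricSet <- c("d_a", "d_v", "v_v", "trbf",
                      "o2a", "o2v", "o2av", "do2", "mo2", "oef",
                      "nfl_rgcl", "ipl", "inl", "opl", "onl", "prl",
                      "irl", "trt_hist", "trt_oct",
                      "abeta42_retina", "abeta40_retina",
                      "abeta42_brain", "abeta40_brain")

.powerMetricSet <- c("o2a", "o2v", "d_v", "v_v")

#' Build the cohort statistics report
#'
#' Computes, for every metric present: per-group summaries (n, mean, SD),
#' pooled-variance two-tailed t-tests between the two groups, the pooled
#' (groups-combined) Pearson correlations of arterial oxygen content vs
#' venous velocity and of NFL/RGCL thickness vs arterial and venous oxygen
#' content, post-hoc powers (noncentral-t for the measured metrics
#' O2A, O2V, D_V and V_V; exact bivariate-normal for the observed
#' correlations), and advisory Shapiro-Wilk normality checks (never gating).
#' No multiple-testing correction is applied; the number of tests is
#' reported.
#'
#' @param x a `SummarizedExperiment` from [measureCohort()] or a data.frame
#'   with columns `animal_id`, `group` and one column per metric.
#' @param alpha significance level.
#' @return a [CohortStatsReport-class].
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 11), n_per_group = 5)
#' buildReport(measureCohort(coh))
#' @export
buildReport <- function(x, alpha = 0.05) {
  tab <- if (is(x, "SummarizedExperiment")) animalTable(x) else x
  stopifnot(is.data.frame(tab), "group" %in% names(tab))
  metrics <- intersect(.reportMetricSet, names(tab))
  missing_all <- setdiff(setdiff(names(tab), c("animal_id", "group")),
                         metrics)
  groups <- unique(tab$group)
  if (length(groups) > 2L) stop("report supports at most two groups")

  summ <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      v <- tab[[m]][tab$group == g]
      v <- v[is.finite(v)]
      if (!length(v)) {
        warning("metric ", m, " missing for all animals of group ", g,
                "; omitted")
        return(NULL)
      }
      data.frame(metric = m, group = g, n = length(v),
                 mean = mean(v), sd = sd(v), stringsAsFactors = FALSE)
    }))
  }))

  tests <- NULL
  if (length(groups) == 2L) {
    tests <- do.call(rbind, lapply(metrics, function(m) {
      a <- tab[[m]][tab$group == groups[1L]]
      b <- tab[[m]][tab$group == groups[2L]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      tt <- twoSampleTTest(a, b, alpha)
      data.frame(metric = m, t = tt$t, df = tt$df, p = tt$p,
                 significant = tt$significant, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(tests))
    tests <- data.frame(metric = character(), t = numeric(), df = numeric(),
                        p = numeric(), significant = logical())

  corr_pairs <- list(c("o2a", "v_v"), c("nfl_rgcl", "o2a"),
                     c("nfl_rgcl", "o2v"))
  correlations <- do.call(rbind, lapply(corr_pairs, function(pr) {
    if (!all(pr %in% names(tab))) return(NULL)
    ok <- is.finite(tab[[pr[1L]]]) & is.finite(tab[[pr[2L]]])
    if (sum(ok) < 4L) return(NULL)
    pc <- pearsonCorrelation(tab[[pr[1L]]][ok], tab[[pr[2L]]][ok])
    data.frame(pair = paste(pr, collapse = "~"), n = pc$n, r = pc$r,
               p = pc$p, stringsAsFactors = FALSE)
  }))
  if (is.null(correlations))
    correlations <- data.frame(pair = character(), n = integer(),
                               r = numeric(), p = numeric())

  powers <- NULL
  if (length(groups) == 2L) {
    powers <- do.call(rbind, lapply(
      intersect(.powerMetricSet, metrics), function(m) {
        s <- summ[summ$metric == m, ]
        if (nrow(s) != 2L || any(s$n < 2L) || any(s$sd == 0)) return(NULL)
        pw <- powerTwoSampleT(s$mean[1L], s$sd[1L], s$n[1L],
                              s$mean[2L], s$sd[2L], s$n[2L], alpha)
        data.frame(design = "two-sample-t", label = m,
                   effect = abs(s$mean[1L] - s$mean[2L]) /
                     sqrt(((s$n[1L] - 1) * s$sd[1L]^2 +
                           (s$n[2L] - 1) * s$sd[2L]^2) /
                          (sum(s$n) - 2)),
                   n = sum(s$n), power = pw, stringsAsFactors = FALSE)
      }))
  }
  corr_powers <- NULL
  if (nrow(correlations)) {
    corr_powers <- do.call(rbind, lapply(seq_len(nrow(correlations)),
      function(i) {
        r <- correlations$r[i]; n <- correlations$n[i]
        if (n < 4L) return(NULL)
        data.frame(design = "correlation", label = correlations$pair[i],
                   effect = abs(r), n = n,
                   power = powerCorrelation(abs(r), n, alpha),
                   stringsAsFactors = FALSE)
      }))
  }
  powers <- rbind(
    if (is.null(powers)) NULL else powers,
    if (is.null(corr_powers)) NULL else corr_powers)
  if (is.null(powers))
    powers <- data.frame(design = character(), label = character(),
                         effect = numeric(), n = integer(),
                         power = numeric())

  normality <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      v <- tab[[m]][tab$group == g]
      v <- v[is.finite(v)]
      if (length(v) < 3L || length(unique(v)) < 3L) return(NULL)
      data.frame(metric = m, group = g, n = length(v),
                 shapiro_p = shapiro.test(v)$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(normality))
    normality <- data.frame(metric = character(), group = character(),
                            n = integer(), shapiro_p = numeric())

  if (length(missing_all))
    warning("columns not in the metric dictionary were ignored: ",
            paste(missing_all, collapse = ", "))

  new("CohortStatsReport",
      summaries = summ, tests = tests, correlations = correlations,
      powers = powers, normality = normality, alpha = alpha,
      nTests = nrow(tests) + nrow(correlations))
}

#' Serialize a report to JSON and a readable text table
#'
#' @param report a [CohortStatsReport-class].
#' @param json_path,txt_path output paths (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
writeReport <- function(report, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(alpha = report@alpha, n_tests = report@nTests,
                summaries = report@summaries, tests = report@tests,
                correlations = report@correlations, powers = report@powers,
                normality_advisory = report@normality)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    wr <- function(...) writeLines(c(...), con)
    wr("Cohort statistics report",
       sprintf("alpha = %g; %d hypothesis tests (no multiplicity correction)",
               report@alpha, report@nTests), "")
    wr("== Group summaries ==")
    wr(utils::capture.output(print(report@summaries, row.names = FALSE)))
    wr("", "== Two-group t-tests (pooled variance, two-tailed) ==")
    wr(utils::capture.output(print(report@tests, row.names = FALSE)))
    wr("", "== Pooled Pearson correlations ==")
    wr(utils::capture.output(print(report@correlations, row.names = FALSE)))
    wr("", "== Post-hoc power ==")
    wr(utils::capture.output(print(report@powers, row.names = FALSE)))
  }
  invisible(c(json = json_path, txt = txt_path))
}

#' Accessors for report components
#'
#' @param report a [CohortStatsReport-class].
#' @return the corresponding data.frame.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
reportSummaries <- function(report) report@summaries

#' @rdname report-accessors
#' @export
reportTests <- function(report) report@tests

#' @rdname report-accessors
#' @export
reportCorrelations <- function(report) report@correlations

#' @rdname report-accessors
#' @export
reportPowers <- function(report) report@powers
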