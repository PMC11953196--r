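# canonical variable order mirroring the printed baseline table
report_variables <- function() c(
  "symptom_months", "age_years", "basal_diameter_um", "minimum_diameter_um",
  "la_mm2", "norm_la", "pra_mm2", "norm_pra", "piin", "ta_mm2",
  "bcva_t0_logmar", "abs_delta_bcva_logmar", "ez_t0_um", "abs_delta_ez_um",
  "elm_t0_um", "abs_delta_elm_um")

# printed correlation-table row order: index vs each metric
correlation_variables <- function() c(
  "minimum_diameter_um", "ta_mm2", "bcva_t0_logmar",
  "abs_delta_bcva_logmar", "ez_t0_um", "abs_delta_ez_um", "elm_t0_um",
  "abs_delta_elm_um", "symptom_months", "age_years")

#' Full statistical report for a scored cohort
#'
#' Reproduces the study's analysis blocks on a scored cohort table:
#' (a) five-number descriptives (with Jarque-Bera normality p) per variable,
#' (b) the index-vs-metric Spearman correlation block with listwise
#' deletion, (c) baseline-vs-follow-up Wilcoxon tests for BCVA and the
#' EZ/ELM defects, (d) the univariate regression of absolute BCVA change on
#' the index, and (e), when grader-2 replicate columns are present, Lin's
#' concordance block.  Significance is flagged at p <= 0.05, per test,
#' without multiplicity correction.
#'
#' @param scored A scored cohort data frame, see [score_cohort()].
#' @param wilcoxon_mode `"rank-sum"` (the named test, default) or
#'   `"signed-rank"` (the conventional paired alternative).
#' @return Object of class `piin_report` (a nested list of blocks).
#' @export
build_report <- function(scored, wilcoxon_mode = "rank-sum") {
  required <- c("la_mm2", "ta_mm2", "pra_mm2", "norm_pra", "norm_la", "piin")
  missing_cols <- setdiff(required, names(scored))
  if (length(missing_cols))
    stop("scored cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "))

  desc <- list()
  for (v in intersect(report_variables(), names(scored))) {
    d <- describe(scored[[v]])
    d$jarque_bera_p <- tryCatch(jarque_bera(scored[[v]])$p_value,
                                error = function(e) NA_real_)
    desc[[v]] <- d
  }
  descriptives <- do.call(rbind, lapply(names(desc), function(v)
    data.frame(variable = v, median = desc[[v]]$median, q1 = desc[[v]]$q1,
               q3 = desc[[v]]$q3, max = desc[[v]]$max, min = desc[[v]]$min,
               n = desc[[v]]$n_nonmissing,
               jarque_bera_p = desc[[v]]$jarque_bera_p)))

  corr <- do.call(rbind, lapply(
    intersect(correlation_variables(), names(scored)), function(v) {
      r <- spearman_cor(scored$piin, scored[[v]])
      data.frame(variable = v, rho = r$rho, p_value = r$p_value,
                 n_used = r$n_used, significant = r$p_value <= 0.05)
    }))

  chg_pairs <- list(bcva_logmar = c("bcva_t0_logmar", "bcva_t1_logmar"),
                    ez_um = c("ez_t0_um", "ez_t1_um"),
                    elm_um = c("elm_t0_um", "elm_t1_um"))
  change <- NULL
  for (nm in names(chg_pairs)) {
    p <- chg_pairs[[nm]]
    if (!all(p %in% names(scored))) next
    w <- wilcoxon_change_test(scored[[p[1]]], scored[[p[2]]],
                              mode = wilcoxon_mode)
    change <- rbind(change, data.frame(
      variable = nm, statistic = w$statistic, p_value = w$p_value,
      mode = w$mode, exact = w$exact, significant = w$p_value <= 0.05))
  }

  regression <- if ("abs_delta_bcva_logmar" %in% names(scored)) {
    univariate_regression(scored$piin, scored$abs_delta_bcva_logmar)
  }

  ccc <- NULL
  if (all(c("grader2_la_mm2", "grader2_ta_mm2") %in% names(scored))) {
    g2_la <- scored$grader2_la_mm2
    g2_pra <- scored$grader2_ta_mm2 - g2_la
    blocks <- list(la_mm2 = list(scored$la_mm2, g2_la),
                   pra_mm2 = list(scored$pra_mm2, g2_pra),
                   ta_mm2 = list(scored$ta_mm2, scored$grader2_ta_mm2))
    ccc <- do.call(rbind, lapply(names(blocks), function(nm) {
      cc <- concordance(blocks[[nm]][[1]], blocks[[nm]][[2]])
      data.frame(variable = nm, ccc = cc$ccc, ci_low = cc$ci_low,
                 ci_high = cc$ci_high, n = cc$n)
    }))
  } else {
    message("grader-2 columns absent: concordance block omitted")
  }

  structure(list(
    package = "piin",
    package_version = as.character(utils::packageVersion("piin")),
    n_eyes = nrow(scored),
    descriptives = descriptives,
    correlations = corr,
    change_tests = change,
    regression = regression,
    concordance = ccc),
    class = "piin_report")
}

#' Write / read a report as JSON
#'
#' Serialization is loss-free for the report's numeric content and is
#' byte-stable for identical inputs (no timestamps are embedded).
#'
#' @param report A `piin_report`.
#' @param path Output path (`.json`).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  structure(obj, class = "piin_report")
}

#' Render a report as plain text
#'
#' Mirrors the row order of the printed descriptive and correlation tables.
#'
#' @param report A `piin_report`.
#' @return Character vector of lines.
#' @export
render_report_text <- function(report) {
  out <- c(sprintf("Photoreceptor Integrity Index report (piin %s)",
                   report$package_version),
           sprintf("Eyes: %d", report$n_eyes), "",
           "== Descriptive statistics (median [q1; q3], min-max) ==")
  d <- report$descriptives
  out <- c(out, sprintf("  %-22s %9.3f [%8.3f; %8.3f]  %8.3f - %8.3f  (n=%d)",
                        d$variable, d$median, d$q1, d$q3, d$min, d$max, d$n))
  out <- c(out, "", "== Spearman correlations with the index ==")
  co <- report$correlations
  out <- c(out, sprintf("  %-22s rho %+6.3f  p %.4g%s  (n=%d)", co$variable,
                        co$rho, co$p_value,
                        ifelse(co$significant, " *", "  "), co$n_used))
  if (!is.null(report$change_tests)) {
    ct <- report$change_tests
    out <- c(out, "", "== Baseline vs follow-up (Wilcoxon) ==",
             sprintf("  %-12s W %9.1f  p %.4g%s [%s]", ct$variable,
                     ct$statistic, ct$p_value,
                     ifelse(ct$significant, " *", "  "), ct$mode))
  }
  if (!is.null(report$regression)) {
    rg <- report$regression
    out <- c(out, "", "== Regression: |delta BCVA| ~ index ==",
             sprintf("  slope %.4f  intercept %.4f  adj.R2 %.4f  p %.4g",
                     rg$slope, rg$intercept, rg$adjusted_r2,
                     rg$slope_p_value))
  }
  if (!is.null(report$concordance)) {
    cc <- report$concordance
    out <- c(out, "", "== Intergrader concordance (CCC, 95% CI) ==",
             sprintf("  %-8s %.4f (%.4f - %.4f)  n=%d", cc$variable, cc$ccc,
                     cc$ci_low, cc$ci_high, cc$n))
  }
  out
}

#' @export
print.piin_report <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

#' Read / write cohort tables
#'
#' Delimited text, UTF-8, comma separator, header row; missing values are
#' empty fields (never sentinel numbers).  Tables round-trip losslessly.
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' @rdname read_cohort
#' @param cohort Data frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
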