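#' Per-direction between-group comparisons of model parameters
#'
#' Runs an independent two-sample t-test per parameter and per direction
#' between the two groups of a parameter table, flagging significance at
#' 0.05 and 0.01 (the star convention of clinical reports). The Welch
#' variant is the default (robust to the unequal variances plausible
#' between patient and control groups); `var_equal = TRUE` gives Student's
#' pooled-variance test. No multiple-testing correction is applied by
#' default, mirroring standard practice in this protocol; `p_adjust =
#' "holm"` is available.
#'
#' @param table data.frame with columns `group` (exactly two levels),
#'   `target_id`, and the parameter columns.
#' @param parameters character vector of parameter columns to test
#'   (default: all numeric columns except `target_id`).
#' @param var_equal logical; `FALSE` (Welch, default) or `TRUE` (Student).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()],
#'   applied across all direction-parameter tests.
#' @return A data.frame of class `stats_result`: one row per direction and
#'   parameter with group means/SDs/n, `t`, `df`, `p`, `sig_05`, `sig_01`.
#' @export
compare_groups <- function(table, parameters = NULL, var_equal = FALSE,
                           p_adjust = "none") {
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) != 2L) {
    ls_abort("`table` must contain exactly two groups",
             "leansim_error_validation", field = "group")
  }
  if (is.null(parameters)) {
    parameters <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))],
      c("target_id", "updrs", "frt"))
  }
  rows <- list()
  for (tid in sort(unique(table$target_id))) {
    d <- table[table$target_id == tid, ]
    for (par in parameters) {
      x1 <- d[[par]][d$group == groups[1]]
      x2 <- d[[par]][d$group == groups[2]]
      x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
      if (length(x1) < 2 || length(x2) < 2) {
        ls_abort(sprintf("fewer than 2 observations for %s, target %s",
                         par, tid), "leansim_error_validation")
      }
      tt <- t.test(x1, x2, var.equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, target_id = tid,
        group1 = groups[1], mean1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
        group2 = groups[2], mean2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$sig_05 <- out$p < 0.05
  out$sig_01 <- out$p < 0.01
  class(out) <- c("stats_result", "data.frame")
  out
}

#' Spearman correlations of control gains with clinical scores
#'
#' For each direction, correlates the identified gains with the clinical
#' measures (UPDRS, FRT) across subjects using Spearman's rank correlation
#' with average-rank tie handling. Expected sign conventions: K_P
#' correlates positively with UPDRS severity and negatively with FRT reach.
#'
#' @param table data.frame with columns `subject`, `target_id`, the gain
#'   columns and the score columns; rows whose score is `NA` (e.g. healthy
#'   controls) are dropped.
#' @param gains gain columns to correlate (default `c("k_p", "k_ff")`).
#' @param scores score columns (default `c("updrs", "frt")`).
#' @return A data.frame of class `stats_result`: one row per direction,
#'   gain and score with `rho`, `p`, `n` and significance flags.
#' @export
correlate_clinical <- function(table, gains = c("k_p", "k_ff"),
                               scores = c("updrs", "frt")) {
  rows <- list()
  for (tid in sort(unique(table$target_id))) {
    d <- table[table$target_id == tid, ]
    for (g in gains) {
      for (sc in scores) {
        ok <- is.finite(d[[g]]) & is.finite(d[[sc]])
        x <- d[[g]][ok]; y <- d[[sc]][ok]
        if (length(x) < 3) {
          ls_abort(sprintf("need >= 3 paired observations for %s vs %s",
                           g, sc), "leansim_error_validation")
        }
        if (sd(x) == 0 || sd(y) == 0) {
          ls_abort(sprintf(
            "undefined correlation: constant input (%s vs %s, target %s)",
            g, sc, tid), "leansim_error_undefined_correlation")
        }
        ct <- suppressWarnings(
          cor.test(x, y, method = "spearman", exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = tid, gain = g, score = sc,
          rho = unname(ct$estimate), p = ct$p.value, n = length(x))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$sig_05 <- out$p < 0.05
  out$sig_01 <- out$p < 0.01
  class(out) <- c("stats_result", "data.frame")
  out
}
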