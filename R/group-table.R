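#' Two-arm group comparison table
#'
#' Assembles the per-parameter report of a two-arm study: mean and SD per
#' arm, the comparison test (a per-parameter override, as when morphometry
#' and VTR are compared by t test but biomechanics by Mann-Whitney, or the
#' data-driven [choose_test()] rule), the two-tailed p value, Cohen's d,
#' and a significance flag at `alpha`. Subjects missing a parameter are
#' excluded pairwise and counted in `n_missing`.
#'
#' @param records data.frame with one row per subject, an `arm` column and
#'   one column per parameter.
#' @param parameters Character vector of parameter column names; default
#'   every numeric column except `arm`/`subject_id`.
#' @param test_override Named character vector mapping parameter name to
#'   `"t"` or `"mann_whitney"`; unlisted parameters use [choose_test()].
#' @param arms Length-2 character vector: reference arm first (d > 0 means
#'   the second arm is larger).
#' @param alpha Significance threshold; default 0.05.
#' @param seed Seed forwarded to the KS Monte-Carlo table.
#' @return data.frame with one row per parameter.
#' @export
group_table <- function(records, parameters = NULL, test_override = NULL,
                        arms = c("Control", "CEMF"), alpha = 0.05,
                        seed = NULL) {
  stopifnot(is.data.frame(records), "arm" %in% names(records))
  if (!all(arms %in% records$arm))
    stop_ovtr("both arms must be present in records", "ovtr_invalid_input")
  if (is.null(parameters)) {
    num <- vapply(records, is.numeric, logical(1))
    parameters <- setdiff(names(records)[num], c("subject_id"))
  }
  rows <- lapply(parameters, function(p) {
    xa <- records[[p]][records$arm == arms[1]]
    xb <- records[[p]][records$arm == arms[2]]
    n_missing <- sum(is.na(xa)) + sum(is.na(xb))
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      return(data.frame(parameter = p, mean_a = NA, sd_a = NA, mean_b = NA,
                        sd_b = NA, test = NA, statistic = NA, p = NA,
                        cohens_d = NA, significant = NA,
                        n_missing = n_missing, stringsAsFactors = FALSE))
    }
    test <- test_override[p]
    if (is.null(test) || is.na(test))
      test <- as.character(choose_test(xa, xb, seed = seed))
    res <- if (test == "t") {
      tt <- students_t(xa, xb)
      list(statistic = tt$t, p = tt$p)
    } else {
      mw <- mann_whitney_u(xa, xb)
      list(statistic = mw$U, p = mw$p)
    }
    d <- cohens_d(xa, xb)
    data.frame(parameter = p,
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               test = test, statistic = res$statistic, p = res$p,
               cohens_d = d, significant = res$p < alpha,
               n_missing = n_missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "arms") <- arms
  attr(out, "alpha") <- alpha
  out
}

#' Render a group table as markdown
#' @param tab data.frame from [group_table()].
#' @return Character vector of markdown lines.
#' @export
format_group_table <- function(tab) {
  arms <- attr(tab, "arms") %||% c("A", "B")
  hdr <- sprintf("| Parameter | %s (mean ± SD) | %s (mean ± SD) | test | p | d |",
                 arms[1], arms[2])
  sep <- "|---|---|---|---|---|---|"
  body <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sprintf("| %s | %.3g ± %.3g | %.3g ± %.3g | %s | %.3g%s | %.3g |",
            r$parameter, r$mean_a, r$sd_a, r$mean_b, r$sd_b, r$test, r$p,
            ifelse(isTRUE(r$significant), "*", ""), r$cohens_d)
  }, character(1))
  c(hdr, sep, body)
}
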