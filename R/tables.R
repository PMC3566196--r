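# Packaged per-subject study tables and the side-by-side reproduction of
# their printed group summaries.

FIXTURE_MD5 <- c(table1.csv = "729a65d7915e1b43a3faa909f3795a18",
                 table2.csv = "efccc593d65651e208324c8e15584e6b",
                 table_means.csv = "221497731aa6abd2f75629355a962d1b")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "cranioflow")
  if (path == "") stop(sprintf("fixture %s not found", file))
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[[file]])))
    stop(sprintf("integrity error: fixture %s checksum mismatch", file))
  path
}

#' Packaged per-subject study tables
#'
#' `load_table1()` returns per-subject flows, drainage fractions and venogram
#' grades (ordinal 1-6, missing as `NA`); `load_table2()` the hydrodynamic
#' parameters (CSF stroke volume, PTP-PG, ICVC, MRICP);
#' `load_subject_records()` the merge of both, one row per subject with the
#' matched `pair_id`. File checksums are verified on every load.
#'
#' @return A data frame.
#' @export
load_table1 <- function() {
  d <- utils::read.csv(fixture_path("table1.csv"), na.strings = "n.a.",
                       stringsAsFactors = FALSE)
  d$mrv_grade <- as.integer(d$mrv_grade)
  d
}

#' @rdname load_table1
#' @export
load_table2 <- function() {
  utils::read.csv(fixture_path("table2.csv"), na.strings = "n.a.",
                  stringsAsFactors = FALSE)
}

#' @rdname load_table1
#' @export
load_subject_records <- function() {
  merge(load_table1(), load_table2()[, c("subject_id", "csf_sv", "ptp_pg",
                                         "icvc", "mricp")],
        by = "subject_id", sort = FALSE)
}

load_printed_means <- function() {
  utils::read.csv(fixture_path("table_means.csv"), stringsAsFactors = FALSE)
}

#' Recompute the printed group summaries and run the statistical battery
#'
#' Every printed group mean/median of the packaged tables is recomputed from
#' the per-subject values and compared with the printed cell. The tolerance
#' per cell is the rounding-propagation bound: half a unit of the per-subject
#' printed precision (which survives averaging) plus half a unit of the mean's
#' own printed precision. The rank-transform mixed-model comparison is run for
#' every continuous variable and the Mann-Whitney U test for the ordinal
#' venogram grade (pairs with a missing grade excluded pairwise).
#'
#' @param records Per-subject records; defaults to the packaged tables.
#' @return Object of class `table_reproduction`: `cells` (printed vs
#'   recomputed with discrepancies), `tests` (one row per variable) and
#'   `all_within` (logical).
#' @export
reproduce_tables <- function(records = load_subject_records()) {
  printed <- load_printed_means()
  cells <- printed
  cells$recomputed <- NA_real_
  cells$n <- NA_integer_
  for (i in seq_len(nrow(printed))) {
    gs <- group_summary(records, printed$variable[i],
                        statistic = printed$statistic[i])
    row <- gs[gs$group == printed$group[i], ]
    cells$recomputed[i] <- round(row$value, printed$mean_digits[i])
    cells$n[i] <- row$n
  }
  cells$discrepancy <- abs(cells$recomputed - cells$printed)
  cells$tolerance <- 0.5 * 10^(-cells$subject_digits) +
    0.5 * 10^(-cells$mean_digits)
  cells$within <- cells$discrepancy <= cells$tolerance + 1e-12

  cont_vars <- c("tcbf", "jvf", "jvf_pct", "dcv_pct", "vv_pct", "ev_pct",
                 "svf_total_pct", "csf_sv", "ptp_pg", "icvc", "mricp")
  tests <- list()
  for (v in cont_vars) {
    res <- paired_rank_lmm_test(records, v)
    tests[[v]] <- data.frame(variable = v, test = res$test,
                             statistic = res$statistic, p_value = res$p_value,
                             n_mTBI = res$n[1L], n_control = res$n[2L],
                             stringsAsFactors = FALSE)
  }
  # venogram grade: ordinal, unpaired nonparametric test with pairwise
  # exclusion of pairs missing a grade
  t1 <- records
  bad_pairs <- unique(t1$pair_id[is.na(t1$mrv_grade)])
  gr <- t1[!t1$pair_id %in% bad_pairs, ]
  res <- mann_whitney_u(gr$mrv_grade[gr$group == "mTBI"],
                        gr$mrv_grade[gr$group == "control"],
                        variable = "mrv_grade")
  tests$mrv_grade <- data.frame(variable = "mrv_grade", test = res$test,
                                statistic = res$statistic,
                                p_value = res$p_value,
                                n_mTBI = res$n[1L], n_control = res$n[2L],
                                stringsAsFactors = FALSE)
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(cells = cells, tests = tests,
                 all_within = all(cells$within)),
            class = "table_reproduction")
}

#' @export
print.table_reproduction <- function(x, ...) {
  cat("Reproduction of printed group summaries\n")
  print(x$cells[, c("table", "variable", "group", "statistic", "printed",
                    "recomputed", "discrepancy", "within")], row.names = FALSE)
  cat(sprintf("\nAll cells within rounding-propagation tolerance: %s\n",
              x$all_within))
  cat("\nGroup comparisons\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
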