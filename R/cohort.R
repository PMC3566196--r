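# Synthetic matched cohorts with known group-level parameters, for power and
# type-I-error studies of the statistical battery.

#' Group-level parameters of a synthetic matched cohort
#'
#' Per-group means and SDs of the drainage and hydrodynamic quantities. The
#' defaults are the group summary rows of the packaged per-subject tables
#' (total cerebral blood flow in ml/min, jugular fraction and secondary
#' fractions in percent of tCBF, ICVC in ml, PTP-PG in mmHg/cm, CSF stroke
#' volume in ml); SDs not printed as group summaries are the sample SDs of the
#' packaged per-subject values.
#'
#' @param n Subjects per group (>= 2).
#' @param seed Default integer seed used by [generate_cohort()].
#' @param mtbi,control Named lists of `c(mean, sd)` entries for `tcbf`,
#'   `jvf_pct`, `svf_pct`, `icvc`, `ptp_pg`, `csf_sv`, plus `svf_split`
#'   (relative DCV/VV/EV shares of the secondary fraction).
#' @return Object of class `cohort_effect_spec`.
#' @export
cohort_effect_spec <- function(n = 15L, seed = 1L,
                               mtbi = list(tcbf = c(838, 147),
                                           jvf_pct = c(60.9, 21),
                                           svf_pct = c(12.3, 10.9),
                                           svf_split = c(DCV = 5.1, VV = 3.2,
                                                         EV = 3.9),
                                           icvc = c(0.48, 0.124),
                                           ptp_pg = c(0.043, 0.0087),
                                           csf_sv = c(0.58, 0.18)),
                               control = list(tcbf = c(779, 112),
                                              jvf_pct = c(76.8, 10),
                                              svf_pct = c(5.5, 3.3),
                                              svf_split = c(DCV = 3.1,
                                                            VV = 0.5,
                                                            EV = 1.8),
                                              icvc = c(0.61, 0.213),
                                              ptp_pg = c(0.041, 0.015),
                                              csf_sv = c(0.54, 0.16))) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("invalid cohort spec: n must be >= 2")
  for (g in list(mtbi, control)) {
    if (g$jvf_pct[1L] < 0 || g$jvf_pct[1L] > 100 ||
        g$svf_pct[1L] < 0 || g$svf_pct[1L] > 100)
      stop("invalid cohort spec: fractions must lie in [0, 100]")
    if (g$jvf_pct[1L] + g$svf_pct[1L] > 100)
      stop("invalid cohort spec: jugular + secondary fraction exceeds 100")
    if (any(vapply(g[c("tcbf", "icvc", "ptp_pg", "csf_sv")],
                   function(x) x[1L] <= 0 || x[2L] < 0, TRUE)))
      stop("invalid cohort spec: means must be positive, SDs non-negative")
  }
  structure(list(n = n, seed = as.integer(seed),
                 groups = list(mTBI = mtbi, control = control)),
            class = "cohort_effect_spec")
}

# Truncated-normal sampler that preserves the target mean: the underlying
# location is solved so that the truncated mean equals `mean` (plain
# truncation would bias e.g. a 60.9 +/- 21 % fraction bounded by [0, 100]).
# Sampling is by inverse CDF.
rtruncnorm_mean <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  if (mean <= lower || mean >= upper)
    stop("invalid spec: target mean outside the truncation interval")
  tmean <- function(mu) {
    al <- (lower - mu) / sd; be <- (upper - mu) / sd
    Z <- stats::pnorm(be) - stats::pnorm(al)
    mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / Z
  }
  mu <- tryCatch(
    stats::uniroot(function(m) tmean(m) - mean,
                   lower = mean - 6 * sd, upper = mean + 6 * sd,
                   tol = 1e-10)$root,
    error = function(e) mean)
  al <- stats::pnorm((lower - mu) / sd); be <- stats::pnorm((upper - mu) / sd)
  mu + sd * stats::qnorm(al + stats::runif(n) * (be - al))
}

# Truncated normal at fixed location (used where a per-subject bound makes the
# target mean infeasible)
rtruncnorm_plain <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  al <- stats::pnorm((lower - mean) / sd); be <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(al + stats::runif(n) * (be - al))
}

#' Generate a synthetic matched cohort
#'
#' Draws per-subject drainage and hydrodynamic quantities from mean-preserving
#' truncated normal distributions at the configured group parameters, enforces
#' jugular + secondary fraction <= 100 per subject (the secondary fraction is
#' truncated to the remaining headroom), splits the secondary fraction among
#' DCV/VV/EV by the configured shares, and derives the compliance index and
#' MRICP from ICVC and PTP-PG under `calibration`. Matched pair IDs are
#' assigned across the two groups.
#'
#' @param effects A [cohort_effect_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @param calibration A [calibration_config()].
#' @return Data frame of subject records (one row per subject, both groups)
#'   with the packaged tables' columns plus `compliance_index`.
#' @export
generate_cohort <- function(effects = cohort_effect_spec(), seed = NULL,
                            calibration = calibration_config()) {
  stopifnot(inherits(effects, "cohort_effect_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(if (is.null(seed)) effects$seed else as.integer(seed))
  n <- effects$n
  rows <- list()
  for (gname in names(effects$groups)) {
    g <- effects$groups[[gname]]
    tcbf <- rtruncnorm_mean(n, g$tcbf[1L], g$tcbf[2L], lower = 0)
    jvf_pct <- rtruncnorm_mean(n, g$jvf_pct[1L], g$jvf_pct[2L], 0, 100)
    svf_pct <- numeric(n)
    for (i in seq_len(n)) {
      headroom <- 100 - jvf_pct[i]
      svf_pct[i] <- if (g$svf_pct[1L] < 0.999 * headroom)
        rtruncnorm_mean(1L, g$svf_pct[1L], g$svf_pct[2L], 0, headroom)
      else
        rtruncnorm_plain(1L, g$svf_pct[1L], g$svf_pct[2L], 0, headroom)
    }
    share <- g$svf_split / sum(g$svf_split)
    icvc <- rtruncnorm_mean(n, g$icvc[1L], g$icvc[2L], lower = 0)
    ptp <- rtruncnorm_mean(n, g$ptp_pg[1L], g$ptp_pg[2L], lower = 0)
    csf_sv <- rtruncnorm_mean(n, g$csf_sv[1L], g$csf_sv[2L], lower = 0)
    ci <- icvc / (ptp * calibration$d)
    prefix <- if (gname == "mTBI") "SYN_MTBI" else "SYN_CTR"
    rows[[gname]] <- data.frame(
      subject_id = sprintf("%s_%02d", prefix, seq_len(n)),
      group = gname, pair_id = seq_len(n),
      age = NA_integer_, sex = NA_character_,
      tcbf = tcbf, jvf = jvf_pct * tcbf / 100, jvf_pct = jvf_pct,
      dcv_pct = svf_pct * share[["DCV"]], vv_pct = svf_pct * share[["VV"]],
      ev_pct = svf_pct * share[["EV"]], svf_total_pct = svf_pct,
      mrv_grade = NA_integer_,
      csf_sv = csf_sv, ptp_pg = ptp, icvc = icvc,
      compliance_index = ci, mricp = calibration$a / ci + calibration$b,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort using the packaged tables' column layout
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path Output CSV path; missing values are written as `n.a.` to match
#'   the packaged fixtures.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "group", "pair_id", "age", "sex", "tcbf", "jvf",
            "jvf_pct", "dcv_pct", "vv_pct", "ev_pct", "svf_total_pct",
            "mrv_grade", "csf_sv", "ptp_pg", "icvc", "mricp")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, na = "n.a.")
  invisible(path)
}
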