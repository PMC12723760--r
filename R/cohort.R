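# Cohort data model: long-format repeated cognitive assessments joined to a
# one-row-per-subject baseline covariate table. This is the universal input
# to every downstream stage.

visit_required_cols <- c("subject_id", "time_years", "pacc", "pacc_version",
                         "cdr_global", "cdr_memory")
visit_biomarker_cols <- c("amyloid_centiloid", "ptau217", "tau_mtl_suvr",
                          "tau_neo_suvr", "hippocampal_volume")
baseline_required_cols <- c("subject_id", "arm", "ptau217", "amyloid_suvr",
                            "amyloid_centiloid", "apoe4_carrier", "sex_female",
                            "age", "education", "hippocampal_volume", "icv")
baseline_optional_cols <- c("tau_pet_composite")
arm_levels <- c("LEARN", "placebo", "solanezumab")

#' Construct and validate a cohort object
#'
#' Checks referential integrity (every visit's subject has exactly one
#' baseline row), sorts visits by subject and time, and re-anchors each
#' subject's times so their earliest visit is 0 (time is modelled as years
#' since each subject's first visit).
#'
#' @param visits Data frame of repeated measures (one row per visit); see
#'   [read_cohort()] for the column contract.
#' @param baseline Data frame of baseline covariates, one row per subject.
#' @return An object of class \code{cohort_data}: a list with elements
#'   \code{visits} and \code{baseline}.
#' @export
cohort_data <- function(visits, baseline) {
  visits <- as.data.frame(visits)
  baseline <- as.data.frame(baseline)
  check_cols(visits, visit_required_cols, "visits")
  check_cols(baseline, baseline_required_cols, "baseline")
  for (col in visit_biomarker_cols)
    if (!col %in% names(visits)) visits[[col]] <- NA_real_
  for (col in baseline_optional_cols)
    if (!col %in% names(baseline)) baseline[[col]] <- NA_real_

  visits$subject_id <- as.character(visits$subject_id)
  baseline$subject_id <- as.character(baseline$subject_id)
  dup <- baseline$subject_id[duplicated(baseline$subject_id)]
  if (length(dup))
    stopf("duplicate baseline row(s) for subject(s): %s",
          paste(unique(dup), collapse = ", "))
  orphan <- setdiff(visits$subject_id, baseline$subject_id)
  if (length(orphan))
    stopf("visit subject(s) missing from baseline table: %s",
          paste(orphan, collapse = ", "))
  if (!all(baseline$arm %in% arm_levels))
    stopf("arm must be one of %s", paste(arm_levels, collapse = "/"))
  if (any(!is.finite(visits$time_years)) || any(visits$time_years < 0, na.rm = TRUE))
    stopf("time_years must be finite and non-negative")

  baseline$active_treatment <- as.integer(baseline$arm == "solanezumab")
  visits <- visits[order(visits$subject_id, visits$time_years), , drop = FALSE]
  t0 <- tapply(visits$time_years, visits$subject_id, min)
  visits$time_years <- visits$time_years - unname(t0[visits$subject_id])
  rownames(visits) <- rownames(baseline) <- NULL
  structure(list(visits = visits, baseline = baseline), class = "cohort_data")
}

check_cols <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s table is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
}

#' Read / write a cohort from CSV
#'
#' CSV dialect: comma-separated, UTF-8, header row required, empty cells for
#' missing values. Visit columns: \code{subject_id, time_years, pacc,
#' pacc_version, cdr_global, cdr_memory} plus optional longitudinal biomarkers
#' (\code{amyloid_centiloid, ptau217, tau_mtl_suvr, tau_neo_suvr,
#' hippocampal_volume}). Baseline columns: \code{subject_id, arm, ptau217,
#' amyloid_suvr, amyloid_centiloid, apoe4_carrier, sex_female, age, education,
#' hippocampal_volume, icv} plus optional \code{tau_pet_composite}.
#'
#' @param visits_path,baseline_path CSV file paths.
#' @return \code{read_cohort}: a validated \code{cohort_data}.
#' @export
read_cohort <- function(visits_path, baseline_path) {
  for (p in c(visits_path, baseline_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  baseline <- utils::read.csv(baseline_path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
  cohort_data(visits, baseline)
}

#' @rdname read_cohort
#' @param cohort A \code{cohort_data}.
#' @export
write_cohort <- function(cohort, visits_path, baseline_path) {
  stopifnot(inherits(cohort, "cohort_data"))
  b <- cohort$baseline
  b$active_treatment <- NULL  # derived on read
  utils::write.csv(cohort$visits, visits_path, row.names = FALSE, na = "")
  utils::write.csv(b, baseline_path, row.names = FALSE, na = "")
  invisible(c(visits_path, baseline_path))
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d subjects, %d visits, median follow-up %.1f y\n",
              nrow(x$baseline), nrow(x$visits),
              stats::median(tapply(x$visits$time_years, x$visits$subject_id, max))))
  invisible(x)
}

#' Clinical Dementia Rating progression rule
#'
#' A subject is a CDR progressor if their CDR Global score is greater than
#' zero at two consecutive visits, or at their last visit. "Consecutive" means
#' consecutive among visits with a non-missing CDR assessment: a missing
#' interim assessment cannot break an observed run.
#'
#' @param cdr_global Numeric vector of CDR Global scores in time order for one
#'   subject (may contain NA).
#' @return \code{1L} or \code{0L}; \code{NA_integer_} when every assessment is
#'   missing (subject excluded from progression summaries).
#' @examples
#' derive_cdr_progression(c(0, 0, 0.5, 0.5)) # 1: two consecutive > 0
#' derive_cdr_progression(c(0, 0.5, 0))      # 0: isolated, not last
#' derive_cdr_progression(c(0, 0, 0.5))      # 1: last visit > 0
#' @export
derive_cdr_progression <- function(cdr_global) {
  obs <- cdr_global[!is.na(cdr_global)]
  if (!length(obs)) return(NA_integer_)
  pos <- obs > 0
  consec <- length(pos) >= 2 && any(pos[-1] & pos[-length(pos)])
  as.integer(consec || pos[length(pos)])
}

#' Baseline characteristics by latent class
#'
#' Descriptive summary in the style of a trial baseline table: per class and
#' overall, mean (SD) for continuous covariates, count (percent) for
#' categorical covariates, and count (percent) of CDR progressors (rule of
#' [derive_cdr_progression()]; subjects with no CDR data are excluded from
#' that denominator). Percentages are always count / the denominator reported
#' in the same table.
#'
#' @param cohort A \code{cohort_data}.
#' @param class_labels Named vector (names = subject_id) of class labels
#'   (integer or character); every subject must be labelled.
#' @return Data frame with columns \code{class, variable, level, n, count,
#'   pct, mean, sd}. Categorical rows carry \code{count}/\code{pct};
#'   continuous rows carry \code{mean}/\code{sd}; \code{n} is the class size
#'   (or non-missing denominator for CDR progression and tau PET).
#' @export
summarize_by_class <- function(cohort, class_labels) {
  stopifnot(inherits(cohort, "cohort_data"))
  b <- cohort$baseline
  unlab <- setdiff(b$subject_id, names(class_labels))
  if (length(unlab))
    stopf("unlabelled subject(s): %s", paste(utils::head(unlab, 5), collapse = ", "))
  cls <- as.character(class_labels[b$subject_id])

  # baseline PACC from the visit at time 0
  v <- cohort$visits
  first <- v[!duplicated(v$subject_id), ]
  b$pacc_baseline <- first$pacc[match(b$subject_id, first$subject_id)]
  b$cdr_progressor <- vapply(
    b$subject_id,
    function(s) derive_cdr_progression(v$cdr_global[v$subject_id == s]),
    integer(1)
  )
  if (all(c("hippocampal_volume", "icv") %in% names(b)) &&
      sum(stats::complete.cases(b[c("hippocampal_volume", "icv")])) >= 3) {
    ok <- stats::complete.cases(b[c("hippocampal_volume", "icv")])
    b$hipp_atrophy_z <- NA_real_
    b$hipp_atrophy_z[ok] <- residualize_and_z(b$hippocampal_volume[ok], b$icv[ok])
  }

  continuous <- intersect(
    c("age", "education", "pacc_baseline", "amyloid_centiloid", "ptau217",
      "hipp_atrophy_z", "tau_pet_composite"), names(b))
  categorical <- list(
    arm = b$arm,
    apoe4_carrier = ifelse(b$apoe4_carrier == 1, "carrier", "non-carrier"),
    sex = ifelse(b$sex_female == 1, "female", "male"),
    cdr_progression = ifelse(is.na(b$cdr_progressor), NA,
                             ifelse(b$cdr_progressor == 1, "progressor",
                                    "non-progressor"))
  )

  groups <- c(split(seq_len(nrow(b)), cls), list(overall = seq_len(nrow(b))))
  rows <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    n_g <- length(idx)
    for (var in continuous) {
      x <- b[[var]][idx]
      rows[[length(rows) + 1L]] <- data.frame(
        class = gname, variable = var, level = NA_character_,
        n = sum(!is.na(x)), count = NA_integer_, pct = NA_real_,
        mean = if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_,
        sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else NA_real_)
    }
    for (var in names(categorical)) {
      x <- categorical[[var]][idx]
      denom <- sum(!is.na(x))
      for (lev in sort(unique(x[!is.na(x)]))) {
        cnt <- sum(x == lev, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          class = gname, variable = var, level = lev,
          n = denom, count = cnt,
          pct = if (denom > 0) 100 * cnt / denom else NA_real_,
          mean = NA_real_, sd = NA_real_)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class = gname, variable = "n_subjects", level = NA_character_,
      n = n_g, count = n_g,
      pct = 100 * n_g / nrow(b), mean = NA_real_, sd = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a class summary table as CSV and aligned plain text
#'
#' @param summary A data frame from [summarize_by_class()].
#' @param csv_path,txt_path Output paths (either may be NULL to skip).
#' @export
write_summary <- function(summary, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(summary, csv_path, row.names = FALSE, na = "")
  if (!is.null(txt_path)) {
    fmt <- summary
    fmt$pct <- ifelse(is.na(fmt$pct), "", sprintf("%.1f%%", fmt$pct))
    fmt$mean <- ifelse(is.na(fmt$mean), "", sprintf("%.2f", fmt$mean))
    fmt$sd <- ifelse(is.na(fmt$sd), "", sprintf("(%.2f)", fmt$sd))
    writeLines(utils::capture.output(print(fmt, row.names = FALSE)), txt_path)
  }
  invisible(summary)
}

#' Expand a class-by-covariate count table into a categorical cohort
#'
#' Helper for validating summary arithmetic against published class-wise
#' baseline count tables: takes a long count table (columns \code{variable},
#' \code{level}, then one count column per class) and expands it into a
#' minimal \code{cohort_data} plus class labels in which every categorical
#' marginal matches the given counts exactly. Continuous covariates are left
#' missing; CDR progressor status is realized as visit sequences
#' (progressors get CDR 0.5 at their final two visits).
#'
#' @param counts Data frame with columns \code{variable, level} and one
#'   integer column per class.
#' @return List with elements \code{cohort} (a \code{cohort_data}) and
#'   \code{labels} (named class vector).
#' @export
cohort_from_class_counts <- function(counts) {
  class_cols <- setdiff(names(counts), c("variable", "level"))
  sizes <- vapply(class_cols, function(cc) {
    v <- counts[counts$variable == "arm", ]
    sum(v[[cc]])
  }, numeric(1))
  labels <- character(0)
  baselines <- list()
  visits <- list()
  sid <- 0L
  for (ci in seq_along(class_cols)) {
    cc <- class_cols[ci]
    n_c <- sizes[ci]
    ids <- sprintf("S%05d", sid + seq_len(n_c)); sid <- sid + n_c
    labels[ids] <- cc
    assign_levels <- function(varname) {
      sub <- counts[counts$variable == varname, ]
      if (sum(sub[[cc]]) != n_c)
        stopf("counts for %s in class %s sum to %d, expected %d",
              varname, cc, sum(sub[[cc]]), n_c)
      rep(sub$level, times = sub[[cc]])
    }
    arm <- assign_levels("arm")
    apoe <- assign_levels("apoe4_carrier")
    sexf <- assign_levels("sex")
    prog <- assign_levels("cdr_progression")
    baselines[[cc]] <- data.frame(
      subject_id = ids, arm = arm,
      ptau217 = NA_real_, amyloid_suvr = NA_real_, amyloid_centiloid = NA_real_,
      apoe4_carrier = as.integer(apoe == "carrier"),
      sex_female = as.integer(sexf == "female"),
      age = NA_real_, education = NA_real_,
      hippocampal_volume = NA_real_, icv = NA_real_)
    cdr <- ifelse(prog == "progressor", 1, 0)
    visits[[cc]] <- data.frame(
      subject_id = rep(ids, each = 3L),
      time_years = rep(c(0, 1, 2), times = n_c),
      pacc = 0, pacc_version = 1L,
      cdr_global = as.vector(vapply(cdr, function(p)
        if (p == 1) c(0, 0.5, 0.5) else c(0, 0, 0), numeric(3))),
      cdr_memory = NA_real_)
  }
  cohort <- cohort_data(do.call(rbind, visits), do.call(rbind, baselines))
  list(cohort = cohort, labels = labels)
}
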