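#' Age decade bin (AGE10)
#'
#' Bins age in years into 10-year decades, `floor(age / 10) * 10`, capped at
#' 90 (ages 90 and above share the top bin).
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @return Integer vector of decade bins in `{0, 10, ..., 90}`.
#' @export
age10 <- function(age) {
  if (any(age < 0 | !is.finite(age))) {
    stop("age must be finite and non-negative", call. = FALSE)
  }
  as.integer(pmin(floor(age / 10) * 10, 90))
}

#' Stratified cohort table of per-posture index means
#'
#' Aggregates per-subject per-posture values into cells keyed by sex, age
#' decade and posture: cell mean, sample SD (n - 1; `NA` with a single
#' subject) and n per index, skipping subjects whose value for that posture
#' is missing.
#'
#' @param subject_long Data.frame in long format with columns `subject_id`,
#'   `sex`, `age10`, `posture`, plus one numeric column per index (see
#'   [cohort_long()]).
#' @param index_cols Index columns to aggregate; defaults to all numeric
#'   columns beyond the keys.
#' @return Object of class `"cohort_table"`: data.frame with one row per
#'   (sex, age10, posture) cell and columns `<index>_mean`, `<index>_sd`,
#'   `<index>_n`.
#' @export
stratified_table <- function(subject_long, index_cols = NULL) {
  keys <- c("subject_id", "sex", "age10", "posture")
  stopifnot(all(keys %in% names(subject_long)))
  if (is.null(index_cols)) {
    index_cols <- setdiff(
      names(subject_long)[vapply(subject_long, is.numeric, logical(1))],
      c("age10"))
  }
  cells <- unique(subject_long[, c("sex", "age10", "posture")])
  cells <- cells[order(cells$sex, cells$age10,
                       match(cells$posture, lying_postures)), ]
  rownames(cells) <- NULL
  for (col in index_cols) {
    cells[[paste0(col, "_mean")]] <- NA_real_
    cells[[paste0(col, "_sd")]] <- NA_real_
    cells[[paste0(col, "_n")]] <- 0L
  }
  for (i in seq_len(nrow(cells))) {
    rows <- subject_long$sex == cells$sex[i] &
      subject_long$age10 == cells$age10[i] &
      subject_long$posture == cells$posture[i]
    for (col in index_cols) {
      v <- subject_long[[col]][rows]
      v <- v[!is.na(v)]
      cells[[paste0(col, "_n")]][i] <- length(v)
      if (length(v) >= 1L) cells[[paste0(col, "_mean")]][i] <- mean(v)
      if (length(v) >= 2L) cells[[paste0(col, "_sd")]][i] <- stats::sd(v)
    }
  }
  class(cells) <- c("cohort_table", "data.frame")
  cells
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d cells (sex x AGE10 x posture)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Eta-squared effect size from a one-way decomposition
#'
#' `eta_sq = SS_effect / SS_total` with `SS_effect = sum_g n_g (mean_g -
#' grand_mean)^2` and `SS_total = sum (y - grand_mean)^2`; the p-value comes
#' from the one-way F-test. With zero total variance the effect size is
#' defined as 0.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List with `ss_effect`, `ss_total`, `eta_sq`, `p`, `n`.
#' @export
#' @examples
#' eta_squared(c(1, 2, 3, 4), c("a", "a", "b", "b"))$eta_sq  # 0.8
eta_squared <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (length(values) < 2L || nlevels(groups) < 2L) {
    stop("need >= 2 values in >= 2 groups", call. = FALSE)
  }
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_effect <- sum(ns * (means - gm)^2)
  ss_total <- sum((values - gm)^2)
  if (ss_total == 0) {
    return(list(ss_effect = 0, ss_total = 0, eta_sq = 0, p = NA_real_,
                n = length(values)))
  }
  p <- stats::anova(stats::lm(values ~ groups))[["Pr(>F)"]][1L]
  list(ss_effect = ss_effect, ss_total = ss_total,
       eta_sq = ss_effect / ss_total, p = p, n = length(values))
}

#' One-within-factor repeated-measures ANOVA for posture effects
#'
#' Tests whether an index differs across the four lying postures within
#' subjects, removing the between-subject block, and optionally the
#' posture-by-group interaction (e.g. posture x AGE10). Complete-case:
#' subjects missing any posture are dropped. Fitted with
#' `aov(value ~ posture + Error(subject))` (or `posture * group` with a
#' grouping factor), the textbook one-within-factor decomposition.
#'
#' @param mat Numeric matrix, one row per subject, one column per posture
#'   (column names are posture labels).
#' @param group Optional between-subject factor, one element per row.
#' @return List with `F_posture`, `p_posture`, `F_interaction`,
#'   `p_interaction` (both `NA` without a group), `n_subjects`.
#' @export
posture_rm_anova <- function(mat, group = NULL) {
  mat <- as.matrix(mat)
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  if (!is.null(group)) {
    group <- factor(group[complete])
    if (nlevels(group) < 2L) group <- NULL  # no between-subject contrast
  }
  if (nrow(mat) < 2L) {
    return(list(F_posture = NA_real_, p_posture = NA_real_,
                F_interaction = NA_real_, p_interaction = NA_real_,
                n_subjects = nrow(mat)))
  }
  n <- nrow(mat)
  k <- ncol(mat)
  long <- data.frame(
    value = as.vector(mat),
    posture = factor(rep(colnames(mat) %||% paste0("p", seq_len(k)),
                         each = n)),
    subject = factor(rep(seq_len(n), times = k))
  )
  pick <- function(tab, term, col) {
    i <- match(term, trimws(rownames(tab)))
    if (is.na(i)) NA_real_ else tab[i, col]
  }
  if (is.null(group)) {
    fit <- stats::aov(value ~ posture + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    F_post <- pick(tab, "posture", "F value")
    p_post <- pick(tab, "posture", "Pr(>F)")
    F_int <- NA_real_
    p_int <- NA_real_
  } else {
    long$group <- rep(group, times = k)
    fit <- stats::aov(value ~ posture * group + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    F_post <- pick(tab, "posture", "F value")
    p_post <- pick(tab, "posture", "Pr(>F)")
    F_int <- pick(tab, "posture:group", "F value")
    p_int <- pick(tab, "posture:group", "Pr(>F)")
  }
  # degenerate case: no variance at all -> an effect sum of squares of zero
  # is reported as F = 0 rather than 0/0
  ss_post <- pick(tab, "posture", "Sum Sq")
  if (!is.na(ss_post) && ss_post < 1e-12 &&
      (is.na(F_post) || !is.finite(F_post))) {
    F_post <- 0; p_post <- 1
  }
  ss_int <- pick(tab, "posture:group", "Sum Sq")
  if (!is.na(ss_int) && ss_int < 1e-12 &&
      (is.na(F_int) || !is.finite(F_int))) {
    F_int <- 0; p_int <- 1
  }
  list(F_posture = unname(F_post), p_posture = unname(p_post),
       F_interaction = unname(F_int), p_interaction = unname(p_int),
       n_subjects = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
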