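#' Decliner classification, matching and association statistics
#'
#' The nested case-control workflow: classify delayed decliners from MMSE
#' trajectories, match non-decliner controls on age and initial stroke
#' severity, compare groups variable-by-variable, and quantify
#' brain-cognition associations up to a voxel-wise logistic model of
#' amyloid uptake.
#'
#' @name clinical_stats
NULL

#' Classify a subject from the MMSE trajectory
#'
#' Decliner: a decline of at least 3 points annually, or an absolute drop
#' of at least 5 points between baseline and the last score. Non-decliner:
#' a decline of one point or less per year and an absolute decline of
#' fewer than 3 points. Trajectories meeting neither definition are
#' `indeterminate`. Annualization is 12 * change / months.
#'
#' @param mmse_baseline baseline MMSE (0-30).
#' @param mmse_final last MMSE (0-30).
#' @param interval_months positive months between baseline and last
#'   evaluation.
#' @return character vector: `"decliner"`, `"non_decliner"` or
#'   `"indeterminate"`.
#' @export
classify_decliner <- function(mmse_baseline, mmse_final, interval_months) {
  if (anyNA(mmse_baseline) || anyNA(mmse_final) || anyNA(interval_months))
    stop("MMSE scores and intervals must not be missing")
  stopifnot(all(interval_months > 0),
            all(mmse_baseline >= 0 & mmse_baseline <= 30),
            all(mmse_final >= 0 & mmse_final <= 30))
  change <- mmse_final - mmse_baseline
  annual_rate <- 12 * change / interval_months
  decliner <- annual_rate <= -3 | change <= -5
  non_decliner <- annual_rate >= -1 & (mmse_baseline - mmse_final) < 3
  ifelse(decliner, "decliner",
         ifelse(non_decliner, "non_decliner", "indeterminate"))
}

#' Match controls to decliners by age and stroke severity
#'
#' Greedy 1:1 matching in a seeded random decliner order. Each decliner is
#' paired with the nearest unused pool member within |age difference| <=
#' `age_tol` years and |NIHSS difference| <= `nihss_tol` points, nearness
#' being |d age| + |d NIHSS| with ties broken by pool row order. Decliners
#' with no admissible partner are reported unmatched, never force-paired.
#'
#' @param decliners data frame with columns `id`, `age_years`,
#'   `nihss_baseline`.
#' @param pool candidate controls, same columns.
#' @param age_tol,nihss_tol matching tolerances (defaults 3 years,
#'   2 points).
#' @param seed optional integer seed for the matching order.
#' @return data frame: `decliner_id`, `control_id` (NA if unmatched),
#'   `age_diff`, `nihss_diff`.
#' @export
match_controls <- function(decliners, pool, age_tol = 3, nihss_tol = 2,
                           seed = NULL) {
  need <- c("id", "age_years", "nihss_baseline")
  stopifnot(all(need %in% names(decliners)), all(need %in% names(pool)))
  if (nrow(pool) == 0L) stop("control pool is empty")
  if (!is.null(seed)) set.seed(seed)
  order_d <- sample.int(nrow(decliners))
  used <- logical(nrow(pool))
  out <- data.frame(decliner_id = decliners$id, control_id = NA_character_,
                    age_diff = NA_real_, nihss_diff = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in order_d) {
    da <- abs(pool$age_years - decliners$age_years[i])
    dn <- abs(pool$nihss_baseline - decliners$nihss_baseline[i])
    ok <- !used & da <= age_tol & dn <= nihss_tol
    if (!any(ok)) next
    cand <- which(ok)
    j <- cand[order(da[cand] + dn[cand], cand)][1L]
    used[j] <- TRUE
    out$control_id[i] <- as.character(pool$id[j])
    out$age_diff[i] <- da[j]
    out$nihss_diff[i] <- dn[j]
  }
  out
}

association_row <- function(statistic_name, estimate, p_value, n, method) {
  data.frame(statistic_name = statistic_name, estimate = estimate,
             p_value = p_value, n = n, method = method,
             stringsAsFactors = FALSE)
}

#' Two-group comparison of a clinical or imaging variable
#'
#' Continuous variables: Student's t-test or Wilcoxon rank-sum. The default
#' policy uses the rank-sum test whenever either group has fewer than
#' `small_n` observations and the t-test otherwise; `test` overrides it.
#' Categorical variables: chi-squared test, falling back to Fisher's exact
#' test when any expected cell count is below 5. All p values are
#' two-sided.
#'
#' @param values_a,values_b the two groups. Continuous: numeric vectors
#'   (>= 2 each). Categorical: factors/characters, or pass a contingency
#'   `table` as `values_a` and leave `values_b` missing.
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param test `"auto"`, `"t"` or `"wilcoxon"` (continuous only).
#' @param categorical_test `"auto"` (expected-count rule), `"fisher"` or
#'   `"chisq"`.
#' @param small_n group-size cutoff for the automatic rank-sum policy.
#' @param statistic_name label carried into the result row.
#' @return one-row data frame: `statistic_name`, `estimate`, `p_value`,
#'   `n`, `method`.
#' @export
group_compare <- function(values_a, values_b = NULL,
                          variable_kind = c("continuous", "categorical"),
                          test = c("auto", "t", "wilcoxon"),
                          categorical_test = c("auto", "fisher", "chisq"),
                          small_n = 15L, statistic_name = "variable") {
  variable_kind <- match.arg(variable_kind)
  test <- match.arg(test)
  categorical_test <- match.arg(categorical_test)
  if (variable_kind == "continuous") {
    a <- values_a[!is.na(values_a)]
    b <- values_b[!is.na(values_b)]
    if (length(a) < 2L || length(b) < 2L)
      stop("need at least 2 observations per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("both groups are constant; comparison is degenerate")
    if (test == "auto")
      test <- if (min(length(a), length(b)) < small_n) "wilcoxon" else "t"
    if (test == "t") {
      ht <- stats::t.test(a, b)
      association_row(statistic_name, unname(diff(rev(ht$estimate))),
                      ht$p.value, length(a) + length(b), "t_test")
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, conf.int = TRUE))
      association_row(statistic_name, unname(ht$estimate), ht$p.value,
                      length(a) + length(b), "wilcoxon")
    }
  } else {
    tab <- if (is.table(values_a) || is.matrix(values_a)) as.table(values_a)
           else table(group = rep(c("a", "b"),
                                  c(length(values_a), length(values_b))),
                      value = c(as.character(values_a),
                                as.character(values_b)))
    if (any(dim(tab) < 2L))
      stop("categorical comparison needs a 2 x k contingency table")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- switch(categorical_test,
                         auto = any(expected < 5),
                         fisher = TRUE, chisq = FALSE)
    if (use_fisher) {
      ht <- stats::fisher.test(tab)
      association_row(statistic_name,
                      if (!is.null(ht$estimate)) unname(ht$estimate)
                      else NA_real_,
                      ht$p.value, sum(tab), "fisher_exact")
    } else {
      ht <- stats::chisq.test(tab, correct = FALSE)
      association_row(statistic_name, unname(ht$statistic), ht$p.value,
                      sum(tab), "chi_square")
    }
  }
}

#' Cohen's d with pooled standard deviation
#'
#' (mean_a - mean_b) / s_pooled, the pooled SD weighting each group's
#' variance by n - 1.
#'
#' @param values_a,values_b numeric vectors, >= 2 observations each.
#' @return effect size d (positive when group a is larger).
#' @export
cohen_d <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero; d is undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Correlation between two measures
#'
#' Spearman's rho by default (matching how the associations are reported),
#' with Pearson's r behind a flag. Small samples without ties get the
#' exact rank-permutation p value via [stats::cor.test()].
#'
#' @param x,y numeric vectors; at least 4 complete pairs.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param statistic_name label carried into the result row.
#' @return one-row data frame as in [group_compare()].
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson"),
                             statistic_name = "correlation") {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant vector")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  association_row(statistic_name, unname(ht$estimate), ht$p.value,
                  length(x), method)
}

#' Linear regression with a group interaction term
#'
#' Ordinary least squares of y on {intercept, x, group, x:group}. The
#' interaction coefficient tests whether the x-y slope differs between
#' groups — the model behind "does WMH burden relate to cognitive change
#' differently in decliners?". Groups are coded 0/1 with decliner = 1 when
#' a factor with those levels is supplied.
#'
#' @param y numeric response.
#' @param x numeric predictor.
#' @param group two-level grouping (0/1 numeric, logical, or factor with
#'   `decliner` coded 1 if present).
#' @return data frame with one row per term: `term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`; the interaction p is also attached
#'   as attribute `interaction_p`.
#' @export
interaction_regression <- function(y, x, group) {
  if (is.character(group)) group <- factor(group)
  if (is.factor(group)) {
    lev <- levels(droplevels(group))
    if (length(lev) != 2L) stop("group must have exactly 2 levels")
    ref <- if ("decliner" %in% lev) setdiff(lev, "decliner")[1L] else
      lev[1L]
    group <- as.numeric(group == setdiff(lev, ref)[1L])
  }
  group <- as.numeric(group)
  stopifnot(all(group %in% c(0, 1)))
  if (length(unique(group)) < 2L) stop("both groups must be represented")
  if (length(y) < 6L) stop("need at least 6 observations")
  mm <- cbind(`(Intercept)` = 1, x = x, group = group,
              `x:group` = x * group)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                qrm$pivot[seq_len(qrm$rank)])]
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ x * group)
  ct <- summary(fit)$coefficients
  out <- data.frame(term = rownames(ct), estimate = ct[, 1L],
                    std_error = ct[, 2L], t_value = ct[, 3L],
                    p_value = ct[, 4L], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "interaction_p") <- out$p_value[out$term == "x:group"]
  out
}

#' Voxel-wise logistic model of group on covariate-adjusted uptake
#'
#' Per in-mask voxel, fits group (decliner = 1) ~ age + sex + education +
#' SUVR by maximum likelihood and reports the Wald statistic and two-sided
#' p value for the SUVR coefficient. Voxels where the fit does not
#' converge or shows complete separation (fitted probabilities at the 0/1
#' boundary) are flagged and excluded from the thresholded mask. The mask
#' keeps voxels at uncorrected p < `alpha` (exploratory convention; no
#' multiplicity correction by default).
#'
#' @param suvr_volumes list of intensity `labeled_volume`s, one per
#'   subject, all on one grid.
#' @param groups 0/1 vector (decliner = 1), or factor/character with a
#'   `decliner` level.
#' @param age,sex,education subject-level covariates; sex coded 0/1.
#' @param brain_mask binary `labeled_volume` restricting the voxel loop.
#' @param alpha uncorrected threshold for the mask (default 0.05).
#' @return a `stat_map`: 3-D arrays `t_values`, `p_values`,
#'   `threshold_mask`, `non_converged` (each NA / 0 outside the brain
#'   mask as appropriate).
#' @export
voxelwise_logistic <- function(suvr_volumes, groups, age, sex, education,
                               brain_mask, alpha = 0.05) {
  n <- length(suvr_volumes)
  if (is.character(groups)) groups <- factor(groups)
  if (is.factor(groups)) groups <- as.numeric(groups == "decliner")
  groups <- as.numeric(groups)
  stopifnot(all(groups %in% c(0, 1)), length(groups) == n,
            length(age) == n, length(sex) == n, length(education) == n)
  if (sum(groups == 1) < 3L || sum(groups == 0) < 3L)
    stop("need at least 3 subjects per group")
  if (n < 6L)
    stop("more coefficients than the data can support: n = ", n,
         " subjects for 5 coefficients")
  for (v in suvr_volumes) check_same_grid(v, brain_mask)
  stopifnot(brain_mask$kind == "mask")
  vox <- which(brain_mask$data == 1)
  suvr_mat <- vapply(suvr_volumes, function(v) as.vector(v$data)[vox],
                     numeric(length(vox)))  # voxel x subject
  shape <- brain_mask$grid_shape
  tmap <- array(NA_real_, shape)
  pmap <- array(NA_real_, shape)
  ncov <- array(0L, shape)
  x_base <- cbind(1, age, sex, education)
  eps <- 1e-8
  for (k in seq_along(vox)) {
    xx <- cbind(x_base, suvr = suvr_mat[k, ])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(xx, groups,
                                      family = stats::binomial())),
      error = function(e) NULL)
    bad <- is.null(fit) || !fit$converged ||
      any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
    if (bad) {
      ncov[vox[k]] <- 1L
      next
    }
    rmat <- qr.R(fit$qr)
    piv <- fit$qr$pivot
    cov <- chol2inv(rmat)
    se <- sqrt(diag(cov))[order(piv)]
    z <- fit$coefficients[5L] / se[5L]
    tmap[vox[k]] <- z
    pmap[vox[k]] <- 2 * stats::pnorm(-abs(z))
  }
  mask <- array(0L, shape)
  mask[vox] <- as.integer(!is.na(pmap[vox]) & pmap[vox] < alpha &
                            ncov[vox] == 0L)
  structure(list(t_values = tmap, p_values = pmap, threshold_mask = mask,
                 non_converged = ncov, alpha = alpha,
                 space_tag = brain_mask$space_tag,
                 voxel_volume_mm3 = brain_mask$voxel_volume_mm3),
            class = "stat_map")
}

#' Write a stat map as a NIfTI pair plus mask
#'
#' @param map a `stat_map`.
#' @param prefix path prefix; writes `<prefix>_t.nii.gz`,
#'   `<prefix>_p.nii.gz`, `<prefix>_mask.nii.gz`.
#' @return the three paths, invisibly.
#' @export
write_stat_map <- function(map, prefix) {
  paths <- paste0(prefix, c("_t.nii.gz", "_p.nii.gz", "_mask.nii.gz"))
  vv <- map$voxel_volume_mm3
  tag <- map$space_tag
  write_volume(labeled_volume(ifelse(is.na(map$t_values), 0,
                                     map$t_values),
                              "intensity", vv, tag), paths[1L])
  write_volume(labeled_volume(ifelse(is.na(map$p_values), 1,
                                     map$p_values),
                              "intensity", vv, tag), paths[2L])
  write_volume(labeled_volume(map$threshold_mask, "mask", vv, tag),
               paths[3L])
  invisible(paths)
}
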