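#' Synthetic cohort generation
#'
#' Generates every input the pipeline consumes — modular block-correlation
#' BOLD time series, clinical records, regionally structured PET volumes
#' with a reference region, and binary lesion masks on a shared grid — with
#' the statistical structure the downstream analysis assumes, so the whole
#' pipeline is testable without patient data. Decliners receive a reduced
#' within-minus-between correlation gap and partially scrambled module
#' membership; MMSE change is a linear function of generating segregation,
#' WMH burden and global SUVR plus Gaussian noise. One seed governs all
#' randomness, and regeneration is bit-identical.
#'
#' @name synthetic_cohort
NULL

#' Default node-to-network partition specification
#'
#' Seven cortical resting-state networks plus subcortical, cerebellar and
#' brainstem pools, sized to echo a 265-region cortical parcellation and
#' scaled proportionally for other node counts.
#'
#' @param n_nodes total node count (default 265).
#' @return named integer vector of nodes per network.
#' @export
default_partition_spec <- function(n_nodes = 265L) {
  base <- c(VN = 34, SMN = 40, DAN = 30, VAN = 28, LN = 26, FPN = 30,
            DMN = 45, subcortical = 16, cerebellum = 12, brainstem = 4)
  if (n_nodes == 265L) return(base)
  scaled <- pmax(round(base / sum(base) * n_nodes), 2L)
  # absorb rounding drift into the largest network
  scaled[which.max(scaled)] <- scaled[which.max(scaled)] +
    (n_nodes - sum(scaled))
  scaled
}

#' Cohort generation parameters
#'
#' Group sizes default to the nested case-control design of the study this
#' package serves (11 decliners, 10 matched non-decliners). The default
#' outcome coefficients are calibrated so that the expected MMSE change is
#' about -6 points in decliners and about 0 in non-decliners, with the WMH
#' coupling acting in decliners only — reproducing the decliner-specific
#' WMH association — while WMH burden itself is drawn from near-identical
#' distributions in both groups.
#'
#' @param n_decliners,n_nondecliners group sizes.
#' @param n_nodes number of parcellation nodes (default 265).
#' @param partition_spec named integer vector, nodes per network.
#' @param timepoints BOLD series length T (default 240, an 8-minute run at
#'   a 2 s repetition time).
#' @param r_within target within-network correlation in [0, 1).
#' @param r_between target between-network correlation in
#'   [0, `r_within`].
#' @param segregation_shift non-negative reduction of the within-between
#'   gap applied to decliners (subtracted from their `r_within`).
#' @param mixing_fraction fraction in [0, 1] of decliner nodes whose module
#'   membership is scrambled in the generating covariance.
#' @param within_jitter_sd subject-level SD of the within correlation.
#' @param outcome_coefs named vector `intercept`, `segregation`,
#'   `wmh_decliner`, `wmh_nondecliner`, `suvr`: linear model for MMSE
#'   change.
#' @param noise_sd residual SD of MMSE change (points).
#' @param seed integer master seed; every stream derives from it.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_decliners = 11L, n_nondecliners = 10L,
                        n_nodes = 265L,
                        partition_spec = default_partition_spec(n_nodes),
                        timepoints = 240L, r_within = 0.5,
                        r_between = 0.1, segregation_shift = 0.15,
                        mixing_fraction = 0.2, within_jitter_sd = 0.04,
                        outcome_coefs = c(intercept = -0.8,
                                          segregation = 8,
                                          wmh_decliner = -6,
                                          wmh_nondecliner = 0,
                                          suvr = -5),
                        noise_sd = 1, seed = 1L) {
  stopifnot(n_decliners >= 1L, n_nondecliners >= 1L,
            sum(partition_spec) == n_nodes, all(partition_spec >= 2L),
            timepoints >= 3L)
  if (r_within >= 1) stop("r_within must be strictly below 1")
  if (r_between < 0 || r_between > r_within)
    stop("need 0 <= r_between <= r_within < 1")
  stopifnot(segregation_shift >= 0,
            mixing_fraction >= 0, mixing_fraction <= 1)
  need <- c("intercept", "segregation", "wmh_decliner", "wmh_nondecliner",
            "suvr")
  if (!all(need %in% names(outcome_coefs)))
    stop("outcome_coefs must name: ", paste(need, collapse = ", "))
  stopifnot(noise_sd >= 0, is.finite(seed))
  structure(list(n_decliners = as.integer(n_decliners),
                 n_nondecliners = as.integer(n_nondecliners),
                 n_nodes = as.integer(n_nodes),
                 partition_spec = partition_spec,
                 timepoints = as.integer(timepoints),
                 r_within = r_within, r_between = r_between,
                 segregation_shift = segregation_shift,
                 mixing_fraction = mixing_fraction,
                 within_jitter_sd = within_jitter_sd,
                 outcome_coefs = outcome_coefs[need],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Read a cohort specification from YAML or JSON
#'
#' Fields absent from the file fall back to the [cohort_spec()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported spec format: .", ext))
  if (!is.null(lst$partition_spec))
    lst$partition_spec <- unlist(lst$partition_spec)
  if (!is.null(lst$outcome_coefs))
    lst$outcome_coefs <- unlist(lst$outcome_coefs)
  if (!is.null(lst$partition_spec) && is.null(lst$n_nodes))
    lst$n_nodes <- sum(lst$partition_spec)
  do.call(cohort_spec, lst)
}

# deterministic substream seed, kept below 2^31
derive_seed <- function(base, j, offset) {
  as.integer((abs(as.numeric(base)) * 48271 + j * 16807 + offset * 69621) %%
               2147483399)
}

clip_r <- function(r) pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)

scramble_membership <- function(membership, fraction) {
  if (fraction <= 0) return(membership)
  mods <- unique(membership)
  if (length(mods) < 2L) return(membership)
  n_sel <- round(fraction * length(membership))
  if (n_sel == 0L) return(membership)
  sel <- sample(length(membership), n_sel)
  for (i in sel) {
    membership[i] <- sample(setdiff(mods, membership[i]), 1L)
  }
  membership
}

block_sigma <- function(membership, r_within, r_between) {
  same <- outer(membership, membership, "==")
  s <- ifelse(same, r_within, r_between)
  diag(s) <- 1
  s
}

repair_psd <- function(s, floor = 1e-10) {
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (!is.null(ch)) return(list(sigma = s, chol = ch, repaired = FALSE))
  e <- eigen(s, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  s2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(s2))
  s2 <- s2 / outer(d, d)
  diag(s2) <- 1
  ch <- tryCatch(chol(s2), error = function(e) NULL)
  if (is.null(ch))
    stop("target correlation matrix is not positive semidefinite even ",
         "after eigenvalue clipping; smallest eigenvalue ",
         format(min(e$values)))
  list(sigma = s2, chol = ch, repaired = TRUE)
}

#' Generate block-correlated BOLD time series
#'
#' Rows are draws from a zero-mean multivariate normal whose target
#' correlation is `r_within` inside network blocks and `r_between` across
#' blocks. A fraction of nodes can first have their module membership
#' scrambled (reassigned uniformly to another module) so canonical and
#' generating structure diverge — the "intermingled modules" condition.
#' The target matrix is repaired to positive semidefinite by eigenvalue
#' clipping if needed.
#'
#' @param partition_spec named integer vector of nodes per network.
#' @param timepoints series length T.
#' @param r_within,r_between target correlations,
#'   0 <= r_between <= r_within < 1.
#' @param mixing_fraction fraction of nodes scrambled before covariance
#'   construction.
#' @param seed optional integer seed.
#' @return a `bold_ts` matrix (T x nodes) with attributes
#'   `canonical_membership` (the unscrambled network per node),
#'   `generating_membership`, and `sigma` (the generating correlation
#'   matrix).
#' @export
generate_block_bold <- function(partition_spec, timepoints, r_within,
                                r_between, mixing_fraction = 0,
                                seed = NULL) {
  if (r_within >= 1) stop("r_within must be strictly below 1")
  if (r_between < 0 || r_between > r_within)
    stop("need 0 <= r_between <= r_within < 1")
  stopifnot(mixing_fraction >= 0, mixing_fraction <= 1, timepoints >= 3L)
  n <- sum(partition_spec)
  if (timepoints < n)
    message("note: timepoints (", timepoints, ") below node count (", n,
            "); sample correlations will be rank-deficient")
  if (!is.null(seed)) set.seed(seed)
  canonical <- rep(names(partition_spec), partition_spec)
  generating <- scramble_membership(canonical, mixing_fraction)
  rep_idx <- stats::ave(seq_len(n), canonical, FUN = seq_along)
  labels <- sprintf("%s_%02d", canonical, rep_idx)
  pr <- repair_psd(block_sigma(generating, r_within, r_between))
  z <- matrix(stats::rnorm(timepoints * n), timepoints, n)
  x <- z %*% pr$chol
  colnames(x) <- labels
  out <- bold_ts(x)
  attr(out, "canonical_membership") <- stats::setNames(canonical, labels)
  attr(out, "generating_membership") <- stats::setNames(generating, labels)
  attr(out, "sigma") <- pr$sigma
  out
}

#' Canonical partition attached to generated BOLD
#'
#' @param bold output of [generate_block_bold()].
#' @param analysis_set networks entering segregation analysis.
#' @return a `canonical_partition`.
#' @export
bold_partition <- function(bold, analysis_set = CORTICAL_NETWORKS) {
  m <- attr(bold, "canonical_membership")
  if (is.null(m)) stop("bold carries no canonical membership attribute")
  canonical_partition(names(m), unname(m), analysis_set = analysis_set)
}

#' Expected system segregation of a block design
#'
#' Closed-form pooled SysSeg of the generating z matrix for a two-value
#' block correlation structure, given the canonical and (possibly
#' scrambled) generating memberships. Serves as the per-subject ground
#' truth `generating_segregation`.
#'
#' @param canonical,generating network label vectors, one entry per node.
#' @param r_within,r_between the generating correlations.
#' @param analysis_set networks entering the pooled means.
#' @param exclude_negative drop negative z values, as in
#'   [system_segregation()].
#' @return expected pooled SysSeg (scalar).
#' @export
block_segregation_expected <- function(canonical, generating, r_within,
                                       r_between,
                                       analysis_set = CORTICAL_NETWORKS,
                                       exclude_negative = TRUE) {
  zw0 <- atanh(clip_r(r_within))
  zb0 <- atanh(clip_r(r_between))
  keep <- which(canonical %in% analysis_set)
  cm <- canonical[keep]
  gm <- generating[keep]
  tab <- table(cm, gm)
  nets <- rownames(tab)
  # within-canonical pairs split by generating-same vs generating-different
  w_same <- sum(vapply(nets, function(m) {
    sum(choose(tab[m, ], 2))
  }, numeric(1)))
  w_tot <- sum(choose(table(cm), 2))
  # between-canonical pairs (each unordered pair once)
  b_same <- 0
  b_tot <- 0
  for (i in seq_along(nets)) {
    for (j in seq_along(nets)) {
      if (j <= i) next
      b_same <- b_same + sum(tab[i, ] * tab[j, ])
      b_tot <- b_tot + sum(tab[i, ]) * sum(tab[j, ])
    }
  }
  mean_two <- function(n_same, n_tot) {
    counts <- c(n_same, n_tot - n_same)
    vals <- c(zw0, zb0)
    if (exclude_negative) {
      counts <- counts[vals >= 0]
      vals <- vals[vals >= 0]
    }
    if (sum(counts) == 0) return(NA_real_)
    sum(counts * vals) / sum(counts)
  }
  zw <- mean_two(w_same, w_tot)
  zb <- mean_two(b_same, b_tot)
  if (is.na(zw) || zw <= 0) return(NA_real_)
  (zw - zb) / zw
}

make_brain_mask <- function(grid_shape) {
  cx <- (grid_shape + 1) / 2
  semi <- grid_shape * 0.42
  ix <- slice.index(array(0, grid_shape), 1L)
  iy <- slice.index(array(0, grid_shape), 2L)
  iz <- slice.index(array(0, grid_shape), 3L)
  inside <- ((ix - cx[1L]) / semi[1L])^2 + ((iy - cx[2L]) / semi[2L])^2 +
    ((iz - cx[3L]) / semi[3L])^2 <= 1
  array(as.integer(inside), grid_shape)
}

#' Generate PET, label, lesion and brain volumes on one grid
#'
#' The brain mask is an ellipsoid filling ~30% of the grid. Region labels
#' partition the brain voxels into contiguous chunks (the reference region
#' among them); PET intensity is the region mean plus optional Gaussian
#' noise. The lesion mask is a union of `lesion_count` axis-aligned cubic
#' blobs placed wholly inside the brain.
#'
#' @param grid_shape integer triple (default 32 x 32 x 32).
#' @param region_means named numeric vector, mean intensity keyed by
#'   positive integer region label (reference excluded).
#' @param reference_label,reference_mean label and mean intensity of the
#'   reference region.
#' @param lesion_count number of lesion blobs.
#' @param noise_sd voxel noise SD on PET intensities (default 0).
#' @param lesion_size blob edge length in voxels (default 2).
#' @param space_tag grid identifier shared by the four volumes.
#' @param seed optional integer seed.
#' @return list with `pet_volume`, `label_volume`, `lesion_mask`,
#'   `brain_mask` (all `labeled_volume`s).
#' @export
generate_labeled_volumes <- function(grid_shape = c(32L, 32L, 32L),
                                     region_means, reference_label,
                                     reference_mean, lesion_count = 0L,
                                     noise_sd = 0, lesion_size = 2L,
                                     space_tag = "synthetic-grid",
                                     seed = NULL) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  labs <- as.integer(names(region_means))
  if (anyNA(labs) || any(labs <= 0))
    stop("region_means must be keyed by positive integer labels")
  if (reference_label %in% labs)
    stop("reference_label must not collide with region_means labels")
  if (!is.null(seed)) set.seed(seed)
  brain <- make_brain_mask(grid_shape)
  vox <- which(brain == 1L)
  all_labs <- c(labs, as.integer(reference_label))
  means <- c(region_means, stats::setNames(reference_mean,
                                           reference_label))
  # contiguous chunks of roughly equal size over the brain voxels
  chunk <- cut(seq_along(vox), breaks = length(all_labs), labels = FALSE)
  label_arr <- array(0L, grid_shape)
  label_arr[vox] <- all_labs[chunk]
  pet <- array(0, grid_shape)
  pet[vox] <- means[as.character(label_arr[vox])] +
    if (noise_sd > 0) stats::rnorm(length(vox), 0, noise_sd) else 0
  lesion <- array(0L, grid_shape)
  if (lesion_count > 0L) {
    placed <- 0L
    attempts <- 0L
    max_attempts <- 500L * lesion_count
    while (placed < lesion_count && attempts < max_attempts) {
      attempts <- attempts + 1L
      lo <- vapply(grid_shape, function(d)
        sample.int(d - lesion_size + 1L, 1L), integer(1))
      rng <- lapply(seq_len(3L), function(k)
        lo[k]:(lo[k] + lesion_size - 1L))
      block <- brain[rng[[1L]], rng[[2L]], rng[[3L]]]
      if (all(block == 1L)) {
        lesion[rng[[1L]], rng[[2L]], rng[[3L]]] <- 1L
        placed <- placed + 1L
      }
    }
    if (placed < lesion_count)
      stop("grid too small to place ", lesion_count,
           " lesion blob(s); placed ", placed)
  }
  lv <- function(data, kind) labeled_volume(data, kind,
                                            space_tag = space_tag)
  list(pet_volume = lv(pet, "intensity"),
       label_volume = lv(label_arr, "label"),
       lesion_mask = lv(lesion, "mask"),
       brain_mask = lv(brain, "mask"))
}

#' Default four-composite map for the synthetic label scheme
#'
#' Eight cortical regions (labels 1-8) grouped into frontal, cingulate,
#' lateral parietal and lateral temporal composites, with label 9 as the
#' cerebellar-gray reference. Real atlases supply their own numbering via
#' a composite map of the same shape.
#' @export
SYNTHETIC_COMPOSITES <- list(frontal = c(1L, 2L), cingulate = c(3L, 4L),
                             lateral_parietal = c(5L, 6L),
                             lateral_temporal = c(7L, 8L))

#' Reference-region label of the synthetic volume scheme
#' @export
SYNTHETIC_REFERENCE_LABEL <- 9L

truncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  for (i in 1:100) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Generate a synthetic nested case-control cohort
#'
#' Produces one `synthetic_subject` per participant: BOLD time series from
#' the subject's generating covariance (decliners get a reduced
#' within-between gap and scrambled membership), PET/label/lesion/brain
#' volumes whose quantitative read-outs match the subject's drawn global
#' SUVR and WMH fraction, and a clinical record whose MMSE change follows
#' the linear outcome model. Per-subject network draws use streams keyed by
#' the within-group index only, so a null configuration (zero shift, zero
#' mixing) gives decliner j and non-decliner j identical network
#' parameters.
#'
#' Subjects whose simulated trajectory fails the classification rule for
#' their intended group have their MMSE noise redrawn up to `max_retries`
#' times; if overall agreement still falls below 90% the specification is
#' reported unsatisfiable.
#'
#' @param spec a `cohort_spec`.
#' @param include_bold generate BOLD series (default TRUE).
#' @param include_volumes generate voxel volumes and derive WMH/SUVR from
#'   them (default TRUE); when FALSE the drawn targets are recorded
#'   directly.
#' @param grid_shape voxel grid for the volumes.
#' @param max_retries MMSE noise redraws per straggling subject.
#' @param enforce_classification require >= 90% agreement between intended
#'   group and [classify_decliner()] (default TRUE). Disable for null
#'   configurations — e.g. zero outcome coefficients — whose trajectories
#'   intentionally carry no group signal.
#' @return a `synthetic_cohort`: list of subjects, each a list with
#'   `id`, `group`, `record` (one-row data frame), `bold`, `pet_volume`,
#'   `label_volume`, `lesion_mask`, `brain_mask`,
#'   `generating_segregation`; the cohort spec is attached as an
#'   attribute.
#' @export
generate_cohort <- function(spec, include_bold = TRUE,
                            include_volumes = TRUE,
                            grid_shape = c(32L, 32L, 32L),
                            max_retries = 20L,
                            enforce_classification = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_brain <- sum(make_brain_mask(grid_shape))
  blob_vol <- 2L^3
  groups <- rep(c("decliner", "non_decliner"),
                c(spec$n_decliners, spec$n_nondecliners))
  within_idx <- c(seq_len(spec$n_decliners), seq_len(spec$n_nondecliners))
  co <- spec$outcome_coefs
  subjects <- vector("list", length(groups))
  agree <- logical(length(groups))

  for (s in seq_along(groups)) {
    grp <- groups[s]
    dec <- grp == "decliner"
    j <- within_idx[s]
    id <- sprintf("%s%02d", if (dec) "D" else "N", j)

    # --- network stream: keyed by within-group index only -------------
    set.seed(derive_seed(spec$seed, j, 1L))
    jit <- stats::rnorm(1L, 0, spec$within_jitter_sd)
    r_w <- spec$r_within - (if (dec) spec$segregation_shift else 0) + jit
    r_w <- min(max(r_w, spec$r_between + 0.01), 0.97)
    mix <- if (dec) spec$mixing_fraction else 0
    canonical <- rep(names(spec$partition_spec), spec$partition_spec)
    generating <- scramble_membership(canonical, mix)
    gen_seg <- block_segregation_expected(canonical, generating, r_w,
                                          spec$r_between)
    bold <- NULL
    if (include_bold) {
      rep_idx <- stats::ave(seq_along(canonical), canonical,
                            FUN = seq_along)
      labels <- sprintf("%s_%02d", canonical, rep_idx)
      pr <- repair_psd(block_sigma(generating, r_w, spec$r_between))
      z <- matrix(stats::rnorm(spec$timepoints * spec$n_nodes),
                  spec$timepoints, spec$n_nodes)
      x <- z %*% pr$chol
      colnames(x) <- labels
      bold <- bold_ts(x)
      attr(bold, "canonical_membership") <- stats::setNames(canonical,
                                                            labels)
      attr(bold, "generating_membership") <- stats::setNames(generating,
                                                             labels)
    }

    # --- clinical stream: group-specific -------------------------------
    set.seed(derive_seed(spec$seed, j, 2L + dec))
    age <- if (dec) truncnorm1(69.2, 3.63, 55, 90) else
      truncnorm1(66.7, 9.02, 55, 90)
    sex_female <- stats::rbinom(1L, 1L, if (dec) 0.545 else 0.10)
    edu <- round(truncnorm1(if (dec) 8.9 else 10.9, 5.8, 0, 22))
    nihss <- min(stats::rpois(1L, if (dec) 3 else 4.5), 12L)
    mmse0 <- round(truncnorm1(if (dec) 29 else 27, 1.2, 20, 30))
    interval <- truncnorm1(if (dec) 68.3 else 67.8,
                           if (dec) 26.8 else 25.2, 24, 140)
    apoe <- stats::rbinom(1L, 1L, if (dec) 0.09 else 0.20) == 1L
    wmh_target <- stats::rlnorm(1L, log(if (dec) 0.58 else 0.52), 0.45)
    suvr_target <- truncnorm1(if (dec) 1.29 else 1.15,
                              if (dec) 0.16 else 0.10, 0.9, 2.0)

    # --- volumes ---------------------------------------------------------
    pet <- labelv <- lesion <- brain <- NULL
    wmh_pct <- wmh_target
    suvr <- suvr_target
    if (include_volumes) {
      region_means <- stats::setNames(rep(suvr_target, 8L), 1:8)
      lesions <- max(0L, round(wmh_target / 100 * n_brain / blob_vol))
      vols <- generate_labeled_volumes(
        grid_shape, region_means,
        reference_label = SYNTHETIC_REFERENCE_LABEL, reference_mean = 1,
        lesion_count = lesions, seed = derive_seed(spec$seed, j, 4L + dec))
      pet <- vols$pet_volume; labelv <- vols$label_volume
      lesion <- vols$lesion_mask; brain <- vols$brain_mask
      wmh_pct <- wmh_volume_fraction(lesion, brain)
      rs <- regional_suvr(pet, labelv, SYNTHETIC_REFERENCE_LABEL)
      suvr <- global_suvr(rs, SYNTHETIC_COMPOSITES)$global_suvr
    }

    # --- outcome model with straggler resampling ------------------------
    wmh_coef <- if (dec) co[["wmh_decliner"]] else co[["wmh_nondecliner"]]
    mu <- co[["intercept"]] + co[["segregation"]] * gen_seg +
      wmh_coef * wmh_pct + co[["suvr"]] * suvr
    mmse1 <- NA_real_
    ok <- FALSE
    retries <- if (enforce_classification) max_retries else 1L
    for (try in seq_len(retries)) {
      change <- mu + stats::rnorm(1L, 0, spec$noise_sd)
      mmse1 <- min(max(round(mmse0 + change), 0), 30)
      ok <- classify_decliner(mmse0, mmse1, interval) == grp
      if (ok) break
    }
    agree[s] <- ok

    record <- data.frame(
      id = id, group = grp, age_years = age, sex_female = sex_female,
      education_years = edu, nihss_baseline = nihss,
      mmse_baseline = mmse0, mmse_final = mmse1,
      mmse_change = mmse1 - mmse0, interval_months = interval,
      wmh_fraction_pct = wmh_pct, global_suvr = suvr,
      apoe_e4 = apoe, generating_segregation = gen_seg,
      stringsAsFactors = FALSE)
    subjects[[s]] <- structure(
      list(id = id, group = grp, record = record, bold = bold,
           pet_volume = pet, label_volume = labelv, lesion_mask = lesion,
           brain_mask = brain, generating_segregation = gen_seg),
      class = "synthetic_subject")
  }
  if (enforce_classification && mean(agree) < 0.9)
    stop(sprintf(
      paste0("unsatisfiable cohort spec: only %.0f%% of subjects meet ",
             "their intended classification after %d retries; adjust ",
             "outcome_coefs or noise_sd"), 100 * mean(agree), max_retries))
  structure(subjects, spec = spec, agreement = mean(agree),
            class = "synthetic_cohort")
}

#' Combined record table of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return data frame with one row per subject.
#' @export
cohort_records <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) s$record))
}

#' Canonical partition of a synthetic cohort's parcellation
#'
#' @param cohort a `synthetic_cohort`.
#' @param analysis_set networks entering segregation analysis.
#' @return a `canonical_partition`.
#' @export
cohort_partition <- function(cohort, analysis_set = CORTICAL_NETWORKS) {
  spec <- attr(cohort, "spec")
  canonical <- rep(names(spec$partition_spec), spec$partition_spec)
  rep_idx <- stats::ave(seq_along(canonical), canonical, FUN = seq_along)
  canonical_partition(sprintf("%s_%02d", canonical, rep_idx), canonical,
                      analysis_set = analysis_set)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  rec <- cohort_records(x)
  cat(sprintf("<synthetic_cohort> %d decliners, %d non-decliners\n",
              sum(rec$group == "decliner"),
              sum(rec$group == "non_decliner")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' BOLD as tab-delimited text (header = node labels), volumes as NIfTI,
#' records as CSV, the canonical partition as a two-column table, and a
#' JSON manifest listing every generated path.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(records = file.path(dir, "records.csv"),
                   partition = file.path(dir, "partition.tsv"),
                   subjects = list())
  utils::write.csv(cohort_records(cohort), manifest$records,
                   row.names = FALSE)
  write_partition(cohort_partition(cohort), manifest$partition)
  for (s in cohort) {
    entry <- list()
    if (!is.null(s$bold)) {
      entry$bold <- file.path(dir, paste0(s$id, "_bold.tsv"))
      write_bold(s$bold, entry$bold)
    }
    for (vol in c("pet_volume", "label_volume", "lesion_mask",
                  "brain_mask")) {
      if (!is.null(s[[vol]])) {
        entry[[vol]] <- file.path(dir,
                                  paste0(s$id, "_", vol, ".nii.gz"))
        write_volume(s[[vol]], entry[[vol]])
      }
    }
    manifest$subjects[[s$id]] <- entry
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest_path)
}
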