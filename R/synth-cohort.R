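#' Define a planted atrophy subtype template
#'
#' A template describes one latent disease subtype: how much thinner (in mm)
#' each cortical ROI is in a full-blown AD case of that subtype, what
#' fraction of patients carry it, and how strongly MCI expresses it relative
#' to AD.
#'
#' @param label short subtype name
#' @param roi_weights numeric vector of per-ROI atrophy magnitudes (mm, >= 0)
#' @param prevalence fraction of patients drawn from this template
#' @param mci_scale fraction in \[0, 1\] scaling AD-level atrophy down to the
#'   MCI level
#' @return an object of class `subtype_template`
#' @export
subtype_template <- function(label, roi_weights, prevalence, mci_scale = 0.5) {
  if (any(roi_weights < 0)) stop_field("roi_weights", "must be >= 0")
  if (prevalence < 0 || prevalence > 1) stop_field("prevalence", "must be in [0, 1]")
  if (mci_scale < 0 || mci_scale > 1) stop_field("mci_scale", "must be in [0, 1]")
  structure(list(label = label, roi_weights = as.numeric(roi_weights),
                 prevalence = prevalence, mci_scale = mci_scale),
            class = "subtype_template")
}

#' Default three-subtype templates
#'
#' Emulates the minimal / temporal-frontal / diffuse atrophy patterns seen in
#' the AD continuum: template MIN has near-zero atrophy (0.02 mm on temporal
#' ROIs), template MID places `effect_mm` on temporal and frontal ROIs, and
#' template DIF spreads two thirds of `effect_mm` over all 68 ROIs. Exact ROI
#' index sets are a documented configuration default.
#'
#' @param n_rois number of ROIs (68 for the Desikan-Killiany atlas)
#' @param effect_mm atrophy depth (mm) on the affected ROI set of template MID
#' @param prevalences length-3 vector of template prevalences (summing to 1)
#' @param mci_scale MCI-to-AD atrophy ratio shared by the templates
#' @return list of three `subtype_template` objects
#' @export
default_templates <- function(n_rois = 68, effect_mm = 0.3,
                              prevalences = c(0.26, 0.345, 0.395),
                              mci_scale = 0.5) {
  prevalences <- prevalences / sum(prevalences)
  w_min <- numeric(n_rois)
  w_mid <- numeric(n_rois)
  w_dif <- rep(effect_mm * 2 / 3, n_rois)
  if (n_rois == 68) {
    w_min[dk_lobe_index("temporal")] <- 0.02
    w_mid[c(dk_lobe_index("temporal"), dk_lobe_index("frontal"))] <- effect_mm
  } else {
    # reduced feature spaces: first third untouched-ish, middle third focal
    w_min[seq_len(max(1, n_rois %/% 6))] <- 0.02
    w_mid[seq_len(max(1, n_rois %/% 2))] <- effect_mm
  }
  list(subtype_template("MIN", w_min, prevalences[1], mci_scale),
       subtype_template("MID", w_mid, prevalences[2], mci_scale),
       subtype_template("DIF", w_dif, prevalences[3], mci_scale))
}

#' Orthogonal planted templates for recovery experiments
#'
#' Each template places `effect_mm` of atrophy on its own disjoint block of
#' ROIs, so the planted patterns are mutually orthogonal — the cleanest
#' configuration for testing whether the estimator recovers known subtypes.
#'
#' @param n_rois number of ROIs
#' @param n_templates number of planted subtypes
#' @param effect_mm atrophy depth (mm) on each template's ROI block
#' @param block_size ROIs per template (default: equal split, at most
#'   `n_rois %/% n_templates`)
#' @param mci_scale MCI-to-AD atrophy ratio
#' @param prevalences template prevalences (default equal)
#' @return list of `subtype_template` objects labeled `T1..Tn`
#' @export
orthogonal_templates <- function(n_rois, n_templates = 3, effect_mm = 0.4,
                                 block_size = n_rois %/% n_templates,
                                 mci_scale = 0.5,
                                 prevalences = rep(1 / n_templates, n_templates)) {
  stopifnot(block_size * n_templates <= n_rois)
  lapply(seq_len(n_templates), function(k) {
    w <- numeric(n_rois)
    w[((k - 1) * block_size + 1):(k * block_size)] <- effect_mm
    subtype_template(sprintf("T%d", k), w, prevalences[k], mci_scale)
  })
}

#' Specify a synthetic cohort
#'
#' Bundles every knob of the cross-sectional generator. Defaults emulate the
#' ADNI-1-like study conditions: 228 CN / 396 MCI / 192 AD subjects, 68
#' Desikan-Killiany ROIs with healthy mean thickness between 2 and 3.2 mm,
#' mild age/sex/education effects, no ICV effect on thickness (thickness,
#' unlike volume, is weakly head-size-dependent; ICV is still residualized
#' downstream), and the three default subtype templates.
#'
#' @param n_cn,n_ad,n_mci group sizes (all > 0)
#' @param n_rois number of thickness features
#' @param roi_baseline_mean per-ROI healthy mean thickness (mm); default a
#'   fixed ramp over 2.0-3.2 mm
#' @param covariate_effects named list with slopes `age` (mm/year), `sex`
#'   (mm, female minus male), `education` (mm/year), `icv` (mm per mm^3);
#'   applied to covariates centered at `age_center` 75 y, education 16 y,
#'   ICV 1.5e6 mm^3
#' @param noise_sd ROI-level Gaussian noise sd (mm)
#' @param templates list of [subtype_template()]s; prevalences must sum to 1
#' @param apoe_rates per-group allele frequencies: named list `CN`, `MCI`,
#'   `AD`, each `c(e2 = ..., e4 = ...)`
#' @param seed master integer seed fixing all randomness
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_cn = 228, n_ad = 192, n_mci = 396, n_rois = 68,
                        roi_baseline_mean = NULL,
                        covariate_effects = list(age = -0.005, sex = 0.02,
                                                 education = 0.002, icv = 0),
                        noise_sd = 0.12,
                        templates = default_templates(n_rois),
                        apoe_rates = list(CN = c(e2 = 0.06, e4 = 0.14),
                                          MCI = c(e2 = 0.04, e4 = 0.30),
                                          AD = c(e2 = 0.03, e4 = 0.40)),
                        seed = 1L) {
  for (f in c("n_cn", "n_ad", "n_mci", "n_rois")) {
    v <- get(f)
    if (length(v) != 1 || !is.finite(v) || v <= 0 || v != round(v))
      stop_field(f, "must be a positive integer")
  }
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (is.null(roi_baseline_mean))
    roi_baseline_mean <- seq(2.0, 3.2, length.out = n_rois)
  if (length(roi_baseline_mean) != n_rois)
    stop_field("roi_baseline_mean", "length must equal n_rois")
  prev <- vapply(templates, function(t) t$prevalence, numeric(1))
  if (abs(sum(prev) - 1) > 1e-8)
    stop_field("templates", "prevalences must sum to 1")
  for (t in templates)
    if (length(t$roi_weights) != n_rois)
      stop_field("templates", sprintf("roi_weights length of '%s' must equal n_rois", t$label))
  need <- setdiff(c("age", "sex", "education", "icv"), names(covariate_effects))
  if (length(need)) stop_field("covariate_effects", paste("missing", paste(need, collapse = ", ")))
  structure(list(n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
                 n_mci = as.integer(n_mci), n_rois = as.integer(n_rois),
                 roi_baseline_mean = roi_baseline_mean,
                 covariate_effects = covariate_effects, noise_sd = noise_sd,
                 templates = templates, apoe_rates = apoe_rates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.roi_colnames <- function(n_rois) {
  if (n_rois == 68) dk_roi_names() else sprintf("roi_%02d_thickness", seq_len(n_rois))
}

.draw_apoe <- function(n, rates) {
  p <- c(e2 = unname(rates["e2"]), e3 = 1 - rates["e2"] - rates["e4"],
         e4 = unname(rates["e4"]))
  a1 <- sample(c("e2", "e3", "e4"), n, replace = TRUE, prob = p)
  a2 <- sample(c("e2", "e3", "e4"), n, replace = TRUE, prob = p)
  data.frame(apoe_a1 = a1, apoe_a2 = a2)
}

# Cognitive scores as linear functions of latent atrophy burden (mm) + noise.
.cog_scores <- function(burden, n) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  data.frame(
    MMSE     = clip(29 - 25 * burden + stats::rnorm(n, 0, 0.9), 0, 30),
    CDRSB    = clip(0.05 + 20 * burden + stats::rnorm(n, 0, 0.4), 0, 18),
    ADAS13   = clip(9.5 + 45 * burden + stats::rnorm(n, 0, 2.5), 0, 85),
    FAQ      = clip(0.2 + 20 * burden + stats::rnorm(n, 0, 1.5), 0, 30),
    ADNI_MEM = 0.97 - 5 * burden + stats::rnorm(n, 0, 0.35),
    ADNI_EF  = 0.64 - 4 * burden + stats::rnorm(n, 0, 0.45),
    ADNI_LAN = 0.78 - 4 * burden + stats::rnorm(n, 0, 0.45),
    ADNI_VS  = 0.23 - 2 * burden + stats::rnorm(n, 0, 0.4)
  )
}

#' Generate a cross-sectional synthetic cohort
#'
#' Draws CN, AD and MCI subjects with covariates, APOE genotypes and ROI
#' thickness. Each AD/MCI subject is assigned a latent subtype by template
#' prevalence; thickness is
#' `baseline + covariate effects - group_scale * roi_weights + noise`,
#' with `group_scale` 1 for AD, the template's `mci_scale` for MCI, and 0
#' for CN. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()]
#' @return list with `subjects` (one row per subject) and `thickness`
#'   (numeric matrix, subjects x ROIs, rownames = subject ids)
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_cn = 20, n_ad = 15, n_mci = 25, seed = 1))
#' dim(coh$thickness)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(derive_seed(spec$seed, 1L))
  n <- spec$n_cn + spec$n_ad + spec$n_mci
  diagnosis <- rep(c("CN", "AD", "MCI"), c(spec$n_cn, spec$n_ad, spec$n_mci))
  subject_id <- sprintf("S%04d", seq_len(n))

  age <- stats::runif(n, 55, 90)
  sex <- ifelse(stats::runif(n) < 0.45, "F", "M")
  education <- round(pmin(pmax(stats::rnorm(n, 16, 3), 6), 20))
  icv <- stats::rnorm(n, 1.5e6, 1.5e5)

  labels <- vapply(spec$templates, function(t) t$label, character(1))
  prev <- vapply(spec$templates, function(t) t$prevalence, numeric(1))
  latent <- rep(NA_character_, n)
  patient <- diagnosis != "CN"
  latent[patient] <- sample(labels, sum(patient), replace = TRUE, prob = prev)

  apoe <- do.call(rbind, lapply(split(seq_len(n), diagnosis), function(idx) {
    cbind(idx = idx, .draw_apoe(length(idx), spec$apoe_rates[[diagnosis[idx[1]]]]))
  }))
  apoe <- apoe[order(apoe$idx), c("apoe_a1", "apoe_a2")]

  ce <- spec$covariate_effects
  cov_term <- ce$age * (age - 75) + ce$sex * (sex == "F") +
    ce$education * (education - 16) + ce$icv * (icv - 1.5e6)

  W <- vapply(spec$templates, function(t) t$roi_weights, numeric(spec$n_rois))
  colnames(W) <- labels
  scale_vec <- numeric(n)
  mci_scales <- vapply(spec$templates, function(t) t$mci_scale, numeric(1))
  names(mci_scales) <- labels
  scale_vec[diagnosis == "AD"] <- 1
  is_mci <- diagnosis == "MCI"
  scale_vec[is_mci] <- mci_scales[latent[is_mci]]

  atrophy <- matrix(0, n, spec$n_rois)
  atrophy[patient, ] <- t(W[, latent[patient], drop = FALSE]) * scale_vec[patient]

  thickness <- matrix(rep(spec$roi_baseline_mean, each = n), n, spec$n_rois) +
    cov_term - atrophy +
    matrix(stats::rnorm(n * spec$n_rois, 0, spec$noise_sd), n, spec$n_rois)
  dimnames(thickness) <- list(subject_id, .roi_colnames(spec$n_rois))

  burden <- scale_vec * colMeans(W)[ifelse(patient, latent, labels[1])]
  burden[!patient] <- 0
  scores <- .cog_scores(burden, n)

  subjects <- data.frame(subject_id = subject_id, diagnosis = diagnosis,
                         age = age, sex = sex, education_years = education,
                         icv_mm3 = icv, apoe, latent_subtype = latent,
                         scores, stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  list(subjects = subjects, thickness = thickness, spec = spec)
}

#' Specify a longitudinal visit schedule
#'
#' @param visits ordered visit codes; baseline first
#' @param missingness named per-visit scan-missing probability (baseline 0)
#' @param conversion_prob named per-template per-period MCI-to-AD probability
#'   (applied at each follow-up visit while still MCI)
#' @param reversion_prob per-period MCI-to-CN probability
#' @return object of class `visit_schedule`
#' @export
visit_schedule <- function(visits = c("bl", "m06", "m12", "m18", "m24", "m36"),
                           missingness = c(bl = 0, m06 = 0.08, m12 = 0.10,
                                           m18 = 0.12, m24 = 0.15, m36 = 0.25),
                           conversion_prob = c(MIN = 0.03, MID = 0.10, DIF = 0.11),
                           reversion_prob = 0.01) {
  assert_prob(missingness, "missingness")
  assert_prob(conversion_prob, "conversion_prob")
  assert_prob(reversion_prob, "reversion_prob")
  if (visits[1] != "bl") stop_field("visits", "baseline 'bl' must come first")
  structure(list(visits = visits, missingness = missingness[visits],
                 conversion_prob = conversion_prob,
                 reversion_prob = reversion_prob),
            class = "visit_schedule")
}

#' Generate longitudinal visits and per-visit thickness
#'
#' Each MCI subject walks the visit schedule: at every follow-up visit a
#' still-MCI subject converts to AD with their template's per-period
#' probability or reverts to CN with `reversion_prob` (conversion and
#' reversion are absorbing). Atrophy evolves continuously through the
#' diagnostic boundary: the conversion-visit scan sits halfway between the
#' MCI and AD atrophy levels of the subject's template, and later visits
#' carry the full AD-level pattern; scans are dropped per-visit with the
#' configured missingness. CN and AD subjects keep their baseline
#' diagnosis. The true conversion visit of every converter is recorded for
#' testing.
#'
#' @param cohort result of [generate_cohort()]
#' @param schedule a [visit_schedule()]
#' @param seed integer seed for the visit stream (independent of the
#'   cross-sectional stream)
#' @return list with `visits` (subject x visit rows: `subject_id`, `visit`,
#'   `scan_present`, `diagnosis`, `age`), `thickness` (named list of per-visit
#'   matrices covering subjects scanned at that visit) and `truth`
#'   (per-subject true conversion/reversion visit or NA)
#' @export
generate_longitudinal <- function(cohort, schedule = visit_schedule(),
                                  seed = cohort$spec$seed) {
  spec <- cohort$spec
  set.seed(derive_seed(seed, 2L))
  subj <- cohort$subjects
  n <- nrow(subj)
  visits <- schedule$visits
  followups <- visits[-1]
  months <- c(bl = 0, m06 = 6, m12 = 12, m18 = 18, m24 = 24, m36 = 36)[visits]

  labels <- vapply(spec$templates, function(t) t$label, character(1))
  W <- vapply(spec$templates, function(t) t$roi_weights, numeric(spec$n_rois))
  colnames(W) <- labels
  mci_scales <- stats::setNames(
    vapply(spec$templates, function(t) t$mci_scale, numeric(1)), labels)

  # diagnosis paths
  diag_path <- matrix(subj$diagnosis, n, length(visits),
                      dimnames = list(subj$subject_id, visits))
  conv_visit <- rep(NA_character_, n)
  rev_visit <- rep(NA_character_, n)
  for (i in which(subj$diagnosis == "MCI")) {
    state <- "MCI"
    p_conv <- schedule$conversion_prob[[subj$latent_subtype[i]]] %||% 0
    for (v in followups) {
      if (state == "MCI") {
        u <- stats::runif(1)
        if (u < p_conv) {
          state <- "AD"; conv_visit[i] <- v
        } else if (u < p_conv + schedule$reversion_prob) {
          state <- "CN"; rev_visit[i] <- v
        }
      }
      diag_path[i, v] <- state
    }
  }

  scan <- matrix(TRUE, n, length(visits), dimnames = list(subj$subject_id, visits))
  for (v in visits)
    scan[, v] <- stats::runif(n) >= schedule$missingness[[v]]

  ce <- spec$covariate_effects
  thickness <- list()
  for (vi in seq_along(visits)) {
    v <- visits[vi]
    idx <- which(scan[, v])
    if (!length(idx)) { thickness[[v]] <- NULL; next }
    age_v <- subj$age[idx] + months[vi] / 12
    cov_term <- ce$age * (age_v - 75) + ce$sex * (subj$sex[idx] == "F") +
      ce$education * (subj$education_years[idx] - 16) +
      ce$icv * (subj$icv_mm3[idx] - 1.5e6)
    scale_vec <- numeric(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      d <- diag_path[i, v]
      lt <- subj$latent_subtype[i]
      # converters pass through the cut-point mid-trajectory: the scan at the
      # conversion visit sits halfway between MCI- and AD-level atrophy, and
      # later visits carry the full AD-level pattern
      scale_vec[j] <- if (is.na(lt) || d == "CN") 0
                      else if (d != "AD") mci_scales[[lt]]
                      else if (!is.na(conv_visit[i]) && v == conv_visit[i])
                        (mci_scales[[lt]] + 1) / 2
                      else 1
    }
    atrophy <- matrix(0, length(idx), spec$n_rois)
    has_t <- !is.na(subj$latent_subtype[idx])
    atrophy[has_t, ] <- t(W[, subj$latent_subtype[idx][has_t], drop = FALSE]) *
      scale_vec[has_t]
    th <- matrix(rep(spec$roi_baseline_mean, each = length(idx)),
                 length(idx), spec$n_rois) + cov_term - atrophy +
      matrix(stats::rnorm(length(idx) * spec$n_rois, 0, spec$noise_sd),
             length(idx), spec$n_rois)
    dimnames(th) <- list(subj$subject_id[idx], .roi_colnames(spec$n_rois))
    thickness[[v]] <- th
  }

  visit_df <- do.call(rbind, lapply(visits, function(v) {
    data.frame(subject_id = subj$subject_id, visit = v,
               scan_present = as.integer(scan[, v]),
               diagnosis = diag_path[, v],
               age = subj$age + months[[v]] / 12,
               stringsAsFactors = FALSE)
  }))
  rownames(visit_df) <- NULL
  truth <- data.frame(subject_id = subj$subject_id,
                      conversion_visit = conv_visit,
                      reversion_visit = rev_visit, stringsAsFactors = FALSE)
  list(visits = visit_df, thickness = thickness, truth = truth,
       schedule = schedule)
}

#' Write cohort tables to delimited files
#'
#' Emits `subjects.tsv`, `thickness_<visit>.tsv` (subject_id + one column per
#' ROI) and, when longitudinal data are supplied, `visits.tsv`. Files
#' round-trip losslessly through [read_cohort_tables()].
#'
#' @param cohort result of [generate_cohort()]
#' @param path output directory (created if absent)
#' @param longitudinal optional result of [generate_longitudinal()]
#' @return invisibly, the written file paths
#' @export
emit_tables <- function(cohort, path, longitudinal = NULL) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  written <- character(0)
  f <- file.path(path, "subjects.tsv")
  utils::write.table(cohort$subjects, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(written, f)
  th_list <- if (is.null(longitudinal)) list(bl = cohort$thickness)
             else longitudinal$thickness
  for (v in names(th_list)) {
    df <- data.frame(subject_id = rownames(th_list[[v]]), th_list[[v]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(path, sprintf("thickness_%s.tsv", v))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(longitudinal)) {
    f <- file.path(path, "visits.tsv")
    utils::write.table(longitudinal$visits, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read cohort tables written by [emit_tables()]
#'
#' @param path directory containing the tables
#' @return list with `subjects`, `thickness` (named list of matrices) and,
#'   if present, `visits`
#' @export
read_cohort_tables <- function(path) {
  subjects <- utils::read.delim(file.path(path, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  th_files <- list.files(path, "^thickness_.*\\.tsv$", full.names = TRUE)
  thickness <- list()
  for (f in th_files) {
    v <- sub("^thickness_(.*)\\.tsv$", "\\1", basename(f))
    df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    thickness[[v]] <- m
  }
  out <- list(subjects = subjects, thickness = thickness)
  vf <- file.path(path, "visits.tsv")
  if (file.exists(vf))
    out$visits <- utils::read.delim(vf, stringsAsFactors = FALSE)
  out
}
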