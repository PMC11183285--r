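#' Run the full subtyping pipeline on a synthetic cohort
#'
#' Chains the stages end to end: generate a cohort (and optionally
#' longitudinal visits), fit the CN covariate model and residualize, fit
#' the mixture of experts on AD vs CN, name experts by severity, map MCI
#' subjects by minimum hyperplane distance, screen follow-up visits,
#' compute conversion series, attribute converters to AD subtypes at
#' conversion time, and tabulate APOE carriers among converters.
#'
#' @param spec a [cohort_spec()]
#' @param config a [moe_config()]
#' @param schedule a [visit_schedule()], or NULL to skip the longitudinal
#'   stages
#' @return list with the artifacts of every stage: `cohort`,
#'   `longitudinal`, `glm_fit`, `residuals`, `model`, `labels`,
#'   `ad_assignments`, `mci_assignments`, `screen`, `series`,
#'   `conversion_by_subtype`, `apoe`, `attribution`
#' @export
run_pipeline <- function(spec = cohort_spec(), config = moe_config(),
                         schedule = visit_schedule()) {
  cohort <- generate_cohort(spec)
  fit <- fit_cn_glm(cohort$thickness, cohort$subjects)
  residuals <- residualize(cohort$thickness, cohort$subjects, fit)
  data <- moe_data(residuals, cohort$subjects)
  model <- fit_moe(data, config)
  labels <- rank_and_name_subtypes(model, data)

  # AD subjects carry memberships: label by argmax membership
  hard <- apply(model$memberships, 1, which.max)
  ad_assignments <- data.frame(
    subject_id = data$ids[data$ad], expert_index = hard,
    subtype_label = unname(labels[hard]), stringsAsFactors = FALSE)

  mci_ids <- cohort$subjects$subject_id[cohort$subjects$diagnosis == "MCI"]
  mci_assignments <- assign_min_distance(
    model, residuals[mci_ids, , drop = FALSE], labels = labels)

  out <- list(cohort = cohort, glm_fit = fit, residuals = residuals,
              model = model, labels = labels,
              ad_assignments = ad_assignments,
              mci_assignments = mci_assignments)
  if (is.null(schedule)) return(out)

  long <- generate_longitudinal(cohort, schedule)
  scr <- screen_periods(long$visits)
  series <- at_risk_series(scr)

  ev <- scr$events[scr$events$to == "AD", , drop = FALSE]
  ev$subtype <- mci_assignments$subtype_label[match(ev$subject_id,
                                                   mci_assignments$subject_id)]
  counts <- do.call(rbind, lapply(unique(ev$subtype), function(s) {
    do.call(rbind, lapply(names(scr$at_risk), function(p) {
      sel <- ev$subtype == s & ev$visit == p
      n_risk <- sum(mci_assignments$subtype_label[
        match(scr$at_risk[[p]], mci_assignments$subject_id)] == s, na.rm = TRUE)
      data.frame(subtype = s, period = p, n_convert = sum(sel),
                 n_at_risk = n_risk, stringsAsFactors = FALSE)
    }))
  }))
  conv <- if (!is.null(counts)) cumulative_conversions(counts) else NULL
  apoe <- if (nrow(ev)) apoe_carrier_stats(ev, cohort$subjects) else NULL

  # converters' thickness at the conversion visit, if scanned there
  conv_th <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    th <- long$thickness[[ev$visit[i]]]
    if (!is.null(th) && ev$subject_id[i] %in% rownames(th))
      th[ev$subject_id[i], , drop = FALSE]
    else NULL
  }))
  # conversion-visit covariates: visit-specific age, other covariates fixed
  subj_conv <- cohort$subjects
  vage <- long$visits$age[match(paste(ev$subject_id, ev$visit),
                                paste(long$visits$subject_id, long$visits$visit))]
  subj_conv$age[match(ev$subject_id, subj_conv$subject_id)] <- vage
  attribution <- attribute_converters(
    model, fit,
    conv_th %||% cohort$thickness[0, , drop = FALSE],
    subj_conv, mci_assignments, labels,
    converter_ids = ev$subject_id)

  c(out, list(longitudinal = long, screen = scr, series = series,
              conversion_by_subtype = conv, apoe = apoe,
              attribution = attribution, events = ev))
}
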