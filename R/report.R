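#' Subtype share and baseline characteristics table
#'
#' Counts and percentage shares per subtype (half-up rounding to one
#' decimal) plus mean +/- sd of covariates and cognitive scores.
#'
#' @param assignments data.frame with `subject_id` and `subtype_label`
#' @param subjects subject table covering every assigned subject
#' @param variables continuous columns to summarize
#' @return object of class `subtype_summary`: data.frame `shares`
#'   (`subtype`, `n`, `share_pct`) and data.frame `characteristics`
#' @export
#' @examples
#' a <- data.frame(subject_id = as.character(1:3),
#'                 subtype_label = c("MIN", "MID", "DIF"))
#' s <- data.frame(subject_id = as.character(1:3), age = c(70, 75, 80))
#' subtype_share_table(a, s, variables = "age")$shares
subtype_share_table <- function(assignments, subjects,
                                variables = c("age", "education_years",
                                              "MMSE", "CDRSB", "ADAS13", "FAQ",
                                              "ADNI_MEM", "ADNI_EF",
                                              "ADNI_LAN", "ADNI_VS")) {
  miss <- setdiff(assignments$subject_id, subjects$subject_id)
  if (length(miss))
    stop("assigned subjects missing from subjects table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lab <- assignments$subtype_label
  lev <- intersect(c("MIN", "MID", "DIF"), unique(lab))
  if (!length(lev)) lev <- sort(unique(lab))
  n <- vapply(lev, function(l) sum(lab == l), integer(1))
  shares <- data.frame(subtype = lev, n = n,
                       share_pct = round_half_up(100 * n / length(lab), 1),
                       stringsAsFactors = FALSE)
  sub <- subjects[match(assignments$subject_id, subjects$subject_id), ]
  variables <- intersect(variables, names(sub))
  chars <- do.call(rbind, lapply(lev, function(l) {
    rows <- sub[lab == l, , drop = FALSE]
    do.call(rbind, lapply(variables, function(v)
      data.frame(subtype = l, variable = v,
                 mean = mean(rows[[v]], na.rm = TRUE),
                 sd = stats::sd(rows[[v]], na.rm = TRUE),
                 stringsAsFactors = FALSE)))
  }))
  rownames(shares) <- rownames(chars) <- NULL
  structure(list(shares = shares, characteristics = chars),
            class = "subtype_summary")
}

#' Flag ROIs with significant atrophy per subtype
#'
#' Per ROI, a Welch two-sample t-test of each subtype's residuals (or
#' thickness) against CN; flagged when p < 0.05 (uncorrected, by design —
#' the flags drive a descriptive atrophy map, not inference). Identical
#' samples short-circuit to p = 1.
#'
#' @param features subjects x ROIs matrix
#' @param groups factor/character per row: "CN" or a subtype label
#' @return data.frame: `subtype`, `roi`, `p_value`, `direction`
#'   (-1 thinner than CN), `flag`
#' @export
roi_atrophy_flags <- function(features, groups) {
  groups <- as.character(groups)
  cn <- features[groups == "CN", , drop = FALSE]
  if (nrow(cn) < 2) stop("need >= 2 CN subjects", call. = FALSE)
  subtypes <- setdiff(unique(groups), "CN")
  out <- list()
  for (s in subtypes) {
    g <- features[groups == s, , drop = FALSE]
    if (nrow(g) < 2)
      stop(sprintf("need >= 2 subjects in group '%s'", s), call. = FALSE)
    for (j in seq_len(ncol(features))) {
      x <- g[, j]; y <- cn[, j]
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      } else stats::t.test(x, y)$p.value
      out[[length(out) + 1]] <- data.frame(
        subtype = s, roi = colnames(features)[j] %||% paste0("roi_", j),
        p_value = p, direction = sign(mean(x) - mean(y)),
        flag = p < 0.05, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative conversions per subtype from per-period counts
#'
#' @param counts data.frame with `subtype`, `period`, `n_convert` and
#'   optionally `n_at_risk`
#' @return data.frame per subtype: per-period counts (wide), `total`, and
#'   per-period rates when denominators are present
#' @export
cumulative_conversions <- function(counts) {
  if (any(counts$n_convert < 0)) stop("negative conversion count", call. = FALSE)
  subtypes <- unique(counts$subtype)
  periods <- unique(counts$period)
  out <- do.call(rbind, lapply(subtypes, function(s) {
    rows <- counts[counts$subtype == s, , drop = FALSE]
    wide <- stats::setNames(rows$n_convert[match(periods, rows$period)], periods)
    df <- data.frame(subtype = s, t(wide), total = sum(wide, na.rm = TRUE),
                     stringsAsFactors = FALSE, check.names = FALSE)
    if ("n_at_risk" %in% names(rows)) {
      rates <- ifelse(rows$n_at_risk > 0, rows$n_convert / rows$n_at_risk, NA)
      df[paste0("rate_", rows$period)] <- as.list(rates)
    }
    df
  }))
  rownames(out) <- NULL
  out
}

.is_carrier <- function(a1, a2, allele) {
  (!is.na(a1) & a1 == allele) | (!is.na(a2) & a2 == allele)
}

#' APOE carrier statistics among converters
#'
#' For each subtype's converters: counts and percentages (half-up, one
#' decimal) of epsilon-4 and epsilon-2 carriers (at least one allele).
#' Converters with missing genotypes are counted in `n_missing_apoe`, never
#' silently dropped.
#'
#' @param events conversion events (`subject_id`) joined with a subtype
#'   column `subtype`
#' @param subjects subject table with `apoe_a1`, `apoe_a2`
#' @return data.frame per subtype: `n_converters`, `e4_carriers`, `e4_pct`,
#'   `e2_carriers`, `e2_pct`, `n_missing_apoe`
#' @export
apoe_carrier_stats <- function(events, subjects) {
  sub <- subjects[match(events$subject_id, subjects$subject_id), ]
  out <- do.call(rbind, lapply(unique(events$subtype), function(s) {
    rows <- sub[events$subtype == s, , drop = FALSE]
    n <- nrow(rows)
    missing <- is.na(rows$apoe_a1) | is.na(rows$apoe_a2)
    e4 <- sum(.is_carrier(rows$apoe_a1, rows$apoe_a2, "e4"))
    e2 <- sum(.is_carrier(rows$apoe_a1, rows$apoe_a2, "e2"))
    data.frame(subtype = s, n_converters = n,
               e4_carriers = e4, e4_pct = round_half_up(100 * e4 / n, 1),
               e2_carriers = e2, e2_pct = round_half_up(100 * e2 / n, 1),
               n_missing_apoe = sum(missing), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-subtype per-visit cognitive trajectory means
#'
#' Mean +/- sd of each scale over the subjects retained (at risk) at each
#' period; no last-observation-carried-forward.
#'
#' @param screen a `screen_result` from [screen_periods()]
#' @param scores long table `subject_id`, `visit`, one column per scale
#' @param assignments data.frame with `subject_id`, `subtype_label`
#' @param scales score columns to summarize
#' @return data.frame: `subtype`, `visit`, `scale`, `n`, `mean`, `sd`
#' @export
trajectory_means <- function(screen, scores, assignments,
                             scales = intersect(c("MMSE", "CDRSB", "ADAS13",
                                                  "FAQ", "ADNI_MEM", "ADNI_EF",
                                                  "ADNI_LAN", "ADNI_VS"),
                                                names(scores))) {
  lab <- assignments$subtype_label[match(scores$subject_id,
                                         assignments$subject_id)]
  periods <- c(bl = NA, stats::setNames(names(screen$at_risk),
                                        names(screen$at_risk)))
  out <- list()
  for (v in c("bl", names(screen$at_risk))) {
    keep_ids <- if (v == "bl") screen$baseline else screen$at_risk[[v]]
    rows <- scores$visit == v & scores$subject_id %in% keep_ids
    for (s in unique(stats::na.omit(lab))) {
      sel <- rows & !is.na(lab) & lab == s
      for (sc in scales) {
        x <- scores[[sc]][sel]
        out[[length(out) + 1]] <- data.frame(
          subtype = s, visit = v, scale = sc, n = sum(!is.na(x)),
          mean = if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_,
          sd = stats::sd(x, na.rm = TRUE), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-comparison p-values for a subtype summary
#'
#' One-way ANOVA across subtypes per continuous variable and chi-square
#' tests for carrier proportions, delegated to `stats::aov` and
#' `stats::chisq.test`. Variables with any group below 2 subjects are
#' skipped with a note.
#'
#' @param subjects subject table
#' @param assignments data.frame with `subject_id`, `subtype_label`
#' @param variables continuous variables to test
#' @param carriers alleles to test as carrier proportions
#' @return data.frame: `variable`, `test`, `p_value`, `note`
#' @export
group_comparison_table <- function(subjects, assignments,
                                   variables = c("age", "education_years",
                                                 "MMSE", "CDRSB", "ADAS13",
                                                 "FAQ", "ADNI_MEM", "ADNI_EF",
                                                 "ADNI_LAN", "ADNI_VS"),
                                   carriers = c("e4", "e2")) {
  sub <- subjects[match(assignments$subject_id, subjects$subject_id), ]
  grp <- factor(assignments$subtype_label)
  out <- list()
  for (v in intersect(variables, names(sub))) {
    sizes <- tapply(!is.na(sub[[v]]), grp, sum)
    if (any(sizes < 2)) {
      out[[length(out) + 1]] <- data.frame(variable = v, test = "anova",
                                           p_value = NA_real_,
                                           note = "skipped: group with n < 2")
      next
    }
    p <- summary(stats::aov(sub[[v]] ~ grp))[[1]][["Pr(>F)"]][1]
    out[[length(out) + 1]] <- data.frame(variable = v, test = "anova",
                                         p_value = p, note = "")
  }
  for (al in carriers) {
    carrier <- .is_carrier(sub$apoe_a1, sub$apoe_a2, al)
    tab <- table(grp, carrier)
    p <- if (ncol(tab) < 2) NA_real_ else
      suppressWarnings(stats::chisq.test(tab)$p.value)
    out[[length(out) + 1]] <- data.frame(variable = paste0("apoe_", al, "_carrier"),
                                         test = "chisq", p_value = p, note = "")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
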