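.screen_visits <- c("bl", "m06", "m12", "m18", "m24", "m36")
.screen_periods <- c("m06", "m12", "m18", "m24")

# subject x visit lookup helpers over the long visit table
.visit_grid <- function(visits) {
  visits <- visits[visits$visit %in% .screen_visits, , drop = FALSE]
  ids <- unique(visits$subject_id)
  scan <- matrix(FALSE, length(ids), length(.screen_visits),
                 dimnames = list(ids, .screen_visits))
  dx <- matrix(NA_character_, length(ids), length(.screen_visits),
               dimnames = list(ids, .screen_visits))
  i <- cbind(match(visits$subject_id, ids), match(visits$visit, .screen_visits))
  scan[i] <- visits$scan_present > 0
  dx[i] <- visits$diagnosis
  list(ids = ids, scan = scan, dx = dx)
}

#' Select the baseline MCI analysis set
#'
#' Subjects diagnosed MCI at baseline with a baseline scan; everyone else
#' is excluded with reason `no_baseline_mci`.
#'
#' @param visits long visit table (`subject_id`, `visit`, `scan_present`,
#'   `diagnosis`)
#' @return list with `retained` ids and `excluded` data.frame
#'   (`subject_id`, `reason`)
#' @export
screen_baseline <- function(visits) {
  g <- .visit_grid(visits)
  if (!length(g$ids))
    return(list(retained = character(0),
                excluded = data.frame(subject_id = character(0),
                                      reason = character(0))))
  ok <- g$scan[, "bl"] & !is.na(g$dx[, "bl"]) & g$dx[, "bl"] == "MCI"
  list(retained = g$ids[ok],
       excluded = data.frame(subject_id = g$ids[!ok],
                             reason = rep("no_baseline_mci", sum(!ok)),
                             stringsAsFactors = FALSE))
}

#' Resolve a subject's month-24 status
#'
#' The 24-month visit is the screening cut-off. A subject with an M24 scan
#' is `observed`. Lacking M24 but holding scans at M06-M18 and M36 with an
#' M36 diagnosis of MCI, the subject is imputed as still-MCI at M24
#' (`imputed_mci_from_m36`). Lacking M24 with an M36 state of AD or CN, the
#' transition time is indeterminable and the subject is excluded
#' (`excluded_indeterminate`).
#'
#' @param visits long visit table
#' @param subject_id one subject id
#' @return one of `"observed"`, `"imputed_mci_from_m36"`,
#'   `"excluded_indeterminate"`
#' @export
resolve_m24 <- function(visits, subject_id) {
  g <- .visit_grid(visits[visits$subject_id == subject_id, , drop = FALSE])
  if (!length(g$ids)) return("excluded_indeterminate")
  scan <- g$scan[1, ]; dx <- g$dx[1, ]
  if (scan[["m24"]]) return("observed")
  mid_ok <- all(scan[c("m06", "m12", "m18", "m36")])
  if (mid_ok && !is.na(dx[["m36"]]) && dx[["m36"]] == "MCI")
    return("imputed_mci_from_m36")
  "excluded_indeterminate"
}

# The backward retention rule, isolated so alternative readings can be
# swapped: a subject counts at period p when scanned at p, or when the scan
# is recovered by a later visit — at p = m18 that is (scan at m24) OR
# (scan at m18, no m24 scan, scan at m36); applied analogously at m12/m06.
.retained_at_period <- function(scan, p) {
  later <- .screen_visits[(match(p, .screen_visits) + 1):length(.screen_visits)]
  scan[[p]] || any(scan[later])
}

#' Sequentially screen follow-up periods and collect events
#'
#' Forward sweep over M06, M12, M18, M24. At each period, subjects observed
#' AD are recorded as conversion events for that period and removed from
#' all later at-risk sets (reason `converted_prior_period`); subjects
#' observed CN are reversion events (`reverted_prior_period`). A subject
#' missing the period's scan stays at risk if a later retained visit covers
#' them; a conversion first seen at a later scan is dated to that visit (no
#' interval imputation). Subjects whose M24 status is indeterminate are
#' excluded with `missing_followup_indeterminate`; M24-imputed subjects are
#' retained and annotated `imputed_from_m36`.
#'
#' @param visits long visit table
#' @param baseline result of [screen_baseline()] (or a character vector of
#'   baseline MCI ids)
#' @param require_scan if TRUE (default) a diagnosis at a scan-less visit
#'   does not trigger an event; if FALSE it does, with a warning
#' @return object of class `screen_result`: `at_risk` (named list of ids
#'   per period), `events` (`subject_id`, `visit`, `to`), `exclusions`
#'   (`subject_id`, `reason`), `annotations`
#' @export
screen_periods <- function(visits, baseline = screen_baseline(visits),
                           require_scan = TRUE) {
  base_ids <- if (is.list(baseline)) baseline$retained else baseline
  base_excl <- if (is.list(baseline)) baseline$excluded else
    data.frame(subject_id = character(0), reason = character(0))
  g <- .visit_grid(visits)

  excl <- base_excl
  annotations <- data.frame(subject_id = character(0), note = character(0),
                            stringsAsFactors = FALSE)
  active <- character(0)
  for (id in base_ids) {
    st <- resolve_m24(visits[visits$subject_id == id, , drop = FALSE], id)
    if (st == "excluded_indeterminate" &&
        !.has_observed_event(g, id, require_scan)) {
      excl <- rbind(excl, data.frame(subject_id = id,
                                     reason = "missing_followup_indeterminate"))
    } else {
      active <- c(active, id)
      if (st == "imputed_mci_from_m36")
        annotations <- rbind(annotations,
                             data.frame(subject_id = id, note = "imputed_from_m36"))
    }
  }

  at_risk <- stats::setNames(vector("list", length(.screen_periods)),
                             .screen_periods)
  events <- data.frame(subject_id = character(0), visit = character(0),
                       to = character(0), stringsAsFactors = FALSE)
  for (p in .screen_periods) {
    at_risk[[p]] <- active
    nxt <- character(0)
    for (id in active) {
      scan <- g$scan[id, ]; dx <- g$dx[id, ]
      has_obs <- scan[[p]] || (!require_scan && !is.na(dx[[p]]))
      if (!require_scan && !scan[[p]] && !is.na(dx[[p]]))
        warning(sprintf("subject %s: diagnosis without scan at %s honored", id, p))
      if (has_obs && !is.na(dx[[p]]) && dx[[p]] == "AD") {
        events <- rbind(events, data.frame(subject_id = id, visit = p, to = "AD"))
        excl <- rbind(excl, data.frame(subject_id = id,
                                       reason = "converted_prior_period"))
      } else if (has_obs && !is.na(dx[[p]]) && dx[[p]] == "CN") {
        events <- rbind(events, data.frame(subject_id = id, visit = p, to = "CN"))
        excl <- rbind(excl, data.frame(subject_id = id,
                                       reason = "reverted_prior_period"))
      } else if (has_obs || .retained_at_period(scan, p)) {
        nxt <- c(nxt, id)
      }
      # neither scanned nor recoverable: silently exits the risk set here
      # (already vetted by the M24 rule, so this only trims trailing gaps)
    }
    active <- nxt
  }
  structure(list(at_risk = at_risk, retained_final = active,
                 events = events, exclusions = excl,
                 annotations = annotations, baseline = base_ids),
            class = "screen_result")
}

.has_observed_event <- function(g, id, require_scan) {
  scan <- g$scan[id, .screen_periods]
  dx <- g$dx[id, .screen_periods]
  obs <- if (require_scan) scan else (scan | !is.na(dx))
  any(obs & !is.na(dx) & dx %in% c("AD", "CN"))
}

#' Per-period at-risk counts and conversion rates
#'
#' @param result a `screen_result` from [screen_periods()]
#' @return data.frame: `period`, `n_at_risk`, `n_convert`, `n_revert`,
#'   `rate` (converters / at-risk; `NA` when no one is at risk)
#' @export
at_risk_series <- function(result) {
  out <- do.call(rbind, lapply(.screen_periods, function(p) {
    n <- length(result$at_risk[[p]])
    ev <- result$events[result$events$visit == p, , drop = FALSE]
    nc <- sum(ev$to == "AD"); nr <- sum(ev$to == "CN")
    if (n == 0 && nc > 0)
      stop(sprintf("impossible state at %s: converters without an at-risk set", p),
           call. = FALSE)
    data.frame(period = p, n_at_risk = n, n_convert = nc, n_revert = nr,
               rate = if (n > 0) nc / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
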