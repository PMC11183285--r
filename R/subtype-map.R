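#' Unsigned geometric distances to every expert hyperplane
#'
#' `distance_k = |w_k . x + b_k| / ||w_k||_2`. Subjects must be
#' residualized with the same CN fit as the training data. A signed variant
#' (positive toward the AD side) is available for sensitivity analysis.
#'
#' @param model a fitted `moe_model`
#' @param X feature matrix (rows = subjects)
#' @param signed if TRUE, return `(w.x + b)/||w||` without the absolute value
#' @return subjects x K distance matrix
#' @export
#' @examples
#' m <- list(experts = list(list(w = c(3, 4), b = 0, d = c(0, 0))))
#' class(m) <- "moe_model"
#' hyperplane_distances(m, matrix(c(1, 1), 1))  # |3+4|/5 = 1.4
hyperplane_distances <- function(model, X, signed = FALSE) {
  X <- rbind(X)
  K <- length(model$experts)
  out <- matrix(0, nrow(X), K, dimnames = list(rownames(X), NULL))
  for (k in seq_len(K)) {
    e <- model$experts[[k]]
    nrm <- sqrt(sum(e$w^2))
    if (nrm == 0)
      stop(sprintf("expert %d has a zero weight vector; no hyperplane distance", k),
           call. = FALSE)
    f <- (drop(X %*% e$w) + e$b) / nrm
    out[, k] <- if (signed) f else abs(f)
  }
  out
}

#' Assign subjects to subtypes by smallest hyperplane distance
#'
#' Each subject (typically MCI) is assigned to the expert whose hyperplane
#' is closest; exact ties resolve to the lowest expert index. The full
#' distance vector is retained.
#'
#' @param model a fitted `moe_model`
#' @param residuals residualized feature matrix of the subjects to assign
#' @param labels optional expert-index -> label map from
#'   [rank_and_name_subtypes()]
#' @return data.frame: `subject_id`, `expert_index`, `subtype_label`,
#'   `d_1..d_K`, `d_min`
#' @export
assign_min_distance <- function(model, residuals, labels = NULL) {
  D <- hyperplane_distances(model, residuals)
  k_star <- apply(D, 1, which.min)
  out <- data.frame(subject_id = rownames(residuals) %||%
                      sprintf("row%d", seq_len(nrow(D))),
                    expert_index = k_star,
                    subtype_label = if (is.null(labels)) NA_character_
                                    else unname(labels[k_star]),
                    stringsAsFactors = FALSE)
  Dd <- as.data.frame(D)
  names(Dd) <- paste0("d_", seq_len(ncol(D)))
  out <- cbind(out, Dd)
  out$d_min <- apply(D, 1, min)
  rownames(out) <- NULL
  out
}

#' Name experts by atrophy severity
#'
#' Scores each expert by the mean ROI residual of its argmax-membership AD
#' subjects (more negative = deeper atrophy) and assigns labels from least
#' to most atrophic: `MIN`, `MID`, `DIF` when K = 3, otherwise `S1..SK`.
#' Equal severities rank by expert index. Labels follow severity, not
#' index, so they are invariant to expert permutation.
#'
#' @param model a fitted `moe_model`
#' @param data the [moe_data()] the model was fitted on
#' @return named character vector: position = expert index, value = label
#' @export
rank_and_name_subtypes <- function(model, data) {
  K <- length(model$experts)
  hard <- apply(model$memberships, 1, which.max)
  Xad <- data$X[data$ad, , drop = FALSE]
  severity <- vapply(seq_len(K), function(k) {
    members <- hard == k
    if (!any(members))
      stop(sprintf("expert %d has no argmax-membership AD subjects", k),
           call. = FALSE)
    mean(rowMeans(Xad[members, , drop = FALSE]))
  }, numeric(1))
  lbl <- if (K == 3) c("MIN", "MID", "DIF") else sprintf("S%d", seq_len(K))
  # least atrophic (largest mean residual) first; ties by index
  rank_order <- order(-severity, seq_len(K))
  labels <- character(K)
  labels[rank_order] <- lbl
  stats::setNames(labels, paste0("expert_", seq_len(K)))
}

#' Attribute converters to AD subtypes at conversion time
#'
#' Residualizes each converter's conversion-visit thickness with the
#' baseline CN fit, applies the min-distance rule, and joins the result
#' with the baseline subtype into a transition table. Converters without a
#' conversion-visit scan are reported as unattributable, not dropped.
#'
#' @param model a fitted `moe_model`
#' @param glm_fit the baseline `cn_glm` used for training features
#' @param conv_thickness thickness matrix of converters at their conversion
#'   visit (rownames = subject ids)
#' @param subjects subject table providing conversion-visit covariates (use
#'   visit-specific age where available)
#' @param baseline_assignments data.frame from [assign_min_distance()] with
#'   baseline `subject_id` and `subtype_label`
#' @param labels expert-index -> label map from [rank_and_name_subtypes()]
#' @param converter_ids ids of all converters; those absent from
#'   `conv_thickness` appear with `ad_subtype = "unattributable"`
#' @return list with `assignments` (per-converter) and `transition`
#'   (baseline_subtype x ad_subtype counts)
#' @export
attribute_converters <- function(model, glm_fit, conv_thickness, subjects,
                                 baseline_assignments, labels,
                                 converter_ids = rownames(conv_thickness)) {
  have <- intersect(converter_ids, rownames(conv_thickness))
  asg <- if (length(have)) {
    res <- residualize(conv_thickness[have, , drop = FALSE], subjects, glm_fit)
    assign_min_distance(model, res, labels = labels)
  } else {
    data.frame(subject_id = character(0), expert_index = integer(0),
               subtype_label = character(0), stringsAsFactors = FALSE)
  }
  missing_ids <- setdiff(converter_ids, have)
  all_asg <- data.frame(
    subject_id = c(asg$subject_id, missing_ids),
    ad_subtype = c(asg$subtype_label, rep("unattributable", length(missing_ids))),
    stringsAsFactors = FALSE)
  bl <- baseline_assignments[match(all_asg$subject_id,
                                   baseline_assignments$subject_id), ]
  all_asg$baseline_subtype <- bl$subtype_label
  lvls <- unique(c(unname(labels), "unattributable"))
  transition <- as.data.frame(
    table(baseline_subtype = factor(all_asg$baseline_subtype, levels = lvls),
          ad_subtype = factor(all_asg$ad_subtype, levels = lvls)),
    stringsAsFactors = FALSE)
  names(transition)[3] <- "count"
  list(assignments = all_asg, transition = transition)
}
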