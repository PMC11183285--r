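#' Bezdek partition coefficient
#'
#' `BPC = (1/N) sum_i sum_k m_ik^2`; 1 for a crisp partition, `1/K` for a
#' maximally fuzzy one. Used as a cluster-validity index during model
#' selection.
#'
#' @param memberships AD x K membership matrix (unit row sums)
#' @return scalar in `[1/K, 1]`
#' @export
#' @examples
#' bezdek_pc(matrix(c(0.5, 0.8, 0.5, 0.2), 2, 2))  # 0.59
bezdek_pc <- function(memberships) {
  mean(rowSums(memberships^2))
}

#' Maximum pairwise inner product of expert weight vectors
#'
#' `W_r = max_{j<k} <w_j/||w_j||, w_k/||w_k||>` (intercepts excluded).
#' Small values mean the experts carve out distinct directions. Undefined
#' for a single expert (returns `NA`).
#'
#' @param experts list of experts with `w`, or a fitted `moe_model`
#' @return scalar in `[-1, 1]`, or `NA` for K = 1
#' @export
pairwise_wr <- function(experts) {
  if (inherits(experts, "moe_model")) experts <- experts$experts
  K <- length(experts)
  if (K < 2) return(NA_real_)
  W <- vapply(experts, function(e) {
    nrm <- sqrt(sum(e$w^2))
    if (nrm == 0) stop("degenerate expert with zero weight vector", call. = FALSE)
    e$w / nrm
  }, numeric(length(experts[[1]]$w)))
  G <- crossprod(W)
  max(G[upper.tri(G)])
}

#' Stratified cross-validated accuracy of the mixture of experts
#'
#' Splits AD and CN subjects separately into `config$cv_folds` folds (seeded
#' from `config$seed`), fits the full estimator on each training set, and
#' classifies the held-out subjects by [predict_label()].
#'
#' @param data a [moe_data()]
#' @param config a [moe_config()]
#' @return list with `acc_mean`, `acc_sd`, `per_fold`, and the fold
#'   assignment vector `folds`
#' @export
cross_validate <- function(data, config) {
  n <- nrow(data$X)
  if (config$cv_folds > min(length(data$ad), length(data$cn)))
    stop("more folds than the smallest class", call. = FALSE)
  set.seed(derive_seed(config$seed, 3L))
  folds <- integer(n)
  for (idx in list(data$ad, data$cn))
    folds[idx] <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
  acc <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    if (!any(data$y[tr] == 1) || !any(data$y[tr] == -1))
      stop("a class is absent from a training fold", call. = FALSE)
    sub <- structure(list(X = data$X[tr, , drop = FALSE], y = data$y[tr],
                          ids = data$ids[tr], ad = which(data$y[tr] == 1),
                          cn = which(data$y[tr] == -1)), class = "moe_data")
    model <- fit_moe(sub, config)
    pred <- predict_label(model, data$X[!tr, , drop = FALSE])
    acc[f] <- mean(pred$label == data$y[!tr])
  }
  list(acc_mean = mean(acc), acc_sd = stats::sd(acc), per_fold = acc,
       folds = folds)
}

#' Grid search over loss penalty, trade-off and class weight
#'
#' Evaluates every `(C, t, rho)` combination: cross-validated accuracy
#' (Acc), the maximum pairwise inner product of the full-data fit's expert
#' weights (W_r), and its Bezdek partition coefficient (BPC). The selected
#' point maximizes Acc, breaking ties by smaller W_r, then larger BPC, then
#' smaller C, then smaller t (the full grid is returned so users can
#' re-select under a different rule).
#'
#' @param data a [moe_data()]
#' @param config a [moe_config()] providing K, folds, seed etc.
#' @param C_grid,t_grid candidate values; default powers of two from 2^-3
#'   to 2^10
#' @param rho_grid candidate AD:CN class-weight ratios (default 1..5)
#' @return object of class `moe_selection`: data.frame `report` with one
#'   row per grid point (`C`, `t`, `rho`, `acc_mean`, `acc_sd`, `wr`,
#'   `bpc`, `selected`) and the winning `config`
#' @export
grid_search_select <- function(data, config,
                               C_grid = 2^(-3:10), t_grid = 2^(-3:10),
                               rho_grid = 1:5) {
  grid <- expand.grid(C = C_grid, t = t_grid, rho = rho_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty parameter grid", call. = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$C <- grid$C[g]; cfg$t <- grid$t[g]; cfg$class_weight <- grid$rho[g]
    cv <- cross_validate(data, cfg)
    full <- fit_moe(data, cfg)
    rows[[g]] <- data.frame(C = cfg$C, t = cfg$t, rho = cfg$rho %||% grid$rho[g],
                            acc_mean = cv$acc_mean, acc_sd = cv$acc_sd,
                            wr = pairwise_wr(full), bpc = bezdek_pc(full$memberships))
  }
  report <- do.call(rbind, rows)
  report$rho <- grid$rho
  # lexicographic selection: Acc desc, W_r asc, BPC desc, C asc, t asc
  wr_cmp <- ifelse(is.na(report$wr), Inf, report$wr)
  ord <- order(-report$acc_mean, wr_cmp, -report$bpc, report$C, report$t)
  sel <- ord[1]
  report$selected <- seq_len(nrow(report)) == sel
  cfg <- config
  cfg$C <- report$C[sel]; cfg$t <- report$t[sel]
  cfg$class_weight <- report$rho[sel]
  structure(list(report = report, config = cfg,
                 rule = "max Acc; ties: min W_r, max BPC, min C, min t"),
            class = "moe_selection")
}

#' Serialize a fitted model to plain-text files
#'
#' Writes a JSON-like description (per expert: ROI-named weights, intercept,
#' centroid) and the membership table as TSV.
#'
#' @param model a fitted `moe_model`
#' @param path basename; writes `<path>.json` and `<path>_memberships.tsv`
#' @return invisibly the written paths
#' @export
write_moe_model <- function(model, path) {
  roi <- model$roi %||% paste0("f", seq_along(model$experts[[1]]$w))
  lines <- c("{", sprintf('  "K": %d,', length(model$experts)), '  "experts": [')
  for (k in seq_along(model$experts)) {
    e <- model$experts[[k]]
    lines <- c(lines, "    {",
      sprintf('      "b": %.15g,', e$b),
      sprintf('      "w": {%s},', paste(sprintf('"%s": %.15g', roi, e$w), collapse = ", ")),
      sprintf('      "d": [%s]', paste(sprintf("%.15g", e$d), collapse = ", ")),
      if (k < length(model$experts)) "    }," else "    }")
  }
  lines <- c(lines, "  ]", "}")
  json <- paste0(path, ".json")
  writeLines(lines, json)
  mtsv <- paste0(path, "_memberships.tsv")
  utils::write.table(as.data.frame(model$memberships), mtsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(json, mtsv))
}
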