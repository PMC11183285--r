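.build_design <- function(subjects, covariates) {
  cols <- list()
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      age = subjects$age,
      sex = as.numeric(subjects$sex == "F"),  # F = 1, M = 0
      education = subjects$education_years,
      icv = subjects$icv_mm3,
      stop_field("covariates", sprintf("unknown covariate '%s'", cv)))
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", covariates)
  X
}

#' Fit per-ROI covariate models on cognitively normal subjects
#'
#' Ordinary least squares of each ROI's thickness on an intercept plus the
#' requested covariates, using CN rows only. The fit is later applied to
#' every subject (CN, MCI, AD) by [residualize()], so that group contrasts
#' are taken relative to the normal-aging expectation. Diagnosis labels of
#' non-CN subjects never enter the fit.
#'
#' @param thickness subjects x ROIs numeric matrix (rownames = subject ids)
#' @param subjects subject table with `subject_id`, `diagnosis`, `age`,
#'   `sex` ("F"/"M"), `education_years`, `icv_mm3`
#' @param covariates covariates to remove, subset of
#'   `c("age", "sex", "education", "icv")`
#' @return object of class `cn_glm`: per-ROI coefficient matrix, residual
#'   standard deviations, and the CN sample size used
#' @export
fit_cn_glm <- function(thickness, subjects,
                       covariates = c("age", "sex", "education", "icv")) {
  cn <- subjects[subjects$diagnosis == "CN", , drop = FALSE]
  if (nrow(cn) < length(covariates) + 2)
    stop(sprintf("too few CN subjects (%d) to fit %d covariates",
                 nrow(cn), length(covariates)), call. = FALSE)
  miss <- setdiff(cn$subject_id, rownames(thickness))
  if (length(miss))
    stop("CN subjects missing from thickness table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  Y <- thickness[cn$subject_id, , drop = FALSE]
  X <- .build_design(cn, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dfres <- max(nrow(X) - ncol(X), 1)
  structure(list(coefficients = beta,
                 sigma = sqrt(colSums(resid^2) / dfres),
                 covariates = covariates, n_cn = nrow(cn),
                 roi = colnames(thickness)),
            class = "cn_glm")
}

#' Remove CN-estimated covariate effects from all subjects
#'
#' Residual = observed thickness minus the [fit_cn_glm()] prediction from
#' the subject's own covariates, applied identically to CN, MCI and AD.
#' CN residual column means are ~0 by construction (OLS orthogonality).
#'
#' @param thickness subjects x ROIs matrix to residualize
#' @param subjects subject table covering every row of `thickness`
#' @param fit a `cn_glm` from [fit_cn_glm()]
#' @return residual matrix of the same shape and dimnames
#' @export
residualize <- function(thickness, subjects, fit) {
  if (!inherits(fit, "cn_glm")) stop("fit must be a cn_glm")
  ids <- rownames(thickness)
  subjects <- subjects[match(ids, subjects$subject_id), , drop = FALSE]
  if (anyNA(subjects$subject_id))
    stop("subjects table missing rows for: ",
         paste(ids[is.na(subjects$subject_id)], collapse = ", "), call. = FALSE)
  covs <- c("age", "education_years", "icv_mm3", "sex")
  bad <- subjects$subject_id[!stats::complete.cases(
    subjects[, intersect(covs, names(subjects)), drop = FALSE])]
  if (length(bad))
    stop("missing covariates for: ", paste(bad, collapse = ", "), call. = FALSE)
  X <- .build_design(subjects, fit$covariates)
  thickness[, fit$roi, drop = FALSE] - X %*% fit$coefficients
}

#' Serialize / read a fitted CN covariate model
#'
#' Small tabular format (one row per ROI: coefficients then residual sd) for
#' reusing a baseline fit on follow-up visits.
#'
#' @param fit a `cn_glm`
#' @param path file to write
#' @return `write_cn_glm` invisibly returns `path`; `read_cn_glm` the fit
#' @export
write_cn_glm <- function(fit, path) {
  df <- data.frame(roi = fit$roi, t(fit$coefficients), sigma = fit$sigma,
                   check.names = FALSE)
  names(df) <- c("roi", rownames(fit$coefficients), "sigma")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# n_cn=%d covariates=%s\n", fit$n_cn,
              paste(fit$covariates, collapse = ",")),
      file = path, append = TRUE)
  invisible(path)
}

#' @rdname write_cn_glm
#' @export
read_cn_glm <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE, stringsAsFactors = FALSE)
  n_cn <- as.integer(sub(".*n_cn=(\\d+).*", "\\1", meta[1]))
  covariates <- strsplit(sub(".*covariates=([^ ]+).*", "\\1", meta[1]), ",")[[1]]
  beta <- t(as.matrix(df[, setdiff(names(df), c("roi", "sigma")), drop = FALSE]))
  colnames(beta) <- df$roi
  structure(list(coefficients = beta,
                 sigma = stats::setNames(df$sigma, df$roi),
                 covariates = covariates, n_cn = n_cn, roi = df$roi),
            class = "cn_glm")
}
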