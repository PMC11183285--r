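# Shared fixtures and independent oracles, all built in code.

# Tiny labeled dataset straight from matrices (bypassing the generator).
make_moe_data <- function(X_ad, X_cn) {
  X <- rbind(X_ad, X_cn)
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  y <- c(rep(1, nrow(X_ad)), rep(-1, nrow(X_cn)))
  structure(list(X = X, y = y, ids = rownames(X),
                 ad = which(y == 1), cn = which(y == -1)),
            class = "moe_data")
}

# Two well-separated planted AD blobs + a CN blob, in p dimensions.
make_blob_data <- function(n_per = 20, p = 6, sep = 3, noise = 0.3, seed = 1) {
  set.seed(seed)
  mu1 <- c(rep(sep, p %/% 2), rep(0, p - p %/% 2))
  mu2 <- c(rep(0, p %/% 2), rep(sep, p - p %/% 2))
  X_ad <- rbind(
    sweep(matrix(rnorm(n_per * p, 0, noise), n_per, p), 2, mu1, "+"),
    sweep(matrix(rnorm(n_per * p, 0, noise), n_per, p), 2, mu2, "+"))
  X_cn <- matrix(rnorm(2 * n_per * p, 0, noise), 2 * n_per, p)
  list(data = make_moe_data(X_ad, X_cn),
       blob = rep(1:2, each = n_per))
}

# Independent oracle for  min sum_k (a_k m_k + c_k m_k^2)  on the simplex:
# enumerate every support set, solve the equality-constrained problem in
# closed form, keep the best feasible solution.
simplex_qp_oracle <- function(a, c) {
  K <- length(a)
  best <- NULL
  best_val <- Inf
  for (mask in seq_len(2^K - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    lam <- (1 + sum(a[idx] / (2 * c[idx]))) / sum(1 / (2 * c[idx]))
    m <- numeric(K)
    m[idx] <- (lam - a[idx]) / (2 * c[idx])
    if (any(m[idx] < -1e-12)) next
    val <- sum(a * m + c * m^2)
    if (val < best_val) { best_val <- val; best <- pmax(m, 0) }
  }
  best
}

# glmnet mapping used as the convex-programming oracle for one expert:
# 0.5*||w||_1 + C*sum(v*(y - b - Xw)^2) corresponds to gaussian glmnet at
# lambda = 1/(4*C*sum(v)) (observation weights are renormalized internally).
l1_expert_oracle <- function(X, y, v, C) {
  fit <- glmnet::glmnet(X, y, family = "gaussian", weights = v,
                        lambda = 1 / (4 * C * sum(v)), standardize = FALSE,
                        intercept = TRUE, thresh = 1e-14)
  cf <- as.numeric(stats::coef(fit))
  list(w = cf[-1], b = cf[1])
}

expert_objective <- function(w, b, X, y, v, C) {
  0.5 * sum(abs(w)) + C * sum(v * (y - b - drop(X %*% w))^2)
}

# Hand-built six-subject visit table covering every screening rule:
#  V1 MCI throughout, fully scanned          -> retained through m24
#  V2 AD at baseline                         -> no_baseline_mci
#  V3 converts to AD at m06                  -> event, excluded after
#  V4 reverts to CN at m12                   -> event, excluded after
#  V5 m24 scan missing, m06-m18 + m36 MCI    -> retained, imputed_from_m36
#  V6 m24 scan missing, m36 state AD         -> missing_followup_indeterminate
make_screen_fixture <- function() {
  row <- function(id, visit, scan, dx)
    data.frame(subject_id = id, visit = visit, scan_present = scan,
               diagnosis = dx, stringsAsFactors = FALSE)
  v <- c("bl", "m06", "m12", "m18", "m24", "m36")
  rbind(
    do.call(rbind, Map(row, "V1", v, 1, "MCI")),
    do.call(rbind, Map(row, "V2", v, 1, "AD")),
    do.call(rbind, Map(row, "V3", v, 1, c("MCI", "AD", "AD", "AD", "AD", "AD"))),
    do.call(rbind, Map(row, "V4", v, 1, c("MCI", "MCI", "CN", "CN", "CN", "CN"))),
    do.call(rbind, Map(row, "V5", v, c(1, 1, 1, 1, 0, 1),
                       c("MCI", "MCI", "MCI", "MCI", NA, "MCI"))),
    do.call(rbind, Map(row, "V6", v, c(1, 1, 1, 1, 0, 1),
                       c("MCI", "MCI", "MCI", "MCI", NA, "AD")))
  )
}

# Expected hand-traced screening outcome for the fixture above.
screen_fixture_expected <- function() {
  list(
    at_risk = list(m06 = c("V1", "V3", "V4", "V5"),
                   m12 = c("V1", "V4", "V5"),
                   m18 = c("V1", "V5"),
                   m24 = c("V1", "V5")),
    events = data.frame(subject_id = c("V3", "V4"), visit = c("m06", "m12"),
                        to = c("AD", "CN"), stringsAsFactors = FALSE),
    exclusions = c(V2 = "no_baseline_mci", V6 = "missing_followup_indeterminate",
                   V3 = "converted_prior_period", V4 = "reverted_prior_period"),
    annotations = c(V5 = "imputed_from_m36")
  )
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
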