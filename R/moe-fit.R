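#' Configuration for the mixture-of-experts estimator
#'
#' @param K number of experts (linear hyperplanes / fuzzy clusters)
#' @param C loss penalty (> 0) multiplying the classification term
#' @param t SVM/FCM trade-off (> 0) multiplying the clustering term. The
#'   clustering distances are summed squared millimetres over all ROIs and
#'   so sit on a much larger raw scale than the unit-scale margin loss; the
#'   default 0.1 keeps the two terms comparable for 68-ROI thickness
#'   residuals. Tune per dataset with [grid_search_select()].
#' @param alpha fuzzy-C-means exponent; fixed default 2 so the closed-form
#'   centroid is the exact minimizer of the clustering term and the
#'   alternating scheme is monotone
#' @param class_weight AD:CN weight ratio rho (>= 1); multiplies the loss of
#'   AD samples only
#' @param loss "squared" (least-squares-SVM style, `(1 - y f)^2`, the
#'   default) or "squared_hinge" (`max(0, 1 - y f)^2`)
#' @param intercept fit an unpenalized intercept per expert (default TRUE);
#'   set FALSE for a strict through-origin hyperplane
#' @param cv_folds stratified cross-validation folds (default 10)
#' @param max_iter maximum alternating sweeps
#' @param tol convergence tolerance on the maximum membership change
#' @param n_restarts random restarts, best final objective kept
#' @param seed integer seed for initialization and fold splits
#' @return object of class `moe_config`
#' @export
moe_config <- function(K = 3, C = 1, t = 0.1, alpha = 2, class_weight = 1,
                       loss = c("squared", "squared_hinge"), intercept = TRUE,
                       cv_folds = 10, max_iter = 100, tol = 1e-4,
                       n_restarts = 5, seed = 1L) {
  loss <- match.arg(loss)
  if (K < 1) stop_field("K", "must be >= 1")
  if (C <= 0) stop_field("C", "must be > 0")
  if (t <= 0) stop_field("t", "must be > 0")
  if (alpha <= 1) stop_field("alpha", "must be > 1")
  if (class_weight < 1) stop_field("class_weight", "must be >= 1")
  if (cv_folds < 2) stop_field("cv_folds", "must be >= 2")
  structure(list(K = as.integer(K), C = C, t = t, alpha = alpha,
                 class_weight = class_weight, loss = loss,
                 intercept = intercept, cv_folds = as.integer(cv_folds),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "moe_config")
}

#' Assemble the labeled dataset for the estimator
#'
#' CN subjects are the shared "anchor" class, labeled -1 in every expert's
#' hyperplane fit; AD subjects are labeled +1 and carry the fuzzy
#' memberships. MCI subjects are excluded here (they are mapped to fitted
#' hyperplanes afterwards).
#'
#' @param residuals residualized thickness matrix (from [residualize()])
#' @param subjects subject table with `subject_id` and `diagnosis`
#' @return object of class `moe_data`: feature matrix `X`, labels `y`
#'   (-1/+1), `ids`, and the AD/CN row indices
#' @export
moe_data <- function(residuals, subjects) {
  keep <- subjects$diagnosis %in% c("CN", "AD")
  subjects <- subjects[keep, , drop = FALSE]
  X <- residuals[subjects$subject_id, , drop = FALSE]
  if (anyNA(X)) stop("missing features in residual matrix", call. = FALSE)
  y <- ifelse(subjects$diagnosis == "AD", 1, -1)
  structure(list(X = X, y = y, ids = subjects$subject_id,
                 ad = which(y == 1), cn = which(y == -1)),
            class = "moe_data")
}

.moe_margin_loss <- function(f, y, loss) {
  if (loss == "squared") (1 - y * f)^2 else pmax(0, 1 - y * f)^2
}

#' Evaluate the joint mixture-of-experts objective
#'
#' Sum over experts of `0.5 * ||w_k||_1` (sparsity), the class-weighted
#' squared-margin loss `C * sum_i s_i m_ik (1 - y_i f_k(x_i))^2`, and the
#' clustering term `t * sum_i m_ik^2 ||x_i - d_k||^2`. Memberships exist for
#' AD subjects only; every CN subject enters every expert's loss with fixed
#' unit weight (the anchor). `s_i` is `class_weight` for AD and 1 for CN.
#'
#' @param model a fitted or hand-built `moe_model` (experts with `w`, `b`,
#'   `d`; `memberships`)
#' @param data a [moe_data()]
#' @param config a [moe_config()] (defaults to the model's own)
#' @return scalar objective value
#' @export
moe_objective <- function(model, data, config = model$config) {
  K <- length(model$experts)
  m <- model$memberships
  if (nrow(m) != length(data$ad) || ncol(m) != K)
    stop("membership matrix does not match data/expert dimensions", call. = FALSE)
  Xad <- data$X[data$ad, , drop = FALSE]
  Xcn <- data$X[data$cn, , drop = FALSE]
  total <- 0
  for (k in seq_len(K)) {
    e <- model$experts[[k]]
    if (length(e$w) != ncol(data$X)) stop("expert weight length mismatch", call. = FALSE)
    f_ad <- drop(Xad %*% e$w) + e$b
    f_cn <- drop(Xcn %*% e$w) + e$b
    l_ad <- .moe_margin_loss(f_ad, 1, config$loss)
    l_cn <- .moe_margin_loss(f_cn, -1, config$loss)
    D <- rowSums(sweep(Xad, 2, e$d)^2)
    total <- total + 0.5 * sum(abs(e$w)) +
      config$C * (config$class_weight * sum(m[, k] * l_ad) + sum(l_cn)) +
      config$t * sum(m[, k]^2 * D)
  }
  total
}

#' Initialize memberships by fuzzy C-means on the AD rows
#'
#' Standard FCM (exponent `alpha`) run to convergence on the AD feature
#' rows; deterministic given `seed`. `K = 1` returns the all-ones column.
#'
#' @param data a [moe_data()]
#' @param K expert count
#' @param seed integer seed
#' @param alpha FCM exponent
#' @return AD x K membership matrix with unit row sums
#' @export
init_memberships <- function(data, K, seed = 1L, alpha = 2) {
  n_ad <- length(data$ad)
  if (K > n_ad) stop(sprintf("K = %d exceeds AD count %d", K, n_ad), call. = FALSE)
  if (K == 1) return(matrix(1, n_ad, 1))
  set.seed(seed)
  fit <- e1071::cmeans(data$X[data$ad, , drop = FALSE], centers = K,
                       m = alpha, iter.max = 200)
  unname(fit$membership)
}

.dead_expert <- function(k) {
  stop(structure(class = c("moe_dead_expert", "error", "condition"),
                 list(message = sprintf("expert %d has vanishing total membership", k),
                      call = NULL, expert = k)))
}

# Coordinate descent for  min_{w,b}  0.5*||w||_1 + C * sum_i v_i (y_i - b - x_i'w)^2
# (for y in {-1,+1} the squared margin loss (1 - y f)^2 equals (y - f)^2).
# Soft-thresholding updates run in compiled code (src/l1cd.cpp).
.l1_wls <- function(X, y, v, C, w0 = NULL, b0 = 0, intercept = TRUE,
                    max_iter = 500, tol = 1e-9) {
  p <- ncol(X)
  w <- if (is.null(w0)) numeric(p) else w0
  .l1cd_cpp(X, y, v, C, w, b0 %||% 0, intercept, max_iter, tol)
}

#' Refit every expert hyperplane at fixed memberships
#'
#' For each expert k, minimizes the weighted L1-penalized squared-margin
#' loss `0.5*||w||_1 + C * sum_i v_i (1 - y_i (w'x_i + b))^2` with
#' `v_i = class_weight * m_ik` for AD subjects and 1 for CN; equivalently a
#' weighted L1 least-squares regression of y on X with unpenalized
#' intercept, solved by coordinate descent (warm-started, so the joint
#' objective cannot increase).
#'
#' @param data a [moe_data()]
#' @param memberships AD x K matrix
#' @param config a [moe_config()]
#' @param warm optional previous expert list for warm starts
#' @return list of K experts (`w`, `b`)
#' @export
update_experts <- function(data, memberships, config, warm = NULL) {
  K <- ncol(memberships)
  n <- nrow(data$X)
  experts <- vector("list", K)
  for (k in seq_len(K)) {
    if (sum(memberships[, k]) < 1e-8) .dead_expert(k)
    v <- numeric(n)
    v[data$ad] <- config$class_weight * memberships[, k]
    v[data$cn] <- 1
    fit <- .l1_wls(data$X, data$y, v, config$C,
                   w0 = warm[[k]]$w, b0 = warm[[k]]$b %||% 0,
                   intercept = config$intercept)
    if (config$loss == "squared_hinge") {
      # working-set refinement: only margin violators carry loss
      for (ws in 1:5) {
        f <- drop(data$X %*% fit$w) + fit$b
        act <- data$y * f < 1
        if (!any(act)) break
        fit2 <- .l1_wls(data$X, data$y, v * act, config$C,
                        w0 = fit$w, b0 = fit$b, intercept = config$intercept)
        if (max(abs(fit2$w - fit$w)) < 1e-8) { fit <- fit2; break }
        fit <- fit2
      }
    }
    experts[[k]] <- list(w = fit$w, b = fit$b)
  }
  experts
}

#' Recompute expert centroids from memberships
#'
#' `d_k = sum_i m_ik^alpha x_i / sum_i m_ik^alpha` over AD subjects — for
#' `alpha = 2` the exact minimizer of the clustering term.
#'
#' @param data a [moe_data()]
#' @param memberships AD x K matrix
#' @param alpha FCM exponent
#' @return K x p matrix of centroids
#' @export
update_centroids <- function(data, memberships, alpha = 2) {
  Xad <- data$X[data$ad, , drop = FALSE]
  K <- ncol(memberships)
  out <- matrix(0, K, ncol(Xad))
  for (k in seq_len(K)) {
    u <- memberships[, k]^alpha
    if (sum(u) <= 0) .dead_expert(k)
    out[k, ] <- colSums(u * Xad) / sum(u)
  }
  out
}

# Exact minimizer of  sum_k a_k m_k + c_k m_k^2  over the probability simplex
# (KKT water-filling: m_k = max(0, (lambda - a_k)/(2 c_k)); the active set is
# {k : a_k < lambda}, a prefix of the a-sorted order).
.simplex_quad <- function(a, c) {
  K <- length(a)
  o <- order(a)
  inv2c <- 1 / (2 * c[o])
  num <- cumsum(a[o] * inv2c)
  den <- cumsum(inv2c)
  lambda <- (1 + num) / den
  j <- K
  for (jj in seq_len(K)) {
    if (jj == K || lambda[jj] <= a[o][jj + 1] + 1e-15) { j <- jj; break }
  }
  pmax(0, (lambda[j] - a) / (2 * c))
}

#' Reoptimize memberships at fixed experts and centroids
#'
#' For each AD subject the row of memberships minimizes
#' `sum_k [C * rho * m_k * L_k + t * m_k^2 * D_k]` over the probability
#' simplex, where `L_k` is the squared-margin loss under expert k and `D_k`
#' the squared distance to its centroid (floored at 1e-12). Solved in closed
#' form via KKT water-filling.
#'
#' @param data a [moe_data()]
#' @param experts list of experts with `w`, `b`, `d` (or a separate
#'   `centroids` matrix)
#' @param config a [moe_config()]
#' @param centroids optional K x p centroid matrix overriding `experts[[k]]$d`
#' @return AD x K membership matrix with unit row sums
#' @export
update_memberships <- function(data, experts, config, centroids = NULL) {
  K <- length(experts)
  Xad <- data$X[data$ad, , drop = FALSE]
  n_ad <- nrow(Xad)
  L <- matrix(0, n_ad, K)
  D <- matrix(0, n_ad, K)
  for (k in seq_len(K)) {
    e <- experts[[k]]
    d <- if (is.null(centroids)) e$d else centroids[k, ]
    f <- drop(Xad %*% e$w) + e$b
    L[, k] <- .moe_margin_loss(f, 1, config$loss)
    D[, k] <- pmax(rowSums(sweep(Xad, 2, d)^2), 1e-12)
  }
  if (any(!is.finite(L))) stop("non-finite loss in membership update", call. = FALSE)
  if (K == 1) return(matrix(1, n_ad, 1))
  a <- config$C * config$class_weight * L
  cc <- config$t * D
  m <- matrix(0, n_ad, K)
  for (i in seq_len(n_ad)) m[i, ] <- .simplex_quad(a[i, ], cc[i, ])
  m
}

#' Fit the semi-supervised mixture of experts
#'
#' Alternates expert refits, centroid updates and membership updates from an
#' FCM initialization until the maximum membership change drops below
#' `config$tol` (or `max_iter` sweeps). The objective recorded after each
#' full sweep is non-increasing (each block update is a descent step for
#' `alpha = 2`). Runs `n_restarts` seeded restarts and keeps the best final
#' objective. Dead experts (vanishing total membership) are re-seeded at the
#' worst-fit AD subject; after three failed rescues an error is raised.
#'
#' @param data a [moe_data()]
#' @param config a [moe_config()]
#' @return object of class `moe_model`: `experts` (each `w`, `b`, `d`),
#'   `memberships`, `objective_trace`, `converged`, `config`
#' @export
fit_moe <- function(data, config) {
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    seed_r <- derive_seed(config$seed, 100L + r)
    res <- tryCatch(.fit_moe_once(data, config, seed_r),
                    moe_dead_expert = function(e) NULL)
    if (is.null(res) || !length(res$trace)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("all restarts failed with dead experts", call. = FALSE)
  experts <- lapply(seq_len(config$K), function(k)
    list(w = best$experts[[k]]$w, b = best$experts[[k]]$b,
         d = best$centroids[k, ]))
  structure(list(experts = experts, memberships = best$memberships,
                 objective_trace = best$trace, converged = best$converged,
                 config = config, roi = colnames(data$X)),
            class = "moe_model")
}

.fit_moe_once <- function(data, config, seed) {
  m <- init_memberships(data, config$K, seed = seed, alpha = config$alpha)
  experts <- NULL
  trace <- numeric(0)
  converged <- FALSE
  rescues <- 0
  it <- 0
  while (it < config$max_iter) {
    it <- it + 1
    step <- tryCatch({
      experts_new <- update_experts(data, m, config, warm = experts)
      centroids <- update_centroids(data, m, alpha = config$alpha)
      m_new <- update_memberships(data, experts_new, config,
                                  centroids = centroids)
      list(experts = experts_new, centroids = centroids, m = m_new)
    }, moe_dead_expert = function(e) e)
    if (inherits(step, "moe_dead_expert")) {
      rescues <- rescues + 1
      if (rescues > 3) stop(step)
      m <- .rescue_dead_expert(data, m, step$expert, experts, config)
      next
    }
    obj <- moe_objective(
      structure(list(experts = lapply(seq_len(config$K), function(k)
        c(step$experts[[k]], list(d = step$centroids[k, ]))),
        memberships = step$m, config = config), class = "moe_model"),
      data, config)
    trace <- c(trace, obj)
    dm <- max(abs(step$m - m))
    experts <- step$experts
    centroids <- step$centroids
    m <- step$m
    if (dm < config$tol) { converged <- TRUE; break }
  }
  list(experts = experts, centroids = centroids, memberships = m,
       trace = trace, converged = converged,
       objective = trace[length(trace)])
}

# Re-seed a dead expert's membership mass at the AD subject the current
# experts fit worst.
.rescue_dead_expert <- function(data, m, k, experts, config) {
  Xad <- data$X[data$ad, , drop = FALSE]
  if (is.null(experts)) {
    worst <- sample.int(nrow(Xad), 1)
  } else {
    L <- vapply(experts, function(e)
      .moe_margin_loss(drop(Xad %*% e$w) + e$b, 1, config$loss),
      numeric(nrow(Xad)))
    worst <- which.max(apply(as.matrix(L), 1, min))
  }
  m[worst, ] <- 0
  m[worst, k] <- 1
  m / rowSums(m)
}

#' Predict labels by nearest-centroid expert routing
#'
#' Each subject is routed to the expert whose centroid is nearest in
#' residual-feature space (ties toward the lowest index) and labeled by the
#' sign of that expert's decision value (exactly 0 maps to +1).
#'
#' @param model a fitted `moe_model`
#' @param X feature matrix (rows = subjects)
#' @return list with `label` (-1/+1) and `expert` (1-based index)
#' @export
predict_label <- function(model, X) {
  X <- rbind(X)
  K <- length(model$experts)
  D <- vapply(model$experts, function(e) rowSums(sweep(X, 2, e$d)^2),
              numeric(nrow(X)))
  D <- matrix(D, nrow(X), K)
  k_star <- apply(D, 1, which.min)
  f <- vapply(seq_len(nrow(X)), function(i) {
    e <- model$experts[[k_star[i]]]
    sum(e$w * X[i, ]) + e$b
  }, numeric(1))
  list(label = ifelse(f >= 0, 1, -1), expert = k_star, decision = f)
}
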