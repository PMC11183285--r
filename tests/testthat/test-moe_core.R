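zero_model <- function(K, p, n_ad, config) {
  structure(list(
    experts = replicate(K, list(w = numeric(p), b = 0, d = numeric(p)),
                        simplify = FALSE),
    memberships = matrix(1 / K, n_ad, K),
    config = config), class = "moe_model")
}

test_that("the objective has its closed form at the zero model", {
  set.seed(2)
  d <- make_moe_data(matrix(rnorm(12), 4, 3), matrix(rnorm(9), 3, 3))
  for (K in 1:3) {
    cfg <- moe_config(K = K, C = 2.5, t = 1e-9, class_weight = 1)
    mod <- zero_model(K, 3, 4, cfg)
    # every margin loss is (1-0)^2 = 1; AD memberships sum to 1 per subject;
    # CN enters each of the K experts with unit weight; t ~ 0 kills clustering
    expect_equal(moe_objective(mod, d), 2.5 * (4 + K * 3), tolerance = 1e-6)
    cfg2 <- cfg; cfg2$C <- 5
    expect_equal(moe_objective(mod, d, cfg2), 2 * moe_objective(mod, d),
                 tolerance = 1e-6)
  }
})

test_that("the objective matches a hand evaluation on a tiny instance", {
  # 2 AD points, 1 CN point, K = 2, everything set by hand
  X_ad <- rbind(c(1, 0), c(0, 1))
  X_cn <- rbind(c(-1, -1))
  d <- make_moe_data(X_ad, X_cn)
  cfg <- moe_config(K = 2, C = 2, t = 0.5, class_weight = 3)
  w1 <- c(0.5, -0.25); b1 <- 0.1; d1 <- c(0.5, 0.5)
  w2 <- c(0, 1); b2 <- -0.2; d2 <- c(0, 1)
  m <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  mod <- structure(list(experts = list(list(w = w1, b = b1, d = d1),
                                       list(w = w2, b = b2, d = d2)),
                        memberships = m, config = cfg), class = "moe_model")
  hand <- 0
  for (k in 1:2) {
    w <- list(w1, w2)[[k]]; b <- c(b1, b2)[k]; dd <- list(d1, d2)[[k]]
    hand <- hand + 0.5 * sum(abs(w))
    for (i in 1:2)  # AD, y = +1, class weight 3
      hand <- hand + 2 * 3 * m[i, k] * (1 - (sum(w * X_ad[i, ]) + b))^2
    hand <- hand + 2 * (1 - (-1) * (sum(w * X_cn[1, ]) + b))^2  # CN anchor
    for (i in 1:2)
      hand <- hand + 0.5 * m[i, k]^2 * sum((X_ad[i, ] - dd)^2)
  }
  expect_equal(moe_objective(mod, d), hand, tolerance = 1e-10)
})

test_that("membership initialization is a seeded FCM over AD rows", {
  blobs <- make_blob_data(n_per = 15, seed = 4)
  m1 <- init_memberships(blobs$data, 2, seed = 9)
  m2 <- init_memberships(blobs$data, 2, seed = 9)
  expect_identical(m1, m2)
  expect_equal(rowSums(m1), rep(1, 30), tolerance = 1e-9)
  # argmax partition must match the planted blobs (up to label switching)
  expect_equal(ari(apply(m1, 1, which.max), blobs$blob), 1)
  expect_equal(init_memberships(blobs$data, 1), matrix(1, 30, 1))
  expect_error(init_memberships(blobs$data, 99), "exceeds")
})

test_that("the expert update matches a convex-programming oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 5 + rep; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, TRUE)
    y[1] <- 1; y[2] <- -1
    v <- runif(n, 0.2, 2)
    C <- runif(1, 0.5, 3)
    mine <- moesubtype:::.l1_wls(X, y, v, C, max_iter = 5000, tol = 1e-12)
    orac <- l1_expert_oracle(X, y, v, C)
    expect_lt(abs(expert_objective(mine$w, mine$b, X, y, v, C) -
                  expert_objective(orac$w, orac$b, X, y, v, C)), 1e-4)
  }
})

test_that("separable data are classified perfectly in the large-C limit", {
  X_ad <- matrix(rnorm(20, 3, 0.3), 20, 1)
  X_cn <- matrix(rnorm(20, -3, 0.3), 20, 1)
  d <- make_moe_data(X_ad, X_cn)
  cfg <- moe_config(K = 1, C = 100, t = 0.1)
  e <- update_experts(d, matrix(1, 20, 1), cfg)
  f <- drop(d$X %*% e[[1]]$w) + e[[1]]$b
  expect_true(all(sign(f) == d$y))
})

test_that("an expert with vanishing membership raises the dead-expert signal", {
  set.seed(6)
  d <- make_moe_data(matrix(rnorm(20), 10, 2), matrix(rnorm(10), 5, 2))
  m <- cbind(rep(1, 10), rep(0, 10))
  cfg <- moe_config(K = 2, C = 1, t = 0.1)
  expect_error(update_experts(d, m, cfg), class = "moe_dead_expert")
  expect_error(update_centroids(d, m), class = "moe_dead_expert")
})

test_that("membership rows solve the simplex QP (oracle spot-checks)", {
  set.seed(7)
  d <- make_moe_data(matrix(rnorm(60), 20, 3), matrix(rnorm(15), 5, 3))
  cfg <- moe_config(K = 3, C = 1.3, t = 0.7, class_weight = 2)
  experts <- lapply(1:3, function(k)
    list(w = rnorm(3), b = rnorm(1), d = rnorm(3)))
  m <- update_memberships(d, experts, cfg)
  expect_equal(rowSums(m), rep(1, 20), tolerance = 1e-9)
  Xad <- d$X[d$ad, ]
  for (i in c(1, 7, 20)) {
    L <- sapply(experts, function(e) (1 - (sum(e$w * Xad[i, ]) + e$b))^2)
    D <- sapply(experts, function(e) max(sum((Xad[i, ] - e$d)^2), 1e-12))
    expect_equal(m[i, ], simplex_qp_oracle(cfg$C * 2 * L, cfg$t * D),
                 tolerance = 1e-6)
  }
  # symmetric losses and distances give the uniform row
  ex2 <- list(list(w = c(1, 0, 0), b = 0, d = c(9, 9, 9)),
              list(w = c(1, 0, 0), b = 0, d = c(9, 9, 9)))
  m2 <- update_memberships(d, ex2, moe_config(K = 2, C = 1, t = 1))
  expect_equal(m2, matrix(0.5, 20, 2), tolerance = 1e-9)
  expect_equal(update_memberships(d, ex2[1], moe_config(K = 1, C = 1, t = 1)),
               matrix(1, 20, 1))
})

test_that("centroids are the alpha-weighted means of the AD rows", {
  X_ad <- rbind(c(1, 0), c(3, 2), c(5, 4))
  d <- make_moe_data(X_ad, matrix(0, 2, 2))
  one_hot <- rbind(c(1, 0), c(1, 0), c(0, 1))
  cen <- update_centroids(d, one_hot, alpha = 2)
  expect_equal(cen[1, ], c(2, 1))
  expect_equal(cen[2, ], c(5, 4))
  uni <- matrix(0.5, 3, 2)
  cen2 <- update_centroids(d, uni, alpha = 2)
  expect_equal(cen2[1, ], colMeans(X_ad))
  expect_equal(cen2[2, ], colMeans(X_ad))
  m <- cbind(c(0.9, 0.1, 0.5))
  cen3 <- update_centroids(d, m, alpha = 2)
  hand <- (0.81 * X_ad[1, ] + 0.01 * X_ad[2, ] + 0.25 * X_ad[3, ]) /
    (0.81 + 0.01 + 0.25)
  expect_equal(cen3[1, ], hand, tolerance = 1e-12)
})

test_that("the K = 1 fit reduces to a single weighted L1 classifier", {
  set.seed(10)
  d <- make_moe_data(matrix(rnorm(40, 1), 20, 2), matrix(rnorm(40, -1), 20, 2))
  cfg <- moe_config(K = 1, C = 1, t = 0.1, n_restarts = 1, seed = 2)
  mod <- fit_moe(d, cfg)
  expect_equal(mod$memberships, matrix(1, 20, 1))
  direct <- update_experts(d, matrix(1, 20, 1), cfg)[[1]]
  direct_obj <- moe_objective(structure(list(
    experts = list(c(direct, list(d = colMeans(d$X[d$ad, ])))),
    memberships = matrix(1, 20, 1), config = cfg), class = "moe_model"), d)
  expect_lt(abs(mod$objective_trace[length(mod$objective_trace)] - direct_obj),
            1e-6)
})

test_that("the objective trace is non-increasing across sweeps", {
  for (seed in 1:3) {
    blobs <- make_blob_data(n_per = 15, sep = 2, noise = 0.5, seed = seed)
    cfg <- moe_config(K = 2, C = 1, t = 0.2, n_restarts = 1, seed = seed)
    mod <- fit_moe(blobs$data, cfg)
    expect_true(all(diff(mod$objective_trace) <= 1e-8))
  }
})

test_that("planted subtypes are recovered on separable synthetic data", {
  blobs <- make_blob_data(n_per = 20, sep = 3, noise = 0.3, seed = 21)
  cfg <- moe_config(K = 2, C = 1, t = 0.2, n_restarts = 2, seed = 5)
  mod <- fit_moe(blobs$data, cfg)
  expect_gte(ari(apply(mod$memberships, 1, which.max), blobs$blob), 0.9)
  # held-out-free sanity: training accuracy is perfect on separable data
  pred <- predict_label(mod, blobs$data$X)
  expect_equal(mean(pred$label == blobs$data$y), 1)
})

test_that("prediction routes through the nearest centroid", {
  mod <- structure(list(experts = list(
    list(w = c(1, 0), b = -10, d = c(5, 5)),
    list(w = c(1, 0), b = 0, d = c(0, 0)))), class = "moe_model")
  p <- predict_label(mod, rbind(c(0.2, 0.1)))
  expect_equal(p$expert, 2L)
  expect_equal(p$label, 1)  # decision value 0.2 >= 0
  p2 <- predict_label(mod, rbind(c(5, 5)))
  expect_equal(p2$expert, 1L)
  expect_equal(p2$label, -1)
  # exactly-zero decision value maps to +1
  mod0 <- structure(list(experts = list(list(w = c(1, 0), b = 0, d = c(0, 0)))),
                    class = "moe_model")
  expect_equal(predict_label(mod0, rbind(c(0, 3)))$label, 1)
})

test_that("memberships approach plain FCM as the trade-off grows", {
  set.seed(12)
  d <- make_moe_data(matrix(rnorm(30), 10, 3), matrix(rnorm(9), 3, 3))
  experts <- list(list(w = rnorm(3), b = 0, d = c(2, 0, 0)),
                  list(w = rnorm(3), b = 0, d = c(-2, 0, 0)))
  cfg <- moe_config(K = 2, C = 1, t = 1e8)
  m <- update_memberships(d, experts, cfg)
  Xad <- d$X[d$ad, ]
  for (i in 1:10) {
    D <- sapply(experts, function(e) sum((Xad[i, ] - e$d)^2))
    fcm <- (1 / D) / sum(1 / D)  # standard FCM memberships, exponent 2
    expect_equal(m[i, ], fcm, tolerance = 1e-5)
  }
})

test_that("cross-validation is stratified, seeded, and exact on separable data", {
  blobs <- make_blob_data(n_per = 15, sep = 3, noise = 0.3, seed = 31)
  cfg <- moe_config(K = 2, C = 1, t = 0.2, cv_folds = 3, n_restarts = 1,
                    seed = 8)
  cv1 <- cross_validate(blobs$data, cfg)
  cv2 <- cross_validate(blobs$data, cfg)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$acc_mean, cv2$acc_mean)
  expect_equal(cv1$acc_mean, 1)
  expect_error(cross_validate(blobs$data, moe_config(K = 2, cv_folds = 50)),
               "folds")
})

test_that("validity indices take their hand-computed values", {
  expect_equal(bezdek_pc(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(bezdek_pc(matrix(1 / 3, 5, 3)), 1 / 3, tolerance = 1e-12)
  expect_equal(bezdek_pc(rbind(c(0.5, 0.5), c(0.8, 0.2))), 0.59)
  ex <- function(w) list(w = w, b = 0, d = NULL)
  expect_equal(pairwise_wr(list(ex(c(1, 0)), ex(c(0, 1)))), 0)
  expect_equal(pairwise_wr(list(ex(c(1, 0)), ex(c(2, 0)))), 1)
  expect_equal(pairwise_wr(list(ex(c(1, 0)), ex(c(cos(pi / 3), sin(pi / 3))))),
               0.5, tolerance = 1e-12)
  expect_true(is.na(pairwise_wr(list(ex(c(1, 0))))))
  expect_error(pairwise_wr(list(ex(c(0, 0)), ex(c(1, 0)))), "degenerate")
})

test_that("grid search applies the documented lexicographic selection rule", {
  blobs <- make_blob_data(n_per = 12, sep = 3, noise = 0.4, seed = 41)
  cfg <- moe_config(K = 2, cv_folds = 2, n_restarts = 1, seed = 3)
  sel <- grid_search_select(blobs$data, cfg, C_grid = c(0.5, 1),
                            t_grid = c(0.1, 0.5), rho_grid = 1)
  rep <- sel$report
  expect_equal(nrow(rep), 4)
  expect_equal(sum(rep$selected), 1)
  win <- rep[rep$selected, ]
  expect_equal(win$acc_mean, max(rep$acc_mean))
  top <- rep[rep$acc_mean == max(rep$acc_mean), ]
  expect_equal(win$wr, min(top$wr))
  top2 <- top[top$wr == min(top$wr), ]
  expect_equal(win$C, min(top2$C))
  # determinism of the whole report
  sel2 <- grid_search_select(blobs$data, cfg, C_grid = c(0.5, 1),
                             t_grid = c(0.1, 0.5), rho_grid = 1)
  expect_equal(sel$report, sel2$report)
  one <- grid_search_select(blobs$data, cfg, C_grid = 1, t_grid = 0.2,
                            rho_grid = 2)
  expect_true(one$report$selected)
  expect_equal(one$config$class_weight, 2)
})

test_that("BPC of any fitted model respects its theoretical bounds", {
  for (seed in 1:3) {
    blobs <- make_blob_data(n_per = 12, sep = 1, noise = 0.8, seed = seed)
    K <- 2 + seed %% 2
    mod <- fit_moe(blobs$data, moe_config(K = K, C = 1, t = 0.2,
                                          n_restarts = 1, seed = seed))
    b <- bezdek_pc(mod$memberships)
    expect_gte(b, 1 / K - 1e-9)
    expect_lte(b, 1 + 1e-9)
  }
})
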