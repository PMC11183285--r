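fake_model <- function(experts) structure(list(experts = experts),
                                          class = "moe_model")

test_that("hyperplane distances follow the normalized geometric formula", {
  mod <- fake_model(list(list(w = c(3, 4), b = 0, d = c(0, 0))))
  expect_equal(unname(hyperplane_distances(mod, rbind(c(1, 1)))[1, 1]), 1.4)
  # a point on the hyperplane has distance zero
  expect_equal(unname(hyperplane_distances(mod, rbind(c(4, -3)))[1, 1]), 0)
  # joint rescaling of (w, b) leaves the distance unchanged
  mod2 <- fake_model(list(list(w = c(3, 4) * -2.7, b = 0.5 * -2.7, d = c(0, 0)),
                          list(w = c(3, 4), b = 0.5, d = c(0, 0))))
  D <- hyperplane_distances(mod2, rbind(c(1, 1), c(-2, 0.3)))
  expect_equal(D[, 1], D[, 2], tolerance = 1e-12)
  # signed mode keeps the side of the boundary
  s <- hyperplane_distances(fake_model(list(list(w = c(1, 0), b = 0))),
                            rbind(c(-2, 0)), signed = TRUE)
  expect_equal(unname(s[1, 1]), -2)
  expect_error(hyperplane_distances(
    fake_model(list(list(w = c(0, 0), b = 0))), rbind(c(1, 1))), "zero weight")
})

test_that("assignment picks the smallest distance with index tie-breaks", {
  mod <- fake_model(list(list(w = c(1, 0), b = 0.5, d = NULL),
                         list(w = c(1, 0), b = 0.2, d = NULL),
                         list(w = c(1, 0), b = 0.9, d = NULL)))
  x <- rbind(origin = c(0, 0))
  asg <- assign_min_distance(mod, x)
  expect_equal(asg$expert_index, 2L)
  expect_equal(asg$d_min, 0.2)
  expect_equal(asg[, c("d_1", "d_2", "d_3")],
               data.frame(d_1 = 0.5, d_2 = 0.2, d_3 = 0.9))
  tie <- fake_model(list(list(w = c(1, 0), b = 0.5),
                         list(w = c(0, 1), b = 0.5)))
  expect_equal(assign_min_distance(tie, x)$expert_index, 1L)
})

test_that("assignment is permutation-equivariant in subject order", {
  set.seed(3)
  mod <- fake_model(lapply(1:3, function(k) list(w = rnorm(4), b = rnorm(1))))
  X <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("P%02d", 1:10), NULL))
  a1 <- assign_min_distance(mod, X)
  perm <- sample(10)
  a2 <- assign_min_distance(mod, X[perm, ])
  expect_equal(a2$expert_index[order(perm)], a1$expert_index)
})

test_that("experts are named by atrophy severity, invariant to index order", {
  # one-hot memberships; mean residuals per expert: -0.05, -0.30, -0.15
  X_ad <- rbind(matrix(-0.05, 3, 4), matrix(-0.30, 3, 4), matrix(-0.15, 3, 4))
  d <- make_moe_data(X_ad, matrix(0, 2, 4))
  m <- matrix(0, 9, 3); m[1:3, 1] <- 1; m[4:6, 2] <- 1; m[7:9, 3] <- 1
  mod <- structure(list(experts = replicate(3, list(w = rnorm(4), b = 0),
                                            simplify = FALSE),
                        memberships = m), class = "moe_model")
  expect_equal(unname(rank_and_name_subtypes(mod, d)), c("MIN", "DIF", "MID"))
  # permuting expert indices permutes names with them
  mod2 <- mod; mod2$memberships <- m[, c(2, 3, 1)]
  expect_equal(unname(rank_and_name_subtypes(mod2, d)), c("DIF", "MID", "MIN"))
  # equal severities rank by expert index; K = 2 gets S labels
  X_eq <- matrix(-0.1, 4, 4)
  d2 <- make_moe_data(X_eq, matrix(0, 2, 4))
  m2 <- matrix(0, 4, 2); m2[1:2, 1] <- 1; m2[3:4, 2] <- 1
  mod3 <- structure(list(experts = replicate(2, list(w = rnorm(4), b = 0),
                                             simplify = FALSE),
                        memberships = m2), class = "moe_model")
  expect_equal(unname(rank_and_name_subtypes(mod3, d2)), c("S1", "S2"))
  m_empty <- m2; m_empty[, 2] <- 0; m_empty[, 1] <- 1
  mod4 <- mod3; mod4$memberships <- m_empty
  expect_error(rank_and_name_subtypes(mod4, d2), "no argmax")
})

test_that("converters with unchanged features keep their baseline subtype", {
  set.seed(14)
  spec <- cohort_spec(n_cn = 40, n_ad = 30, n_mci = 30, n_rois = 12,
                      templates = orthogonal_templates(12, 3, 0.4), seed = 14)
  coh <- generate_cohort(spec)
  fit <- fit_cn_glm(coh$thickness, coh$subjects)
  res <- residualize(coh$thickness, coh$subjects, fit)
  d <- moe_data(res, coh$subjects)
  mod <- fit_moe(d, moe_config(K = 3, C = 1, t = 0.1, n_restarts = 2, seed = 1))
  labels <- rank_and_name_subtypes(mod, d)
  mci_ids <- coh$subjects$subject_id[coh$subjects$diagnosis == "MCI"]
  bl <- assign_min_distance(mod, res[mci_ids, ], labels = labels)
  out <- attribute_converters(mod, fit, coh$thickness[mci_ids[1:5], ],
                              coh$subjects, bl, labels)
  expect_equal(out$assignments$ad_subtype,
               bl$subtype_label[match(out$assignments$subject_id,
                                      bl$subject_id)])
  expect_equal(sum(out$transition$count), 5)
  # missing conversion-visit scans are reported, never dropped
  out2 <- attribute_converters(mod, fit, coh$thickness[mci_ids[1:2], ],
                               coh$subjects, bl, labels,
                               converter_ids = mci_ids[1:3])
  expect_true("unattributable" %in% out2$assignments$ad_subtype)
  expect_equal(nrow(out2$assignments), 3)
  # an empty converter set yields an empty transition table
  out3 <- attribute_converters(mod, fit, coh$thickness[0, , drop = FALSE],
                               coh$subjects, bl, labels,
                               converter_ids = character(0))
  expect_equal(nrow(out3$assignments), 0)
  expect_equal(sum(out3$transition$count), 0)
})

test_that("synthetic converters are attributed to their planted subtype", {
  spec <- cohort_spec(n_cn = 120, n_ad = 120, n_mci = 60, n_rois = 30,
                      templates = orthogonal_templates(30, 3, 0.4,
                                                       mci_scale = 0.5),
                      noise_sd = 0.1, seed = 23)
  coh <- generate_cohort(spec)
  fit <- fit_cn_glm(coh$thickness, coh$subjects)
  res <- residualize(coh$thickness, coh$subjects, fit)
  d <- moe_data(res, coh$subjects)
  mod <- fit_moe(d, moe_config(K = 3, C = 1, t = 0.1, n_restarts = 2, seed = 2))
  labels <- rank_and_name_subtypes(mod, d)
  # map planted template -> expert label via the AD truth
  truth_ad <- coh$subjects$latent_subtype[coh$subjects$diagnosis == "AD"]
  hard <- apply(mod$memberships, 1, which.max)
  lab_of <- sapply(split(unname(labels[hard]), truth_ad),
                   function(x) names(which.max(table(x))))
  # converters: MCI subjects at full AD-level atrophy of their template
  mci <- coh$subjects[coh$subjects$diagnosis == "MCI", ]
  W <- sapply(spec$templates, function(t) t$roi_weights)
  colnames(W) <- sapply(spec$templates, function(t) t$label)
  set.seed(99)
  # conversion-visit atrophy: halfway between MCI (0.5) and AD (1.0) level,
  # matching the generator's mid-trajectory convention
  conv_th <- coh$thickness[mci$subject_id, ] -
    t(W[, mci$latent_subtype]) * 0.25
  bl <- assign_min_distance(mod, res[mci$subject_id, ], labels = labels)
  out <- attribute_converters(mod, fit, conv_th, coh$subjects, bl, labels)
  hit <- out$assignments$ad_subtype ==
    lab_of[mci$latent_subtype[match(out$assignments$subject_id,
                                    mci$subject_id)]]
  expect_gte(mean(hit), 0.8)
})
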