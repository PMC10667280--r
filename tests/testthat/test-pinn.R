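test_that("the analytic loss gradient matches finite differences", {
  set.seed(42)
  geom <- centred_tumour_1d(length_cm = 10, nx = 12, diameter_cm = 4)
  p <- baseline_parameters()
  pl <- plasma_model(a = 7, half_life_h = 24)
  pair <- snapshot_pair(rep(0, 12), runif(12, 0, 2), 0, 7.2e5, geom)
  scheme <- irk_gauss(4)
  h <- 1e-6
  for (mode in list(c("voxel", "logistic"), c("network", "none"))) {
    cfg <- pinn_config(hidden_layers = 2, nodes_per_layer = 7, seed = 3,
                       pressure = mode[1], squash = mode[2])
    prob <- ifpinn:::build_training_problem(pair, p, pl, scheme)
    set.seed(cfg$seed)
    net <- ifpinn:::mlp_init(1, rep(7, 2), if (mode[1] == "voxel") 4 else 5)
    n_net <- length(ifpinn:::mlp_pack(net))
    v <- c(ifpinn:::mlp_pack(net), if (mode[1] == "voxel") rnorm(12, 0.4, 0.2))
    v <- v + rnorm(length(v), 0, 0.1)
    res <- ifpinn:::pinn_loss_grad(v, prob, net, n_net, scheme, cfg)
    idx <- sort(sample(seq_along(v), 25))
    num <- vapply(idx, function(i) {
      vp <- v; vp[i] <- vp[i] + h; vm <- v; vm[i] <- vm[i] - h
      (ifpinn:::pinn_loss_grad(vp, prob, net, n_net, scheme, cfg, want_grad = FALSE)$loss -
       ifpinn:::pinn_loss_grad(vm, prob, net, n_net, scheme, cfg, want_grad = FALSE)$loss) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - res$grad[idx])) / max(abs(num)), 1e-6)
  }
})

test_that("the projected envelope gradient matches finite differences", {
  set.seed(8)
  geom <- centred_tumour_1d(length_cm = 10, nx = 10, diameter_cm = 4)
  p <- baseline_parameters()
  pl <- plasma_model(a = 7, half_life_h = 24)
  pair <- snapshot_pair(rep(0, 10), runif(10, 0, 1), 0, 7.2e5, geom)
  scheme <- irk_gauss(3)
  cfg <- pinn_config(seed = 1)
  prob <- ifpinn:::build_training_problem(pair, p, pl, scheme)
  theta <- rnorm(10, 0, 0.5)
  g <- ifpinn:::projected_loss_grad(theta, prob, scheme, cfg)$grad
  h <- 1e-6
  num <- vapply(seq_len(10), function(i) {
    tp <- theta; tp[i] <- tp[i] + h; tm <- theta; tm[i] <- tm[i] - h
    (ifpinn:::projected_loss_grad(tp, prob, scheme, cfg, want_grad = FALSE)$loss -
     ifpinn:::projected_loss_grad(tm, prob, scheme, cfg, want_grad = FALSE)$loss) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - g)) / max(abs(num)), 1e-5)
})

test_that("rk_reconstruct is exact for a quiescent system and linear in scale", {
  geom <- centred_tumour_1d(nx = 12, diameter_cm = 4)
  p <- unclass(mouse_parameters()); p$kd_N <- p$kd_T <- 0
  p <- do.call(tissue_parameters, p)
  scheme <- irk_gauss(5)
  pair <- snapshot_pair(rep(2, 12), rep(2, 12), 0, 3600, geom)
  k <- matrix(2, 12, 5)
  # uniform P = P_v, no plasma, no elimination: g is identically zero
  rec <- rk_reconstruct(k, rep(p$P_v, 12), pair, p,
                        plasma_model(a = 0, b = 0), scheme)
  expect_equal(rec$u1_hat, k, tolerance = 1e-14)
  expect_equal(rec$u2_hat, k, tolerance = 1e-14)

  # homogeneity: doubling stages and plasma doubles the reconstructions
  set.seed(2)
  p2 <- baseline_parameters()
  P <- runif(12, 0, 25)
  k <- matrix(runif(60), 12, 5)
  pl <- plasma_model(a = 7, half_life_h = 24)
  pl2 <- plasma_model(a = 14, half_life_h = 24)
  r1 <- rk_reconstruct(k, P, pair, p2, pl, scheme)
  r2 <- rk_reconstruct(2 * k, P, pair, p2, pl2, scheme)
  expect_equal(r2$u1_hat, 2 * r1$u1_hat, tolerance = 1e-12)
  expect_equal(r2$u2_hat, 2 * r1$u2_hat, tolerance = 1e-12)
})

test_that("stages sampled from the forward trajectory reconstruct the snapshots", {
  p <- baseline_parameters()
  geom <- centred_tumour_1d(nx = 40, diameter_cm = 2)
  pl <- plasma_model(a = 7, half_life_h = 24)
  P <- solve_pressure(geom, p)
  scheme <- irk_gauss(30)
  t2 <- 200 * 3600
  tg <- sort(unique(c(seq(0, t2, length.out = 6001), scheme$c * t2)))
  C <- solve_transport(P, p, pl, geom, tg)
  k <- vapply(scheme$c * t2,
              function(t) C$values[, which.min(abs(tg - t))],
              numeric(40))
  u2 <- C$values[, ncol(C$values)]
  pair <- snapshot_pair(C$values[, 1], u2, 0, t2, geom)
  rec <- rk_reconstruct(k, P, pair, p, pl, scheme)
  expect_lt(max(abs(rec$u1_hat)) / max(u2), 1e-4)
  expect_lt(max(abs(rec$u2_hat - u2)) / max(u2), 1e-4)
})

test_that("the data loss is a mean of squared residuals over voxels and stages", {
  geom <- centred_tumour_1d(nx = 10, diameter_cm = 4)
  set.seed(5)
  u1 <- runif(10); u2 <- runif(10)
  pair <- snapshot_pair(u1, u2, 0, 100, geom)
  U1 <- matrix(u1, 10, 4); U2 <- matrix(u2, 10, 4)
  expect_equal(pinn_loss(U1, U2, pair), 0)
  expect_equal(pinn_loss(U1, U2 + 0.3, pair), 0.09, tolerance = 1e-12)
  # permutation invariance over voxels
  o <- sample(10)
  pair_o <- snapshot_pair(u1[o], u2[o], 0, 100, geom)
  expect_equal(pinn_loss(U1[o, ] + 0.1, U2[o, ], pair_o),
               pinn_loss(U1 + 0.1, U2, pair))
})

test_that("training reduces the loss, is seed-deterministic, and bounded", {
  case <- baseline_case(noise_level = 0, seed = 3, nx = 50)
  fit <- ifp_pinn(case$pair, case$params, case$plasma, q = 8,
                  config = quick_config(seed = 7))
  expect_lt(fit$final_loss, fit$loss_trace$loss[1])
  expect_true(all(coef(fit) >= 0 & coef(fit) <= case$params$P_v))
  fit2 <- ifp_pinn(case$pair, case$params, case$plasma, q = 8,
                   config = quick_config(seed = 7))
  expect_identical(coef(fit), coef(fit2))
  fit3 <- ifp_pinn(case$pair, case$params, case$plasma, q = 8,
                   config = quick_config(seed = 8))
  expect_false(identical(coef(fit), coef(fit3)))
})

test_that("accumulation curve and mean IFP summaries are consistent", {
  fit <- cached_baseline_fit()
  case <- baseline_case()
  mask <- case$geom$mask
  ac <- accumulation_curve(fit)
  expect_equal(nrow(ac), fit$scheme$q + 2)
  expect_equal(ac$concentration[1], 0)              # u1 is a zero image
  expect_equal(ac$concentration[nrow(ac)], mean(case$pair$u2[mask]))
  expect_true(all(diff(ac$time) > 0))
  # mean_ifp identities
  expect_equal(mean_ifp(rep(12.5, 100), mask), 12.5)
  expect_equal(mean_ifp(case$pressure, mask),
               mean(case$pressure$values[mask]), tolerance = 1e-14)
  expect_error(mean_ifp(case$pressure, rep(FALSE, 100)), "empty")
})

test_that("fit methods expose pressure, residuals and forward projection", {
  fit <- cached_baseline_fit()
  case <- baseline_case()
  expect_length(coef(fit), 100)
  expect_equal(residuals(fit), case$pair$u2 - fitted(fit)$u2)
  s <- summary(fit)
  expect_s3_class(s, "summary.ifp_pinn")
  expect_lte(s$mean_ifp, case$params$P_v)
  proj <- predict(fit, times = seq(0, 7.2e5, length.out = 30))
  expect_s3_class(proj, "concentration_field")
  expect_equal(dim(proj$values), c(100, 30))
  expect_output(print(fit), "interstitial fluid pressure")
})

test_that("the full inverse pipeline recovers a 3D spherical tumour", {
  geom <- centred_tumour_3d(length_cm = 3.5, nx = 7, diameter_cm = 1.6)
  p <- baseline_parameters()
  pl <- plasma_model(a = 7, half_life_h = 24)
  truth <- solve_pressure(geom, p, extension = 2)
  tg <- seq(0, 200 * 3600, length.out = 40)
  conc <- solve_transport(truth, p, pl, geom, tg)
  pair <- make_snapshots(conc, geom, 0, 200 * 3600, noise_level = 0.025,
                         seed = 4)
  fit <- ifp_pinn(pair, p, pl, q = 4, config = quick_config(seed = 2))
  expect_lt(fit$final_loss, fit$loss_trace$loss[1])
  expect_true(all(coef(fit) >= 0 & coef(fit) <= p$P_v))
  expect_lt(relative_mse(fit$pressure, truth, geom$mask), 0.05)
  # pressure contrast between tumour and the far field is recovered
  expect_gt(mean(coef(fit)[geom$mask]), 3 * mean(coef(fit)[!geom$mask]))
})
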