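# Shared fixtures: cohorts and trained fits reused across test files.
# Everything is generated in code with fixed seeds; trained fits are cached
# in this environment so each is fit exactly once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Regime A cohort with Gaussian noise SD 15 h at study scale (n = 20,000,
# 9:1 split) plus the default point regressor: the alpha-calibration testbed.
fx_regA <- function() fixture("regA", function() {
  coh <- generate_cohort(cohort_spec(20000, regime = "A", seed = 11,
                                     noise_sd_hours = 15))
  sp <- split_train_test(coh, 0.9, seed = 12)
  train <- coh[sp$train_idx]
  test <- coh[sp$test_idx]
  reg <- train_regressor(train, net_config(seed = 13, max_epochs = 200))
  list(cohort = coh, split = sp, train = train, test = test, reg = reg,
       pred_test = predict_los(reg, test))
})

# Homoscedastic Gaussian cohort (noise SD 30 h) with the full non-GAN model
# zoo: regressor, error network, distributional networks.
fx_homo <- function() fixture("homo", function() {
  coh <- generate_cohort(cohort_spec(20000, regime = "A", seed = 41,
                                     noise_sd_hours = 30))
  sp <- split_train_test(coh, 0.9, seed = 42)
  train <- coh[sp$train_idx]
  test <- coh[sp$test_idx]
  s <- sd(train$los_hours)
  reg <- train_regressor(train, net_config(seed = 43, max_epochs = 150))
  errnet <- train_error_net(train, reg, net_config(seed = 43, max_epochs = 150))
  # lambda = (achievable residual SD)^2 in standardized units makes the
  # loss3 resting sigma equal that residual SD (see vignette)
  lam <- (reg$rmse_train / s)^2
  dist3_cal <- train_dist_net(train, loss_config("loss3", lambda_penalty = lam),
                              net_config(seed = 43, max_epochs = 400,
                                         early_stop_patience = 20))
  dist3_unit <- train_dist_net(train, loss_config("loss3"),
                               net_config(seed = 43, max_epochs = 200))
  dist2 <- train_dist_net(train, loss_config("loss2_overlap"),
                          net_config(seed = 43, max_epochs = 400,
                                     early_stop_patience = 20))
  list(cohort = coh, train = train, test = test, y_scale = s,
       reg = reg, errnet = errnet, lambda_cal = lam,
       dist3_cal = dist3_cal, dist3_unit = dist3_unit, dist2 = dist2)
})

# Rich heteroscedastic cohort (regime C, 136 features) and the fits used for
# sigma(x) recovery; heavier weight decay for the mostly-noise feature set.
fx_regC <- function() fixture("regC", function() {
  coh <- generate_cohort(cohort_spec(20000, regime = "C", seed = 31))
  sp <- split_train_test(coh, 0.9, seed = 32)
  train <- coh[sp$train_idx]
  test <- coh[sp$test_idx]
  cfg <- net_config(seed = 33, max_epochs = 300, weight_decay = 1e-2,
                    early_stop_patience = 20)
  reg <- train_regressor(train, cfg)
  errnet <- train_error_net(train, reg, cfg)
  dist3 <- train_dist_net(train, loss_config("loss3"), cfg)
  list(cohort = coh, train = train, test = test,
       reg = reg, errnet = errnet, dist3 = dist3)
})

# Reduced-scale conditional WGAN-GP on a regime C cohort.
fx_gan <- function() fixture("gan", function() {
  coh <- generate_cohort(cohort_spec(2000, regime = "C", seed = 51))
  gan <- train_wgan_gp(coh, gan_config(seed = 52, max_epochs = 200))
  list(cohort = coh, gan = gan,
       summary = predict_gan_summary(gan, coh, n = 100, seed = 53))
})

# Tiny cohort for cheap structural tests.
fx_tiny <- function() fixture("tiny", function() {
  generate_cohort(cohort_spec(300, regime = "A", seed = 71))
})
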