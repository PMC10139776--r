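small_sched <- function() {
  list(lambda1 = schedule_config(1, 0.5, 1, 2),
       lambda2 = schedule_config(0.5, 0.5, 0, 0),
       lambda3 = schedule_config(0, 1, 1, 2))
}

test_that("a short run completes with a full, identity-consistent loss log", {
  patches <- generate_dataset(4, synthetic_spec(image_size = 32, n_seeds = 4,
                                                border_width = 1.5),
                              base_seed = 50)
  tc <- train_config(epochs = 2, batch_size = 2, learning_rate = 1e-3,
                     rng_seed = 5, schedules = small_sched())
  fit <- train_network(patches, tiny_net_cfg(), tc,
                       morph_par = morph_params(adaptive_block_size = 7))
  expect_s3_class(fit, "selfseg_fit")
  expect_identical(nrow(fit$log), 2L)
  expect_true(all(c("epoch", "L_PR", "L_Rec_i", "L_Rec_o", "L_Rec", "L_Mor",
                    "total", "lambda1", "lambda2", "lambda3") %in%
                    names(fit$log)))
  expect_true(all(is.finite(as.matrix(fit$log))))
  # componentwise identities hold for every logged epoch
  expect_equal(fit$log$L_Rec,
               fit$log$lambda1 * fit$log$L_Rec_i +
                 (1 - fit$log$lambda1) * fit$log$L_Rec_o)
  expect_equal(fit$log$total,
               fit$log$L_PR + fit$log$lambda2 * fit$log$L_Rec +
                 fit$log$lambda3 * fit$log$L_Mor)
  # component ranges
  expect_true(all(fit$log$L_PR >= -1 & fit$log$L_PR <= 1))
  expect_true(all(fit$log$L_Rec >= 0 & fit$log$L_Mor >= 0))
})

test_that("morphology weight stays zero through the pretraining stage", {
  patches <- generate_dataset(2, synthetic_spec(image_size = 32, n_seeds = 4,
                                                border_width = 1.5),
                              base_seed = 60)
  tc <- train_config(epochs = 3, batch_size = 2, learning_rate = 1e-3,
                     rng_seed = 6)  # default schedules: t1 = 40
  fit <- train_network(patches, tiny_net_cfg(), tc,
                       morph_par = morph_params(adaptive_block_size = 7))
  expect_true(all(fit$log$lambda3 == 0))
  expect_equal(fit$log$total,
               fit$log$L_PR + fit$log$lambda2 * fit$log$L_Rec)
})

test_that("training is reproducible from the configured seed", {
  patches <- generate_dataset(3, synthetic_spec(image_size = 32, n_seeds = 4,
                                                border_width = 1.5),
                              base_seed = 70)
  tc <- train_config(epochs = 2, batch_size = 3, learning_rate = 1e-3,
                     rng_seed = 9, schedules = small_sched())
  mp <- morph_params(adaptive_block_size = 7)
  f1 <- train_network(patches, tiny_net_cfg(), tc, morph_par = mp)
  f2 <- train_network(patches, tiny_net_cfg(), tc, morph_par = mp)
  expect_identical(f1$log, f2$log)
  x <- patches[[1]]$image
  expect_identical(decode(f1$net, encode(f1$net, x)),
                   decode(f2$net, encode(f2$net, x)))
})

test_that("run directories capture losses, config snapshot and checkpoint", {
  dir <- withr::local_tempdir()
  patches <- generate_dataset(2, synthetic_spec(image_size = 32, n_seeds = 4,
                                                border_width = 1.5),
                              base_seed = 80)
  tc <- train_config(epochs = 2, batch_size = 2, learning_rate = 1e-3,
                     rng_seed = 3, schedules = small_sched(),
                     checkpoint_every = 1L)
  fit <- train_network(patches, tiny_net_cfg(), tc,
                       morph_par = morph_params(adaptive_block_size = 7),
                       out_dir = dir)
  expect_true(file.exists(file.path(dir, "losses.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "checkpoint_final.rds")))
  expect_true(file.exists(file.path(dir, "checkpoint_0001.rds")))
  log2 <- utils::read.csv(file.path(dir, "losses.csv"))
  expect_equal(log2$total, fit$log$total)
  net2 <- load_checkpoint(file.path(dir, "checkpoint_final.rds"))
  x <- patches[[1]]$image
  expect_identical(decode(net2, encode(net2, x)),
                   decode(fit$net, encode(fit$net, x)))
})

test_that("stage check validates schedule replay and flags malformed logs", {
  sch <- default_schedules()
  log <- data.frame(epoch = 1:80)
  log$lambda1 <- schedule_factor(log$epoch, sch$lambda1)
  log$lambda2 <- schedule_factor(log$epoch, sch$lambda2)
  log$lambda3 <- schedule_factor(log$epoch, sch$lambda3)
  rep <- pretrain_stage_check(log, sch)
  expect_true(rep$morphology_inactive_pretraining)
  expect_true(rep$lambda_traces_match)
  expect_true(rep$lambda1_transition_monotone)
  expect_identical(rep$pretraining_epochs, 40L)
  # the lambda1 trace over the transition follows the linear law exactly
  trans <- log$epoch > 40 & log$epoch < 70
  expect_equal(log$lambda1[trans], 1 - 0.5 * (log$epoch[trans] - 40) / 30)
  expect_true(all(log$lambda3[log$epoch >= 70] == 1))

  # fixed-weight (step) configuration: constant traces over all epochs
  fixed <- list(lambda1 = schedule_config(1, 1, 0, 0),
                lambda2 = schedule_config(0.5, 0.5, 0, 0),
                lambda3 = schedule_config(1, 1, 0, 0))
  logf <- data.frame(epoch = 1:20)
  logf$lambda1 <- schedule_factor(logf$epoch, fixed$lambda1)
  logf$lambda2 <- schedule_factor(logf$epoch, fixed$lambda2)
  logf$lambda3 <- schedule_factor(logf$epoch, fixed$lambda3)
  expect_identical(unique(logf$lambda1), 1)
  expect_identical(unique(logf$lambda3), 1)
  expect_true(pretrain_stage_check(logf, fixed)$lambda_traces_match)

  expect_error(pretrain_stage_check(data.frame(epoch = 1:3)), "malformed")
})

test_that("degenerate inputs abort with clear diagnostics", {
  expect_error(train_network(list(), tiny_net_cfg(),
                             train_config(epochs = 1)), "empty")
  expect_error(
    train_network(list(matrix(0.5, 25, 25)), tiny_net_cfg(),
                  train_config(epochs = 1)),
    "divisible")
})
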