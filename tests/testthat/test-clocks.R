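# deterministic noiseless fixture: transformed age is an exact linear
# function of 5 CpGs
planted_linear <- function(n = 100, p = 60, seed = 42) {
  set.seed(seed)
  beta <- matrix(runif(n * p, 0.05, 0.95), n, p,
                 dimnames = list(sprintf("s%03d", 1:n),
                                 sprintf("cpg%05d", 1:p)))
  # coefficients scaled so every age stays inside (0, 42): the target is an
  # exactly linear, noiseless function of the 5 support CpGs
  coefs <- c(10, -8, 6, 5, -4)
  age <- drop(beta[, 1:5] %*% coefs) + 20
  sheet <- data.frame(sample_id = rownames(beta), species = "macaque",
                      tissue = "blood", age = age, sex = "F",
                      max_lifespan = 42, maturity_age = 4,
                      stringsAsFactors = FALSE)
  list(beta = beta, sheet = sheet, support = colnames(beta)[1:5])
}

test_that("a noiseless planted linear model is recovered with near-perfect accuracy", {
  px <- planted_linear()
  # noiseless data: use the full-resolution lambda path so the optimal
  # penalty (near zero) is reachable
  clock <- fit_clock(px$beta, px$sheet, age_transform("identity"), seed = 1,
                     nlambda = 100, lambda_min_ratio = 1e-4, thresh = 1e-9)
  expect_true(all(px$support %in% names(clock$weights)))
  # accuracy on fresh draws from the same model
  px2 <- planted_linear(seed = 43)
  pred <- predict_age(clock, px2$beta)
  m <- evaluate_predictions(px2$sheet$age, pred)
  expect_gt(m$R, 0.99)
  expect_lt(m$mae, 0.5)
})

test_that("refitting with the same data and seed reproduces the model exactly", {
  px <- planted_linear()
  c1 <- fit_clock(px$beta, px$sheet, seed = 7)
  c2 <- fit_clock(px$beta, px$sheet, seed = 7)
  expect_identical(c1$weights, c2$weights)
  expect_identical(c1$lambda, c2$lambda)
})

test_that("fit_clock rejects degenerate inputs", {
  px <- planted_linear(n = 30)
  sheet_const <- px$sheet
  sheet_const$age <- 20
  expect_error(fit_clock(px$beta, sheet_const), "constant")
  expect_error(fit_clock(px$beta[1:6, ], px$sheet[1:6, ]), "folds")
})

test_that("prediction is the linear predictor through the inverse transform", {
  px <- planted_linear(n = 20)
  # intercept-only model: every prediction equals the intercept
  m0 <- structure(list(intercept = 7, weights = c(cpg00001 = 0),
                       transform = age_transform("identity"), alpha = 0.5,
                       lambda = 1, scope = list(species = "macaque",
                                                tissues = "blood"),
                       n_train = 20),
                  class = "clock_model")
  expect_equal(unname(predict_age(m0, px$beta)), rep(7, 20))
  # missing clock CpGs are a hard error naming the ids
  m1 <- m0
  m1$weights <- c(cpgXXXXX = 1)
  expect_error(predict_age(m1, px$beta), "cpgXXXXX")
  # relative transform: raw prediction times species lifespan
  m2 <- m0
  m2$transform <- age_transform("relative")
  m2$intercept <- 0.5
  expect_error(predict_age(m2, px$beta), "sheet")
  expect_equal(unname(predict_age(m2, px$beta, px$sheet)), rep(21, 20))
})

test_that("evaluate_predictions reports R, MAE and the signed offset", {
  m <- evaluate_predictions(1:10, 1:10)
  expect_equal(unlist(m[c("R", "mae", "medse")]), c(R = 1, mae = 0, medse = 0))
  m9 <- evaluate_predictions(1:10, 1:10 + 9)
  expect_equal(unlist(m9[c("R", "mae", "medse")]), c(R = 1, mae = 9, medse = 9))
  anti <- evaluate_predictions(1:10, 20 - (1:10))
  expect_equal(anti$R, -1)
  expect_true(is.na(evaluate_predictions(rep(5, 4), 1:4)$R))
  expect_true(is.na(evaluate_predictions(c(1, 2), c(1, 2))$R))
})

test_that("LOOCV never lets the held-out sample influence its own prediction", {
  cfg <- tiny_config(seed = 8, n_cpgs = 200L)
  sim <- generate_dataset(cfg)
  keep <- seq_len(30)
  beta <- sim$beta[keep, ]
  sheet <- sim$sheet[keep, ]
  cv1 <- loocv_clock(beta, sheet, seed = 3)
  # wildly corrupt one sample's age label: its own LOOCV prediction (fitted
  # without it) must be unchanged
  sheet2 <- sheet
  sheet2$age[7] <- 1e3 * sheet$age[7] + 500
  cv2 <- suppressWarnings(loocv_clock(beta, sheet2, seed = 3))
  expect_equal(cv1$predictions$pred[7], cv2$predictions$pred[7])
  # ...while other samples' predictions do see the corrupted label
  expect_false(isTRUE(all.equal(cv1$predictions$pred[-7],
                                cv2$predictions$pred[-7])))
})

test_that("k = n fold CV reproduces leave-one-out predictions", {
  cfg <- tiny_config(seed = 2, n_cpgs = 200L)
  sim <- generate_dataset(cfg)
  keep <- seq_len(24)
  beta <- sim$beta[keep, ]
  sheet <- sim$sheet[keep, ]
  loo <- loocv_clock(beta, sheet, seed = 5)
  kf <- suppressWarnings(kfold_clock(beta, sheet, k = 24, seed = 5))
  d <- merge(loo$predictions, kf$predictions, by = "sample_id")
  expect_equal(d$pred.x, d$pred.y)
})

test_that("species-stratified folds contain every species and report per-species metrics", {
  cfg <- sim_config(species = list(tiny_design("macaque"),
                                   tiny_design("human", max_lifespan = 122.5,
                                               maturity_age = 15)),
                    n_cpgs = 300L, n_causal_per_tissue = 40L,
                    shared_set_size = 10L, shared_min_tissues = 2L, seed = 3)
  sim <- generate_dataset(cfg)
  cv <- kfold_clock(sim$beta, sim$sheet, age_transform("relative"), k = 5,
                    seed = 1)
  folds <- split(sim$sheet$species, cv$predictions$fold)
  expect_true(all(vapply(folds, function(s) length(unique(s)) == 2, TRUE)))
  expect_setequal(cv$by_species$species, c("macaque", "human"))
  # single-species input: per-species metrics coincide with overall
  mac <- sim$sheet$species == "macaque"
  cv1 <- kfold_clock(sim$beta[mac, ], sim$sheet[mac, ], k = 5, seed = 1)
  expect_equal(nrow(cv1$by_species), 1)
  expect_equal(cv1$by_species$R, cv1$R)
})

test_that("LOHO holds out one species' samples one at a time", {
  cfg <- sim_config(species = list(tiny_design("macaque", 30L, 0L),
                                   tiny_design("human", 15L, 0L,
                                               max_lifespan = 122.5,
                                               maturity_age = 15)),
                    n_cpgs = 200L, n_causal_per_tissue = 30L,
                    shared_set_size = 10L, shared_min_tissues = 1L, seed = 4)
  sim <- generate_dataset(cfg)
  expect_error(loho_clock(sim$beta, sim$sheet, holdout_species = "vervet"),
               "not present")
  cv <- loho_clock(sim$beta, sim$sheet, age_transform("relative"),
                   holdout_species = "human", seed = 2)
  expect_equal(cv$n, 15)
  expect_true(all(cv$predictions$sample_id %in%
                    sim$sheet$sample_id[sim$sheet$species == "human"]))
  # with the companion species removed, LOHO reduces to LOOCV
  hum <- sim$sheet$species == "human"
  cv_loho <- loho_clock(sim$beta[hum, ], sim$sheet[hum, ],
                        holdout_species = "human", seed = 2)
  cv_loo <- loocv_clock(sim$beta[hum, ], sim$sheet[hum, ], seed = 2)
  expect_equal(cv_loho$predictions$pred, cv_loo$predictions$pred,
               tolerance = 1e-8)
})

test_that("stronger penalties keep weakly fewer CpGs", {
  px <- planted_linear()
  y <- px$sheet$age
  fit <- glmnet::glmnet(px$beta, y, alpha = 0.5)
  # support size along the path, ordered by increasing lambda
  nz <- fit$df[order(fit$lambda)]
  expect_true(all(diff(nz) <= 0))
  expect_lt(nz[length(nz)], nz[1])
})
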