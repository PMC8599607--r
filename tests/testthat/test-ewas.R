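test_that("the correlation screen matches the closed form at r = 0.5, n = 27", {
  # t = 0.5 * sqrt(25) / sqrt(0.75) = 2.8867513; p and Z follow from the
  # t-distribution with 25 df and the inverse normal
  r <- 0.5; n <- 27
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(tstat, 2.8867513459, tolerance = 1e-9)
  p <- 2 * stats::pt(-tstat, n - 2)
  expect_equal(p, 0.00791273835801, tolerance = 1e-9)
  expect_equal(stats::qnorm(1 - p / 2), 2.6557707598, tolerance = 1e-8)
})

test_that("the screen agrees with an independent cor.test oracle to 1e-10", {
  set.seed(10)
  n <- 27
  beta <- matrix(runif(n * 100), n, 100,
                 dimnames = list(NULL, sprintf("cpg%05d", 1:100)))
  ages <- runif(n, 1, 40)
  scr <- screen_age_association(beta, ages)
  for (j in seq_len(100)) {
    ct <- stats::cor.test(ages, beta[, j])
    expect_equal(scr$r[j], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(scr$p[j], ct$p.value, tolerance = 1e-10)
    expect_equal(abs(scr$z[j]),
                 stats::qnorm(ct$p.value / 2, lower.tail = FALSE),
                 tolerance = 1e-8)
    expect_equal(sign(scr$z[j]), sign(scr$r[j]))
  }
})

test_that("perfect correlation underflows to the Z cap; constant CpGs are NA", {
  ages <- seq(1, 40, length.out = 50)
  beta <- cbind(up = (ages - 1) / 39, down = 1 - (ages - 1) / 39,
                flat = rep(0.5, 50))
  scr <- screen_age_association(beta, ages)
  expect_equal(scr$z[1], 40)
  expect_equal(scr$z[2], -40)
  expect_true(is.na(scr$r[3]) && is.na(scr$z[3]))
  expect_error(screen_age_association(beta[1:3, ], ages[1:3]), "4 samples")
  expect_error(screen_age_association(beta, rep(7, 50)), "constant")
})

test_that("Stouffer combination matches hand-computed cases", {
  # four tissues, equal n, all Z = 2: Z_meta = 2*4/sqrt(4) = 4
  expect_equal(stouffer_meta(rep(2, 4), rep(10, 4))$z_meta, 4)
  # equal Z across k strata gives Z * sqrt(k)
  expect_equal(stouffer_meta(rep(1.7, 9), rep(5, 9))$z_meta, 1.7 * 3)
  # single stratum: identity
  expect_equal(stouffer_meta(2.3, 12)$z_meta, 2.3)
  # equal-n cancellation
  expect_equal(stouffer_meta(c(3, -3), c(8, 8))$z_meta, 0)
  # sqrt-n weighting: hand formula
  z <- c(2, -1); n <- c(100, 25)
  expect_equal(stouffer_meta(z, n)$z_meta,
               (10 * 2 + 5 * -1) / sqrt(125))
  # missing strata are dropped; all-missing yields NA
  expect_equal(stouffer_meta(c(2, NA), c(10, 10))$z_meta, 2)
  expect_true(is.na(stouffer_meta(c(NA, NA), c(5, 5))$z_meta))
  # invariance to stratum order and weight rescaling (equal weights)
  expect_equal(stouffer_meta(c(1, 2, 3), c(4, 9, 16))$z_meta,
               stouffer_meta(c(3, 1, 2), c(16, 4, 9))$z_meta)
})

test_that("run_ewas combines tissues and joins annotation", {
  cfg <- tiny_config(seed = 6)
  sim <- generate_dataset(cfg)
  ann <- generate_annotation(cfg, sim$truth)
  ew <- run_ewas(sim$beta, sim$sheet, ann)
  expect_setequal(attr(ew, "tissues"), c("blood", "skin"))
  expect_true(all(c("blood_z", "skin_p", "meta_z", "meta_p", "meta_q",
                    "gene", "region") %in% names(ew)))
  # meta Z agrees with the scalar combiner on a few CpGs
  nvec <- attr(ew, "tissue_n")
  for (i in c(1, 50, 200)) {
    expect_equal(ew$meta_z[i],
                 stouffer_meta(c(ew$blood_z[i], ew$skin_z[i]),
                               nvec[c("blood", "skin")])$z_meta)
  }
  # a tissue below min_n is skipped with a warning
  small <- sim$sheet
  small$tissue[small$tissue == "skin"][1:18] <- "blood"
  expect_warning(run_ewas(sim$beta, small, min_n = 10), "skipped")
})

test_that("select_top applies the p threshold, direction split, |Z| order and cap", {
  toy <- data.frame(
    cpg = c("c1", "c2", "c3", "c4", "c5", "c6"),
    p = c(1e-5, 1e-5, 1e-3, 1e-6, 0.2, 1e-7),
    stringsAsFactors = FALSE
  )
  toy$z <- c(1, -1, 1, 1, -1, -1) * stats::qnorm(1 - toy$p / 2)
  top <- select_top(toy, p_threshold = 1e-4, cap = 2)
  expect_equal(top$hyper$cpg, c("c4", "c1")) # p = 1e-6 then the + 1e-5
  expect_equal(top$hypo$cpg, c("c6", "c2"))  # p = 1e-7 then the - 1e-5
  # no CpG passes the threshold
  none <- select_top(data.frame(cpg = "c1", z = 1, p = 0.5))
  expect_equal(nrow(none$hyper), 0)
  expect_equal(nrow(none$hypo), 0)
  # infinite cap returns every passing CpG
  all_top <- select_top(toy, p_threshold = 1e-4, cap = Inf)
  expect_equal(nrow(all_top$hyper) + nrow(all_top$hypo), 4)
  # deterministic lexicographic tie-break at equal |Z|
  tie <- data.frame(cpg = c("b", "a"), z = c(5, 5), p = c(1e-7, 1e-7))
  expect_equal(select_top(tie, cap = 1)$hyper$cpg, "a")
})

test_that("upset_overlap partitions the union exactly", {
  up <- upset_overlap(list(A = c("1", "2"), B = c("2", "3")))
  expect_setequal(up$pattern, c("A", "B", "A&B"))
  expect_equal(sum(up$count), 3)
  expect_equal(up$count[up$pattern == "A&B"], 1)
  expect_equal(up$members[up$pattern == "A&B"][[1]], "2")
  # disjoint sets: no multi-set pattern
  up2 <- upset_overlap(list(A = c("1"), B = c("2")))
  expect_true(all(up2$degree == 1))
  expect_error(upset_overlap(list(A = "1")), "2")
})

test_that("region_distribution compares foreground with background composition", {
  cfg <- tiny_config(seed = 7)
  ann <- generate_annotation(cfg)
  # foreground = background: every represented class at ratio 1
  rd <- region_distribution(ann$cpg_id, ann)
  present <- rd$bg_n > 0
  expect_true(all(rd$ratio[present] == 1))
  # empty foreground: all fractions zero
  rd0 <- region_distribution(character(0), ann)
  expect_true(all(rd0$fg_frac == 0))
  # unannotated foreground CpGs are tallied with a warning
  expect_warning(rdu <- region_distribution("missing_cpg", ann), "missing")
  expect_equal(rdu$fg_n[rdu$region == "unannotated"], 1)
})

test_that("under a null generator the screen p-values are uniform", {
  ks_p <- vapply(1:3, function(s) {
    cfg <- sim_config(species = list(tiny_design(n_blood = 60L, n_skin = 0L)),
                      n_cpgs = 800L, effect_scale = 0, seed = 100 + s)
    sim <- generate_dataset(cfg)
    scr <- screen_age_association(sim$beta, sim$sheet$age)
    stats::ks.test(scr$p, "punif")$p.value
  }, 0)
  expect_gte(sum(ks_p > 0.01), 2)
})
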