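test_that("comparative Ct reproduces hand arithmetic and fixes control at 1", {
  tab <- data.frame(
    sample_id = rep(c("c1", "t1"), each = 2),
    group = rep(c("control", "treated"), each = 2),
    gene = rep(c("GAPDH", "TARGET"), 2),
    replicate = 1L,
    ct = c(15, 22, 15, 20))
  fe <- relative_expression(tab, control_group = "control")
  expect_equal(fe$fold[fe$group == "control"], 1)
  expect_equal(fe$ddct[fe$group == "treated"], -2)
  expect_equal(fe$fold[fe$group == "treated"], 4)
  # adding a constant to every Ct changes nothing
  tab2 <- tab; tab2$ct <- tab2$ct + 3.7
  expect_equal(relative_expression(tab2, control_group = "control")$fold,
               fe$fold)
  # row order invariance
  expect_equal(relative_expression(tab[sample(nrow(tab)), ],
                                   control_group = "control")$fold,
               fe$fold)
})

test_that("samples without housekeeping are dropped with a warning", {
  tab <- data.frame(
    sample_id = c("c1", "c1", "t1"),
    group = c("control", "control", "treated"),
    gene = c("GAPDH", "TARGET", "TARGET"),
    replicate = 1L, ct = c(15, 22, 20))
  expect_warning(fe <- relative_expression(tab, control_group = "control"),
                 "t1")
  expect_false("treated" %in% fe$group)
})

test_that("noiseless generator folds are returned exactly", {
  folds <- matrix(c(1, 4, 1, 0.5), 2, 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("ctrl", "trt")))
  g <- gen_ct_table(genes = c("A", "B"), groups = c("ctrl", "trt"),
                    true_folds = folds, ct_sd = 0, seed = 1)
  fe <- relative_expression(g$table, control_group = "ctrl")
  for (gene in c("A", "B")) for (grp in c("ctrl", "trt")) {
    expect_equal(fe$fold[fe$gene == gene & fe$group == grp],
                 unname(folds[gene, grp]), tolerance = 1e-12)
  }
})

test_that("4PL fit recovers exact parameters from noiseless data", {
  p <- gen_elisa_plate(od_sd = 0, seed = 1)
  cv <- fit_4pl(p$plate$concentration, p$plate$od)
  truth <- c(a = 0.05, d = 2.4, c = 150, b = 1.2)
  expect_equal(unname(cv$params[names(truth)]), unname(truth),
               tolerance = 1e-6)
  # inflection identity and inverse-forward round trip
  expect_equal(inverse_4pl(cv, predict_4pl(cv, 150)), 150, tolerance = 1e-8)
  xs <- c(10, 60, 200, 800)
  expect_equal(inverse_4pl(cv, predict_4pl(cv, xs)), xs, tolerance = 1e-8)
  expect_error(inverse_4pl(cv, 3.0), "outside")
  expect_error(fit_4pl(c(1, 2, 3, 4), c(1, 2, 3, 4)), "5 distinct")
})

test_that("noisy-plate EC50 recovery stays within 5% median error", {
  errs <- vapply(1:50, function(s) {
    pl <- gen_elisa_plate(od_sd = 0.02, seed = s)
    f <- fit_4pl(pl$plate$concentration, pl$plate$od)
    abs(f$params[["c"]] - 150) / 150
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("noisy Ct fold recovery stays within the simulation bound", {
  lerr <- vapply(1:200, function(s) {
    g <- gen_ct_table(genes = "A", groups = c("ctrl", "trt"),
                      true_folds = matrix(c(1, 3), 1, 2,
                                          dimnames = list("A", c("ctrl", "trt"))),
                      ct_sd = 0.3, n_replicates = 3, seed = s)
    fe <- relative_expression(g$table, control_group = "ctrl")
    abs(log2(fe$fold[fe$group == "trt"]) - log2(3))
  }, numeric(1))
  expect_lt(stats::median(lerr), 0.35)
})
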