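test_that("domain construction validates inputs and fixes interfaces", {
  expect_error(build_domain(n_cells = 5), "n_cells")
  d1 <- build_domain(n_cells = 100)
  d2 <- build_domain(n_cells = 200)
  expect_equal(d1$L, d2$L)
  expect_equal(d1$interfaces, d2$interfaces)
  expect_error(build_domain(monolayer = list(position = 5e-3)), "outside")
})

test_that("pure-diffusion steady state is linear with midpoint 1/2", {
  dom <- build_domain(n_cells = 100, monolayer = NULL)
  p <- steady_profile(dom, 0)
  expect_equal(p$c, 1 - dom$x / dom$L, tolerance = 1e-10)
  expect_equal(p$c[which.min(abs(dom$x - dom$L / 2))], 0.5, tolerance = 1e-2)
})

test_that("numeric steady state matches closed forms for all schemes at low cell Peclet", {
  dom <- build_domain(n_cells = 400, monolayer = NULL)
  for (Pe in c(1, 3, 15)) {
    v <- Pe * 6.5e-11 / dom$L
    exact <- oracle_advdiff(dom$x, dom$L, Pe)
    for (sch in c("exponential", "central", "upwind")) {
      err <- max(abs(steady_profile(dom, v, scheme = sch)$c - exact))
      lim <- if (sch == "upwind") 1e-2 else 1e-4
      expect_lt(err, lim)
    }
  }
})

test_that("upwind error decays at least first order under grid refinement", {
  Pe <- 3
  err_at <- function(n) {
    dom <- build_domain(n_cells = n, monolayer = NULL)
    v <- Pe * 6.5e-11 / dom$L
    max(abs(steady_profile(dom, v, scheme = "upwind")$c -
              oracle_advdiff(dom$x, dom$L, Pe)))
  }
  e50 <- err_at(50); e100 <- err_at(100)
  expect_gt(e50 / e100, 1.8)
})

test_that("transient runs conserve mass with closed boundaries and obey the maximum principle", {
  dom <- build_domain(n_cells = 60, monolayer = NULL,
                      boundary = list(left = list(type = "closed"),
                                      right = list(type = "closed")))
  set.seed(3)
  init <- runif(60)
  f <- simulate_transport(dom, 0, t_end = 6 * 3600, dt = 120,
                          output_times = seq(0, 6 * 3600, 3600),
                          initial = init)
  mass0 <- sum(init)
  expect_lt(max(abs(rowSums(f$conc) - mass0)) / mass0, 1e-10)
  expect_true(all(f$conc >= -1e-12 & f$conc <= max(init) + 1e-12))
  # Dirichlet source-free run stays within [0, source]
  domd <- build_domain(n_cells = 60, monolayer = NULL)
  fd <- simulate_transport(domd, 1e-7, t_end = 12 * 3600, dt = 300,
                           initial = 0)
  expect_true(all(fd$conc >= -1e-12 & fd$conc <= 1 + 1e-12))
})

test_that("explicit stepping refuses unstable steps and matches implicit when stable", {
  dom <- build_domain(n_cells = 50, monolayer = NULL)
  expect_error(simulate_transport(dom, 0, t_end = 3600, dt = 600,
                                  method = "explicit"), "implicit")
  dt_ok <- 0.3 * dom$dx^2 / max(dom$D)
  fe <- simulate_transport(dom, 0, t_end = 2000, dt = dt_ok,
                           output_times = c(0, 2000), method = "explicit")
  fi <- simulate_transport(dom, 0, t_end = 2000, dt = dt_ok,
                           output_times = c(0, 2000), method = "implicit")
  expect_equal(fe$conc[2, ], fi$conc[2, ], tolerance = 5e-3)
})

test_that("two-layer analytic profile: drop fraction and limits", {
  ana <- steady_two_layer_analytic(6.5e-11, 2e-3, 1e-8)
  expect_equal(ana$drop_fraction_monolayer, 0.7647, tolerance = 1e-3)
  # numeric steady state with the membrane at the far face agrees
  dom <- build_domain(n_cells = 400, monolayer = list(permeability = 1e-8))
  p <- steady_profile(dom, 0)
  expect_equal(p$c, 1 - ana$flux * dom$x / 6.5e-11, tolerance = 1e-8)
  # infinitely permeable monolayer: no interface drop
  ana_inf <- steady_two_layer_analytic(6.5e-11, 2e-3, 1e3)
  expect_lt(ana_inf$drop_fraction_monolayer, 1e-6)
  # thicker gel takes a larger share of the drop
  expect_lt(steady_two_layer_analytic(6.5e-11, 4e-3, 1e-8)$drop_fraction_monolayer,
            ana$drop_fraction_monolayer)
})

test_that("secreted solute spreads upstream: half at rest, less as Pe grows", {
  dom <- build_domain(n_cells = 201, monolayer = NULL)
  s0 <- secretion_under_flow(dom, 0)
  expect_equal(s0$upstream_fraction, 0.5, tolerance = 1e-6)
  ups <- vapply(c(0, 1, 3, 15), function(Pe)
    secretion_under_flow(dom, Pe * 6.5e-11 / dom$L)$upstream_fraction,
    numeric(1))
  expect_true(all(diff(ups) < 0))
  # source-rate invariance
  s1 <- secretion_under_flow(dom, 1e-7, source_rate = 1)
  s2 <- secretion_under_flow(dom, 1e-7, source_rate = 137)
  expect_equal(s1$upstream_fraction, s2$upstream_fraction, tolerance = 1e-6)
})

test_that("per-solute transport is independent of other solutes in the config", {
  cfg <- default_config()
  doms <- lapply(cfg$solutes, function(s)
    build_domain(layers = cfg$layers[1], solute = s, n_cells = 80))
  runs_fwd <- lapply(doms, simulate_transport, velocity = 1e-7,
                     t_end = 6 * 3600)
  runs_rev <- lapply(rev(doms), simulate_transport, velocity = 1e-7,
                     t_end = 6 * 3600)
  expect_identical(runs_fwd[[1]]$conc, runs_rev[[2]]$conc)
  expect_identical(runs_fwd[[2]]$conc, runs_rev[[1]]$conc)
  expect_false(isTRUE(all.equal(runs_fwd[[1]]$conc, runs_fwd[[2]]$conc)))
})

test_that("line profiles round-trip rendered images", {
  # noiseless linear profile
  img <- matrix(rep(seq(0, 1, length.out = 50), each = 8), nrow = 8)
  pr <- extract_line_profile(img, pixel_size = 2)
  expect_equal(pr$intensity, seq(0, 1, length.out = 50))
  expect_equal(pr$position, (1:50 - 0.5) * 2)
  expect_gt(stats::cor(pr$position, pr$intensity)^2, 1 - 1e-12)
  # 1-px ROI equals the raw row
  pr1 <- extract_line_profile(img, roi = list(x = c(1, 50), y = c(3, 3)))
  expect_equal(pr1$intensity, img[3, ])
  expect_error(extract_line_profile(img, roi = list(x = c(10, 60), y = c(1, 8))),
               "ROI")
  # noisy image of the Pe = 15 steady profile: mid-gel value within 3 sd
  dom <- build_domain(n_cells = 100, monolayer = NULL)
  v <- 15 * 6.5e-11 / dom$L
  f <- simulate_transport(dom, v, t_end = 48 * 3600,
                          output_times = c(0, 48 * 3600))
  gi <- gen_intensity_series(f, sampling_interval = 48 * 3600,
                             noise_sd = 0.02, n_rows = 32, seed = 1)
  pr2 <- extract_line_profile(gi$images[[2]])
  mid <- which.min(abs(dom$x - dom$L / 2))
  expect_lt(abs(pr2$intensity[mid] - 0.9994), 3 * 0.02)
})
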