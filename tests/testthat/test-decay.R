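# canonical two-step chain: full-length transcript cleaved by RNase Y, the
# downstream fragment degraded 5'-3' by RNase J1
chain_pathway <- function(kY = 0.3, kJ = 0.7) {
  decay_pathway(
    species = data.frame(id = c("FL", "D"), start = c(0, 400),
                         end = c(1300, 1300)),
    reactions = data.frame(type = c("endocleave", "exo5to3"),
                           enzyme = c("Y", "J1"), parent = c("FL", "D"),
                           products = c("D", ""), rate = c(kY, kJ)))
}

test_that("a single species decays as a closed-form exponential", {
  pw <- decay_pathway(data.frame(id = "A", start = 0, end = 100),
                      data.frame(type = "exo3to5", enzyme = "",
                                 parent = "A", products = "", rate = log(2) / 5))
  tc <- simulate_decay_timecourse(pw, timepoints = c(0, 5, 10), x0 = c(A = 1))
  expect_equal(unname(tc$abundance["A", ]), c(1, 0.5, 0.25), tolerance = 1e-9)
})

test_that("the two-compartment chase matches the analytic solution to 1e-6", {
  kY <- 0.3; kJ <- 0.7
  t <- c(0, 1, 2.5, 5, 7.5, 10, 15)
  tc <- simulate_decay_timecourse(chain_pathway(kY, kJ), timepoints = t,
                                  x0 = c(FL = 1, D = 0))
  analytic <- kY / (kJ - kY) * (exp(-kY * t) - exp(-kJ * t))
  rel_err <- abs(tc$abundance["D", -1] - analytic[-1]) / analytic[-1]
  expect_lt(max(rel_err), 1e-6)
  expect_equal(unname(tc$abundance["FL", ]), exp(-kY * t), tolerance = 1e-9)
})

test_that("J1 depletion makes the downstream fragment accumulate", {
  t <- seq(0, 15, by = 1.25)
  wt <- simulate_decay_timecourse(chain_pathway(), timepoints = t,
                                  x0 = c(FL = 1, D = 0))
  dep <- simulate_decay_timecourse(chain_pathway(), depletion_scenario(30),
                                   timepoints = t, depleted = "J1",
                                   x0 = c(FL = 1, D = 0))
  expect_gt(max(dep$abundance["D", ]), max(wt$abundance["D", ]))

  # Y depletion: full-length stabilized, downstream fragment produced less
  depY <- simulate_decay_timecourse(chain_pathway(), depletion_scenario(30),
                                    timepoints = t, depleted = "Y",
                                    x0 = c(FL = 1, D = 0))
  expect_true(all(depY$abundance["FL", -1] > wt$abundance["FL", -1]))
  expect_lt(max(depY$abundance["D", ]), max(wt$abundance["D", ]))
})

test_that("with all rates zero every species is frozen in every condition", {
  pw <- decay_pathway(data.frame(id = c("FL", "D"), start = c(0, 400),
                                 end = c(1300, 1300)),
                      data.frame(type = c("endocleave", "exo5to3"),
                                 enzyme = c("Y", "J1"), parent = c("FL", "D"),
                                 products = c("D", ""), rate = c(0, 0)))
  for (depl in list(NULL, "Y", "J1")) {
    tc <- simulate_decay_timecourse(pw, timepoints = c(0, 5, 10),
                                    depleted = depl, x0 = c(FL = 1, D = 1))
    expect_equal(tc$abundance, matrix(1, 2, 3, dimnames = list(c("FL", "D"), NULL)))
  }
})

test_that("nucleotide mass is non-increasing once synthesis stops", {
  set.seed(23)
  t <- seq(0, 20, by = 2)
  for (i in 1:10) {
    cut <- sample(200:1100, 1)
    rates <- runif(4, 0, 1)
    pw <- decay_pathway(
      species = data.frame(id = c("FL", "U", "D"),
                           start = c(0, 0, cut), end = c(1300, cut, 1300)),
      reactions = data.frame(
        type = c("endocleave", "exo3to5", "exo5to3", "exo3to5"),
        enzyme = c("Y", "", "J1", ""),
        parent = c("FL", "U", "D", "FL"),
        products = c("U;D", "", "", ""),
        rate = rates))
    tc <- simulate_decay_timecourse(pw, timepoints = t,
                                    x0 = c(FL = 1, U = 0.2, D = 0.2))
    lens <- with(pw$species, end - start)
    mass <- colSums(tc$abundance * lens)
    expect_true(all(diff(mass) <= 1e-9))
  }
})

test_that("half-life fitting is exact on noiseless exponentials", {
  expect_equal(fit_half_life(c(1, 0.5, 0.25), times = c(0, 5, 10))$half_life, 5.0)
  set.seed(2)
  for (k in c(0.05, 0.3, 1.5)) {
    t <- sort(c(0, runif(4, 0.5, 12)))
    f <- fit_half_life(2.7 * exp(-k * t), times = t)
    expect_equal(f$half_life, log(2) / k, tolerance = 1e-9)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
  # constant series: stable sentinel, not a negative half-life
  f0 <- fit_half_life(c(1, 1, 1), times = c(0, 5, 10))
  expect_true(f0$stable)
  expect_equal(f0$half_life, Inf)
  # censoring and input validation
  expect_warning(fit_half_life(c(1, 0.5, 0.25, 0), times = c(0, 5, 10, 15)),
                 "censoring")
  expect_error(fit_half_life(c(1, 0.5), times = c(0, 5)), ">= 3")
})

test_that("sigW-like half-lives are recovered within 10% under noise", {
  set.seed(41)
  t <- c(0, 1, 2, 4, 6, 8)
  recovered <- sapply(c(1.3, 4.3), function(hl) {
    k <- log(2) / hl
    mean(replicate(50, {
      y <- exp(-k * t) * exp(rnorm(length(t), 0, 0.1))
      fit_half_life(y, times = t)$half_life
    }))
  })
  expect_lt(abs(recovered[1] - 1.3) / 1.3, 0.1)
  expect_lt(abs(recovered[2] - 4.3) / 4.3, 0.1)
})

test_that("band patterns show fragment stabilization under the right depletion", {
  bp <- predict_band_pattern(chain_pathway(), depletion_scenario(30),
                             probe_position = 800)
  get <- function(cond, sp, col) bp[bp$condition == cond & bp$species == sp, col]
  expect_true(get("J1", "D", "visible"))
  expect_gte(get("J1", "D", "half_life") / get("wt", "D", "half_life"), 2)
  expect_gt(get("Y", "FL", "half_life"), get("wt", "FL", "half_life"))
  # probe inside the downstream fragment sees both FL and D (FL spans it)
  expect_setequal(unique(bp$species), c("FL", "D"))
  expect_warning(predict_band_pattern(chain_pathway(), probe_position = 5000),
                 "outside every species")
})

test_that("depletion never shortens any species' fitted half-life", {
  set.seed(57)
  t <- seq(0, 30, by = 2.5)
  for (i in 1:8) {
    kY <- runif(1, 0.1, 0.8); kJ <- runif(1, 0.1, 0.8)
    pw <- chain_pathway(kY, kJ)
    for (enz in c("Y", "J1")) {
      for (sp in c("FL", "D")) {
        hl <- function(depl) {
          tc <- simulate_decay_timecourse(pw, depletion_scenario(30),
                                          timepoints = t, depleted = depl,
                                          x0 = c(FL = 1, D = 0.1))
          tr <- tc$abundance[sp, ]
          peak <- which.max(tr)
          peak <- min(peak, length(t) - 2)
          fit_half_life(tr[peak:length(t)], times = t[peak:length(t)])$half_life
        }
        expect_gte(hl(enz), hl(NULL) - 1e-8)
      }
    }
  }
})

test_that("abundance changes split into transcriptional vs post-transcriptional", {
  expect_equal(classify_effect(4, 1.1), "transcriptional")
  expect_equal(classify_effect(4, 4), "post_transcriptional")
  expect_equal(classify_effect(4, 2), "mixed")
  # at steady state abundance tracks synthesis x half-life: a matched
  # fold-change in half-life explains the accumulation entirely
  expect_equal(classify_effect(2.9, 2), "post_transcriptional")
  expect_error(classify_effect(-1, 2), "positive")
})

test_that("pathway validation rejects cycles, negative rates, unknown species", {
  sp <- data.frame(id = c("A", "B"), start = c(0, 0), end = c(100, 50))
  expect_error(decay_pathway(sp, data.frame(type = "endocleave", enzyme = "Y",
                                            parent = "A", products = "C",
                                            rate = 0.1)), "unknown species")
  expect_error(decay_pathway(sp, data.frame(type = "exo3to5", enzyme = "",
                                            parent = "A", products = "",
                                            rate = -1)), ">= 0")
  expect_error(decay_pathway(sp, data.frame(type = c("endocleave", "endocleave"),
                                            enzyme = "Y", parent = c("A", "B"),
                                            products = c("B", "A"),
                                            rate = 0.1)), "cycle")
})
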