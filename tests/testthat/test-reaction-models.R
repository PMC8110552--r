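test_that("survival process table has the eight prescribed channels", {
  p <- survival_params(b_X = 1, b_M = 7, s = 1, d_X = 0, d_MX = 0,
                       d_M = 9, h = 15)
  tbl <- build_survival_processes(p)
  expect_s3_class(tbl, "process_table")
  expect_equal(nrow(tbl), 8L)
  expect_equal(sum(tbl$rate), 28)
  expect_equal(tbl$prob[tbl$channel == "birth_M"], 7 / 28)
  expect_equal(sum(tbl$prob), 1, tolerance = 1e-12)
  # melanophore death is exclusively interaction-driven: every M -> S
  # channel requires a partner, and the long-range ones (partner M or S at
  # rate d_M, partner X at rate d_MX) all act at range h
  m_death <- tbl[tbl$focal == 2 & tbl$product == 0, ]
  expect_true(all(!is.na(m_death$partner_state)))
  long <- m_death[!is.na(m_death$partner_range) & m_death$partner_range > 1, ]
  expect_equal(sort(long$rate), c(0, 9, 9))
  expect_equal(unique(long$partner_range), 15L)
  expect_setequal(long$partner_state, c(0L, 1L, 2L))
  # perfect survival protection at d_MX = 0
  expect_equal(tbl$prob[tbl$channel == "death_M_remote_X"], 0)
})

test_that("zero-weight channels are retained with stable ordering", {
  p1 <- survival_params(b_X = 1, b_M = 0, d_X = 0, d_M = 0, s = 0, h = 3)
  p2 <- survival_params(b_X = 2, b_M = 1, d_X = 3, d_M = 4, s = 5, h = 3)
  t1 <- build_survival_processes(p1)
  t2 <- build_survival_processes(p2)
  expect_equal(t1$channel, t2$channel)
  expect_equal(nrow(t1), 8L)
  expect_equal(t1$prob, c(1, rep(0, 7)))
})

test_that("promotion process table has the seven prescribed channels", {
  p <- promotion_params(b_X = 1, s = 1, l_X = 2.5, b_M = 0, d_X = 0,
                        d_M = 0, h = 16)
  tbl <- build_promotion_processes(p)
  expect_equal(nrow(tbl), 7L)
  expect_equal(sum(tbl$rate), 5.5)
  expect_equal(tbl$prob[tbl$channel == "promo_M_by_remote_X"], 2.5 / 5.5)
  # simple melanophore death exists here (unlike the survival set)
  expect_true(any(tbl$focal == 2 & tbl$product == 0 &
                    is.na(tbl$partner_state)))
  # uniform probabilities when all rates are equal
  pe <- promotion_params(b_X = 2, b_M = 2, d_X = 2, d_M = 2, s = 2,
                         l_X = 2, h = 4)
  expect_equal(build_promotion_processes(pe)$prob, rep(1 / 7, 7))
})

test_that("promotion table without birth or promotion cannot create M", {
  p <- promotion_params(b_X = 1, s = 1, l_X = 0, b_M = 0, d_M = 1, h = 5)
  tbl <- build_promotion_processes(p)
  makers <- tbl[tbl$product == 2L, ]
  expect_true(all(makers$prob == 0))
})

test_that("channel probabilities only depend on rate ratios", {
  set.seed(42)
  for (i in 1:5) {
    r <- round(stats::runif(7, 0.1, 5), 3)
    p1 <- survival_params(b_X = r[1], b_M = r[2], d_X = r[3], d_M = r[4],
                          d_MX = r[5] / 10, s_X = r[6], s_M = r[7], h = 4)
    c_scale <- 3.7
    p2 <- survival_params(b_X = r[1] * c_scale, b_M = r[2] * c_scale,
                          d_X = r[3] * c_scale, d_M = r[4] * c_scale,
                          d_MX = r[5] / 10 * c_scale, s_X = r[6] * c_scale,
                          s_M = r[7] * c_scale, h = 4)
    expect_equal(build_survival_processes(p1)$prob,
                 build_survival_processes(p2)$prob, tolerance = 1e-12)
  }
})

test_that("parameter validation enforces the model constraints", {
  expect_error(survival_params(b_X = -1), "non-negative")
  expect_error(survival_params(h = 0), "positive integer")
  expect_error(survival_params(h = 2.5), "positive integer")
  expect_error(promotion_params(l_X = Inf), "finite")
  expect_warning(survival_params(d_M = 1, d_MX = 2), "d_MX")
  # the s alias sets both short-range rates
  p <- survival_params(s = 0.3)
  expect_equal(p$s_X, 0.3)
  expect_equal(p$s_M, 0.3)
  # an all-zero table cannot be normalized
  expect_error(build_survival_processes(
    survival_params(b_X = 0, b_M = 0, d_X = 0, d_M = 0, s = 0, h = 1)),
    "zero")
})

test_that("parameters round-trip through the flat config file", {
  p <- survival_params(b_X = 1, b_M = 7, d_M = 9, d_MX = 0.25, s_X = 0.5,
                       s_M = 1.5, h = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_params(p, path)
  expect_equal(read_params(path), p)
  # key=value dialect with explicit model
  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# promotion run", "b_X=1", "s=1", "l_X=2.5", "h=16"), cfg)
  q <- read_params(cfg, model = "promotion")
  expect_s3_class(q, "promotion_params")
  expect_equal(q$l_X, 2.5)
  expect_equal(q$s_X, 1)
  writeLines(c("b_X=1", "bogus=2"), cfg)
  expect_error(read_params(cfg, model = "survival"), "unknown config key")
})
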