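surv_table <- function(...) build_survival_processes(survival_params(...))

test_that("a step on an empty lattice with only births fires a birth", {
  tbl <- surv_table(b_X = 1, b_M = 0, d_X = 0, d_M = 0, s = 0, h = 3)
  set.seed(1)
  res <- mc_step(init_lattice(10, 10), tbl)
  expect_true(res$changed)
  expect_equal(sum(res$lattice == 1L), 1L)
  expect_equal(sum(res$lattice != 0L), 1L)
})

test_that("an all-X lattice with d_X = 0 is frozen under survival dynamics", {
  # every channel either needs an S or M focal, needs an M partner, or has
  # zero weight: no iteration can ever change the lattice
  tbl <- surv_table(b_X = 1, b_M = 7, d_X = 0, d_M = 9, s = 1, h = 5)
  l <- init_lattice(20, 20, "all_X")
  set.seed(2)
  res <- stripesim:::mc_chunk(l, tbl, 1e5)
  expect_equal(res$changed, 0)
  expect_identical(unclass(res$grid)[, ], unclass(l)[, ])
})

test_that("remote xanthophores fully protect a melanophore when d_MX = 0", {
  tbl <- surv_table(b_X = 0, b_M = 0, d_X = 0, d_M = 9, d_MX = 0, s = 0,
                    h = 4)
  l <- init_lattice(15, 15, "all_X")
  l[8, 8] <- 2L
  set.seed(3)
  res <- stripesim:::mc_chunk(l, tbl, 1e5)
  expect_identical(unclass(res$grid)[, ], unclass(l)[, ])
})

test_that("each iteration changes at most one cell", {
  tbl <- surv_table(b_X = 1, b_M = 2, d_X = 0.5, d_M = 3, s = 1, h = 3)
  l <- init_lattice(15, 15, "random", seed = 4)
  set.seed(4)
  for (i in 1:300) {
    res <- mc_step(l, tbl)
    expect_lte(sum(res$lattice != l), 1L)
    l <- res$lattice
  }
})

test_that("runs are bit-reproducible from the seed", {
  tbl <- surv_table(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 5)
  r1 <- run_static(init_lattice(40, 40), tbl, 5e5, snapshot_every = 2e5,
                   seed = 9)
  r2 <- run_static(init_lattice(40, 40), tbl, 5e5, snapshot_every = 2e5,
                   seed = 9)
  expect_identical(unclass(r1$final), unclass(r2$final))
  expect_identical(r1$snapshots$lattice, r2$snapshots$lattice)
  expect_equal(r1$snapshots$iteration, c(0, 2e5, 4e5, 5e5))

  sched <- growth_schedule(target_cols = 12, iterations_per_growth = 1e4,
                           post_growth_iterations = 1e4)
  tblp <- build_promotion_processes(
    promotion_params(b_X = 1, s = 1, l_X = 2.5, h = 4))
  g1 <- run_growing(init_lattice(30, 1), tblp, sched, seed = 5)
  g2 <- run_growing(init_lattice(30, 1), tblp, sched, seed = 5)
  expect_identical(unclass(g1$final), unclass(g2$final))
})

test_that("no melanophore can appear without a creating channel", {
  tbl <- surv_table(b_X = 1, b_M = 0, d_X = 0.2, d_M = 5, s = 1, h = 3)
  rec <- run_static(init_lattice(30, 30), tbl, 2e6, snapshot_every = 2e6,
                    seed = 6)
  expect_equal(sum(rec$final == 2L), 0L)
  tblp <- build_promotion_processes(
    promotion_params(b_X = 1, s = 1, l_X = 0, b_M = 0, d_M = 1, h = 5))
  recp <- run_static(init_lattice(30, 30), tblp, 2e6, snapshot_every = 2e6,
                     seed = 6)
  expect_equal(sum(recp$final == 2L), 0L)
})

test_that("without melanophores and X death the lattice fills with X", {
  # M is never born; X only dies next to an M; so all-X is absorbing and
  # reachable from the empty lattice
  tbl <- surv_table(b_X = 1, b_M = 0, d_X = 0, d_M = 9, s = 1, h = 3)
  rec <- run_static(init_lattice(50, 50), tbl, 3e6, snapshot_every = 3e6,
                    seed = 7)
  expect_true(all(rec$final == 1L))
})

test_that("growth bookkeeping: one empty column per event until target", {
  tblp <- build_promotion_processes(
    promotion_params(b_X = 1, s = 1, l_X = 2.5, h = 3))
  sched <- growth_schedule(target_cols = 6, iterations_per_growth = 1000,
                           post_growth_iterations = 0)
  rec <- run_growing(init_lattice(20, 1), tblp, sched, seed = 8)
  expect_equal(ncol(rec$final), 6L)
  expect_equal(max(rec$snapshots$iteration), 5 * 1000)
  expect_true(all(c("initial", "growth") %in% rec$snapshots$phase))
  # trapezoidal growth adds rows too
  sched2 <- growth_schedule(target_cols = 6, iterations_per_growth = 500,
                            post_growth_iterations = 0, target_rows = 24)
  rec2 <- run_growing(init_lattice(20, 1), tblp, sched2, seed = 8)
  expect_equal(dim(rec2$final), c(24L, 6L))
})

test_that("a degenerate schedule reproduces the static run exactly", {
  tbl <- surv_table(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 4)
  sched <- growth_schedule(target_cols = 25, iterations_per_growth = 10,
                           post_growth_iterations = 3e5)
  g <- run_growing(init_lattice(25, 25), tbl, sched, seed = 11)
  s <- run_static(init_lattice(25, 25), tbl, 3e5, snapshot_every = 3e5,
                  seed = 11)
  expect_identical(unclass(g$final), unclass(s$final))
})

test_that("ablation during growth empties the center at the trigger", {
  tblp <- build_promotion_processes(
    promotion_params(b_X = 1, s = 1, l_X = 2.5, h = 3))
  sched <- growth_schedule(target_cols = 10, iterations_per_growth = 2000,
                           post_growth_iterations = 0)
  rec <- run_growing(init_lattice(16, 1), tblp, sched,
                     ablation = ablation_spec(0.5, 0.75, 0.75), seed = 12)
  ab <- rec$snapshots[rec$snapshots$phase == "ablation", ]
  expect_equal(nrow(ab), 1L)
  lat <- ab$lattice[[1]]
  br <- floor(0.75 * nrow(lat)); bc <- floor(0.75 * ncol(lat))
  r0 <- floor((nrow(lat) - br) / 2); c0 <- floor((ncol(lat) - bc) / 2)
  expect_true(all(lat[(r0 + 1):(r0 + br), (c0 + 1):(c0 + bc)] == 0L))
})

test_that("record summaries expose occupancies per snapshot", {
  tbl <- surv_table(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 4)
  rec <- run_static(init_lattice(20, 20), tbl, 4e5, snapshot_every = 2e5,
                    seed = 13)
  td <- tidy(rec)
  expect_equal(nrow(td), 3L)
  expect_equal(td$frac_S + td$frac_X + td$frac_M, rep(1, 3))
  expect_equal(td$frac_S[1], 1)
  g <- glance(rec)
  expect_equal(g$iterations, 4e5)
  expect_equal(g$model, "survival")
})
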