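test_that("per-branch rates divide counts by duration and classify changes", {
  tr <- tree4()
  m <- presence_matrix(rbind(
    f1 = c(A = 1, B = 1, C = 0, D = 0),   # gain on (A,B) stem
    f2 = c(A = 1, B = 1, C = 0, D = 0),
    f3 = c(A = 1, B = 1, C = 0, D = 1),   # gain on root stem, loss on C
    f4 = c(A = 0, B = 0, C = 0, D = 1)))  # singleton D
  dm <- dollo_map(m, tr, n_reps = 3, seed = 1)
  br <- branch_rates(dm)
  ab <- ape::getMRCA(tr$phy, match(c("A", "B"), tr$phy$tip.label))
  row_ab <- br[br$branch == ab, ]
  expect_equal(row_ab$gains, 2L)
  expect_equal(row_ab$gain_rate, 2 / row_ab$duration)
  expect_equal(row_ab$class, "gains_only")
  row_c <- br[br$branch == match("C", tr$phy$tip.label), ]
  expect_equal(row_c$losses, 1L)
  expect_equal(row_c$class, "loss_majority")
  # rate x duration recovers the count everywhere
  ok <- br$duration > 0
  expect_equal(br$gain_rate[ok] * br$duration[ok], as.numeric(br$gains[ok]),
               tolerance = 1e-9)
  # conservation: branch gains sum to family count, losses to loss total
  expect_equal(sum(br$gains), nrow(m))
  expect_equal(sum(br$losses), sum(dm$loss_counts))
})

test_that("the >=75% gains class excludes pure-gain and loss-majority branches", {
  counts <- data.frame(gains = c(3, 3, 1, 0), losses = c(0, 1, 3, 0))
  cls <- with(counts, ifelse(gains + losses == 0, "unchanged",
              ifelse(losses == 0, "gains_only",
              ifelse(losses > gains, "loss_majority",
              ifelse(gains / (gains + losses) >= 0.75, "ge75_gains", "mixed")))))
  expect_equal(cls, c("gains_only", "ge75_gains", "loss_majority", "unchanged"))
})

test_that("zero-duration branches keep counts but report NA rates", {
  phy <- ape::read.tree(text = "((A:0,B:100):100,(C:100,D:100):100):50;")
  tr <- timetree(phy)
  m <- presence_matrix(rbind(f = c(A = 1, B = 0, C = 0, D = 0)))
  br <- branch_rates(dollo_map(m, tr, n_reps = 2, seed = 1))
  row_a <- br[br$branch == match("A", tr$phy$tip.label), ]
  expect_equal(row_a$gains, 1L)
  expect_true(is.na(row_a$gain_rate))
})

test_that("binned series follow the half-open older-edge convention", {
  # single event at 305 Ma: bin [310, 300) gets it, all others zero
  tr <- tree4()
  m <- presence_matrix(rbind(f = c(A = 1, B = 1, C = 1, D = 1)))
  dm <- dollo_map(m, tr, n_reps = 1, seed = 1)
  dm$events$time <- 305
  rs <- rate_series(dm, bin_width = 10, horizon = 720)
  g <- as.data.frame(rs)[as.data.frame(rs)$type == "gain", ]
  expect_equal(g$mean[g$bin_start == 310], 1)
  expect_equal(sum(g$mean), 1)
  # an event exactly on an edge belongs to the younger bin
  dm$events$time <- 310
  g2 <- as.data.frame(rate_series(dm, 10, 720))
  g2 <- g2[g2$type == "gain", ]
  expect_equal(g2$mean[g2$bin_start == 310], 1)
  expect_equal(g2$mean[g2$bin_start == 320], 0)
})

test_that("per-replicate bin counts are conserved and events beyond the horizon error", {
  tr <- fixture_tree35()
  sim <- sim_gainloss_matrix(tr, 0.02, 2e-3, seed = 31)
  dm <- dollo_map(sim$matrix, tr, n_reps = 10, seed = 2)
  rs <- rate_series(dm)
  counts <- attr(rs, "counts")
  expect_equal(unname(rowSums(counts$gain)), rep(dm$n_families, 10))
  expect_equal(unname(rowSums(counts$loss)), rep(sum(dm$loss_counts), 10))
  expect_error(rate_series(dm, horizon = 300), "horizon")
})

test_that("a gain on a branch spanning two bins splits its mass evenly", {
  phy <- ape::read.tree(text = "(A:600,B:600):20;")  # root at 600, stem to 620
  tr <- timetree(phy)
  m <- presence_matrix(rbind(f = c(A = 1, B = 1)))
  dm <- dollo_map(m, tr, n_reps = 4000, seed = 8)
  g <- as.data.frame(rate_series(dm))
  g <- g[g$type == "gain", ]
  expect_equal(g$mean[g$bin_start == 620], 0.5, tolerance = 0.05)
  expect_equal(g$mean[g$bin_start == 610], 0.5, tolerance = 0.05)
  expect_true(all(g$hi >= g$mean & g$lo <= g$mean))
})

test_that("lineage summaries follow the published table conventions and are path-additive", {
  stats <- dollomap:::gain_loss_stats
  homo <- stats(301, 22)
  expect_equal(round(homo$ratio, 2), 13.68)
  expect_equal(round(homo$pct_loss, 2), 7.31)
  ciona <- stats(40, 14)
  expect_equal(round(ciona$ratio, 2), 2.86)
  expect_equal(round(ciona$pct_loss, 2), 35.00)
  none <- stats(8, 0)
  expect_true(is.na(none$ratio) && is.na(none$pct_loss))

  tr <- tree4()
  m <- presence_matrix(rbind(
    f1 = c(A = 1, B = 1, C = 0, D = 1),
    f2 = c(A = 1, B = 0, C = 0, D = 0),
    f3 = c(A = 1, B = 1, C = 1, D = 1)))
  dm <- dollo_map(m, tr, n_reps = 2, seed = 1)
  ls <- lineage_summary(dm)
  br <- branch_rates(dm)
  # additivity: tip totals = parent-path totals + terminal-branch counts
  for (tip_lab in tr$phy$tip.label) {
    tip <- match(tip_lab, tr$phy$tip.label)
    path <- dollomap:::.root_path(tr, tip)
    ids <- c(tr$root, path[-1])
    expect_equal(ls$gains[ls$tip == tip_lab],
                 sum(br$gains[br$branch %in% ids]))
    parent_ids <- setdiff(ids, tip)
    expect_equal(ls$gains[ls$tip == tip_lab],
                 sum(br$gains[br$branch %in% parent_ids]) +
                   br$gains[br$branch == tip])
  }
  # deep shared events are recorded in all descendant taxa
  expect_true(all(ls$gains >= rowSums(t(m))[ls$tip] * 0))
  expect_equal(ls$gains[ls$tip == "A"], 3)
})

test_that("loss-count distribution conserves families and matches construction", {
  tr <- tree4()
  m <- presence_matrix(rbind(
    s1 = c(A = 1, B = 0, C = 0, D = 0),
    s2 = c(A = 0, B = 1, C = 0, D = 0),
    l1 = c(A = 1, B = 1, C = 0, D = 1),    # 1 loss
    l2 = c(A = 1, B = 0, C = 0, D = 1)))   # 2 losses
  dm <- dollo_map(m, tr, n_reps = 2, seed = 1)
  h <- loss_count_distribution(dm)
  expect_equal(as.integer(h), c(2L, 1L, 1L))
  expect_equal(sum(h), nrow(m))
})

test_that("rate outlier flagging follows the percentile rule", {
  tr <- fixture_tree35()
  sim <- sim_gainloss_matrix(tr, 0.05, 0, seed = 32)
  dm <- dollo_map(sim$matrix, tr, n_reps = 2, seed = 1)
  br <- branch_rates(dm)
  fl <- flag_rate_outliers(br)
  expect_match(attr(fl, "method"), "percentile")
  # inflate one branch tenfold beyond everything else
  br2 <- br
  br2$gain_rate[which.max(br2$gain_rate)] <- 10 * max(br2$gain_rate, na.rm = TRUE)
  fl2 <- flag_rate_outliers(br2)
  expect_true(fl2$high_gain_rate[which.max(br2$gain_rate)])
  # equal rates flag nothing
  br3 <- br
  br3$gain_rate <- 1
  fl3 <- flag_rate_outliers(br3)
  expect_false(any(fl3$high_gain_rate | fl3$low_gain_rate))
  # too few branches disables flagging
  expect_warning(fl4 <- flag_rate_outliers(br[1:3, ]), "fewer than 5")
  expect_false(any(fl4$high_gain_rate))
})

test_that("a programmed burst branch is flagged high", {
  tr <- fixture_tree35()
  deep <- tr$branches$branch[which.max(tr$branches$duration * (tr$branches$branch >
            length(tr$phy$tip.label)))]
  sim <- sim_gainloss_matrix(tr, 0.05, 0, seed = 33,
                             burst = stats::setNames(30, deep))
  dm <- dollo_map(sim$matrix, tr, n_reps = 2, seed = 1)
  fl <- flag_rate_outliers(branch_rates(dm))
  expect_true(fl$high_gain_rate[fl$branch == deep])
})

test_that("binned 95% intervals cover the analytic expectation most of the time", {
  # one gain uniform on a branch spanning two bins: expectation 0.5 per bin
  phy <- ape::read.tree(text = "(A:600,B:600):20;")
  tr <- timetree(phy)
  m <- presence_matrix(rbind(f = c(A = 1, B = 1)))
  hits <- 0
  for (s in 1:20) {
    dm <- dollo_map(m, tr, n_reps = 200, seed = s)
    g <- as.data.frame(rate_series(dm))
    g <- g[g$type == "gain" & g$bin_start == 620, ]
    if (g$lo <= 0.5 && g$hi >= 0.5) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})
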